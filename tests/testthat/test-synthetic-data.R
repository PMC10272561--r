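# The generators define the study conditions; these tests pin their
# statistical structure and reproducibility.

test_that("bulk generator is reproducible and rejects invalid specs", {
  expect_error(module_plant_spec(n_modules = 0), "integer")
  expect_error(module_plant_spec(noise_sd = 0), "noise_sd")
  expect_error(module_plant_spec(within_module_loading = 0), "loading")
  expect_error(module_plant_spec(trait_module = 9), "trait_module")

  spec <- module_plant_spec(n_modules = 2, genes_per_module = 20,
                            n_background_genes = 30, n_cases = 15,
                            n_controls = 15, seed = 3)
  a <- generate_bulk_expression(spec)
  b <- generate_bulk_expression(spec)
  expect_identical(a, b)
  expect_false(anyDuplicated(rownames(a$expr)) > 0)
  expect_false(anyDuplicated(colnames(a$expr)) > 0)
  expect_equal(sum(a$trait), 15)
})

test_that("factor model matches its closed-form within-module correlation", {
  # noiseless limit: loading 1, jitter 0, vanishing noise -> correlation 1
  sim0 <- generate_bulk_expression(module_plant_spec(
    n_modules = 1, genes_per_module = 10, n_background_genes = 1,
    within_module_loading = 1, loading_jitter = 0, noise_sd = 1e-8,
    n_cases = 20, n_controls = 20, seed = 1
  ))
  mod_genes <- names(sim0$truth$module)[sim0$truth$module == "module_1"]
  cc <- cor(t(sim0$expr[mod_genes, ]))
  expect_true(all(abs(cc - 1) < 1e-6))

  # loading 0.8, noise 0.6 -> mean pairwise correlation 0.64 within +-0.05.
  # The closed form assumes a unit-variance factor, so the trait shift (which
  # inflates the trait module's factor variance) is switched off.
  sim <- generate_bulk_expression(module_plant_spec(
    n_modules = 1, genes_per_module = 50, n_background_genes = 10,
    within_module_loading = 0.8, loading_jitter = 0, noise_sd = 0.6,
    trait_effect = 0, n_cases = 100, n_controls = 100, seed = 2
  ))
  mod_genes <- names(sim$truth$module)[sim$truth$module == "module_1"]
  cc <- cor(t(sim$expr[mod_genes, ]))
  mean_off <- mean(cc[upper.tri(cc)])
  expect_lt(abs(mean_off - 0.8^2 / (0.8^2 + 0.6^2)), 0.05)

  # default jitter keeps the closed form within the same band
  simj <- generate_bulk_expression(module_plant_spec(
    n_modules = 1, genes_per_module = 50, n_background_genes = 10,
    trait_effect = 0, seed = 4
  ))
  mg <- names(simj$truth$module)[simj$truth$module == "module_1"]
  ccj <- cor(t(simj$expr[mg, ]))
  expect_lt(abs(mean(ccj[upper.tri(ccj)]) - 0.64), 0.05)
})

test_that("a null trait effect leaves eigengene-trait correlations near zero", {
  sim <- generate_bulk_expression(module_plant_spec(trait_effect = 0, seed = 5))
  for (m in paste0("module_", 1:4)) {
    genes <- names(sim$truth$module)[sim$truth$module == m]
    e <- module_eigengene(sim$expr, genes)
    expect_lt(abs(cor(e, sim$trait)), 0.2)
  }
})

test_that("network generator emits a preferential-attachment edge table", {
  expect_error(network_plant_spec(n_nodes = 3, edges_per_new_node = 3), "exceed")
  expect_error(network_plant_spec(score_high = 1200), "score")

  tree <- generate_ppi_network(network_plant_spec(
    n_nodes = 10, edges_per_new_node = 1, seed = 1
  ))
  expect_equal(nrow(tree), 9)

  spec <- network_plant_spec(n_nodes = 2000, edges_per_new_node = 2,
                             score_low = 400, score_high = 800, seed = 2)
  net <- generate_ppi_network(spec)
  expect_identical(net, generate_ppi_network(spec))
  expect_true(all(net$combined_score >= 400 & net$combined_score <= 800))
  # each edge once: no reversed duplicates
  key <- paste(pmin(net$protein1, net$protein2), pmax(net$protein1, net$protein2))
  expect_false(anyDuplicated(key) > 0)
  deg <- table(c(net$protein1, net$protein2))
  expect_gt(max(deg), 10 * median(deg))
})

test_that("drug generator plants targets near hubs and draws sane potencies", {
  net <- generate_ppi_network(network_plant_spec(n_nodes = 100, seed = 3))
  g <- igraph::graph_from_data_frame(net[, 1:2], directed = FALSE)
  hubs <- names(sort(igraph::degree(g), decreasing = TRUE))[1:5]

  # radius 0: planted drugs target hubs only; exact drug count
  dt0 <- generate_drug_table(
    drug_plant_spec(n_null_drugs = 0, n_planted_drugs = 5,
                    targets_per_drug = c(2, 4), planting_radius = 0, seed = 1),
    net, hubs
  )
  expect_equal(length(unique(dt0$drugs$drug_id)), 5)
  expect_true(all(dt0$drugs$target_symbol %in% hubs))
  expect_true(all(dt0$truth))

  # radius 1: planted targets within one hop of the hub set
  dt1 <- generate_drug_table(
    drug_plant_spec(n_null_drugs = 2, n_planted_drugs = 3,
                    targets_per_drug = c(2, 4), planting_radius = 1, seed = 2),
    net, hubs
  )
  eligible <- unique(names(unlist(igraph::ego(g, 1, hubs))))
  planted_rows <- dt1$drugs$drug_id %in% names(dt1$truth)[dt1$truth]
  expect_true(all(dt1$drugs$target_symbol[planted_rows] %in% eligible))

  expect_error(
    generate_drug_table(drug_plant_spec(seed = 1), net, "NOT_A_NODE"),
    "NOT_A_NODE"
  )

  # potency filter survival ~ Phi(1) at mean 7, sd 1, threshold > 6
  dtp <- generate_drug_table(
    drug_plant_spec(n_null_drugs = 100, n_planted_drugs = 0,
                    targets_per_drug = c(10, 10), seed = 4),
    net, hubs
  )
  frac <- mean(dtp$drugs$pchembl > 6)
  expect_lt(abs(frac - pnorm(1)), 0.05)
})

test_that("count generator produces NB counts with the planted structure", {
  expect_error(cell_population_spec(nb_dispersion = 0), "nb_dispersion")
  expect_error(cell_population_spec(cell_types = c(A = 5)), "2")

  mod <- synthetic_gene_symbols(20)
  spec <- cell_population_spec(cell_types = c(A = 150, B = 150),
                               active_type = "B", n_genes = 60, seed = 6)
  sim <- generate_counts(spec, mod)
  expect_identical(as.matrix(sim$counts),
                   as.matrix(generate_counts(spec, mod)$counts))
  x <- as.matrix(sim$counts)
  expect_true(all(x >= 0 & x == round(x)))

  # no planted effect: normalized module-gene means equal across types
  # within sampling error (per-cell module means compared by t-test)
  norm <- as.matrix(lognormalize(sim$counts))
  cell_means <- colMeans(norm[mod, ])
  tt <- t.test(cell_means[sim$annotations$cell_type == "A"],
               cell_means[sim$annotations$cell_type == "B"])
  expect_gt(tt$p.value, 0.001)

  # MTX round trip is lossless
  d <- withr::local_tempdir()
  write_counts_mtx(sim$counts, d, sim$annotations)
  back <- read_counts_mtx(d)
  expect_equal(as.matrix(back$counts), x)
  expect_equal(back$annotations$cell_type, sim$annotations$cell_type)
})
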