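# Unit tests for the module-detection chain, each step against a hand
# example or a generator truth at small scale.

make_expr <- function(nr, nc, seed = 1) {
  withr::with_seed(seed, {
    matrix(rnorm(nr * nc), nr, nc,
           dimnames = list(synthetic_gene_symbols(nr),
                           sprintf("S%03d", seq_len(nc))))
  })
}

test_that("variance filter keeps the most variable genes", {
  e <- make_expr(5, 10)
  e["SG00001", ] <- 3                      # constant
  e["SG00002", ] <- e["SG00002", ] * 10    # inflated
  expect_identical(rownames(filter_variable_genes(e, 1)), "SG00002")
  expect_identical(filter_variable_genes(e, 5), e)
  expect_error(filter_variable_genes(e, 0), "integer")
  expect_error(filter_variable_genes(e, 6), "exceeds")

  # on planted data the filter recovers module genes almost exclusively
  sim <- generate_bulk_expression(module_plant_spec(seed = 11))
  mod_genes <- names(sim$truth$module)[sim$truth$module != "background"]
  kept <- rownames(filter_variable_genes(sim$expr, length(mod_genes)))
  expect_gte(mean(kept %in% mod_genes), 0.95)
})

test_that("outlier samples are removed by static cut of the sample tree", {
  e <- make_expr(40, 20, seed = 2)
  e[, "S003"] <- e[, "S003"] + 50
  out <- remove_outlier_samples(e, height_threshold = 20, min_cluster_size = 5)
  expect_identical(out$removed, "S003")
  expect_equal(ncol(out$expr), 19)

  none <- remove_outlier_samples(e, height_threshold = Inf)
  expect_identical(none$removed, character(0))

  # determinism
  expect_identical(remove_outlier_samples(e, 20, 5),
                   remove_outlier_samples(e, 20, 5))
  expect_error(remove_outlier_samples(e[, 1:2], 10), "3 samples")
})

test_that("bicor matches its definition and resists gross outliers", {
  withr::local_seed(3)
  x <- rnorm(50)
  expect_equal(bicor(x, x), 1)
  expect_equal(bicor(x, -x), -1)
  expect_error(bicor(x, x[-1]), "equal length")
  expect_error(bicor(1:2, 1:2), "3")

  # MAD = 0 falls back to the mean-centered (Pearson) form for that vector
  y <- c(rep(0, 20), 1, 2)
  z <- rnorm(22)
  vy <- y - mean(y)
  vz <- coexscreen:::bicor_prepare(z)
  expect_equal(bicor(y, z), sum(vy * vz) / sqrt(sum(vy^2) * sum(vz^2)))

  # clean bivariate normal: close to Pearson; with outliers: more robust
  withr::local_seed(4)
  n <- 1000
  u <- rnorm(n)
  a <- u + 0.8 * rnorm(n)          # rho ~ 0.78 with b below
  b <- u + 0.8 * rnorm(n)
  expect_lt(abs(bicor(a, b) - cor(a, b)), 0.05)
  rho_clean <- cor(a, b)
  idx <- sample(n, 20)
  a_out <- a
  a_out[idx] <- a_out[idx] + sample(c(-15, 15), 20, replace = TRUE)
  expect_lt(abs(bicor(a_out, b) - rho_clean), abs(cor(a_out, b) - rho_clean))

  # matrix agrees with pairwise evaluation
  e <- make_expr(6, 30, seed = 5)
  bm <- bicor_matrix(e)
  expect_equal(bm[2, 5], bicor(e[2, ], e[5, ]))
  expect_equal(bm, t(bm))
})

test_that("scale-free fit scores true power laws high and the scan obeys its contract", {
  sf <- coexscreen:::scale_free_fit
  # exact Pareto quantiles: a noise-free power-law connectivity
  pareto <- ppoints(2000)^(-1 / 1.5)
  expect_gt(sf(pareto)$fit_r2, 0.9)
  withr::local_seed(6)
  deg <- igraph::degree(igraph::sample_pa(2000, m = 2, directed = FALSE))
  expect_gt(sf(deg)$fit_r2, 0.9)                      # BA degrees
  # anti-scale-free (increasing frequency with k) is negated
  anti <- 2 - pareto / 100
  expect_lt(sf(anti[anti > 0])$fit_r2, 0)

  e <- generate_bulk_expression(module_plant_spec(
    n_modules = 2, genes_per_module = 30, n_background_genes = 40,
    n_cases = 40, n_controls = 40, seed = 7
  ))$expr
  scan <- pick_soft_threshold(e, powers = 1:8)
  expect_true(all(scan$table$fit_r2 >= -1 & scan$table$fit_r2 <= 1))
  expect_true(all(diff(scan$table$mean_connectivity) < 0))
  expect_true(scan$chosen_power %in% 1:8)
  # reachable target selects the smallest qualifying power and flags success
  scan0 <- pick_soft_threshold(e, powers = 3:8, r2_target = -1)
  expect_true(scan0$reached_target)
  expect_equal(scan0$chosen_power, 3)
})

test_that("adjacency and TOM match their formulas", {
  e <- make_expr(5, 30, seed = 8)
  cm <- bicor_matrix(e)
  a1 <- adjacency(e, 1, cor_mat = cm)
  expect_equal(a1[1, 2], abs(cm[1, 2]))
  a3 <- adjacency(e, 3, cor_mat = cm)
  expect_true(all(a3 >= 0 & a3 <= 1))
  off <- upper.tri(a1)
  expect_true(all(a3[off] <= a1[off]))
  s2 <- adjacency(e, 2, network_type = "signed", cor_mat = cm)
  expect_equal(s2[1, 2], ((1 + cm[1, 2]) / 2)^2)

  # 3-node toy: all off-diagonal 0.5 -> TOM_12 = (0.25 + 0.5)/(1 + 1 - 0.5)
  toy <- matrix(0.5, 3, 3)
  diag(toy) <- 1
  expect_equal(tom_similarity(toy)[1, 2], 0.5)

  # binary adjacency, identical neighborhoods, a_ij = 1 -> TOM = 1
  bin <- matrix(0, 4, 4)
  bin[1, 2] <- bin[2, 1] <- 1
  bin[1, 3] <- bin[3, 1] <- bin[2, 3] <- bin[3, 2] <- 1
  bin[1, 4] <- bin[4, 1] <- bin[2, 4] <- bin[4, 2] <- 1
  diag(bin) <- 1
  expect_equal(tom_similarity(bin)[1, 2], 1)

  tm <- tom_similarity(a3)
  expect_true(all(tm >= 0 & tm <= 1 + 1e-12))
  expect_equal(tm, t(tm))
  expect_error(tom_similarity(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("static-cut detection separates clean blocks and handles edge cases", {
  # two perfect blocks: within-dissimilarity 0, between 1
  d <- matrix(1, 6, 6)
  d[1:3, 1:3] <- 0
  d[4:6, 4:6] <- 0
  dimnames(d) <- list(synthetic_gene_symbols(6), synthetic_gene_symbols(6))
  asg <- detect_modules(d, min_module_size = 2, cut_height = 0.5)
  expect_equal(sort(unique(asg)), c("module_1", "module_2"))
  expect_equal(length(unique(asg[1:3])), 1)

  # cut height 0: every gene a singleton -> all grey
  expect_warning(asg0 <- detect_modules(d, min_module_size = 2, cut_height = 0),
                 "grey")
  expect_true(all(asg0 == "grey"))
})

test_that("eigengenes summarize modules and respect the sign convention", {
  withr::local_seed(9)
  base <- rnorm(30)
  e <- rbind(
    g1 = 2 * base + 1, g2 = 0.5 * base - 3, g3 = base,
    g4 = rnorm(30), g5 = rnorm(30)
  )
  colnames(e) <- sprintf("S%03d", 1:30)
  me <- module_eigengene(e, c("g1", "g2", "g3"))
  expect_equal(sd(me), 1)
  for (g in c("g1", "g2", "g3")) expect_gt(cor(me, e[g, ]), 0.999)
  expect_error(module_eigengene(e, c("g1", "missing")), "missing")

  # planted factor is recovered almost exactly
  sim <- generate_bulk_expression(module_plant_spec(
    n_modules = 1, genes_per_module = 50, n_background_genes = 10,
    loading_jitter = 0, seed = 10
  ))
  genes <- names(sim$truth$module)[sim$truth$module == "module_1"]
  me1 <- module_eigengene(sim$expr, genes)
  expect_gte(abs(cor(me1, sim$truth$factors[, "module_1"])), 0.95)
  expect_gte(mean(cor(t(sim$expr[genes, ]), me1)), 0)
})

test_that("eigengene merging joins split factors and is conservative", {
  sim <- generate_bulk_expression(module_plant_spec(
    n_modules = 2, genes_per_module = 40, n_background_genes = 10,
    n_cases = 60, n_controls = 60, seed = 12
  ))
  truth <- sim$truth$module
  # artificially split module_1 into two labels
  asg <- truth
  half <- names(truth)[truth == "module_1"][1:20]
  asg[half] <- "module_3"
  asg <- asg[asg != "background"]
  merged <- merge_close_modules(sim$expr[names(asg), ], asg)
  expect_equal(length(setdiff(unique(merged), "grey")), 2)
  m1 <- unique(merged[names(truth)[truth == "module_1"]])
  expect_length(m1, 1)

  # threshold 0 leaves the assignment untouched; count never increases
  same <- merge_close_modules(sim$expr[names(asg), ], asg, merge_cut_height = 0)
  expect_equal(length(unique(same)), length(unique(asg)))
})

test_that("grey and oversized modules are excluded from the retained set", {
  asg <- c(rep("module_1", 1001), rep("module_2", 1000), rep("grey", 5))
  names(asg) <- synthetic_gene_symbols(2006)
  res <- drop_invalid_modules(asg, max_size = 1000)
  expect_identical(retained_modules(res), "module_2")
  expect_true("module_1" %in% attr(res, "excluded"))
  expect_true("grey" %in% attr(res, "excluded"))

  no_grey <- c(rep("module_1", 10), rep("module_2", 3))
  names(no_grey) <- synthetic_gene_symbols(13)
  expect_setequal(retained_modules(drop_invalid_modules(no_grey, 5)), "module_2")
})

test_that("module-trait correlation flags the constructed association", {
  withr::local_seed(13)
  me <- cbind(assoc = rnorm(100), null = rnorm(100))
  trait <- as.integer(me[, "assoc"] + rnorm(100, sd = 0.3) > 0)
  rownames(me) <- sprintf("S%03d", 1:100)
  tab <- module_trait_correlation(me, trait)
  expect_identical(tab$module[1], "assoc")
  expect_lt(tab$p[1], 1e-6)
  expect_lt(abs(tab$r[tab$module == "null"]), 0.25)
  expect_error(
    module_trait_correlation(cbind(flat = rep(1, 100)), trait), "constant"
  )
})

test_that("kME matches Pearson recomputation and ranks hubs correctly", {
  sim <- generate_bulk_expression(module_plant_spec(
    n_modules = 1, genes_per_module = 40, n_background_genes = 10,
    loading_jitter = 0, seed = 14
  ))
  genes <- names(sim$truth$module)[sim$truth$module == "module_1"]
  me <- module_eigengenes(sim$expr, sim$truth$module, "module_1")
  k <- kme(sim$expr, me)
  expect_true(all(k >= -1 & k <= 1))
  g <- genes[7]
  expect_equal(k[g, "module_1"], cor(sim$expr[g, ], me[, "module_1"]))
  # closed form: kME ~ loading / sqrt(loading^2 + noise^2)
  expect_lt(abs(mean(k[genes, "module_1"]) - 0.8 / sqrt(0.8^2 + 0.6^2)), 0.05)

  asg <- sim$truth$module
  expect_identical(hub_genes(k, asg, "module_1", n = 1),
                   rownames(k)[which.max(k[, "module_1"])])
  expect_length(hub_genes(k, asg, "module_1", n = 10), 10)
  all_of_them <- hub_genes(k, asg, "module_1", n = 100)
  expect_length(all_of_them, 40)
  expect_true(isTRUE(attr(all_of_them, "short")))
})

test_that("module assignment is invariant to affine gene rescaling", {
  sim <- generate_bulk_expression(module_plant_spec(
    n_modules = 2, genes_per_module = 30, n_background_genes = 40,
    n_cases = 50, n_controls = 50, seed = 15
  ))
  fit1 <- coexpression_chain(sim$expr, sim$trait, top_variable = 60,
                             powers = 1:6, min_module_size = 10)
  shifted <- sim$expr
  g <- rownames(shifted)[5]
  shifted[g, ] <- 3 * shifted[g, ] + 7
  fit2 <- coexpression_chain(shifted, sim$trait, top_variable = 60,
                             powers = 1:6, min_module_size = 10)
  expect_identical(fit1$assignment[[g]], fit2$assignment[[g]])
  # and the whole pipeline is deterministic
  fit3 <- coexpression_chain(sim$expr, sim$trait, top_variable = 60,
                             powers = 1:6, min_module_size = 10)
  expect_identical(coexscreen:::drop_attributes(fit1$assignment),
                   coexscreen:::drop_attributes(fit3$assignment))
})
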