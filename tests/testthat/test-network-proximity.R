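# Network ingestion, target filtering, distances against a brute-force
# oracle, the pseudo-target background and the full screen.

test_that("edge ingestion applies the score threshold and deduplicates", {
  edges <- data.frame(
    protein1 = c("a", "b", "b", "a", "c", "x"),
    protein2 = c("b", "a", "c", "a", "d", "y"),
    combined_score = c(600, 700, 599, 900, 650, 800)
  )
  g <- load_string_edges(edges, restrict_to_lcc = FALSE)
  # 599 dropped, self-loop dropped, a-b/b-a collapsed: a-b, c-d, x-y remain
  expect_equal(igraph::ecount(g), 3)
  expect_false(igraph::are_adjacent(g, "b", "c"))
  ab <- igraph::E(g)[igraph::V(g)["a"] %--% igraph::V(g)["b"]]
  expect_equal(ab$combined_score, 700)

  # strict boundary: score exactly at the threshold is dropped
  gs <- load_string_edges(edges, score_threshold = 650, strict = TRUE,
                          restrict_to_lcc = FALSE)
  expect_equal(igraph::ecount(gs), 2)   # c-d at 650 dropped; a-b(700), x-y(800)
  expect_false("c" %in% igraph::V(gs)$name)

  # LCC restriction keeps the larger component
  two <- data.frame(
    protein1 = c(letters[1:7], "x"),
    protein2 = c(letters[2:8], "y"),
    combined_score = 900
  )
  glcc <- load_string_edges(two)
  expect_equal(igraph::vcount(glcc), 8)
  expect_true(igraph::graph_attr(glcc, "restricted_to_lcc"))

  bad <- edges
  bad$combined_score[2] <- "oops"
  expect_error(load_string_edges(bad), "lines")
})

test_that("potency filter is strictly 'over' and reports emptied drugs", {
  tab <- data.frame(
    drug_id = c("d1", "d1", "d1", "d2", "d2"),
    drug_name = c("one", "one", "one", "two", "two"),
    target_symbol = c("t1", "t2", "t3", "t4", "t5"),
    pchembl = c(6.0, 7.2, 5.1, 5.9, 6.0)
  )
  res <- filter_effective_targets(tab)
  expect_identical(res$targets$d1, "t2")   # 6.0 dropped (strict), 7.2 kept
  expect_identical(res$excluded, "d2")     # all targets <= 6

  tab$pchembl[1] <- NA
  expect_error(filter_effective_targets(tab, missing = "error"), "missing")
  expect_silent(filter_effective_targets(tab, missing = "drop"))
})

test_that("shortest distances match Floyd-Warshall on random graphs", {
  withr::local_seed(70)
  for (s in 1:20) {
    n <- sample(5:50, 1)
    edges <- random_connected_edges(n, extra = sample(0:n, 1), seed = 100 + s)
    g <- load_string_edges(edges, restrict_to_lcc = FALSE)
    nodes <- igraph::V(g)$name
    oracle <- oracle_floyd_warshall(nodes, edges$protein1, edges$protein2)
    got <- shortest_distances(g, nodes)
    expect_equal(got[nodes, nodes], oracle, tolerance = 0)
  }
  g1 <- load_string_edges(random_connected_edges(10, 3, 1),
                          restrict_to_lcc = FALSE)
  d <- shortest_distances(g1, igraph::V(g1)$name[1])
  expect_equal(unname(d[1, rownames(d)[1]]), 0)     # d(x, x) = 0
  nb <- igraph::neighbors(g1, rownames(d)[1])$name[1]
  expect_equal(unname(d[1, nb]), 1)                 # adjacent nodes
  expect_error(shortest_distances(g1, "nope"), "nope")
})

test_that("proximity D matches hand computation and is symmetric", {
  path3 <- data.frame(protein1 = c("a", "b"), protein2 = c("b", "c"),
                      combined_score = 900)
  g <- load_string_edges(path3)
  expect_equal(proximity_D(g, "a", "a")$D, 0)
  expect_equal(proximity_D(g, "a", c("b", "c"))$D, 1.5)
  expect_equal(proximity_D(g, c("b", "c"), "a")$D, 1.5)
  pd <- proximity_D(g, c("a", "ghost"), "c")
  expect_equal(pd$n_x_mapped, 1)
  expect_identical(pd$unmapped_x, "ghost")
})

test_that("background sampling matches exhaustive enumeration and is seeded", {
  path5 <- data.frame(protein1 = c("a", "b", "c", "d"),
                      protein2 = c("b", "c", "d", "e"),
                      combined_score = 900)
  g <- load_string_edges(path5)
  hubs <- c("a", "b")   # asymmetric hub set: node-to-hub means vary
  rm_dist <- coexscreen:::node_mean_hub_distance(g, hubs)
  pairs <- utils::combn(names(rm_dist), 2)
  exact_mu <- mean(apply(pairs, 2, function(p) mean(rm_dist[p])))
  bg <- sample_background(g, 2, hubs, n_samples = 4000, seed = 5)
  expect_lt(abs(bg$mu - exact_mu), 3 * bg$sigma / sqrt(4000))
  expect_gt(bg$sigma, 0)
  bg2 <- sample_background(g, 2, hubs, n_samples = 4000, seed = 5)
  expect_identical(bg$samples, bg2$samples)
  expect_error(sample_background(g, 5, hubs), "below")
})

test_that("gaussian check accepts normal samples and flags degeneracy", {
  withr::local_seed(71)
  bg <- structure(
    list(samples = rnorm(1000, 2.8, 0.2), mu = 2.8, sigma = 0.2),
    class = "background_distribution"
  )
  chk <- gaussian_check(bg)
  expect_lt(chk$ks_statistic, 0.05)
  expect_false(chk$degenerate)
  expect_equal(nrow(chk$qq), 1000)

  const <- structure(list(samples = rep(2, 100), mu = 2, sigma = 0),
                     class = "background_distribution")
  expect_true(gaussian_check(const)$degenerate)
})

test_that("z-and-p arithmetic matches direct evaluation", {
  expect_equal(z_and_p(2.8, 2.8, 0.1)$z, 0)
  expect_equal(z_and_p(2.8, 2.8, 0.1)$p, 0.5)
  zp <- z_and_p(2.428, 2.867, 0.056)
  expect_equal(zp$z, (2.428 - 2.867) / 0.056)
  expect_equal(zp$p, pnorm(zp$z))
  expect_equal(round(z_and_p(1.733, 2.874, 0.233)$z, 2), -4.9)
  expect_error(z_and_p(1, 2, 0), "sigma")
  two <- z_and_p(2.4, 2.8, 0.2, alternative = "two.sided")
  expect_equal(two$p, 2 * pnorm(-2))
})

test_that("the screen is deterministic and its cached backgrounds equal per-drug sampling", {
  net <- generate_ppi_network(network_plant_spec(n_nodes = 200, seed = 8))
  g <- load_string_edges(net)
  hubs <- names(sort(igraph::degree(g), decreasing = TRUE))[1:5]
  dt <- generate_drug_table(
    drug_plant_spec(n_null_drugs = 30, n_planted_drugs = 5,
                    targets_per_drug = c(3, 10), seed = 8),
    net, hubs
  )
  sc1 <- screen_drugs(g, dt$drugs, hubs, n_background = 200, seed = 13)
  sc2 <- screen_drugs(g, dt$drugs, hubs, n_background = 200, seed = 13)
  expect_identical(sc1$table, sc2$table)
  expect_identical(sort(sc1$table$rank), seq_len(nrow(sc1$table)))
  expect_true(all(sc1$table$p_adj >= sc1$table$p - 1e-15))

  # cached-by-size background is bit-identical to a direct draw with the
  # same derived sub-seed
  size <- sc1$table$n_targets[1]
  direct <- sample_background(
    g, size, hubs, n_samples = 200,
    seed = derive_seed(13, paste0("background_size_", size))
  )
  expect_identical(sc1$backgrounds[[as.character(size)]]$samples,
                   direct$samples)

  # drugs whose targets never map are skipped with a reason
  ghost <- data.frame(drug_id = "dX", drug_name = "ghost",
                      target_symbol = "NOWHERE", pchembl = 9)
  sc3 <- screen_drugs(g, rbind(dt$drugs, ghost), hubs,
                      n_background = 100, seed = 13)
  expect_true("dX" %in% sc3$skipped$drug_id)

  # report formatting carries the targets|mean|SD triple
  rep20 <- top_drugs_report(sc1, 5)
  expect_equal(nrow(rep20), 5)
  expect_match(rep20$background[1], "^\\d+\\|\\d+\\.\\d{3}\\|\\d+\\.\\d{3}$")
})

test_that("tightening the planting radius improves planted ranks", {
  med_rank <- vapply(c(2, 1, 0), function(r) {
    net <- generate_ppi_network(network_plant_spec(seed = 3))
    g <- load_string_edges(net)
    hubs <- names(sort(igraph::degree(g), decreasing = TRUE))[1:10]
    dt <- generate_drug_table(
      drug_plant_spec(planting_radius = r, seed = 3), net, hubs
    )
    sc <- screen_drugs(g, dt$drugs, hubs, n_background = 500, seed = 3)
    median(sc$table$rank[dt$truth[sc$table$drug_id]])
  }, numeric(1))
  expect_true(all(diff(med_rank) <= 0))
  expect_lt(med_rank[3], med_rank[1])
})
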