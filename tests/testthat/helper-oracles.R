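# Independent brute-force oracles. These deliberately re-derive each
# quantity with the most naive correct algorithm available, so they share no
# code path with the implementation they check.

# All-pairs shortest paths by Floyd-Warshall on an edge table.
oracle_floyd_warshall <- function(nodes, from, to) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_along(from)) {
    a <- from[i]
    b <- to[i]
    d[a, b] <- 1
    d[b, a] <- 1
  }
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}

# Average precision by explicit threshold enumeration.
oracle_auprc <- function(scores, labels) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  pos <- sum(labels == 1)
  prev_recall <- 0
  area <- 0
  for (t in thresholds) {
    called <- scores >= t
    tp <- sum(called & labels == 1)
    fp <- sum(called & labels == 0)
    recall <- tp / pos
    precision <- tp / (tp + fp)
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Step-up BH definition applied literally.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# One-sided (enrichment) hypergeometric tail by explicit summation of
# binomial-coefficient terms.
oracle_hypergeom_p <- function(n_universe, size_a, size_b, overlap) {
  upper <- min(size_a, size_b)
  total <- choose(n_universe, size_b)
  sum(vapply(overlap:upper, function(j) {
    choose(size_a, j) * choose(n_universe - size_a, size_b - j) / total
  }, numeric(1)))
}

# Raw single-sample enrichment score computed by a literal walk of the
# ranked gene list.
oracle_ssgsea_raw <- function(x, set_idx, alpha) {
  n <- length(x)
  r <- unname(rank(-x, ties.method = "average"))
  ord <- order(r, seq_len(n))
  in_set <- ord %in% set_idx
  w_total <- sum(r[set_idx]^alpha)
  p_in_cum <- 0
  out_seen <- 0
  score <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      p_in_cum <- p_in_cum + r[ord[i]]^alpha / w_total
    } else {
      out_seen <- out_seen + 1
    }
    score <- score + p_in_cum - out_seen / (n - length(set_idx))
  }
  score
}

# Connected random graph: a random spanning tree plus extra random edges.
random_connected_edges <- function(n, extra, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(n))
    from <- to <- character(0)
    for (i in 2:n) {
      from <- c(from, nodes[sample.int(i - 1, 1)])
      to <- c(to, nodes[i])
    }
    for (e in seq_len(extra)) {
      pair <- sample(nodes, 2)
      from <- c(from, pair[1])
      to <- c(to, pair[2])
    }
    data.frame(protein1 = from, protein2 = to,
               combined_score = 900L, stringsAsFactors = FALSE)
  })
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Best-matching detected module for a set of true module genes.
best_matching_module <- function(assignment, true_genes) {
  mods <- retained_modules(assignment)
  js <- vapply(mods, function(m) {
    jaccard(true_genes, names(assignment)[assignment == m])
  }, numeric(1))
  list(module = mods[which.max(js)], jaccard = max(js))
}
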