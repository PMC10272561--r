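# Drug screening by PPI network proximity: score-thresholded STRING-dialect
# edge ingestion, effective-target filtering, shortest-path proximity
# D(X, Y), a size-matched pseudo-target Gaussian null, and a BH-ranked
# per-drug report.

#' Load a STRING-dialect edge list as an undirected simple graph
#'
#' Keeps edges whose combined score passes the threshold, drops self-loops,
#' collapses duplicate (including reversed) edges keeping the maximal score,
#' and optionally restricts to the largest connected component so every
#' node pair has a finite distance.
#'
#' @param edges File path or data.frame with columns `protein1`, `protein2`,
#'   `combined_score`.
#' @param score_threshold Minimal combined score (default 600).
#' @param strict Use `> threshold` instead of the default `>=`.
#' @param restrict_to_lcc Keep only the largest connected component
#'   (default TRUE; ties broken by first component index).
#' @return An igraph object with graph attributes `score_threshold`,
#'   `strict`, `restricted_to_lcc` and `n_nodes_before_lcc`.
#' @export
load_string_edges <- function(edges, score_threshold = 600, strict = FALSE,
                              restrict_to_lcc = TRUE) {
  if (is.character(edges)) {
    edges <- utils::read.delim(edges, stringsAsFactors = FALSE)
  }
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(edges))) {
    stop_invalid("edge table must have columns: ", paste(need, collapse = ", "))
  }
  score <- suppressWarnings(as.numeric(edges$combined_score))
  bad <- which(is.na(score) | !nzchar(as.character(edges$protein1)) |
                 !nzchar(as.character(edges$protein2)))
  if (length(bad) > 0) {
    stop_invalid("malformed edge rows at lines: ",
                 paste(utils::head(bad, 10), collapse = ", "))
  }
  keep <- if (strict) score > score_threshold else score >= score_threshold
  kept <- edges[keep, , drop = FALSE]
  if (nrow(kept) == 0) stop_invalid("no edge passes the score threshold")
  g <- igraph::graph_from_data_frame(
    data.frame(from = kept$protein1, to = kept$protein2,
               combined_score = score[keep]),
    directed = FALSE
  )
  g <- igraph::simplify(g, remove.loops = TRUE, remove.multiple = TRUE,
                        edge.attr.comb = list(combined_score = "max"))
  n_before <- igraph::vcount(g)
  if (restrict_to_lcc) {
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  }
  g <- igraph::set_graph_attr(g, "score_threshold", score_threshold)
  g <- igraph::set_graph_attr(g, "strict", strict)
  g <- igraph::set_graph_attr(g, "restricted_to_lcc", restrict_to_lcc)
  g <- igraph::set_graph_attr(g, "n_nodes_before_lcc", n_before)
  g
}

#' Filter drug targets by potency
#'
#' Keeps target rows with pChEMBL strictly above `pchembl_min` ("over 6" is
#' strict); drugs left with no effective target are excluded and listed.
#'
#' @param drug_table Data.frame with columns `drug_id`, `target_symbol`,
#'   `pchembl` (and optionally `drug_name`).
#' @param pchembl_min Potency threshold (default 6).
#' @param missing How to treat missing potency values: `"drop"` the rows
#'   (default) or `"error"`.
#' @return Object of class `drug_target_sets`: `targets` (named list
#'   drug_id -> unique target symbols), `info` (data.frame `drug_id`,
#'   `drug_name`, `n_targets`), `excluded` (drug ids with no surviving
#'   target).
#' @export
filter_effective_targets <- function(drug_table, pchembl_min = 6,
                                     missing = c("drop", "error")) {
  missing <- match.arg(missing)
  need <- c("drug_id", "target_symbol", "pchembl")
  if (!all(need %in% names(drug_table))) {
    stop_invalid("drug table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyNA(drug_table$pchembl)) {
    if (missing == "error") stop_invalid("missing pChEMBL values present")
    drug_table <- drug_table[!is.na(drug_table$pchembl), , drop = FALSE]
  }
  all_drugs <- unique(drug_table$drug_id)
  kept <- drug_table[drug_table$pchembl > pchembl_min, , drop = FALSE]
  targets <- lapply(split(kept$target_symbol, kept$drug_id), function(t) {
    sort(unique(t))
  })
  targets <- targets[order(names(targets))]
  names_by_id <- if ("drug_name" %in% names(drug_table)) {
    tapply(drug_table$drug_name, drug_table$drug_id, function(v) v[1])
  } else {
    stats::setNames(names(targets), names(targets))
  }
  structure(
    list(
      targets = targets,
      info = data.frame(
        drug_id = names(targets),
        drug_name = unname(names_by_id[names(targets)]),
        n_targets = lengths(targets),
        row.names = NULL, stringsAsFactors = FALSE
      ),
      excluded = setdiff(all_drugs, names(targets)),
      pchembl_min = pchembl_min
    ),
    class = "drug_target_sets"
  )
}

#' Unweighted shortest-path distances from a set of source nodes
#'
#' @param network igraph object.
#' @param sources Node labels; at least one must map into the network.
#' @return Matrix of hop counts, mapped sources x all nodes (`Inf` for
#'   unreachable pairs); attribute `unmapped` lists symbols not in the graph.
#' @export
shortest_distances <- function(network, sources) {
  nodes <- igraph::V(network)$name
  mapped <- intersect(sources, nodes)
  if (length(mapped) == 0) {
    stop_invalid("no source maps into the network; missing: ",
                 paste(utils::head(sources, 10), collapse = ", "))
  }
  d <- igraph::distances(network, v = mapped, weights = NA)
  attr(d, "unmapped") <- setdiff(sources, nodes)
  d
}

#' Average shortest-path proximity between two node sets
#'
#' `D(X, Y) = sum_{x,y} d(x, y) / (|X'| * |Y'|)` over the members of each set
#' that map into the network.
#'
#' @param network igraph object (restrict to its largest connected component
#'   to guarantee finite distances).
#' @param x,y Node label sets (targets and hubs).
#' @return List: `D`, `n_x_mapped`, `n_y_mapped`, `unmapped_x`, `unmapped_y`.
#' @export
proximity_D <- function(network, x, y) {
  nodes <- igraph::V(network)$name
  xm <- intersect(unique(x), nodes)
  ym <- intersect(unique(y), nodes)
  if (length(xm) == 0 || length(ym) == 0) {
    stop_invalid("no mapped member in X or Y")
  }
  d <- igraph::distances(network, v = xm, to = ym, weights = NA)
  list(D = mean(d), n_x_mapped = length(xm), n_y_mapped = length(ym),
       unmapped_x = setdiff(unique(x), nodes),
       unmapped_y = setdiff(unique(y), nodes))
}

# Mean hop distance from every node to the hub set; the proximity of a
# target set is the mean of this vector over its members.
node_mean_hub_distance <- function(network, hubs) {
  nodes <- igraph::V(network)$name
  hm <- intersect(unique(hubs), nodes)
  if (length(hm) == 0) {
    stop_invalid("no hub maps into the network; missing: ",
                 paste(utils::head(hubs, 10), collapse = ", "))
  }
  d <- igraph::distances(network, to = hm, weights = NA)
  stats::setNames(rowMeans(d), nodes)
}

#' Pseudo-target background distribution of D
#'
#' Draws `n_samples` sets of `size` distinct nodes uniformly at random from
#' the network (hub overlap permitted), computes D to the hub set for each,
#' and records the Gaussian fit (mean and unbiased SD).
#'
#' @param network igraph object.
#' @param size Target-set size (1 <= size < number of nodes).
#' @param y Hub node labels.
#' @param n_samples Number of draws (default 1000).
#' @param seed Seed.
#' @return Object of class `background_distribution`: `samples`, `mu`,
#'   `sigma`, `size`, `n_samples`.
#' @export
sample_background <- function(network, size, y, n_samples = 1000, seed = 1) {
  size <- assert_count(size, "size")
  n_samples <- assert_count(n_samples, "n_samples")
  n_nodes <- igraph::vcount(network)
  if (size >= n_nodes) stop_invalid("`size` must be below the node count")
  rm_dist <- node_mean_hub_distance(network, y)
  draws <- with_rng(seed, {
    vapply(seq_len(n_samples), function(i) {
      mean(rm_dist[sample.int(n_nodes, size)])
    }, numeric(1))
  })
  structure(
    list(samples = draws, mu = mean(draws), sigma = stats::sd(draws),
         size = size, n_samples = n_samples),
    class = "background_distribution"
  )
}

#' Normality check of a background distribution
#'
#' Advisory only: theoretical-vs-empirical quantile pairs and a
#' Kolmogorov-Smirnov statistic against the fitted Gaussian. Never blocks a
#' screen.
#'
#' @param bg A [sample_background()] result (>= 30 samples).
#' @return List: `ks_statistic`, `qq` (data.frame `theoretical`,
#'   `empirical`), `degenerate`.
#' @export
gaussian_check <- function(bg) {
  s <- bg$samples
  if (length(s) < 30) stop_invalid("need >= 30 background samples")
  if (bg$sigma == 0 || !is.finite(bg$sigma)) {
    return(list(ks_statistic = NA_real_, qq = NULL, degenerate = TRUE))
  }
  pp <- stats::ppoints(length(s))
  qq <- data.frame(
    theoretical = stats::qnorm(pp, bg$mu, bg$sigma),
    empirical = stats::quantile(s, pp, names = FALSE)
  )
  ks <- suppressWarnings(
    stats::ks.test(s, "pnorm", bg$mu, bg$sigma)$statistic
  )
  list(ks_statistic = unname(ks), qq = qq, degenerate = FALSE)
}

#' Z-score and p-value of an observed proximity
#'
#' `Z = (D - mu) / sigma`; the default p-value is the one-sided lower-tail
#' standard-normal probability (a small D, i.e. targets close to the module
#' hubs, is significant).
#'
#' @param d Observed proximity D(X, Y).
#' @param mu,sigma Background Gaussian parameters (`sigma > 0`).
#' @param alternative `"less"` (default) or `"two.sided"`.
#' @return List: `z`, `p`.
#' @export
z_and_p <- function(d, mu, sigma, alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!is.finite(sigma) || sigma <= 0) stop_invalid("`sigma` must be > 0")
  z <- (d - mu) / sigma
  p <- switch(alternative,
    less = stats::pnorm(z),
    two.sided = 2 * stats::pnorm(-abs(z))
  )
  list(z = z, p = p)
}

#' Screen a drug collection against module hubs by network proximity
#'
#' For every drug with at least one target mapped into the network, computes
#' D to the hub set, a size-matched pseudo-target background (cached per
#' target-set size; each size draws a stable sub-seed from the master seed,
#' so results do not depend on drug order), Z and one-sided p; BH-adjusts
#' across all screened drugs and ranks ascending by adjusted p (ties by Z,
#' then drug id).
#'
#' @param network igraph object (LCC-restricted for finite distances).
#' @param drugs A [filter_effective_targets()] result, or a raw drug table
#'   (then filtered at `pchembl_min = 6` first).
#' @param hubs Module hub node labels.
#' @param n_background Background draws per target-set size (default 1000).
#' @param seed Master seed.
#' @param top_k Rows of the headline report (default 20).
#' @param alternative P-value sidedness, see [z_and_p()].
#' @return Object of class `proximity_screen`: `table` (data.frame `rank`,
#'   `drug_id`, `drug_name`, `n_targets`, `mu`, `sigma`, `proximity`, `z`,
#'   `p`, `p_adj`), `skipped` (data.frame `drug_id`, `reason`), `top_k`,
#'   `backgrounds` (list per size).
#' @export
screen_drugs <- function(network, drugs, hubs, n_background = 1000, seed = 1,
                         top_k = 20, alternative = "less") {
  if (!inherits(drugs, "drug_target_sets")) {
    drugs <- filter_effective_targets(drugs)
  }
  nodes <- igraph::V(network)$name
  rm_dist <- node_mean_hub_distance(network, hubs)
  mapped <- lapply(drugs$targets, intersect, y = nodes)
  screenable <- names(mapped)[lengths(mapped) > 0]
  if (length(screenable) == 0) stop_invalid("no screenable drug (no targets map)")
  unscreenable <- setdiff(names(mapped), screenable)
  skipped <- data.frame(
    drug_id = unscreenable,
    reason = rep("no_mapped_targets", length(unscreenable)),
    stringsAsFactors = FALSE
  )

  sizes <- sort(unique(lengths(mapped[screenable])))
  backgrounds <- lapply(sizes, function(s) {
    sample_background(network, s, hubs, n_samples = n_background,
                      seed = derive_seed(seed, paste0("background_size_", s)))
  })
  names(backgrounds) <- as.character(sizes)

  rows <- lapply(screenable, function(id) {
    tg <- mapped[[id]]
    bg <- backgrounds[[as.character(length(tg))]]
    d <- mean(rm_dist[tg])
    zp <- z_and_p(d, bg$mu, bg$sigma, alternative)
    data.frame(drug_id = id, n_targets = length(tg), mu = bg$mu,
               sigma = bg$sigma, proximity = d, z = zp$z, p = zp$p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- bh_adjust(tab$p)
  tab <- tab[order(tab$p_adj, tab$z, tab$drug_id), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  name_of <- stats::setNames(drugs$info$drug_name, drugs$info$drug_id)
  tab$drug_name <- unname(name_of[tab$drug_id])
  tab <- tab[, c("rank", "drug_id", "drug_name", "n_targets", "mu", "sigma",
                 "proximity", "z", "p", "p_adj")]
  rownames(tab) <- NULL
  structure(
    list(table = tab, skipped = skipped, top_k = min(top_k, nrow(tab)),
         backgrounds = backgrounds, seed = seed),
    class = "proximity_screen"
  )
}

#' Headline report of a proximity screen
#'
#' The top drugs by BH-adjusted p, with the background summarized in the
#' compact `targets|mean|SD` form.
#'
#' @param screen A [screen_drugs()] result.
#' @param top_k Number of rows (defaults to the screen's `top_k`).
#' @return Data.frame `rank`, `drug_id`, `drug_name`, `background`
#'   (`"n|mu|sigma"`), `proximity`, `p_adj`.
#' @export
top_drugs_report <- function(screen, top_k = NULL) {
  if (is.null(top_k)) top_k <- screen$top_k
  tab <- utils::head(screen$table, top_k)
  data.frame(
    rank = tab$rank,
    drug_id = tab$drug_id,
    drug_name = tab$drug_name,
    background = sprintf("%d|%.3f|%.3f", tab$n_targets, tab$mu, tab$sigma),
    proximity = round(tab$proximity, 3),
    p_adj = signif(tab$p_adj, 3),
    stringsAsFactors = FALSE
  )
}

#' @export
print.proximity_screen <- function(x, ...) {
  cat("Proximity screen:", nrow(x$table), "drugs screened,",
      nrow(x$skipped), "skipped\n")
  print(top_drugs_report(x), row.names = FALSE)
  invisible(x)
}
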