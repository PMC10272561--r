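# Weighted co-expression module detection: biweight midcorrelation,
# soft-threshold selection against a scale-free fit target, topological
# overlap, static tree cut, eigengenes, module-trait correlation, kME and
# hub ranking.

#' Keep the k most variable genes
#'
#' @param expr Genes x samples numeric matrix.
#' @param k Number of genes to keep (1 <= k <= nrow(expr)).
#' @return The submatrix of the `k` genes with largest sample standard
#'   deviation, in the original gene order; sample order untouched. Ties are
#'   broken lexicographically by gene id.
#' @export
filter_variable_genes <- function(expr, k) {
  assert_matrix_like(expr, "expr")
  k <- assert_count(k, "k")
  if (k > nrow(expr)) stop_invalid("`k` exceeds the number of genes")
  sds <- apply(expr, 1, stats::sd)
  keep <- rownames(expr)[order(-sds, rownames(expr))][seq_len(k)]
  expr[rownames(expr) %in% keep, , drop = FALSE]
}

#' Remove outlier samples by static cut of a sample dendrogram
#'
#' Samples are clustered by average-linkage on Euclidean distances of the
#' gene-standardized matrix; the tree is cut at `height_threshold` and samples
#' falling in clusters smaller than `min_cluster_size` are dropped.
#'
#' @param expr Genes x samples matrix (>= 3 samples).
#' @param height_threshold Static cut height; `Inf` removes nothing.
#' @param min_cluster_size Minimal cluster size to keep.
#' @return List: `expr` (remaining samples), `removed` (dropped sample ids).
#' @export
remove_outlier_samples <- function(expr, height_threshold,
                                   min_cluster_size = 10) {
  assert_matrix_like(expr, "expr")
  if (ncol(expr) < 3) stop_invalid("need >= 3 samples")
  min_cluster_size <- assert_count(min_cluster_size, "min_cluster_size")
  z <- standardize_genes(expr)
  hc <- stats::hclust(stats::dist(t(z)), method = "average")
  cl <- if (is.finite(height_threshold)) {
    stats::cutree(hc, h = height_threshold)
  } else {
    rep(1L, ncol(expr))
  }
  sizes <- table(cl)
  keep <- cl %in% as.integer(names(sizes)[sizes >= min_cluster_size])
  if (!any(keep)) stop_invalid("all samples would be removed; raise the threshold")
  list(
    expr = expr[, keep, drop = FALSE],
    removed = colnames(expr)[!keep]
  )
}

# Gene-wise standardization (rows to mean 0, sd 1); constant rows become 0.
standardize_genes <- function(expr) {
  mu <- rowMeans(expr)
  sd <- apply(expr, 1, stats::sd)
  sd[sd == 0] <- 1
  (expr - mu) / sd
}

#' Biweight midcorrelation of two vectors
#'
#' Robust correlation: observations are weighted by `(1 - u^2)^2` with
#' `u = (x - median) / (9 * MAD)` and weight zero where `|u| >= 1`; the
#' correlation of the weighted, median-centered vectors is returned. A vector
#' with zero MAD falls back to its Pearson (mean-centered, unweighted) form.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A correlation in \[-1, 1\].
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("`x` and `y` must have equal length")
  if (length(x) < 3) stop_invalid("need length >= 3")
  vx <- bicor_prepare(x)
  vy <- bicor_prepare(y)
  den <- sqrt(sum(vx^2) * sum(vy^2))
  if (den == 0) stop_invalid("bicor undefined for a constant vector")
  min(1, max(-1, sum(vx * vy) / den))
}

# Median-centered, biweight-weighted vector (Pearson fallback when MAD = 0).
bicor_prepare <- function(x) {
  med <- stats::median(x)
  madv <- stats::median(abs(x - med))
  if (madv == 0) return(x - mean(x))
  u <- (x - med) / (9 * madv)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  (x - med) * w
}

#' Pairwise biweight midcorrelation matrix
#'
#' @param expr Genes x samples matrix (>= 3 samples).
#' @return Genes x genes symmetric correlation matrix with unit diagonal.
#' @export
bicor_matrix <- function(expr) {
  assert_matrix_like(expr, "expr")
  if (ncol(expr) < 3) stop_invalid("need >= 3 samples")
  v <- t(apply(expr, 1, bicor_prepare))
  norms <- sqrt(rowSums(v^2))
  if (any(norms == 0)) {
    stop_invalid("constant gene(s): ",
                 paste(rownames(expr)[norms == 0], collapse = ", "))
  }
  r <- tcrossprod(v / norms)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Scale-free fit of a connectivity distribution
#'
#' Bins `log10(k)` into `n_bins` equal-width bins, then regresses
#' `log10(frequency)` on `log10(mean k per bin)` over occupied bins. The
#' signed R-squared is negated when the slope is positive (a scale-free
#' topology requires a decreasing frequency-connectivity relation).
#'
#' @param k Connectivity vector (entries <= 0 are ignored).
#' @param n_bins Number of bins.
#' @return List: `fit_r2`, `slope`, `n_occupied`.
#' @keywords internal
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  logk <- log10(k)
  if (length(unique(logk)) < 2) stop_invalid("degenerate connectivity distribution")
  bins <- cut(logk, breaks = n_bins, include.lowest = TRUE)
  freq <- tapply(k, bins, length)
  meank <- tapply(k, bins, mean)
  occupied <- !is.na(freq) & freq > 0
  if (sum(occupied) < 3) stop_invalid("fewer than 3 occupied connectivity bins")
  x <- log10(meank[occupied])
  y <- log10(freq[occupied])
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[["x"]]
  list(fit_r2 = if (slope > 0) -r2 else r2, slope = slope,
       n_occupied = sum(occupied))
}

#' Scan soft-threshold powers against a scale-free topology target
#'
#' For each candidate power the weighted connectivity
#' `k_i = sum_j |bicor_ij|^power` (j != i) is computed and its distribution is
#' scored by [scale_free_fit()]. The chosen power is the smallest one whose
#' signed fit reaches `r2_target`; if none does, the power with the maximal
#' fit is chosen and flagged.
#'
#' @param expr Genes x samples matrix.
#' @param powers Candidate integer powers.
#' @param r2_target Signed scale-free fit target (default 0.9).
#' @param n_bins Connectivity histogram bins.
#' @param cor_mat Optional precomputed correlation matrix (avoids recomputing
#'   bicor when the caller also needs it).
#' @return Object of class `soft_threshold_scan`: `table` (data.frame `power`,
#'   `fit_r2`, `mean_connectivity`), `chosen_power`, `reached_target`.
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_target = 0.9,
                                n_bins = 10, cor_mat = NULL) {
  if (length(powers) == 0) stop_invalid("`powers` must be nonempty")
  if (is.null(cor_mat)) cor_mat <- bicor_matrix(expr)
  a0 <- abs(cor_mat)
  diag(a0) <- 0
  rows <- lapply(powers, function(p) {
    k <- rowSums(a0^p)
    fit <- scale_free_fit(k, n_bins = n_bins)
    data.frame(power = p, fit_r2 = fit$fit_r2, mean_connectivity = mean(k))
  })
  tab <- do.call(rbind, rows)
  hit <- tab$power[tab$fit_r2 >= r2_target]
  reached <- length(hit) > 0
  chosen <- if (reached) min(hit) else tab$power[which.max(tab$fit_r2)]
  structure(
    list(table = tab, chosen_power = chosen, reached_target = reached,
         r2_target = r2_target),
    class = "soft_threshold_scan"
  )
}

#' @export
print.soft_threshold_scan <- function(x, ...) {
  cat("Soft-threshold scan (target signed R^2 =", x$r2_target, ")\n")
  print(x$table, row.names = FALSE)
  cat("chosen power:", x$chosen_power,
      if (!x$reached_target) "(target not reached; maximal fit used)" else "", "\n")
  invisible(x)
}

#' Soft-thresholded adjacency matrix
#'
#' @param expr Genes x samples matrix (ignored when `cor_mat` is given).
#' @param power Integer soft power >= 1.
#' @param network_type `"unsigned"` (`|r|^power`) or `"signed"`
#'   (`((1 + r)/2)^power`).
#' @param cor_mat Optional precomputed correlation matrix.
#' @return Genes x genes adjacency in \[0, 1\] with unit diagonal.
#' @export
adjacency <- function(expr, power, network_type = c("unsigned", "signed"),
                      cor_mat = NULL) {
  network_type <- match.arg(network_type)
  power <- assert_count(power, "power")
  if (is.null(cor_mat)) cor_mat <- bicor_matrix(expr)
  a <- switch(network_type,
    unsigned = abs(cor_mat)^power,
    signed = ((1 + cor_mat) / 2)^power
  )
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_u a_iu a_uj` (u != i, j) and `k_i = sum_u a_iu` (u != i);
#' diagonal 1. Dissimilarity for clustering is `1 - TOM`.
#'
#' @param adj Square symmetric adjacency with entries in \[0, 1\].
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) {
    stop_invalid("`adj` must be a square matrix")
  }
  if (max(abs(adj - t(adj))) > 1e-10) stop_invalid("`adj` must be symmetric")
  if (min(adj) < -1e-12 || max(adj) > 1 + 1e-12) {
    stop_invalid("adjacency entries must lie in [0, 1]")
  }
  a <- adj
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  tom <- (l + a) / (outer(k, k, pmin) + 1 - a)
  diag(tom) <- 1
  tom
}

#' Detect modules by static cut of the TOM dendrogram
#'
#' Average-linkage hierarchical clustering on the dissimilarity, cut at a
#' fixed height; clusters smaller than `min_module_size` are labeled
#' `"grey"` (unassigned). Retained modules are labeled `module_1`,
#' `module_2`, ... by decreasing size (ties broken by the lexicographically
#' smallest member gene).
#'
#' @param diss Square symmetric dissimilarity (e.g. `1 - TOM`).
#' @param min_module_size Minimal module size (default 30).
#' @param cut_height Static cut height; `NULL` places the cut in the middle
#'   of the widest gap between consecutive merge heights in the upper half of
#'   the dendrogram (the largest separation between the within-module and
#'   between-module merge regimes).
#' @return Named character vector gene -> module label, with attributes
#'   `cut_height` and `dendrogram`.
#' @export
detect_modules <- function(diss, min_module_size = 30, cut_height = NULL) {
  if (!is.matrix(diss) || nrow(diss) != ncol(diss)) {
    stop_invalid("`diss` must be a square matrix")
  }
  if (max(abs(diss - t(diss))) > 1e-10) stop_invalid("`diss` must be symmetric")
  min_module_size <- assert_count(min_module_size, "min_module_size")
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  if (is.null(cut_height)) cut_height <- widest_gap_cut(hc$height)
  cl <- if (cut_height <= 0) {
    stats::setNames(seq_len(nrow(diss)), rownames(diss))
  } else {
    stats::cutree(hc, h = cut_height)
  }
  labels <- canonical_module_labels(cl, min_module_size)
  if (all(labels == "grey")) {
    warning("static cut produced no module of size >= ", min_module_size,
            "; all genes left grey")
  }
  structure(labels, cut_height = cut_height, dendrogram = hc)
}

# Default static cut: midpoint of the widest gap between consecutive sorted
# merge heights in the upper half of the dendrogram. Separates the tight
# within-module merges from the diffuse between-module/background merges
# without assuming where either regime sits on the height axis.
widest_gap_cut <- function(heights) {
  h <- sort(heights)
  upper <- h[h >= stats::median(h)]
  if (length(upper) < 2) {
    return(stats::quantile(h, 0.99, names = FALSE))
  }
  gaps <- diff(upper)
  i <- which.max(gaps)
  (upper[i] + upper[i + 1]) / 2
}

# Relabel integer cluster ids as module_1.. by decreasing size; small
# clusters become "grey".
canonical_module_labels <- function(cl, min_module_size) {
  genes <- names(cl)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  first_gene <- vapply(big, function(id) min(genes[cl == id]), character(1))
  ord <- big[order(-sizes[big], first_gene)]
  labels <- rep("grey", length(cl))
  names(labels) <- genes
  for (i in seq_along(ord)) {
    labels[cl == as.integer(ord[i])] <- sprintf("module_%d", i)
  }
  labels
}

#' Module eigengene
#'
#' First right-singular vector of the gene-standardized module submatrix,
#' scaled to unit variance and sign-flipped so that its mean correlation with
#' the module's genes is non-negative.
#'
#' @param expr Genes x samples matrix with >= 2 samples.
#' @param genes Nonempty vector of module gene ids, all present in `expr`.
#' @return Named per-sample numeric vector.
#' @export
module_eigengene <- function(expr, genes) {
  assert_matrix_like(expr, "expr")
  if (length(genes) == 0) stop_invalid("module gene list is empty")
  if (ncol(expr) < 2) stop_invalid("need >= 2 samples")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0) {
    stop_invalid("module genes absent from expression matrix: ",
                 paste(missing, collapse = ", "))
  }
  z <- standardize_genes(expr[genes, , drop = FALSE])
  e <- svd(z, nu = 0, nv = 1)$v[, 1]
  s <- stats::sd(e)
  if (s == 0) stop_invalid("degenerate eigengene (constant)")
  e <- e / s
  mean_cor <- mean(stats::cor(t(z), e))
  if (!is.na(mean_cor) && mean_cor < 0) e <- -e
  stats::setNames(e, colnames(expr))
}

#' Eigengene matrix for a module assignment
#'
#' @param expr Genes x samples matrix.
#' @param assignment Named gene -> module label vector.
#' @param modules Modules to compute (default: all non-grey labels).
#' @return Samples x modules matrix of unit-variance eigengenes.
#' @export
module_eigengenes <- function(expr, assignment, modules = NULL) {
  if (is.null(modules)) {
    modules <- setdiff(unique(assignment), "grey")
    modules <- modules[order(module_index(modules))]
  }
  if (length(modules) == 0) stop_invalid("no modules to summarize")
  me <- vapply(modules, function(m) {
    module_eigengene(expr, names(assignment)[assignment == m])
  }, numeric(ncol(expr)))
  rownames(me) <- colnames(expr)
  me
}

module_index <- function(labels) {
  as.integer(sub("^module_", "", labels))
}

#' Merge modules with highly correlated eigengenes
#'
#' Iteratively merges the closest pair of modules whose eigengene
#' dissimilarity `1 - cor` falls below `merge_cut_height`, recomputing
#' eigengenes after each merge, until no pair qualifies. Labels are then
#' re-canonicalized by decreasing size.
#'
#' @param expr Genes x samples matrix.
#' @param assignment Named gene -> module label vector.
#' @param merge_cut_height Eigengene dissimilarity threshold (default 0.1).
#' @return Updated assignment vector.
#' @export
merge_close_modules <- function(expr, assignment, merge_cut_height = 0.1) {
  assignment <- drop_attributes(assignment)
  repeat {
    modules <- setdiff(unique(assignment), "grey")
    if (length(modules) < 2 || merge_cut_height <= 0) break
    me <- module_eigengenes(expr, assignment, modules)
    d <- 1 - stats::cor(me)
    diag(d) <- Inf
    idx <- arrayInd(which.min(d), dim(d))
    if (d[idx] >= merge_cut_height) break
    a <- colnames(me)[idx[1]]
    b <- colnames(me)[idx[2]]
    keep <- if (sum(assignment == a) >= sum(assignment == b)) a else b
    assignment[assignment %in% c(a, b)] <- keep
  }
  relabel_by_size(assignment)
}

relabel_by_size <- function(assignment) {
  genes <- names(assignment)
  modules <- setdiff(unique(assignment), "grey")
  if (length(modules) == 0) return(assignment)
  sizes <- vapply(modules, function(m) sum(assignment == m), integer(1))
  first_gene <- vapply(modules, function(m) min(genes[assignment == m]), character(1))
  ord <- modules[order(-sizes, first_gene)]
  out <- assignment
  for (i in seq_along(ord)) {
    out[assignment == ord[i]] <- sprintf("module_%d", i)
  }
  out
}

drop_attributes <- function(x) {
  nm <- names(x)
  attributes(x) <- NULL
  names(x) <- nm
  x
}

#' Exclude grey and oversized modules from the retained set
#'
#' Genes keep their labels; the retained-module list (attribute `retained`)
#' excludes `"grey"` and any module with strictly more than `max_size` genes.
#'
#' @param assignment Named gene -> module label vector.
#' @param max_size Maximal retained module size (default 1000; "over" is
#'   strict, so a module of exactly `max_size` genes is retained).
#' @return The assignment with attributes `retained` and `excluded`.
#' @export
drop_invalid_modules <- function(assignment, max_size = 1000) {
  assignment <- drop_attributes(assignment)
  modules <- setdiff(unique(assignment), "grey")
  modules <- modules[order(module_index(modules))]
  sizes <- vapply(modules, function(m) sum(assignment == m), integer(1))
  retained <- modules[sizes <= max_size]
  structure(assignment,
            retained = retained,
            excluded = c(intersect(unique(assignment), "grey"),
                         modules[sizes > max_size]))
}

#' Retained modules of an assignment
#'
#' @param assignment Assignment vector, ideally after
#'   [drop_invalid_modules()].
#' @return Character vector of retained module labels.
#' @export
retained_modules <- function(assignment) {
  r <- attr(assignment, "retained")
  if (is.null(r)) {
    r <- setdiff(unique(assignment), "grey")
    r <- r[order(module_index(r))]
  }
  r
}

#' Module-trait correlation
#'
#' Pearson (point-biserial, for a binary trait) correlation of each module
#' eigengene with the trait, with a two-sided p-value from the t-distribution
#' on n - 2 degrees of freedom.
#'
#' @param eigengenes Samples x modules matrix.
#' @param trait Per-sample 0/1 vector aligned to the eigengene rows.
#' @return Data.frame `module`, `r`, `p`, ordered by decreasing `|r|`.
#' @export
module_trait_correlation <- function(eigengenes, trait) {
  if (nrow(eigengenes) != length(trait)) {
    stop_invalid("trait and eigengenes are not aligned")
  }
  if (length(unique(trait)) < 2) stop_invalid("trait must contain both classes")
  n <- length(trait)
  out <- lapply(colnames(eigengenes), function(m) {
    e <- eigengenes[, m]
    if (stats::sd(e) == 0) stop_invalid("constant eigengene for ", m)
    r <- stats::cor(e, trait)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    data.frame(module = m, r = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
  })
  tab <- do.call(rbind, out)
  tab[order(-abs(tab$r), tab$module), , drop = FALSE]
}

#' Module membership (kME) table
#'
#' Pearson correlation of every gene with every module eigengene.
#'
#' @param expr Genes x samples matrix.
#' @param eigengenes Samples x modules matrix.
#' @return Genes x modules matrix of correlations.
#' @export
kme <- function(expr, eigengenes) {
  if (ncol(expr) != nrow(eigengenes)) {
    stop_invalid("expression and eigengenes are not aligned")
  }
  k <- stats::cor(t(expr), eigengenes)
  k[k > 1] <- 1
  k[k < -1] <- -1
  k
}

#' Top hub genes of a module by kME
#'
#' @param kme_table Genes x modules kME matrix.
#' @param assignment Named gene -> module label vector.
#' @param module Module label.
#' @param n Number of hubs (default 10). When the module has fewer genes, all
#'   are returned and the result carries attribute `short = TRUE`.
#' @return Character vector of hub gene ids, by decreasing own-module kME
#'   (ties broken lexicographically).
#' @export
hub_genes <- function(kme_table, assignment, module, n = 10) {
  n <- assert_count(n, "n")
  genes <- names(assignment)[assignment == module]
  genes <- intersect(genes, rownames(kme_table))
  if (length(genes) == 0) stop_invalid("module ", module, " has no genes in the kME table")
  vals <- kme_table[genes, module]
  ord <- genes[order(-vals, genes)]
  out <- ord[seq_len(min(n, length(ord)))]
  if (length(ord) < n) attr(out, "short") <- TRUE
  out
}

#' Run the full co-expression module chain
#'
#' Variance filter, optional outlier-sample removal, soft-threshold scan,
#' adjacency, TOM, static-cut detection, eigengene merge, size/grey exclusion,
#' module-trait correlation, kME and hub listing, in one call.
#'
#' @param expr Genes x samples matrix.
#' @param trait Per-sample 0/1 vector.
#' @param top_variable Genes kept by the variance filter (capped at the number
#'   of genes).
#' @param powers Candidate soft powers.
#' @param r2_target Scale-free fit target.
#' @param outlier_height Static cut height for sample outlier removal;
#'   `NULL` skips the step.
#' @param outlier_min_cluster Minimal retained sample-cluster size.
#' @param network_type `"unsigned"` or `"signed"`.
#' @param min_module_size,cut_height,merge_cut_height,max_module_size
#'   Module detection parameters (see the individual steps).
#' @param n_hubs Hub genes per retained module.
#' @return Object of class `coexpression_fit` with components `expr`
#'   (filtered matrix), `removed_samples`, `scan`, `power`, `assignment`
#'   (with retained/excluded attributes), `eigengenes`, `trait_cor`,
#'   `kme`, `hubs` (named list per retained module).
#' @export
coexpression_chain <- function(expr, trait, top_variable = 5000, powers = 1:12,
                               r2_target = 0.9, outlier_height = NULL,
                               outlier_min_cluster = 10,
                               network_type = "unsigned", min_module_size = 30,
                               cut_height = NULL, merge_cut_height = 0.1,
                               max_module_size = 1000, n_hubs = 10) {
  assert_matrix_like(expr, "expr")
  if (ncol(expr) != length(trait)) stop_invalid("trait not aligned to samples")
  removed <- character(0)
  if (!is.null(outlier_height)) {
    o <- remove_outlier_samples(expr, outlier_height, outlier_min_cluster)
    expr <- o$expr
    removed <- o$removed
    trait <- trait[colnames(expr)]
  }
  expr <- filter_variable_genes(expr, min(top_variable, nrow(expr)))
  cor_mat <- bicor_matrix(expr)
  scan <- pick_soft_threshold(expr, powers, r2_target, cor_mat = cor_mat)
  adj <- adjacency(expr, scan$chosen_power, network_type, cor_mat = cor_mat)
  tom <- tom_similarity(adj)
  assignment <- detect_modules(1 - tom, min_module_size, cut_height)
  assignment <- merge_close_modules(expr, assignment, merge_cut_height)
  assignment <- drop_invalid_modules(assignment, max_module_size)
  retained <- retained_modules(assignment)
  if (length(retained) == 0) stop_invalid("no module retained after filtering")
  me <- module_eigengenes(expr, assignment, retained)
  trait_cor <- module_trait_correlation(me, trait)
  kme_tab <- kme(expr, me)
  hubs <- lapply(retained, function(m) hub_genes(kme_tab, assignment, m, n_hubs))
  names(hubs) <- retained
  structure(
    list(expr = expr, trait = trait, removed_samples = removed, scan = scan,
         power = scan$chosen_power, assignment = assignment, eigengenes = me,
         trait_cor = trait_cor, kme = kme_tab, hubs = hubs),
    class = "coexpression_fit"
  )
}

#' @export
print.coexpression_fit <- function(x, ...) {
  retained <- retained_modules(x$assignment)
  cat("Co-expression fit:", nrow(x$expr), "genes x", ncol(x$expr), "samples\n")
  cat("soft power:", x$power,
      if (!x$scan$reached_target) "(scale-free target not reached)" else "", "\n")
  cat("retained modules:", length(retained), "\n")
  print(utils::head(x$trait_cor, 10), row.names = FALSE)
  invisible(x)
}
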