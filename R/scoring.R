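# Module activity scoring: rank-based single-sample enrichment for bulk
# matrices, bin-controlled additive scores for cells, library-size
# normalization and pseudo-bulk aggregation.

#' Single-sample rank-based enrichment score (ssGSEA-style)
#'
#' Per sample, genes are ranked by expression descending (rank 1 = highest;
#' ties by average rank). Walking the ranked list, the weighted in-set
#' cumulative fraction `P_in(i) = sum_{g in S, rank <= i} rank_g^alpha /
#' sum_{g in S} rank_g^alpha` is compared with the unweighted out-of-set
#' fraction `P_out(i)`; the score is `sum_i (P_in(i) - P_out(i))`. With
#' `minmax_normalize` the scores are divided by their range across samples.
#'
#' @param expr Genes x samples matrix.
#' @param gene_set Character vector of set genes; at least one must be present
#'   in `expr` and the set must not cover the whole gene universe.
#' @param alpha Rank-weight exponent (default 0.25).
#' @param minmax_normalize Divide scores by `max - min` across samples
#'   (default TRUE; skipped with a warning when the range is zero).
#' @return Named per-sample numeric vector.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25, minmax_normalize = TRUE) {
  assert_matrix_like(expr, "expr")
  alpha <- assert_number(alpha, "alpha", lower = 0)
  present <- intersect(unique(gene_set), rownames(expr))
  if (length(present) == 0) stop_invalid("no gene of the set is present in `expr`")
  if (length(present) == nrow(expr)) {
    stop_invalid("gene set covers the whole universe; out-of-set walk undefined")
  }
  n <- nrow(expr)
  in_set <- rownames(expr) %in% present
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    r <- rank(-expr[, j], ties.method = "average")
    ord <- order(r, rownames(expr))
    set_ord <- in_set[ord]
    w <- (r[ord]^alpha) * set_ord
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!set_ord) / (n - length(present))
    sum(p_in - p_out)
  }, numeric(1))
  names(scores) <- colnames(expr)
  if (minmax_normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) {
      scores <- scores / rng
    } else {
      warning("score range is zero; min-max normalization skipped")
    }
  }
  scores
}

#' Library-size log-normalization of counts
#'
#' `value = ln(1 + count / library_size * scale)` per cell.
#'
#' @param counts Genes x cells matrix (dense or sparse); every cell must have
#'   a positive library size.
#' @param scale Scale factor (default 1e4).
#' @return Matrix of the same class and dimensions.
#' @export
lognormalize <- function(counts, scale = 1e4) {
  libs <- Matrix::colSums(counts)
  if (any(libs <= 0)) {
    stop_invalid("cells with zero library size: ",
                 paste(colnames(counts)[libs <= 0], collapse = ", "))
  }
  if (methods::is(counts, "sparseMatrix")) {
    out <- counts %*% Matrix::Diagonal(x = scale / libs)
    out <- methods::as(out, "CsparseMatrix")
    out@x <- log1p(out@x)
    dimnames(out) <- dimnames(counts)
    out
  } else {
    log1p(sweep(counts, 2, libs, "/") * scale)
  }
}

#' Bin-controlled additive module score per cell
#'
#' Genes are binned into `n_bins` equal-frequency bins by average expression
#' across cells; for each set gene, `n_ctrl` control genes are sampled from
#' its bin (set genes excluded; without replacement when the bin is large
#' enough, with replacement otherwise). The score of a cell is the mean
#' expression of the set genes minus the mean expression of the pooled
#' control draws.
#'
#' @param norm Genes x cells normalized matrix (e.g. [lognormalize()] output).
#' @param gene_set Character vector of set genes (>= 1 present).
#' @param n_bins Expression bins (default 24; reduced with a warning when
#'   there are fewer genes than bins).
#' @param n_ctrl Control genes sampled per set gene (default 100).
#' @param seed Seed for the control draws.
#' @return Named per-cell numeric vector.
#' @export
additive_module_score <- function(norm, gene_set, n_bins = 24, n_ctrl = 100,
                                  seed = 1) {
  n_bins <- assert_count(n_bins, "n_bins")
  n_ctrl <- assert_count(n_ctrl, "n_ctrl")
  genes <- rownames(norm)
  present <- intersect(unique(gene_set), genes)
  if (length(present) == 0) stop_invalid("no gene of the set is present in `norm`")
  avg <- Matrix::rowMeans(norm)
  # each bin must be able to offer control candidates, so never use more
  # bins than half the gene universe
  max_bins <- max(1L, length(genes) %/% 2L)
  if (n_bins > max_bins) {
    warning("more bins than the gene universe supports; reducing to ",
            max_bins, " bins")
    n_bins <- max_bins
  }
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bin) <- genes
  ctrl <- with_rng(seed, {
    unlist(lapply(present, function(g) {
      pool <- setdiff(genes[bin == bin[[g]]], present)
      if (length(pool) == 0) {
        stop_invalid("no control candidates in the bin of gene ", g)
      }
      sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    }), use.names = FALSE)
  })
  set_mean <- Matrix::colMeans(norm[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(norm[ctrl, , drop = FALSE])
  stats::setNames(as.numeric(set_mean - ctrl_mean), colnames(norm))
}

#' Pseudo-bulk aggregation of single-cell counts
#'
#' Sums counts per gene within each sample.
#'
#' @param counts Genes x cells matrix (dense or sparse).
#' @param sample_labels Per-cell sample labels (no missing values).
#' @return Dense genes x samples matrix; columns in sorted label order.
#' @export
pseudobulk <- function(counts, sample_labels) {
  if (length(sample_labels) != ncol(counts)) {
    stop_invalid("`sample_labels` must label every cell")
  }
  if (anyNA(sample_labels) || any(!nzchar(sample_labels))) {
    stop_invalid("unlabeled cell(s) in `sample_labels`")
  }
  f <- factor(sample_labels, levels = sort(unique(sample_labels)))
  ind <- Matrix::sparseMatrix(
    i = seq_along(f), j = as.integer(f), x = 1,
    dims = c(length(f), nlevels(f))
  )
  out <- as.matrix(counts %*% ind)
  dimnames(out) <- list(rownames(counts), levels(f))
  out
}
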