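# Reusable association statistics: Spearman correlation, Wilcoxon rank-sum
# group comparison, Fisher's-exact gene-set overlap, over-representation
# enrichment with BH correction, and cluster-vs-rest marker calling.

#' Spearman rank correlation with a t-approximation p-value
#'
#' Pearson correlation of average-ranked data; two-sided p-value from
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 4; neither constant.
#' @return List: `rho`, `p`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("`x` and `y` must have equal length")
  if (length(x) < 4) stop_invalid("need length >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_invalid("correlation undefined for a constant vector")
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  n <- length(x)
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Two-group Wilcoxon rank-sum test
#'
#' Exact enumeration when both groups have at most 8 observations and there
#' are no ties; otherwise the normal approximation with tie correction.
#'
#' @param values Numeric vector.
#' @param groups Two-level grouping (factor or vector) aligned to `values`.
#' @return List: `statistic` (Mann-Whitney U for the first level), `p`
#'   (two-sided), `method`.
#' @export
wilcoxon_two_group <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2) stop_invalid("`groups` must have exactly 2 levels")
  x <- values[g == levels(g)[1]]
  y <- values[g == levels(g)[2]]
  if (length(x) == 0 || length(y) == 0) stop_invalid("both groups must be nonempty")
  if (length(unique(values)) == 1) {
    return(list(statistic = length(x) * length(y) / 2, p = 1,
                method = "degenerate"))
  }
  ties <- anyDuplicated(values) > 0
  exact <- length(x) <= 8 && length(y) <= 8 && !ties
  res <- stats::wilcox.test(x, y, exact = exact, correct = FALSE)
  list(statistic = unname(res$statistic), p = res$p.value,
       method = if (exact) "exact" else "normal")
}

#' Fisher's exact overlap of two gene sets
#'
#' Builds the 2x2 table `(k, |A|-k, |B|-k, N-|A|-|B|+k)` over a finite
#' universe and reports the one-sided enrichment p-value (hypergeometric
#' upper tail) and the sample odds ratio.
#'
#' @param set_a,set_b Character vectors, both subsets of `universe`.
#' @param universe Nonempty character vector.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return Object of class `contingency_summary`: `n_universe`, `size_a`,
#'   `size_b`, `overlap`, `odds_ratio` (NaN and `degenerate = TRUE` when a
#'   margin is empty), `p`.
#' @export
fisher_overlap <- function(set_a, set_b, universe,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- unique(universe)
  if (length(universe) == 0) stop_invalid("`universe` must be nonempty")
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(setdiff(set_a, universe)) > 0 ||
      length(setdiff(set_b, universe)) > 0) {
    stop_invalid("both sets must be subsets of the universe")
  }
  n <- length(universe)
  a <- length(set_a)
  b <- length(set_b)
  k <- length(intersect(set_a, set_b))
  tab <- matrix(c(k, a - k, b - k, n - a - b + k), 2, 2)
  p <- switch(alternative,
    greater = stats::phyper(k - 1, a, n - a, b, lower.tail = FALSE),
    two.sided = stats::fisher.test(tab)$p.value
  )
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  structure(
    list(n_universe = n, size_a = a, size_b = b, overlap = k,
         odds_ratio = or, p = p,
         degenerate = !is.finite(or)),
    class = "contingency_summary"
  )
}

#' @export
print.contingency_summary <- function(x, ...) {
  cat(sprintf(
    "Overlap %d of |A|=%d, |B|=%d in N=%d; OR=%s, p=%.3g%s\n",
    x$overlap, x$size_a, x$size_b, x$n_universe,
    format(x$odds_ratio, digits = 3), x$p,
    if (x$degenerate) " (degenerate margins)" else ""
  ))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `adj_i = min_{j: p_j >= p_i} p_j * m / rank_j`,
#' capped at 1.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Over-representation enrichment of a gene list against pathway sets
#'
#' One [fisher_overlap()] enrichment test per pathway (pathways intersected
#' with the universe), BH adjustment across pathways, and a significance flag
#' at `alpha`.
#'
#' @param gene_list Genes of interest (subset of `universe`).
#' @param pathways Named list of gene vectors (e.g. [read_gmt()] output).
#' @param universe Background gene universe.
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @return Data.frame `pathway`, `n_pathway`, `n_overlap`, `odds_ratio`, `p`,
#'   `p_adj`, `significant`, ordered by `p` then pathway name.
#' @export
ora_enrichment <- function(gene_list, pathways, universe, alpha = 0.05) {
  if (length(pathways) == 0) stop_invalid("empty pathway collection")
  if (is.null(names(pathways)) || anyDuplicated(names(pathways))) {
    stop_invalid("`pathways` must be uniquely named")
  }
  gene_list <- unique(gene_list)
  if (length(setdiff(gene_list, universe)) > 0) {
    stop_invalid("`gene_list` must be a subset of the universe")
  }
  rows <- lapply(names(pathways), function(nm) {
    pw <- intersect(pathways[[nm]], universe)
    ov <- fisher_overlap(gene_list, pw, universe)
    data.frame(pathway = nm, n_pathway = length(pw), n_overlap = ov$overlap,
               odds_ratio = ov$odds_ratio, p = ov$p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- bh_adjust(tab$p)
  tab$significant <- tab$p_adj < alpha
  tab[order(tab$p, tab$pathway), , drop = FALSE]
}

#' Cluster-vs-rest marker genes
#'
#' For each cluster, every gene is tested cluster-vs-rest by the Wilcoxon
#' rank-sum test on normalized values; the average log2 fold change uses the
#' `expm1`-mean convention `log2(mean(expm1(in)) + 1) - log2(mean(expm1(out)) + 1)`
#' consistent with log1p library-size normalization. P-values are BH-adjusted
#' within cluster and a gene passes when `avg_log2FC > lfc_threshold` and
#' `p_adj < alpha`.
#'
#' @param norm Genes x cells normalized matrix.
#' @param clusters Per-cell cluster labels (>= 2 clusters).
#' @param lfc_threshold Average log2 fold-change threshold (default 0.5).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Data.frame `gene`, `cluster`, `avg_log2FC`, `p`, `p_adj`, `pass`.
#' @export
marker_genes <- function(norm, clusters, lfc_threshold = 0.5, alpha = 0.05) {
  if (length(clusters) != ncol(norm)) {
    stop_invalid("`clusters` must label every cell")
  }
  cl <- factor(clusters)
  if (nlevels(cl) < 2) stop_invalid("need >= 2 clusters")
  if (any(table(cl) == 1)) {
    warning("singleton cluster(s) present; normal approximation only")
  }
  norm <- as.matrix(norm)
  out <- lapply(levels(cl), function(cc) {
    inn <- cl == cc
    m_in <- rowMeans(expm1(norm[, inn, drop = FALSE]))
    m_out <- rowMeans(expm1(norm[, !inn, drop = FALSE]))
    lfc <- log2(m_in + 1) - log2(m_out + 1)
    pv <- apply(norm, 1, function(v) {
      wilcoxon_two_group(v, ifelse(inn, "in", "out"))$p
    })
    data.frame(gene = rownames(norm), cluster = cc, avg_log2FC = lfc,
               p = pv, p_adj = bh_adjust(pv), stringsAsFactors = FALSE,
               row.names = NULL)
  })
  tab <- do.call(rbind, out)
  tab$pass <- tab$avg_log2FC > lfc_threshold & tab$p_adj < alpha
  tab
}
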