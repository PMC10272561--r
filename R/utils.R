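# Internal validation and reproducibility helpers.

stop_invalid <- function(...) stop(..., call. = FALSE)

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x %% 1 != 0 || x < min) {
    stop_invalid(sprintf("`%s` must be a single integer >= %s", name, format(min)))
  }
  as.integer(x)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict_lower) x > lower else x >= lower) &&
    (if (strict_upper) x < upper else x <= upper)
  if (!ok) {
    stop_invalid(sprintf(
      "`%s` must be a single number in %s%s, %s%s", name,
      if (strict_lower) "(" else "[", format(lower), format(upper),
      if (strict_upper) ")" else "]"
    ))
  }
  as.numeric(x)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(sprintf("`%s` must be TRUE or FALSE", name))
  }
  x
}

assert_matrix_like <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_invalid(sprintf("`%s` must be a numeric matrix", name))
  }
  if (anyNA(x)) stop_invalid(sprintf("`%s` must not contain missing values", name))
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    stop_invalid(sprintf("`%s` must have unique row names", name))
  }
  if (is.null(colnames(x)) || anyDuplicated(colnames(x))) {
    stop_invalid(sprintf("`%s` must have unique column names", name))
  }
  invisible(x)
}

#' Derive a stable sub-seed from a master seed and a label
#'
#' Fans a single master seed out to independent, reproducible stage or
#' replicate seeds. The mapping is a small deterministic string hash, so the
#' same (seed, label) pair always yields the same sub-seed regardless of the
#' order in which sub-seeds are requested.
#'
#' @param seed Master seed (single integer).
#' @param label Character label naming the consumer (e.g. `"background_size_5"`).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  seed <- assert_count(seed, "seed", min = 0)
  h <- 0
  for (k in utf8ToInt(as.character(label))) h <- (h * 131 + k) %% 1048573
  as.integer((as.numeric(seed) %% 2147000000 + h * 2011 + 1) %% 2147483646) + 1L
}

# Run `expr` under a temporary RNG state seeded with `seed`.
with_rng <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

#' Synthetic gene symbols
#'
#' A deterministic shared symbol universe so that expression matrices, PPI
#' networks and drug-target tables overlap by construction.
#'
#' @param n Number of symbols.
#' @param prefix Symbol prefix.
#' @return Character vector of `n` unique symbols.
#' @export
synthetic_gene_symbols <- function(n, prefix = "SG") {
  n <- assert_count(n, "n")
  sprintf("%s%05d", prefix, seq_len(n))
}
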