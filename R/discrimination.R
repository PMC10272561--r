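# Case/control discrimination of module hub genes: ridge-stabilized logistic
# regression, precision-recall curves (average-precision convention) and
# repeated stratified cross-validation.

#' Cross-validation plan
#'
#' @param k Folds (>= 2; default 5).
#' @param replicates Replicates (default 3).
#' @param stratified Stratify folds by class (default TRUE).
#' @param seed Master seed; each replicate draws a stable sub-seed.
#' @return Object of class `cv_plan`.
#' @export
cv_plan <- function(k = 5, replicates = 3, stratified = TRUE, seed = 1) {
  structure(
    list(k = assert_count(k, "k", min = 2),
         replicates = assert_count(replicates, "replicates"),
         stratified = assert_flag(stratified, "stratified"),
         seed = assert_count(seed, "seed", min = 0)),
    class = "cv_plan"
  )
}

#' Ridge-stabilized logistic regression
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least squares
#' with a tiny ridge penalty on the (internally standardized) coefficients,
#' which keeps separable data finite. Standardization statistics come from
#' the training data only and are stored in the model.
#'
#' @param x Samples x features numeric matrix.
#' @param y 0/1 labels; both classes must be present.
#' @param ridge Ridge penalty (default 1e-6).
#' @param max_iter,tol IRLS iteration cap and penalized-deviance convergence
#'   tolerance.
#' @return Object of class `logistic_model` with a [predict][predict.logistic_model]
#'   method returning class-1 probabilities.
#' @export
logistic_fit <- function(x, y, ridge = 1e-6, max_iter = 200, tol = 1e-8) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop_invalid("`x` and `y` are not aligned")
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2) {
    stop_invalid("`y` must contain both 0 and 1")
  }
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- cbind(1, sweep(sweep(x, 2, center), 2, scale, "/"))
  p <- ncol(xs)
  pen <- diag(c(0, rep(ridge, p - 1)), p)
  beta <- numeric(p)
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(xs %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    h <- crossprod(xs, xs * w) + pen
    beta_new <- drop(solve(h, crossprod(xs, w * z)))
    eta <- drop(xs %*% beta_new)
    log1pexp <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
    dev <- -2 * sum(y * eta - log1pexp) + ridge * sum(beta_new[-1]^2)
    delta <- abs(dev_old - dev) / (abs(dev) + 1e-10)
    beta <- beta_new
    if (delta < tol) {
      return(structure(
        list(coefficients = beta[-1], intercept = beta[1],
             center = center, scale = scale, iterations = it,
             deviance = dev),
        class = "logistic_model"
      ))
    }
    dev_old <- dev
  }
  stop_invalid(sprintf(
    "IRLS did not converge in %d iterations (last relative deviance change %.3g)",
    max_iter, delta
  ))
}

#' @export
predict.logistic_model <- function(object, newdata, ...) {
  x <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, "/")
  stats::plogis(drop(object$intercept + x %*% object$coefficients))
}

#' Precision-recall curve and its area (average precision)
#'
#' Thresholds are placed at every distinct score, descending, with tied
#' scores grouped at a single threshold. The area follows the step-wise
#' average-precision rule `sum_i (R_i - R_{i-1}) * P_i` (no interpolation).
#'
#' @param scores Numeric decision scores (higher = more case-like).
#' @param labels 0/1 labels; at least one positive and one negative.
#' @return Object of class `pr_curve`: `points` (data.frame `threshold`,
#'   `recall`, `precision`) and `area`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop_invalid("scores/labels mismatch")
  if (!all(labels %in% c(0, 1))) stop_invalid("labels must be 0/1")
  pos <- sum(labels == 1)
  if (pos == 0) stop_invalid("no positive labels")
  if (pos == length(labels)) stop_invalid("no negative labels")
  ord <- order(-scores)
  s <- scores[ord]
  l <- labels[ord]
  last_of_group <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(l)[last_of_group]
  fp <- cumsum(1 - l)[last_of_group]
  recall <- tp / pos
  precision <- tp / (tp + fp)
  area <- sum(diff(c(0, recall)) * precision)
  structure(
    list(points = data.frame(threshold = s[last_of_group],
                             recall = recall, precision = precision),
         area = area),
    class = "pr_curve"
  )
}

#' @export
print.pr_curve <- function(x, ...) {
  cat("Precision-recall curve with", nrow(x$points),
      "thresholds; AUPRC =", format(x$area, digits = 4), "\n")
  invisible(x)
}

# Stratified (or plain) fold assignment; re-drawn up to 10 times if some
# fold misses a class.
assign_folds <- function(y, k, stratified, seed) {
  n <- length(y)
  for (attempt in seq_len(10)) {
    folds <- with_rng(seed + attempt - 1L, {
      f <- integer(n)
      if (stratified) {
        for (cls in unique(y)) {
          idx <- which(y == cls)
          f[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
        }
      } else {
        f <- sample(rep(seq_len(k), length.out = n))
      }
      f
    })
    ok <- all(vapply(seq_len(k), function(i) {
      length(unique(y[folds != i])) == 2 && sum(folds == i) > 0
    }, logical(1)))
    if (ok) {
      if (attempt > 1) warning("fold assignment re-drawn (", attempt - 1,
                               " draws missed a class)")
      return(folds)
    }
  }
  stop_invalid("could not build folds containing both classes in 10 attempts")
}

#' Repeated cross-validated AUPRC
#'
#' Per replicate, samples are assigned to stratified folds under a
#' replicate-specific sub-seed; out-of-fold predicted probabilities are
#' pooled into one precision-recall curve per replicate, and the median area
#' over replicates is reported.
#'
#' @param x Samples x features matrix (e.g. hub-gene expression).
#' @param y 0/1 labels.
#' @param plan A [cv_plan()].
#' @param ridge Ridge passed to [logistic_fit()].
#' @return List: `median_auprc`, `replicate_auprc` (numeric vector),
#'   `folds` (data.frame `replicate`, `fold`, `n_test`).
#' @export
repeated_cv_auprc <- function(x, y, plan = cv_plan(), ridge = 1e-6) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) < 2 * plan$k) stop_invalid("need n >= 2k samples")
  rep_area <- numeric(plan$replicates)
  fold_rows <- list()
  for (r in seq_len(plan$replicates)) {
    sub <- derive_seed(plan$seed, paste0("cv_replicate_", r))
    folds <- assign_folds(y, plan$k, plan$stratified, sub)
    pred <- numeric(length(y))
    for (i in seq_len(plan$k)) {
      test <- folds == i
      fit <- logistic_fit(x[!test, , drop = FALSE], y[!test], ridge = ridge)
      pred[test] <- predict(fit, x[test, , drop = FALSE])
      fold_rows[[length(fold_rows) + 1L]] <-
        data.frame(replicate = r, fold = i, n_test = sum(test))
    }
    rep_area[r] <- auprc(pred, y)$area
  }
  list(median_auprc = stats::median(rep_area),
       replicate_auprc = rep_area,
       folds = do.call(rbind, fold_rows))
}

#' AUPRC of every retained module's hubs
#'
#' Convenience wrapper reproducing the module-ranking step: for each retained
#' module, its hub genes' expression is used as features in
#' [repeated_cv_auprc()].
#'
#' @param fit A [coexpression_chain()] result.
#' @param plan A [cv_plan()].
#' @return Data.frame `module`, `n_hubs`, `median_auprc`, ordered by
#'   decreasing median AUPRC.
#' @export
module_discrimination <- function(fit, plan = cv_plan()) {
  rows <- lapply(names(fit$hubs), function(m) {
    feats <- t(fit$expr[fit$hubs[[m]], , drop = FALSE])
    cv <- repeated_cv_auprc(feats, fit$trait, plan)
    data.frame(module = m, n_hubs = length(fit$hubs[[m]]),
               median_auprc = cv$median_auprc)
  })
  tab <- do.call(rbind, rows)
  tab[order(-tab$median_auprc, tab$module), , drop = FALSE]
}
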