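#' ROC curve summary of a single marker
#'
#' AUC by the Mann-Whitney U identity (ties counted one half), an
#' operating point chosen by Youden's J, and a p-value from the normal
#' approximation to U (via [stats::wilcox.test()]). Markers that score
#' lower in cases than controls are re-oriented so the reported AUC is
#' `max(auc, 1 - auc)`, with the orientation recorded -- the same miRNA
#' can be up-regulated in one cancer and down-regulated in another.
#'
#' @param scores Numeric per-sample marker values.
#' @param labels Vector distinguishing the classes: either a logical
#'   (TRUE = case) or a character/factor containing `"case"` entries.
#' @return A list of class `roc_result`: `auc` (oriented), `auc_raw`,
#'   `direction` (`">"` if cases score higher), `sensitivity`,
#'   `specificity`, `threshold`, `p_value`, `n_case`, `n_control`.
#' @examples
#' roc_auc(c(1, 2, 3, 4), c("control", "control", "case", "case"))$auc
#' @export
roc_auc <- function(scores, labels) {
  is_case <- if (is.logical(labels)) labels else labels == "case"
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  if (length(scores) != length(is_case) || anyNA(scores)) {
    stop("scores must match labels and contain no NA", call. = FALSE)
  }
  r <- rank(scores)
  auc_raw <- (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  direction <- if (auc_raw >= 0.5) ">" else "<"
  oriented <- if (direction == ">") scores else -scores
  auc <- max(auc_raw, 1 - auc_raw)

  ## Youden's J over candidate thresholds (midpoints between sorted values)
  s <- sort(unique(oriented))
  thr <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else s
  sens <- vapply(thr, function(th) mean(oriented[is_case] > th), numeric(1))
  spec <- vapply(thr, function(th) mean(oriented[!is_case] <= th), numeric(1))
  best <- which.max(sens + spec - 1)

  p <- suppressWarnings(stats::wilcox.test(
    scores[is_case], scores[!is_case], exact = FALSE,
    correct = FALSE)$p.value)

  structure(list(auc = auc, auc_raw = auc_raw, direction = direction,
                 sensitivity = sens[best], specificity = spec[best],
                 threshold = thr[best], p_value = p,
                 n_case = n1, n_control = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "AUC %.3f (direction %s), sens %.3f / spec %.3f, p = %.3g (%d case / %d control)\n",
    x$auc, x$direction, x$sensitivity, x$specificity, x$p_value,
    x$n_case, x$n_control))
  invisible(x)
}

## Percentile bootstrap CI for the oriented AUC; resamples within class.
boot_auc_ci <- function(scores, is_case, n_boot = 1000, level = 0.95) {
  idx1 <- which(is_case); idx0 <- which(!is_case)
  reps <- vapply(seq_len(n_boot), function(b) {
    i1 <- sample(idx1, length(idx1), replace = TRUE)
    i0 <- sample(idx0, length(idx0), replace = TRUE)
    s <- c(scores[i1], scores[i0])
    lab <- rep(c(TRUE, FALSE), c(length(i1), length(i0)))
    r <- rank(s)
    a <- (sum(r[lab]) - length(i1) * (length(i1) + 1) / 2) /
      (length(i1) * length(i0))
    max(a, 1 - a)
  }, numeric(1))
  stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                  names = FALSE)
}

#' Ridge-logistic panel combiner with cross-validated AUC
#'
#' Combines the panel miRNAs into one diagnostic score: a logistic model
#' on `log2(normalised value + pseudocount)` fitted by penalised maximum
#' likelihood (L2 ridge, default 1e-3 -- enough to tame complete
#' separation without materially shrinking the weights). Performance is
#' the mean AUC over stratified k-fold cross-validation; the returned
#' scores and weights come from a fit on all samples.
#'
#' @param values Numeric matrix, panel features x samples, of normalised
#'   counts (at least 2 features).
#' @param labels Class labels as in [roc_auc()].
#' @param seed Optional integer seed for the fold assignment.
#' @param pseudocount Added before the log transform.
#' @param ridge L2 penalty passed to [glmnet::glmnet()] as `lambda`.
#' @param nfolds Folds for cross-validation (reduced to the minority class
#'   size when needed so every fold holds both classes).
#' @return A list of class `panel_combiner`: `weights` (named, including
#'   the intercept), `scores` (full-data linear predictor), `cv_auc`,
#'   `fold_auc`, `nfolds`.
#' @export
fit_panel_combiner <- function(values, labels, seed = NULL,
                               pseudocount = 1, ridge = 1e-3, nfolds = 5) {
  if (nrow(values) < 2) {
    stop("panel combiner needs at least 2 features", call. = FALSE)
  }
  is_case <- if (is.logical(labels)) labels else labels == "case"
  if (!any(is_case) || all(is_case)) {
    stop("both classes must be present", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  x <- t(log2(values + pseudocount))
  y <- factor(is_case, levels = c(FALSE, TRUE))

  fit_one <- function(xtr, ytr) {
    glmnet::glmnet(xtr, ytr, family = "binomial", alpha = 0,
                   lambda = ridge, standardize = FALSE)
  }
  full <- fit_one(x, y)
  beta <- as.numeric(stats::coef(full))
  names(beta) <- rownames(stats::coef(full))
  scores <- drop(stats::predict(full, x))

  nfolds <- min(nfolds, sum(is_case), sum(!is_case))
  fold <- integer(length(is_case))
  fold[is_case] <- sample(rep_len(seq_len(nfolds), sum(is_case)))
  fold[!is_case] <- sample(rep_len(seq_len(nfolds), sum(!is_case)))
  fold_auc <- vapply(seq_len(nfolds), function(k) {
    test <- fold == k
    f <- fit_one(x[!test, , drop = FALSE], y[!test])
    pred <- drop(stats::predict(f, x[test, , drop = FALSE]))
    roc_auc(pred, is_case[test])$auc_raw
  }, numeric(1))

  structure(list(weights = beta, scores = scores,
                 cv_auc = mean(pmax(fold_auc, 1 - fold_auc)),
                 fold_auc = fold_auc, nfolds = nfolds),
            class = "panel_combiner")
}

#' @export
print.panel_combiner <- function(x, ...) {
  cat(sprintf("panel combiner: %d-fold CV AUC %.3f\n", x$nfolds, x$cv_auc))
  invisible(x)
}

#' Explained-variance fractions from PCA
#'
#' Fractions of total variance carried by the principal components of the
#' column-centred sample matrix (samples as observations, features as
#' variables), computed from the singular values. Fractions are
#' non-increasing and sum to 1 when all components are requested.
#'
#' @param values Numeric matrix, features x samples (at least 2 samples).
#' @param n_components How many leading fractions to return (default all).
#' @return Numeric vector of explained-variance fractions.
#' @export
pca_variance <- function(values, n_components = NULL) {
  if (ncol(values) < 2) stop("need at least 2 samples", call. = FALSE)
  X <- t(values)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  d <- svd(Xc, nu = 0, nv = 0)$d
  tot <- sum(d^2)
  k <- min(dim(Xc))
  if (tot <= 1e-12 * length(Xc)) {
    warning("constant matrix: no variance to explain")
    frac <- rep(0, k)
  } else {
    frac <- d^2 / tot
  }
  if (!is.null(n_components)) frac <- frac[seq_len(min(n_components,
                                                       length(frac)))]
  frac
}
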