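#' Per-timepoint log2 fold changes against the overall mean
#'
#' For each miRNA, every time point's mean normalised count is compared to
#' the mean normalised count over all samples:
#' `X_t = log2((mean at t + pseudocount) / (overall mean + pseudocount))`.
#' The resulting vector X (one entry per time point, ordered by ascending
#' hours) is the series the MAD stability score summarises.
#'
#' @param nm A `normalized_matrix` of the healthy time course.
#' @param st Matching sample table with `timepoint_h` set for all samples.
#' @param pseudocount Added to both means before the ratio.
#' @return Numeric matrix, features x time points; columns named
#'   `log2fc_<t>h`.
#' @export
timepoint_log2fc <- function(nm, st, pseudocount = 1) {
  stopifnot(inherits(nm, "normalized_matrix"))
  validate_sample_table(st)
  st <- st[match(nm$sample_ids, st$sample_id), , drop = FALSE]
  if (anyNA(st$sample_id) || anyNA(st$timepoint_h)) {
    stop("every matrix sample needs a row with timepoint_h set", call. = FALSE)
  }
  tps <- sort(unique(st$timepoint_h))
  if (length(tps) < 2) stop("need at least 2 time points", call. = FALSE)
  overall <- rowMeans(nm$values)
  X <- vapply(tps, function(tp) {
    idx <- which(st$timepoint_h == tp)
    if (length(idx) == 0) stop("time point ", tp, " h has no samples",
                               call. = FALSE)
    log2((rowMeans(nm$values[, idx, drop = FALSE]) + pseudocount) /
           (overall + pseudocount))
  }, numeric(nrow(nm$values)))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  dimnames(X) <- list(nm$feature_ids, sprintf("log2fc_%gh", tps))
  X
}

#' MAD stability score
#'
#' The scaled median absolute deviation
#' `b * median(|X - median(X)|)`; with the default `b = 1.4826` the score
#' is a consistent estimate of the standard deviation under normality.
#' Medians of even-length vectors use the midpoint of the two central
#' order statistics, so scores are reproducible bit for bit.
#'
#' @param x Non-empty numeric vector (a miRNA's per-timepoint log2 fold
#'   changes).
#' @param b Consistency constant.
#' @return Non-negative scalar.
#' @examples
#' mad_score(c(-0.2, -0.1, 0, 0.1, 0.2))  # 1.4826 * 0.1
#' @export
mad_score <- function(x, b = 1.4826) {
  if (length(x) == 0 || anyNA(x)) {
    stop("x must be a non-empty numeric vector without NA", call. = FALSE)
  }
  b * stats::median(abs(x - stats::median(x)))
}

#' Threshold window around the median
#'
#' The interval `median(X) +/- k * MAD(X)` within which a miRNA's fold
#' changes are considered ordinary; values strictly outside it are
#' outliers.
#'
#' @param x Non-empty numeric vector.
#' @param b MAD consistency constant.
#' @param k Window half-width in MAD units.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
threshold_window <- function(x, b = 1.4826, k = 3) {
  m <- stats::median(x)
  h <- k * mad_score(x, b)
  c(lower = m - h, upper = m + h)
}

#' Select stable miRNAs
#'
#' @param profiles A stability data frame (from [stability_profiles()]) or
#'   any data frame with columns `feature_id` and `mad`.
#' @param mad_cutoff Stability cutoff; the comparison is strict
#'   (`mad < mad_cutoff`), so a MAD exactly at the cutoff is excluded.
#' @return Character vector of stable feature ids.
#' @export
select_stable <- function(profiles, mad_cutoff = 0.2) {
  stopifnot(is.data.frame(profiles),
            all(c("feature_id", "mad") %in% names(profiles)))
  profiles$feature_id[profiles$mad < mad_cutoff]
}

#' Cluster temporal profiles
#'
#' Groups miRNAs by the similarity of their per-timepoint log2 fold-change
#' vectors: agglomerative hierarchical clustering (Euclidean distance,
#' Ward linkage) cut at `k` groups. Average linkage chains heavy-tailed
#' profile sets into one blob plus singletons, so Ward's minimum-variance
#' criterion is used instead. The procedure is deterministic;
#' `seed` is accepted for interface uniformity but unused. Identical
#' profiles (all-zero distances) are split arbitrarily but reproducibly by
#' the merge order.
#'
#' @param X Features x time points matrix of log2 fold changes.
#' @param k Number of clusters (2 <= k <= number of features).
#' @param seed Ignored; the algorithm is deterministic.
#' @return Integer cluster labels named by feature. The label of the
#'   cluster with the lowest mean MAD -- the "stable cluster" -- is
#'   attached as attribute `"stable_cluster"`.
#' @export
cluster_profiles <- function(X, k, seed = NULL) {
  if (k < 2 || k > nrow(X)) {
    stop("k must satisfy 2 <= k <= number of features", call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  names(labels) <- rownames(X)
  mads <- apply(X, 1, mad_score)
  cluster_mad <- tapply(mads, labels, mean)
  attr(labels, "stable_cluster") <-
    as.integer(names(cluster_mad)[which.min(cluster_mad)])
  labels
}

#' Single-component cosinor fit
#'
#' Least-squares fit of `y = M + A cos(2 pi (t - phi) / tau)` via the
#' linear parameterisation `y = M + beta cos(2 pi t / tau) +
#' gamma sin(2 pi t / tau)`, with `A = sqrt(beta^2 + gamma^2)` and the
#' acrophase `phi = (tau / 2 pi) atan2(gamma, beta)` folded into
#' `[0, tau)`. The zero-amplitude (no-rhythm) test is the F test of
#' `beta = gamma = 0` against the intercept-only model.
#'
#' @param y Numeric measurements (at least 4).
#' @param times_h Observation times in hours, same length as `y`.
#' @param period_h Assumed rhythm period (hours).
#' @return A list of class `cosinor_fit`: `mesor`, `amplitude`,
#'   `acrophase_h`, `period_h`, `p_amplitude`.
#' @examples
#' t <- seq(0, 21, by = 3)
#' f <- cosinor_fit(5 + 2 * cos(2 * pi * t / 24), t, 24)
#' c(f$mesor, f$amplitude, f$acrophase_h)
#' @export
cosinor_fit <- function(y, times_h, period_h = 24) {
  if (length(y) != length(times_h)) {
    stop("y and times_h must have equal length", call. = FALSE)
  }
  if (length(y) < 4) {
    stop("cosinor fit needs at least 4 observations (3 parameters)",
         call. = FALSE)
  }
  if (period_h <= 0) stop("period_h must be > 0", call. = FALSE)
  cb <- cos(2 * pi * times_h / period_h)
  sb <- sin(2 * pi * times_h / period_h)
  fit <- stats::lm(y ~ cb + sb)
  co <- stats::coef(fit)
  co[is.na(co)] <- 0
  amplitude <- sqrt(co[["cb"]]^2 + co[["sb"]]^2)
  acrophase <- (atan2(co[["sb"]], co[["cb"]]) * period_h / (2 * pi)) %% period_h
  if (period_h - acrophase < 1e-9 * period_h) acrophase <- 0
  rss1 <- sum(stats::residuals(fit)^2)
  rss0 <- sum((y - mean(y))^2)
  df2 <- stats::df.residual(fit)
  eps <- 1e-12 * max(rss0, 1)
  if (rss0 - rss1 <= eps) {
    p <- 1                      # no rhythmic variance explained
  } else if (rss1 <= eps || df2 < 1) {
    p <- 0                      # noiseless rhythm, F unbounded
  } else {
    f <- ((rss0 - rss1) / 2) / (rss1 / df2)
    p <- stats::pf(f, 2, df2, lower.tail = FALSE)
  }
  structure(list(mesor = unname(co[["(Intercept)"]]),
                 amplitude = unname(amplitude),
                 acrophase_h = unname(acrophase),
                 period_h = period_h,
                 p_amplitude = p),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "cosinor fit (period %g h): mesor %.4g, amplitude %.4g, acrophase %.4g h, p(no rhythm) = %.3g\n",
    x$period_h, x$mesor, x$amplitude, x$acrophase_h, x$p_amplitude))
  invisible(x)
}

#' Full stability profiling of a healthy time course
#'
#' Chains the step-one analyses: per-timepoint log2 fold changes, MAD
#' score, median +/- k x MAD threshold window, stable flag, temporal
#' clustering, and a cosinor rhythm check. The cosinor fit runs by default
#' on the per-sample log2 normalised values of the time points within the
#' first `rhythm_max_h` hours (default 72 h) -- a circadian-scale rhythm
#' is not identifiable from single samples taken weeks apart -- with the
#' full series available via `rhythm_max_h = Inf`.
#'
#' @param nm A `normalized_matrix` of the healthy time course (after
#'   expression filtering).
#' @param st Matching sample table.
#' @param config A [pipeline_config()].
#' @param rhythm_max_h Latest time point (hours) entering the cosinor fit.
#' @param cosinor_on `"samples"` fits the rhythm to per-sample log2
#'   normalised values; `"timepoints"` to the per-timepoint fold-change
#'   series X.
#' @return A data frame with one row per miRNA: `feature_id`, the X
#'   columns `log2fc_<t>h`, `median_fc`, `mad`, `lower`, `upper`,
#'   `stable`, `cluster`, `cosinor_amplitude`, `cosinor_acrophase_h`,
#'   `cosinor_p`. The stable-cluster label is attached as attribute
#'   `"stable_cluster"`.
#' @export
stability_profiles <- function(nm, st, config = pipeline_config(),
                               rhythm_max_h = 72,
                               cosinor_on = c("samples", "timepoints")) {
  stopifnot(inherits(nm, "normalized_matrix"),
            inherits(config, "pipeline_config"))
  cosinor_on <- match.arg(cosinor_on)
  X <- timepoint_log2fc(nm, st, pseudocount = config$pseudocount)
  med <- apply(X, 1, stats::median)
  mad <- apply(X, 1, mad_score, b = config$mad_b)
  lower <- med - config$window_k * mad
  upper <- med + config$window_k * mad

  if (nrow(X) >= config$n_clusters && config$n_clusters >= 2) {
    cl <- cluster_profiles(X, config$n_clusters)
    stable_cluster <- attr(cl, "stable_cluster")
  } else {
    cl <- rep(NA_integer_, nrow(X))
    stable_cluster <- NA_integer_
  }

  st2 <- st[match(nm$sample_ids, st$sample_id), , drop = FALSE]
  tps <- sort(unique(st2$timepoint_h))
  if (cosinor_on == "samples") {
    keep <- which(st2$timepoint_h <= rhythm_max_h)
    times <- st2$timepoint_h[keep]
    series <- log2(nm$values[, keep, drop = FALSE] + config$pseudocount)
  } else {
    keep <- which(tps <= rhythm_max_h)
    times <- tps[keep]
    series <- X[, keep, drop = FALSE]
  }
  cos_fit <- apply(series, 1, function(y)
    cosinor_fit(y, times, period_h = config$cosinor_period_h))

  out <- data.frame(
    feature_id = nm$feature_ids,
    X,
    median_fc = med,
    mad = mad,
    lower = lower,
    upper = upper,
    stable = mad < config$mad_cutoff,
    cluster = as.integer(cl),
    cosinor_amplitude = vapply(cos_fit, `[[`, numeric(1), "amplitude"),
    cosinor_acrophase_h = vapply(cos_fit, `[[`, numeric(1), "acrophase_h"),
    cosinor_p = vapply(cos_fit, `[[`, numeric(1), "p_amplitude"),
    row.names = NULL,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  attr(out, "stable_cluster") <- stable_cluster
  out
}
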