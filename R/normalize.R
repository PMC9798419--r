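#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference features
#' of `count / geometric mean of that feature across samples`. The
#' reference set is the features with strictly positive counts in every
#' sample, so no log of zero enters the geometric means. Dividing each
#' column by its factor puts samples on a common scale regardless of
#' sequencing depth.
#'
#' @param m A count matrix (features x samples).
#' @return Named numeric vector of positive per-sample factors.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 3,
#'             dimnames = list(paste0("miR-", 1:3), c("a", "b")))
#' size_factors(m)  # b is twice a
#' @export
size_factors <- function(m) {
  validate_count_matrix(m)
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref)) {
    stop("no feature has positive counts in every sample; ",
         "filter empty features/samples before normalising", call. = FALSE)
  }
  refm <- m[ref, , drop = FALSE]
  geo <- exp(rowMeans(log(refm)))
  sf <- apply(refm / geo, 2, stats::median)
  stats::setNames(sf, colnames(m))
}

#' Normalise a count matrix by median-of-ratios size factors
#'
#' @param m A count matrix.
#' @return A list of class `normalized_matrix` with elements `values`
#'   (features x samples, `counts / size_factor`), `size_factors`,
#'   `feature_ids` and `sample_ids`.
#' @seealso [size_factors()]
#' @export
normalize_counts <- function(m) {
  sf <- size_factors(m)
  values <- sweep(m, 2, sf, "/")
  structure(list(values = values, size_factors = sf,
                 feature_ids = rownames(m), sample_ids = colnames(m)),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("size factors: ", paste(signif(utils::head(x$size_factors, 5), 4),
                              collapse = ", "),
      if (length(x$size_factors) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

## Subset a normalized_matrix to a feature set (order of `ids` kept).
subset_features <- function(nm, ids) {
  stopifnot(inherits(nm, "normalized_matrix"))
  missing_ids <- setdiff(ids, nm$feature_ids)
  if (length(missing_ids)) {
    stop("unknown feature id(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  nm$values <- nm$values[ids, , drop = FALSE]
  nm$feature_ids <- ids
  nm
}

#' Drop features with low mean normalised expression
#'
#' Keeps features whose mean normalised value across all samples is at
#' least `min_mean`; low-expressed features are a major source of
#' false-positive fold changes.
#'
#' @param nm A `normalized_matrix`.
#' @param min_mean Minimum mean normalised count (default 20).
#' @return The filtered `normalized_matrix`; discarded ids are attached as
#'   attribute `"discarded"`.
#' @export
filter_low_expression <- function(nm, min_mean = 20) {
  stopifnot(inherits(nm, "normalized_matrix"))
  if (min_mean <= 0) stop("min_mean must be > 0", call. = FALSE)
  keep <- rowMeans(nm$values) >= min_mean
  out <- subset_features(nm, nm$feature_ids[keep])
  attr(out, "discarded") <- nm$feature_ids[!keep]
  out
}

#' Features expressed at every time point
#'
#' Returns the ids whose mean normalised value within every time-point
#' group reaches `min_mean` -- the operational reading of "expressed in
#' all time points" for a healthy time course.
#'
#' @param nm A `normalized_matrix` of the healthy time course.
#' @param st Matching sample table with `timepoint_h` set.
#' @param min_mean Per-time-point mean threshold (default 20).
#' @return Character vector of feature ids.
#' @export
common_features <- function(nm, st, min_mean = 20) {
  stopifnot(inherits(nm, "normalized_matrix"))
  validate_sample_table(st)
  st <- st[match(nm$sample_ids, st$sample_id), , drop = FALSE]
  if (anyNA(st$sample_id)) {
    stop("sample table does not cover all matrix samples", call. = FALSE)
  }
  tps <- sort(unique(st$timepoint_h))
  if (length(tps) == 0 || anyNA(tps)) {
    stop("healthy time-course samples must have timepoint_h", call. = FALSE)
  }
  ok <- rep(TRUE, nrow(nm$values))
  for (tp in tps) {
    idx <- which(st$timepoint_h == tp)
    if (length(idx) == 0) stop("time point ", tp, " h has no samples",
                               call. = FALSE)
    ok <- ok & rowMeans(nm$values[, idx, drop = FALSE]) >= min_mean
  }
  nm$feature_ids[ok]
}
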