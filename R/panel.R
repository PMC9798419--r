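#' Is a fold change outside its threshold window?
#'
#' A fold change counts as an outlier only when it lies strictly outside
#' the closed window `[lower, upper]` -- values on the border are inside,
#' the conservative tie rule.
#'
#' @param fc Numeric fold change(s); `NA` propagates.
#' @param window Numeric `c(lower, upper)` with `lower <= upper`.
#' @return Logical, same length as `fc`.
#' @export
is_outlier <- function(fc, window) {
  lower <- window[[1]]; upper <- window[[2]]
  if (is.na(lower) || is.na(upper) || lower > upper) {
    stop("window must satisfy lower <= upper", call. = FALSE)
  }
  fc < lower | fc > upper
}

#' Distance of a fold change from the threshold window
#'
#' Zero on the closed window; otherwise the distance to the nearer border.
#' Continuous in `fc`.
#'
#' @inheritParams is_outlier
#' @return Non-negative numeric, same length as `fc`.
#' @export
window_distance <- function(fc, window) {
  lower <- window[[1]]; upper <- window[[2]]
  if (is.na(lower) || is.na(upper) || lower > upper) {
    stop("window must satisfy lower <= upper", call. = FALSE)
  }
  pmax(lower - fc, fc - upper, 0)
}

#' Outlier fraction of one candidate across datasets
#'
#' Counts the datasets in which the candidate is present, significant
#' (BH-adjusted p below `fdr_alpha`) and outside its healthy threshold
#' window, over the datasets in which it is present. When `adj_p` is
#' `NULL` (worked-example mode with published fold changes only) the
#' significance gate is skipped and the denominator is every dataset with
#' a fold change.
#'
#' @param fc Named numeric vector of per-dataset log2 fold changes (`NA` =
#'   absent from that dataset).
#' @param window Numeric `c(lower, upper)`.
#' @param adj_p Optional vector of BH-adjusted p-values aligned with `fc`.
#' @param fdr_alpha Significance gate.
#' @return List: `fraction`, `n_outlier`, `n_present`.
#' @export
outlier_fraction <- function(fc, window, adj_p = NULL, fdr_alpha = 0.05) {
  present <- !is.na(fc)
  if (!any(present)) {
    stop("candidate is absent from every dataset", call. = FALSE)
  }
  out <- is_outlier(fc, window)
  if (!is.null(adj_p)) {
    out <- out & !is.na(adj_p) & adj_p < fdr_alpha
  }
  n_out <- sum(out[present])
  list(fraction = n_out / sum(present),
       n_outlier = n_out,
       n_present = sum(present))
}

#' Select the pan-cancer panel
#'
#' For every stable candidate, counts the cancer datasets in which its
#' fold change escapes the healthy threshold window (gated on BH-adjusted
#' significance when available), ranks candidates by their mean distance
#' from the window, and selects those outside the window in strictly more
#' than `min_outlier_fraction` of datasets.
#'
#' @param windows Data frame with columns `feature_id`, `lower`, `upper`
#'   for the stable candidates.
#' @param fc Numeric matrix, candidates x datasets, of per-dataset log2
#'   fold changes (`NA` where a candidate is absent after filtering;
#'   absent datasets are excluded from the denominator).
#' @param adj_p Optional matrix of BH-adjusted p-values aligned with `fc`;
#'   `NULL` skips the significance gate.
#' @param config A [pipeline_config()] supplying `min_outlier_fraction`
#'   and `fdr_alpha`.
#' @return A list of class `panel_report`: `table` (one row per candidate,
#'   sorted by `rank_score` descending: `feature_id`, `lower`, `upper`,
#'   `n_datasets_present`, `n_outlier`, `outlier_fraction`, `rank_score`,
#'   `selected`), plus the `outlier` and `distance` matrices and the input
#'   `fc`/`adj_p`.
#' @examples
#' ref <- panel_reference()
#' rep <- select_panel(ref$windows, ref$log2fc)
#' rep$table[, c("feature_id", "outlier_fraction", "selected")]
#' @export
select_panel <- function(windows, fc, adj_p = NULL,
                         config = pipeline_config()) {
  stopifnot(is.data.frame(windows),
            all(c("feature_id", "lower", "upper") %in% names(windows)),
            inherits(config, "pipeline_config"))
  if (nrow(windows) == 0) {
    warning("empty stable set: nothing to select")
    empty <- data.frame(feature_id = character(0), lower = numeric(0),
                        upper = numeric(0), n_datasets_present = integer(0),
                        n_outlier = integer(0), outlier_fraction = numeric(0),
                        rank_score = numeric(0), selected = logical(0))
    return(structure(list(table = empty, outlier = NULL, distance = NULL,
                          fc = fc, adj_p = adj_p),
                     class = "panel_report"))
  }
  ids <- windows$feature_id
  fc <- fc[ids, , drop = FALSE]
  if (!is.null(adj_p)) adj_p <- adj_p[ids, , drop = FALSE]

  out_mat <- matrix(NA, nrow(fc), ncol(fc), dimnames = dimnames(fc))
  dist_mat <- out_mat
  n_present <- integer(nrow(fc))
  n_out <- integer(nrow(fc))
  frac <- numeric(nrow(fc))
  rank_score <- numeric(nrow(fc))
  for (i in seq_len(nrow(fc))) {
    w <- c(windows$lower[i], windows$upper[i])
    row_fc <- fc[i, ]
    present <- !is.na(row_fc)
    n_present[i] <- sum(present)
    if (n_present[i] == 0) {
      frac[i] <- NA_real_
      rank_score[i] <- NA_real_
      next
    }
    o <- is_outlier(row_fc, w)
    if (!is.null(adj_p)) o <- o & !is.na(adj_p[i, ]) & adj_p[i, ] <
        config$fdr_alpha
    out_mat[i, ] <- o
    dist_mat[i, ] <- window_distance(row_fc, w)
    n_out[i] <- sum(o[present])
    frac[i] <- n_out[i] / n_present[i]
    rank_score[i] <- mean(dist_mat[i, present])
  }
  tab <- data.frame(
    feature_id = ids,
    lower = windows$lower,
    upper = windows$upper,
    n_datasets_present = n_present,
    n_outlier = n_out,
    outlier_fraction = frac,
    rank_score = rank_score,
    selected = !is.na(frac) & frac > config$min_outlier_fraction,
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$rank_score, tab$feature_id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, outlier = out_mat, distance = dist_mat,
                 fc = fc, adj_p = adj_p),
            class = "panel_report")
}

#' @export
print.panel_report <- function(x, ...) {
  sel <- x$table$feature_id[x$table$selected]
  cat(sprintf("panel_report: %d candidate(s), %d selected\n",
              nrow(x$table), length(sel)))
  if (length(sel)) cat("selected:", paste(sel, collapse = ", "), "\n")
  invisible(x)
}
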