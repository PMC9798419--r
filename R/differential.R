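#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment controlling the false discovery rate: p-values are
#' sorted ascending, `q_i = p_(i) * m / i`, monotonicity is enforced from
#' the largest rank down, values are capped at 1 and returned in the
#' original order. Delegates to [stats::p.adjust()] after validating the
#' input.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  if (any(is.na(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Case/control differential expression for one dataset
#'
#' Per miRNA: `log2fc = log2((mean_case + pc) / (mean_control + pc))` on
#' normalised values; the p-value comes from Welch's unequal-variance t
#' test on `log2(value + pc)`, and `adj_p` from [bh_adjust()] across the
#' dataset's features. This light-weight stage supplies exactly the two
#' quantities the panel-selection step consumes -- a per-dataset log2 fold
#' change and an FDR-adjusted p-value.
#'
#' Degenerate features (zero variance in both groups) get p = 1 when the
#' group means agree and p = 0 otherwise.
#'
#' @param nm A `normalized_matrix` of one cancer dataset (after
#'   expression filtering).
#' @param st Matching sample table with conditions `case` and `control`.
#' @param pseudocount Added to means and values before logs.
#' @return Data frame of per-feature records: `feature_id`, `dataset_id`,
#'   `base_mean`, `log2fc`, `p_value`, `adj_p`.
#' @export
de_test <- function(nm, st, pseudocount = 1) {
  stopifnot(inherits(nm, "normalized_matrix"))
  validate_sample_table(st)
  st <- st[match(nm$sample_ids, st$sample_id), , drop = FALSE]
  dataset <- unique(st$dataset_id)
  if (length(dataset) != 1) {
    stop("de_test expects a single dataset; got: ",
         paste(dataset, collapse = ", "), call. = FALSE)
  }
  case <- which(st$condition == "case")
  ctrl <- which(st$condition == "control")
  if (length(case) < 3 || length(ctrl) < 3) {
    stop(sprintf("dataset '%s' needs >= 3 case and >= 3 control samples",
                 dataset), call. = FALSE)
  }
  v <- nm$values
  mean_case <- rowMeans(v[, case, drop = FALSE])
  mean_ctrl <- rowMeans(v[, ctrl, drop = FALSE])
  log2fc <- log2((mean_case + pseudocount) / (mean_ctrl + pseudocount))

  lv <- log2(v + pseudocount)
  m1 <- rowMeans(lv[, case, drop = FALSE])
  m0 <- rowMeans(lv[, ctrl, drop = FALSE])
  n1 <- length(case); n0 <- length(ctrl)
  v1 <- rowSums((lv[, case, drop = FALSE] - m1)^2) / (n1 - 1)
  v0 <- rowSums((lv[, ctrl, drop = FALSE] - m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  tstat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m0[degenerate], 1, 0)

  data.frame(
    feature_id = nm$feature_ids,
    dataset_id = dataset,
    base_mean = rowMeans(v),
    log2fc = log2fc,
    p_value = p,
    adj_p = bh_adjust(p),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
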