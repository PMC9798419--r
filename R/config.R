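#' Pipeline configuration
#'
#' Bundles every tunable constant of the discovery pipeline. Defaults are
#' the values used throughout: the Gaussian-consistency MAD constant
#' b = 1.4826, +/- 3 x MAD threshold windows, a MAD < 0.2 stability cutoff,
#' a mean-normalised-count >= 20 expression filter, and selection of
#' candidates outside their window in strictly more than 80% of datasets at
#' BH-adjusted p < 0.05.
#'
#' @param pseudocount Positive value added to numerator and denominator
#'   means before any log2 ratio. With the mean >= 20 expression filter a
#'   pseudocount of 1 perturbs fold changes by under 5%.
#' @param min_mean_count Features with mean normalised count below this are
#'   discarded to avoid false positives.
#' @param mad_b Consistency constant of the MAD scale estimator; 1.4826
#'   makes the MAD estimate the standard deviation under normality.
#' @param window_k Half-width of the threshold window in MAD units.
#' @param mad_cutoff A miRNA is called stable when its MAD is strictly
#'   below this value (log2 units).
#' @param min_outlier_fraction A stable candidate is selected for the panel
#'   when its outlier fraction across cancer datasets is strictly greater
#'   than this.
#' @param fdr_alpha BH-adjusted p-value threshold gating the per-dataset
#'   outlier calls.
#' @param n_clusters Number of temporal-profile clusters.
#' @param cosinor_period_h Period (hours) of the cosinor rhythm fit.
#' @param rng_seed Integer seed controlling every stochastic step of a run.
#'
#' @return A list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(mad_cutoff = 0.2)
#' cfg$window_k
#' @export
pipeline_config <- function(pseudocount = 1,
                            min_mean_count = 20,
                            mad_b = 1.4826,
                            window_k = 3,
                            mad_cutoff = 0.2,
                            min_outlier_fraction = 0.8,
                            fdr_alpha = 0.05,
                            n_clusters = 5L,
                            cosinor_period_h = 24,
                            rng_seed = 1L) {
  cfg <- list(
    pseudocount = pseudocount,
    min_mean_count = min_mean_count,
    mad_b = mad_b,
    window_k = window_k,
    mad_cutoff = mad_cutoff,
    min_outlier_fraction = min_outlier_fraction,
    fdr_alpha = fdr_alpha,
    n_clusters = as.integer(n_clusters),
    cosinor_period_h = cosinor_period_h,
    rng_seed = as.integer(rng_seed)
  )
  for (nm in setdiff(names(cfg), "rng_seed")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop("config field '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  for (nm in c("min_outlier_fraction", "fdr_alpha")) {
    if (cfg[[nm]] > 1) {
      stop("config field '", nm, "' must lie in (0, 1]", call. = FALSE)
    }
  }
  if (is.na(cfg$rng_seed)) stop("rng_seed must be an integer", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("mirstab pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
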