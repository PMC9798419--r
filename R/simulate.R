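#' Default healthy time-course sampling grid
#'
#' The nine nominal sampling times of the healthy blood time course, in
#' hours: 0, 3, 6, 24, 48, 72 h, then day 7, day 30 and day 60 mapped to
#' 168, 720 and 1440 h.
#'
#' @return Numeric vector of length 9.
#' @export
default_timepoints <- function() c(0, 3, 6, 24, 48, 72, 168, 720, 1440)

#' Temporal pattern specification
#'
#' Describes the expected normalised expression of one miRNA over time.
#' Five kinds emulate the oscillation classes seen in healthy blood
#' time courses:
#' \describe{
#'   \item{flat}{constant baseline (the "stable" class; amplitude must be 0)}
#'   \item{cosine}{rhythmic: baseline x 2^(A cos(2 pi (t - acrophase)/period))}
#'   \item{drift}{monotone trend reaching `amplitude_log2` log2 units at the
#'     last time point}
#'   \item{spike}{a single-timepoint excursion of `amplitude_log2` log2 units}
#'   \item{noisy}{flat in expectation but heavily overdispersed}
#' }
#'
#' @param kind Pattern kind, one of `"flat"`, `"cosine"`, `"drift"`,
#'   `"spike"`, `"noisy"`.
#' @param baseline_mean Expected normalised count at baseline (> 0).
#' @param amplitude_log2 Peak deviation in log2 units (>= 0; 0 for flat).
#' @param period_h Rhythm period in hours (cosine only).
#' @param acrophase_h Peak time in hours (cosine only).
#' @param spike_timepoint Index into the time-point grid receiving the
#'   excursion (spike only).
#' @param dispersion Negative-binomial dispersion alpha; counts are drawn
#'   with variance mu + alpha mu^2 (the standard RNA-seq overdispersion
#'   form).
#' @return A list of class `pattern_spec`.
#' @examples
#' sp <- pattern_spec("cosine", baseline_mean = 100, amplitude_log2 = 1,
#'                    period_h = 24, acrophase_h = 0)
#' pattern_mean(sp, t = c(0, 12))
#' @export
pattern_spec <- function(kind = c("flat", "cosine", "drift", "spike", "noisy"),
                         baseline_mean,
                         amplitude_log2 = 0,
                         period_h = 24,
                         acrophase_h = 0,
                         spike_timepoint = 1L,
                         dispersion = 0.05) {
  kind <- match.arg(kind)
  if (!is.numeric(baseline_mean) || baseline_mean <= 0) {
    stop("baseline_mean must be > 0", call. = FALSE)
  }
  if (amplitude_log2 < 0) stop("amplitude_log2 must be >= 0", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  if (kind %in% c("flat", "noisy") && amplitude_log2 != 0) {
    stop(kind, " patterns must have amplitude_log2 = 0", call. = FALSE)
  }
  if (kind == "cosine" && period_h <= 0) {
    stop("period_h must be > 0", call. = FALSE)
  }
  structure(list(kind = kind, baseline_mean = baseline_mean,
                 amplitude_log2 = amplitude_log2, period_h = period_h,
                 acrophase_h = acrophase_h,
                 spike_timepoint = as.integer(spike_timepoint),
                 dispersion = dispersion),
            class = "pattern_spec")
}

#' Expected normalised count of a pattern at given times
#'
#' Evaluates `baseline_mean * 2^deviation(t)`: deviation is 0 for flat and
#' noisy patterns, a cosine of the given amplitude/period/acrophase for
#' rhythmic ones, a linear ramp `amplitude_log2 * t / t_max` for drift, and
#' `amplitude_log2` at the spike time point (0 elsewhere).
#'
#' @param spec A [pattern_spec()].
#' @param t Time(s) in hours (>= 0).
#' @param timepoints_h The sampling grid, needed to resolve the spike index
#'   and the drift end point.
#' @return Expected normalised count(s), same length as `t`.
#' @export
pattern_mean <- function(spec, t, timepoints_h = default_timepoints()) {
  stopifnot(inherits(spec, "pattern_spec"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  dev <- switch(spec$kind,
    flat = ,
    noisy = rep(0, length(t)),
    cosine = spec$amplitude_log2 *
      cos(2 * pi * (t - spec$acrophase_h) / spec$period_h),
    drift = spec$amplitude_log2 * t / max(timepoints_h),
    spike = ifelse(t == timepoints_h[spec$spike_timepoint],
                   spec$amplitude_log2, 0)
  )
  spec$baseline_mean * 2^dev
}

## Draw one NB count vector; size = 1/alpha so that var = mu + alpha mu^2.
nb_draw <- function(mu, dispersion) {
  stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Simulate a healthy time-course dataset
#'
#' For each subject x time-point sample a library-size factor
#' `s = 2^N(0, library_size_log2_sd^2)` is drawn, then per miRNA a count
#' `NB(mean = s * pattern_mean(spec, t), dispersion = spec$dispersion)`.
#' The defaults reproduce a 10-subject x 9-time-point layout (90 samples).
#'
#' @param specs Named list of [pattern_spec()] objects, one per miRNA.
#' @param n_subjects Number of subjects (>= 2).
#' @param timepoints_h Sampling grid in hours (>= 3 time points).
#' @param library_size_log2_sd Standard deviation of the per-sample log2
#'   library-size factor (0 disables library-size variation).
#' @param seed Optional integer seed; a given seed yields identical output.
#' @return A list with `counts` (count matrix), `samples` (sample table,
#'   condition `"healthy"`, dataset `"healthy"`) and `truth` (list with
#'   `stable_ids` -- the flat miRNAs -- and `pattern_of`).
#' @export
generate_healthy_timecourse <- function(specs,
                                        n_subjects = 10,
                                        timepoints_h = default_timepoints(),
                                        library_size_log2_sd = 0.25,
                                        seed = NULL) {
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  if (length(timepoints_h) < 3) {
    stop("need at least 3 time points", call. = FALSE)
  }
  if (is.null(names(specs)) || anyDuplicated(names(specs))) {
    stop("specs must be a uniquely named list", call. = FALSE)
  }
  if (library_size_log2_sd < 0) {
    stop("library_size_log2_sd must be >= 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  tp <- sort(timepoints_h)
  grid <- expand.grid(subject = seq_len(n_subjects), tp = tp,
                      KEEP.OUT.ATTRS = FALSE)
  sample_id <- sprintf("S%02d_T%04dh", grid$subject, grid$tp)
  lib <- 2^stats::rnorm(nrow(grid), 0, library_size_log2_sd)

  counts <- matrix(0L, nrow = length(specs), ncol = nrow(grid),
                   dimnames = list(names(specs), sample_id))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    mu <- lib * pattern_mean(sp, grid$tp, timepoints_h = tp)
    counts[i, ] <- nb_draw(mu, sp$dispersion)
  }
  samples <- data.frame(
    sample_id = sample_id,
    subject_id = sprintf("S%02d", grid$subject),
    timepoint_h = grid$tp,
    condition = "healthy",
    dataset_id = "healthy",
    stringsAsFactors = FALSE
  )
  truth <- list(
    stable_ids = names(specs)[vapply(specs, function(s) s$kind == "flat",
                                     logical(1))],
    pattern_of = specs
  )
  list(counts = counts, samples = samples, truth = truth)
}

#' Simulate a cancer case/control dataset
#'
#' Control samples are drawn at each miRNA's `baseline_mean`; case samples
#' at `baseline_mean * 2^effect` (effect 0 if the miRNA has no planted
#' effect). Negative-binomial noise and library-size factors as in
#' [generate_healthy_timecourse()].
#'
#' @param specs Named list of [pattern_spec()] objects.
#' @param planted_effects Named numeric vector of log2 effects; names must
#'   be a subset of `names(specs)`.
#' @param n_case,n_control Group sizes (each >= 3).
#' @param dataset_id Dataset label used in the sample table.
#' @param library_size_log2_sd As in [generate_healthy_timecourse()].
#' @param seed Optional integer seed.
#' @return A list with `counts` and `samples`.
#' @export
generate_cancer_study <- function(specs,
                                  planted_effects = numeric(0),
                                  n_case,
                                  n_control,
                                  dataset_id = "cancer",
                                  library_size_log2_sd = 0.25,
                                  seed = NULL) {
  if (n_case < 3 || n_control < 3) {
    stop("n_case and n_control must each be >= 3", call. = FALSE)
  }
  unknown <- setdiff(names(planted_effects), names(specs))
  if (length(unknown)) {
    stop("planted effect for unknown miRNA(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  n <- n_case + n_control
  condition <- rep(c("case", "control"), c(n_case, n_control))
  sample_id <- sprintf("%s_%s%02d", dataset_id, condition,
                       c(seq_len(n_case), seq_len(n_control)))
  lib <- 2^stats::rnorm(n, 0, library_size_log2_sd)

  effect <- stats::setNames(rep(0, length(specs)), names(specs))
  effect[names(planted_effects)] <- planted_effects

  counts <- matrix(0L, nrow = length(specs), ncol = n,
                   dimnames = list(names(specs), sample_id))
  is_case <- condition == "case"
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    mu <- lib * sp$baseline_mean * 2^(effect[i] * is_case)
    counts[i, ] <- nb_draw(mu, sp$dispersion)
  }
  samples <- data.frame(
    sample_id = sample_id,
    subject_id = sample_id,
    timepoint_h = NA_real_,
    condition = condition,
    dataset_id = dataset_id,
    stringsAsFactors = FALSE
  )
  list(counts = counts, samples = samples)
}

## Rough analytic estimate of the MAD a flat miRNA accrues from counting
## noise alone: sd of a per-timepoint log2 ratio of NB means.
expected_flat_mad <- function(baseline_mean, dispersion, n_subjects) {
  sqrt((1 / baseline_mean + dispersion) / n_subjects) / log(2)
}

#' Simulate a complete discovery scenario with ground truth
#'
#' One call builds everything [run_pipeline()] needs: a healthy time course
#' whose miRNAs follow a mix of temporal patterns (40% flat, 20% cosine,
#' 15% drift, 15% spike, 10% noisy), plus a set of cancer case/control
#' datasets in which a planted panel of flat miRNAs receives log2 effects
#' in every dataset. Baseline means are log-uniform on \[50, 800\] (safely
#' above the mean >= 20 filter); cosine amplitudes are uniform on
#' \[0.5, 1.5\] log2 units with periods uniform on \[26, 60\] h and random
#' acrophases; drift and spike amplitudes are uniform on \[1, 2\].
#' Planted effect magnitudes must exceed
#' `window_k * expected flat MAD + 0.3` so that panel recovery has a
#' definite answer; infeasible settings are rejected.
#'
#' @param config A [pipeline_config()]; supplies `window_k` and the default
#'   seed.
#' @param n_mirnas Number of miRNAs.
#' @param n_datasets Number of cancer datasets.
#' @param panel_size Number of flat miRNAs given cancer effects
#'   (`panel_size <=` number of flat miRNAs).
#' @param effect_range_log2 Range of planted |log2 effect| magnitudes;
#'   signs are random per miRNA x dataset.
#' @param n_subjects,timepoints_h Healthy time-course layout.
#' @param n_case,n_control Cancer group sizes per dataset.
#' @param library_size_log2_sd Per-sample log2 library-size sd.
#' @param seed Integer seed (defaults to `config$rng_seed`).
#' @return A list with `healthy` (counts + samples), `cancer_studies`
#'   (named list of counts + samples), `truth` (a scenario-truth list:
#'   `stable_ids`, `kind_of`, `pattern_of`, `planted_panel`, `effect_log2`
#'   matrix) and `config`.
#' @examples
#' sc <- generate_scenario(n_mirnas = 40, n_datasets = 3, panel_size = 2,
#'                         seed = 1)
#' sc$truth$planted_panel
#' @export
generate_scenario <- function(config = pipeline_config(),
                              n_mirnas = 200,
                              n_datasets = 11,
                              panel_size = 7,
                              effect_range_log2 = c(1, 2.5),
                              n_subjects = 10,
                              timepoints_h = default_timepoints(),
                              n_case = 20,
                              n_control = 20,
                              library_size_log2_sd = 0.25,
                              seed = config$rng_seed) {
  stopifnot(inherits(config, "pipeline_config"))
  if (n_mirnas < 10) stop("n_mirnas too small", call. = FALSE)
  if (n_datasets < 1) stop("need at least one cancer dataset", call. = FALSE)
  set.seed(seed)

  props <- c(flat = 0.40, cosine = 0.20, drift = 0.15, spike = 0.15,
             noisy = 0.10)
  counts_per_kind <- diff(c(0, round(cumsum(props) * n_mirnas)))
  kinds <- rep(names(props), counts_per_kind)
  ids <- sprintf("sim-miR-%03d", seq_len(n_mirnas))
  names(kinds) <- ids

  if (panel_size > sum(kinds == "flat")) {
    stop("infeasible: panel_size exceeds the number of flat miRNAs",
         call. = FALSE)
  }

  baseline <- 2^stats::runif(n_mirnas, log2(50), log2(800))
  specs <- vector("list", n_mirnas)
  names(specs) <- ids
  for (i in seq_len(n_mirnas)) {
    k <- kinds[i]
    specs[[i]] <- switch(k,
      flat = pattern_spec("flat", baseline[i],
                          dispersion = stats::runif(1, 0.02, 0.08)),
      cosine = pattern_spec("cosine", baseline[i],
                            amplitude_log2 = stats::runif(1, 0.5, 1.5),
                            period_h = stats::runif(1, 26, 60),
                            acrophase_h = stats::runif(1, 0, 60),
                            dispersion = stats::runif(1, 0.02, 0.08)),
      drift = pattern_spec("drift", baseline[i],
                           amplitude_log2 = stats::runif(1, 1, 2),
                           dispersion = stats::runif(1, 0.02, 0.08)),
      spike = pattern_spec("spike", baseline[i],
                           amplitude_log2 = stats::runif(1, 1, 2),
                           spike_timepoint = sample(length(timepoints_h), 1),
                           dispersion = stats::runif(1, 0.02, 0.08)),
      noisy = pattern_spec("noisy", baseline[i],
                           dispersion = stats::runif(1, 0.5, 1.5))
    )
  }
  ## identifiability floor for planted effects
  worst_mad <- expected_flat_mad(min(baseline), 0.08, n_subjects)
  floor_needed <- config$window_k * config$mad_b * worst_mad + 0.3
  if (min(abs(effect_range_log2)) < floor_needed) {
    stop(sprintf(
      "infeasible: planted effects (min %.2f) below identifiability floor %.2f",
      min(abs(effect_range_log2)), floor_needed), call. = FALSE)
  }

  flat_ids <- ids[kinds == "flat"]
  planted_panel <- if (panel_size > 0) sort(sample(flat_ids, panel_size))
                   else character(0)
  effect_log2 <- matrix(0, nrow = n_mirnas, ncol = n_datasets,
                        dimnames = list(ids,
                                        sprintf("cancer%02d",
                                                seq_len(n_datasets))))
  for (m in planted_panel) {
    mag <- stats::runif(n_datasets, effect_range_log2[1], effect_range_log2[2])
    sgn <- sample(c(-1, 1), n_datasets, replace = TRUE)
    effect_log2[m, ] <- mag * sgn
  }

  healthy <- generate_healthy_timecourse(
    specs, n_subjects = n_subjects, timepoints_h = timepoints_h,
    library_size_log2_sd = library_size_log2_sd, seed = seed + 1000L)

  cancer_studies <- lapply(seq_len(n_datasets), function(d) {
    eff <- effect_log2[, d]
    generate_cancer_study(
      specs, planted_effects = eff[eff != 0],
      n_case = n_case, n_control = n_control,
      dataset_id = colnames(effect_log2)[d],
      library_size_log2_sd = library_size_log2_sd,
      seed = seed + 1000L + d)
  })
  names(cancer_studies) <- colnames(effect_log2)

  truth <- list(stable_ids = flat_ids,
                kind_of = kinds,
                pattern_of = specs,
                planted_panel = planted_panel,
                effect_log2 = effect_log2)
  list(healthy = list(counts = healthy$counts, samples = healthy$samples),
       cancer_studies = cancer_studies,
       truth = truth,
       config = config)
}
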