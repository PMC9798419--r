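## Run `expr`, re-raising any error with the pipeline stage name attached.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

fmt_num <- function(x) formatC(x, digits = 8, format = "g")

#' Run the full discovery pipeline
#'
#' Chains normalisation, stability profiling, per-dataset differential
#' expression, panel selection and (optionally) ROC evaluation:
#'
#' 1. The healthy time course is normalised by median-of-ratios size
#'    factors and restricted to miRNAs whose mean normalised count reaches
#'    `config$min_mean_count` at every time point.
#' 2. Stability profiles (per-timepoint log2 fold changes, MAD, threshold
#'    window, clustering, cosinor) are computed; miRNAs with
#'    `MAD < config$mad_cutoff` form the stable candidate set.
#' 3. Every cancer dataset is normalised independently, filtered on mean
#'    expression, and tested case vs control.
#' 4. Stable candidates outside their healthy window (with BH-adjusted
#'    p < `config$fdr_alpha`) in strictly more than
#'    `config$min_outlier_fraction` of the datasets where they survive
#'    filtering are selected as the panel.
#' 5. For each dataset, every selected miRNA gets a ROC summary with a
#'    seeded bootstrap confidence interval, and the panel a cross-validated
#'    ridge-logistic combined AUC.
#'
#' The run is deterministic given `config$rng_seed`.
#'
#' @param config A [pipeline_config()].
#' @param healthy List with `counts` (count matrix) and `samples` (sample
#'   table) of the healthy time course.
#' @param cancer_studies Named list of cancer datasets, each a list with
#'   `counts` and `samples`.
#' @param out_dir Optional directory; when given, writes `stability.tsv`,
#'   `de_<dataset>.tsv`, `panel.tsv`, `auc.tsv` and `pipeline.log`.
#' @param evaluate Run the ROC/combiner stage (stage 5)?
#' @param n_boot Bootstrap replicates for the AUC confidence intervals.
#' @return A list of class `pancancer_run`: `config`, `stability` (data
#'   frame), `stable_ids`, `de` (named list of data frames), `panel`
#'   (a `panel_report`), `auc` (data frame or NULL), `log` (character).
#' @examples
#' sc <- generate_scenario(n_mirnas = 40, n_datasets = 3, panel_size = 2,
#'                         seed = 1)
#' run <- run_pipeline(sc$config, sc$healthy, sc$cancer_studies,
#'                     evaluate = FALSE)
#' run$panel$table$feature_id[run$panel$table$selected]
#' @export
run_pipeline <- function(config, healthy, cancer_studies,
                         out_dir = NULL, evaluate = TRUE, n_boot = 1000) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(cancer_studies) == 0) {
    stop("no cancer datasets", call. = FALSE)
  }
  if (is.null(names(cancer_studies))) {
    names(cancer_studies) <- vapply(cancer_studies, function(s)
      unique(s$samples$dataset_id)[1], character(1))
  }
  set.seed(config$rng_seed)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  note("mirstab run, seed %d", config$rng_seed)

  ## stage 1: healthy normalisation + expression filter
  keep <- NULL; nmh <- NULL
  with_stage("normalization", {
    validate_count_matrix(healthy$counts)
    validate_sample_table(healthy$samples, healthy$counts)
    nmh <- normalize_counts(healthy$counts)
    keep <- common_features(nmh, healthy$samples,
                            min_mean = config$min_mean_count)
    nmh <- subset_features(nmh, keep)
  })
  note("healthy: %d of %d miRNAs expressed (mean >= %g) at all time points",
       length(keep), nrow(healthy$counts), config$min_mean_count)

  ## stage 2: stability
  stability <- with_stage("stability",
    stability_profiles(nmh, healthy$samples, config))
  stable_ids <- select_stable(stability, config$mad_cutoff)
  note("stability: %d of %d miRNAs stable (MAD < %g); stable cluster %s",
       length(stable_ids), nrow(stability), config$mad_cutoff,
       format(attr(stability, "stable_cluster")))

  ## stage 3: per-dataset differential expression
  de <- list()
  norm_cancer <- list()
  with_stage("differential", {
    for (ds in names(cancer_studies)) {
      study <- cancer_studies[[ds]]
      validate_count_matrix(study$counts)
      validate_sample_table(study$samples, study$counts)
      nm <- filter_low_expression(normalize_counts(study$counts),
                                  min_mean = config$min_mean_count)
      norm_cancer[[ds]] <- nm
      de[[ds]] <- de_test(nm, study$samples,
                          pseudocount = config$pseudocount)
      note("de %s: %d miRNAs tested, %d at adj p < %g", ds,
           nrow(de[[ds]]), sum(de[[ds]]$adj_p < config$fdr_alpha),
           config$fdr_alpha)
    }
  })

  ## stage 4: panel selection
  panel <- with_stage("panel_selection", {
    windows <- stability[stability$feature_id %in% stable_ids,
                         c("feature_id", "lower", "upper")]
    fc <- matrix(NA_real_, nrow(windows), length(de),
                 dimnames = list(windows$feature_id, names(de)))
    adj <- fc
    for (ds in names(de)) {
      idx <- match(windows$feature_id, de[[ds]]$feature_id)
      fc[, ds] <- de[[ds]]$log2fc[idx]
      adj[, ds] <- de[[ds]]$adj_p[idx]
    }
    select_panel(windows, fc, adj, config)
  })
  selected <- panel$table$feature_id[panel$table$selected]
  note("panel: %d candidate(s), %d selected (> %g of datasets outside window)",
       nrow(panel$table), length(selected), config$min_outlier_fraction)

  ## stage 5: evaluation
  auc_tab <- NULL
  if (evaluate && length(selected) > 0) {
    auc_tab <- with_stage("evaluation", {
      rows <- list()
      for (ds in names(cancer_studies)) {
        nm <- norm_cancer[[ds]]
        st <- cancer_studies[[ds]]$samples
        st <- st[match(nm$sample_ids, st$sample_id), , drop = FALSE]
        is_case <- st$condition == "case"
        present <- intersect(selected, nm$feature_ids)
        for (id in present) {
          sc <- log2(nm$values[id, ] + config$pseudocount)
          r <- roc_auc(sc, is_case)
          ci <- boot_auc_ci(sc, is_case, n_boot = n_boot)
          rows[[length(rows) + 1L]] <- data.frame(
            dataset_id = ds, id = id, auc = r$auc,
            ci_low = ci[1], ci_high = ci[2],
            sensitivity = r$sensitivity, specificity = r$specificity,
            p_value = r$p_value, stringsAsFactors = FALSE)
        }
        if (length(present) >= 2) {
          comb <- fit_panel_combiner(
            nm$values[present, , drop = FALSE], is_case,
            pseudocount = config$pseudocount)
          ci <- boot_auc_ci(comb$scores, is_case, n_boot = n_boot)
          r <- roc_auc(comb$scores, is_case)
          rows[[length(rows) + 1L]] <- data.frame(
            dataset_id = ds, id = "panel", auc = comb$cv_auc,
            ci_low = ci[1], ci_high = ci[2],
            sensitivity = r$sensitivity, specificity = r$specificity,
            p_value = r$p_value, stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    })
    note("evaluation: %d ROC summaries", NROW(auc_tab))
  }

  res <- structure(list(config = config, stability = stability,
                        stable_ids = stable_ids, de = de, panel = panel,
                        auc = auc_tab, log = log_lines),
                   class = "pancancer_run")
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

## Write the intermediate tables of a run to a directory.
write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, file) {
    num <- vapply(df, is.numeric, logical(1)) &
      !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], fmt_num)
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(res$stability, "stability.tsv")
  for (ds in names(res$de)) wt(res$de[[ds]], sprintf("de_%s.tsv", ds))

  ptab <- res$panel$table
  if (nrow(ptab) > 0 && !is.null(res$panel$fc)) {
    fc <- res$panel$fc[ptab$feature_id, , drop = FALSE]
    colnames(fc) <- paste0("fc_", colnames(fc))
    out <- res$panel$outlier[ptab$feature_id, , drop = FALSE]
    colnames(out) <- paste0("outlier_", colnames(out))
    ptab <- cbind(ptab, fc, out)
  }
  wt(ptab, "panel.tsv")
  if (!is.null(res$auc)) wt(res$auc, "auc.tsv")
  writeLines(res$log, file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}

#' @export
print.pancancer_run <- function(x, ...) {
  cat("mirstab pipeline run\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}
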