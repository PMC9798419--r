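test_that("pattern_mean evaluates the five temporal forms", {
  tp <- default_timepoints()

  flat <- pattern_spec("flat", 100)
  expect_equal(pattern_mean(flat, c(0, 7, 1440)), rep(100, 3))

  cosine <- pattern_spec("cosine", 100, amplitude_log2 = 1, period_h = 24,
                         acrophase_h = 0)
  expect_equal(pattern_mean(cosine, 0), 200)   # peak: 100 * 2^1
  expect_equal(pattern_mean(cosine, 12), 50)   # trough: 100 * 2^-1

  drift <- pattern_spec("drift", 64, amplitude_log2 = 2)
  expect_equal(pattern_mean(drift, max(tp)), 256)  # 64 * 2^2 at t_max
  expect_equal(pattern_mean(drift, 0), 64)

  spike <- pattern_spec("spike", 100, amplitude_log2 = 3, spike_timepoint = 4)
  expect_equal(pattern_mean(spike, tp[4]), 800)
  expect_equal(pattern_mean(spike, tp[5]), 100)

  expect_error(pattern_mean(flat, -1), ">= 0")
  expect_error(pattern_spec("flat", 100, amplitude_log2 = 1), "amplitude")
  expect_error(pattern_spec("flat", -5), "baseline_mean")
})

test_that("healthy time course has the 10 x 9 layout and is seeded", {
  specs <- list(a = pattern_spec("flat", 100),
                b = pattern_spec("cosine", 100, amplitude_log2 = 1))
  h <- generate_healthy_timecourse(specs, seed = 11)
  expect_equal(ncol(h$counts), 90)
  expect_equal(nrow(h$counts), 2)
  expect_equal(length(unique(h$samples$timepoint_h)), 9)
  expect_true(all(h$counts >= 0 & h$counts == round(h$counts)))
  expect_identical(h$truth$stable_ids, "a")

  h2 <- generate_healthy_timecourse(specs, seed = 11)
  expect_identical(h$counts, h2$counts)
  h3 <- generate_healthy_timecourse(specs, seed = 12)
  expect_false(identical(h$counts, h3$counts))

  expect_error(generate_healthy_timecourse(specs, n_subjects = 1), ">= 2")
  expect_error(generate_healthy_timecourse(specs, timepoints_h = c(0, 3)),
               "3 time points")
})

test_that("variance collapses to the Poisson limit as dispersion -> 0", {
  # NB(mu, alpha -> 0) converges to Poisson(mu): mean mu, variance ~ mu.
  specs <- list(a = pattern_spec("flat", 100, dispersion = 1e-8))
  h <- generate_healthy_timecourse(specs, n_subjects = 30,
                                   library_size_log2_sd = 0, seed = 5)
  x <- as.numeric(h$counts)
  expect_equal(mean(x), 100, tolerance = 0.02)     # SE ~ 10/sqrt(270)
  expect_lt(abs(var(x) / mean(x) - 1), 0.25)       # Fano factor ~ 1
})

test_that("cancer studies place the planted effect on case means", {
  specs <- list(a = pattern_spec("flat", 200, dispersion = 1e-4),
                b = pattern_spec("flat", 200, dispersion = 1e-4))
  cs <- generate_cancer_study(specs, c(a = 2), n_case = 200, n_control = 200,
                              library_size_log2_sd = 0, seed = 3)
  is_case <- cs$samples$condition == "case"
  lfc <- log2(rowMeans(cs$counts[, is_case]) / rowMeans(cs$counts[, !is_case]))
  expect_lt(abs(lfc[["a"]] - 2), 0.1)   # law of large numbers
  expect_lt(abs(lfc[["b"]]), 0.1)       # unplanted miRNA stays at 0

  expect_error(generate_cancer_study(specs, c(zz = 1), 5, 5), "zz")
  expect_error(generate_cancer_study(specs, n_case = 0, n_control = 5),
               ">= 3")
})

test_that("null cancer studies show no persistent fold changes", {
  specs <- lapply(1:5, function(i) pattern_spec("flat", 300,
                                                dispersion = 0.05))
  names(specs) <- paste0("m", 1:5)
  cs <- generate_cancer_study(specs, n_case = 100, n_control = 100,
                              library_size_log2_sd = 0, seed = 9)
  is_case <- cs$samples$condition == "case"
  lfc <- log2(rowMeans(cs$counts[, is_case]) / rowMeans(cs$counts[, !is_case]))
  expect_true(all(abs(lfc) < 0.2))
})

test_that("generate_scenario plants a coherent ground truth", {
  sc <- generate_scenario(n_mirnas = 60, n_datasets = 4, panel_size = 3,
                          seed = 21)
  tr <- sc$truth
  # exact partition into the five kinds
  expect_equal(length(tr$kind_of), 60)
  expect_setequal(unique(tr$kind_of),
                  c("flat", "cosine", "drift", "spike", "noisy"))
  # planted panel is a subset of the flat (stable) miRNAs
  expect_equal(length(tr$planted_panel), 3)
  expect_true(all(tr$planted_panel %in% tr$stable_ids))
  # effects are planted only on the panel, in every dataset
  nonzero <- rownames(tr$effect_log2)[rowSums(tr$effect_log2 != 0) > 0]
  expect_setequal(nonzero, tr$planted_panel)
  expect_true(all(tr$effect_log2[tr$planted_panel, ] != 0))
  expect_true(all(abs(tr$effect_log2[tr$planted_panel, ]) >= 1))
  expect_equal(length(sc$cancer_studies), 4)

  # empty panel
  sc0 <- generate_scenario(n_mirnas = 60, n_datasets = 2, panel_size = 0,
                           seed = 22)
  expect_length(sc0$truth$planted_panel, 0)

  # two seeds: different counts, same dimensions
  sc2 <- generate_scenario(n_mirnas = 60, n_datasets = 4, panel_size = 3,
                           seed = 22)
  expect_equal(dim(sc2$healthy$counts), dim(sc$healthy$counts))
  expect_false(identical(sc2$healthy$counts, sc$healthy$counts))

  # infeasible settings are refused
  expect_error(generate_scenario(n_mirnas = 60, panel_size = 30, seed = 1),
               "infeasible")
  expect_error(generate_scenario(n_mirnas = 60, panel_size = 2,
                                 effect_range_log2 = c(0.1, 0.2), seed = 1),
               "infeasible")
})
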