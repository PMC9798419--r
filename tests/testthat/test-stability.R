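test_that("per-timepoint log2 fold changes compare each time to the overall mean", {
  h <- tiny_healthy(n_feat = 5, n_subjects = 6, seed = 31)
  nm <- normalize_counts(h$counts)
  X <- timepoint_log2fc(nm, h$samples, pseudocount = 1)
  expect_equal(dim(X), c(5, 9))

  # brute-force recomputation
  st <- h$samples[match(nm$sample_ids, h$samples$sample_id), ]
  for (f in rownames(X)) {
    overall <- mean(nm$values[f, ])
    for (tp in sort(unique(st$timepoint_h))) {
      mt <- mean(nm$values[f, st$timepoint_h == tp])
      expect_equal(X[f, sprintf("log2fc_%gh", tp)],
                   log2((mt + 1) / (overall + 1)))
    }
  }

  # identical means at every time point -> X all zero
  m <- matrix(100L, 2, 6,
              dimnames = list(c("a", "b"), sprintf("s%d", 1:6)))
  st2 <- data.frame(sample_id = colnames(m), subject_id = colnames(m),
                    timepoint_h = rep(c(0, 3, 6), 2), condition = "healthy",
                    dataset_id = "healthy")
  X2 <- timepoint_log2fc(normalize_counts(m), st2)
  expect_equal(unname(X2), matrix(0, 2, 3))

  # time-point mean 40 vs overall 20 with vanishing pseudocount -> 1
  m3 <- matrix(c(40L, 10L, 10L), 1, 3,
               dimnames = list("a", c("s1", "s2", "s3")))
  st3 <- data.frame(sample_id = colnames(m3), subject_id = colnames(m3),
                    timepoint_h = c(0, 3, 6), condition = "healthy",
                    dataset_id = "healthy")
  nm3 <- normalize_counts(m3)
  nm3$values <- m3 * 1.0          # bypass size factors for the hand check
  X3 <- timepoint_log2fc(nm3, st3, pseudocount = 1e-9)
  expect_equal(X3[1, "log2fc_0h"], 1, tolerance = 1e-8)
})

test_that("mad_score matches hand values and the classic estimator", {
  expect_equal(mad_score(rep(3.7, 9)), 0)
  expect_equal(mad_score(c(-0.2, -0.1, 0, 0.1, 0.2)), 1.4826 * 0.1)

  set.seed(77)
  for (i in 1:10) {
    x <- rnorm(sample(5:20, 1))
    expect_equal(mad_score(x), stats::mad(x))      # independent route
    c0 <- runif(1, -10, 10); s0 <- runif(1, 0.1, 5)
    expect_equal(mad_score(x + c0), mad_score(x), tolerance = 1e-12)
    expect_equal(mad_score(s0 * x), s0 * mad_score(x), tolerance = 1e-12)
  }

  # robustness: corrupting floor((n-1)/2) of 9 entries keeps the score finite
  x <- rnorm(9)
  x[1:4] <- c(1e9, -1e9, 1e12, 1e7)
  expect_true(is.finite(mad_score(x)))
  expect_error(mad_score(numeric(0)), "non-empty")
})

test_that("threshold windows are median +/- k x MAD", {
  x <- c(-0.2, -0.1, 0, 0.1, 0.2)
  w <- threshold_window(x, k = 3)
  expect_equal(unname(w), c(-0.44478, 0.44478))
  expect_equal(unname(threshold_window(rep(2, 5))), c(2, 2))  # degenerate

  set.seed(5)
  for (i in 1:5) {
    x <- rnorm(9); c0 <- runif(1, -5, 5)
    expect_equal(threshold_window(x + c0), threshold_window(x) + c0,
                 tolerance = 1e-12)
    w <- threshold_window(x, k = 3)
    expect_equal((w[["upper"]] - w[["lower"]]) / 2, 3 * mad_score(x))
  }
})

test_that("stable selection is strict at the cutoff and monotone", {
  prof <- data.frame(feature_id = c("a", "b", "c"),
                     mad = c(0.1999, 0.2, 0.5))
  expect_identical(select_stable(prof, 0.2), "a")      # 0.2 exactly is out
  expect_identical(select_stable(prof, Inf), c("a", "b", "c"))
  expect_true(all(select_stable(prof, 0.2) %in% select_stable(prof, 0.3)))
})

test_that("profile clustering separates planted groups and flags the calm one", {
  # two well-separated groups: flat vs high-amplitude cosine
  specs <- c(lapply(1:10, function(i) pattern_spec("flat", 200)),
             lapply(1:10, function(i)
               pattern_spec("cosine", 200, amplitude_log2 = 2,
                            period_h = 40, acrophase_h = i)))
  names(specs) <- sprintf("m%02d", 1:20)
  h <- generate_healthy_timecourse(specs, seed = 3)
  X <- timepoint_log2fc(normalize_counts(h$counts), h$samples)
  cl <- cluster_profiles(X, 2)
  truth <- rep(1:2, each = 10)
  expect_equal(mclust::adjustedRandIndex(cl, truth), 1)
  # the lowest-MAD cluster is the flat one
  expect_equal(unname(cl[1:10]),
               rep(attr(cl, "stable_cluster"), 10))

  expect_error(cluster_profiles(X, 1), "k must")
  expect_error(cluster_profiles(X, 21), "k must")

  # identical profiles: a full, deterministic partition is still returned
  X0 <- matrix(0, 6, 9, dimnames = list(paste0("z", 1:6), NULL))
  cl0 <- cluster_profiles(X0, 2)
  expect_length(cl0, 6)
  expect_identical(cluster_profiles(X0, 2), cl0)
})

test_that("the lowest-MAD cluster excludes oscillating and noisy miRNAs", {
  for (seed in c(1, 2, 3)) {
    sc <- generate_scenario(seed = seed)
    nm <- normalize_counts(sc$healthy$counts)
    X <- timepoint_log2fc(nm, sc$healthy$samples)
    cl <- cluster_profiles(X, 5)
    kinds <- sc$truth$kind_of[rownames(X)]
    in_stable <- cl == attr(cl, "stable_cluster")
    expect_lte(mean(kinds[in_stable] %in% c("cosine", "noisy")), 0.1)
  }
})

test_that("cosinor recovers a noiseless rhythm and flags constants as arrhythmic", {
  t <- seq(0, 21, by = 3)
  f <- cosinor_fit(5 + 2 * cos(2 * pi * t / 24), t, period_h = 24)
  expect_equal(f$mesor, 5, tolerance = 1e-6)
  expect_equal(f$amplitude, 2, tolerance = 1e-6)
  expect_equal(f$acrophase_h, 0, tolerance = 1e-6)

  # shifted peak: acrophase recovered modulo the period
  f2 <- cosinor_fit(1 + 0.5 * cos(2 * pi * (t - 7) / 24), t, period_h = 24)
  expect_equal(f2$acrophase_h, 7, tolerance = 1e-6)

  f0 <- cosinor_fit(rep(4, 8), t, period_h = 24)
  expect_equal(f0$amplitude, 0, tolerance = 1e-9)
  expect_gt(f0$p_amplitude, 0.5)

  expect_error(cosinor_fit(1:3, c(0, 3, 6)), "at least 4")
})

test_that("the zero-amplitude test detects planted circadian rhythms", {
  n_seeds <- 20
  hit_cos <- numeric(n_seeds)
  calm_flat <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    specs <- c(lapply(1:10, function(i) pattern_spec("flat", 150)),
               lapply(1:10, function(i)
                 pattern_spec("cosine", 150, amplitude_log2 = 1,
                              period_h = 24,
                              acrophase_h = 2.4 * i)))
    names(specs) <- sprintf("m%02d", 1:20)
    h <- generate_healthy_timecourse(specs, seed = 400 + s)
    nm <- normalize_counts(h$counts)
    prof <- stability_profiles(nm, h$samples, pipeline_config())
    hit_cos[s] <- mean(prof$cosinor_p[11:20] < 0.05)
    calm_flat[s] <- mean(prof$cosinor_p[1:10] > 0.05)
  }
  expect_gte(mean(hit_cos), 0.9)    # planted 1-log2 rhythms detected
  expect_gte(mean(calm_flat), 0.8)  # flat miRNAs rarely called rhythmic
})
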