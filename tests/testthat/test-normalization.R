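test_that("size factors reproduce median-of-ratios exactly", {
  # identical columns -> all factors 1
  m <- random_counts(6, 1, seed = 3)[, c(1, 1, 1)]
  colnames(m) <- c("a", "b", "c")
  expect_equal(unname(size_factors(m)), rep(1, 3))

  # doubling one column doubles its factor relative to the others
  m <- random_counts(10, 3, seed = 4)
  m2 <- m; m2[, 2] <- m2[, 2] * 2L
  sf <- size_factors(m2)
  expect_equal(sf[["s02"]] / sf[["s01"]],
               2 * size_factors(m)[["s02"]] / size_factors(m)[["s01"]],
               tolerance = 1e-12)

  # hand-checkable 3 x 3 fixture vs the brute-force oracle
  m3 <- matrix(c(10, 100, 40,
                 20, 200, 80,
                 10, 50, 40), nrow = 3,
               dimnames = list(c("f1", "f2", "f3"), c("a", "b", "c")))
  expect_equal(unname(size_factors(m3)), unname(bf_size_factors(m3)))

  # random matrices vs the oracle
  for (seed in 1:5) {
    m <- random_counts(10, 8, seed = seed)
    expect_equal(unname(size_factors(m)), unname(bf_size_factors(m)),
                 tolerance = 1e-12)
  }

  # all-zero feature rows are excluded from the reference set, not fatal
  m <- random_counts(5, 4, seed = 6)
  m[2, ] <- 0L
  expect_silent(size_factors(m))
  m[] <- 0L
  expect_error(size_factors(m), "filter")
})

test_that("size factors agree with the DESeq2 implementation", {
  # odd reference-set size: the raw-scale and log-scale medians coincide
  # on a single order statistic, so the two routes must agree exactly
  m <- random_counts(49, 12, lambda = 80, seed = 7)
  sf_ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(size_factors(m)), unname(sf_ref), tolerance = 1e-10)

  # even reference sets: midpoint conventions differ only marginally
  m2 <- random_counts(50, 12, lambda = 80, seed = 8)
  sf2 <- DESeq2::estimateSizeFactorsForMatrix(m2)
  expect_equal(unname(size_factors(m2)), unname(sf2), tolerance = 1e-3)
})

test_that("normalisation is invariant to column rescaling", {
  m <- random_counts(12, 6, seed = 8)
  nm <- normalize_counts(m)
  expect_equal(nm$values,
               sweep(m, 2, nm$size_factors, "/"))

  # rescaling one of n columns by c shifts the geometric-mean reference by
  # c^(1/n), so normalised values are recovered up to that common factor;
  # relative expression (what every downstream ratio uses) is unchanged
  m2 <- m
  m2[, 3] <- m2[, 3] * 5L
  nm2 <- normalize_counts(m2)
  ratio <- nm2$values / nm$values
  expect_equal(unname(ratio),
               matrix(5^(1 / ncol(m)), nrow(m), ncol(m)),
               tolerance = 1e-9)
  expect_equal(nm2$values / mean(nm2$values), nm$values / mean(nm$values),
               tolerance = 1e-9)

  # identical columns: normalised values equal the raw counts
  mi <- random_counts(6, 1, seed = 9)[, c(1, 1)]
  colnames(mi) <- c("a", "b")
  expect_equal(normalize_counts(mi)$values, mi * 1.0, ignore_attr = FALSE)
})

test_that("low-expression filtering is strict at the threshold and monotone", {
  m <- matrix(as.integer(c(rep(19, 4), rep(20, 4), rep(500, 4))),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("low", "edge", "high"), letters[1:4]))
  nm <- normalize_counts(m)
  nm$values <- m * 1.0     # exact means, free of geomean round-off
  f <- filter_low_expression(nm, min_mean = 20)
  expect_setequal(f$feature_ids, c("edge", "high"))  # mean 19.9x < 20 is out
  expect_identical(attr(f, "discarded"), "low")

  # tiny threshold keeps everything
  expect_equal(filter_low_expression(nm, 1e-4)$feature_ids, nm$feature_ids)

  # monotone: raising min_mean never adds features
  nm_big <- normalize_counts(random_counts(30, 6, lambda = 30, seed = 10))
  kept <- lapply(c(5, 20, 40), function(mm)
    filter_low_expression(nm_big, mm)$feature_ids)
  expect_true(all(kept[[2]] %in% kept[[1]]))
  expect_true(all(kept[[3]] %in% kept[[2]]))
})

test_that("common_features requires expression at every time point", {
  h <- tiny_healthy(n_feat = 4, n_subjects = 5, baseline = 100, seed = 13)
  nm <- normalize_counts(h$counts)

  # brute-force oracle: per-time-point group means
  st <- h$samples[match(nm$sample_ids, h$samples$sample_id), ]
  oracle <- rownames(nm$values)[apply(
    sapply(sort(unique(st$timepoint_h)), function(tp)
      rowMeans(nm$values[, st$timepoint_h == tp, drop = FALSE]) >= 20),
    1, all)]
  expect_setequal(common_features(nm, h$samples, 20), oracle)
  expect_setequal(common_features(nm, h$samples, 20), rownames(h$counts))

  # a feature above threshold at 8 of 9 time points is excluded
  m <- h$counts
  drop_tp <- h$samples$sample_id[h$samples$timepoint_h == 48]
  m["miR-01", drop_tp] <- 0L
  nm2 <- normalize_counts(m)
  expect_false("miR-01" %in% common_features(nm2, h$samples, 20))
  expect_true("miR-02" %in% common_features(nm2, h$samples, 20))
})
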