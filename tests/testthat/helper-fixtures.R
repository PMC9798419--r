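# Shared fixtures and independent brute-force oracles.

# Random all-positive count matrix.
random_counts <- function(n_feat = 5, n_samp = 4, lambda = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(n_feat * n_samp, lambda) + 1L, n_feat, n_samp,
              dimnames = list(sprintf("miR-%02d", seq_len(n_feat)),
                              sprintf("s%02d", seq_len(n_samp))))
  m
}

# Brute-force median-of-ratios: per sample, the median over all-positive
# features of count / geometric mean, computed on the raw scale.
bf_size_factors <- function(m) {
  ref <- apply(m, 1, function(r) all(r > 0))
  geo <- apply(m[ref, , drop = FALSE], 1, function(r) prod(r)^(1 / length(r)))
  apply(m[ref, , drop = FALSE], 2, function(cnt) median(cnt / geo))
}

# All-pairs AUC: probability a random case outranks a random control,
# ties counted one half.
bf_auc <- function(scores, is_case) {
  cs <- scores[is_case]; ct <- scores[!is_case]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# Minimal healthy bundle: flat miRNAs only, small and fast.
tiny_healthy <- function(n_feat = 6, n_subjects = 4, baseline = 200,
                         dispersion = 0.05, seed = 42) {
  specs <- lapply(seq_len(n_feat), function(i)
    pattern_spec("flat", baseline, dispersion = dispersion))
  names(specs) <- sprintf("miR-%02d", seq_len(n_feat))
  generate_healthy_timecourse(specs, n_subjects = n_subjects, seed = seed)
}
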