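# Small fixtures built in code; all seeded for reproducibility.

tiny_cohort <- function(n_kd = 10, n_fc = 10, n_compounds = 12,
                        n_informative = 3, effect_size = 2, seed = 42,
                        ...) {
  simulate_cohort(cohort_spec(n_kd = n_kd, n_fc = n_fc,
                              n_compounds = n_compounds,
                              n_informative = n_informative,
                              effect_size = effect_size, seed = seed, ...))
}

tiny_table <- function(..., normalize = TRUE) {
  tab <- cohort_feature_table(tiny_cohort(...))
  if (normalize) normalize_by_creatinine(tab) else tab
}

# A hand-built color_difference from a delta matrix.
cd_from_deltas <- function(deltas, id = "sub",
                           compounds = sprintf("C%03d",
                                               seq_len(nrow(deltas)))) {
  compute_difference_vector(deltas, blank_rgb = c(0, 0, 0),
                            compounds = compounds, subject_id = id)
}

# Brute-force AUC by pair enumeration (independent oracle).
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments
# (independent oracle; tie-free data, small n + m only).
mw_exact_enum <- function(x, y) {
  n <- length(x); m <- length(y)
  vals <- c(x, y)
  U_obs <- sum(outer(x, y, ">"))
  combs <- utils::combn(n + m, n)
  Us <- apply(combs, 2, function(ix) {
    xs <- vals[ix]; ys <- vals[-ix]
    sum(outer(xs, ys, ">"))
  })
  u_low <- min(U_obs, n * m - U_obs)
  min(1, 2 * mean(Us <= u_low))
}
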