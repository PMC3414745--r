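# Fixture builders shared across the test files. All data are generated in
# code; no binary fixtures.

# Balanced dataset from explicit per-subject response rows.
ds_from_matrix <- function(values, groups, times = seq_len(ncol(values))) {
  n <- nrow(values)
  rm_data(subject = rep(sprintf("s%02d", seq_len(n)), each = ncol(values)),
          group = rep(groups, each = ncol(values)),
          time = rep(times, n),
          response = as.vector(t(values)))
}

# Noise-free linear profiles y = intercept + slope * t per subject.
ds_linear <- function(intercepts, slopes, groups, times = c(2, 4, 6, 8)) {
  vals <- outer(intercepts, times, function(a, t) a) +
    outer(slopes, times, function(b, t) b * t)
  ds_from_matrix(vals, groups, times)
}

# Dataset shaped like a small two-group growth study: n1 + n2 subjects,
# m shared times, gaussian noise around group-specific linear trends.
ds_growth <- function(n1 = 11, n2 = 16, times = c(8, 10, 12, 14), seed = 42) {
  set.seed(seed)
  n <- n1 + n2
  g <- rep(c("girl", "boy"), c(n1, n2))
  slope <- ifelse(g == "boy", 0.8, 0.5)
  icpt <- ifelse(g == "boy", 16, 17) + rnorm(n, 0, 1.5)
  vals <- icpt + outer(slope, times) + matrix(rnorm(n * length(times), 0, 1),
                                              n, length(times))
  ds_from_matrix(vals, g, times)
}

# 3-SE tolerance for comparing two independent Monte Carlo rejection-rate
# estimates (the reference value comes from a 1000-replicate study).
rate_tol <- function(p_ref, reps_mine, reps_ref = 1000) {
  3 * sqrt(p_ref * (1 - p_ref) * (1 / reps_ref + 1 / reps_mine))
}

expect_rate <- function(rate, p_ref, reps_mine, reps_ref = 1000) {
  expect_lt(abs(rate - p_ref), rate_tol(p_ref, reps_mine, reps_ref))
}

# Random full-rank (m-1) x m contrast matrix with zero row sums.
random_contrast <- function(m, seed = 1) {
  set.seed(seed)
  repeat {
    A <- matrix(rnorm((m - 1) * m), m - 1, m)
    C <- A - rowMeans(A)
    if (qr(C)$rank == m - 1) return(C)
  }
}
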