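# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# A small valid subject data.frame (not yet classed).
make_subject_df <- function(n = 10, seed = 42) {
  corthick:::with_seed(seed, data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    age = runif(n, 40, 80),
    gender = sample(c(1, 2), n, replace = TRUE),
    education = round(runif(n, 10, 20)),
    rfd = runif(n, 0.05, 0.4),
    total_cognition = rnorm(n),
    stringsAsFactors = FALSE))
}

# Random positive thickness values over the canonical 68 regions.
make_thickness <- function(n = 10, seed = 43) {
  corthick:::with_seed(seed, {
    vals <- matrix(rnorm(68 * n, 2.5, 0.2), 68, n)
    thickness_matrix(vals, dk_regions(), sprintf("s%02d", seq_len(n)))
  })
}

# Raw scores for the 12 cognitive tests.
make_cognitive_raw <- function(n = 6, seed = 44) {
  tests <- unlist(cognitive_tests(), use.names = FALSE)
  corthick:::with_seed(seed, {
    m <- sapply(tests, function(t) rnorm(n, 50, 10))
    as.data.frame(m, check.names = FALSE)
  })
}

# A null simulation: no covariate effects, no pattern, homoscedastic noise.
null_sim_config <- function(seed, n_subjects = 353, noise_sd = 0.1) {
  sim_config(
    n_subjects = n_subjects,
    region_effects = matrix(0, 68, 3,
                            dimnames = list(dk_regions(),
                                            c("gender", "rfd", "age"))),
    pattern_strength = 0, pattern_expr_sd = 0,
    noise_sd = noise_sd, seed = seed)
}

# All permutations of 1..n as an (n!) x n matrix (test oracle use only).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

# Exact binomial acceptance band for a rejection count. `conf` < 0.95 per
# check when several calibration checks form one family (Bonferroni), so the
# family-wise false-alarm rate stays at ~5%.
binom_band <- function(n_tests, alpha = 0.05, conf = 0.95) {
  lo <- (1 - conf) / 2
  stats::qbinom(c(lo, 1 - lo), n_tests, alpha) / n_tests
}
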