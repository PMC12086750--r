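# Independent oracles used to cross-check the implementation. They share no
# code path with the package internals: Gaussian tails come from numerical
# integration of the density, binomial probabilities from an explicit
# choose()-based pmf and full double enumeration, and simulation oracles draw
# fresh samples from the generating distributions instead of resampling.

# Pr(X >= lower) for X ~ Normal(mean, sd), by quadrature of the density
oracle_gauss_tail <- function(lower, mean = 0, sd = 1) {
  stats::integrate(function(x) stats::dnorm(x, mean, sd), lower, Inf,
                   rel.tol = 1e-12)$value
}

# explicit binomial pmf, no dbinom
oracle_binom_pmf <- function(k, n, p) {
  exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p))
}

# Pr(k2 - k1 <= m * n) by full (n+1)^2 enumeration, inclusive inequality
oracle_exact_diff_le <- function(n, p1, p2, m) {
  k <- 0:n
  pm1 <- oracle_binom_pmf(k, n, p1)
  pm2 <- oracle_binom_pmf(k, n, p2)
  ok <- outer(k, k, function(k1, k2) (k2 - k1) <= m * n + 1e-9)
  sum(outer(pm1, pm2) * ok)
}

# smallest n with prob_fun(n) >= target, plain linear scan
oracle_scan_first <- function(prob_fun, target, n_max) {
  for (n in seq_len(n_max)) if (prob_fun(n) >= target) return(n)
  stop("oracle scan exhausted without crossing the target")
}

# sample-median-of-KM difference between two fresh exponential cohorts,
# replicated; the direct-simulation stand-in for the bootstrap
oracle_direct_median_diffs <- function(median1, median2, n, reps) {
  r1 <- log(2) / median1
  r2 <- log(2) / median2
  vapply(seq_len(reps), function(i) {
    a <- sort(stats::rexp(n, r1))
    b <- sort(stats::rexp(n, r2))
    # with no censoring the KM median is the usual type-1 quantile:
    # smallest order statistic with empirical survival <= 1/2
    a[ceiling(n / 2)] - b[ceiling(n / 2)]
  }, numeric(1))
}

# empirical survival-at-t difference between fresh exponential cohorts
oracle_direct_survat_diffs <- function(median1, median2, n, tstar, reps) {
  r1 <- log(2) / median1
  r2 <- log(2) / median2
  vapply(seq_len(reps), function(i) {
    mean(stats::rexp(n, r1) > tstar) - mean(stats::rexp(n, r2) > tstar)
  }, numeric(1))
}

# Across-source standard error of a bootstrap estimate, by double bootstrap:
# regenerate K independent synthetic sources at the phase-III scale, rerun the
# (reduced-replicate) bootstrap on each, and subtract the replicate-noise
# variance from the across-source variance.
source_sampling_se <- function(n_source = c(378L, 377L), medians = c(15.1, 12.7),
                               n_per_arm = 300L, margin = 1.5,
                               K = 10L, reps_each = 1000L, seed0 = 5000L) {
  est <- t(vapply(seq_len(K), function(k) {
    src <- gen_exponential_cohort(median = medians, n = n_source,
                                  arm = c("approved", "control"),
                                  seed = seed0 + k)
    b <- bootstrap_verify(src, "approved", "control", n_per_arm, margin,
                          reps = reps_each, seed = seed0 + 10000L + k)
    c(b$p_noninf, b$p_inf)
  }, numeric(2)))
  rep_noise <- colMeans(est * (1 - est)) / reps_each
  se2 <- pmax(0, apply(est, 2, stats::var) - rep_noise)
  list(se_noninf = sqrt(se2[1]), se_inf = sqrt(se2[2]))
}

case_study_spec <- function(p = 1) {
  tte_design_spec(15.1, 12.7, margin_ratio = 0.90,
                  q_threshold = 0.90, z_threshold = 0.80, p_noncensor = p)
}
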