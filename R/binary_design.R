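#' Specify a binary-endpoint practical non-inferiority design
#'
#' Binary analogue of [tte_design_spec()]: per-arm success counts are
#' binomial, \eqn{n_i \sim \mathrm{Bin}(n, p_i)}, and the margin is an
#' absolute difference in proportions (percentage points / 100). The first
#' perspective assumes both arms share the approved dose's success
#' probability; the second assumes the reduced dose falls back to the
#' historical-control rate.
#'
#' @param p_approved Success probability of the approved dose (set to the
#'   experimental-arm rate of the prior phase III trial).
#' @param p_reduced_inferior Success probability regarded as a meaningful
#'   decrement (the historical-control rate). Must be below `p_approved`.
#' @param margin_points Margin as a difference in proportions, in (0, 1).
#'   Must be smaller than `p_approved - p_reduced_inferior` for the
#'   inferiority perspective to be attainable.
#' @param q_threshold,z_threshold Design thresholds Q and Z.
#' @param n_cap Upper bound for the grid searches.
#' @param exact_limit Per-arm n above which Monte Carlo replaces exact
#'   enumeration.
#' @param mc_reps Monte Carlo replicates used above `exact_limit`.
#' @param seed Seed for the Monte Carlo branch of the grid searches.
#' @return An object of class `binary_design_spec`.
#' @export
binary_design_spec <- function(p_approved, p_reduced_inferior, margin_points,
                               q_threshold = 0.80, z_threshold = 0.80,
                               n_cap = 100000L, exact_limit = 2000L,
                               mc_reps = 100000L, seed = 20260926L) {
  .assert_prob(p_approved, "p_approved")
  .assert_prob(p_reduced_inferior, "p_reduced_inferior")
  .assert(p_reduced_inferior < p_approved,
          "`p_reduced_inferior` must be smaller than `p_approved`")
  .assert_prob(margin_points, "margin_points")
  .assert(margin_points < p_approved - p_reduced_inferior,
          "`margin_points` must be below the true rate difference, otherwise the inferiority perspective is unattainable")
  .assert_prob(q_threshold, "q_threshold")
  .assert_prob(z_threshold, "z_threshold")
  .assert_count(n_cap, "n_cap")
  .assert_count(exact_limit, "exact_limit")
  .assert_count(mc_reps, "mc_reps", min = 1000L)
  structure(list(
    p_approved = p_approved, p_reduced_inferior = p_reduced_inferior,
    margin_points = margin_points,
    q_threshold = q_threshold, z_threshold = z_threshold,
    n_cap = as.integer(n_cap), exact_limit = as.integer(exact_limit),
    mc_reps = as.integer(mc_reps), seed = as.integer(seed)
  ), class = "binary_design_spec")
}

#' @export
print.binary_design_spec <- function(x, ...) {
  cat("Binary-endpoint practical non-inferiority design\n")
  cat(sprintf("  approved rate %.3f; reference decrement rate %.3f; margin %.3f (%.0f pp)\n",
              x$p_approved, x$p_reduced_inferior, x$margin_points, 100 * x$margin_points))
  cat(sprintf("  thresholds: Q = %.2f, Z = %.2f; exact up to n = %d, then %d MC reps\n",
              x$q_threshold, x$z_threshold, x$exact_limit, x$mc_reps))
  invisible(x)
}

# Pr(k2/n - k1/n <= m) for k1 ~ Bin(n, p1), k2 ~ Bin(n, p2), independent.
# The event is inclusive on the lattice: k1 >= k2 - m*n, i.e.
# k1 >= ceiling(k2 - m*n) with a small tolerance guarding float noise in m*n.
.exact_prob_diff_le <- function(n, p1, p2, m) {
  k2 <- 0:n
  a <- ceiling(k2 - m * n - 1e-9)
  sum(stats::dbinom(k2, n, p2) * stats::pbinom(a - 1, n, p1, lower.tail = FALSE))
}

#' Exact probability of practical non-inferiority (binary endpoint)
#'
#' Under the first perspective both arms share a common success probability
#' (`p_common`). The returned value is the exact joint-binomial probability
#' \eqn{\Pr(\hat p_2 - \hat p_1 \le \mathrm{MPE})}, the inequality inclusive.
#'
#' @param n_per_arm Per-arm sample size.
#' @param p_common Common success probability under equivalence.
#' @param margin_points Margin as a difference in proportions.
#' @param exact_limit Largest n for which exact enumeration is performed;
#'   larger n must use [mc_prob()].
#' @return A probability.
#' @export
exact_prob_noninf <- function(n_per_arm, p_common, margin_points,
                              exact_limit = 2000L) {
  .assert_count(n_per_arm, "n_per_arm")
  .assert_prob(p_common, "p_common")
  .assert(is.numeric(margin_points) && length(margin_points) == 1L && margin_points >= 0,
          "`margin_points` must be a single non-negative number")
  .assert(n_per_arm <= exact_limit,
          sprintf("n_per_arm = %d exceeds exact_limit = %d: use mc_prob() for Monte Carlo estimation",
                  n_per_arm, exact_limit))
  .exact_prob_diff_le(n_per_arm, p_common, p_common, margin_points)
}

#' Exact probability of concluding practical inferiority (binary endpoint)
#'
#' Under the second perspective the approved arm keeps `p_approved` while
#' the reduced arm falls to `p_reduced_inferior`; returns the exact
#' probability of the strict complement event
#' \eqn{\Pr(\hat p_2 - \hat p_1 > \mathrm{MPE})}.
#'
#' @param n_per_arm Per-arm sample size.
#' @param spec A [binary_design_spec()].
#' @return A probability.
#' @export
exact_prob_inf <- function(n_per_arm, spec) {
  stopifnot(inherits(spec, "binary_design_spec"))
  .assert_count(n_per_arm, "n_per_arm")
  .assert(n_per_arm <= spec$exact_limit,
          sprintf("n_per_arm = %d exceeds exact_limit = %d: use mc_prob() for Monte Carlo estimation",
                  n_per_arm, spec$exact_limit))
  1 - .exact_prob_diff_le(n_per_arm, spec$p_reduced_inferior, spec$p_approved,
                          spec$margin_points)
}

#' Monte Carlo probability for the binary endpoint
#'
#' Seeded simulation of trial replicates: each replicate draws
#' \eqn{k_1 \sim \mathrm{Bin}(n, p_1)} and \eqn{k_2 \sim \mathrm{Bin}(n,
#' p_2)} and evaluates the same lattice inequality as the exact routines
#' (inclusive for `"noninf"`, strict for `"inf"`). Bit-reproducible for a
#' fixed seed.
#'
#' @param n_per_arm Per-arm sample size.
#' @param rate_arm1,rate_arm2 Success probabilities of the two arms
#'   (arm 2 is the reduced dose whose shortfall the margin bounds).
#' @param margin_points Margin as a difference in proportions.
#' @param mc_reps Number of replicates (at least 1000).
#' @param seed RNG seed.
#' @param event `"noninf"` for \eqn{\Pr(\hat p_2 - \hat p_1 \le m)},
#'   `"inf"` for the strict complement.
#' @return A list with `estimate`, `se` (binomial standard error), `reps`,
#'   `event`, `seed`.
#' @export
mc_prob <- function(n_per_arm, rate_arm1, rate_arm2, margin_points,
                    mc_reps = 100000L, seed = 20260926L,
                    event = c("noninf", "inf")) {
  event <- match.arg(event)
  .assert_count(n_per_arm, "n_per_arm")
  .assert_prob(rate_arm1, "rate_arm1", open_left = FALSE, open_right = FALSE)
  .assert_prob(rate_arm2, "rate_arm2", open_left = FALSE, open_right = FALSE)
  .assert_count(mc_reps, "mc_reps", min = 1000L)
  hit <- .with_seed(seed, {
    k1 <- stats::rbinom(mc_reps, n_per_arm, rate_arm1)
    k2 <- stats::rbinom(mc_reps, n_per_arm, rate_arm2)
    le <- (k2 - k1) <= margin_points * n_per_arm + 1e-9
    if (event == "noninf") le else !le
  })
  est <- mean(hit)
  list(estimate = est, se = sqrt(est * (1 - est) / mc_reps),
       reps = as.integer(mc_reps), event = event, seed = as.integer(seed))
}

# pi_n / kappa_n at a single n, switching to MC above exact_limit.
# MC seeds are offset by n so each grid point is an independent,
# reproducible stream.
.binary_prob_at <- function(n, spec, which = c("noninf", "inf")) {
  which <- match.arg(which)
  if (n <= spec$exact_limit) {
    if (which == "noninf")
      .exact_prob_diff_le(n, spec$p_approved, spec$p_approved, spec$margin_points)
    else
      1 - .exact_prob_diff_le(n, spec$p_reduced_inferior, spec$p_approved, spec$margin_points)
  } else {
    rates <- if (which == "noninf") c(spec$p_approved, spec$p_approved)
             else c(spec$p_reduced_inferior, spec$p_approved)
    mc_prob(n, rates[1L], rates[2L], spec$margin_points, spec$mc_reps,
            seed = (spec$seed + n) %% .Machine$integer.max, event = which)$estimate
  }
}

# Exact binomial probabilities on the lattice are not monotone in n, so the
# grid search scans every integer n rather than bisecting.
.binary_scan <- function(spec, which, target) {
  for (n in seq_len(spec$n_cap)) {
    if (.binary_prob_at(n, spec, which) >= target) return(n)
  }
  .stop_unattainable(sprintf(
    "no per-arm n up to n_cap = %d attains the %s threshold %.3f", spec$n_cap,
    if (which == "noninf") "Q" else "Z", target))
}

#' Smallest per-arm sample size meeting Q (binary endpoint)
#' @param spec A [binary_design_spec()].
#' @return The smallest integer n with \eqn{\pi_n \ge Q}.
#' @export
n_hat_noninf_binary <- function(spec) {
  stopifnot(inherits(spec, "binary_design_spec"))
  .binary_scan(spec, "noninf", spec$q_threshold)
}

#' Smallest per-arm sample size meeting Z (binary endpoint)
#' @param spec A [binary_design_spec()].
#' @return The smallest integer n with \eqn{\kappa_n \ge Z}.
#' @export
n_hat_inf_binary <- function(spec) {
  stopifnot(inherits(spec, "binary_design_spec"))
  .binary_scan(spec, "inf", spec$z_threshold)
}

#' Recommended per-arm sample size for a binary endpoint
#'
#' Maximum of the two grid-search solutions, with both components and the
#' probabilities achieved at the recommended n.
#'
#' @param spec A [binary_design_spec()].
#' @return A list of class `pni_recommendation`.
#' @export
recommended_n_binary <- function(spec) {
  stopifnot(inherits(spec, "binary_design_spec"))
  n1 <- n_hat_noninf_binary(spec)
  n2 <- n_hat_inf_binary(spec)
  n <- max(n1, n2)
  structure(list(
    n_noninf = n1, n_inf = n2, recommended = n,
    prob_noninf = .binary_prob_at(n, spec, "noninf"),
    prob_inf = .binary_prob_at(n, spec, "inf"),
    q_threshold = spec$q_threshold, z_threshold = spec$z_threshold
  ), class = "pni_recommendation")
}
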