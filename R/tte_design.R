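#' Specify a time-to-event practical non-inferiority design
#'
#' A dose-optimization (dose-reduction) trial compares a reduced dose of an
#' approved drug against the approved regimen and declares the reduced dose
#' practically non-inferior when the *observed* difference in median survival
#' lies within a pre-specified margin. Under the exponential survival model
#' with rate \eqn{\lambda = \ln 2 / \tilde{T}} (median \eqn{\tilde{T}}), a
#' margin stated as a ratio of medians maps one-to-one onto a log-hazard
#' margin \eqn{\mathrm{MPE} = \ln(\mathrm{ratio}) < 0}, because the hazard
#' ratio equals the inverse ratio of medians.
#'
#' The design is evaluated from two perspectives:
#' \describe{
#'   \item{non-inferiority (\eqn{\pi_n})}{probability that the observed
#'     difference falls within the margin, assuming the doses are truly
#'     equivalent; must reach the threshold `q_threshold` (Q).}
#'   \item{inferiority (\eqn{\kappa_n})}{probability that the observed
#'     difference falls outside the margin, assuming the reduced dose truly
#'     has the efficacy of the historical control (or another meaningful
#'     decrement); must reach the threshold `z_threshold` (Z).}
#' }
#'
#' The margin may be given either as a ratio of medians in (0, 1)
#' (`margin_ratio`) or as an absolute width in months (`margin_months`,
#' converted internally via `1 - margin_months / median_approved`); the ratio
#' is the canonical stored form.
#'
#' @param median_approved Median survival of the approved dose, in months.
#' @param median_reference_inferior Median survival regarded as a meaningful
#'   decrement — typically the historical control arm of the prior phase III
#'   trial. Must be smaller than `median_approved`.
#' @param margin_ratio Margin as a ratio of medians, in (0, 1). Exactly one
#'   of `margin_ratio` and `margin_months` must be supplied.
#' @param margin_months Margin as an absolute width in months.
#' @param q_threshold Threshold Q for the non-inferiority perspective.
#' @param z_threshold Threshold Z for the inferiority perspective.
#' @param p_noncensor Probability p that a patient's event is observed
#'   (non-censoring probability), in (0, 1]. It enters the sampling variance
#'   \eqn{2/(np)} of the difference of log rate estimates.
#' @param n_cap Upper bound for the per-arm sample-size grid searches.
#'
#' @return An object of class `tte_design_spec`.
#' @examples
#' spec <- tte_design_spec(15.1, 12.7, margin_ratio = 0.90,
#'                         q_threshold = 0.90, z_threshold = 0.80)
#' prob_practical_noninf(300, spec)
#' prob_practical_inf(300, spec)
#' @export
tte_design_spec <- function(median_approved, median_reference_inferior,
                            margin_ratio = NULL, margin_months = NULL,
                            q_threshold = 0.80, z_threshold = 0.80,
                            p_noncensor = 1, n_cap = 100000L) {
  .assert(is.numeric(median_approved) && length(median_approved) == 1L && median_approved > 0,
          "`median_approved` must be a single positive number of months")
  .assert(is.numeric(median_reference_inferior) && length(median_reference_inferior) == 1L &&
            median_reference_inferior > 0,
          "`median_reference_inferior` must be a single positive number of months")
  .assert(median_reference_inferior < median_approved,
          "`median_reference_inferior` must be smaller than `median_approved` (the reference decrement must be worse)")
  .assert(xor(is.null(margin_ratio), is.null(margin_months)),
          "supply exactly one of `margin_ratio` or `margin_months`")
  if (is.null(margin_ratio)) {
    .assert(is.numeric(margin_months) && length(margin_months) == 1L &&
              margin_months > 0 && margin_months < median_approved,
            "`margin_months` must lie in (0, median_approved)")
    margin_ratio <- 1 - margin_months / median_approved
  }
  .assert_prob(margin_ratio, "margin_ratio")
  .assert_prob(q_threshold, "q_threshold")
  .assert_prob(z_threshold, "z_threshold")
  .assert_prob(p_noncensor, "p_noncensor", open_right = FALSE)
  .assert_count(n_cap, "n_cap")

  structure(list(
    median_approved = median_approved,
    median_reference_inferior = median_reference_inferior,
    margin_ratio = margin_ratio,
    q_threshold = q_threshold,
    z_threshold = z_threshold,
    p_noncensor = p_noncensor,
    n_cap = as.integer(n_cap)
  ), class = "tte_design_spec")
}

#' @export
print.tte_design_spec <- function(x, ...) {
  mm <- margin_as_months(x)
  cat("Time-to-event practical non-inferiority design\n")
  cat(sprintf("  approved median: %.1f months; reference decrement: %.1f months\n",
              x$median_approved, x$median_reference_inferior))
  cat(sprintf("  margin: ratio of medians %.3f (threshold median %.1f, width %.1f months)\n",
              x$margin_ratio, mm$threshold_median, mm$margin_width))
  cat(sprintf("  thresholds: Q = %.2f, Z = %.2f; non-censoring p = %.2f\n",
              x$q_threshold, x$z_threshold, x$p_noncensor))
  invisible(x)
}

.tte_sd <- function(n, p) sqrt(2 / (n * p))

#' Probability of practical non-inferiority (time-to-event)
#'
#' Computes \eqn{\pi_n = \Pr(\mathrm{MPE} \le \ln\hat\lambda_2 -
#' \ln\hat\lambda_1)} under the assumption that the two doses are truly
#' equivalent (\eqn{\lambda_1 = \lambda_2}). The difference of log rate
#' estimates is normally distributed with mean 0 and variance \eqn{2/(np)},
#' so \eqn{\pi_n = \Phi(-\ln(\mathrm{ratio})\sqrt{np/2})}. Ties at the
#' margin count as non-inferior (inclusive inequality).
#'
#' @param n_per_arm Per-arm sample size(s); vectorized.
#' @param spec A [tte_design_spec()].
#' @return Probability (or vector of probabilities) in [0, 1].
#' @export
prob_practical_noninf <- function(n_per_arm, spec) {
  stopifnot(inherits(spec, "tte_design_spec"))
  .assert(is.numeric(n_per_arm) && length(n_per_arm) >= 1L && all(n_per_arm >= 1) &&
            all(n_per_arm == floor(n_per_arm)),
          "`n_per_arm` must contain positive integers")
  stats::pnorm(-log(spec$margin_ratio) / .tte_sd(n_per_arm, spec$p_noncensor))
}

#' Probability of concluding practical inferiority (time-to-event)
#'
#' Computes \eqn{\kappa_n = \Pr(\ln\hat\lambda_2 - \ln\hat\lambda_1 <
#' \mathrm{MPE})} under the second design perspective: the reduced dose truly
#' has the median of the reference decrement, so the difference of log rate
#' estimates is centred at the true log ratio of medians
#' \eqn{\ln(\tilde T_{\mathrm{ref}} / \tilde T_{\mathrm{approved}})} with
#' variance \eqn{2/(np)}.
#'
#' @inheritParams prob_practical_noninf
#' @return Probability (or vector of probabilities) in [0, 1].
#' @export
prob_practical_inf <- function(n_per_arm, spec) {
  stopifnot(inherits(spec, "tte_design_spec"))
  .assert(is.numeric(n_per_arm) && length(n_per_arm) >= 1L && all(n_per_arm >= 1) &&
            all(n_per_arm == floor(n_per_arm)),
          "`n_per_arm` must contain positive integers")
  .assert(spec$median_reference_inferior < spec$median_approved,
          "the reference decrement median must be below the approved median")
  mu <- log(spec$median_reference_inferior / spec$median_approved)
  stats::pnorm((log(spec$margin_ratio) - mu) / .tte_sd(n_per_arm, spec$p_noncensor))
}

# First n in 1..n_cap (ascending, step 1) whose probability meets `target`.
# The scan is chunked so the Gaussian CDF is evaluated vectorized.
.scan_first_n <- function(prob_fun, target, n_cap, what) {
  lo <- 1L
  chunk <- 4096L
  while (lo <= n_cap) {
    hi <- min(n_cap, lo + chunk - 1L)
    ns <- lo:hi
    hit <- which(prob_fun(ns) >= target)
    if (length(hit)) return(ns[hit[1L]])
    lo <- hi + 1L
    chunk <- min(chunk * 4L, 262144L)
  }
  .stop_unattainable(sprintf(
    "no per-arm n up to n_cap = %d attains %s; increase n_cap or relax the design", n_cap, what))
}

#' Smallest per-arm sample size meeting the non-inferiority threshold Q
#'
#' Grid search for \eqn{\hat n^{\mathrm{non\text{-}inf}} = \arg\min_n
#' \{\pi_n \ge Q\}}, scanning every integer n from 1 up to `n_cap`.
#'
#' @param spec A [tte_design_spec()].
#' @return The smallest integer n with \eqn{\pi_n \ge Q}.
#' @export
n_hat_noninf <- function(spec) {
  stopifnot(inherits(spec, "tte_design_spec"))
  .scan_first_n(function(n) prob_practical_noninf(n, spec),
                spec$q_threshold, spec$n_cap,
                sprintf("pi_n >= Q = %.3f (margin ratio %.3f)", spec$q_threshold, spec$margin_ratio))
}

#' Smallest per-arm sample size meeting the inferiority threshold Z
#'
#' Grid search for \eqn{\hat n^{\mathrm{inf}} = \arg\min_n \{\kappa_n \ge
#' Z\}}. Requires the true log ratio of medians to lie strictly outside the
#' margin (otherwise \eqn{\kappa_n} does not tend to 1 and the design is
#' unattainable for Z > 1/2).
#'
#' @param spec A [tte_design_spec()].
#' @return The smallest integer n with \eqn{\kappa_n \ge Z}.
#' @export
n_hat_inf <- function(spec) {
  stopifnot(inherits(spec, "tte_design_spec"))
  mu <- log(spec$median_reference_inferior / spec$median_approved)
  if (mu >= log(spec$margin_ratio) && spec$z_threshold > 0.5) {
    .stop_unattainable(paste0(
      "the true ratio of medians lies inside the margin (",
      sprintf("%.3f >= %.3f", exp(mu), spec$margin_ratio),
      "): kappa_n cannot reach Z > 0.5 for any n"))
  }
  .scan_first_n(function(n) prob_practical_inf(n, spec),
                spec$z_threshold, spec$n_cap,
                sprintf("kappa_n >= Z = %.3f", spec$z_threshold))
}

#' Recommended per-arm sample size (both perspectives)
#'
#' The recommended per-arm n is
#' \eqn{\max(\hat n^{\mathrm{non\text{-}inf}}, \hat n^{\mathrm{inf}})}, so
#' that both the Q threshold on \eqn{\pi_n} and the Z threshold on
#' \eqn{\kappa_n} are met.
#'
#' @param spec A [tte_design_spec()].
#' @return A list of class `pni_recommendation` with components
#'   `n_noninf`, `n_inf`, `recommended`, and the achieved probabilities
#'   `prob_noninf` / `prob_inf` at the recommended n.
#' @export
recommended_n <- function(spec) {
  stopifnot(inherits(spec, "tte_design_spec"))
  n1 <- n_hat_noninf(spec)
  n2 <- n_hat_inf(spec)
  n <- max(n1, n2)
  structure(list(
    n_noninf = n1, n_inf = n2, recommended = n,
    prob_noninf = prob_practical_noninf(n, spec),
    prob_inf = prob_practical_inf(n, spec),
    q_threshold = spec$q_threshold, z_threshold = spec$z_threshold
  ), class = "pni_recommendation")
}

#' @export
print.pni_recommendation <- function(x, ...) {
  cat("Recommended per-arm sample size:", x$recommended, "\n")
  cat(sprintf("  non-inferiority perspective: n = %d (Q = %.2f)\n", x$n_noninf, x$q_threshold))
  cat(sprintf("  inferiority perspective:     n = %d (Z = %.2f)\n", x$n_inf, x$z_threshold))
  cat(sprintf("  achieved at n = %d: pi = %.4f (%s), kappa = %.4f (%s)\n",
              x$recommended, x$prob_noninf, .pct(x$prob_noninf),
              x$prob_inf, .pct(x$prob_inf)))
  invisible(x)
}

#' Express the margin on the months scale
#'
#' Translates the stored ratio-of-medians margin into a threshold median
#' (the smallest median the reduced dose may show and still be practically
#' non-inferior) and a margin width in months, both rounded to one decimal
#' as medians are conventionally reported.
#'
#' @param spec A [tte_design_spec()].
#' @return A list with `threshold_median` and `margin_width`, in months.
#' @examples
#' margin_as_months(tte_design_spec(15.1, 12.7, margin_ratio = 0.90))
#' @export
margin_as_months <- function(spec) {
  stopifnot(inherits(spec, "tte_design_spec"))
  thr <- round(spec$margin_ratio * spec$median_approved, 1)
  list(threshold_median = thr,
       margin_width = round(spec$median_approved - thr, 1))
}

#' Operating-characteristic curve over a grid of sample sizes
#'
#' Evaluates \eqn{\pi_n} and \eqn{\kappa_n} over a grid of per-arm sample
#' sizes, giving the design curves from which the two argmin sample sizes
#' are read off.
#'
#' @param spec A [tte_design_spec()].
#' @param n_min,n_max Grid limits (per arm), `1 <= n_min <= n_max`.
#' @param step Grid step.
#' @return A data frame of class `operating_characteristics` with columns
#'   `n_per_arm`, `prob_noninf`, `prob_inf`.
#' @export
design_curve <- function(spec, n_min, n_max, step = 1L) {
  stopifnot(inherits(spec, "tte_design_spec"))
  .assert_count(n_min, "n_min"); .assert_count(n_max, "n_max"); .assert_count(step, "step")
  .assert(n_min <= n_max, "`n_min` must not exceed `n_max` (empty grid)")
  ns <- seq.int(n_min, n_max, by = step)
  structure(data.frame(
    n_per_arm = as.integer(ns),
    prob_noninf = prob_practical_noninf(ns, spec),
    prob_inf = prob_practical_inf(ns, spec)
  ), class = c("operating_characteristics", "data.frame"),
  q_threshold = spec$q_threshold, z_threshold = spec$z_threshold)
}

#' Plot an operating-characteristic curve
#'
#' Renders \eqn{\pi_n} and \eqn{\kappa_n} against the per-arm sample size,
#' with horizontal reference lines at the design thresholds Q and Z.
#'
#' @param x An `operating_characteristics` data frame from [design_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.operating_characteristics <- function(x, ...) {
  long <- data.frame(
    n_per_arm = rep(x$n_per_arm, 2L),
    probability = c(x$prob_noninf, x$prob_inf),
    perspective = rep(c("P[non-inf] (equivalent doses)",
                        "P[inf] (reduced dose at reference decrement)"),
                      each = nrow(x))
  )
  refs <- data.frame(threshold = c(attr(x, "q_threshold"), attr(x, "z_threshold")),
                     label = c("Q", "Z"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_per_arm, y = .data$probability,
                                     colour = .data$perspective)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = refs,
                        ggplot2::aes(yintercept = .data$threshold, linetype = .data$label)) +
    ggplot2::labs(x = "patients per arm", y = "probability",
                  colour = NULL, linetype = "threshold") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
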