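#' Bootstrap verification of a practical non-inferiority design
#'
#' Verifies a closed-form sample-size calculation by resampling individual
#' patient data, mirroring how a design team would stress-test the
#' calculation against the phase III data actually in hand. Two scenarios
#' are simulated, `reps` replicates each:
#'
#' \describe{
#'   \item{non-inferiority}{both simulated arms are drawn with replacement
#'     (size `n_per_arm`) from the approved arm's patients, imposing exact
#'     equivalence; `p_noninf` is the fraction of replicates whose observed
#'     difference in Kaplan-Meier medians (approved minus reduced) is within
#'     `margin_months`.}
#'   \item{inferiority}{the simulated approved arm is drawn from
#'     `approved_arm` and the simulated reduced arm from
#'     `reduced_source_arm` (typically the historical control); `p_inf` is
#'     the fraction of replicates whose difference exceeds `margin_months`.}
#' }
#'
#' A replicate arm whose median is not reached is treated as median
#' `Inf`: an unreached reduced-arm median classifies the replicate as
#' non-inferior, an unreached approved-arm median (with the reduced median
#' finite) as inferior. Counts of such replicates are reported; none are
#' dropped.
#'
#' @param data A [survival_dataset()] with both source arms.
#' @param approved_arm Label of the arm carrying the approved dose's data.
#' @param reduced_source_arm Label of the arm the inferiority scenario draws
#'   the reduced dose from.
#' @param n_per_arm Simulated per-arm sample size (may exceed the source arm
#'   size; sampling is with replacement).
#' @param margin_months Margin of practical non-inferiority, in months.
#' @param reps Number of bootstrap replicates per scenario.
#' @param seed RNG seed.
#' @return An object of class `bootstrap_report`: replicate-level median
#'   differences per scenario (`diff_noninf`, `diff_inf`), estimates
#'   `p_noninf` / `p_inf` with Monte Carlo standard errors, unreached-median
#'   counts, and the inputs.
#' @examples
#' src <- gen_exponential_cohort(median = c(15.1, 12.7), n = c(120, 120),
#'                               arm = c("approved", "control"), seed = 1)
#' bootstrap_verify(src, "approved", "control", n_per_arm = 100,
#'                  margin_months = 1.5, reps = 200, seed = 2)
#' @export
bootstrap_verify <- function(data, approved_arm, reduced_source_arm, n_per_arm,
                             margin_months, reps = 10000L, seed = 20260926L) {
  stopifnot(inherits(data, "survival_dataset"))
  .assert(approved_arm %in% data$arm, sprintf("arm '%s' not in dataset", approved_arm))
  .assert(reduced_source_arm %in% data$arm, sprintf("arm '%s' not in dataset", reduced_source_arm))
  .assert_count(n_per_arm, "n_per_arm")
  .assert(is.numeric(margin_months) && length(margin_months) == 1L && margin_months >= 0,
          "`margin_months` must be a single non-negative number")
  .assert_count(reps, "reps")

  app <- data[data$arm == approved_arm, ]
  red <- data[data$arm == reduced_source_arm, ]
  if (n_per_arm > nrow(app) || n_per_arm > nrow(red))
    message(sprintf("n_per_arm = %d exceeds a source arm size (%d / %d); resampling with replacement",
                    n_per_arm, nrow(app), nrow(red)))

  draw_med <- function(t, e) {
    i <- sample.int(length(t), n_per_arm, replace = TRUE)
    .km_median_fast(t[i], e[i])
  }

  res <- .with_seed(seed, {
    d_ni <- numeric(reps); d_inf <- numeric(reps)
    for (r in seq_len(reps)) {
      # non-inferiority scenario: both roles resampled from the approved arm
      d_ni[r] <- draw_med(app$time, app$event) - draw_med(app$time, app$event)
      # inferiority scenario: reduced role falls back to the historical control
      d_inf[r] <- draw_med(app$time, app$event) - draw_med(red$time, red$event)
    }
    list(d_ni = d_ni, d_inf = d_inf)
  })

  classify <- function(d) {
    # d = approved median - reduced median; NaN arises only when both are Inf,
    # i.e. the reduced median is unreached -> non-inferior by policy
    noninf <- ifelse(is.nan(d), TRUE, d <= margin_months)
    list(noninf = noninf, unreached = sum(is.infinite(d) | is.nan(d)))
  }
  cl_ni <- classify(res$d_ni)
  cl_inf <- classify(res$d_inf)
  p_ni <- mean(cl_ni$noninf)
  p_inf <- mean(!cl_inf$noninf)

  structure(list(
    diff_noninf = res$d_ni, diff_inf = res$d_inf,
    p_noninf = p_ni, p_inf = p_inf,
    se_noninf = sqrt(p_ni * (1 - p_ni) / reps),
    se_inf = sqrt(p_inf * (1 - p_inf) / reps),
    unreached_noninf = cl_ni$unreached, unreached_inf = cl_inf$unreached,
    reps = as.integer(reps), seed = as.integer(seed),
    n_per_arm = as.integer(n_per_arm), margin_months = margin_months,
    approved_arm = approved_arm, reduced_source_arm = reduced_source_arm,
    statistic = "km_median_difference"
  ), class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("Bootstrap verification (%d replicates/scenario, n = %d/arm, margin %.2f %s)\n",
              x$reps, x$n_per_arm, x$margin_months,
              if (identical(x$statistic, "km_median_difference")) "months" else "proportion points"))
  cat(sprintf("  P[non-inf] = %.4f (%s; MC se %.4f)\n", x$p_noninf, .pct(x$p_noninf), x$se_noninf))
  cat(sprintf("  P[inf]     = %.4f (%s; MC se %.4f)\n", x$p_inf, .pct(x$p_inf), x$se_inf))
  if (x$unreached_noninf + x$unreached_inf > 0)
    cat(sprintf("  replicates with unreached median: %d (non-inf scenario), %d (inf scenario)\n",
                x$unreached_noninf, x$unreached_inf))
  invisible(x)
}

#' Plot a bootstrap report as scenario histograms
#'
#' Histograms of the replicate-level observed differences for the two
#' scenarios, with a vertical line at the margin.
#'
#' @param x A [bootstrap_verify()] or [fixed_time_verify()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.bootstrap_report <- function(x, ...) {
  df <- data.frame(
    difference = c(x$diff_noninf, x$diff_inf),
    scenario = rep(c("equivalent doses", "reduced dose at reference decrement"),
                   c(length(x$diff_noninf), length(x$diff_inf)))
  )
  df <- df[is.finite(df$difference), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$difference)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = x$margin_months, linetype = "dashed") +
    ggplot2::facet_wrap(~scenario, ncol = 1L) +
    ggplot2::labs(x = "observed difference (approved - reduced)", y = "replicates") +
    ggplot2::theme_minimal()
}

#' Calibrate the margin against conventional non-inferiority
#'
#' For each candidate margin, simulates equivalence-scenario replicates
#' (both arms resampled with replacement from the approved arm's data) and
#' reports, among replicates achieving practical non-inferiority (observed
#' median difference within the margin), the fraction that would also have
#' achieved *conventional* non-inferiority. Conventional non-inferiority is
#' declared when the upper limit of the two-sided (1 - 2 alpha) confidence
#' interval for the hazard ratio (reduced vs approved) falls below
#' `conventional_margin_hr`. The hazard ratio is estimated by the
#' exponential-rate MLE \eqn{\hat\lambda = d / \sum t} per arm, with
#' log-hazard-ratio variance \eqn{1/d_1 + 1/d_2}; this keeps the
#' calibration inside the exponential framework of the closed-form
#' calculation rather than fitting a Cox model.
#'
#' @param data A [survival_dataset()].
#' @param approved_arm Arm supplying the equivalence-scenario patients.
#' @param n_per_arm Simulated per-arm size.
#' @param candidate_margins Positive candidate margins, in months.
#' @param conventional_margin_hr Conventional non-inferiority margin on the
#'   hazard-ratio scale, greater than 1.
#' @param alpha One-sided level of the conventional test.
#' @param reps Replicates (shared across candidate margins).
#' @param seed RNG seed.
#' @return A data frame with one row per candidate margin: the margin, the
#'   number of conditioning replicates, and the conditional probability of
#'   conventional non-inferiority (`NA` when no replicate meets practical
#'   non-inferiority).
#' @export
margin_calibration <- function(data, approved_arm, n_per_arm, candidate_margins,
                               conventional_margin_hr, alpha = 0.025,
                               reps = 10000L, seed = 20260926L) {
  stopifnot(inherits(data, "survival_dataset"))
  .assert(approved_arm %in% data$arm, sprintf("arm '%s' not in dataset", approved_arm))
  .assert_count(n_per_arm, "n_per_arm")
  .assert(is.numeric(candidate_margins) && length(candidate_margins) >= 1L &&
            all(candidate_margins > 0), "`candidate_margins` must be positive")
  .assert(is.numeric(conventional_margin_hr) && length(conventional_margin_hr) == 1L &&
            conventional_margin_hr > 1,
          "`conventional_margin_hr` must exceed 1 on the hazard scale")
  .assert_prob(alpha, "alpha")
  .assert_count(reps, "reps")

  app <- data[data$arm == approved_arm, ]
  zq <- stats::qnorm(1 - alpha)

  sim <- .with_seed(seed, {
    d <- numeric(reps); conv <- logical(reps)
    for (r in seq_len(reps)) {
      ia <- sample.int(nrow(app), n_per_arm, replace = TRUE)
      ir <- sample.int(nrow(app), n_per_arm, replace = TRUE)
      ta <- app$time[ia]; ea <- app$event[ia]
      tr <- app$time[ir]; er <- app$event[ir]
      d[r] <- .km_median_fast(ta, ea) - .km_median_fast(tr, er)
      da <- sum(ea); dr <- sum(er)
      if (da > 0 && dr > 0) {
        # HR of reduced vs approved under the exponential model
        loghr <- log(dr / sum(tr)) - log(da / sum(ta))
        conv[r] <- exp(loghr + zq * sqrt(1 / da + 1 / dr)) < conventional_margin_hr
      } else conv[r] <- FALSE
    }
    list(d = d, conv = conv)
  })

  out <- lapply(candidate_margins, function(m) {
    # same signed within-margin rule as bootstrap_verify
    within <- ifelse(is.nan(sim$d), TRUE, sim$d <= m)
    k <- sum(within)
    data.frame(margin_months = m, n_conditioning = k,
               conditional_prob_conventional_ni = if (k == 0L) NA_real_ else mean(sim$conv[within]))
  })
  out <- do.call(rbind, out)
  attr(out, "reps") <- as.integer(reps)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Bootstrap verification on a fixed-time survival difference
#'
#' Variant of [bootstrap_verify()] in which the replicate statistic is the
#' difference in Kaplan-Meier survival probabilities at a fixed time point
#' (for example one-year survival), compared against a margin in proportion
#' points. Scenarios, resampling, and reporting mirror [bootstrap_verify()].
#'
#' @inheritParams bootstrap_verify
#' @param t_star Evaluation time in months; must be within the observed
#'   follow-up of both source arms.
#' @param margin_points Margin as a difference in survival probabilities.
#' @return A `bootstrap_report` whose `diff_*` components are differences in
#'   survival probability at `t_star`.
#' @export
fixed_time_verify <- function(data, approved_arm, reduced_source_arm, n_per_arm,
                              t_star, margin_points, reps = 10000L,
                              seed = 20260926L) {
  stopifnot(inherits(data, "survival_dataset"))
  .assert(approved_arm %in% data$arm, sprintf("arm '%s' not in dataset", approved_arm))
  .assert(reduced_source_arm %in% data$arm, sprintf("arm '%s' not in dataset", reduced_source_arm))
  .assert_count(n_per_arm, "n_per_arm")
  .assert(is.numeric(t_star) && length(t_star) == 1L && t_star > 0,
          "`t_star` must be a single positive time in months")
  .assert(is.numeric(margin_points) && length(margin_points) == 1L && margin_points >= 0,
          "`margin_points` must be a single non-negative number")
  .assert_count(reps, "reps")

  app <- data[data$arm == approved_arm, ]
  red <- data[data$arm == reduced_source_arm, ]
  .assert(t_star <= max(app$time) && t_star <= max(red$time),
          sprintf("t_star = %.2f exceeds the observed follow-up of a source arm", t_star))

  draw_surv <- function(t, e) {
    i <- sample.int(length(t), n_per_arm, replace = TRUE)
    .km_surv_at_fast(t[i], e[i], t_star)
  }

  res <- .with_seed(seed, {
    d_ni <- numeric(reps); d_inf <- numeric(reps)
    for (r in seq_len(reps)) {
      d_ni[r] <- draw_surv(app$time, app$event) - draw_surv(app$time, app$event)
      d_inf[r] <- draw_surv(app$time, app$event) - draw_surv(red$time, red$event)
    }
    list(d_ni = d_ni, d_inf = d_inf)
  })

  p_ni <- mean(res$d_ni <= margin_points)
  p_inf <- mean(res$d_inf > margin_points)
  structure(list(
    diff_noninf = res$d_ni, diff_inf = res$d_inf,
    p_noninf = p_ni, p_inf = p_inf,
    se_noninf = sqrt(p_ni * (1 - p_ni) / reps),
    se_inf = sqrt(p_inf * (1 - p_inf) / reps),
    unreached_noninf = 0L, unreached_inf = 0L,
    reps = as.integer(reps), seed = as.integer(seed),
    n_per_arm = as.integer(n_per_arm), margin_months = margin_points,
    approved_arm = approved_arm, reduced_source_arm = reduced_source_arm,
    t_star = t_star, statistic = "fixed_time_survival_difference"
  ), class = "bootstrap_report")
}
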