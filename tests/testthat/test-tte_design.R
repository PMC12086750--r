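test_that("closed-form pi and kappa match numerical-integration oracles and the case study", {
  spec <- case_study_spec()

  # equivalence perspective at the case-study margin
  expect_equal(prob_practical_noninf(300, spec),
               oracle_gauss_tail(log(0.90), 0, sqrt(2 / 300)), tolerance = 1e-9)
  expect_equal(round(prob_practical_noninf(300, spec), 4), 0.9015)

  # inferiority perspective centred at the true log ratio of medians
  expect_equal(prob_practical_inf(300, spec),
               1 - oracle_gauss_tail(log(0.90), log(12.7 / 15.1), sqrt(2 / 300)),
               tolerance = 1e-9)
  expect_equal(round(prob_practical_inf(300, spec), 4), 0.7966)

  # degenerate margins: ratio -> 1 gives a symmetric Gaussian about 0
  near1 <- tte_design_spec(15.1, 12.7, margin_ratio = 1 - 1e-12)
  expect_equal(prob_practical_noninf(17, near1), 0.5, tolerance = 1e-5)
  # true ratio of medians exactly on the margin centres D on the margin
  on_margin <- tte_design_spec(15.1, 15.1 * 0.9, margin_ratio = 0.9)
  expect_equal(prob_practical_inf(123, on_margin), 0.5)

  expect_error(prob_practical_noninf(0, spec), "positive integer")
  expect_error(tte_design_spec(15.1, 12.7, margin_ratio = 0.9, p_noncensor = 1.2),
               "p_noncensor")
  expect_error(tte_design_spec(12.7, 15.1, margin_ratio = 0.9), "smaller")
})

test_that("sample-size searches equal independent linear-scan oracles", {
  spec <- case_study_spec()
  scan_pi <- function(s) oracle_scan_first(
    function(n) oracle_gauss_tail(log(s$margin_ratio), 0, sqrt(2 / (n * s$p_noncensor))),
    s$q_threshold, 1000)
  scan_kappa <- function(s) oracle_scan_first(
    function(n) 1 - oracle_gauss_tail(log(s$margin_ratio),
                                      log(s$median_reference_inferior / s$median_approved),
                                      sqrt(2 / (n * s$p_noncensor))),
    s$z_threshold, 2000)

  expect_identical(n_hat_noninf(spec), 296L)
  expect_identical(n_hat_noninf(spec), scan_pi(spec))
  expect_identical(n_hat_inf(spec), 309L)
  expect_identical(n_hat_inf(spec), scan_kappa(spec))

  # halving the non-censoring probability doubles the variance, hence ~2x n
  half <- case_study_spec(p = 0.5)
  expect_identical(n_hat_noninf(half), 592L)
  expect_identical(n_hat_noninf(half), scan_pi(half))

  # the true ratio of medians is 12.7/15.1 = 0.841: widening the margin ratio
  # to 0.95 moves it away from the true effect, so fewer patients suffice,
  # while 0.87 sits closer to the true effect and needs more
  wide <- tte_design_spec(15.1, 12.7, margin_ratio = 0.95, z_threshold = 0.80)
  expect_identical(n_hat_inf(wide), scan_kappa(wide))
  expect_lt(n_hat_inf(wide), n_hat_inf(spec))
  toward <- tte_design_spec(15.1, 12.7, margin_ratio = 0.87, z_threshold = 0.80)
  expect_identical(n_hat_inf(toward), scan_kappa(toward))
  expect_gt(n_hat_inf(toward), n_hat_inf(spec))

  # grid-start answers when the threshold is already met at n = 1
  expect_identical(n_hat_noninf(tte_design_spec(15.1, 12.7, margin_ratio = 0.9,
                                                q_threshold = 0.5)), 1L)
  expect_identical(n_hat_inf(tte_design_spec(15.1, 12.7, margin_ratio = 0.9,
                                             z_threshold = 0.5)), 1L)
})

test_that("recommended n is the max of the two perspectives and ignores a generous cap", {
  spec <- case_study_spec()
  rec <- recommended_n(spec)
  expect_identical(rec$recommended, 309L)
  expect_identical(rec$recommended, max(rec$n_noninf, rec$n_inf))
  expect_gte(rec$prob_noninf, spec$q_threshold)
  expect_gte(rec$prob_inf, spec$z_threshold)

  q_drives <- tte_design_spec(15.1, 12.7, margin_ratio = 0.9,
                              q_threshold = 0.99, z_threshold = 0.5)
  expect_identical(recommended_n(q_drives)$recommended, n_hat_noninf(q_drives))

  capped <- tte_design_spec(15.1, 12.7, margin_ratio = 0.9, q_threshold = 0.90,
                            z_threshold = 0.80, n_cap = 400L)
  expect_identical(recommended_n(capped)$recommended, rec$recommended)
  tiny_cap <- tte_design_spec(15.1, 12.7, margin_ratio = 0.9, q_threshold = 0.90,
                              z_threshold = 0.80, n_cap = 100L)
  expect_error(recommended_n(tiny_cap), class = "pni_unattainable_design")
  # true effect inside the margin: kappa can never reach Z > 0.5
  inside <- tte_design_spec(15.1, 14.5, margin_ratio = 0.9, z_threshold = 0.8)
  expect_error(n_hat_inf(inside), class = "pni_unattainable_design")
})

test_that("the margin translates to the months scale", {
  expect_equal(margin_as_months(case_study_spec()),
               list(threshold_median = 13.6, margin_width = 1.5))
  expect_equal(margin_as_months(tte_design_spec(12.0, 8.0, margin_ratio = 0.75)),
               list(threshold_median = 9.0, margin_width = 3.0))
  # a margin entered in months is stored as the equivalent ratio
  by_months <- tte_design_spec(15.1, 12.7, margin_months = 1.5)
  expect_equal(by_months$margin_ratio, 1 - 1.5 / 15.1)
  expect_equal(margin_as_months(by_months)$margin_width, 1.5)
})

test_that("closed-form pi agrees with Monte Carlo under the exponential model", {
  # synthetic equal-median arms, rate estimator log(lambda-hat) = log(d / total time)
  n <- 60L
  reps <- 10000L
  spec <- tte_design_spec(15.1, 12.7, margin_ratio = 0.90)
  d <- withr::with_seed(424242, {
    lam <- log(2) / 15.1
    t1 <- matrix(rexp(n * reps, lam), nrow = reps)
    t2 <- matrix(rexp(n * reps, lam), nrow = reps)
    log(n / rowSums(t2)) - log(n / rowSums(t1))
  })
  pi_mc <- mean(d >= log(0.90))
  pi_cf <- prob_practical_noninf(n, spec)
  expect_lt(abs(pi_mc - pi_cf), 3 * sqrt(pi_cf * (1 - pi_cf) / reps))
})

test_that("pi and kappa are monotone, complementary, and scale invariant", {
  spec <- case_study_spec()
  ns <- c(1, 2, 5, 10, 50, 100, 300, 1000)
  pis <- prob_practical_noninf(ns, spec)
  kas <- prob_practical_inf(ns, spec)
  expect_true(all(pis >= 0 & pis <= 1) && all(kas >= 0 & kas <= 1))
  expect_true(all(diff(pis) > 0))
  expect_true(all(diff(kas) > 0))

  # pi strictly increasing in the non-censoring probability
  p_grid <- c(0.2, 0.5, 0.8, 1)
  expect_true(all(diff(sapply(p_grid, function(p)
    prob_practical_noninf(100, case_study_spec(p = p)))) > 0))

  # the two equivalence-perspective states partition the outcome space
  for (n in ns) {
    pr_below <- stats::pnorm(log(spec$margin_ratio) / sqrt(2 / (n * spec$p_noncensor)))
    expect_equal(prob_practical_noninf(n, spec) + pr_below, 1, tolerance = 1e-12)
  }

  # only the ratio of medians enters: rescale both medians by a constant
  for (c_ in c(0.1, 3.7, 120)) {
    scaled <- tte_design_spec(15.1 * c_, 12.7 * c_, margin_ratio = 0.90,
                              q_threshold = 0.90, z_threshold = 0.80)
    expect_equal(prob_practical_noninf(300, scaled), prob_practical_noninf(300, spec))
    expect_equal(prob_practical_inf(300, scaled), prob_practical_inf(300, spec))
    expect_identical(recommended_n(scaled)$recommended, 309L)
  }
})

test_that("design_curve tabulates both probabilities over the grid", {
  spec <- case_study_spec()
  curve <- design_curve(spec, 10, 400, step = 10)
  expect_s3_class(curve, "operating_characteristics")
  row300 <- curve[curve$n_per_arm == 300, ]
  expect_equal(round(row300$prob_noninf, 2), 0.90)
  expect_equal(round(row300$prob_inf, 2), 0.80)
  # both operating characteristics non-decreasing across the whole grid
  expect_true(all(diff(curve$prob_noninf) >= 0))
  expect_true(all(diff(curve$prob_inf) >= 0))

  expect_identical(nrow(design_curve(spec, 300, 300)), 1L)
  expect_error(design_curve(spec, 10, 5), "empty grid")
})
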