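#' Generate exponential survival cohorts
#'
#' Seeded generator producing individual patient data with the structure
#' the closed-form calculations assume: event times
#' \eqn{T \sim \mathrm{Exp}(\lambda)} with \eqn{\lambda = \ln 2 /
#' \tilde{T}}, and independent right-censoring calibrated so the expected
#' non-censoring probability equals `p_noncensor`.
#'
#' Two censoring families are available:
#' \describe{
#'   \item{`"exponential"`}{censoring times \eqn{C \sim
#'     \mathrm{Exp}(\lambda_c)}; then \eqn{p = \lambda / (\lambda +
#'     \lambda_c)} in closed form, so \eqn{\lambda_c = \lambda (1 - p)/p}.}
#'   \item{`"uniform"`}{administrative censoring \eqn{C \sim U(0, U)}; the
#'     horizon U solving \eqn{p = 1 - (1 - e^{-\lambda U})/(\lambda U)} is
#'     found by root-finding.}
#' }
#' With `p_noncensor = 1` no censoring is applied.
#'
#' Arguments `median`, `n`, `arm`, and `p_noncensor` are recycled to a
#' common number of arms, so a two-arm phase-III-like source dataset is one
#' call.
#'
#' @param median Median survival per arm, months.
#' @param n Patients per arm.
#' @param arm Arm labels (default `"arm1"`, `"arm2"`, ...).
#' @param p_noncensor Target probability that the event is observed.
#' @param censoring Censoring family, `"exponential"` or `"uniform"`.
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @return A [survival_dataset()].
#' @examples
#' gen_exponential_cohort(median = c(15.1, 12.7), n = c(378, 377),
#'                        arm = c("C25", "mitoxantrone"), seed = 42)
#' @export
gen_exponential_cohort <- function(median, n, arm = NULL, p_noncensor = 1,
                                   censoring = c("exponential", "uniform"),
                                   seed = 20260926L) {
  censoring <- match.arg(censoring)
  k <- max(length(median), length(n), length(arm), length(p_noncensor))
  if (is.null(arm)) arm <- paste0("arm", seq_len(k))
  median <- rep_len(median, k); n <- rep_len(as.integer(n), k)
  arm <- rep_len(as.character(arm), k); p_noncensor <- rep_len(p_noncensor, k)
  .assert(all(median > 0), "`median` must be positive")
  .assert(all(n >= 1), "`n` must be positive")
  .assert(all(p_noncensor > 0 & p_noncensor <= 1), "`p_noncensor` must lie in (0, 1]")
  .assert(!anyDuplicated(arm), "arm labels must be distinct")

  .with_seed(seed, {
    parts <- lapply(seq_len(k), function(i) {
      lam <- log(2) / median[i]
      tt <- stats::rexp(n[i], rate = lam)
      p <- p_noncensor[i]
      if (p >= 1) {
        ev <- rep(1L, n[i]); obs <- tt
      } else {
        cc <- switch(censoring,
          exponential = stats::rexp(n[i], rate = lam * (1 - p) / p),
          uniform = {
            u <- stats::uniroot(
              function(U) 1 - (1 - exp(-lam * U)) / (lam * U) - p,
              lower = 1e-8 / lam, upper = 1e8 / lam, tol = 1e-10)$root
            stats::runif(n[i], 0, u)
          })
        ev <- as.integer(tt <= cc)
        obs <- pmin(tt, cc)
      }
      data.frame(arm = arm[i], time = obs, event = ev)
    })
    all <- do.call(rbind, parts)
    survival_dataset(all$arm, all$time, all$event)
  })
}

#' Generate a binomial success count
#'
#' One seeded binomial draw \eqn{k \sim \mathrm{Bin}(n, p)}, the elementary
#' fixture for the binary-endpoint calculations.
#'
#' @param p_success Success probability in [0, 1].
#' @param n Number of patients.
#' @param seed RNG seed.
#' @return An integer success count.
#' @export
gen_binary_cohort <- function(p_success, n, seed = 20260926L) {
  .assert_prob(p_success, "p_success", open_left = FALSE, open_right = FALSE)
  .assert_count(n, "n")
  .with_seed(seed, stats::rbinom(1L, n, p_success))
}
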