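---
title: "Designing dose-optimization trials with a margin of practical non-inferiority"
author: "pnidesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing dose-optimization trials with a margin of practical non-inferiority}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnidesign)
```

## The design problem

Registered oncology doses frequently sit at the maximum tolerated dose, and
post-approval dose-optimization trials ask whether a reduced dose preserves
efficacy with better tolerability. Powering such a trial as a conventional
non-inferiority study — requiring the confidence limit of the hazard ratio
to exclude a fixed margin — typically demands a confirmatory-scale sample
size that is unrealistic after approval. The design implemented here
replaces the confidence-interval criterion with a bound on the *observed*
efficacy difference: a margin of practical non-inferiority. If the observed
difference in median survival (or response proportion) between the reduced
and approved dose falls within the margin, the efficacy component of the
decision is satisfied, and pre-specified secondary endpoints
(quality of life, PK/PD) carry the rest of the decision. The efficacy
readout is deliberately an estimation criterion, not a test.

Because nothing is "rejected", the design is judged by two operating
characteristics at per-arm size $n$:

* $\pi_n$, the probability that the observed difference lies **within** the
  margin when the doses are truly equivalent. The trial should reach a
  threshold $Q$ (we use 0.90 in the case study) so that an equivalent
  reduced dose is likely to be recognized as such.
* $\kappa_n$, the probability that the observed difference lies **outside**
  the margin when the reduced dose in truth only achieves a meaningful
  decrement — canonically, the historical control median of the prior
  phase III trial. The trial should reach a threshold $Z$ (0.80 here) so
  that a dose which merely matches the old control is likely to be flagged
  as practically inferior.

The two probabilities refer to the two exhaustive states of the trial
outcome, so under either data-generating assumption the within-margin and
outside-margin probabilities sum to one; this identity is tested exactly.

## Time-to-event endpoints: the exponential closed form

With survival times $T_i \sim \mathrm{Exp}(\lambda_i)$,
$\lambda_i = \ln 2 / \tilde T_i$, the hazard ratio equals the inverse ratio
of medians, so a margin expressed as a ratio of medians
$r \in (0,1)$ is equivalently a log-hazard margin
$\mathrm{MPE} = \ln r < 0$. The contrast
$\ln\hat\lambda_2 - \ln\hat\lambda_1$ of the per-arm rate estimators is
asymptotically Gaussian with variance $2/(n p)$, where $p$ is the
probability that a patient's event is observed; censoring enters the
calculation only through this scalar. Hence

$$\pi_n = \Phi\!\left(-\ln r\,\sqrt{np/2}\right), \qquad
  \kappa_n = \Phi\!\left(\big(\ln r - \ln(\tilde T_{\mathrm{ref}}/\tilde
  T_{\mathrm{appr}})\big)\sqrt{np/2}\right),$$

and the recommended per-arm size is
$\max(\hat n^{\text{non-inf}}, \hat n^{\text{inf}})$ with
$\hat n^{\text{non-inf}} = \operatorname{argmin}_n\{\pi_n \ge Q\}$ and
$\hat n^{\text{inf}} = \operatorname{argmin}_n\{\kappa_n \ge Z\}$.

```{r closed-form}
spec <- tte_design_spec(15.1, 12.7, margin_ratio = 0.90,
                        q_threshold = 0.90, z_threshold = 0.80)
c(pi_300 = prob_practical_noninf(300, spec),
  kappa_300 = prob_practical_inf(300, spec))
recommended_n(spec)
```

Only the ratio of the two medians enters these formulas — rescaling both
medians by any positive constant changes nothing, a property the test
suite checks — and ties at the margin count as non-inferior (the
inequality is inclusive; this has measure zero under the Gaussian but is
fixed for consistency with the binary lattice).

Numerical choices worth stating:

* The argmin searches scan every integer $n$ starting at 1 (a threshold of
  0.5 or less is met immediately at the grid start) in vectorized chunks up
  to `n_cap` (default 100{,}000), and raise a structured
  "unattainable design" error naming the limiting parameter when the cap is
  reached — e.g. when the margin ratio is 1, or when the true ratio of
  medians lies inside the margin so that $\kappa_n$ can never exceed 0.5.
* The margin may be entered as a ratio (`margin_ratio = 0.90`) or as an
  absolute width in months (`margin_months = 1.5`); the ratio is the
  canonical stored form, and `margin_as_months()` converts back, rounding
  to one decimal as medians are conventionally reported.
* Probabilities are kept at full double precision; rounding to whole
  percentages happens only in printed summaries.
* `p_noncensor` is a single value common to both arms, matching the
  variance $2/(np)$; per-arm censoring rates are out of scope.

## Binary endpoints: exact lattice probabilities

For response-type endpoints the success counts are
$k_i \sim \mathrm{Bin}(n, p_i)$ and the margin is an absolute difference in
proportions. $\pi_n$ is the exact joint-binomial probability
$\Pr(\hat p_2 - \hat p_1 \le m)$ (inclusive), computed as a single
convolution over the $k_2$ lattice with vectorized binomial tails —
$O(n)$ CDF evaluations rather than the $O(n^2)$ double sum, which the test
suite retains as the independent enumeration oracle. $\kappa_n$ is the
strict-complement probability with the approved rate kept and the reduced
arm dropped to the historical-control rate. Above `exact_limit` (default
2000 per arm) a seeded Monte Carlo estimator with `mc_reps` (default
100{,}000) replicates takes over; exact and simulated routes are checked
against each other to within Monte Carlo error.

On the lattice $\pi_n$ is **not** monotone in $n$: at common rate $1/2$ and
margin $0.05$, $\pi_1 = 0.75 > \pi_2 = 0.6875$, because the margin admits
no additional lattice points until $m \cdot n$ reaches the next integer.
The grid searches therefore scan every integer $n$ (no bisection), and the
counterexample is kept as a regression test. The inclusive/strict
convention matters at exactly these lattice points and is applied
consistently in the exact and Monte Carlo routes.

## Kaplan–Meier estimation and the bootstrap verification

The closed form rests on exponentiality and on a Gaussian approximation,
so the package verifies any calculated size against patient-level data.
`km_estimate()` wraps the product-limit estimator of
`survival::survfit()`; the median convention is the smallest observed
event time with $\hat S(t) \le 0.5$, ties place events before censorings,
and an unreached median is the explicit value `Inf`, not an error. The
resampling loops use an internal product-limit shortcut on raw vectors for
speed; a test asserts exact agreement with the `survfit`-backed path
across randomized censored datasets.

`bootstrap_verify()` simulates the two design perspectives by resampling
with replacement, at the trial's per-arm size, from the source arms:

* non-inferiority scenario — **both** simulated arms are drawn from the
  approved arm's patients, the natural reading of "the reduced dose is
  equivalent to the approved dose";
* inferiority scenario — the simulated approved arm is drawn from the
  approved arm and the simulated reduced arm from the historical control
  arm.

Each replicate computes the difference of Kaplan–Meier medians, and
$P_{\text{non-inf}}$ / $P_{\text{inf}}$ are the within-/outside-margin
fractions. A replicate arm whose median is unreached enters as $+\infty$:
an unreached reduced-arm median classifies as non-inferior, an unreached
approved-arm median as inferior, and the counts of such replicates are
reported rather than dropped.

### What the verification shows — and how much the source data matter

Two effects make the bootstrap differ from the closed form even when the
data are exactly exponential:

1. **Statistic efficiency.** The bootstrap works on the months scale with
   sample medians, whose asymptotic standard deviation for exponential
   data is $\tilde T/(\ln 2\,\sqrt n)$ — about 1.44 times that of the
   MLE-based estimate underlying the Gaussian closed form. The direct
   consequence is a flatter operating characteristic: at $n = 300$ fresh
   exponential draws give within-margin probabilities near 0.80 (vs 0.90)
   and outside-margin probabilities near 0.72 (vs 0.80).
2. **Conditioning on the source.** The bootstrap conditions on one finite
   source dataset. At a phase-III scale of roughly 380 patients per arm the
   source median itself has a standard deviation above one month — most of
   a 1.5-month margin — so $P_{\text{inf}}$ in particular can move by
   tenths from one source to another. This is not a defect: verifying
   against the data actually in hand is the point of the stage, and a
   source whose observed separation is small *should* report a fragile
   inferiority perspective.

The tests treat both effects honestly: bootstrap estimates are compared
with an independent direct-simulation oracle (fresh exponential cohorts,
no resampling) and with the closed-form values within three *combined*
standard errors, where the combined term adds the across-source standard
deviation — estimated by a small double bootstrap over independently
regenerated sources, with replicate noise subtracted — to the two Monte
Carlo standard errors. The across-source term dominates for
$P_{\text{inf}}$. Consequently, a pass demonstrates internal consistency
of the machinery under the stated generating conditions; it does not
certify that any particular real dataset will reproduce closed-form
values, and on real (non-exponential) data the bootstrap is the more
trustworthy of the two — which is why it exists.

Problem sizes used by the default runs: 10{,}000 bootstrap replicates per
scenario at $n = 300$ per arm from synthetic sources of 378/377 patients
(the scale of the motivating phase III trial), and a 12-source double
bootstrap at 1{,}000 replicates each for the across-source term.

### Margin calibration and fixed-time variants

`margin_calibration()` runs the equivalence scenario and reports, per
candidate margin, the probability of achieving *conventional*
non-inferiority given that practical non-inferiority was achieved — a
quantitative handle for choosing the margin. The conventional criterion is
the upper $(1-2\alpha)$ confidence limit of the hazard ratio falling below
a conventional margin; the hazard ratio is estimated by the
exponential-rate MLE $\hat\lambda = d/\sum t$ per arm with log-HR variance
$1/d_1 + 1/d_2$. This is a deliberate modelling choice — it keeps the
calibration self-contained within the module's exponential framework
rather than fitting a Cox model, and it is the package's own convention
since no particular test is canonical here.

`fixed_time_verify()` replaces the median difference with the difference
in Kaplan–Meier survival probabilities at a fixed horizon (for example,
one-year survival) against a margin in proportion points, for settings
where a landmark probability is the natural efficacy summary.

## The synthetic-data generator

`gen_exponential_cohort()` produces the data structure the calculations
assume: exponential event times at the requested medians with independent
right-censoring calibrated to a target non-censoring probability $p$ —
exponentially distributed censoring by default (the calibration
$\lambda_c = \lambda(1-p)/p$ is closed-form), or uniform administrative
censoring with the horizon solved by root-finding. The defaults of the
shipped case study are medians 15.1 and 12.7 months, source sizes 378 and
377, and $p = 1$ (the illustrative no-censoring setting of the worked
design). What the generator deliberately does **not** emulate: real
survival data are rarely exponential (non-constant hazards, cure
fractions), censoring is usually administrative and staggered by accrual,
and arms may censor at different rates. Tests passing on generated data
therefore validate the calculations and their internal consistency under
the stated model, not the exponential assumption itself; the bootstrap
stage on user-supplied IPD is the guard against model misfit.

## Known limitations

* No accrual or follow-up-time modelling: censoring is the scalar $p$.
* No conventional non-inferiority sample-size calculator; the conventional
  criterion appears only inside the calibration simulation.
* The binary module offers exact enumeration and Monte Carlo only — no
  continuity-corrected normal approximations.
* Reproducing the motivating trial's own bootstrap percentages requires
  its reconstructed patient-level data, which are not redistributable
  here; the package reproduces the procedure on synthetic or user-supplied
  IPD.
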