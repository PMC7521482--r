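---
title: "Estimating cognitive health expectancy with a progressive illness-death model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cognitive health expectancy with a progressive illness-death model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogexpect)
```

## The problem

Healthy behaviors in late life — never smoking, a varied diet, marriage,
leisure activity — are known to lower both the risk of cognitive impairment
(CI) and the risk of death. Relative risks alone, however, cannot say
whether the extra years such factors buy are years lived *with* or
*without* impairment. Health expectancy methods answer that question by
partitioning total remaining life expectancy (TLE) at an age into expected
years free of CI (CIFLE) and years with CI (CILE), with TLE = CIFLE + CILE.
`cogexpect` implements the full pipeline: cohort preparation, a
continuous-time multistate model for interval-censored panel data, the
multistate life table, and bootstrap group comparisons, together with a
synthetic-cohort generator so every stage can be validated against known
truth.

## The model

Subjects move among three states: 1 = CI-free, 2 = CI, 3 = dead. The
process is progressive — transitions 1→2, 1→3, 2→3 are allowed, recovery
2→1 is not (observed recoveries in survey data are treated as recording
error and censored during panel assembly). Each transition intensity is
log-linear in age and covariates:

$$q_{rs}(a, x) = \exp\{\beta_{0,rs} + \beta_{a,rs}\,(a - a_0) +
\beta_{x,rs}' x\},$$

a Gompertz-type hazard with proportional covariate effects, the standard
parametric realization of "proportional hazards with piecewise-constant
rates" for panel data; `age_effect = "constant"` switches the age slopes
off. Ages are centred at a reference age $a_0$ (default 65 or 80) purely
for numeric conditioning.

### Likelihood for interval-censored panel data

Cognitive states are seen only at survey waves, so the age at CI onset is
interval-censored; death ages are known exactly; missing cognitive states
carry no information beyond survival. The subject likelihood multiplies,
over consecutive *known* states:

* living pair $s \to s'$ over $(t_0, t_1)$: $P_{ss'}(t_0, t_1)$;
* exact death at $t$ after last living state $s$:
  $\sum_{r\in\{1,2\}} P_{sr}(t_0, t)\, q_{r3}(t)$ (intensity at the death
  age, the left-limit convention for exactly observed absorbing times);
* alive at $t$ with unknown state (right censoring):
  $\sum_{r\in\{1,2\}} P_{sr}(t_0, t)$.

Missing living states between two known states are bridged by the spanning
interval, so inserting one changes nothing (a property the tests assert).
Post-stratification weights enter as frequency weights; the covariance is
the inverse observed information without a sandwich correction (a
documented simplification — with informative weights the intervals are
approximate).

### Transition probabilities

Over an interval, the upper-triangular structure of the generator gives
closed forms when rates are constant:
$P_{11} = e^{-(q_{12}+q_{13})\Delta}$, $P_{22} = e^{-q_{23}\Delta}$,
$P_{12} = q_{12}\,(e^{-(q_{12}+q_{13})\Delta} - e^{-q_{23}\Delta}) /
(q_{23} - q_{12} - q_{13})$, with the removable singularity at
$q_{23} = q_{12}+q_{13}$ handled by its limit
$q_{12}\Delta e^{-q_{23}\Delta}$ whenever the denominator is below
$10^{-8}$. Age-varying intensities are frozen at the midpoints of pieces of
at most `piece_step` (default 0.25 y) and composed by Chapman–Kolmogorov
multiplication; the error is $O(\text{piece\_step})$ and halving the step
moves the probabilities by less than $10^{-4}$ at the default settings.
The implementation is checked against two independent oracles — a generic
matrix exponential and high-resolution ODE integration of the Kolmogorov
forward equations — to $10^{-8}$ on random parameter draws.

### From intensities to expectancies

The multistate life table integrates state-occupancy probabilities over
age on a monthly grid (trapezoidal rule, error $O(h^2)$, well below every
tolerance used here):

$$e_{1r}(a) = \int_a^{a_{\max}} P_{1r}(a, u)\, du, \qquad r \in \{1, 2\},$$

giving CIFLE $= e_{11}$, CILE $= e_{12}$, TLE $= e_{11}+e_{12}$, and the
proportion of remaining life free of CI, $100\,e_{11}/\text{TLE}$. The
grid truncates at `max_age` (default 110); the probability of still being
alive there is reported as *truncation mass*, warned about above $10^{-3}$
and an error above 5% (raise `max_age`). For constant rates the integrals
have closed forms (CIFLE $= 1/(q_{12}+q_{13})$, TLE $=$ CIFLE
$+\, q_{12}/((q_{12}+q_{13})q_{23})$) that the grid implementation
reproduces within 0.1%.

### Adjusted expectancies

Published "adjusted" expectancies can mean either covariates fixed at
reference values or averaging over the cohort's covariate distribution.
`expectancies()` takes an explicit profile (exposure set to each level,
confounders at reference by default), and averaging over observed
confounders can be done by averaging expectancy results over profiles;
the profile is always recorded in the result, so the choice is explicit
rather than implicit.

## Group comparisons

`bootstrap_differences()` resamples *subjects* (not observations) with
replacement, realized as multinomial frequency weights on the precomputed
likelihood structure with each replicate's optimizer started at the
full-data estimate; percentile 2.5/97.5 intervals are taken over B
replicates (default 500, the conventional choice for life-table
bootstraps). Percentile rather than BCa intervals are used because nothing
in the target analyses requires second-order accuracy and percentile
intervals are transparent. Replicates that fail to converge are dropped
and counted; more than 10% failures flags the result unreliable.
Post-stratification weights are carried into each replicate (multiplied by
the resample counts); a `reweight` callback allows recomputing them per
replicate instead.

The qualitative reading of a difference is made reproducible by a single
deterministic rule in `classify_change()`:

* **absolute increase** — the CIFLE gain is significant (95% CI above 0)
  and strictly exceeds the TLE gain, i.e. every gained year is CI-free;
* **relative increase** — otherwise, the proportion of life free of CI
  rises significantly;
* **relative reduction** — that proportion falls significantly;
* **no change** — none of the above.

Strict inequality in the first rule matters: with published values rounded
to one decimal, gains in TLE and CIFLE can print as equal while the
proportion rises significantly, and such rows read naturally (and are
reported) as relative increases. The rule reproduces every qualitative
classification printed alongside the tables it was checked against.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of a multi-wave longevity
survey of Chinese older adults: entry ages 65–105 drawn from bands that
deliberately oversample the oldest-old (roughly balancing young-old,
octogenarians, nonagenarians, and a centenarian share — the design that
post-stratification weights later undo), five waves at three-year
offsets, Bernoulli baseline covariates, latent trajectories from known
intensities, states observed only at waves with a 5% missing-state
probability after baseline, and exactly dated deaths.

Two details deserve emphasis:

* **Follow-up consistency.** Deaths are ascertained only through each
  subject's follow-up end $F_i = \min(\text{entry} + \text{last offset},
  \text{horizon})$, and subjects alive at the 110-year administrative
  horizon whose scheduled waves run past it receive an explicit
  right-censor record there. Recording deaths beyond the last wave while
  crediting survival only to the last wave would make the censoring
  informative and biases mortality upward by ~10% at these settings — a
  pitfall the test suite guards against via Wald-coverage checks.
* **Exactness.** Simulation steps freeze intensities over 0.25-year
  steps and draw competing exponentials within each; for age-constant
  intensities this is exact by memorylessness (and the constant-rate
  cohort path draws the event times directly), for Gompertz intensities
  the error is $O(\text{step})$, negligible against every tolerance used.

What the generator does *not* emulate: item-level cMMSE responses (states
are emitted directly; the score classifier is tested on hand-written score
fixtures), informative dropout, calendar-period effects, covariate
missingness, and misclassification of the cognitive state. Passing
recovery tests on these cohorts therefore demonstrates correctness of the
estimation machinery under the model's own assumptions, not robustness to
violations of them.

## Cohort preparation

* `classify_cognition()` applies the education-specific cMMSE cutoffs in
  wide use for Chinese cohorts: 17/18 (no formal education), 20/21 (1–6
  years), 24/25 (7+ years); "unable to answer" items are scored incorrect
  upstream, and an uncompleted screen is a missing state.
* `classify_diet()` codes a healthy dietary pattern as at least three of
  fruit, green leafy vegetables, legumes and fish eaten at least weekly.
* `build_risk_profile()` counts three protective components — never
  smoking with a healthy diet, marriage with spouse present, any of four
  leisure activities — into low / medium-low / medium-high / high risk.
* `assemble_panel()` excludes subjects with missing baseline state (with
  a logged count), censors apparent recoveries rather than overwriting
  them (censoring discards the contradiction without fabricating a state;
  the alternative — recoding the later observation to CI — would assert
  information the data do not contain), and converts trailing missing
  living states into right-censor records.
* `post_stratification_weights()` rescales stratum ratios
  (target/sample) to subject-level mean 1; 5-year age bands to 99 plus
  100+ match census tabulation granularity.
* Covariate missingness is **not** imputed here: synthetic covariates are
  complete, so a chained-equations imputation layer would be untestable
  against anything; subjects with missing baseline covariates are
  excluded with a count.

## Numerical choices and degenerate inputs

* Optimizer: BFGS on the packed log-scale parameters, finite-difference
  gradients (step $10^{-6}$), crude occurrence/exposure starting rates,
  relative tolerance $10^{-10}$; the gradient norm at the optimum is
  reported. The covariance uses a central-difference Hessian (step
  $10^{-4}$).
* A transition with no observed events is non-identified: its baseline
  runs to the boundary ($\hat q < 10^{-4}$), it is flagged, and its
  standard error is reported as `NA` rather than a number.
* A path with zero probability returns `-Inf` with a warning (not an
  error), and the optimizer's objective clamps it, so BFGS can back away
  from impossible regions.
* Transition probabilities are clipped only within $10^{-12}$ of [0, 1];
  larger violations raise an error rather than being silently repaired.
* Fitting fully separate models per sex (rather than a sex-stratified
  baseline) follows the stronger reading of sex-specific analyses; the
  workflow scripts do exactly that.

## Problem sizes used in validation

The test suite and the acceptance script validate at desk scale, chosen
so that Monte-Carlo error, not compute, is the binding constraint: Wald
coverage over 100 replicates of 3,000-subject cohorts; expectancy
recovery against the latent truth of a 10,000-subject cohort entering at
65 (agreement within 3 Monte-Carlo standard errors); bootstrap null
coverage over 50 repetitions of 500-subject two-group cohorts at B = 200
(the conventional B = 500 stays the package default); oracle agreement on
1,000 random parameter draws. The analysis scripts use 2,000 subjects per
sex and B = 100 for the same reason.

## Known limitations

* No misclassification (hidden-Markov) layer for the cognitive state;
  with few observed recoveries such a model is unstable anyway.
* No time-varying covariates, frailty, or informative-dropout handling.
* Frequency-weighted likelihood without sandwich covariance; intervals
  under strong weighting are approximate (the bootstrap, which resamples
  subjects, is the safer inferential route there).
* Expectancies extrapolate the fitted hazard beyond the oldest observed
  ages up to the truncation age; with Gompertz slopes this is a model
  assumption, not an observation.
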