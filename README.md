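# cogexpect

Cognitive health expectancy from progressive illness-death models.

`cogexpect` is an R package plus a worked analysis pipeline for asking how
much of the life expectancy of older adults is spent free of cognitive
impairment (CI), and how modifiable factors (diet, smoking, marriage,
leisure activity) shift that partition. It targets interval-censored panel
data of the kind produced by multi-wave longevity surveys: cognitive
states observed only at waves roughly three years apart, exactly dated
deaths, intermittent missing states, and designed oversampling of the
oldest-old.

## The model

Subjects move through three states — 1 = CI-free, 2 = CI, 3 = dead — with
no recovery. Transition intensities are Gompertz-type with proportional
covariate effects,

    q_rs(a, x) = exp(b0_rs + ba_rs (a - a0) + bx_rs' x),   rs in {12, 13, 23},

fitted by maximum likelihood on the interval-censored panel: living state
pairs contribute transition probabilities P_ss'(t0, t1), exact deaths
contribute sum_r P_sr(t0, t) q_r3(t), and alive-with-unknown-state records
contribute sum_r P_sr (right censoring). Transition probabilities come
from closed-form constant-rate solutions on short age pieces composed by
Chapman–Kolmogorov multiplication. Fitted intensities are converted into
state occupancy curves and integrated over age (multistate life table) to
give total life expectancy (TLE), CI-free life expectancy (CIFLE), CI
life expectancy (CILE = TLE − CIFLE), and the proportion of remaining
life free of CI. Group differences get percentile bootstrap confidence
intervals by resampling subjects and refitting, and a deterministic rule
classifies each contrast as an absolute increase, relative increase,
relative reduction, or no change in CI-free years.

A synthetic-cohort generator with known true intensities stands in for
restricted survey data, so every stage is validated by parameter and
expectancy recovery. The methods vignette
(`vignettes/cognitive-health-expectancy.Rmd`) documents the model,
numerical choices, and what the synthetic cohorts do and do not emulate.

## Worked example

```r
library(cogexpect)

# a synthetic cohort with a protective dietary effect on CI onset
truep <- intensity_params(0.055, 0.035, 0.11,
                          age_slope = c(0.08, 0.09, 0.08), ref_age = 80,
                          coefs = list("12" = c(diet = -0.35)))
coh <- generate_cohort(simulation_config(2000, truep,
                                         covariates = list(diet = 0.4),
                                         seed = 101))

spec <- illness_death_spec(covariates = list("12" = "diet"),
                           age_effect = "gompertz", ref_age = 80)
fit <- fit_illness_death(coh$panel, spec)

expectancies(fit$params, profile = c(diet = 1), grid = age_grid(65, 110))
```

The analysis scripts run this end to end at a larger scale. From the
fitted men's cohort (step 3–4 of `analysis/`), expectancies at age 65 by
dietary pattern:

```
  sex start_age diet  tle cifle cile proportion_cifle
  men        65    0 17.0  14.1  3.0             82.6
  men        65    1 19.1  16.4  2.7             85.9
```

i.e. a 65-year-old man with a healthy dietary pattern is expected to live
19.1 more years of which 16.4 are CI-free, against 17.0 and 14.1 for an
unhealthy pattern. The bootstrap comparison (step 5, B = 100) prints

```
age 65, diet=1 vs diet=0: dTLE 2.04 (1.00 to 3.25),
                          dCIFLE 2.32 (1.45 to 3.72),
                          dProp 3.3 (0.4 to 7.3)
classification: absolute_increase
```

— the CI-free gain exceeds the total gain with a confidence interval
above zero, so every year gained is a year without impairment (an
"absolute increase"), which is exactly the generating truth (the
simulated diet effect protects against onset far more than against
death).

## The analysis workflow

Numbered drivers under `analysis/`, each a thin narrative over package
functions, writing tables to `results/`:

1. `01_simulate_cohort.R` — synthetic men's and women's cohorts (2,000
   subjects each) with known Gompertz intensities.
2. `02_prepare_panel.R` — cMMSE classification, dietary pattern, risk
   profiles, panel assembly, post-stratification weights, sensitivity
   filters.
3. `03_fit_transitions.R` — sex-specific illness-death fits with
   diet and functional-limitation effects.
4. `04_life_expectancy.R` — multistate life tables at ages 65 and 85.
5. `05_compare_groups.R` — bootstrap differences, change classification,
   publication-style report tables.

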