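# mshle — multistate healthy life expectancy from interval-censored panels

`mshle` estimates how a time-varying exposure — loneliness, in the bundled
study — shapes life expectancy (LE), healthy life expectancy (HLE) and the
healthy share of remaining life (HLE/LE) in an aging cohort, from panel
data in which health states are seen only at interviews years apart and
deaths are reported between waves. It is aimed at population-health and
biostatistics researchers working with CLHLS-style longitudinal surveys
of older adults.

## The model

The package embeds a fine-step discrete-time Markov chain over
{healthy (1), unhealthy (2), dead (3)} between the irregular interviews
(an interpolated-Markov-chain multistate life table). Each exit from a
living state *j* carries a multinomial logit in age and covariates,

  η_jk(x, z) = a_jk + b_jk (x − 65) + c_jk′ z,
  p^jk = exp(η_jk) / (1 + Σ_{k′≠j} exp(η_jk′)),

with death absorbing (row (0, 0, 1)). Probabilities over an interview gap
are ordered products of one-step matrices, which makes the likelihood of
interval-censored episodes — including deaths at exact reported ages —
directly computable. From a fitted chain the package derives the stable
(period) prevalence w²(x), state-conditional expectancies
e^ij = h Σ_u ₍ᵤ₎p^ij + (h/2) δ_ij, and population-based quantities
e^.j = (1 − w²) e^1j + w² e^2j, with LE = e^.1 + e^.2, HLE = e^.1 and
HLE/LE in percent, plus percentile parametric-bootstrap confidence
intervals. A Kannisto logistic hazard fit (μ(x) = a·e^{b(x−65)} /
(1 + a·e^{b(x−65)})) validates old-age mortality, and reporting helpers
compute the derived summaries used in published tables: HLE/LE ratios,
gender differences (GD, men − women) and age decrements (AD, ratio at 65
minus ratio at 99).

Because the original survey microdata are access-restricted, the package
ships a synthetic cohort generator with a known ground truth emulating the
study design (four waves at 0/3/6/10 years, ages 65–99, Kannisto-like
mortality, time-varying loneliness, attrition, survey weights), so every
stage is testable end to end.

## Worked example

```r
library(mshle)

model    <- true_model(h = 0.25)                       # known ground truth
gen      <- generate_cohort(sim_config(n = 2000, seed = 1, model = model))
elig     <- apply_eligibility(gen$cohort)
episodes <- build_histories(elig$cohort)
fit      <- fit_transitions(episodes, h = 0.25, covariates = "lonely")
fit
#> Embedded Markov chain over {healthy, unhealthy, dead}
#> step h = 0.25 years, age cap = 110
#>      (Intercept)   age65  lonely
#> 1->2     -4.6668  0.0822  0.1044
#> 1->3     -6.0308  0.0677  0.3843
#> 2->1     -1.6469 -0.0306 -0.2765
#> 2->3     -5.1272  0.0977  0.4276
#> log-likelihood -5137.0032 (converged)

tab <- hle_table(fit, c(65, 75, 85),
                 profiles = list(`non-lonely` = c(lonely = 0),
                                 lonely       = c(lonely = 1)),
                 n_draws = 500, seed = 1)
tab[, c("profile", "age", "le", "le_lower", "le_upper", "hle", "ratio")]
#>      profile age    le le_lower le_upper   hle ratio
#> 1 non-lonely  65 21.08    20.22    21.77 17.43  82.7
#> 2 non-lonely  75 13.62    12.98    14.23 10.23  75.1
#> 3 non-lonely  85  7.47     6.92     8.11  4.75  63.7
#> 4     lonely  65 17.60    16.38    18.69 14.45  82.1
#> 5     lonely  75 10.78     9.94    11.65  7.95  73.7
#> 6     lonely  85  5.54     4.90     6.29  3.43  61.9
```

The positive fitted `lonely` effects on both death logits (+0.38, +0.43;
true values +0.35) reproduce the planted harm: at every age the lonely
profile has about 2–3.5 fewer expected years of life and of healthy life,
with 95% CIs from 500 seeded coefficient draws. `hle_le_ratio()`,
`gender_difference()` and `age_decrement()` turn such tables (or the
bundled published values from `reference_tables()`) into the reported
summary statistics.

The full study workflow lives in `analysis/01_simulate_cohort.R` through
`analysis/04_report.R` — thin numbered drivers that simulate the cohort,
fit overall and by gender, build the life tables and write the report
tables and figures under `results/`. `run_pipeline(demo_config())` runs
the same stages end to end from one configuration.

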