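---
title: "Multistate healthy life expectancy from interval-censored panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate healthy life expectancy from interval-censored panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mshle)
```

## The estimation problem

Aging panels such as the Chinese Longitudinal Healthy Longevity Survey
(CLHLS) interview people every few years, record a binary health state at
each interview (here: free of ADL limitation vs limited, or good
self-rated health vs not), and learn death dates from family informants
between waves. Between two interviews three to four years apart a person
may move between health states many times; treating the panel as a
one-step chain at the interview spacing would badly distort age-specific
transition probabilities. The interpolated-Markov-chain approach instead
embeds a fine-step discrete-time chain — here `h` years per step — between
the interviews, and estimates the step-level model by maximum likelihood
from the interval-censored observations.

The state space is healthy (1), unhealthy (2), dead (3); death is
absorbing. Each exit from a living state `j` carries a multinomial logit

$$\eta_{jk}(x, z) = a_{jk} + b_{jk}\,(x - 65) + c_{jk}'z,$$

so the one-step matrix at age $x$ under covariates $z$ is

$$
{}_h P_x = \begin{pmatrix}
p^{11} & p^{12} & p^{13}\\
p^{21} & p^{22} & p^{23}\\
0 & 0 & 1
\end{pmatrix},
\qquad
p^{jk} = \frac{e^{\eta_{jk}}}{1 + \sum_{k' \ne j} e^{\eta_{jk'}}} .
$$

Age enters linearly on the logit scale, the classical default for this
family; a quadratic term is deliberately not included (the data spacing
rarely identifies it well), and age is centered at 65 purely for optimizer
conditioning — this is the same model as an uncentered intercept.
Loneliness enters $z$ as a binary time-varying covariate; further baseline
controls (gender, residence, education, ...) can be added as extra
columns.

Probabilities over an interval are ordered products of one-step matrices
with age advancing by `h` each step, which is what makes the likelihood of
an episode observed `t` years apart computable: for an episode ending in
an observed living state the contribution is the corresponding entry of
the interval product; for a death at a known exact age the contribution is
survival within the living states up to the step containing the death age
times the transition into death in that step. The matrix product sums over
the unobserved living path automatically. Episodes are weighted by survey
weights normalized to mean one (a pseudo-likelihood), and the coefficient
covariance is the inverse of the numerically differenced observed
information.

Two behaviours of the likelihood are worth knowing. Logits are clipped at
±50 before exponentiation, which changes nothing within floating-point
resolution but prevents overflow under extreme coefficients. And episodes
whose probability underflows to zero return `-Inf` with a diagnostic
listing the episode group, rather than a silent `NaN`.

## From the fitted chain to LE, HLE and HLE/LE

Three quantities are derived from a fitted model at each age $x$ and
covariate profile:

* **Stable (period) prevalence** $w^2(x)$: the within-alive share of the
  unhealthy state reached by running the age-inhomogeneous chain into age
  $x$ from an earlier age, independent of the starting state. It is
  computed by prepending earlier one-step factors to the interval product
  until the prevalence stops moving and loses memory of the starting
  state (tolerance `1e-6`, maximum burn-in 30 years). For ages near the
  lower end of the fitted range the burn-in extends below age 65 by
  smooth extrapolation of the logits; without this the mixing weight at
  65 would depend on an arbitrary starting state, and the population-based
  quantities at the youngest reported age would be undefined.

* **State-conditional expectancies**
  $e^{ij}(x) = h \sum_{u\ge1} {}_u p^{ij}_x + (h/2)\,\delta_{ij}$:
  expected years in state $j$ given state $i$ at $x$. The half-step
  diagonal term is the trapezoid end-correction of the discretized
  occupancy integral; under it the homogeneous-chain closed form is
  exactly $h\,(I-Q)^{-1} - (h/2) I$, which the test suite uses as an
  oracle. Sums run to an age cap (default 110) where death is forced,
  guaranteeing finite expectancies; summation stops early once remaining
  survival drops below `1e-8`.

* **Population-based quantities**:
  $e^{.j} = [1 - w^2]\,e^{1j} + w^2\,e^{2j}$, healthy life expectancy
  HLE $= e^{.1}$, LE $= e^{.1} + e^{.2}$ (additive by construction, and
  asserted to machine precision), and the ratio $100\,\mathrm{HLE/LE}$.

Confidence intervals are percentile parametric bootstrap: coefficient
vectors are drawn from the asymptotic normal sampling distribution of the
fit (500 draws by default, seeded), each target is recomputed per draw,
and the 2.5/97.5 percentiles are reported. The original analyses do not
name their interval method; the bootstrap was chosen because it respects
the nonlinearity of the life-table map, and a delta-method route is
available as a cross-check in `one_year_table()`. The draw loop is
vectorized across draws, so a full CI table costs one propagation pass.

## Step length, rounding and other numerical choices

* **Step `h`**: 1 month by default in `fit_transitions()` and
  `true_model()`; the bundled study runs use a quarter (`h = 0.25`) — at
  quarterly resolution the discretization error in LE is a small fraction
  of a year while fits on 10,000-person cohorts take seconds rather than
  minutes. Results always carry the `h` they were computed with.
* **Grid snapping**: episode start ages are rounded to the nearest step
  multiple of the age-65 grid, and elapsed times to the nearest whole
  number of steps; a death is placed in the step containing its exact
  reported age (`ceiling`). With interview gaps of whole years and
  sub-annual steps these roundings are at most `h/2` of age, mean-zero
  across episodes.
* **Starting values**: death-transition intercepts start at −4,
  morbidity/recovery at −2, slopes and covariate effects at 0; BFGS with a
  Nelder–Mead restart on non-convergence.
* **Reporting rounding**: one decimal, half away from zero, applied only
  in the reporting layer; internals stay unrounded. Published tables
  occasionally print differences computed from their own unrounded
  internals, so the reporting functions expose both the from-rounded
  value and the printed one rather than forcing agreement.
* **Gender difference sign**: men minus women. The published footnote
  reads the other way around, but every printed positive value matches
  men − women; the package follows the numbers, not the footnote.

## What the synthetic cohort emulates — and what it does not

All estimation machinery is exercised on synthetic cohorts with a known
ground truth, because the survey microdata are access-restricted. The
generator mirrors the study design: about 15,000 (default runs use
10,000) community-dwelling individuals aged 65–99 at baseline (mean near
73), four waves at 0/3/6/10 years, two-way healthy↔unhealthy transitions
with absorbing death, exact death ages as reported by informants, 5%
per-wave dropout, and two-point urban/rural sampling weights normalized
to mean one.

Default true coefficients (quarterly step) were calibrated once, before
any testing, to CLHLS-like magnitudes: baseline 96% ADL-healthy and 25%
lonely; old-age mortality rising log-linearly with age at a
Kannisto-compatible slope, higher from the unhealthy state; LE at 65 near
21 years for the non-lonely and 18 for the lonely; and a harmful
loneliness effect planted on the death (+0.35) and morbidity (+0.30)
logits, none on recovery. Loneliness evolves as its own two-state chain
(annual onset 0.02, remission 0.06, stationary share 25%); these slow
dynamics reflect how persistent single-item loneliness is at these ages.
Because the estimator carries loneliness forward from the episode-opening
interview (LOCF), within-episode loneliness changes are a deliberate,
mild misspecification of the fitted model relative to the generator — the
same gap the original analysis faces with any time-varying covariate
observed only at interviews.

The generator does **not** emulate: item-level questionnaire responses
(states are generated directly), measurement error (an optional
misclassification rate defaults to zero), calibration of weights to
census margins, informative dropout, or the survey's actual attrition
pattern. Passing tests therefore demonstrate that the estimation and
life-table machinery is correct under the assumed data-generating family
and observation scheme — not that the model is correct for any particular
real survey.

## Verification strategy and problem sizes

The test suite checks every layer against an independent oracle:
dichotomization rules against the published coding sentences; interval
products against a brute-force left-to-right multiplication; conditional
expectancies against the fundamental-matrix closed form and a geometric
series; stable prevalence against the dominant left-eigenvector of the
living block; intercept-only fits against closed-form multinomial
frequencies; and the full pipeline against planted-effect directions.
Replicated parameter recovery uses 20 cohorts of 10,000 individuals at
the quarterly step — large enough for the asymptotic Wald intervals to be
trusted, small enough that the whole experiment runs in minutes — and
demands each true coefficient be covered in at least 90% of replicates.
The demo pipeline configuration (2,000 individuals) exists purely to keep
end-to-end smoke and determinism checks fast.

## Known limitations

* Two living states only; no frailty or random effects; discrete-time
  logits rather than continuous-time intensities (at sub-annual steps the
  practical difference for LE/HLE is below the reporting precision).
* The covariance of weighted fits is model-based (inverse information);
  it does not account for the sampling design beyond the weights
  themselves.
* Published point estimates from the restricted survey cannot be
  reproduced from scratch here; the package reproduces their *derived*
  statistics exactly from the printed values, and their qualitative
  structure from synthetic data.
* Stable prevalence below age ~75 relies on logit extrapolation below
  the fitted age range; with pathological fitted slopes (tiny samples)
  the burn-in may not converge, in which case the routine warns and
  reports its last iterate.
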