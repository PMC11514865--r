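Package: mshle
Title: Multi-State Healthy Life Expectancy from Interval-Censored Panel Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates age- and covariate-dependent transition probabilities
    among healthy, unhealthy and dead states from interval-censored
    longitudinal panel data by embedding a fine-step (interpolated) Markov
    chain between irregular interviews, and converts the fitted model into
    multistate life-table quantities: stable (period) prevalence,
    state-conditional expectancies, and population-based life expectancy
    (LE), healthy life expectancy (HLE) and the HLE/LE ratio with parametric
    bootstrap confidence intervals. Includes a synthetic longitudinal cohort
    generator emulating a CLHLS-like aging panel (waves at 0/3/6/10 years,
    Kannisto-type old-age mortality, time-varying loneliness, attrition,
    survey weights), coding rules for ADL / self-rated health / loneliness
    items, weighted descriptive tables, and reporting helpers for
    gender-difference and age-decrement summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
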