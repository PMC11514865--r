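# Shared fixture builders. Everything is generated in code; no data files.

# Homogeneous-chain coefficients hitting exact one-step probabilities
# (no age slope, no covariate effect unless supplied).
hom_coef <- function(p12, p13, p21, p23, h = 1, covariates = character(),
                     cov_effects = NULL, cap = 2000) {
  p11 <- 1 - p12 - p13
  p22 <- 1 - p21 - p23
  stopifnot(p11 > 0, p22 > 0)
  eta <- function(p, pstay) if (p <= 0) -50 else log(p / pstay)
  cf <- cbind(c(eta(p12, p11), eta(p13, p11), eta(p21, p22), eta(p23, p22)),
              0,
              if (length(covariates)) cov_effects else NULL)
  transition_coefficients(cf, h = h, covariates = covariates, cap = cap)
}

# One-row episode table.
one_episode <- function(age_start, state_start, elapsed, end_state,
                        end_type = if (end_state == 3) "death" else "state",
                        lonely = 0, weight = 1) {
  data.frame(id = "e1", age_start = age_start, state_start = state_start,
             lonely = lonely, elapsed = elapsed, end_type = end_type,
             end_state = end_state, weight = weight)
}

# A small hand-checkable person-wave cohort: 4 individuals.
toy_cohort <- function() {
  data.frame(
    id = rep(c("a", "b", "c", "d"), c(4L, 2L, 1L, 3L)),
    wave = c(1:4, 1:2, 1L, 1:3),
    interview_age = c(70, 73, 76, 80,    # a: four interviews
                      68, 71,            # b: dies between waves 2 and 3
                      66,                # c: baseline only
                      72, 75, 78),       # d: missing health at wave 2
    health_state = c(1, 1, 2, 2,  1, 2,  1,  2, NA, 1),
    lonely = c(0, 0, 1, 1,  0, 0,  1,  1, 1, 0),
    female = c(0, 0, 0, 0,  1, 1,  0,  1, 1, 1),
    weight = c(rep(1.2, 4), rep(0.8, 2), 1, rep(1.0, 3)),
    death_age = c(rep(NA, 4), rep(72.4, 2), NA, rep(NA, 3)))
}

# Quarterly-step study conditions used across estimation tests.
study_model <- function() true_model(h = 0.25)
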