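test_that("one-step matrix has the multinomial-logit form", {
  cf <- transition_coefficients(matrix(0, 4, 3), h = 1,
                                covariates = "lonely")
  P <- step_matrix(cf, 70, c(lonely = 0))
  expect_equal(P[1, ], c(healthy = 1, unhealthy = 1, dead = 1) / 3)
  expect_equal(P[2, ], c(healthy = 1, unhealthy = 1, dead = 1) / 3)
  ## death is absorbing at any age
  expect_equal(P[3, ], c(healthy = 0, unhealthy = 0, dead = 1))
  expect_equal(step_matrix(cf, 99, c(lonely = 1))[3, ],
               c(healthy = 0, unhealthy = 0, dead = 1))
  ## strongly negative exit logits pin the diagonal
  cf2 <- transition_coefficients(cbind(c(-50, -50, 0, 0), 0, 0), h = 1,
                                 covariates = "lonely")
  expect_equal(step_matrix(cf2, 70, c(lonely = 0))[1, ],
               c(healthy = 1, unhealthy = 0, dead = 0), tolerance = 1e-12)
  ## rows are stochastic under arbitrary coefficients
  set.seed(4)
  for (i in 1:20) {
    cfr <- transition_coefficients(matrix(rnorm(12, 0, 2), 4, 3), h = 0.25,
                                   covariates = "lonely")
    Pr <- step_matrix(cfr, runif(1, 65, 105), c(lonely = rbinom(1, 1, 0.5)))
    expect_equal(unname(rowSums(Pr)), c(1, 1, 1), tolerance = 1e-12)
    expect_true(all(Pr >= 0 & Pr <= 1))
  }
})

test_that("profiles are validated against the declared covariates", {
  cf <- transition_coefficients(matrix(0, 4, 3), h = 1,
                                covariates = "lonely")
  expect_error(step_matrix(cf, 70, NULL), "profile")
  expect_error(step_matrix(cf, 70, c(lonely = 0, female = 1)), "undeclared")
  expect_error(step_matrix(cf, 70, c(female = 1)), "missing covariate")
})

test_that("interval probabilities chain one-step matrices correctly", {
  cf <- transition_coefficients(cbind(c(-2, -3, -1.5, -2.5),
                                      c(0.05, 0.08, -0.02, 0.09),
                                      c(0.3, 0.4, 0.1, 0.2)),
                                h = 0.25, covariates = "lonely", cap = 120)
  pr <- c(lonely = 1)
  ## single step reduces to the one-step matrix
  expect_equal(interval_probability(cf, 70, 0.25, pr),
               step_matrix(cf, 70, pr))
  ## homogeneous chain: two steps equal the matrix square
  hom <- hom_coef(0.1, 0.05, 0.2, 0.1, h = 0.25)
  P1 <- step_matrix(hom, 80, NULL)
  expect_equal(interval_probability(hom, 80, 0.5, NULL), P1 %*% P1,
               tolerance = 1e-12, ignore_attr = TRUE)
  ## Chapman-Kolmogorov on the homogeneous chain
  expect_equal(interval_probability(hom, 80, 8, NULL),
               interval_probability(hom, 80, 4, NULL) %*%
                 interval_probability(hom, 80, 4, NULL),
               tolerance = 1e-10, ignore_attr = TRUE)
  ## 36 inhomogeneous steps against an independent left-to-right product
  cfm <- unclass(cf$coef)
  oracle <- diag(3)
  for (u in 1:36) {
    a <- 70 + (u - 1) * 0.25
    x <- c(1, a - 65, 1)
    e <- exp(cfm %*% x)
    M <- rbind(c(1, e[1], e[2]) / (1 + e[1] + e[2]),
               c(e[3], 1, e[4]) / (1 + e[3] + e[4]),
               c(0, 0, 1))
    oracle <- oracle %*% M
  }
  expect_equal(unname(interval_probability(cf, 70, 9, pr)), oracle,
               tolerance = 1e-12)
  expect_error(interval_probability(cf, 118, 9, pr), "beyond the age cap")
  expect_error(interval_probability(cf, 70, 0, pr), "positive")
})

test_that("episode log-likelihood matches hand-computed factors", {
  hom <- hom_coef(0.3, 0.2, 0.25, 0.15, h = 1)
  ## observed 1 -> 2 over one step
  expect_equal(episode_loglik(hom, one_episode(70, 1, 1, 2)), log(0.3))
  ## death exactly one step after observation in state 1
  expect_equal(episode_loglik(hom, one_episode(70, 1, 1, 3)), log(0.2))
  ## two-step episode 1 -> 1: matrix-squared living entry
  P2 <- step_matrix(hom, 70, NULL) %*% step_matrix(hom, 71, NULL)
  expect_equal(episode_loglik(hom, one_episode(70, 1, 2, 1)), log(P2[1, 1]))
  ## death in the second step: survive one step in living states, then die
  P1 <- step_matrix(hom, 70, NULL)
  pd <- P1[1, 1] * P1[1, 3] + P1[1, 2] * P1[2, 3]
  expect_equal(episode_loglik(hom, one_episode(70, 1, 2, 3)), log(pd))
  ## three-episode fixture totals the hand-summed value
  eps3 <- rbind(one_episode(70, 1, 1, 2), one_episode(75, 2, 1, 1),
                one_episode(80, 2, 1, 3))
  hand <- log(0.3) + log(0.25) + log(0.15)
  expect_equal(sum(vapply(1:3, function(i)
    episode_loglik(hom, eps3[i, ]), numeric(1))), hand)
  ## an episode whose probability underflows to zero diagnoses and
  ## returns -Inf: staying alive for 60 years when both living states
  ## face certain immediate death
  doomed <- transition_coefficients(cbind(c(-50, 50, -50, 50), 0),
                                    h = 1, cap = 2000)
  expect_warning(ll <- episode_loglik(doomed, one_episode(70, 1, 60, 1)),
                 "zero-probability")
  expect_identical(ll, -Inf)
})

test_that("intercept-only fit reproduces weighted transition frequencies", {
  set.seed(3)
  eps <- data.frame(id = as.character(1:200), age_start = 70,
                    state_start = rep(c(1L, 2L), c(100L, 100L)), lonely = 0L,
                    elapsed = 1, end_type = "state",
                    end_state = c(rep(1:3, c(50L, 30L, 20L)),
                                  rep(1:3, c(20L, 60L, 20L))),
                    weight = runif(200, 0.5, 2))
  eps$end_type[eps$end_state == 3L] <- "death"
  fit <- fit_transitions(eps, h = 1, covariates = character(),
                         include_age = FALSE)
  P <- step_matrix(fit, 70)
  w <- eps$weight
  for (j in 1:2) {
    own <- eps$state_start == j
    freq <- vapply(1:3, function(k) sum(w[own & eps$end_state == k]) /
                     sum(w[own]), numeric(1))
    expect_equal(unname(P[j, ]), freq, tolerance = 1e-6)
  }
})

test_that("estimates are invariant to weight scale, id labels and row order", {
  gen <- generate_cohort(sim_config(n = 600L, seed = 21L,
                                    model = study_model()))
  eps <- build_histories(apply_eligibility(gen$cohort)$cohort)
  f1 <- fit_transitions(eps, h = 0.25)
  scaled <- eps; scaled$weight <- eps$weight * 7.3
  f2 <- fit_transitions(scaled, h = 0.25)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-6)
  shuffled <- eps[rev(seq_len(nrow(eps))), ]
  shuffled$id <- paste0("zz_", shuffled$id)
  f3 <- fit_transitions(shuffled, h = 0.25)
  expect_equal(f1$coef, f3$coef, tolerance = 1e-6)
})

test_that("degenerate episode sets are rejected", {
  eps <- one_episode(70, 1, 1, 2)
  expect_error(fit_transitions(eps, h = 1), "each living state")
  expect_error(fit_transitions(eps[0, ], h = 1), "no episodes|each living state")
})

test_that("one-year tables are stochastic and respect planted effects", {
  gen <- generate_cohort(sim_config(n = 2000L, seed = 13L,
                                    model = study_model()))
  eps <- build_histories(apply_eligibility(gen$cohort)$cohort)
  fit <- fit_transitions(eps, h = 0.25)
  ages <- c(65, 75, 85)
  tb0 <- one_year_table(fit, ages, c(lonely = 0), n_draws = 150L, seed = 8L)
  tb1 <- one_year_table(fit, ages, c(lonely = 1), n_draws = 150L, seed = 8L)
  ## rows sum to one at every age
  for (tb in list(tb0, tb1)) for (a in ages) for (o in c("healthy", "unhealthy")) {
    expect_equal(sum(tb$estimate[tb$age == a & tb$origin == o]), 1,
                 tolerance = 1e-9)
  }
  ## the harmful planted loneliness effect raises death risk at every age
  d0 <- tb0$estimate[tb0$origin == "healthy" & tb0$destination == "dead"]
  d1 <- tb1$estimate[tb1$origin == "healthy" & tb1$destination == "dead"]
  expect_true(all(d1 > d0))
  expect_true(all(tb0$se >= 0))
  ## one-year step model: table equals the one-step matrix directly
  hom <- hom_coef(0.1, 0.05, 0.2, 0.1, h = 1, cap = 110)
  hom2 <- transition_coefficients(hom$coef, h = 1, cap = 110,
                                  vcov = diag(0, 8), convergence = list())
  tbh <- one_year_table(hom2, 80, NULL, n_draws = 100L)
  expect_equal(tbh$estimate, as.vector(step_matrix(hom2, 80)[1:2, ]),
               tolerance = 1e-12)
  ## delta-method route agrees with bootstrap to leading order
  tbd <- one_year_table(fit, 75, c(lonely = 0), se_method = "delta")
  tbb <- one_year_table(fit, 75, c(lonely = 0), n_draws = 400L, seed = 5L)
  expect_equal(tbd$estimate, tbb$estimate)
  expect_true(all(abs(tbd$se - tbb$se) <= 0.35 * pmax(tbd$se, 1e-8)))
})
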