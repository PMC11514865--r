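test_that("stable prevalence honours symmetry and absorbing structure", {
  ## symmetric living chain: both states equally likely among the alive
  sym <- hom_coef(0.2, 0.05, 0.2, 0.05, h = 0.25, cap = 120)
  w <- stable_prevalence(sym, 95, burn_in = 30, tolerance = 1e-8)
  expect_equal(w$w1, 0.5, tolerance = 1e-7)
  expect_equal(w$w1 + w$w2, 1)
  expect_true(w$converged)
  ## no recovery and no mortality: unhealthy absorbs the living
  onew <- hom_coef(0.2, 0, 0, 0, h = 0.25, cap = 120)
  w <- stable_prevalence(onew, 95, burn_in = 30, tolerance = 1e-8)
  expect_equal(w$w2, 1, tolerance = 1e-6)
})

test_that("stable prevalence matches the dominant-eigenvector oracle", {
  hom <- hom_coef(0.12, 0.04, 0.25, 0.09, h = 0.25, cap = 200)
  Q <- step_matrix(hom, 80, NULL)[1:2, 1:2]
  ev <- eigen(t(Q))
  dom <- which.max(Re(ev$values))
  v <- Re(ev$vectors[, dom])
  v <- v / sum(v)
  w <- stable_prevalence(hom, 95, burn_in = 30, tolerance = 1e-12)
  expect_equal(w$w1, v[1], tolerance = 1e-8)
  ## start-state independence at convergence
  expect_equal(unname(w$w_by_start[1, 1]), unname(w$w_by_start[2, 1]),
               tolerance = 1e-8)
})

test_that("prevalence burn-in warns when it cannot converge", {
  ## nearly frozen living chain cannot mix within the span
  slow <- hom_coef(1e-6, 0.01, 1e-6, 0.01, h = 1, cap = 200)
  expect_warning(stable_prevalence(slow, 95, burn_in = 5, tolerance = 1e-10),
                 "did not converge")
})

test_that("conditional expectancies match closed forms", {
  ## immediate certain death leaves only the trapezoid half-step
  lethal <- transition_coefficients(cbind(c(-50, 50, -50, 50), 0),
                                    h = 0.5, cap = 110)
  e <- conditional_expectancies(lethal, 70)
  expect_equal(unname(e), matrix(c(0.25, 0, 0, 0.25), 2), tolerance = 1e-10)
  ## homogeneous chain: fundamental-matrix oracle h (I-Q)^{-1} - h/2 I
  hom <- hom_coef(0.1, 0.05, 0.2, 0.1, h = 0.25, cap = 2000)
  Q <- step_matrix(hom, 70, NULL)[1:2, 1:2]
  oracle <- 0.25 * solve(diag(2) - Q) - 0.125 * diag(2)
  expect_equal(unname(conditional_expectancies(hom, 70)), oracle,
               tolerance = 1e-6, ignore_attr = TRUE)
  ## pure survival with annual death probability q: geometric series
  q <- 0.07
  iso <- hom_coef(0, q, 0, q, h = 1, cap = 3000)
  e <- conditional_expectancies(iso, 70)
  expect_equal(e[1, 1], (1 - q) / q + 0.5, tolerance = 1e-5)
  expect_equal(e[1, 2], 0, tolerance = 1e-10)
})

test_that("population expectancies mix by prevalence and stay additive", {
  fit <- transition_coefficients(true_model(h = 0.25)$coef, h = 0.25,
                                 covariates = "lonely", cap = 110)
  for (lon in 0:1) for (x in c(65, 80, 95)) {
    pe <- population_expectancies(fit, x, c(lonely = lon))
    expect_identical(pe$le, pe$hle + pe$ule)      # exact additivity
    expect_true(pe$ratio >= 0 && pe$ratio <= 100)
    e <- pe$e_cond
    expect_equal(pe$hle, (1 - pe$w2) * e[1, 1] + pe$w2 * e[2, 1])
  }
  ## degenerate mixture: w2 = 0 collapses onto the healthy-conditional row
  pure <- hom_coef(1e-9, 0.05, 0.9, 0.05, h = 1, cap = 300)
  pe <- population_expectancies(pure, 95, burn_in = 20)
  e <- conditional_expectancies(pure, 95)
  expect_equal(pe$hle, e[1, 1], tolerance = 1e-4)
  ## LE decreases in starting age under positive mortality
  les <- vapply(c(65, 70, 75, 80, 85, 90, 95), function(x)
    population_expectancies(fit, x, c(lonely = 0))$le, numeric(1))
  expect_true(all(diff(les) < 0))
})

test_that("halving the step changes LE by less than the discretization bound", {
  ## one smooth continuous-time model, embedded exactly at each step
  ## length: step probabilities are the matrix exponential of the living
  ## generator, so LE differences reflect discretization alone
  G <- rbind(c(-0.10, 0.06), c(0.12, -0.20))   # off-diagonal exits to death
  expm2 <- function(A) {
    ev <- eigen(A)
    Re(ev$vectors %*% diag(exp(ev$values)) %*% solve(ev$vectors))
  }
  le_h <- function(h) {
    Ph <- expm2(G * h)
    cf <- hom_coef(Ph[1, 2], 1 - sum(Ph[1, ]), Ph[2, 1], 1 - sum(Ph[2, ]),
                   h = h, cap = 3000)
    conditional_expectancies(cf, 70)[1, 1] +
      conditional_expectancies(cf, 70)[1, 2]
  }
  expect_lt(abs(le_h(0.5) - le_h(0.25)), 0.25)
})

test_that("parametric bootstrap intervals behave like intervals", {
  gen <- generate_cohort(sim_config(n = 1500L, seed = 17L,
                                    model = study_model()))
  eps <- build_histories(apply_eligibility(gen$cohort)$cohort)
  fit <- fit_transitions(eps, h = 0.25)
  target <- function(cf) {
    pe <- population_expectancies(cf, 75, c(lonely = 1))
    c(le = pe$le, hle = pe$hle)
  }
  ci <- suppressWarnings(
    confidence_intervals(fit, target, n_draws = 200L, seed = 3L))
  expect_true(all(ci$lower <= ci$estimate + 1e-9))
  expect_true(all(ci$upper >= ci$estimate - 1e-9))
  ## determinism for a fixed seed
  ci2 <- suppressWarnings(
    confidence_intervals(fit, target, n_draws = 200L, seed = 3L))
  expect_identical(ci, ci2)
  ## zero covariance collapses the interval onto the point estimate
  flat <- transition_coefficients(fit$coef, h = fit$h, covariates = "lonely",
                                  cap = fit$cap, vcov = 0 * fit$vcov,
                                  convergence = list())
  ci0 <- suppressWarnings(
    confidence_intervals(flat, target, n_draws = 100L, seed = 1L))
  expect_equal(ci0$lower, ci0$estimate, tolerance = 1e-12)
  expect_equal(ci0$upper, ci0$estimate, tolerance = 1e-12)
  ## quadrupled covariance roughly doubles the width on the same draws
  wide <- transition_coefficients(fit$coef, h = fit$h, covariates = "lonely",
                                  cap = fit$cap, vcov = 4 * fit$vcov,
                                  convergence = list())
  ciw <- suppressWarnings(
    confidence_intervals(wide, target, n_draws = 200L, seed = 3L))
  ratio <- (ciw$upper - ciw$lower) / (ci$upper - ci$lower)
  expect_true(all(ratio > 1.6 & ratio < 2.6))
  expect_error(confidence_intervals(fit, target, n_draws = 50L), "n_draws")
})

test_that("the fast draw-vectorized table agrees with the scalar route", {
  gen <- generate_cohort(sim_config(n = 1200L, seed = 23L,
                                    model = study_model()))
  eps <- build_histories(apply_eligibility(gen$cohort)$cohort)
  fit <- fit_transitions(eps, h = 0.25)
  tb <- hle_table(fit, c(70, 85), list(lonely = c(lonely = 1)),
                  n_draws = 150L, seed = 6L)
  for (i in seq_len(nrow(tb))) {
    pe <- population_expectancies(fit, tb$age[i], c(lonely = 1))
    expect_equal(tb$le[i], pe$le, tolerance = 1e-9)
    expect_equal(tb$ratio[i], pe$ratio, tolerance = 1e-9)
    expect_true(tb$le_lower[i] <= tb$le[i] && tb$le[i] <= tb$le_upper[i])
  }
})

test_that("Kannisto fitting recovers parameters and degenerate shapes", {
  x <- seq(65, 100, by = 2.5)
  a <- 0.01; b <- 0.1
  mu <- a * exp(b * (x - 65)) / (1 + a * exp(b * (x - 65)))
  exposure <- rep(5e4, length(x))
  kf <- kannisto_fit(x, mu * exposure, exposure)
  expect_equal(kf$a, a, tolerance = 1e-3)
  expect_equal(kf$b, b, tolerance = 1e-3)
  ## hazard stays below one even far beyond the data
  expect_lt(kf$hazard(130), 1)
  expect_gt(kf$b, 0)
  ## constant rates give a flat hazard
  flat <- kannisto_fit(x, 0.05 * exposure, exposure)
  expect_equal(flat$b, 0, tolerance = 1e-6)
  expect_error(kannisto_fit(x[1:3], mu[1:3] * 100, rep(100, 3)), "at least 4")
  expect_error(kannisto_fit(x, mu * 100, rep(0, length(x))), "positive")
  expect_warning(kannisto_fit(x, rep(0, length(x)), exposure), "boundary")
})

test_that("simulated old-age mortality is Kannisto-like", {
  ## death rates by 5-year band from the generator feed an increasing
  ## logistic hazard (b > 0)
  gen <- generate_cohort(sim_config(n = 4000L, seed = 29L,
                                    model = study_model()))
  eps <- build_histories(apply_eligibility(gen$cohort)$cohort)
  mid <- eps$age_start + eps$elapsed / 2
  band <- pmin(5 * floor(mid / 5), 100)
  exposure <- tapply(eps$elapsed, band, sum)
  deaths <- tapply(eps$end_type == "death", band, sum)
  keep <- exposure > 10
  kf <- kannisto_fit(as.numeric(names(exposure))[keep] + 2.5,
                     deaths[keep], exposure[keep])
  expect_gt(kf$b, 0)
  expect_true(all(kf$hazard(seq(65, 110)) < 1))
})
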