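## Multistate life-table quantities from a fitted transition model.
##
## All propagation works on the 2x2 living-state block of the step matrix;
## the dead state is absorbing so it never feeds back. The engine is
## vectorized across coefficient draws so parametric-bootstrap confidence
## intervals cost one propagation pass, not one per draw.

# Column indices of transition j's coefficients in the column-major
# flattening of the 4 x p coefficient matrix.
.tr_idx <- function(j, p) seq(j, 4L * p, by = 4L)

# Per-step living-block probabilities for all draws at one age.
# draws: n x (4p) matrix; z: covariate values; returns list of n-vectors.
.draws_step <- function(Mlist, tcent, z) {
  xv <- c(1, tcent, z)
  e12 <- exp(.clip_eta(as.vector(Mlist[[1L]] %*% xv)))
  e13 <- exp(.clip_eta(as.vector(Mlist[[2L]] %*% xv)))
  e21 <- exp(.clip_eta(as.vector(Mlist[[3L]] %*% xv)))
  e23 <- exp(.clip_eta(as.vector(Mlist[[4L]] %*% xv)))
  d1 <- 1 + e12 + e13
  d2 <- 1 + e21 + e23
  list(p11 = 1 / d1, p12 = e12 / d1, p13 = e13 / d1,
       p21 = e21 / d2, p22 = 1 / d2, p23 = e23 / d2)
}

.draws_Mlist <- function(draws, p) lapply(1:4, function(j)
  draws[, .tr_idx(j, p), drop = FALSE])

# Stable prevalence for all draws: living-block product from age x-t back
# to x accumulated by prepending earlier steps, fixed burn-in of nb steps.
.draws_prevalence <- function(Mlist, x, z, h, nb) {
  n <- nrow(Mlist[[1L]])
  b11 <- b22 <- rep(1, n); b12 <- b21 <- rep(0, n)
  for (k in seq_len(nb)) {
    P <- .draws_step(Mlist, (x - 65) - k * h, z)
    n11 <- P$p11 * b11 + P$p12 * b21
    n12 <- P$p11 * b12 + P$p12 * b22
    n21 <- P$p21 * b11 + P$p22 * b21
    n22 <- P$p21 * b12 + P$p22 * b22
    b11 <- n11; b12 <- n12; b21 <- n21; b22 <- n22
  }
  b12 / (b11 + b12)
}

# Conditional expectancies for all draws: forward occupancy from x to the
# cap, trapezoid end-correction h/2 on the diagonal.
.draws_expectancies <- function(Mlist, x, z, h, cap) {
  n <- nrow(Mlist[[1L]])
  o11 <- o22 <- rep(1, n); o12 <- o21 <- rep(0, n)
  s11 <- s12 <- s21 <- s22 <- rep(0, n)
  u <- 0L
  while (x + u * h < cap - 1e-9) {
    P <- .draws_step(Mlist, (x - 65) + u * h, z)
    n11 <- o11 * P$p11 + o12 * P$p21
    n12 <- o11 * P$p12 + o12 * P$p22
    n21 <- o21 * P$p11 + o22 * P$p21
    n22 <- o21 * P$p12 + o22 * P$p22
    o11 <- n11; o12 <- n12; o21 <- n21; o22 <- n22
    s11 <- s11 + o11; s12 <- s12 + o12
    s21 <- s21 + o21; s22 <- s22 + o22
    u <- u + 1L
    if (max(o11 + o12, o21 + o22) < 1e-8) break
  }
  list(e11 = h * s11 + h / 2, e12 = h * s12,
       e21 = h * s21, e22 = h * s22 + h / 2)
}

#' Stable (period) prevalence of the living states
#'
#' The within-alive distribution over states 1 and 2 at age `x` reached by
#' running the age-inhomogeneous chain from an earlier starting age,
#' independent of the starting state. The burn-in span is grown (by
#' prepending earlier steps to the interval product) until the prevalence
#' from both starting states agrees and has stopped moving, within
#' `tolerance`. Ages below the fitted range are extrapolated through the
#' logit model when the burn-in requires them.
#'
#' @param coeffs an `ms_coef` object.
#' @param x age (years) at which prevalence is evaluated.
#' @param profile named covariate values.
#' @param burn_in maximum burn-in span in years.
#' @param tolerance convergence tolerance on the prevalence proportions.
#' @return List of class `prevalence_vector`: `age`, `w1`, `w2`,
#'   `t` (burn-in achieved, years), `converged`, and the per-start-state
#'   prevalences `w_by_start`.
#' @export
stable_prevalence <- function(coeffs, x, profile = NULL, burn_in = 30,
                              tolerance = 1e-6) {
  stopifnot(burn_in > 0, tolerance > 0)
  z <- .profile_z(coeffs, profile)
  h <- coeffs$h
  nb <- as.integer(round(burn_in / h))
  B <- diag(2)
  w_prev <- c(NA_real_, NA_real_)
  t_ach <- NA_real_
  converged <- FALSE
  Z1 <- matrix(z, nrow = 1L)
  for (k in seq_len(nb)) {
    P <- .step_probs6(coeffs$coef, x - k * h, Z1)
    A <- rbind(c(P$p11, P$p12), c(P$p21, P$p22))
    B <- A %*% B
    w <- B[, 1L] / (B[, 1L] + B[, 2L])
    if (k > 1L && max(abs(w - w_prev)) < tolerance &&
        abs(w[1L] - w[2L]) < tolerance) {
      t_ach <- k * h
      converged <- TRUE
      break
    }
    w_prev <- w
  }
  if (!converged) {
    t_ach <- nb * h
    warning("stable prevalence did not converge within the burn-in span; ",
            "returning the last iterate")
    w <- B[, 1L] / (B[, 1L] + B[, 2L])
  }
  structure(list(age = x, w1 = w[1L], w2 = 1 - w[1L], t = t_ach,
                 converged = converged,
                 w_by_start = rbind(`from 1` = c(w[1L], 1 - w[1L]),
                                    `from 2` = c(w[2L], 1 - w[2L]))),
            class = "prevalence_vector")
}

#' State-conditional life expectancies
#'
#' The expected years spent in each living state `j` after age `x` given
#' the state `i` occupied at `x`:
#' \deqn{e^{ij}(x) = h \sum_{u \ge 1} {}_{u}p_x^{ij} + (h/2)\,\delta_{ij},}
#' the half-step diagonal term being the trapezoid end-correction of the
#' discretized occupancy integral. The sum runs to the age cap, where
#' death is forced, or until remaining survival falls below 1e-8.
#'
#' @inheritParams stable_prevalence
#' @return 2x2 matrix (rows: state at `x`; columns: state occupied).
#' @export
conditional_expectancies <- function(coeffs, x, profile = NULL) {
  z <- .profile_z(coeffs, profile)
  p <- ncol(coeffs$coef)
  Mlist <- .draws_Mlist(matrix(.cf_par(coeffs$coef), nrow = 1L), p)
  ee <- .draws_expectancies(Mlist, x, z, coeffs$h, coeffs$cap)
  matrix(c(ee$e11, ee$e21, ee$e12, ee$e22), 2L, 2L,
         dimnames = list(c("from healthy", "from unhealthy"),
                         c("healthy years", "unhealthy years")))
}

#' Population-based expectancies at an age
#'
#' Mixes the state-conditional expectancies by the stable prevalence:
#' \deqn{e^{.j} = [1 - w^2(x)]\, e^{1j} + w^2(x)\, e^{2j},}
#' giving healthy life expectancy HLE = e^{.1}, unhealthy years
#' e^{.2}, total LE = e^{.1} + e^{.2} (exact by construction), and the
#' ratio 100 HLE/LE.
#'
#' @inheritParams stable_prevalence
#' @return List of class `expectancy_result` with `age`, `profile`,
#'   `e_cond` (2x2), `w2`, `hle`, `ule`, `le`, `ratio`.
#' @export
population_expectancies <- function(coeffs, x, profile = NULL,
                                    burn_in = 30, tolerance = 1e-6) {
  w <- stable_prevalence(coeffs, x, profile, burn_in, tolerance)
  e <- conditional_expectancies(coeffs, x, profile)
  hle <- (1 - w$w2) * e[1L, 1L] + w$w2 * e[2L, 1L]
  ule <- (1 - w$w2) * e[1L, 2L] + w$w2 * e[2L, 2L]
  le <- hle + ule
  if (le <= 0) stop("life expectancy is zero; HLE/LE undefined")
  structure(list(age = x, profile = profile, e_cond = e, w2 = w$w2,
                 prevalence_t = w$t, hle = hle, ule = ule, le = le,
                 ratio = 100 * hle / le),
            class = "expectancy_result")
}

#' @export
print.expectancy_result <- function(x, ...) {
  cat(sprintf("Age %g: LE %.2f = HLE %.2f + %.2f unhealthy years (HLE/LE %.1f%%)\n",
              x$age, x$le, x$hle, x$ule, x$ratio))
  invisible(x)
}

#' Parametric-bootstrap confidence intervals
#'
#' Draws coefficient vectors from the asymptotic sampling distribution of
#' the fit, re-evaluates a target function under each draw, and reports
#' percentile 95% intervals. Deterministic for a fixed seed.
#'
#' @param fit an `ms_fit` object (with covariance).
#' @param target function taking an `ms_coef` object and returning a named
#'   numeric vector of quantities.
#' @param n_draws number of draws (>= 100).
#' @param seed RNG seed.
#' @param level confidence level.
#' @return Data frame with columns `target`, `estimate`, `lower`, `upper`.
#' @export
confidence_intervals <- function(fit, target, n_draws = 500L, seed = 1L,
                                 level = 0.95) {
  stopifnot(n_draws >= 100L)
  draws <- draw_coefficients(fit, n_draws, seed)
  point <- target(fit)
  vals <- apply(draws, 1L, function(par) {
    target(transition_coefficients(.par_cf(par, fit$coef), h = fit$h,
                                   covariates = fit$covariates,
                                   cap = fit$cap))
  })
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  a <- (1 - level) / 2
  data.frame(target = names(point),
             estimate = as.numeric(point),
             lower = apply(vals, 1L, stats::quantile, probs = a),
             upper = apply(vals, 1L, stats::quantile, probs = 1 - a),
             row.names = NULL)
}

#' Life-table summary with confidence intervals
#'
#' Population-based LE, HLE and HLE/LE at each requested age and covariate
#' profile, with percentile parametric-bootstrap 95% confidence intervals
#' computed draw-vectorized (one propagation pass for all draws).
#'
#' @param fit an `ms_fit` object.
#' @param ages ages at which to evaluate.
#' @param profiles named list of covariate profiles (names label rows).
#' @param n_draws bootstrap draw count.
#' @param seed bootstrap seed.
#' @param burn_in prevalence burn-in span in years.
#' @return Data frame, one row per (profile, age), with point estimates and
#'   CI bounds for LE, HLE, unhealthy years and HLE/LE (%).
#' @export
hle_table <- function(fit, ages, profiles = list(overall = NULL),
                      n_draws = 500L, seed = 1L, burn_in = 30) {
  p <- ncol(fit$coef)
  draws <- draw_coefficients(fit, n_draws, seed)
  nb <- as.integer(round(burn_in / fit$h))
  Mlist <- .draws_Mlist(draws, p)
  rows <- list()
  for (pl in names(profiles)) {
    z <- .profile_z(fit, profiles[[pl]])
    for (x in ages) {
      pt <- population_expectancies(fit, x, profiles[[pl]], burn_in = burn_in)
      w2 <- .draws_prevalence(Mlist, x, z, fit$h, nb)
      ee <- .draws_expectancies(Mlist, x, z, fit$h, fit$cap)
      hle <- (1 - w2) * ee$e11 + w2 * ee$e21
      ule <- (1 - w2) * ee$e12 + w2 * ee$e22
      le <- hle + ule
      ratio <- 100 * hle / pmax(le, 1e-12)
      q <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
      qle <- q(le); qh <- q(hle); qu <- q(ule); qr <- q(ratio)
      rows[[length(rows) + 1L]] <- data.frame(
        profile = pl, age = x,
        le = pt$le, le_lower = qle[1L], le_upper = qle[2L],
        hle = pt$hle, hle_lower = qh[1L], hle_upper = qh[2L],
        ule = pt$ule, ule_lower = qu[1L], ule_upper = qu[2L],
        ratio = pt$ratio, ratio_lower = qr[1L], ratio_upper = qr[2L])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_draws") <- n_draws
  attr(out, "seed") <- seed
  class(out) <- c("hle_table", "data.frame")
  out
}

#' Fit the Kannisto old-age mortality model
#'
#' The Kannisto hazard \eqn{\mu(x) = a e^{b(x - x_0)} / (1 + a e^{b(x -
#' x_0)})} is logistic in age, so binomial maximum likelihood reduces to a
#' logit GLM of deaths on centered age.
#'
#' @param age age-group midpoints (years), at least 4 groups.
#' @param deaths death counts per group (may be weighted, non-integer).
#' @param exposure persons (or person-years) at risk per group, all > 0.
#' @param x0 centering age for the parameterization.
#' @return List of class `kannisto_fit`: `a`, `b`, their standard errors
#'   (log scale for `a`), `deviance`, `x0`, `age_range`, and a `hazard`
#'   function of age.
#' @export
kannisto_fit <- function(age, deaths, exposure, x0 = 65) {
  stopifnot(length(age) == length(deaths), length(age) == length(exposure))
  if (length(age) < 4L) stop("at least 4 age groups are required")
  if (any(exposure <= 0)) stop("all exposures must be positive")
  if (all(deaths == 0)) warning("no deaths observed; fit is at the boundary")
  t <- age - x0
  fit <- suppressWarnings(
    stats::glm(cbind(deaths, exposure - deaths) ~ t, family = stats::binomial()))
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  a <- unname(exp(cf[1L])); b <- unname(cf[2L])
  structure(list(a = a, b = b, se_log_a = unname(se[1L]), se_b = unname(se[2L]),
                 deviance = stats::deviance(fit), x0 = x0,
                 age_range = range(age),
                 hazard = function(x) {
                   u <- a * exp(b * (x - x0)); u / (1 + u)
                 }),
            class = "kannisto_fit")
}

#' @export
print.kannisto_fit <- function(x, ...) {
  cat(sprintf("Kannisto logistic hazard: a = %.5f, b = %.4f (age centered at %g)\n",
              x$a, x$b, x$x0))
  cat(sprintf("deviance %.3f on ages %g-%g\n", x$deviance,
              x$age_range[1L], x$age_range[2L]))
  invisible(x)
}
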