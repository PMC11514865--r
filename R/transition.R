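.TRANSITIONS <- c("1->2", "1->3", "2->1", "2->3")

## Coefficient container ------------------------------------------------

#' Transition coefficients for the embedded Markov chain
#'
#' The chain moves over states 1 = healthy, 2 = unhealthy, 3 = dead on a
#' fine time step of `h` years. Each off-diagonal transition from a living
#' state carries a multinomial logit
#' \deqn{\eta_{jk}(x, z) = a_{jk} + b_{jk} (x - 65) + c_{jk}' z,}
#' and within an origin state \eqn{p_{jk} = e^{\eta_{jk}} / (1 + \sum_{k'}
#' e^{\eta_{jk'}})}, with the stay probability taking the remaining mass.
#' Death is absorbing. Age is centered at 65 internally; this is a pure
#' reparameterization of an uncentered intercept.
#'
#' @param coef numeric 4 x (2 + ncov) matrix; rows `1->2`, `1->3`, `2->1`,
#'   `2->3`; columns `(Intercept)`, `age65`, then one per covariate.
#' @param h step length in years (default one month).
#' @param covariates character vector of covariate names (may be empty).
#' @param cap age (years) at which death is forced, closing the life table.
#' @param vcov optional covariance of the coefficient vector
#'   (column-major flattening of `coef`).
#' @param convergence optional list of fit diagnostics.
#' @return An object of class `ms_coef` (and `ms_fit` when `vcov` given).
#' @export
transition_coefficients <- function(coef, h = 1 / 12, covariates = character(),
                                    cap = 110, vcov = NULL, convergence = NULL) {
  p <- 2L + length(covariates)
  coef <- matrix(as.numeric(coef), nrow = 4L, ncol = p,
                 dimnames = list(.TRANSITIONS,
                                 c("(Intercept)", "age65", covariates)))
  stopifnot(h > 0, h <= 1, cap > 99)
  obj <- structure(list(coef = coef, h = h, covariates = covariates,
                        cap = cap, age_ref = 65, vcov = vcov,
                        convergence = convergence),
                   class = if (is.null(vcov)) "ms_coef" else c("ms_fit", "ms_coef"))
  if (!is.null(vcov)) {
    npar <- length(coef)
    stopifnot(is.matrix(vcov), nrow(vcov) == npar, ncol(vcov) == npar)
    ev <- eigen((vcov + t(vcov)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-6 * max(abs(ev), 1e-12))
      stop("coefficient covariance is not positive semidefinite")
  }
  obj
}

#' @export
print.ms_coef <- function(x, ...) {
  cat("Embedded Markov chain over {healthy, unhealthy, dead}\n")
  cat(sprintf("step h = %.4g years, age cap = %g\n", x$h, x$cap))
  print(round(x$coef, 4))
  if (!is.null(x$convergence))
    cat(sprintf("log-likelihood %.4f (%s)\n", x$convergence$loglik,
                if (isTRUE(x$convergence$converged)) "converged" else "NOT converged"))
  invisible(x)
}

.cf_par <- function(coef) as.vector(coef)
.par_cf <- function(par, template) {
  matrix(par, nrow = nrow(template), ncol = ncol(template),
         dimnames = dimnames(template))
}

.profile_z <- function(object, profile) {
  cv <- object$covariates
  if (!length(cv)) return(numeric(0))
  if (is.null(profile)) stop("a covariate profile is required")
  profile <- unlist(profile)
  miss <- setdiff(cv, names(profile))
  if (length(miss)) stop("profile is missing covariate(s): ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(names(profile), cv)
  if (length(extra)) stop("profile has undeclared covariate(s): ",
                          paste(extra, collapse = ", "))
  as.numeric(profile[cv])
}

## Step probabilities, vectorized over (age, Z) rows --------------------

.clip_eta <- function(eta) pmin(pmax(eta, -50), 50)

# Returns the six living-origin probabilities at ages `age` (vector) with
# covariate rows Z (matrix, possibly 0 columns), as a list of vectors.
.step_probs6 <- function(coef, age, Z) {
  n <- length(age)
  X <- cbind(1, age - 65,
             if (!is.null(Z) && ncol(Z)) Z else NULL)
  Eta <- .clip_eta(X %*% t(coef))          # n x 4: (1->2, 1->3, 2->1, 2->3)
  E <- exp(Eta)
  d1 <- 1 + E[, 1L] + E[, 2L]
  d2 <- 1 + E[, 3L] + E[, 4L]
  list(p11 = 1 / d1, p12 = E[, 1L] / d1, p13 = E[, 2L] / d1,
       p21 = E[, 3L] / d2, p22 = 1 / d2, p23 = E[, 4L] / d2)
}

#' One-step transition matrix
#'
#' The 3x3 stochastic matrix of h-step transition probabilities at a given
#' age under a covariate profile. The dead row is exactly (0, 0, 1).
#'
#' @param coeffs an `ms_coef` object.
#' @param age age in years at the start of the step.
#' @param profile named covariate values (may be `NULL` when the model has
#'   no covariates).
#' @return 3x3 matrix, rows = origin state, columns = destination.
#' @export
step_matrix <- function(coeffs, age, profile = NULL) {
  z <- .profile_z(coeffs, profile)
  p <- .step_probs6(coeffs$coef, age, matrix(z, nrow = 1L))
  m <- rbind(c(p$p11, p$p12, p$p13),
             c(p$p21, p$p22, p$p23),
             c(0, 0, 1))
  dimnames(m) <- list(c("healthy", "unhealthy", "dead"),
                      c("healthy", "unhealthy", "dead"))
  m
}

#' Transition probabilities over an interval
#'
#' Chains one-step matrices over an interval, the age advancing by `h` at
#' each step and the covariate profile held fixed (last observation carried
#' forward). The elapsed time is rounded to the nearest whole number of
#' steps.
#'
#' @inheritParams step_matrix
#' @param age_start age in years opening the interval.
#' @param elapsed interval length in years (> 0).
#' @return 3x3 matrix of interval transition probabilities.
#' @export
interval_probability <- function(coeffs, age_start, elapsed, profile = NULL) {
  if (elapsed <= 0) stop("elapsed time must be positive")
  h <- coeffs$h
  nsteps <- max(1L, as.integer(round(elapsed / h)))
  if (abs(elapsed - nsteps * h) > h / 2 + 1e-12)
    warning(sprintf("elapsed %.4f not a multiple of h; using %d steps",
                    elapsed, nsteps))
  if (age_start + nsteps * h > coeffs$cap + 1e-9)
    stop("interval extends beyond the age cap")
  z <- .profile_z(coeffs, profile)
  Z1 <- matrix(z, nrow = 1L)
  P <- diag(3)
  for (u in seq_len(nsteps)) {
    P <- P %*% .step3(coeffs$coef, age_start + (u - 1L) * h, Z1)
  }
  dimnames(P) <- list(c("healthy", "unhealthy", "dead"),
                      c("healthy", "unhealthy", "dead"))
  P
}

.step3 <- function(coef, age, Z1) {
  p <- .step_probs6(coef, age, Z1)
  rbind(c(p$p11, p$p12, p$p13),
        c(p$p21, p$p22, p$p23),
        c(0, 0, 1))
}

## Likelihood -----------------------------------------------------------

# Snap episodes to the step grid and collapse identical likelihood
# contributions. Episode start ages are rounded to the nearest grid age
# 65 + i*h; observed-state episodes use round(elapsed/h) steps (min 1);
# death episodes place the death in the step containing the exact death
# age, i.e. ceiling(elapsed/h) steps.
.prepare_episodes <- function(episodes, h, covariates, cap) {
  if (!nrow(episodes)) stop("no episodes to fit")
  if (!all(episodes$state_start %in% 1:2)) stop("origin states must be 1 or 2")
  if (!all(episodes$end_state %in% 1:3)) stop("end states must be 1, 2 or 3")
  Z <- if (length(covariates))
    as.matrix(episodes[, covariates, drop = FALSE]) else
    matrix(numeric(0), nrow = nrow(episodes), ncol = 0L)
  i0 <- as.integer(round((episodes$age_start - 65) / h))
  death <- episodes$end_type == "death"
  m <- integer(nrow(episodes))
  m[!death] <- pmax(1L, as.integer(round(episodes$elapsed[!death] / h)))
  m[death] <- pmax(1L, as.integer(ceiling(episodes$elapsed[death] / h - 1e-9)))
  over <- 65 + (i0 + m) * h > cap + 1e-9
  if (any(over)) stop(sum(over), " episode(s) extend beyond the age cap")
  w <- normalize_weights(episodes$weight)
  key <- paste(i0, m, episodes$state_start, death, episodes$end_state,
               apply(Z, 1L, paste, collapse = ","), sep = "|")
  grp <- match(key, unique(key))
  ng <- max(grp)
  first <- match(seq_len(ng), grp)
  list(i0 = i0[first], m = m[first],
       origin = episodes$state_start[first],
       death = death[first], end_state = episodes$end_state[first],
       Z = Z[first, , drop = FALSE],
       w = as.vector(tapply(w, grp, sum)),
       n_episodes = nrow(episodes), n_groups = ng, h = h)
}

# Weighted log-likelihood of grouped episodes under coefficient matrix cf.
# Forward propagation of the living-state occupancy row vector; death
# episodes absorb through the dead column of their final step.
.grouped_loglik <- function(cf, prep, details = FALSE) {
  h <- prep$h
  ord <- order(prep$m, decreasing = TRUE)
  i0 <- prep$i0[ord]; m <- prep$m[ord]; origin <- prep$origin[ord]
  death <- prep$death[ord]; endst <- prep$end_state[ord]
  Z <- prep$Z[ord, , drop = FALSE]; w <- prep$w[ord]
  ng <- prep$n_groups
  r1 <- as.numeric(origin == 1L)
  r2 <- as.numeric(origin == 2L)
  lik <- numeric(ng)
  maxm <- m[1L]
  n_active <- findInterval(-seq_len(maxm), -m) # groups 1..n_active[u] have m >= u
  for (u in seq_len(maxm)) {
    na <- n_active[u]
    ii <- seq_len(na)
    age <- 65 + (i0[ii] + u - 1L) * h
    P <- .step_probs6(cf, age, Z[ii, , drop = FALSE])
    fin <- m[ii] == u
    dth <- fin & death[ii]
    if (any(dth)) {
      jd <- ii[dth]
      lik[jd] <- r1[jd] * P$p13[dth] + r2[jd] * P$p23[dth]
    }
    t1 <- r1[ii] * P$p11 + r2[ii] * P$p21
    t2 <- r1[ii] * P$p12 + r2[ii] * P$p22
    upd <- !dth
    r1[ii[upd]] <- t1[upd]
    r2[ii[upd]] <- t2[upd]
    sf <- fin & !death[ii]
    if (any(sf)) {
      js <- ii[sf]
      lik[js] <- ifelse(endst[js] == 1L, r1[js], r2[js])
    }
  }
  if (any(lik <= 0)) {
    bad <- which(lik <= 0)
    if (details)
      warning("zero-probability episode group(s): ",
              paste(sprintf("(start %g, %d steps, origin %d)",
                            65 + i0[bad] * h, m[bad], origin[bad]),
                    collapse = "; "))
    return(-Inf)
  }
  sum(w * log(lik))
}

#' Log-likelihood of a single episode
#'
#' The contribution of one transition episode to the interval-censored
#' likelihood: for an episode ending in an observed living state, the
#' interval transition probability into that state; for a death-in-interval
#' episode, survival in the living states up to the step containing the
#' exact death age, then the transition into death within that step (the
#' unobserved living path is summed automatically by the matrix products).
#'
#' @param coeffs an `ms_coef` object.
#' @param episode one-row data frame with columns `age_start`,
#'   `state_start`, `elapsed`, `end_type`, `end_state`, `weight`, and the
#'   model's covariate columns.
#' @return Scalar log-likelihood (`-Inf`, with a diagnostic warning, for a
#'   zero-probability episode).
#' @export
episode_loglik <- function(coeffs, episode) {
  stopifnot(nrow(episode) == 1L)
  episode$weight <- 1
  prep <- .prepare_episodes(episode, coeffs$h, coeffs$covariates, coeffs$cap)
  .grouped_loglik(coeffs$coef, prep, details = TRUE)
}

#' Fit the transition model by maximum pseudo-likelihood
#'
#' Maximizes the weighted interval-censored log-likelihood of the episode
#' table over the multinomial-logit coefficients by quasi-Newton (BFGS)
#' iteration, with a Nelder-Mead restart if the gradient-based pass fails
#' to converge. Weights are normalized to mean 1; the covariance of the
#' estimates is the inverse of the numerically differenced observed
#' information.
#'
#' @param episodes an episode table from [build_histories()].
#' @param h step length in years.
#' @param covariates names of episode columns entering the logits
#'   (default `"lonely"`).
#' @param cap age at which the life table is closed by forced death.
#' @param start optional starting coefficient matrix; by default death
#'   intercepts start at -4, morbidity/recovery intercepts at -2, all
#'   slopes and covariate effects at 0.
#' @param include_age when `FALSE`, the age slopes are fixed at zero
#'   (intercept-plus-covariates model).
#' @param control passed to [stats::optim()] (sensible defaults supplied).
#' @return An `ms_fit` object.
#' @export
fit_transitions <- function(episodes, h = 1 / 12, covariates = "lonely",
                            cap = 110, start = NULL, include_age = TRUE,
                            control = list()) {
  template <- transition_coefficients(matrix(0, 4, 2 + length(covariates)),
                                      h = h, covariates = covariates,
                                      cap = cap)$coef
  if (is.null(start)) {
    start <- template
    start[, "(Intercept)"] <- c(-2, -4, -2, -4)
  }
  if (!any(episodes$state_start == 1L) || !any(episodes$state_start == 2L))
    stop("need at least one episode starting in each living state")
  prep <- .prepare_episodes(episodes, h, covariates, cap)
  npar <- length(template)
  free <- rep(TRUE, npar)
  if (!include_age) {
    free[matrix(seq_len(npar), nrow = 4L)[, 2L]] <- FALSE
    start[, "age65"] <- 0
  }
  full_par <- function(pf) {
    par <- .cf_par(start)
    par[free] <- pf
    par
  }
  negll <- function(pf) {
    v <- -.grouped_loglik(.par_cf(full_par(pf), template), prep)
    if (!is.finite(v)) v <- 1e10
    v
  }
  nfree <- sum(free)
  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-12,
                                 ndeps = rep(1e-6, nfree)), control)
  opt <- stats::optim(.cf_par(start)[free], negll, method = "BFGS",
                      control = ctrl)
  if (opt$convergence != 0) {
    opt2 <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                         control = list(maxit = 2000L, reltol = 1e-12))
    if (opt2$value < opt$value) opt <- opt2
  }
  H <- stats::optimHess(opt$par, negll,
                        control = list(ndeps = rep(1e-5, nfree)))
  vc <- tryCatch(solve(H), error = function(e) NULL)
  singular <- is.null(vc)
  if (singular) {
    warning("singular observed information; using pseudo-inverse")
    ei <- eigen((H + t(H)) / 2, symmetric = TRUE)
    pos <- ei$values > max(ei$values) * 1e-10
    vc <- ei$vectors[, pos, drop = FALSE] %*%
      diag(1 / ei$values[pos], sum(pos)) %*% t(ei$vectors[, pos, drop = FALSE])
  }
  vc <- (vc + t(vc)) / 2
  ## numerical Hessians can leave tiny negative eigenvalues; clamp them
  ei <- eigen(vc, symmetric = TRUE)
  vc <- ei$vectors %*% diag(pmax(ei$values, 0), length(ei$values)) %*%
    t(ei$vectors)
  vc_full <- matrix(0, npar, npar)
  vc_full[free, free] <- vc
  g <- .num_grad(negll, opt$par)
  transition_coefficients(.par_cf(full_par(opt$par), template), h = h,
                          covariates = covariates, cap = cap, vcov = vc_full,
                          convergence = list(
                            loglik = -opt$value,
                            converged = opt$convergence == 0,
                            iterations = opt$counts[["function"]],
                            gradient_norm = sqrt(sum(g^2)),
                            singular_information = singular,
                            n_episodes = prep$n_episodes,
                            n_groups = prep$n_groups))
}

.num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- eps
    (f(x + e) - f(x - e)) / (2 * eps)
  }, numeric(1))
}

#' Draw coefficient vectors from the asymptotic sampling distribution
#'
#' Multivariate normal draws centered at the estimates with the fitted
#' covariance, used by the parametric bootstrap for standard errors and
#' confidence intervals.
#'
#' @param fit an `ms_fit` object.
#' @param n_draws number of draws.
#' @param seed RNG seed.
#' @return `n_draws` x npar matrix (column-major coefficient layout).
#' @export
draw_coefficients <- function(fit, n_draws = 500L, seed = 1L) {
  if (is.null(fit$vcov)) stop("fit has no covariance")
  par <- .cf_par(fit$coef)
  npar <- length(par)
  ei <- eigen((fit$vcov + t(fit$vcov)) / 2, symmetric = TRUE)
  if (min(ei$values) < -1e-6 * max(abs(ei$values), 1e-12))
    stop("covariance is not positive semidefinite")
  L <- ei$vectors %*% diag(sqrt(pmax(ei$values, 0)), npar)
  old <- .save_seed(seed)
  on.exit(.restore_seed(old))
  Zr <- matrix(stats::rnorm(n_draws * npar), n_draws, npar)
  sweep(Zr %*% t(L), 2L, par, `+`)
}

.save_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' One-year transition probability table
#'
#' One-year transition probabilities at the requested ages (the product of
#' 1/h one-step matrices), with standard errors by parametric bootstrap
#' (default) or the delta method, in the long layout
#' (origin, destination, age, estimate, SE).
#'
#' @param fit an `ms_fit` object.
#' @param ages ages (years) at which to evaluate.
#' @param profile named covariate values.
#' @param se_method `"bootstrap"` or `"delta"`.
#' @param n_draws bootstrap draw count.
#' @param seed bootstrap seed.
#' @return Data frame with one row per (age, origin, destination).
#' @export
one_year_table <- function(fit, ages, profile = NULL,
                           se_method = c("bootstrap", "delta"),
                           n_draws = 500L, seed = 1L) {
  se_method <- match.arg(se_method)
  if (any(ages < 65 | ages + 1 > fit$cap)) stop("ages outside the model grid")
  states <- c("healthy", "unhealthy", "dead")
  point <- lapply(ages, function(a) interval_probability(fit, a, 1, profile))
  one_year_fn <- function(par) {
    cf2 <- transition_coefficients(.par_cf(par, fit$coef), h = fit$h,
                                   covariates = fit$covariates, cap = fit$cap)
    unlist(lapply(ages, function(a)
      interval_probability(cf2, a, 1, profile)[1:2, ]))
  }
  if (se_method == "bootstrap") {
    draws <- draw_coefficients(fit, n_draws, seed)
    vals <- apply(draws, 1L, one_year_fn)
    ses <- apply(vals, 1L, stats::sd)
  } else {
    par <- .cf_par(fit$coef)
    J <- vapply(seq_along(par), function(i) {
      e <- numeric(length(par)); e[i] <- 1e-6
      (one_year_fn(par + e) - one_year_fn(par - e)) / 2e-6
    }, numeric(6L * length(ages)))
    ses <- sqrt(pmax(rowSums((J %*% fit$vcov) * J), 0))
  }
  est <- unlist(lapply(point, function(P) as.vector(P[1:2, ])))
  data.frame(age = rep(ages, each = 6L),
             origin = rep(rep(states[1:2], 3L), length(ages)),
             destination = rep(rep(states, each = 2L), length(ages)),
             estimate = est, se = ses, row.names = NULL)
}
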