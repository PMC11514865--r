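## Synthetic CLHLS-like cohort generator.
##
## Ground truth is an embedded Markov chain of the same family the
## estimator fits (multinomial logits in centered age and covariates),
## plus a two-state Markov chain for loneliness, observed at irregular
## interview waves with attrition. Every knob downstream analyses rely on
## (effect sizes, wave schedule, dropout, weights, seed) lives here.

#' Ground-truth transition model for simulation
#'
#' Default calibration (per step of length `h`, age centered at 65):
#' old-age mortality rising roughly Kannisto/Gompertz-like with age,
#' higher from the unhealthy state; onset of limitation rising with age;
#' recovery declining with age; a harmful loneliness effect planted on the
#' death and morbidity logits. Intercepts shift by `log(h)` so annualized
#' rates are step-invariant; at `h = 1/4` the default intercepts are
#' (-4.8, -6.3, -1.8, -5.0) for 1->2, 1->3, 2->1, 2->3. Baseline
#' prevalences elsewhere in the generator target about 25% lonely and 96%
#' healthy, echoing a CLHLS-like cohort.
#'
#' @param h step length in years (default one month).
#' @param coef optional 4 x (2 + ncov) coefficient matrix (rows `1->2`,
#'   `1->3`, `2->1`, `2->3`; columns intercept, age65 slope, covariates).
#' @param covariates covariate names (default `"lonely"`).
#' @param lonely_onset,lonely_remission annual probabilities of switching
#'   loneliness state (converted internally to per-step). Defaults give a
#'   25% stationary lonely share with slow, persistent dynamics.
#' @param cap age at which the trajectory stops (forced end of life table).
#' @return List of class `true_model`.
#' @export
true_model <- function(h = 1 / 12, coef = NULL, covariates = "lonely",
                       lonely_onset = 0.02, lonely_remission = 0.06,
                       cap = 110) {
  stopifnot(h > 0, h <= 1, lonely_onset >= 0, lonely_onset <= 1,
            lonely_remission >= 0, lonely_remission <= 1)
  if (is.null(coef)) {
    base_q <- c(-4.8, -6.3, -1.8, -5.0)       # intercepts at h = 1/4
    coef <- cbind(`(Intercept)` = base_q + log(h / 0.25),
                  age65 = c(0.085, 0.092, -0.03, 0.095),
                  lonely = c(0.30, 0.35, 0.00, 0.35))
    if (!identical(covariates, "lonely"))
      stop("supply `coef` explicitly for covariates other than 'lonely'")
  }
  cf <- transition_coefficients(coef, h = h, covariates = covariates, cap = cap)
  structure(list(coef = cf$coef, h = h, covariates = covariates, cap = cap,
                 lonely_onset_step = 1 - (1 - lonely_onset)^h,
                 lonely_remission_step = 1 - (1 - lonely_remission)^h),
            class = "true_model")
}

#' Interview wave schedule
#'
#' @param offsets follow-up offsets in years from baseline (first must
#'   be 0). Default 0/3/6/10 emulates a four-wave panel with 3/3/4-year
#'   gaps.
#' @param dropout per-follow-up-wave probability of dropping out (scalar or
#'   one value per follow-up wave); a dropout at a wave censors all later
#'   waves.
#' @return List of class `wave_schedule`.
#' @export
wave_schedule <- function(offsets = c(0, 3, 6, 10), dropout = 0.05) {
  if (!length(offsets)) stop("empty wave schedule")
  stopifnot(offsets[1L] == 0, all(diff(offsets) > 0),
            all(dropout >= 0), all(dropout < 1))
  k <- length(offsets) - 1L
  dropout <- rep_len(dropout, max(k, 1L))
  structure(list(offsets = offsets, dropout = dropout), class = "wave_schedule")
}

#' Simulation configuration
#'
#' @param n cohort size.
#' @param seed RNG seed.
#' @param model a [true_model()].
#' @param schedule a [wave_schedule()].
#' @param baseline_age_rate exponential rate of the baseline age
#'   distribution above 65 (truncated at `baseline_age_max`); the default
#'   gives a mean near 73 years.
#' @param baseline_age_max upper truncation of baseline age.
#' @param p_female,p_rural baseline covariate mixes.
#' @param p_lonely,p_healthy baseline loneliness and health prevalences.
#' @param rural_weight,urban_weight two-point sampling-weight values
#'   (normalized to mean 1 on output).
#' @param misclassification probability an interview records the wrong
#'   living state (default 0: waves observe the latent path exactly).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n = 1000L, seed = 1L, model = true_model(),
                       schedule = wave_schedule(),
                       baseline_age_rate = 0.125, baseline_age_max = 99,
                       p_female = 0.52, p_rural = 0.576,
                       p_lonely = 0.25, p_healthy = 0.96,
                       rural_weight = 0.85, urban_weight = 1.20,
                       misclassification = 0) {
  stopifnot(n >= 1L, baseline_age_rate > 0, baseline_age_max <= model$cap,
            p_lonely >= 0, p_lonely <= 1, p_healthy >= 0, p_healthy <= 1,
            misclassification >= 0, misclassification < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate one latent trajectory
#'
#' Steps the health chain and the loneliness chain forward from baseline on
#' the model's step grid until death or the age cap. Health transitions use
#' the loneliness value current at the start of each step; a death in a
#' step is recorded at the end of that step.
#'
#' @param model a [true_model()].
#' @param baseline list with `age`, `state` (1/2), `lonely` (0/1) and any
#'   extra covariates named in `model$covariates`.
#' @return List with `path` (data frame `age`, `state`, `lonely` at each
#'   step start while alive) and `death_age` (`NA` if alive at the cap).
#' @export
simulate_trajectory <- function(model, baseline) {
  h <- model$h
  cv <- model$covariates
  extra <- setdiff(cv, "lonely")
  nmax <- as.integer(ceiling((model$cap - baseline$age) / h)) + 1L
  age <- state <- lon <- numeric(nmax)
  a <- baseline$age; s <- baseline$state; l <- baseline$lonely
  death_age <- NA_real_
  k <- 0L
  while (a < model$cap - 1e-9) {
    k <- k + 1L
    age[k] <- a; state[k] <- s; lon[k] <- l
    vals <- c(lonely = l)
    if (length(extra)) vals <- c(vals, unlist(baseline[extra]))
    z <- as.numeric(vals[cv])
    P <- .step_probs6(model$coef, a, matrix(z, nrow = 1L))
    pr <- if (s == 1L) c(P$p11, P$p12, P$p13) else c(P$p21, P$p22, P$p23)
    s_next <- sample.int(3L, 1L, prob = pr)
    if (s_next == 3L) { death_age <- a + h; break }
    l <- if (l == 1L) {
      if (stats::runif(1L) < model$lonely_remission_step) 0L else 1L
    } else {
      if (stats::runif(1L) < model$lonely_onset_step) 1L else 0L
    }
    s <- s_next
    a <- a + h
  }
  list(path = data.frame(age = age[seq_len(k)], state = state[seq_len(k)],
                         lonely = lon[seq_len(k)]),
       death_age = death_age)
}

#' Observe a latent trajectory at interview waves
#'
#' Samples the latent path at the scheduled wave ages. A death between
#' waves is reported with its exact age (as by proxy informants); a dropout
#' at a follow-up wave censors all later waves, and deaths after dropout go
#' unreported. Individuals dying before the first follow-up still
#' contribute their baseline observation plus the death record.
#'
#' @param traj output of [simulate_trajectory()].
#' @param baseline_age age at the baseline wave.
#' @param schedule a [wave_schedule()].
#' @param misclassification per-interview probability of recording the
#'   opposite living state.
#' @return List with `observations` (data frame `wave`, `interview_age`,
#'   `health_state`, `lonely`), `death_age` (NA when unobserved or alive)
#'   and `censor_age` (age at last contact).
#' @export
observe_waves <- function(traj, baseline_age, schedule, misclassification = 0) {
  if (!length(schedule$offsets)) stop("empty wave schedule")
  wave_ages <- baseline_age + schedule$offsets
  path <- traj$path
  h_grid <- if (nrow(path) > 1L) path$age[2L] - path$age[1L] else Inf
  obs <- list()
  censor_age <- baseline_age
  death_reported <- NA_real_
  for (k in seq_along(wave_ages)) {
    wa <- wave_ages[k]
    if (k > 1L && stats::runif(1L) < schedule$dropout[k - 1L]) {
      ## drop out: this wave is the last contact if still alive, but the
      ## interview itself is the final one (no later waves observed)
      if (!is.na(traj$death_age) && traj$death_age <= wa) {
        death_reported <- traj$death_age
        break
      }
      i <- findInterval(wa + 1e-9, path$age)
      st <- path$state[i]; lo <- path$lonely[i]
      if (misclassification > 0 && stats::runif(1L) < misclassification)
        st <- 3L - st
      obs[[length(obs) + 1L]] <- data.frame(wave = k, interview_age = wa,
                                            health_state = st, lonely = lo)
      censor_age <- wa
      break
    }
    if (!is.na(traj$death_age) && traj$death_age <= wa) {
      death_reported <- traj$death_age
      break
    }
    i <- findInterval(wa + 1e-9, path$age)
    if (i < 1L) i <- 1L
    st <- path$state[i]; lo <- path$lonely[i]
    if (misclassification > 0 && stats::runif(1L) < misclassification)
      st <- 3L - st
    obs[[length(obs) + 1L]] <- data.frame(wave = k, interview_age = wa,
                                          health_state = st, lonely = lo)
    censor_age <- wa
  }
  list(observations = do.call(rbind, obs), death_age = death_reported,
       censor_age = censor_age)
}

# Lockstep simulation of all latent trajectories on the model's step grid,
# up to the last scheduled wave. Individuals advance on their own age grid
# (baseline age + k*h); health transitions use the loneliness value current
# at the start of each step; a death in a step is recorded at its end.
.simulate_panel <- function(model, age0, state0, lonely0, Zfix) {
  n <- length(age0)
  h <- model$h
  cv <- model$covariates
  s <- as.integer(state0); l <- as.integer(lonely0)
  death_age <- rep(NA_real_, n)
  kmax <- attr(Zfix, "kmax")
  wave_k <- attr(Zfix, "wave_k")          # step indices (0-based) of waves
  nw <- length(wave_k)
  Wstate <- matrix(NA_integer_, n, nw)
  Wlonely <- matrix(NA_integer_, n, nw)
  for (k in 0:(kmax - 1L)) {
    iw <- match(k, wave_k)
    if (!is.na(iw)) {
      alive <- s < 3L
      Wstate[alive, iw] <- s[alive]
      Wlonely[alive, iw] <- l[alive]
    }
    alive <- which(s < 3L)
    if (!length(alive)) break
    a <- age0[alive] + k * h
    Z <- cbind(lonely = l[alive], Zfix[alive, , drop = FALSE])
    P <- .step_probs6(model$coef, a, Z[, cv, drop = FALSE])
    u <- stats::runif(length(alive))
    from1 <- s[alive] == 1L
    ns <- integer(length(alive))
    ns[from1] <- 1L + (u[from1] > P$p11[from1]) +
      (u[from1] > P$p11[from1] + P$p12[from1])
    ns[!from1] <- ifelse(u[!from1] <= P$p21[!from1], 1L,
                         ifelse(u[!from1] <= P$p21[!from1] + P$p22[!from1],
                                2L, 3L))
    died <- ns == 3L
    death_age[alive[died]] <- a[died] + h
    s[alive] <- ns
    surv <- alive[!died]
    if (length(surv)) {
      flip <- stats::runif(length(surv))
      lon <- l[surv] == 1L
      l[surv] <- ifelse(lon,
                        ifelse(flip < model$lonely_remission_step, 0L, 1L),
                        ifelse(flip < model$lonely_onset_step, 1L, 0L))
    }
  }
  iw <- match(kmax, wave_k)
  if (!is.na(iw)) {
    alive <- s < 3L
    Wstate[alive, iw] <- s[alive]
    Wlonely[alive, iw] <- l[alive]
  }
  list(state = Wstate, lonely = Wlonely, death_age = death_age)
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws baseline attributes, simulates latent trajectories and panel
#' observation for `n` individuals, and returns the person-wave cohort
#' table in the dialect [build_histories()] reads, together with the
#' ground truth (true coefficients, config, per-individual latent summary
#' and the generator's own episode records). The latent simulation runs
#' vectorized across individuals on the step grid; wave offsets must be
#' whole numbers of steps.
#'
#' @param config a [sim_config()].
#' @return List of class `synthetic_cohort`: `cohort` (person-wave data
#'   frame), `truth` (list with `coef`, `h`, `config`, `seed`), `latent`
#'   (per-individual summary) and `episodes` (the generator's episode
#'   records, same layout as [build_histories()] output).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .save_seed(config$seed)
  on.exit(.restore_seed(old))
  model <- config$model
  n <- config$n
  h <- model$h
  offsets <- config$schedule$offsets
  wave_k <- round(offsets / h)
  if (max(abs(wave_k * h - offsets)) > 1e-9)
    stop("wave offsets must be whole numbers of model steps")

  age0 <- 65 + stats::rexp(n, config$baseline_age_rate)
  while (any(age0 > config$baseline_age_max)) {
    i <- age0 > config$baseline_age_max
    age0[i] <- 65 + stats::rexp(sum(i), config$baseline_age_rate)
  }
  age0 <- round(age0, 2)
  female <- stats::rbinom(n, 1L, config$p_female)
  rural <- stats::rbinom(n, 1L, config$p_rural)
  lonely0 <- stats::rbinom(n, 1L, config$p_lonely)
  state0 <- ifelse(stats::rbinom(n, 1L, config$p_healthy) == 1L, 1L, 2L)
  w <- ifelse(rural == 1L, config$rural_weight, config$urban_weight)
  w <- w / mean(w)

  Zfix <- cbind(female = female, rural = rural)
  attr(Zfix, "kmax") <- max(wave_k)
  attr(Zfix, "wave_k") <- wave_k
  lat_panel <- .simulate_panel(model, age0, state0, lonely0, Zfix)

  ## observation: dropout, death reporting and assembly, vectorized.
  ## Per individual, waves are attended in order; the first wave at or
  ## after the death age triggers a death report instead of an interview;
  ## a dropout draw at a follow-up wave makes that interview the last one,
  ## and deaths after dropout go unreported.
  nw <- length(offsets)
  drop_u <- matrix(stats::runif(n * (nw - 1L)), n, nw - 1L)
  mis_u <- if (config$misclassification > 0)
    matrix(stats::runif(n * nw), n, nw) else NULL
  da <- lat_panel$death_age
  rel_death <- ifelse(is.na(da), Inf, da - age0)
  ## offsets increasing, so the count of waves at/after death locates the
  ## first one; k_death = nw + 1 means no death before any scheduled wave
  k_death <- nw + 1L - rowSums(outer(rel_death, offsets, `<=`))
  hit <- sweep(drop_u, 2L, config$schedule$dropout[seq_len(nw - 1L)], `<`)
  fd <- max.col(cbind(hit * 1, 1), ties.method = "first")
  k_drop <- ifelse(fd <= nw - 1L, fd + 1L, nw)
  reported <- k_death <= k_drop
  K <- ifelse(reported, k_death - 1L, k_drop)
  death_obs <- ifelse(reported, da, NA_real_)

  Wstate <- lat_panel$state
  if (!is.null(mis_u)) {
    flip <- mis_u < config$misclassification & !is.na(Wstate)
    Wstate[flip] <- 3L - Wstate[flip]
  }
  ids <- sprintf("id%06d", seq_len(n))
  idx <- rep(seq_len(n), K)
  wv <- sequence(K)
  cell <- cbind(idx, wv)
  cohort <- data.frame(id = ids[idx], wave = wv,
                       interview_age = age0[idx] + offsets[wv],
                       health_state = Wstate[cell],
                       lonely = lat_panel$lonely[cell],
                       female = female[idx], rural = rural[idx],
                       weight = w[idx], death_age = death_obs[idx])
  lat <- data.frame(id = ids, baseline_age = age0, baseline_state = state0,
                    baseline_lonely = lonely0, true_death_age = da,
                    observed_death_age = death_obs,
                    censor_age = age0 + offsets[K], n_obs = K)
  ## generator's own episode records (independent of build_histories)
  i2 <- rep(seq_len(n), pmax(K - 1L, 0L))
  k2 <- sequence(pmax(K - 1L, 0L))
  st_eps <- data.frame(id = ids[i2], age_start = age0[i2] + offsets[k2],
                       state_start = Wstate[cbind(i2, k2)],
                       lonely = lat_panel$lonely[cbind(i2, k2)],
                       elapsed = offsets[k2 + 1L] - offsets[k2],
                       end_type = "state",
                       end_state = Wstate[cbind(i2, k2 + 1L)],
                       weight = w[i2])
  di <- which(reported)
  de_eps <- data.frame(id = ids[di], age_start = age0[di] + offsets[K[di]],
                       state_start = Wstate[cbind(di, K[di])],
                       lonely = lat_panel$lonely[cbind(di, K[di])],
                       elapsed = da[di] - (age0[di] + offsets[K[di]]),
                       end_type = "death", end_state = 3L,
                       weight = w[di])
  episodes <- rbind(st_eps, de_eps)
  episodes <- episodes[order(episodes$id, episodes$age_start), , drop = FALSE]
  rownames(episodes) <- NULL
  structure(list(cohort = cohort,
                 truth = list(coef = model$coef, h = model$h,
                              covariates = model$covariates,
                              cap = model$cap, seed = config$seed,
                              config = config),
                 latent = lat,
                 episodes = episodes),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to CSV plus ground-truth JSON
#'
#' @param x a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort_path <- file.path(dir, "cohort.csv")
  truth_path <- file.path(dir, "truth.json")
  utils::write.csv(x$cohort, cohort_path, row.names = FALSE)
  truth <- list(coef = as.data.frame(x$truth$coef), h = x$truth$h,
                covariates = x$truth$covariates, cap = x$truth$cap,
                seed = x$truth$seed)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(cohort = cohort_path, truth = truth_path))
}
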