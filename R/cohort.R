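#' Eligibility criteria for a longitudinal aging cohort
#'
#' @param min_age,max_age baseline age window in years (inclusive).
#' @param require_community_dwelling exclude individuals living in a care
#'   facility at baseline (uses the `in_facility` column when present).
#' @param min_followup_waves minimum number of follow-up contacts beyond
#'   baseline; a reported death counts as a follow-up contact.
#' @param require_valid_health_measures exclude individuals with missing
#'   health state or loneliness at baseline.
#' @return An object of class `eligibility_criteria`.
#' @export
eligibility_criteria <- function(min_age = 65, max_age = 99,
                                 require_community_dwelling = TRUE,
                                 min_followup_waves = 1L,
                                 require_valid_health_measures = TRUE) {
  stopifnot(min_age < max_age, min_followup_waves >= 0L)
  structure(list(min_age = min_age, max_age = max_age,
                 require_community_dwelling = require_community_dwelling,
                 min_followup_waves = min_followup_waves,
                 require_valid_health_measures = require_valid_health_measures),
            class = "eligibility_criteria")
}

.check_cohort_table <- function(cohort) {
  need <- c("id", "interview_age", "health_state", "lonely", "weight")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(cohort$weight < 0, na.rm = TRUE)) stop("negative weights")
  dup <- duplicated(cohort[, c("id", "interview_age")])
  if (any(dup))
    stop("duplicate (id, interview_age) rows for id(s): ",
         paste(unique(cohort$id[dup]), collapse = ", "))
  invisible(cohort)
}

#' Apply baseline eligibility filtering
#'
#' Filters a person-wave cohort table on the standard inclusion criteria
#' (community dwelling, baseline age window, at least one follow-up contact,
#' valid baseline health measures), applied in that order. The exclusion log
#' counts individuals removed by each criterion in application order, so the
#' counts sum to the number of individuals dropped.
#'
#' @param cohort data frame, one row per person-wave, with columns `id`,
#'   `interview_age`, `health_state`, `lonely`, `weight`; optional
#'   `death_age` (constant within id) and `in_facility` (baseline flag).
#' @param criteria an [eligibility_criteria()] object.
#' @return A list with `cohort` (filtered table) and `exclusions`
#'   (data frame `criterion`, `n_excluded`).
#' @export
apply_eligibility <- function(cohort, criteria = eligibility_criteria()) {
  if (!nrow(cohort)) stop("empty cohort table")
  .check_cohort_table(cohort)
  cohort <- cohort[order(cohort$id, cohort$interview_age), , drop = FALSE]
  first <- !duplicated(cohort$id)
  base <- cohort[first, , drop = FALSE]
  n_obs <- table(cohort$id)[as.character(base$id)]
  has_death <- if ("death_age" %in% names(base)) !is.na(base$death_age)
               else rep(FALSE, nrow(base))

  keep <- rep(TRUE, nrow(base))
  log <- list()
  drop_step <- function(bad, label) {
    newly <- keep & bad
    log[[length(log) + 1L]] <<- data.frame(criterion = label,
                                           n_excluded = sum(newly))
    keep <<- keep & !bad
  }
  if (criteria$require_community_dwelling && "in_facility" %in% names(base)) {
    drop_step(!is.na(base$in_facility) & base$in_facility == 1, "care_facility")
  } else {
    drop_step(rep(FALSE, nrow(base)), "care_facility")
  }
  drop_step(base$interview_age < criteria$min_age |
              base$interview_age > criteria$max_age, "baseline_age")
  drop_step((as.integer(n_obs) - 1L + as.integer(has_death)) <
              criteria$min_followup_waves, "no_followup")
  if (criteria$require_valid_health_measures) {
    drop_step(is.na(base$health_state) | is.na(base$lonely), "invalid_baseline_measures")
  } else {
    drop_step(rep(FALSE, nrow(base)), "invalid_baseline_measures")
  }

  ids_kept <- base$id[keep]
  out <- cohort[cohort$id %in% ids_kept, , drop = FALSE]
  if (!nrow(out)) warning("all individuals excluded by eligibility criteria")
  rownames(out) <- NULL
  list(cohort = out,
       exclusions = do.call(rbind, log))
}

#' Build per-individual transition episodes
#'
#' Assembles the episodes that enter the interval-censored likelihood: one
#' episode per consecutive pair of valid observations, plus a terminal
#' death episode from the last observation to the exact death age when a
#' death is recorded. Waves with a missing health state are dropped for
#' that individual, keeping adjacent waves. Loneliness (and any other
#' time-varying covariate) is carried forward from the observation opening
#' each episode (LOCF).
#'
#' @param cohort person-wave data frame as in [apply_eligibility()];
#'   optional `death_age` column gives the exact (fractional) age at death.
#' @param covariates names of additional baseline covariate columns to carry
#'   onto episodes.
#' @return Data frame of class `episode_table`: `id`, `age_start`,
#'   `state_start`, `lonely`, `elapsed`, `end_type` (`"state"` or
#'   `"death"`), `end_state` (1/2 for living, 3 for death), `weight`,
#'   plus requested covariate columns. Individuals contributing no episode
#'   (single observation, no death) are listed in the
#'   `attr(, "no_episode_ids")` attribute.
#' @export
build_histories <- function(cohort, covariates = character()) {
  .check_cohort_table(cohort)
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) stop("unknown covariate column(s): ", paste(miss, collapse = ", "))
  cohort <- cohort[order(cohort$id, cohort$interview_age), , drop = FALSE]
  has_death <- "death_age" %in% names(cohort)

  eps <- vector("list", length(unique(cohort$id)))
  no_ep <- character()
  k <- 0L
  for (rows in split(seq_len(nrow(cohort)), cohort$id)) {
    d <- cohort[rows, , drop = FALSE]
    death_age <- if (has_death) d$death_age[1L] else NA_real_
    obs <- d[!is.na(d$health_state) & !is.na(d$lonely), , drop = FALSE]
    if (!is.na(death_age)) {
      late <- obs$interview_age > death_age
      if (any(late))
        stop("observation after recorded death for id ", d$id[1L])
    }
    n <- nrow(obs)
    n_ep <- max(n - 1L, 0L) + as.integer(!is.na(death_age) && n > 0L)
    if (n_ep == 0L) { no_ep <- c(no_ep, as.character(d$id[1L])); next }
    a0 <- s0 <- l0 <- el <- es <- numeric(n_ep)
    et <- character(n_ep)
    j <- 0L
    if (n > 1L) for (i in seq_len(n - 1L)) {
      j <- j + 1L
      a0[j] <- obs$interview_age[i]; s0[j] <- obs$health_state[i]
      l0[j] <- obs$lonely[i]
      el[j] <- obs$interview_age[i + 1L] - obs$interview_age[i]
      et[j] <- "state"; es[j] <- obs$health_state[i + 1L]
    }
    if (!is.na(death_age)) {
      j <- j + 1L
      a0[j] <- obs$interview_age[n]; s0[j] <- obs$health_state[n]
      l0[j] <- obs$lonely[n]
      el[j] <- death_age - obs$interview_age[n]
      et[j] <- "death"; es[j] <- 3
      if (el[j] <= 0) stop("death age not after last observation for id ", d$id[1L])
    }
    out <- data.frame(id = rep(d$id[1L], n_ep), age_start = a0,
                      state_start = as.integer(s0), lonely = as.integer(l0),
                      elapsed = el, end_type = et, end_state = as.integer(es),
                      weight = rep(d$weight[1L], n_ep))
    for (cv in covariates) out[[cv]] <- rep(d[[cv]][1L], n_ep)
    k <- k + 1L
    eps[[k]] <- out
  }
  res <- if (k) do.call(rbind, eps[seq_len(k)]) else
    data.frame(id = character(), age_start = numeric(), state_start = integer(),
               lonely = integer(), elapsed = numeric(), end_type = character(),
               end_state = integer(), weight = numeric())
  rownames(res) <- NULL
  attr(res, "no_episode_ids") <- no_ep
  class(res) <- c("episode_table", "data.frame")
  res
}

#' Normalize sampling weights to mean one
#'
#' Pseudo-likelihood fits use weights scaled to mean 1 so the information
#' matrix keeps its sample-size interpretation.
#'
#' @param w non-negative weights.
#' @return Rescaled weights with mean 1.
#' @export
normalize_weights <- function(w) {
  if (any(w < 0, na.rm = TRUE)) stop("negative weights")
  m <- mean(w, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) stop("weights must have positive mean")
  w / m
}
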