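#' Default generating population
#'
#' The population used by the synthetic cohort generator unless overridden:
#' the package's engineering-default typical values (elimination rates
#' 0.05/0.1/0.2 per day for coaching/therapy/psychiatry, `s50 = 1`,
#' `r = 0.05`/day), a moderate log-scale between-subject SD of 0.3 on all
#' five parameters, and a residual SD of 0.1 severity units. These are
#' explicitly the package's own choices, not values reported for any real
#' cohort.
#'
#' @return A [population_params()] object.
#' @export
default_population <- function() {
  population_params(structural_params(0.05, 0.1, 0.2, s50 = 1, r = 0.05),
                    omega = 0.3, sigma = 0.1)
}

#' The five synthetic profile archetypes
#'
#' @return Character vector: sustained `response`, `saturated` (sustained
#'   cadence, partial resolution), `rebound` (care stops and symptoms
#'   return), `multiphasic` (a lapse followed by re-engagement), and
#'   `poor_fit` (symptom dynamics decoupled from the schedule).
#' @export
archetypes <- function() {
  c("response", "saturated", "rebound", "multiphasic", "poor_fit")
}

#' Synthetic cohort configuration
#'
#' Describes the study conditions the generator emulates: every patient
#' enters severe (severity 1 at day 0); symptom reports are requested every
#' 30 or 60 days (jittered, and completed with a fixed probability so
#' realised report counts are sparse); follow-up varies widely; per-service
#' session cadences are set so cohort mean session counts bracket roughly
#' 1.7 coaching, 16 therapy and 3.5 psychiatry sessions per patient over a
#' 450-day reference follow-up; and a shared per-patient engagement factor
#' scales all cadences, inducing positive correlation between service types.
#'
#' @param n_patients Number of patients.
#' @param seed Root seed; all draws come from per-patient sub-streams.
#' @param report_interval Candidate report intervals in days.
#' @param report_mix Mixture probabilities over `report_interval`.
#' @param report_jitter SD (days) of report-time jitter.
#' @param report_completion Probability a requested report is completed.
#' @param followup_range Min/max follow-up (days), drawn uniformly.
#' @param cadence_targets Named expected session counts per service over
#'   `cadence_ref_days` of follow-up.
#' @param cadence_ref_days Reference follow-up for the targets.
#' @param engagement_sd Log-scale SD of the shared engagement factor.
#' @param archetype_mix Named proportions over [archetypes()] (must sum
#'   to 1).
#' @param population Generating [population_params()].
#' @param snap Snap observed severities to the 0.125 two-item grid
#'   (default `TRUE`).
#' @param poor_fit_walk_sd Per-report SD of the random-walk disturbance
#'   added to the latent severity of `poor_fit` patients.
#' @param max_resample Resampling attempts per patient to satisfy the
#'   inclusion rule before failing.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, seed = 1L,
                          report_interval = c(30, 60),
                          report_mix = c(0.5, 0.5),
                          report_jitter = 3, report_completion = 0.6,
                          followup_range = c(180, 720),
                          cadence_targets = c(coaching = 1.7, therapy = 16,
                                              psychiatry = 3.5),
                          cadence_ref_days = 450, engagement_sd = 0.4,
                          archetype_mix = c(response = 0.35,
                                            saturated = 0.25,
                                            rebound = 0.15,
                                            multiphasic = 0.15,
                                            poor_fit = 0.10),
                          population = default_population(), snap = TRUE,
                          poor_fit_walk_sd = 0.2, max_resample = 50L) {
  if (n_patients < 1L) stop_input("`n_patients` must be >= 1")
  if (abs(sum(archetype_mix) - 1) > 1e-8)
    stop_input("`archetype_mix` proportions must sum to 1")
  if (!setequal(names(archetype_mix), archetypes()))
    stop_input("`archetype_mix` must be named over the five archetypes")
  if (!setequal(names(cadence_targets), service_types()))
    stop_input("`cadence_targets` must be named over the service types")
  stopifnot(inherits(population, "population_params"),
            length(followup_range) == 2L,
            followup_range[1] <= followup_range[2],
            length(report_interval) == length(report_mix))
  structure(list(n_patients = as.integer(n_patients),
                 seed = as.integer(seed),
                 report_interval = report_interval, report_mix = report_mix,
                 report_jitter = report_jitter,
                 report_completion = report_completion,
                 followup_range = followup_range,
                 cadence_targets = cadence_targets[service_types()],
                 cadence_ref_days = cadence_ref_days,
                 engagement_sd = engagement_sd,
                 archetype_mix = archetype_mix[archetypes()],
                 population = population, snap = snap,
                 poor_fit_walk_sd = poor_fit_walk_sd,
                 max_resample = as.integer(max_resample)),
            class = "cohort_config")
}

#' Draw individual parameters from the population
#'
#' Log-scale deviations are drawn from centred normals with SDs `omega`;
#' realised parameters are `typical * exp(eta)`.
#'
#' @param pop A [population_params()].
#' @param n Number of individuals.
#' @param seed Integer seed (draws are reproducible bit-for-bit).
#' @return A list of [individual_params()].
#' @export
sample_individual_parameters <- function(pop, n, seed = 1L) {
  stopifnot(inherits(pop, "population_params"))
  set.seed(seed)
  lapply(seq_len(n), function(i)
    individual_params(rnorm(5, 0, pop$omega), pop))
}

archetype_windows <- function(archetype, followup) {
  switch(archetype,
    response = ,
    saturated = ,
    poor_fit = list(c(0, followup)),
    rebound = {
      gap <- max(90, 0.25 * followup)
      if (followup - gap < 30)
        stop_input("follow-up of ", followup, " days is too short for the ",
                   "rebound archetype (needs a >= 90 day terminal gap)")
      list(c(0, followup - gap))
    },
    multiphasic = {
      if (followup < 180)
        stop_input("follow-up of ", followup, " days is too short for the ",
                   "multiphasic archetype (needs >= 180 days)")
      a <- 0.4 * followup
      gap <- max(60, 0.15 * followup)
      list(c(0, a), c(a + gap, followup))
    },
    stop_input("unknown archetype: ", archetype))
}

#' Generate a session schedule for one synthetic patient
#'
#' Sessions arrive as independent Poisson streams per service within the
#' archetype's active windows: sustained cadence for `response` and
#' `saturated`; cadence then a terminal gap of at least 90 days with no
#' re-engagement for `rebound`; cadence, a gap of at least 60 days, then a
#' re-engagement block (guaranteed non-empty) for `multiphasic`; and sparse
#' irregular sessions at half cadence for `poor_fit` (whose misfit is
#' induced downstream in the observation generator).
#'
#' @param archetype One of [archetypes()].
#' @param cadence_targets Named expected counts per service over
#'   `cadence_ref_days`.
#' @param followup Follow-up length in days.
#' @param engagement Per-patient factor scaling all cadence rates.
#' @param cadence_ref_days Reference follow-up for the targets.
#' @param seed Optional seed.
#' @return Session events as from [session_events()].
#' @export
generate_schedule <- function(archetype, cadence_targets, followup,
                              engagement = 1, cadence_ref_days = 450,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  windows <- archetype_windows(archetype, followup)
  rate_scale <- engagement * if (archetype == "poor_fit") 0.5 else 1
  times <- c()
  svcs <- c()
  for (svc in service_types()) {
    rate <- rate_scale * cadence_targets[[svc]] / cadence_ref_days
    for (w in windows) {
      len <- w[2] - w[1]
      nn <- rpois(1, rate * len)
      if (nn > 0) {
        times <- c(times, runif(nn, w[1], w[2]))
        svcs <- c(svcs, rep(svc, nn))
      }
    }
  }
  if (archetype == "multiphasic") {
    w2 <- windows[[2]]
    if (!any(times >= w2[1])) {
      times <- c(times, w2[1])
      svcs <- c(svcs, "therapy")
    }
  }
  session_events(times, svcs)
}

#' Generate severity observations for one synthetic patient
#'
#' The entry report at day 0 is exactly severe (severity 1). Subsequent
#' report times step forward by a drawn interval (30 or 60 days by default)
#' plus Gaussian jitter, and each is completed with probability
#' `report_completion`. Observed severity is the model trajectory under the
#' patient's true parameters plus additive Gaussian noise, optionally
#' snapped to the nearest multiple of 0.125 (emulating the two-item score
#' construction) and clamped to \[0, 1\]. For the `poor_fit` archetype an
#' independent random-walk disturbance is added to the latent severity
#' before noise, so the schedule no longer explains the symptoms.
#'
#' @param indiv An [individual_params()] (the patient's true parameters).
#' @param events The patient's session events.
#' @param config A [cohort_config()].
#' @param followup Follow-up length (days).
#' @param archetype One of [archetypes()].
#' @param seed Optional seed.
#' @return Severity observations as from [severity_observations()].
#' @export
generate_observations <- function(indiv, events, config, followup,
                                  archetype = "response", seed = NULL) {
  stopifnot(inherits(indiv, "individual_params"),
            inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  t <- 0
  times <- numeric()
  repeat {
    step <- sample(length(config$report_interval), 1L,
                   prob = config$report_mix)
    t <- t + max(1, config$report_interval[step] +
                   rnorm(1, 0, config$report_jitter))
    if (t > followup) break
    if (runif(1) < config$report_completion) times <- c(times, t)
  }
  sigma <- config$population$sigma
  if (length(times)) {
    dep <- simulate_trajectory(events, indiv$realized, times)$severity
    if (archetype == "poor_fit")
      dep <- pmin(1, pmax(0, dep + cumsum(rnorm(length(dep), 0,
                                                config$poor_fit_walk_sd))))
    sev <- dep + rnorm(length(dep), 0, sigma)
    if (config$snap) sev <- round(sev / 0.125) * 0.125
    sev <- pmin(1, pmax(0, sev))
  } else {
    sev <- numeric()
  }
  severity_observations(c(0, times), c(1, sev))
}

#' Generate a full synthetic cohort with its ground-truth ledger
#'
#' Draws each patient's archetype, follow-up, engagement factor, true
#' parameters, schedule and observations from deterministic per-patient
#' sub-streams of the root seed, resampling any patient whose draw fails the
#' inclusion rule (at least two reports with a session in between) up to
#' `max_resample` times.
#'
#' @param config A [cohort_config()].
#' @return A list of class `sd_cohort`: `records` (list of
#'   [patient_record()]s, all inclusion-eligible), `truth` (a `data.frame`
#'   ledger of each patient's archetype, follow-up, engagement and true
#'   parameters), `config`, and `n_resampled` (total discarded draws).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  pop <- config$population
  set.seed(seed_stream(config$seed, "archetypes"))
  arch <- sample(archetypes(), n, replace = TRUE,
                 prob = config$archetype_mix)
  ids <- sprintf("P%04d", seq_len(n))
  records <- vector("list", n)
  truth <- vector("list", n)
  n_resampled <- 0L
  for (i in seq_len(n)) {
    id <- ids[i]
    set.seed(seed_stream(config$seed, id, "patient"))
    followup <- runif(1, config$followup_range[1], config$followup_range[2])
    engagement <- exp(rnorm(1, 0, config$engagement_sd))
    eta <- rnorm(5, 0, pop$omega)
    indiv <- individual_params(eta, pop)
    rec <- NULL
    for (try in seq_len(config$max_resample)) {
      set.seed(seed_stream(config$seed, id, "draw", try))
      events <- generate_schedule(arch[i], config$cadence_targets, followup,
                                  engagement, config$cadence_ref_days)
      obs <- generate_observations(indiv, events, config, followup, arch[i])
      cand <- patient_record(id, events, obs)
      if (is_eligible(cand)) {
        rec <- cand
        n_resampled <- n_resampled + (try - 1L)
        break
      }
    }
    if (is.null(rec))
      stop_input("could not draw an inclusion-eligible record for ", id,
                 " in ", config$max_resample, " attempts; the configured ",
                 "session/report rates may make inclusion unreachable")
    records[[i]] <- rec
    truth[[i]] <- data.frame(id = id, archetype = arch[i],
                             followup = followup, engagement = engagement,
                             t(setNames(eta, paste0("eta_",
                                                    sd_param_names()))),
                             t(as_param_vector(indiv$realized)),
                             stringsAsFactors = FALSE)
  }
  structure(list(records = records, truth = do.call(rbind, truth),
                 config = config, n_resampled = n_resampled),
            class = "sd_cohort")
}

#' @export
print.sd_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients (%d draw(s) resampled)\n",
              length(x$records), x$n_resampled))
  print(table(x$truth$archetype))
  invisible(x)
}
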