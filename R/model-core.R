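#' Available mental healthcare service types
#'
#' The three session types offered by the modelled healthcare system, in the
#' clinical triaging order: coaching (unlicensed professional), therapy
#' (licensed therapist or counselor), and psychiatry (treatment and
#' medication management). Every session event carries exactly one of these.
#'
#' @return Character vector of the three service type names.
#' @export
service_types <- function() c("coaching", "therapy", "psychiatry")

#' Names of the five structural model parameters
#'
#' @return Character vector: the three per-service elimination rate constants,
#'   the response sensitivity `s50`, and the relative symptom turnover rate
#'   `r`.
#' @export
sd_param_names <- function() {
  c("k_out_coaching", "k_out_therapy", "k_out_psychiatry", "s50", "r")
}

#' Structural parameters of the session-dosing model
#'
#' Bundles the five per-individual constants of the indirect-response model:
#' one first-order elimination rate constant (1/day) per latent service
#' compartment, the response sensitivity `s50` (the latent treatment mass
#' producing half-maximal inhibition, in the same arbitrary unit-bolus mass
#' units), and the relative symptom turnover rate `r` (1/day). `r` serves as
#' both the zero-order production and first-order elimination rate of the
#' symptom compartment, which caps severity at the severe level (1).
#'
#' @param k_out_coaching,k_out_therapy,k_out_psychiatry Elimination rate
#'   constants of the latent service compartments (1/day), strictly positive.
#' @param s50 Response sensitivity (latent mass units), strictly positive.
#' @param r Symptom generation/elimination rate (1/day), strictly positive.
#' @return An object of class `structural_params`.
#' @examples
#' structural_params(0.05, 0.1, 0.2, s50 = 1, r = 0.05)
#' @export
structural_params <- function(k_out_coaching, k_out_therapy, k_out_psychiatry,
                              s50, r) {
  p <- c(k_out_coaching = k_out_coaching, k_out_therapy = k_out_therapy,
         k_out_psychiatry = k_out_psychiatry, s50 = s50, r = r)
  if (length(p) != 5L || anyNA(p) || !is.numeric(p))
    stop_input("all five structural parameters must be single numeric values")
  if (any(p <= 0))
    stop_input("structural parameters must be strictly positive; got ",
               paste(names(p)[p <= 0], collapse = ", "), " <= 0")
  structure(as.list(p), class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat("Structural session-dosing parameters:\n")
  print(unlist(x))
  invisible(x)
}

as_param_vector <- function(params) {
  stopifnot(inherits(params, "structural_params"))
  unlist(params)[sd_param_names()]
}

kout_for <- function(params, service) {
  k <- c(coaching = params$k_out_coaching, therapy = params$k_out_therapy,
         psychiatry = params$k_out_psychiatry)
  unname(k[service])
}

#' Construct a table of session events
#'
#' @param time Numeric vector of session times in days since the patient's
#'   baseline (non-negative). Multiple sessions may share a time; co-timed
#'   sessions stack additively as two unit boluses.
#' @param service Character vector of service types (one of
#'   [service_types()] per event), recycled if length 1.
#' @return A `data.frame` with columns `time` and `service`, sorted by time.
#' @examples
#' session_events(c(0, 7, 14), "therapy")
#' @export
session_events <- function(time = numeric(), service = character()) {
  if (length(time) == 0L)
    return(data.frame(time = numeric(), service = character(),
                      stringsAsFactors = FALSE))
  if (length(service) == 1L) service <- rep(service, length(time))
  if (length(service) != length(time))
    stop_input("`time` and `service` must have equal length")
  if (!is.numeric(time) || anyNA(time) || any(time < 0))
    stop_input("session times must be non-negative days since baseline")
  bad <- !service %in% service_types()
  if (any(bad))
    stop_input("unknown service type(s): ",
               paste(unique(service[bad]), collapse = ", "))
  o <- order(time)
  data.frame(time = as.numeric(time[o]), service = service[o],
             stringsAsFactors = FALSE)
}

#' Construct a table of severity observations
#'
#' @param time Numeric vector of report times in days since baseline.
#' @param severity Numeric vector of severities in \[0, 1\] (the two-item
#'   DSM-L1 depression average normalised by 4).
#' @return A `data.frame` with columns `time` and `severity`, sorted by time.
#' @export
severity_observations <- function(time = numeric(), severity = numeric()) {
  if (length(time) != length(severity))
    stop_input("`time` and `severity` must have equal length")
  if (length(time) == 0L)
    return(data.frame(time = numeric(), severity = numeric()))
  if (!is.numeric(time) || anyNA(time) || any(time < 0))
    stop_input("observation times must be non-negative days since baseline")
  if (!is.numeric(severity) || anyNA(severity) ||
      any(severity < 0 | severity > 1))
    stop_input("severity values must lie in [0, 1]")
  o <- order(time)
  data.frame(time = as.numeric(time[o]), severity = as.numeric(severity[o]))
}

#' A single patient's longitudinal record
#'
#' @param id Patient identifier (coerced to character).
#' @param events Session events as returned by [session_events()].
#' @param observations Severity observations as returned by
#'   [severity_observations()].
#' @return An object of class `patient_record`.
#' @seealso [is_eligible()] for the modelling inclusion rule.
#' @export
patient_record <- function(id, events, observations) {
  if (length(id) != 1L || is.na(id))
    stop_input("`id` must be a single non-missing identifier")
  events <- session_events(events$time, events$service)
  observations <- severity_observations(observations$time,
                                        observations$severity)
  structure(list(id = as.character(id), events = events,
                 observations = observations),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("Patient %s: %d session(s), %d observation(s), %s\n", x$id,
              nrow(x$events), nrow(x$observations),
              if (is_eligible(x)) "inclusion-eligible" else "NOT eligible"))
  invisible(x)
}

#' Modelling inclusion rule
#'
#' A record is eligible for the modelling analysis when it has at least two
#' severity reports with at least one treatment session (of any kind)
#' strictly between the times of some pair of reports.
#'
#' @param record A [patient_record()].
#' @return `TRUE` or `FALSE`.
#' @export
is_eligible <- function(record) {
  stopifnot(inherits(record, "patient_record"))
  obs <- record$observations
  ev <- record$events
  if (nrow(obs) < 2L || nrow(ev) < 1L) return(FALSE)
  any(ev$time > min(obs$time) & ev$time < max(obs$time))
}

#' Severity score from the two DSM-L1 depression items
#'
#' Averages the anhedonia and depressed-mood items (each scored 0--4) and
#' normalises by the maximum item score (4), yielding a severity fraction in
#' \[0, 1\] on a 0.125 grid.
#'
#' @param anhedonia,depressed_mood Integer item scores in `0:4`. Vectorised.
#' @return Numeric severity fraction(s) in \[0, 1\].
#' @examples
#' severity_from_items(4, 4)  # severe entry criterion -> 1
#' severity_from_items(2, 3)  # 0.625
#' @export
severity_from_items <- function(anhedonia, depressed_mood) {
  check_item <- function(x, name) {
    if (!is.numeric(x) || anyNA(x) || any(x != as.integer(x)) ||
        any(x < 0 | x > 4))
      stop_input("`", name, "` must be an integer item score between 0 and 4")
  }
  check_item(anhedonia, "anhedonia")
  check_item(depressed_mood, "depressed_mood")
  (anhedonia + depressed_mood) / 2 / 4
}

#' Combined latent treatment mass
#'
#' Each session deposits a unit bolus into its service compartment, which
#' decays with that service's first-order rate constant; the combined mass
#' `TRT(t)` is the superposition over all sessions at or before `t`.
#'
#' @param events Session events ([session_events()]).
#' @param params [structural_params()].
#' @param t Numeric vector of times (days, non-negative).
#' @return Numeric vector of non-negative masses, one per element of `t`.
#' @export
treatment_mass <- function(events, params, t) {
  stopifnot(inherits(params, "structural_params"))
  if (!is.numeric(t) || anyNA(t) || any(t < 0))
    stop_input("`t` must be non-negative (days since baseline)")
  if (nrow(events) == 0L) return(rep(0, length(t)))
  k <- kout_for(params, events$service)
  vapply(t, function(tt) {
    keep <- events$time <= tt
    sum(exp(-k[keep] * (tt - events$time[keep])))
  }, numeric(1))
}

#' Hill-type inhibition of symptom production
#'
#' Fractional inhibition `trt / (trt + s50)`, a capacity-limited function
#' with the maximum effect fixed to 1 (and therefore omitted): inhibition is
#' strictly increasing in the treatment mass and bounded below 1, so symptom
#' production can at most be turned off, never reversed.
#'
#' @param trt Non-negative treatment mass (vectorised).
#' @param s50 Response sensitivity, strictly positive.
#' @return Inhibition fraction(s) in \[0, 1).
#' @export
inhibition <- function(trt, s50) {
  if (!is.numeric(s50) || length(s50) != 1L || is.na(s50) || s50 <= 0)
    stop_input("`s50` must be a single strictly positive number")
  if (!is.numeric(trt) || anyNA(trt) || any(trt < 0))
    stop_input("`trt` must be non-negative")
  trt / (trt + s50)
}

#' Simulate a severity trajectory
#'
#' Solves the indirect-response equation
#' `dDep/dt = r * (1 - TRT(t) / (TRT(t) + s50)) - r * Dep` with
#' `Dep(0) = dep0` by adaptive Runge--Kutta (Cash--Karp 4(5)), restarting the
#' integration at every session time because the latent mass has a derivative
#' discontinuity at each bolus. With no treatment the equation balances at
#' severity 1 (the severe entry level); treatment inhibits production and
#' pulls severity down toward `s50 / (TRT + s50)`.
#'
#' @param events Session events ([session_events()]).
#' @param params [structural_params()].
#' @param grid Sorted non-negative times (days) at which to report severity.
#' @param dep0 Initial severity in (0, 1\]; defaults to 1 (cohorts screened in
#'   at the severe level).
#' @param const_inhibition Test hook: force the inhibition term to this
#'   constant in \[0, 1\], bypassing the treatment mass.
#' @param const_mass Test hook: hold the latent mass constant at this value.
#' @param rtol,atol Relative/absolute solver tolerances.
#' @return A `data.frame` with columns `time` and `severity`.
#' @examples
#' p <- structural_params(0.05, 0.1, 0.2, s50 = 0.5, r = 0.1)
#' ev <- session_events(0, "therapy")
#' simulate_trajectory(ev, p, grid = c(0, 7, 14))
#' @export
simulate_trajectory <- function(events, params, grid, dep0 = 1,
                                const_inhibition = NULL, const_mass = NULL,
                                rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(params, "structural_params"))
  if (!is.numeric(grid) || anyNA(grid) || any(grid < 0))
    stop_input("`grid` times must be non-negative")
  if (is.unsorted(grid))
    stop_input("`grid` must be sorted in non-decreasing order")
  if (!is.numeric(dep0) || length(dep0) != 1L || is.na(dep0) ||
      dep0 <= 0 || dep0 > 1)
    stop_input("`dep0` must lie in (0, 1]")
  hook <- 0L
  hookval <- 0
  if (!is.null(const_inhibition)) {
    if (const_inhibition < 0 || const_inhibition > 1)
      stop_input("`const_inhibition` must lie in [0, 1]")
    hook <- 1L
    hookval <- const_inhibition
  } else if (!is.null(const_mass)) {
    if (const_mass < 0) stop_input("`const_mass` must be non-negative")
    hook <- 2L
    hookval <- const_mass
  }
  events <- session_events(events$time, events$service)
  sev <- dep_solve_cpp(as.numeric(grid), events$time,
                       match(events$service, service_types()) - 1L,
                       c(params$k_out_coaching, params$k_out_therapy,
                         params$k_out_psychiatry),
                       params$s50, params$r, dep0, hook, hookval, rtol, atol)
  data.frame(time = as.numeric(grid), severity = sev)
}
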