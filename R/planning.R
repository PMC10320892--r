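#' A single recurring item of a treatment schedule
#'
#' @param service One of [service_types()].
#' @param interval Days between sessions (positive); `q7d` means
#'   `interval = 7`.
#' @param start First session day (planning clock).
#' @param end End of the item's window; sessions are planned at `start`,
#'   `start + interval`, ... strictly before `end` (endpoint-exclusive).
#' @return A list of class `schedule_item`.
#' @export
schedule_item <- function(service, interval, start = 0, end) {
  if (!service %in% service_types())
    stop_input("unknown service type: ", service)
  if (!is.numeric(interval) || interval <= 0)
    stop_input("`interval` must be a positive number of days")
  if (!is.numeric(start) || start < 0 || !is.numeric(end) || start >= end)
    stop_input("need 0 <= start < end")
  structure(list(service = service, interval = as.numeric(interval),
                 start = as.numeric(start), end = as.numeric(end)),
            class = "schedule_item")
}

#' A declarative future treatment schedule
#'
#' @param items List of [schedule_item()]s (may be empty: no planned care).
#' @param horizon Total simulated days; every item must end at or before it.
#' @return A list of class `treatment_schedule`.
#' @examples
#' treatment_schedule(list(schedule_item("therapy", 14, 0, 180)),
#'                    horizon = 360)
#' @export
treatment_schedule <- function(items = list(), horizon) {
  if (inherits(items, "schedule_item")) items <- list(items)
  ok <- vapply(items, function(x) inherits(x, "schedule_item"), logical(1))
  if (length(items) && !all(ok))
    stop_input("`items` must be a list of schedule_item objects")
  if (!is.numeric(horizon) || horizon <= 0)
    stop_input("`horizon` must be a positive number of days")
  for (it in items)
    if (it$end > horizon)
      stop_input("schedule item ends after the horizon (", it$end, " > ",
                 horizon, ")")
  structure(list(items = items, horizon = as.numeric(horizon)),
            class = "treatment_schedule")
}

#' Parse the schedule mini-language
#'
#' Comma-separated items of the form `"<service>:q<N>d[:<start>-<end>]"`,
#' e.g. `"therapy:q14d:0-180, coaching:q30d"` — a therapy session every 14
#' days over days 0--180 plus a coaching session every 30 days over the whole
#' horizon.
#'
#' @param text Schedule string.
#' @param horizon Total simulated days (also the default item window end).
#' @return A [treatment_schedule()].
#' @export
parse_schedule <- function(text, horizon) {
  text <- trimws(text)
  if (!nzchar(text)) return(treatment_schedule(list(), horizon))
  parts <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  items <- lapply(parts, function(p) {
    f <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(f) < 2L || length(f) > 3L)
      stop_input("cannot parse schedule item '", p,
                 "'; expected <service>:q<N>d[:<start>-<end>]")
    m <- regmatches(f[2], regexec("^q([0-9.]+)d$", f[2]))[[1]]
    if (length(m) != 2L)
      stop_input("cannot parse frequency '", f[2], "' in '", p,
                 "'; expected q<N>d")
    interval <- as.numeric(m[2])
    start <- 0
    end <- horizon
    if (length(f) == 3L) {
      w <- regmatches(f[3], regexec("^([0-9.]+)-([0-9.]+)$", f[3]))[[1]]
      if (length(w) != 3L)
        stop_input("cannot parse window '", f[3], "' in '", p,
                   "'; expected <start>-<end>")
      start <- as.numeric(w[2])
      end <- as.numeric(w[3])
    }
    schedule_item(f[1], interval, start, end)
  })
  treatment_schedule(items, horizon)
}

#' Expand a schedule into session events
#'
#' Each item contributes sessions at `start`, `start + interval`, ...
#' strictly before `end`; items are merged and sorted.
#'
#' @param schedule A [treatment_schedule()].
#' @return Session events as from [session_events()].
#' @examples
#' expand_schedule(treatment_schedule(
#'   list(schedule_item("therapy", 7, 0, 28)), horizon = 28))
#' @export
expand_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  if (!length(schedule$items))
    return(session_events())
  parts <- lapply(schedule$items, function(it) {
    n_last <- ceiling((it$end - it$start) / it$interval) - 1
    times <- it$start + it$interval * seq(0, max(0, n_last))
    times <- times[times < it$end]
    data.frame(time = times, service = rep(it$service, length(times)),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, parts)
  session_events(all$time, all$service)
}

#' Simulate a candidate treatment plan for one individual
#'
#' Expands the schedule, simulates the severity trajectory from the severe
#' entry level over the horizon with the individual's structural parameters,
#' and summarises it against a response threshold. The default threshold
#' 0.625 is the midpoint between mild and moderate two-item averages (the
#' top of the sub-moderate band); it is user-overridable.
#'
#' @param indiv [structural_params()] for the individual (their
#'   empirical-Bayes estimates, or the typical values for unclassifiable
#'   patients).
#' @param schedule A [treatment_schedule()].
#' @param threshold Response threshold in (0, 1).
#' @param grid_step Simulation grid step in days (default 0.25 for
#'   crossing-time resolution).
#' @param dep0 Initial severity.
#' @return A list of class `plan_result`: `trajectory` (`time`, `severity`),
#'   `events`, and `metrics` (`min_severity`, `time_below_threshold` in days,
#'   `first_below` — first sub-threshold time or `NA`, `relapse_time` — first
#'   grid time at or after the final session where severity is at or above
#'   the threshold, or `NA` if it never recrosses, and `final_severity`).
#' @export
simulate_plan <- function(indiv, schedule, threshold = 0.625,
                          grid_step = 0.25, dep0 = 1) {
  stopifnot(inherits(indiv, "structural_params"),
            inherits(schedule, "treatment_schedule"))
  if (threshold <= 0 || threshold >= 1)
    stop_input("`threshold` must lie strictly between 0 and 1")
  if (grid_step <= 0) stop_input("`grid_step` must be positive")
  events <- expand_schedule(schedule)
  grid <- seq(0, schedule$horizon, by = grid_step)
  if (grid[length(grid)] < schedule$horizon)
    grid <- c(grid, schedule$horizon)
  traj <- simulate_trajectory(events, indiv, grid, dep0 = dep0)
  sev <- traj$severity
  below <- sev < threshold
  # time spent below threshold: each grid interval credited by its right end
  time_below <- sum(diff(grid)[below[-1]])
  first_below <- if (any(below)) grid[which(below)[1]] else NA_real_
  t_last <- if (nrow(events)) max(events$time) else 0
  after <- grid >= t_last
  recross <- after & !below
  relapse <- if (any(recross)) grid[which(recross)[1]] else NA_real_
  structure(list(trajectory = traj, events = events,
                 metrics = list(min_severity = min(sev),
                                time_below_threshold = time_below,
                                first_below = first_below,
                                relapse_time = relapse,
                                final_severity = sev[length(sev)],
                                n_sessions = nrow(events),
                                threshold = threshold)),
            class = "plan_result")
}

#' Compare candidate treatment plans for one individual
#'
#' Simulates each named schedule and ranks them: plans that never relapse
#' rank best, then later relapse beats earlier, then more time below the
#' threshold; ties are broken in favour of fewer total sessions.
#'
#' @param indiv [structural_params()] for the individual.
#' @param schedules Named list of [treatment_schedule()]s.
#' @param threshold,grid_step,dep0 Passed to [simulate_plan()].
#' @return A `data.frame` ranked best-first, one row per plan, with the plan
#'   metrics and a `rank` column.
#' @export
compare_plans <- function(indiv, schedules, threshold = 0.625,
                          grid_step = 0.25, dep0 = 1) {
  if (inherits(schedules, "treatment_schedule"))
    schedules <- list(plan = schedules)
  if (!length(schedules)) stop_input("need at least one schedule")
  if (is.null(names(schedules)) || any(!nzchar(names(schedules))))
    names(schedules) <- paste0("plan", seq_along(schedules))
  rows <- lapply(names(schedules), function(nm) {
    m <- simulate_plan(indiv, schedules[[nm]], threshold, grid_step,
                       dep0)$metrics
    data.frame(plan = nm, n_sessions = m$n_sessions,
               min_severity = m$min_severity,
               time_below_threshold = m$time_below_threshold,
               first_below = m$first_below, relapse_time = m$relapse_time,
               final_severity = m$final_severity, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  relapse_key <- ifelse(is.na(out$relapse_time), Inf, out$relapse_time)
  o <- order(-relapse_key, -out$time_below_threshold, out$n_sessions)
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
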