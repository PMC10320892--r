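DATASET_HEADER <- c("ID", "TIME", "EVID", "TYPE", "DV")

write_csv12 <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df)) {
    cells <- vapply(df, function(col) {
      if (is.numeric(col)) num12(col) else as.character(col)
    }, character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    cells[is.na(cells)] <- ""
    writeLines(apply(cells, 1L, paste, collapse = ","), con)
  }
  invisible(path)
}

#' Write patient records as an event-record dataset
#'
#' One CSV row per session event or severity observation, in the
#' pharmacometric event-record convention: columns `ID`, `TIME` (days),
#' `EVID` (1 for session events, 0 for observations), `TYPE` (the service
#' type for events; the literal `dsm_l1` for observations) and `DV` (the
#' severity fraction for observations, empty for events). Within a patient,
#' rows are sorted by time with events before observations at equal times —
#' except at time 0, where the baseline observation anchors the record and
#' precedes any same-day session. Numbers are serialised at 12 significant
#' digits so identical inputs produce byte-identical files.
#'
#' @param records A list of [patient_record()]s or an `sd_cohort`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(records, path) {
  if (inherits(records, "sd_cohort")) records <- records$records
  if (inherits(records, "patient_record")) records <- list(records)
  rows <- lapply(records, function(rec) {
    ev <- rec$events
    obs <- rec$observations
    df <- rbind(
      if (nrow(ev)) data.frame(ID = rec$id, TIME = ev$time, EVID = 1L,
                               TYPE = ev$service, DV = NA_real_,
                               stringsAsFactors = FALSE),
      if (nrow(obs)) data.frame(ID = rec$id, TIME = obs$time, EVID = 0L,
                                TYPE = "dsm_l1", DV = obs$severity,
                                stringsAsFactors = FALSE))
    # events before observations at equal time; time-0 observation first
    key <- ifelse(df$TIME == 0, df$EVID, 1L - df$EVID)
    df[order(df$TIME, key), , drop = FALSE]
  })
  write_csv12(do.call(rbind, rows), path)
}

#' Read an event-record dataset into patient records
#'
#' Validates every row (header, `EVID` in 0/1, `TYPE` consistent with
#' `EVID`, `DV` present and in \[0, 1\] exactly when `EVID = 0`,
#' non-negative `TIME`); all row failures are aggregated into a single
#' error listing file line numbers. Valid rows are grouped by `ID` and
#' stably sorted by time. Ineligible patients (per [is_eligible()]) are
#' retained but flagged in the attached validation report.
#'
#' @param path Dataset CSV path.
#' @return A named list of [patient_record()]s with attribute `report`
#'   (list: `n_rows`, `n_patients`, `ineligible_ids`).
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop_input("dataset file not found: ", path)
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(df), DATASET_HEADER))
    stop_input("dataset header must be exactly ",
               paste(DATASET_HEADER, collapse = ","), "; got ",
               paste(names(df), collapse = ","))
  if (nrow(df) == 0L) stop_input("dataset contains no rows")
  errs <- character()
  add_err <- function(rows, msg) {
    if (any(rows))
      errs <<- c(errs, paste0("line ", which(rows) + 1L, ": ", msg))
  }
  time <- suppressWarnings(as.numeric(df$TIME))
  add_err(is.na(time), "TIME is not a number")
  add_err(!is.na(time) & time < 0, "TIME is negative")
  add_err(!df$EVID %in% c("0", "1"), "EVID must be 0 or 1")
  evid <- suppressWarnings(as.integer(df$EVID))
  is_obs <- !is.na(evid) & evid == 0L
  is_ev <- !is.na(evid) & evid == 1L
  add_err(is_obs & df$TYPE != "dsm_l1",
          "TYPE must be dsm_l1 for observation rows (EVID=0)")
  add_err(is_ev & !df$TYPE %in% service_types(),
          paste0("TYPE must be one of ",
                 paste(service_types(), collapse = "/"),
                 " for session rows (EVID=1)"))
  dv <- suppressWarnings(as.numeric(df$DV))
  add_err(is_obs & (is.na(df$DV) | !nzchar(df$DV)),
          "DV is required for observation rows (EVID=0)")
  add_err(is_obs & nzchar(df$DV) & is.na(dv), "DV is not a number")
  add_err(is_obs & !is.na(dv) & (dv < 0 | dv > 1), "DV outside [0, 1]")
  add_err(is_ev & nzchar(df$DV) & !is.na(df$DV),
          "DV must be empty for session rows (EVID=1)")
  add_err(!nzchar(df$ID), "ID is empty")
  if (length(errs))
    stop_input("invalid dataset ", path, " (", length(errs),
               " row error(s)):\n  ", paste(errs, collapse = "\n  "))
  ids <- unique(df$ID)
  records <- lapply(ids, function(id) {
    sub <- df$ID == id
    patient_record(id,
                   session_events(time[sub & is_ev],
                                  df$TYPE[sub & is_ev]),
                   severity_observations(time[sub & is_obs],
                                         dv[sub & is_obs]))
  })
  names(records) <- ids
  elig <- vapply(records, is_eligible, logical(1))
  attr(records, "report") <- list(n_rows = nrow(df),
                                  n_patients = length(records),
                                  ineligible_ids = ids[!elig])
  records
}

#' Serialise a fitted model to JSON
#'
#' Writes population parameters, per-patient empirical-Bayes parameters,
#' the prediction table and the iteration trace, with a schema version, at
#' 12 significant digits.
#'
#' @param fit An `sd_fit` from [fit_population()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "sd_fit"))
  obj <- list(
    schema_version = "1.0",
    seed = fit$seed,
    dep0 = fit$dep0,
    population = list(typical = unlist(fit$population$typical),
                      omega = fit$population$omega,
                      sigma = fit$population$sigma),
    individuals = lapply(fit$individuals, function(ip)
      list(eta = ip$eta, realized = as_param_vector(ip$realized))),
    predictions = fit$predictions,
    trace = fit$trace,
    accept_rate = fit$accept_rate,
    excluded_ids = fit$excluded_ids,
    config = list(n_explore = fit$config$n_explore,
                  n_smooth = fit$config$n_smooth,
                  n_chains = fit$config$n_chains, n_mh = fit$config$n_mh,
                  init_typical = unlist(fit$config$init_typical),
                  init_omega = fit$config$init_omega,
                  init_sigma = fit$config$init_sigma))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 12,
                       dataframe = "columns", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fitted model back from JSON
#'
#' @param path A JSON file written by [write_fit_json()].
#' @return An `sd_fit` object (sufficient for triage and planning).
#' @export
read_fit_json <- function(path) {
  if (!file.exists(path)) stop_input("fit file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  typ <- do.call(structural_params, as.list(obj$population$typical))
  pop <- population_params(typ, obj$population$omega, obj$population$sigma)
  individuals <- lapply(obj$individuals, function(ip)
    individual_params(unlist(ip$eta), pop))
  structure(list(population = pop, individuals = individuals,
                 predictions = as.data.frame(obj$predictions),
                 trace = as.data.frame(obj$trace),
                 accept_rate = obj$accept_rate,
                 seed = obj$seed, config = obj$config,
                 dep0 = obj$dep0 %||% 1,
                 excluded_ids = unlist(obj$excluded_ids) %||% character()),
            class = "sd_fit")
}
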