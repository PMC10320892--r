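#' Individual weighted residual (IWRES)
#'
#' Weights an individual residual (`observed - individual_predicted`) by the
#' residual SD of the additive error model, turning it into a z-score-like
#' fit diagnostic.
#'
#' @param residual Numeric residual(s) on the severity scale.
#' @param sigma Residual SD, strictly positive.
#' @return Numeric IWRES value(s).
#' @export
iwres <- function(residual, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop_input("`sigma` must be a single strictly positive number")
  residual / sigma
}

#' Summarise IWRES for one patient
#'
#' Observations at time exactly 0 are removed before summarising: severity is
#' initialised at the observed entry level, so those residuals are always
#' zero and say nothing about fit quality.
#'
#' @param time Observation times (days).
#' @param observed,predicted Observed severities and individual predictions.
#' @param sigma Residual SD.
#' @return A list of class `iwres_summary` with `iwres_values`, `mean_abs`
#'   (absolute value of the mean IWRES), `sd` (sample SD, `NA` when fewer
#'   than two post-baseline observations) and `n_used`.
#' @export
iwres_summary <- function(time, observed, predicted, sigma) {
  if (length(time) != length(observed) || length(time) != length(predicted))
    stop_input("`time`, `observed` and `predicted` must have equal length")
  keep <- time != 0
  iw <- iwres(observed[keep] - predicted[keep], sigma)
  n <- length(iw)
  structure(list(iwres_values = iw,
                 mean_abs = if (n >= 1L) abs(mean(iw)) else NA_real_,
                 sd = if (n >= 2L) sd(iw) else NA_real_,
                 n_used = n),
            class = "iwres_summary")
}

#' The four support classes
#'
#' @return Character vector of the class labels in decreasing strength of
#'   evidence, ending with the not-enough-data label.
#' @export
support_classes <- function() {
  c("supported", "semi_supported", "unsupported", "unclassifiable")
}

#' Classify the support level of an individual model fit
#'
#' Grades the absolute mean IWRES (supported when \eqn{\le 1}, semi-supported
#' in (1, 1.5], unsupported above 1.5) and the IWRES SD (supported when
#' \eqn{\le 1.5}, semi-supported in (1.5, 2], unsupported above 2)
#' separately, and returns the worse of the two grades — the cautious
#' combination, flagging questionable fits for review. Patients with fewer
#' than two post-baseline observations cannot be classified. Threshold
#' boundaries are inclusive: a value equal to a threshold takes the better
#' class.
#'
#' @param summary An [iwres_summary()].
#' @return One of [support_classes()].
#' @export
classify_support <- function(summary) {
  stopifnot(inherits(summary, "iwres_summary"))
  if (summary$n_used < 2L) return("unclassifiable")
  grade_mean <- if (summary$mean_abs <= 1) 1L
    else if (summary$mean_abs <= 1.5) 2L else 3L
  grade_sd <- if (summary$sd <= 1.5) 1L
    else if (summary$sd <= 2) 2L else 3L
  support_classes()[max(grade_mean, grade_sd)]
}

#' Triage every patient in a fitted cohort
#'
#' Computes the IWRES summary and support class of every fitted patient and
#' tabulates the cohort: counts per class, percentages of the whole cohort,
#' and percentages of the classifiable patients only.
#'
#' @param fit An `sd_fit` from [fit_population()].
#' @return An object of class `sd_triage`: `table` (per-patient `id`,
#'   `n_used`, `mean_abs`, `sd`, `class`) and `summary` (per-class `n`,
#'   `pct_total`, `pct_classified`).
#' @export
triage_cohort <- function(fit) {
  stopifnot(inherits(fit, "sd_fit"))
  preds <- fit$predictions
  sigma <- fit$population$sigma
  ids <- names(fit$individuals)
  rows <- lapply(ids, function(id) {
    p <- preds[preds$id == id, , drop = FALSE]
    s <- iwres_summary(p$time, p$observed, p$pred_ind, sigma)
    data.frame(id = id, n_used = s$n_used, mean_abs = s$mean_abs,
               sd = s$sd, class = classify_support(s),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  cls <- factor(tab$class, levels = support_classes())
  counts <- as.integer(table(cls))
  n_total <- nrow(tab)
  n_classified <- sum(tab$class != "unclassifiable")
  pct_classified <- ifelse(support_classes() == "unclassifiable", NA_real_,
                           if (n_classified > 0)
                             100 * counts / n_classified else NA_real_)
  summary <- data.frame(class = support_classes(), n = counts,
                        pct_total = 100 * counts / n_total,
                        pct_classified = pct_classified,
                        stringsAsFactors = FALSE)
  structure(list(table = tab, summary = summary),
            class = "sd_triage")
}

#' @export
print.sd_triage <- function(x, ...) {
  cat("Support-level triage of individual fits\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a triage report
#'
#' @param triage An [triage_cohort()] result.
#' @param csv_path Per-patient CSV report path.
#' @param json_path Cohort-summary JSON path.
#' @return Invisibly, the triage object.
#' @export
write_triage <- function(triage, csv_path, json_path = NULL) {
  stopifnot(inherits(triage, "sd_triage"))
  tab <- triage$table
  tab$mean_abs <- num12(tab$mean_abs)
  tab$sd <- num12(tab$sd)
  write_csv12(tab, csv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(schema_version = "1.0",
                              summary = triage$summary),
                         json_path, dataframe = "rows", digits = 12,
                         na = "null", pretty = TRUE)
  }
  invisible(triage)
}
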