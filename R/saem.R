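#' SAEM estimation settings
#'
#' Configuration of the stochastic approximation EM fit: two phases (an
#' exploration phase with step size 1, then a smoothing phase with step size
#' `1/iteration`), several Metropolis--Hastings chains per patient with a few
#' transitions per E-step, and log-scale initial estimates. The initial
#' typical values default to the package's engineering defaults (not values
#' reported anywhere): elimination rates 0.05, 0.1, 0.2/day for
#' coaching/therapy/psychiatry — reflecting the clinical triaging hierarchy —
#' `s50 = 1` latent mass unit and `r = 0.05`/day.
#'
#' @param n_explore Iterations in the exploration phase (step size 1).
#' @param n_smooth Iterations in the smoothing phase (step size `1/k`).
#' @param n_chains MH chains per patient.
#' @param n_mh MH transitions per chain per E-step.
#' @param init_typical Initial typical values ([structural_params()]).
#' @param init_omega Initial log-scale BSV SDs (length 5 or scalar).
#' @param init_sigma Initial residual SD.
#' @param prop_scale Overall multiplier on the adaptive multivariate
#'   proposal (base scale `2.38/sqrt(d)` times the Cholesky factor of each
#'   patient's running chain covariance); per-patient scales additionally
#'   adapt toward `accept_target` during the exploration phase.
#' @param accept_target Target MH acceptance rate for proposal adaptation.
#' @param omega_min Lower floor on each estimated `omega` (keeps the
#'   stochastic E-step mixing even when BSV collapses).
#' @param sigma_min Lower floor on `sigma`.
#' @param anneal Simulated-annealing factor: during the exploration phase
#'   `sigma` and `omega` may shrink by at most this factor per iteration, so
#'   the chains keep exploring while the variances contract (set to 0 to
#'   disable).
#' @param rtol,atol Trajectory solver tolerances used inside the stochastic
#'   E-step only; orders of magnitude below the residual noise the
#'   trajectories are compared against. Empirical-Bayes estimates and the
#'   reported predictions always use the tight simulation default
#'   (`1e-8`).
#' @return A list of class `saem_config`.
#' @export
saem_config <- function(n_explore = 300L, n_smooth = 100L, n_chains = 3L,
                        n_mh = 5L,
                        init_typical = structural_params(0.05, 0.1, 0.2,
                                                         s50 = 1, r = 0.05),
                        init_omega = 0.5, init_sigma = 0.2,
                        prop_scale = 1, accept_target = 0.3,
                        omega_min = 0.01, sigma_min = 1e-4, anneal = 0.95,
                        rtol = 1e-4, atol = 1e-6) {
  stopifnot(inherits(init_typical, "structural_params"))
  if (length(init_omega) == 1L) init_omega <- rep(init_omega, 5L)
  if (n_explore < 1L || n_smooth < 1L || n_chains < 1L || n_mh < 1L)
    stop_input("iteration, chain and transition counts must be >= 1")
  if (any(init_omega < 0) || init_sigma <= 0)
    stop_input("`init_omega` must be >= 0 and `init_sigma` > 0")
  structure(list(n_explore = as.integer(n_explore),
                 n_smooth = as.integer(n_smooth),
                 n_chains = as.integer(n_chains), n_mh = as.integer(n_mh),
                 init_typical = init_typical,
                 init_omega = setNames(as.numeric(init_omega),
                                       sd_param_names()),
                 init_sigma = init_sigma, prop_scale = prop_scale,
                 accept_target = accept_target,
                 omega_min = omega_min, sigma_min = sigma_min,
                 anneal = anneal, rtol = rtol, atol = atol),
            class = "saem_config")
}

#' Fit the hierarchical session-dosing model by SAEM
#'
#' Alternates a stochastic E-step (Metropolis--Hastings samples of each
#' patient's individual log-parameters given the current population
#' parameters) with a stochastic-approximation M-step (running averages of
#' the complete-data sufficient statistics update the typical values, the
#' diagonal between-subject SDs `omega` and the residual SD `sigma`). Only
#' inclusion-eligible records are fitted; ineligible ones are dropped with a
#' warning. Patients are processed in id order and every patient/iteration
#' receives its own deterministic RNG sub-stream derived from `seed`, so
#' permuting the input cohort cannot change the estimates.
#'
#' After the population fit, empirical-Bayes (MAP) individual parameters and
#' predictions are computed for every fitted patient.
#'
#' @param cohort A list of [patient_record()]s (at least 2 eligible).
#' @param config A [saem_config()].
#' @param seed Integer root seed.
#' @param dep0 Initial severity (default 1).
#' @return An object of class `sd_fit` with elements `population`
#'   ([population_params()]), `individuals` (named list of
#'   [individual_params()]), `predictions` (one row per observation: `id`,
#'   `time`, `observed`, `pred_pop`, `pred_ind`, `residual`, `iwres`),
#'   `trace` (per-iteration population parameter estimates), `accept_rate`,
#'   `seed`, `config`, and `excluded_ids`.
#' @export
fit_population <- function(cohort, config = saem_config(), seed = 1L,
                           dep0 = 1) {
  stopifnot(inherits(config, "saem_config"))
  if (inherits(cohort, "patient_record")) cohort <- list(cohort)
  ok <- vapply(cohort, function(r) inherits(r, "patient_record"), logical(1))
  if (!all(ok)) stop_input("`cohort` must be a list of patient records")
  elig <- vapply(cohort, is_eligible, logical(1))
  excluded <- vapply(cohort[!elig], `[[`, character(1), "id")
  cohort <- cohort[elig]
  if (length(cohort) < 2L)
    stop_input("need at least two inclusion-eligible patients to fit the ",
               "population model (got ", length(cohort), ")")
  if (length(excluded))
    warning(length(excluded), " ineligible record(s) excluded from fitting: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  ids <- vapply(cohort, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop_input("duplicated patient ids in cohort")
  cohort <- cohort[order(ids)]
  ids <- ids[order(ids)]

  # pre-extracted per-patient data (post-baseline observations only)
  pdata <- lapply(cohort, function(rec) {
    obs <- post_baseline_obs(rec)
    list(id = rec$id, obs_t = obs$time, obs_y = obs$severity,
         ev_t = rec$events$time,
         ev_svc = match(rec$events$service, service_types()) - 1L,
         m = nrow(obs))
  })
  n <- length(pdata)
  total_m <- sum(vapply(pdata, `[[`, integer(1), "m"))
  if (total_m == 0L)
    stop_input("no post-baseline observations in the cohort")

  logmu <- log(as_param_vector(config$init_typical))
  omega <- pmax(config$init_omega, 0)
  sigma <- config$init_sigma
  C <- config$n_chains

  # chain states: per-patient C x 5 matrices of individual log-parameters,
  # dispersed around the initial typical values
  state <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seed_stream(seed, ids[i], "init"))
    z <- matrix(rnorm(C * 5L), C, 5L)
    state[[i]] <- sweep(sweep(z, 2L, pmax(omega, 0.1) * 0.5, `*`),
                        2L, logmu, `+`)
  }

  K <- config$n_explore + config$n_smooth
  trace <- matrix(NA_real_, K, 11L,
                  dimnames = list(NULL, c(sd_param_names(),
                                          paste0("omega_", sd_param_names()),
                                          "sigma")))
  A1 <- logmu
  A2 <- logmu^2 + pmax(omega, 0.1)^2
  A3 <- sigma^2
  acc <- numeric(K)
  estim <- config$init_omega > 0  # omega = 0 requested -> parameter fixed
  free <- which(estim)
  nf <- length(free)
  prop_fac <- rep(1, n)  # per-patient adaptive proposal scale factors
  # Per-patient adaptive proposal covariances (Haario-style adaptive
  # Metropolis): running first and second moments of each patient's own
  # chains capture the local shape (ridges) of that patient's conditional
  # posterior. A diagonal floor keeps proposals from collapsing; adaptation
  # freezes when the smoothing phase starts.
  pm1 <- lapply(state, colMeans)
  pm2 <- lapply(state, function(ph) crossprod(ph) / nrow(ph))
  ss_cache <- rep(list(rep(NA_real_, C)), n)
  base_L <- function(Scov) {
    out <- matrix(0, 5L, 5L)
    if (nf > 0) {
      Creg <- Scov + diag((0.05 * pmax(omega, 0.02))^2, 5L)
      Creg <- Creg[free, free, drop = FALSE]
      ch <- tryCatch(chol(Creg), error = function(e) diag(sqrt(diag(Creg)),
                                                          nrow(Creg)))
      out[free, free] <- t(ch) * (2.38 / sqrt(nf)) * config$prop_scale
    }
    out
  }

  for (k in seq_len(K)) {
    gamma <- if (k <= config$n_explore) 1 else 1 / (k - config$n_explore)
    s1 <- numeric(5L)
    s2 <- numeric(5L)
    s3 <- 0
    acck <- 0
    for (i in seq_len(n)) {
      pd <- pdata[[i]]
      set.seed(seed_stream(seed, pd$id, k))
      Scov_i <- pm2[[i]] - tcrossprod(pm1[[i]])
      up <- mh_update_cpp(state[[i]], pd$obs_t, pd$obs_y, pd$ev_t, pd$ev_svc,
                          logmu, omega, sigma, config$n_mh,
                          prop_fac[i] * base_L(Scov_i), dep0,
                          config$rtol, config$atol, ss_cache[[i]])
      state[[i]] <- up$phi
      ss_cache[[i]] <- up$ss
      s1 <- s1 + colMeans(up$phi)
      s2 <- s2 + colMeans(up$phi^2)
      s3 <- s3 + mean(up$ss)
      acck <- acck + up$accept
      if (k <= config$n_explore) {
        # Robbins-Monro adaptation of the proposal scale toward the target
        # acceptance rate, plus running-moment updates of the proposal
        # covariance; both frozen once the smoothing phase starts
        prop_fac[i] <- min(10, max(1e-3, prop_fac[i] *
          exp(0.4 * (up$accept - config$accept_target))))
        pm1[[i]] <- pm1[[i]] + 0.1 * (colMeans(up$phi) - pm1[[i]])
        pm2[[i]] <- pm2[[i]] + 0.1 * (crossprod(up$phi) / nrow(up$phi) -
                                        pm2[[i]])
      }
    }
    acc[k] <- acck / n
    s1 <- s1 / n
    s2 <- s2 / n
    s3 <- s3 / total_m
    A1 <- A1 + gamma * (s1 - A1)
    A2 <- A2 + gamma * (s2 - A2)
    A3 <- A3 + gamma * (s3 - A3)
    logmu <- ifelse(estim, A1, logmu)
    omega_new <- ifelse(estim,
                        pmax(sqrt(pmax(A2 - A1^2, 0)), config$omega_min), 0)
    sigma_new <- max(sqrt(A3), config$sigma_min)
    if (k <= config$n_explore && config$anneal > 0) {
      # simulated annealing: cap the shrinkage rate while exploring
      omega_new <- ifelse(estim, pmax(omega_new, config$anneal * omega),
                          omega_new)
      sigma_new <- max(sigma_new, config$anneal * sigma)
    }
    omega <- omega_new
    sigma <- sigma_new
    if (any(!is.finite(c(logmu, omega, sigma)))) {
      stop_input("SAEM diverged (non-finite parameters) at iteration ", k,
                 "; inspect the iteration trace")
    }
    trace[k, ] <- c(exp(logmu), omega, sigma)
  }

  pop <- population_params(do.call(structural_params,
                                   as.list(exp(logmu))), omega, sigma)

  # empirical-Bayes step and predictions
  individuals <- vector("list", n)
  names(individuals) <- ids
  pred_rows <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- cohort[[i]]
    eb <- empirical_bayes(rec, pop, seed = seed, dep0 = dep0)
    individuals[[i]] <- eb
    obs <- rec$observations
    pi_ <- predict_record(rec, eb$realized, dep0)
    pp <- predict_record(rec, pop$typical, dep0)
    res <- obs$severity - pi_
    pred_rows[[i]] <- data.frame(id = rec$id, time = obs$time,
                                 observed = obs$severity, pred_pop = pp,
                                 pred_ind = pi_, residual = res,
                                 iwres = res / pop$sigma,
                                 stringsAsFactors = FALSE)
  }

  structure(list(population = pop, individuals = individuals,
                 predictions = do.call(rbind, pred_rows),
                 trace = data.frame(iteration = seq_len(K), trace),
                 accept_rate = mean(acc), seed = as.integer(seed),
                 config = config, dep0 = dep0,
                 excluded_ids = as.character(excluded)),
            class = "sd_fit")
}

#' @export
print.sd_fit <- function(x, ...) {
  cat(sprintf("Session-dosing SAEM fit: %d patients, %d iterations\n",
              length(x$individuals), nrow(x$trace)))
  print(x$population)
  cat(sprintf(" mean MH acceptance: %.2f\n", x$accept_rate))
  if (length(x$excluded_ids))
    cat(" excluded (ineligible):", paste(x$excluded_ids, collapse = ", "),
        "\n")
  invisible(x)
}
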