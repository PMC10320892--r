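#' Population (hierarchical) parameters
#'
#' The hierarchical layer of the model: typical (central tendency) structural
#' parameters, log-scale between-subject standard deviations (diagonal
#' `omega`, one per structural parameter; a zero fixes that parameter at its
#' typical value for everyone), and the additive residual standard deviation
#' `sigma` on the severity scale.
#'
#' @param typical A [structural_params()] object.
#' @param omega Numeric vector of 5 non-negative log-scale SDs (named or in
#'   [sd_param_names()] order).
#' @param sigma Residual SD, strictly positive.
#' @return An object of class `population_params`.
#' @export
population_params <- function(typical, omega, sigma) {
  stopifnot(inherits(typical, "structural_params"))
  if (length(omega) == 1L) omega <- rep(omega, 5L)
  if (length(omega) != 5L || anyNA(omega) || any(omega < 0))
    stop_input("`omega` must be 5 non-negative log-scale SDs")
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop_input("`sigma` must be a single strictly positive residual SD")
  structure(list(typical = typical,
                 omega = setNames(as.numeric(omega), sd_param_names()),
                 sigma = as.numeric(sigma)),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("Population session-dosing parameters\n typical:\n")
  print(unlist(x$typical))
  cat(" omega (log-scale BSV SD):\n")
  print(x$omega)
  cat(sprintf(" sigma (residual SD): %.4g\n", x$sigma))
  invisible(x)
}

#' Individual parameters as log-scale deviations from the typical values
#'
#' Realised parameters are `typical * exp(eta)` elementwise, which keeps them
#' strictly positive; `eta = 0` reproduces the typical individual.
#'
#' @param eta Numeric vector of 5 log-scale deviations.
#' @param pop A [population_params()] object supplying the typical values.
#' @return An object of class `individual_params` with elements `eta` and
#'   `realized` (a [structural_params()]).
#' @export
individual_params <- function(eta, pop) {
  stopifnot(inherits(pop, "population_params"))
  if (length(eta) != 5L || anyNA(eta))
    stop_input("`eta` must be 5 finite log-scale deviations")
  eta <- setNames(as.numeric(eta), sd_param_names())
  realized <- as_param_vector(pop$typical) * exp(eta)
  structure(list(eta = eta,
                 realized = do.call(structural_params, as.list(realized))),
            class = "individual_params")
}

# Post-baseline observations only: residuals at time 0 are structurally zero
# (severity is initialised at the observed entry level) and carry no
# likelihood information.
post_baseline_obs <- function(record) {
  obs <- record$observations
  obs[obs$time > 0, , drop = FALSE]
}

predict_record <- function(record, params, dep0 = 1, rtol = 1e-8,
                           atol = 1e-8) {
  obs <- record$observations
  if (nrow(obs) == 0L) return(numeric())
  simulate_trajectory(record$events, params, obs$time, dep0 = dep0,
                      rtol = rtol, atol = atol)$severity
}

#' MAP objective for one individual's random effects
#'
#' Minus twice the unnormalised log-posterior of the individual log-scale
#' deviations `eta`: the Gaussian residual log-likelihood of the
#' post-baseline observations given the realised parameters, plus the
#' Gaussian prior on each `eta` component with a positive `omega`; prior
#' terms are dropped (and `eta` held at 0) wherever `omega` is 0.
#'
#' @param record An inclusion-eligible [patient_record()].
#' @param indiv An [individual_params()] object.
#' @param pop A [population_params()] object.
#' @param dep0 Initial severity (default 1).
#' @param rtol,atol Solver tolerances.
#' @return A single number; smaller is a better (more probable) fit.
#' @export
individual_objective <- function(record, indiv, pop, dep0 = 1,
                                 rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(record, "patient_record"),
            inherits(indiv, "individual_params"),
            inherits(pop, "population_params"))
  if (pop$sigma <= 0) stop_input("`sigma` must be strictly positive")
  obs <- post_baseline_obs(record)
  ll <- 0
  if (nrow(obs) > 0L) {
    pred <- simulate_trajectory(record$events, indiv$realized, obs$time,
                                dep0 = dep0, rtol = rtol,
                                atol = atol)$severity
    ll <- sum(dnorm(obs$severity, mean = pred, sd = pop$sigma, log = TRUE))
  }
  free <- pop$omega > 0
  lprior <- sum(dnorm(indiv$eta[free], 0, pop$omega[free], log = TRUE))
  -2 * (ll + lprior)
}

#' Empirical-Bayes (MAP) individual parameter estimates
#'
#' Minimises [individual_objective()] over the free components of `eta`
#' (those with positive `omega`) by multi-start local optimisation
#' (`nlminb`): one start at the prior mode `eta = 0` plus `n_starts - 1`
#' random draws from the prior, seeded deterministically from `seed` and the
#' patient id.
#'
#' @param record An inclusion-eligible [patient_record()].
#' @param pop A [population_params()] object.
#' @param seed Integer seed for the random starts.
#' @param n_starts Total number of optimisation starts.
#' @param dep0,rtol,atol Passed to the trajectory solver.
#' @return An [individual_params()] with attributes `objective` (value at the
#'   optimum) and `n_starts_converged`.
#' @export
empirical_bayes <- function(record, pop, seed = 1L, n_starts = 4L, dep0 = 1,
                            rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(record, "patient_record"),
            inherits(pop, "population_params"))
  free <- pop$omega > 0
  obs <- post_baseline_obs(record)
  if (!any(free) || nrow(obs) == 0L) {
    out <- individual_params(rep(0, 5), pop)
    attr(out, "objective") <- individual_objective(record, out, pop,
                                                   dep0, rtol, atol)
    attr(out, "n_starts_converged") <- n_starts
    return(out)
  }
  typ <- as_param_vector(pop$typical)
  ev <- record$events
  ev_k_svc <- match(ev$service, service_types()) - 1L
  omega <- pop$omega
  obj <- function(eta_free) {
    eta <- rep(0, 5)
    eta[free] <- eta_free
    phi <- log(typ) + eta
    pred <- dep_solve_cpp(obs$time, ev$time, ev_k_svc, exp(phi[1:3]),
                          exp(phi[4]), exp(phi[5]), dep0, 0L, 0,
                          rtol, atol)
    ll <- sum(dnorm(obs$severity, pred, pop$sigma, log = TRUE))
    lprior <- sum(dnorm(eta[free], 0, omega[free], log = TRUE))
    -2 * (ll + lprior)
  }
  set.seed(seed_stream(seed, record$id, "eb"))
  starts <- c(list(rep(0, sum(free))),
              lapply(seq_len(max(0L, n_starts - 1L)), function(i)
                rnorm(sum(free), 0, omega[free])))
  best <- NULL
  n_ok <- 0L
  for (s in starts) {
    fit <- tryCatch(nlminb(s, obj, control = list(iter.max = 300)),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best))
    stop_input("empirical-Bayes optimisation failed from all ", n_starts,
               " starts for patient ", record$id)
  eta <- rep(0, 5)
  eta[free] <- best$par
  out <- individual_params(eta, pop)
  attr(out, "objective") <- best$objective
  attr(out, "n_starts_converged") <- n_ok
  out
}
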