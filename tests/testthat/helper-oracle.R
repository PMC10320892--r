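# Independent oracle for the severity trajectory: the integrating-factor
# solution Dep(t) = e^(-r t) dep0 + r * int_0^t e^(-r (t - s)) (1 - I(s)) ds
# evaluated by adaptive quadrature (stats::integrate), split at event times
# where the inhibition term has derivative kinks. Deliberately shares no code
# with the package's Runge-Kutta path.
oracle_dep <- function(events, params, t, dep0 = 1) {
  vapply(t, function(tt) {
    if (tt == 0) return(dep0)
    integrand <- function(s) {
      m <- treatment_mass(events, params, s)
      exp(-params$r * (tt - s)) * (1 - m / (m + params$s50))
    }
    brk <- sort(unique(c(0, events$time[events$time < tt], tt)))
    total <- 0
    for (i in seq_len(length(brk) - 1L)) {
      total <- total + stats::integrate(integrand, brk[i], brk[i + 1L],
                                        rel.tol = 1e-12, abs.tol = 1e-13,
                                        subdivisions = 500L)$value
    }
    exp(-params$r * tt) * dep0 + params$r * total
  }, numeric(1))
}

# Random but reproducible structural parameters / event histories for
# property-style sweeps.
random_params <- function() {
  structural_params(exp(runif(1, log(0.01), log(0.3))),
                    exp(runif(1, log(0.02), log(0.5))),
                    exp(runif(1, log(0.05), log(0.8))),
                    s50 = exp(runif(1, log(0.2), log(5))),
                    r = exp(runif(1, log(0.01), log(0.2))))
}

random_events <- function(n_max = 25, t_max = 200) {
  n <- sample(0:n_max, 1)
  if (n == 0) return(session_events())
  session_events(runif(n, 0, t_max),
                 sample(service_types(), n, replace = TRUE))
}

# Brute-force re-statement of the support-level rules, written as a plain
# rule table independent of classify_support()'s implementation.
oracle_support <- function(mean_abs, sd, n_used = 5L) {
  if (n_used < 2L) return("unclassifiable")
  mgrade <- if (mean_abs <= 1) "supported"
    else if (mean_abs > 1 && mean_abs <= 1.5) "semi_supported"
    else "unsupported"
  sgrade <- if (sd <= 1.5) "supported"
    else if (sd > 1.5 && sd <= 2) "semi_supported"
    else "unsupported"
  lv <- c(supported = 1, semi_supported = 2, unsupported = 3)
  names(lv)[max(lv[mgrade], lv[sgrade])]
}

# Small deterministic two-patient cohort for IO / fitting contracts.
tiny_cohort <- function() {
  list(
    patient_record("A",
                   session_events(c(5, 20, 40, 60), "therapy"),
                   severity_observations(c(0, 30, 62, 90),
                                         c(1, 0.75, 0.5, 0.375))),
    patient_record("B",
                   session_events(c(10, 30), c("coaching", "psychiatry")),
                   severity_observations(c(0, 45, 80), c(1, 0.875, 0.625))))
}

# An iwres_summary built directly from raw IWRES values.
summary_from_iwres <- function(values) {
  iwres_summary(time = seq_along(values), observed = values,
                predicted = rep(0, length(values)), sigma = 1)
}
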