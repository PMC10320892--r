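make_pop <- function(omega = 0.3, sigma = 0.1) {
  population_params(structural_params(0.05, 0.1, 0.2, s50 = 1, r = 0.05),
                    omega = omega, sigma = sigma)
}

test_that("individual parameters exponentiate deviations from the typicals", {
  pop <- make_pop()
  ip0 <- individual_params(rep(0, 5), pop)
  expect_equal(unlist(ip0$realized), unlist(pop$typical))
  ip <- individual_params(c(0.5, -0.5, 0, 1, -1), pop)
  expect_equal(ip$realized$k_out_coaching, 0.05 * exp(0.5))
  expect_equal(ip$realized$r, 0.05 * exp(-1))
  expect_true(all(unlist(ip$realized) > 0))
})

test_that("the MAP objective matches a direct density-product oracle", {
  pop <- make_pop(omega = 0, sigma = 1)
  # two post-baseline observations sitting exactly on the no-treatment
  # steady state: both residuals are zero
  rec <- patient_record("A", session_events(10, "therapy"),
                        severity_observations(c(0, 30, 60), c(1, 1, 1)))
  # a session decreases predictions, so force zero residuals with no events
  rec0 <- patient_record("A0", session_events(),
                         severity_observations(c(0, 30, 60), c(1, 1, 1)))
  ip <- individual_params(rep(0, 5), pop)
  expect_equal(individual_objective(rec0, ip, pop),
               2 * (-2 * log(1 / sqrt(2 * pi))), tolerance = 1e-9)
  # random small cases against brute-force density evaluation
  set.seed(3)
  for (i in 1:5) {
    pop2 <- make_pop(omega = runif(5, 0.1, 0.6), sigma = runif(1, 0.05, 0.3))
    eta <- rnorm(5, 0, 0.3)
    ip2 <- individual_params(eta, pop2)
    rec2 <- patient_record("B", random_events(10, 80),
                           severity_observations(c(0, 20, 50, 80),
                                                 c(1, 0.75, 0.5, 0.625)))
    obs <- rec2$observations[rec2$observations$time > 0, ]
    pred <- simulate_trajectory(rec2$events, ip2$realized, obs$time)$severity
    brute <- -2 * (sum(log(dnorm(obs$severity, pred, pop2$sigma))) +
                   sum(log(dnorm(eta, 0, pop2$omega))))
    expect_lt(abs(individual_objective(rec2, ip2, pop2) - brute), 1e-8)
  }
})

test_that("zero-variance priors force the typical values", {
  pop <- make_pop(omega = 0, sigma = 0.1)
  rec <- tiny_cohort()[[1]]
  eb <- empirical_bayes(rec, pop)
  expect_equal(unname(eb$eta), rep(0, 5))
  expect_equal(unlist(eb$realized), unlist(pop$typical))
})

test_that("no post-baseline data returns the prior mode", {
  pop <- make_pop(omega = 2, sigma = 0.1)
  rec <- patient_record("flat", session_events(5, "therapy"),
                        severity_observations(0, 1))
  eb <- empirical_bayes(rec, pop)
  expect_equal(unname(eb$eta), rep(0, 5))
})

test_that("empirical Bayes recovers known deviations from dense data", {
  pop <- make_pop(omega = 2, sigma = 1e-3)
  eta_true <- c(0.4, -0.3, 0.25, 0.5, -0.4)
  ip <- individual_params(eta_true, pop)
  set.seed(21)
  ev <- session_events(sort(runif(30, 0, 300)),
                       sample(service_types(), 30, replace = TRUE,
                              prob = c(0.3, 0.4, 0.3)))
  tt <- seq(10, 360, by = 10)
  dep <- simulate_trajectory(ev, ip$realized, tt)$severity
  rec <- patient_record("dense", ev,
                        severity_observations(c(0, tt), c(1, dep)))
  eb <- empirical_bayes(rec, pop, seed = 5)
  expect_lt(max(abs(eb$eta - eta_true)), 0.05)
})

test_that("MAP dominance: the EB optimum beats the prior mode", {
  pop <- make_pop(omega = 0.4, sigma = 0.1)
  for (rec in tiny_cohort()) {
    eb <- empirical_bayes(rec, pop)
    f_eb <- individual_objective(rec, eb, pop)
    f_0 <- individual_objective(rec, individual_params(rep(0, 5), pop), pop)
    expect_lte(f_eb, f_0 + 1e-8)
  }
})

test_that("EB estimates shrink to zero as residual noise grows", {
  # one free parameter (r); increasing sigma must shrink |eta| monotonically
  typ <- structural_params(0.05, 0.1, 0.2, s50 = 1, r = 0.05)
  rec <- patient_record("s", session_events(c(10, 30, 50), "therapy"),
                        severity_observations(c(0, 20, 40, 60, 90),
                                              c(1, 0.875, 0.625, 0.5, 0.5)))
  etas <- sapply(c(0.02, 0.05, 0.1, 0.3, 1), function(sg) {
    pop <- population_params(typ, omega = c(0, 0, 0, 0, 0.7), sigma = sg)
    abs(empirical_bayes(rec, pop)$eta[["r"]])
  })
  expect_true(all(diff(etas) < 1e-6))
  expect_lt(etas[5], 0.05)
})

test_that("SAEM recovers typical values from a degenerate-noise cohort", {
  pop <- population_params(structural_params(0.05, 0.1, 0.2, 1, 0.05),
                           omega = 0, sigma = 1e-3)
  cfg <- cohort_config(n_patients = 50, seed = 4, population = pop,
                       snap = FALSE,
                       archetype_mix = c(response = 1, saturated = 0,
                                         rebound = 0, multiphasic = 0,
                                         poor_fit = 0))
  co <- generate_cohort(cfg)
  fit <- fit_population(co$records,
                        saem_config(n_explore = 300, n_smooth = 100),
                        seed = 9)
  est <- unlist(fit$population$typical)
  truth <- c(0.05, 0.1, 0.2, 1, 0.05)
  expect_lt(max(abs(est / truth - 1)), 0.01)
  expect_lt(fit$population$sigma, 0.01)
})

test_that("permuting patient order leaves the estimates identical", {
  co <- generate_cohort(cohort_config(n_patients = 12, seed = 6))
  cfg <- saem_config(n_explore = 15, n_smooth = 10)
  f1 <- fit_population(co$records, cfg, seed = 3)
  f2 <- fit_population(rev(co$records), cfg, seed = 3)
  expect_identical(unlist(f1$population$typical),
                   unlist(f2$population$typical))
  expect_identical(f1$population$omega, f2$population$omega)
  expect_identical(f1$population$sigma, f2$population$sigma)
  expect_identical(f1$trace, f2$trace)
})

test_that("population parameter averages stabilise after burn-in", {
  co <- generate_cohort(cohort_config(n_patients = 40, seed = 8))
  fit <- fit_population(co$records,
                        saem_config(n_explore = 60, n_smooth = 200),
                        seed = 12)
  # in the smoothing phase the estimate sequence is itself the running
  # average of the sufficient statistics; it must settle to < 1% movement
  # over the final 20% of iterations
  tr <- fit$trace[, c(sd_param_names(), "sigma")]
  n <- nrow(tr)
  drift <- abs(unlist(tr[n, ]) / unlist(tr[n - round(0.2 * n), ]) - 1)
  expect_true(all(drift < 0.01))
})

test_that("fitting demands at least two eligible patients", {
  rec <- tiny_cohort()[[1]]
  expect_error(fit_population(list(rec), saem_config()), "at least two")
  bad <- patient_record("nob", session_events(200, "therapy"),
                        severity_observations(c(0, 30), c(1, 0.5)))
  expect_error(
    suppressWarnings(fit_population(list(rec, bad), saem_config())),
    "at least two")
  expect_error(fit_population(list(), saem_config()), "at least two")
})

test_that("predictions align one-to-one with observations", {
  co <- generate_cohort(cohort_config(n_patients = 8, seed = 14))
  fit <- fit_population(co$records, saem_config(n_explore = 15,
                                                n_smooth = 10), seed = 2)
  n_obs <- sum(sapply(co$records, function(r) nrow(r$observations)))
  expect_identical(nrow(fit$predictions), n_obs)
  expect_equal(fit$predictions$residual,
               fit$predictions$observed - fit$predictions$pred_ind)
  # time-0 rows predict the entry severity exactly
  t0 <- fit$predictions[fit$predictions$time == 0, ]
  expect_equal(t0$pred_ind, rep(1, nrow(t0)))
  expect_equal(t0$residual, rep(0, nrow(t0)))
})
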