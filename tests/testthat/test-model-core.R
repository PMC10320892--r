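test_that("severity score averages the two items and normalises by 4", {
  expect_identical(severity_from_items(4, 4), 1)
  expect_identical(severity_from_items(0, 0), 0)
  expect_identical(severity_from_items(2, 3), 0.625)
  # vectorised, always on the 0.125 grid
  grid <- expand.grid(a = 0:4, d = 0:4)
  s <- severity_from_items(grid$a, grid$d)
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(abs(s / 0.125 - round(s / 0.125)) < 1e-12))
  expect_error(severity_from_items(5, 0), "anhedonia")
  expect_error(severity_from_items(1, -1), "depressed_mood")
  expect_error(severity_from_items(1.5, 2), "anhedonia")
})

test_that("structural parameters must be strictly positive", {
  expect_error(structural_params(0, 0.1, 0.2, 1, 0.05), "positive")
  expect_error(structural_params(0.05, 0.1, 0.2, -1, 0.05), "positive")
  p <- structural_params(0.05, 0.1, 0.2, 1, 0.05)
  expect_s3_class(p, "structural_params")
  expect_identical(unname(unlist(p)["r"]), 0.05)
})

test_that("treatment mass superposes unit boluses with per-service decay", {
  p <- structural_params(0.05, 0.1, 0.2, s50 = 1, r = 0.05)
  expect_identical(treatment_mass(session_events(), p, c(0, 10, 50)),
                   c(0, 0, 0))
  ev1 <- session_events(0, "therapy")
  expect_equal(treatment_mass(ev1, p, 10), exp(-1), tolerance = 1e-12)
  ev2 <- session_events(c(0, 7), "therapy")
  expect_equal(treatment_mass(ev2, p, 10), exp(-1) + exp(-0.3),
               tolerance = 1e-12)
  # future events contribute nothing
  expect_equal(treatment_mass(ev2, p, 5), exp(-0.5), tolerance = 1e-12)
  expect_error(treatment_mass(ev1, p, -1), "non-negative")
})

test_that("treatment mass equals the brute-force per-event sum", {
  set.seed(42)
  for (i in 1:20) {
    p <- random_params()
    ev <- random_events(n_max = 50)
    t <- runif(1, 0, 250)
    k <- c(coaching = p$k_out_coaching, therapy = p$k_out_therapy,
           psychiatry = p$k_out_psychiatry)[ev$service]
    brute <- sum(exp(-k[ev$time <= t] * (t - ev$time[ev$time <= t])))
    expect_lt(abs(treatment_mass(ev, p, t) - brute), 1e-10)
  }
})

test_that("inhibition is the bounded Hill function with Emax fixed at 1", {
  expect_identical(inhibition(0, 1), 0)
  expect_identical(inhibition(2.5, 2.5), 0.5)
  expect_identical(inhibition(9 * 0.3, 0.3), 0.9)
  trt <- seq(0, 50, by = 0.5)
  i <- inhibition(trt, 1.3)
  expect_true(all(diff(i) > 0))
  expect_true(all(i < 1))
  expect_error(inhibition(1, 0), "s50")
  expect_error(inhibition(-0.1, 1), "non-negative")
})

test_that("trajectory closed-form limits hold", {
  p <- structural_params(0.05, 0.1, 0.2, s50 = 1, r = 0.05)
  grid <- seq(0, 200, by = 10)
  # no treatment: production balances elimination at the severe level
  expect_equal(simulate_trajectory(session_events(), p, grid)$severity,
               rep(1, length(grid)), tolerance = 1e-9)
  # no treatment from a partial severity: dep0 e^(-rt) + (1 - e^(-rt))
  tr <- simulate_trajectory(session_events(), p, grid, dep0 = 0.4)
  expect_equal(tr$severity,
               0.4 * exp(-0.05 * grid) + (1 - exp(-0.05 * grid)),
               tolerance = 1e-7)
  # full-inhibition hook: pure exponential decay
  tr <- simulate_trajectory(session_events(), p, grid, const_inhibition = 1)
  expect_equal(tr$severity, exp(-0.05 * grid), tolerance = 1e-7)
  r <- 0.05
  tr <- simulate_trajectory(session_events(), p, c(0, 20), const_inhibition = 1)
  expect_equal(tr$severity[2], exp(-1), tolerance = 1e-7)
  # constant-mass hook settles at s50 / (M + s50)
  M <- 3
  tr <- simulate_trajectory(session_events(), p, c(0, 20 / p$r),
                            const_mass = M)
  expect_equal(tr$severity[2], p$s50 / (M + p$s50), tolerance = 1e-4)
})

test_that("trajectory matches the integrating-factor quadrature oracle", {
  p <- structural_params(0.05, 0.1, 0.2, s50 = 0.5, r = 0.1)
  ev <- session_events(0, "therapy")
  expect_equal(simulate_trajectory(ev, p, 14)$severity,
               oracle_dep(ev, p, 14), tolerance = 1e-7)
  set.seed(7)
  for (i in 1:10) {
    p <- random_params()
    ev <- random_events()
    tt <- sort(runif(3, 0, 220))
    expect_equal(simulate_trajectory(ev, p, tt)$severity,
                 oracle_dep(ev, p, tt), tolerance = 1e-6)
  }
})

test_that("severity stays in (0, 1] and treatment never increases it", {
  set.seed(11)
  grid <- seq(0, 300, by = 5)
  for (i in 1:15) {
    p <- random_params()
    ev <- random_events()
    sev <- simulate_trajectory(ev, p, grid)$severity
    expect_true(all(sev > 0 & sev <= 1 + 1e-6))
    # add one extra session at a random time: never worse later
    tnew <- runif(1, 0, 250)
    ev2 <- session_events(c(ev$time, tnew),
                          c(ev$service, sample(service_types(), 1)))
    sev2 <- simulate_trajectory(ev2, p, grid)$severity
    expect_true(all(sev2[grid >= tnew] <= sev[grid >= tnew] + 1e-8))
  }
})

test_that("co-timed sessions stack additively", {
  p <- structural_params(0.05, 0.1, 0.2, s50 = 1, r = 0.05)
  ev2 <- session_events(c(10, 10), "therapy")
  expect_equal(treatment_mass(ev2, p, 20),
               2 * treatment_mass(session_events(10, "therapy"), p, 20),
               tolerance = 1e-12)
  sev2 <- simulate_trajectory(ev2, p, c(0, 30))$severity[2]
  sev1 <- simulate_trajectory(session_events(10, "therapy"), p,
                              c(0, 30))$severity[2]
  expect_lt(sev2, sev1)
})

test_that("trajectory input validation rejects bad grids and dep0", {
  p <- structural_params(0.05, 0.1, 0.2, s50 = 1, r = 0.05)
  expect_error(simulate_trajectory(session_events(), p, c(10, 5)), "sorted")
  expect_error(simulate_trajectory(session_events(), p, c(-1, 5)),
               "non-negative")
  expect_error(simulate_trajectory(session_events(), p, 10, dep0 = 0),
               "dep0")
  expect_error(simulate_trajectory(session_events(), p, 10, dep0 = 1.2),
               "dep0")
  expect_error(simulate_trajectory(session_events(), p, 10,
                                   const_inhibition = 1.4), "const_inhibition")
})

test_that("patient records enforce the inclusion rule definition", {
  r1 <- patient_record("X", session_events(15, "therapy"),
                       severity_observations(c(0, 30), c(1, 0.5)))
  expect_true(is_eligible(r1))
  # session outside the observation span
  r2 <- patient_record("Y", session_events(40, "therapy"),
                       severity_observations(c(0, 30), c(1, 0.5)))
  expect_false(is_eligible(r2))
  # single observation
  r3 <- patient_record("Z", session_events(15, "therapy"),
                       severity_observations(0, 1))
  expect_false(is_eligible(r3))
  # no sessions at all
  r4 <- patient_record("W", session_events(),
                       severity_observations(c(0, 30), c(1, 0.5)))
  expect_false(is_eligible(r4))
})
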