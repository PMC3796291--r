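# Forward PK simulation: closed forms, superposition, clearance models, AUC.

test_that("one-compartment depot profile matches the Bateman closed form", {
  p <- pk_params(ka = 1, cl = 0.5, v1 = 1)
  pr <- conc_profile(p, dose_events(0, 1), times = c(0.5, 1, 2))
  bateman <- function(t) 1 * 1 / (1 * (1 - 0.5)) * (exp(-0.5 * t) - exp(-t))
  expect_equal(pr$conc, bateman(c(0.5, 1, 2)), tolerance = 1e-10)
  expect_equal(pr$conc[2], 0.4773, tolerance = 1e-4)
})

test_that("profiles are linear in dose and zero without doses", {
  p <- pk_params(ka = 1.2, cl = 0.8, v1 = 1.5, q = 0.4, v2 = 2)
  d1 <- dose_events(c(0, 10), c(2, 3))
  d2 <- dose_events(c(0, 10), c(4, 6))
  tt <- c(1, 5, 12, 24)
  expect_equal(2 * conc_profile(p, d1, tt)$conc,
               conc_profile(p, d2, tt)$conc, tolerance = 1e-12)
  expect_equal(conc_profile(p, dose_events(), tt)$conc, rep(0, 4))
})

test_that("superposition: a multi-dose profile is the sum of its single-dose profiles", {
  set.seed(42)
  for (i in 1:5) {
    p <- pk_params(ka = runif(1, 0.5, 2), cl = runif(1, 0.3, 2),
                   v1 = runif(1, 0.5, 3), q = runif(1, 0, 0.6),
                   v2 = runif(1, 1, 3))
    times <- sort(runif(6, 0.5, 30))
    dt <- c(0, 6, 14)
    da <- runif(3, 1, 5)
    total <- conc_profile(p, dose_events(dt, da), times)$conc
    parts <- Reduce(`+`, lapply(1:3, function(k) {
      conc_profile(p, dose_events(dt[k], da[k]), times)$conc
    }))
    expect_equal(total, parts, tolerance = 1e-10)
  }
})

test_that("two-compartment model with q = 0 collapses to one compartment", {
  p1 <- pk_params(ka = 1, cl = 0.7, v1 = 1.2)
  p2 <- pk_params(ka = 1, cl = 0.7, v1 = 1.2, q = 0, v2 = 5)
  tt <- c(0.5, 2, 6, 12)
  d <- dose_events(c(0, 8), c(1, 2))
  expect_equal(conc_profile(p1, d, tt)$conc, conc_profile(p2, d, tt)$conc,
               tolerance = 1e-12)
})

test_that("zero-order absorption converges to a bolus as duration -> 0", {
  p <- pk_params(ka = 1, cl = 0.5, v1 = 1)
  tt <- c(1, 2, 4)
  bolus <- (1 / 1) * exp(-0.5 * tt)  # D/V e^{-ke t}
  zo <- conc_profile(p, dose_events(0, 1, dur = 1e-5), tt)$conc
  expect_equal(zo, bolus, tolerance = 1e-4)
})

test_that("analytic profiles agree with a fine-step brute-force integrator within 0.1%", {
  cases <- list(
    list(p = pk_params(ka = 1.2, cl = 0.6, v1 = 1),
         d = dose_events(c(0, 10), c(2, 2))),
    list(p = pk_params(ka = 0.9, cl = 0.5, v1 = 1.2, q = 0.3, v2 = 2),
         d = dose_events(0, 3)),
    list(p = pk_params(ka = 1, cl = 0.8, v1 = 1, q = 0.25, v2 = 1.5),
         d = dose_events(c(0, 6), c(2, 4), dur = 1))
  )
  tt <- c(2, 5, 9, 14)
  for (cs in cases) {
    a <- conc_profile(cs$p, cs$d, tt)$conc
    b <- euler_conc(cs$p, cs$d, tt, h = 2e-4)
    expect_lt(max(abs(a - b) / b), 1e-3)
  }
})

test_that("numerical route handles time-varying clearance and matches brute force", {
  p <- pk_params(ka = 1, cl = 0.5, v1 = 1, cl_induced = 1,
                 induction_start = 5, induction_end = 20)
  d <- dose_events(c(0, 8, 16), rep(2, 3))
  tt <- c(2, 10, 18, 22)
  a <- conc_profile(p, d, tt)$conc  # auto -> ODE when clearance varies
  b <- euler_conc(p, d, tt, h = 2e-4)
  expect_lt(max(abs(a - b) / b), 1e-3)
})

test_that("clearance_at follows the linear induction ramp", {
  p <- pk_params(ka = 1, cl = 2, v1 = 1, cl_induced = 4,
                 induction_start = 24, induction_end = 168)
  expect_equal(clearance_at(p, 0), 2)
  expect_equal(clearance_at(p, 10 * 24), 4)      # constant thereafter
  expect_equal(clearance_at(p, (24 + 168) / 2), 3)  # day-4 midpoint
  expect_error(pk_params(ka = 1, cl = 2, v1 = 1, cl_induced = 4,
                         induction_start = 100, induction_end = 50),
               "induction_end")
  expect_error(clearance_at(p, -1), ">= 0")
})

test_that("dose-dependent clearance power model", {
  m <- cl_dose_model(theta1 = 10, reference_dose = 30, pwr = 1)
  expect_equal(dose_dependent_clearance(m, 30), 10)
  expect_equal(dose_dependent_clearance(m, 60), 5)
  m2 <- cl_dose_model(theta1 = 10, pwr = 0, eta = 0.1)
  expect_equal(dose_dependent_clearance(m2, 7), 10 * exp(0.1),
               tolerance = 1e-12)
  expect_error(dose_dependent_clearance(m, 0), "dose")
})

test_that("conc_profile derives each dose's clearance from its dose level", {
  pr <- drug_properties(fu = 0.5, ic50_invitro = 1, nmol_per_mg = 1000)
  m <- cl_dose_model(theta1 = 2, reference_dose = 30, pwr = 0.5)
  p <- pk_params(ka = 1, cl = 999, v1 = 1.2)  # cl overridden by the model
  tt <- c(1, 3, 6)
  with_model <- conc_profile(p, dose_events(0, 120), tt, cl_dose = m,
                             props = pr)
  p_eq <- pk_params(ka = 1, cl = dose_dependent_clearance(m, 120), v1 = 1.2)
  direct <- conc_profile(p_eq, dose_events(0, 120 * 1000), tt)
  expect_equal(with_model$conc, direct$conc, tolerance = 1e-10)
})

test_that("auc_last implements the linear trapezoidal rule without extrapolation", {
  expect_equal(auc_last(c(0, 4), c(3, 3)), 12)
  expect_equal(auc_last(c(0, 1, 2), c(0, 2, 0)), 2)
  expect_equal(auc_last(5, 3), 0)  # single observation, degenerate interval
  expect_error(auc_last(c(2, 1), c(1, 1)), "increasing")
  # exact on piecewise-linear profiles
  tt <- c(0, 1, 2.5, 4, 7)
  cc <- c(0, 4, 3, 3, 0)
  exact <- sum(diff(tt) * (cc[-1] + cc[-5]) / 2)
  expect_identical(auc_last(tt, cc), exact)
})

test_that("invalid inputs are rejected", {
  expect_error(pk_params(ka = 1, cl = -1, v1 = 1), "positive")
  expect_error(pk_params(ka = 1, cl = 1, v1 = 1, q = 0.5), "v2")
  expect_error(dose_events(-1, 1), ">= 0")
  expect_error(dose_events(0, 0), "> 0")
  p <- pk_params(ka = 1, cl = 1, v1 = 1)
  expect_error(conc_profile(p, dose_events(0, 1), c(-1, 2)), ">= 0")
  expect_error(conc_profile(p, dose_events(0, 1), c(2, 1)), "increasing")
})
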