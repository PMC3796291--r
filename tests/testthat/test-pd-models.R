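# Indirect-response systems and the double-delta transform.

zero_conc <- function(t) rep(0, length(t))

test_that("UACR turnover: steady state, disease rise and saturation limit", {
  # uacr0 = kin/kout is a fixed point under zero drug
  p <- uacr_irm_params(kin = 2, kout = 0.1, imax = 1, ic50 = 1, uacr0 = 20)
  tr <- simulate_uacr(p, zero_conc, t_grid = c(1, 5, 20))
  expect_equal(tr$uacr, rep(20, 3), tolerance = 1e-7)
  # untreated disease trajectory rises monotonically towards kin/kout
  p2 <- uacr_irm_params(kin = 2, kout = 0.1, imax = 1, ic50 = 1, uacr0 = 5)
  tr2 <- simulate_uacr(p2, zero_conc, t_grid = c(5, 15, 40, 120))
  expect_true(all(diff(tr2$uacr) > 0))
  expect_true(all(tr2$uacr < 20))
  expect_equal(tr2$uacr[4], 20, tolerance = 1e-4)
  # full inhibition at saturating concentration: pure exponential decay
  p3 <- uacr_irm_params(kin = 2, kout = 0.1, imax = 1, ic50 = 1, uacr0 = 10)
  tr3 <- simulate_uacr(p3, function(t) rep(1e9, length(t)), t_grid = 10)
  expect_equal(tr3$uacr, 10 * exp(-1), tolerance = 1e-6)
})

test_that("delta response: no input without drug, closed-form steady state and approach", {
  p <- delta_irm_params(kin_max = 1, kout = 0.5, ec50 = 2)
  expect_equal(simulate_delta_response(p, zero_conc, c(1, 10))$delta,
               c(0, 0), tolerance = 1e-10)
  # constant C = EC50: dss = kin_max * 0.5 / kout = 1
  cfun <- function(t) rep(2, length(t))
  tr <- simulate_delta_response(p, cfun, c(1 / 0.5, 40))
  expect_equal(tr$delta[2], 1, tolerance = 1e-6)
  expect_equal(tr$delta[1], 1 * (1 - exp(-1)), tolerance = 1e-6)
})

test_that("trajectories match a fine-step brute-force integrator within 0.1%", {
  cfun <- function(t) 5 * exp(-0.3 * t)
  pu <- uacr_irm_params(kin = 1.5, kout = 0.2, imax = 0.8, ic50 = 2,
                        uacr0 = 4)
  a <- simulate_uacr(pu, cfun, t_grid = c(2, 5, 10))$uacr
  b <- euler_irm("uacr", kin = 1.5, kout = 0.2, imax = 0.8, pot = 2, y0 = 4,
                 cfun = cfun, t_out = c(2, 5, 10), h = 5e-4)
  expect_lt(max(abs(a - b) / b), 1e-3)
  pd <- delta_irm_params(kin_max = 1.2, kout = 0.4, ec50 = 1.5)
  a2 <- simulate_delta_response(pd, cfun, t_grid = c(2, 5, 10))$delta
  b2 <- euler_irm("delta", kin = 1.2, kout = 0.4, pot = 1.5, y0 = 0,
                  cfun = cfun, t_out = c(2, 5, 10), h = 5e-4)
  expect_lt(max(abs(a2 - b2) / abs(b2)), 1e-3)
})

test_that("monotonicity in the driving concentration", {
  tg <- c(2, 6, 12)
  pu <- uacr_irm_params(kin = 2, kout = 0.15, imax = 0.9, ic50 = 3,
                        uacr0 = 5)
  lo <- simulate_uacr(pu, function(t) rep(1, length(t)), tg)$uacr
  hi <- simulate_uacr(pu, function(t) rep(10, length(t)), tg)$uacr
  expect_true(all(hi < lo))
  pd <- delta_irm_params(kin_max = 1, kout = 0.3, ec50 = 3)
  dlo <- simulate_delta_response(pd, function(t) rep(1, length(t)), tg)$delta
  dhi <- simulate_delta_response(pd, function(t) rep(10, length(t)), tg)$delta
  expect_true(all(dhi > dlo))
})

test_that("imax = 0 makes the UACR system concentration-independent", {
  p0 <- uacr_irm_params(kin = 2, kout = 0.1, imax = 0, ic50 = 1, uacr0 = 8)
  tg <- c(3, 9, 18)
  a <- simulate_uacr(p0, zero_conc, tg)$uacr
  b <- simulate_uacr(p0, function(t) rep(500, length(t)), tg)$uacr
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("negative driving concentrations are rejected", {
  pu <- uacr_irm_params(kin = 1, kout = 0.1, imax = 1, ic50 = 1, uacr0 = 5)
  expect_error(simulate_uacr(pu, function(t) rep(-1, length(t)), 1:3),
               "negative")
  pd <- delta_irm_params(kin_max = 1, kout = 0.1, ec50 = 1)
  expect_error(simulate_delta_response(pd, function(t) -t, 1:3), "negative")
})

test_that("double-delta transform: arithmetic, anchoring and invariances", {
  veh <- data.frame(time = c(0, 14, 27), value = c(4.0, 3.8, 3.6))
  subj <- data.frame(time = c(0, 14, 27), value = c(4.2, 4.5, 4.4))
  dd <- double_delta(subj, veh)
  expect_identical(dd$delta[dd$time == 0], 0)
  expect_equal(dd$delta[dd$time == 14], (4.5 - 4.2) - (3.8 - 4.0))
  # identical series -> all zeros
  expect_equal(double_delta(veh, veh)$delta, c(0, 0, 0))
  # constant vehicle -> plain change from baseline
  vc <- data.frame(time = c(0, 14, 27), value = rep(4, 3))
  expect_equal(double_delta(subj, vc)$delta, subj$value - subj$value[1])
  # invariance to adding a constant to both series
  dd2 <- double_delta(transform(subj, value = value + 7),
                      transform(veh, value = value + 7))
  expect_equal(dd2$delta, dd$delta)
  # vehicle interpolated at unsampled subject times
  s2 <- data.frame(time = c(0, 7), value = c(4.2, 4.3))
  d3 <- double_delta(s2, veh)
  expect_equal(d3$delta[2], (4.3 - 4.2) - (3.9 - 4.0))
})

test_that("double-delta input validation", {
  veh <- data.frame(time = c(0, 14), value = c(4, 3.8))
  expect_error(double_delta(data.frame(time = c(7, 14), value = c(1, 2)),
                            veh), "time-0")
  expect_error(double_delta(data.frame(time = c(0, 14), value = c(1, 2)),
                            data.frame(time = c(7, 14), value = c(1, 2))),
               "time-0")
  expect_error(double_delta(data.frame(time = c(0, 30), value = c(1, 2)),
                            veh), "cover")
})

test_that("vehicle_reference pools animals (and studies) by arithmetic mean", {
  obs <- data.frame(ID = rep(1:3, each = 2),
                    TIME = rep(c(0, 14), 3),
                    DV = c(4, 3.8, 4.2, 4.0, 4.4, 4.2))
  vr <- vehicle_reference(obs)
  expect_equal(vr$value, c(mean(c(4, 4.2, 4.4)), mean(c(3.8, 4.0, 4.2))))
  # single animal: reference equals the animal's series
  one <- vehicle_reference(obs[obs$ID == 2, ])
  expect_equal(one$value, c(4.2, 4.0))
  expect_error(vehicle_reference(obs[0, ]), "empty")
})
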