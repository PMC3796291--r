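# Synthetic-study generators: design compliance, determinism, noise-off
# exactness and qualitative dose-response structure.

test_that("the default chronic design enumerates 5 groups of 11 per study", {
  d <- nf_chronic()
  per_subject <- d[!duplicated(d$ID), ]
  counts <- table(per_subject$GROUP)
  expect_equal(length(counts), 10L)  # two studies x 5 arms
  expect_true(all(counts == 11))
  expect_equal(sum(grepl("^A:", per_subject$GROUP)), 55)
  expect_equal(sum(grepl("^B:", per_subject$GROUP)), 55)
})

test_that("generators are byte-identical under the same seed", {
  des <- chronic_design(n_per_group = 2)
  a <- generate_chronic_study(des, seed = 17)
  b <- generate_chronic_study(des, seed = 17)
  expect_identical(a, b)
  c1 <- generate_acute_study(seed = 23)
  c2 <- generate_acute_study(seed = 23)
  expect_identical(c1, c2)
  expect_false(identical(a, generate_chronic_study(des, seed = 18)))
})

test_that("default truth carries the published potencies and properties", {
  tr <- default_truth()
  expect_equal(tr$pd$uacr$ic50[["PF-03882845"]], 10.4)
  expect_equal(tr$pd$uacr$ic50[["eplerenone"]], 671)
  expect_equal(tr$pd$delta_k$ec50[["PF-03882845"]], 874)
  expect_equal(tr$pd$delta_k$ec50[["eplerenone"]], 988)
  expect_equal(tr$pd$nak$ec50[["PF-03882845"]], 3.10)
  expect_equal(tr$props[["PF-03882845"]]$fu, 0.0038)
  expect_equal(tr$props[["eplerenone"]]$ic50_invitro, 109)
})

test_that("with noise and variability off every observation equals the model prediction", {
  d <- nf_chronic()
  tr <- noise_free_truth()
  # concentration samples reproduce the exact profile for a treated animal
  id <- d$ID[d$GROUP == "B:d5" & d$EVID == 1][1]
  sub <- d[d$ID == id, ]
  pk <- tr$pk[["PF-03882845"]]$chronic
  p <- pk_params(ka = pk$ka, cl = pk$cl, v1 = pk$v1, q = pk$q, v2 = pk$v2,
                 cl_induced = pk$cl * pk$ind_fold)
  conc_obs <- sub[sub$EVID == 0 & sub$CMT == 1, ]
  pr <- conc_profile(p, dose_events(sub$TIME[sub$EVID == 1],
                                    rep(5 * 2273, sum(sub$EVID == 1))),
                     conc_obs$TIME, method = "ode")
  expect_equal(as.numeric(conc_obs$DV), pr$conc, tolerance = 1e-6)
  # vehicle-aldosterone UACR follows the untreated turnover trajectory
  vid <- d$ID[d$GROUP == "A:veh_aldo"][1]
  vobs <- d[d$ID == vid & d$CMT == 2, ]
  pu <- tr$pd$uacr
  up <- uacr_irm_params(pu$kin, pu$kout, pu$imax, 1, pu$uacr0_mean)
  traj <- simulate_uacr(up, function(t) rep(0, length(t)),
                        vobs$TIME / 24)$uacr
  expect_equal(as.numeric(vobs$DV), traj, tolerance = 1e-7)
  # sham animals stay at their baseline
  sid <- d$ID[d$GROUP == "A:veh_sham"][1]
  sobs <- d[d$ID == sid & d$CMT == 2, ]
  expect_equal(as.numeric(sobs$DV), rep(pu$uacr0_mean, 3))
})

test_that("acute urine observations sit at the interval midpoints with zeroed vehicle deltas", {
  des <- acute_design(n_per_group = 2)
  a <- generate_acute_study(des, noise_free_truth(), seed = 4)
  nak <- a[a$CMT == 4 & a$EVID == 0, ]
  expect_setequal(unique(nak$TIME), c(0, 1, 3, 5.5))
  # noise off: every vehicle animal's double delta is identically zero
  veh <- nak[grepl(":veh$", nak$GROUP), ]
  vr <- vehicle_reference(data.frame(time = veh$TIME, value = veh$DV))
  for (id in unique(veh$ID)) {
    one <- veh[veh$ID == id, ]
    dd <- double_delta(data.frame(time = one$TIME, value = one$DV), vr)
    expect_equal(dd$delta, rep(0, nrow(one)))
  }
  # plasma sampling design: 0, 1, 2, 4, 7 h
  pl <- a[a$CMT == 1 & a$EVID == 0, ]
  expect_setequal(unique(pl$TIME), c(0, 1, 2, 4, 7))
})

test_that("noise-free group-mean responses are monotone in dose (qualitative in-vivo pattern)", {
  d <- nf_chronic()
  last_uacr <- d[d$CMT == 2 & d$TIME == max(d$TIME[d$CMT == 2]), ]
  gm <- tapply(as.numeric(last_uacr$DV), last_uacr$GROUP, mean)
  # UACR falls monotonically with dose for each drug, below vehicle-aldo
  expect_true(gm[["A:d15"]] > gm[["A:d50"]])
  expect_true(gm[["A:d50"]] > gm[["A:d450"]])
  expect_true(gm[["B:d5"]] > gm[["B:d15"]])
  expect_true(gm[["B:d15"]] > gm[["B:d50"]])
  expect_true(all(gm[c("A:d15", "A:d450", "B:d5", "B:d50")] <
                    gm[["A:veh_aldo"]]))
  # equal doses: PF-03882845 suppresses UACR more than eplerenone
  expect_lt(gm[["B:d15"]], gm[["A:d15"]])
  expect_lt(gm[["B:d50"]], gm[["A:d50"]])
})

test_that("generated datasets round-trip losslessly through the io module", {
  des <- chronic_design(n_per_group = 1)
  d <- generate_chronic_study(des, seed = 33)
  path <- tempfile(fileext = ".csv")
  write_dataset(d, path)
  r <- read_dataset(path)
  attributes(d) <- attributes(d)[c("names", "class", "row.names")]
  rownames(d) <- rownames(r) <- NULL
  expect_equal(r, d, tolerance = 1e-12)
})
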