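# Two-stage estimation: individual PK fits, pooled PD fits, bootstrap.

simple_props <- function() drug_properties(fu = 0.5, ic50_invitro = 1,
                                           nmol_per_mg = 1000, name = "X")

# one subject's noise-free records from a known one-compartment truth
make_subject <- function(truth = list(ka = 1.2, cl = 0.8, v1 = 1.5),
                         times = c(0.25, 0.5, 1, 2, 3, 5, 8, 12, 18, 24),
                         noise_cv = 0, seed = 1) {
  p <- pk_params(ka = truth$ka, cl = truth$cl, v1 = truth$v1)
  d_mg <- 10
  pr <- conc_profile(p, dose_events(0, d_mg * 1000), times)
  dv <- pr$conc
  if (noise_cv > 0) {
    set.seed(seed)
    dv <- dv * (1 + rnorm(length(dv), 0, noise_cv))
  }
  list(doses = data.frame(time = 0, amt = d_mg, dur = 0),
       obs = data.frame(time = times, dv = dv))
}

test_that("noise-free individual PK fit recovers the truth within 0.1%", {
  st <- pk_structure(1, "depot", props = simple_props(),
                     estimate = c("ka", "cl", "v1"))
  f <- fit_pk_individual(make_subject(), st,
                         init = c(ka = 1, cl = 1, v1 = 1),
                         n_restarts = 5, seed = 2)
  # the one-compartment depot model has the classic flip-flop twin optimum
  # (ka and ke exchanged, volume rescaled) with an identical concentration
  # curve, so compare the identifiable quantities: clearance and the
  # unordered {ka, ke} pair
  expect_lt(abs(f$estimates[["cl"]] / 0.8 - 1), 1e-3)
  rates <- sort(c(f$estimates[["ka"]],
                  f$estimates[["cl"]] / f$estimates[["v1"]]))
  expect_lt(max(abs(rates / sort(c(1.2, 0.8 / 1.5)) - 1)), 1e-3)
  # and the fitted curve reproduces the data
  pfit <- pk_params(ka = f$estimates[["ka"]], cl = f$estimates[["cl"]],
                    v1 = f$estimates[["v1"]])
  sub <- make_subject()
  pred <- conc_profile(pfit, dose_events(0, 10 * 1000), sub$obs$time)$conc
  expect_lt(max(abs(pred / sub$obs$dv - 1)), 1e-3)
  expect_true(is.finite(f$objective))
  # asymptotic CI brackets the estimate for each parameter
  expect_true(all(f$ci$lower <= unname(f$estimates[f$ci$param]) + 1e-8))
  expect_true(all(f$ci$upper >= unname(f$estimates[f$ci$param]) - 1e-8))
})

test_that("under-determined fits fail loudly", {
  sub <- make_subject(times = c(1, 4))
  st <- pk_structure(1, "depot", props = simple_props(),
                     estimate = c("ka", "cl", "v1"))
  expect_error(fit_pk_individual(sub, st,
                                 init = c(ka = 1, cl = 1, v1 = 1)),
               "under-determined")
})

test_that("with 20% proportional noise the median CL error over 200 subjects is below 10%", {
  st <- pk_structure(1, "depot", props = simple_props(),
                     estimate = c("ka", "cl", "v1"))
  err <- vapply(1:200, function(i) {
    sub <- make_subject(noise_cv = 0.2, seed = 100 + i)
    f <- fit_pk_individual(sub, st, init = c(ka = 1, cl = 1, v1 = 1),
                           n_restarts = 1, seed = i, compute_ci = FALSE)
    abs(f$estimates[["cl"]] / 0.8 - 1)
  }, numeric(1))
  expect_lt(median(err), 0.1)
})

# a reduced two-drug chronic study with identical PK and drug properties for
# both drugs (so the only drug difference is the UACR potency); PK carried at
# truth to isolate the pooled PD fit
twin_truth <- function() {
  tr <- default_truth()
  shared_pk <- list(ka = 1.2, cl = 2, v1 = 1.5, q = 0, v2 = NA_real_,
                    ind_fold = 1.6, induction_start = 24,
                    induction_end = 168, absorption = "depot", dur = 0)
  tr$pk[["PF-03882845"]]$chronic <- shared_pk
  tr$pk[["eplerenone"]]$chronic <- shared_pk
  pp <- drug_properties(fu = 0.5, ic50_invitro = 1, nmol_per_mg = 2000)
  tr$props <- list("PF-03882845" = pp, "eplerenone" = pp)
  tr$pd$uacr$ic50 <- c("PF-03882845" = 40, "eplerenone" = 900)
  noise_free_truth(tr)
}

truth_pk_table <- function(data, truth) {
  ids <- unique(data$ID[data$EVID == 1])
  do.call(rbind, lapply(ids, function(id) {
    drug <- unique(stats::na.omit(data$DRUG[data$ID == id]))
    p <- truth$pk[[drug]]$chronic
    data.frame(ID = id, DRUG = drug, GROUP = data$GROUP[data$ID == id][1],
               DOSE = data$DOSE[data$ID == id][1],
               ka = p$ka, cl = p$cl, v1 = p$v1, q = p$q, v2 = p$v2,
               ind_fold = p$ind_fold, induction_start = p$induction_start,
               induction_end = p$induction_end, converged = TRUE,
               objective = 0, n_obs = 10, stringsAsFactors = FALSE)
  }))
}

twin_fixture <- function() {
  if (is.null(.fixture_env$twin)) {
    tr <- twin_truth()
    d <- generate_chronic_study(chronic_design(n_per_group = 3), tr, seed = 8)
    .fixture_env$twin <- list(truth = tr, data = d,
                              pk = truth_pk_table(d, tr))
  }
  .fixture_env$twin
}

test_that("pooled noise-free PD fit recovers shared parameters and both potencies within 1%", {
  fx <- twin_fixture()
  fit <- fit_pd_pooled(fx$data, fx$pk, "uacr", fx$truth$props, seed = 3,
                       n_restarts = 2, compute_ci = FALSE)
  tr <- fx$truth$pd$uacr
  expect_lt(abs(fit$estimates[["kin"]] / tr$kin - 1), 0.01)
  expect_lt(abs(fit$estimates[["kout"]] / tr$kout - 1), 0.01)
  expect_lt(abs(fit$estimates[["imax"]] / tr$imax - 1), 0.01)
  expect_lt(abs(fit$estimates[["ic50_PF-03882845"]] / 40 - 1), 0.01)
  expect_lt(abs(fit$estimates[["ic50_eplerenone"]] / 900 - 1), 0.01)
  # profiled per-animal baselines are reported and near the common truth
  expect_equal(nrow(fit$baseline), fit$n_subjects)
  expect_lt(max(abs(fit$baseline$uacr0 / 30 - 1)), 0.02)
})

test_that("swapping the drug labels swaps the potency estimates", {
  fx <- twin_fixture()
  fit1 <- fit_pd_pooled(fx$data, fx$pk, "uacr", fx$truth$props, seed = 3,
                        n_restarts = 1, compute_ci = FALSE)
  swap <- function(x) {
    y <- x
    y[x == "PF-03882845"] <- "eplerenone"
    y[x == "eplerenone"] <- "PF-03882845"
    y
  }
  d2 <- fx$data
  d2$DRUG <- swap(d2$DRUG)
  pk2 <- fx$pk
  pk2$DRUG <- swap(pk2$DRUG)
  fit2 <- fit_pd_pooled(d2, pk2, "uacr", fx$truth$props, seed = 3,
                        n_restarts = 1, compute_ci = FALSE)
  expect_equal(fit2$estimates[["ic50_eplerenone"]],
               fit1$estimates[["ic50_PF-03882845"]], tolerance = 1e-6)
  expect_equal(fit2$estimates[["ic50_PF-03882845"]],
               fit1$estimates[["ic50_eplerenone"]], tolerance = 1e-6)
  expect_equal(fit2$estimates[["kin"]], fit1$estimates[["kin"]],
               tolerance = 1e-6)
})

test_that("the PD stage never modifies the stage-1 PK parameters", {
  fx <- twin_fixture()
  pk_before <- fx$pk
  invisible(fit_pd_pooled(fx$data, fx$pk, "uacr", fx$truth$props, seed = 1,
                          n_restarts = 1, compute_ci = FALSE))
  expect_identical(fx$pk, pk_before)
})

test_that("estimates are invariant to the ordering of subjects in the table", {
  fx <- twin_fixture()
  fit1 <- fit_pd_pooled(fx$data, fx$pk, "uacr", fx$truth$props, seed = 3,
                        n_restarts = 1, compute_ci = FALSE)
  ord <- order(-as.numeric(fx$data$ID), fx$data$TIME)
  d2 <- fx$data[ord, ]
  pk2 <- fx$pk[order(-as.numeric(fx$pk$ID)), ]
  fit2 <- fit_pd_pooled(d2, pk2, "uacr", fx$truth$props, seed = 3,
                        n_restarts = 1, compute_ci = FALSE)
  expect_equal(fit2$estimates, fit1$estimates, tolerance = 1e-6)
})

test_that("bootstrap CIs are reproducible, degenerate on constant data, and validated", {
  d <- data.frame(ID = 1:12, TIME = 0, AMT = NA, RATE = NA,
                  DV = rep(5, 12), EVID = 0, MDV = 0, CMT = 2, DOSE = 0,
                  GROUP = rep(c("a:veh", "a:d1"), 6), DRUG = NA)
  fit_fun <- function(dd) c(mu = mean(dd$DV))
  b1 <- bootstrap_ci(fit_fun, d, n_boot = 25, seed = 42)
  b2 <- bootstrap_ci(fit_fun, d, n_boot = 25, seed = 42)
  expect_identical(b1$ci, b2$ci)
  expect_identical(b1$replicates, b2$replicates)
  # zero-variability data: zero-width interval at the point estimate
  expect_equal(b1$ci$lower, 5)
  expect_equal(b1$ci$upper, 5)
  expect_error(bootstrap_ci(fit_fun, d, n_boot = 1), "n_boot")
})

test_that("nominal 95% bootstrap CIs cover the truth at close to nominal rate", {
  n_sub <- 60
  n_rep <- 250
  mu <- 3
  cover <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(5000 + r)
    d <- data.frame(ID = seq_len(n_sub), TIME = 0, AMT = NA, RATE = NA,
                    DV = rnorm(n_sub, mu, 1), EVID = 0, MDV = 0, CMT = 2,
                    DOSE = 0, GROUP = "s:veh", DRUG = NA)
    b <- bootstrap_ci(function(dd) c(mu = mean(dd$DV)), d, n_boot = 399,
                      seed = r)
    cover[r] <- b$ci$lower <= mu && mu <= b$ci$upper
  }
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})
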