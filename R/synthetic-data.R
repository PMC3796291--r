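# Synthetic-study generator.
#
# Emulates the two chronic 27-day uninephrectomised aldosterone-salt rat
# studies (study A: eplerenone; study B: PF-03882845; 5 groups x n = 11 each,
# BID oral dosing at 6 am / 4 pm giving alternating 10 h / 14 h intervals,
# sparse PK sampling on days 1/14/26/27, UACR on days 0/14/25, serum K+ on
# days 0/14/27) and the acute urinary Na+/K+ study (single dose at 8 am,
# urine intervals 0-2 / 2-4 / 4-7 h timestamped at their midpoints, plasma at
# 0/1/2/4/7 h).  Group labels follow the convention "<study>:<arm>" with arms
# "veh_sham", "veh_aldo", "veh" and "d<dose>".

.BID_OFFSETS <- c(0, 10)  # 6 am and 4 pm, hours after the first daily dose

.bid_times <- function(days) {
  sort(as.vector(outer((seq_len(days) - 1) * 24, .BID_OFFSETS, `+`)))
}

#' Chronic 27-day study design
#'
#' Default design: two studies of 5 groups x 11 animals (vehicle-sham,
#' vehicle-aldosterone, and three BID dose groups per drug), aldosterone
#' infusion in all non-sham groups, dosing at 6 am / 4 pm for 27 days, PK
#' samples at 1/2/4/7 h on days 1 and 26, 7 h post-dose on day 14 and ~16 h
#' after the final dose, UACR on days 0/14/25 and serum K+ on days 0/14/27.
#'
#' @param n_per_group animals per group (default 11).
#' @param days treatment duration in days (default 27).
#' @export
chronic_design <- function(n_per_group = 11, days = 27) {
  if (n_per_group < 1) .stopf("n_per_group must be >= 1")
  dose_times <- .bid_times(days)
  last_dose <- max(dose_times)
  terminal <- last_dose + 16
  pk_times <- c(1, 2, 4, 7,                 # day 1
                13 * 24 + 7,                # day 14, 7 h post first daily dose
                25 * 24 + c(1, 2, 4, 7),    # day 26
                terminal)                   # day 27 necropsy
  uacr_times <- c(0, 14, 25) * 24
  k_times <- c(0, 13 * 24 + 7, terminal)
  t_end <- terminal
  if (any(c(pk_times, uacr_times, k_times) > t_end)) {
    .stopf("sampling schedule extends beyond the study length")
  }
  structure(list(
    kind = "chronic",
    studies = list(
      A = list(drug = "eplerenone", doses = c(15, 50, 450)),
      B = list(drug = "PF-03882845", doses = c(5, 15, 50))
    ),
    n_per_group = n_per_group,
    days = days,
    dose_times = dose_times,
    pk_times = pk_times,
    uacr_times = uacr_times,
    k_times = k_times,
    t_end = t_end
  ), class = "study_design")
}

#' Acute urinary Na+/K+ study design
#'
#' Default design: two single-dose studies (eplerenone 5/30/300 mg/kg,
#' PF-03882845 3/10/30 mg/kg, each with a vehicle group), urine collected over
#' 0-2, 2-4 and 4-7 h post dose (observations timestamped at the interval
#' midpoints 1, 3 and 5.5 h plus a time-0 baseline), plasma at 0/1/2/4/7 h.
#'
#' @param n_per_group animals per group; the acute group size is not a
#'   reported design parameter, 6 is this package's documented choice.
#' @export
acute_design <- function(n_per_group = 6) {
  if (n_per_group < 1) .stopf("n_per_group must be >= 1")
  iv <- rbind(c(0, 2), c(2, 4), c(4, 7))
  structure(list(
    kind = "acute",
    studies = list(
      epl = list(drug = "eplerenone", doses = c(5, 30, 300)),
      pf = list(drug = "PF-03882845", doses = c(3, 10, 30))
    ),
    n_per_group = n_per_group,
    plasma_times = c(0, 1, 2, 4, 7),
    urine_intervals = iv,
    urine_midpoints = rowMeans(iv),
    t_end = 7
  ), class = "study_design")
}

#' Default simulation truth
#'
#' The study conditions used by the generators.  Potencies are the published
#' chronic total-concentration estimates (UACR IC50 10.4 nM for PF-03882845
#' and 671 nM for eplerenone; serum-K+ EC50 874 and 988 nM) and the acute
#' normalised EC50s (3.10 and 5.92); unbound fractions (0.0038 / 0.68) and
#' in-vitro potencies (0.75 / 109 nM) match the drugs' reported properties.
#' Turnover rates, baseline distributions, between-animal CVs, residual error
#' magnitudes and molar conversion factors are artifact choices documented in
#' the methods vignette (chosen so the untreated aldosterone group roughly
#' triples its UACR by day 26 and the dose groups' exposures bracket the
#' potencies).
#'
#' @return object of class `sim_truth`.
#' @export
default_truth <- function() {
  structure(list(
    props = list(
      "PF-03882845" = drug_properties(fu = 0.0038, ic50_invitro = 0.75,
                                      nmol_per_mg = 2273,
                                      name = "PF-03882845"),
      "eplerenone" = drug_properties(fu = 0.68, ic50_invitro = 109,
                                     nmol_per_mg = 2413,
                                     name = "eplerenone")
    ),
    pk = list(
      "PF-03882845" = list(
        chronic = list(ka = 1.5, cl = 2, v1 = 1.5, q = 0.5, v2 = 2,
                       ind_fold = 1.8, induction_start = 24,
                       induction_end = 168, absorption = "depot", dur = 0),
        acute = list(ka = 1.5, cl = 2, v1 = 1.5, q = 0, v2 = NA_real_,
                     ind_fold = 1, absorption = "depot", dur = 0)
      ),
      "eplerenone" = list(
        chronic = list(ka = 1.2, cl = 3, v1 = 1.5, q = 0, v2 = NA_real_,
                       ind_fold = 1.8, induction_start = 24,
                       induction_end = 168, absorption = "depot", dur = 0),
        acute = list(ka = 1, cl = NA_real_, v1 = 1, q = 0.5, v2 = 2,
                     ind_fold = 1, absorption = "zero_order", dur = 1,
                     cl_dose = list(theta1 = 3, reference_dose = 30,
                                    pwr = 0.3))
      )
    ),
    bsv_cv = c(ka = 0.25, cl = 0.25, v1 = 0.25),
    pd = list(
      uacr = list(kin = 6, kout = 0.06, imax = 0.9,        # per day
                  ic50 = c("PF-03882845" = 10.4, "eplerenone" = 671),
                  uacr0_mean = 30, uacr0_cv = 0.3),
      delta_k = list(kin_max = 0.25, kout = 0.2,           # per day
                     ec50 = c("PF-03882845" = 874, "eplerenone" = 988),
                     k_baseline_mean = 4.4, k_baseline_sd = 0.15,
                     vehicle_k_drop = 0.4),
      nak = list(kin_max = 1.5, kout = 0.35,               # per hour
                 ec50 = c("PF-03882845" = 3.10, "eplerenone" = 5.92),
                 baseline_mean = 3.5, baseline_sd = 0.3)
    ),
    sigma = list(conc = 0.15, uacr = 0.25, serum_k = 0.15, nak = 0.4)
  ), class = "sim_truth")
}

#' Remove all stochastic components from a simulation truth
#'
#' Sets residual error magnitudes, between-animal PK CVs and all baseline
#' variability to zero so the generators become fully deterministic: every
#' observation equals the model prediction.
#'
#' @param truth a `sim_truth` object.
#' @export
noise_free_truth <- function(truth = default_truth()) {
  truth$bsv_cv[] <- 0
  truth$pd$uacr$uacr0_cv <- 0
  truth$pd$delta_k$k_baseline_sd <- 0
  truth$pd$nak$baseline_sd <- 0
  truth$sigma <- lapply(truth$sigma, function(x) 0)
  truth
}

# draw subject-level PK parameters (log-normal around the typical values)
.draw_pk <- function(tpk, cv) {
  p <- tpk
  for (nm in c("ka", "cl", "v1")) {
    if (!is.na(p[[nm]]) && cv[[nm]] > 0) {
      p[[nm]] <- p[[nm]] * exp(stats::rnorm(1, 0, cv[[nm]]))
    }
  }
  p
}

.pk_params_from_list <- function(p) {
  pk_params(ka = p$ka, cl = p$cl, v1 = p$v1, q = p$q %||% 0,
            v2 = p$v2 %||% NA_real_,
            cl_induced = p$cl * (p$ind_fold %||% 1),
            induction_start = p$induction_start %||% 24,
            induction_end = p$induction_end %||% 168)
}

.row_block <- function(id, time, amt, rate, dv, evid, mdv, cmt, dose, group,
                       drug) {
  n <- length(time)
  data.frame(ID = rep_len(id, n), TIME = time,
             AMT = rep_len(amt, n), RATE = rep_len(rate, n),
             DV = rep_len(dv, n), EVID = rep_len(evid, n),
             MDV = rep_len(mdv, n), CMT = rep_len(cmt, n),
             DOSE = rep_len(dose, n), GROUP = rep_len(group, n),
             DRUG = rep_len(drug, n), stringsAsFactors = FALSE)
}

.prop_noise <- function(x, cv) {
  if (cv <= 0) return(x)
  pmax(x * (1 + stats::rnorm(length(x), 0, cv)), 0.01 * abs(x))
}

.add_noise <- function(x, sd) {
  if (sd <= 0) return(x)
  x + stats::rnorm(length(x), 0, sd)
}

#' Generate a chronic two-study dataset
#'
#' Simulates dose events and observations for the default chronic design:
#' per-animal concentration samples (proportional error), UACR trajectories
#' from the turnover model (proportional error; vehicle-aldosterone animals
#' follow the untreated rising trajectory, sham animals stay at baseline) and
#' raw serum K+ (additive error; an aldosterone-driven decline plus the
#' drug-induced delta response).
#'
#' @param design a [chronic_design()].
#' @param truth a [default_truth()]-shaped `sim_truth`.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return a NONMEM-style data.frame (see [read_dataset()] for the column
#'   contract) with the truth and seed attached as attributes.
#' @export
generate_chronic_study <- function(design = chronic_design(),
                                   truth = default_truth(), seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  if (design$kind != "chronic") .stopf("design must be a chronic design")
  .with_seed(seed, {
    rows <- list()
    id <- 0L
    grid <- sort(unique(c(seq(0, design$t_end, by = 0.25), design$t_end,
                          design$dose_times, design$pk_times,
                          design$uacr_times, design$k_times)))
    pdU <- truth$pd$uacr
    pdK <- truth$pd$delta_k
    for (study in names(design$studies)) {
      st <- design$studies[[study]]
      props <- truth$props[[st$drug]]
      if (is.null(props)) .stopf("no drug properties for '%s'", st$drug)
      tpk <- truth$pk[[st$drug]]$chronic
      arms <- c("veh_sham", "veh_aldo", paste0("d", st$doses))
      arm_dose <- c(0, 0, st$doses)
      # draw every animal's random effects first, then solve the PK and PD
      # systems for the whole study in batched lsoda calls
      roster <- list()
      for (a in seq_along(arms)) {
        for (k in seq_len(design$n_per_group)) {
          id <- id + 1L
          dose <- arm_dose[a]
          u0 <- pdU$uacr0_mean *
            exp(if (pdU$uacr0_cv > 0) stats::rnorm(1, 0, pdU$uacr0_cv) else 0)
          k0 <- stats::rnorm(1, pdK$k_baseline_mean, pdK$k_baseline_sd)
          roster[[length(roster) + 1L]] <- list(
            id = id, arm = arms[a], dose = dose, treated = dose > 0,
            aldo = arms[a] != "veh_sham",
            group = paste0(study, ":", arms[a]),
            u0 = u0, k0 = k0,
            pk = if (dose > 0) .draw_pk(tpk, truth$bsv_cv) else NULL)
        }
      }
      n_st <- length(roster)
      treated_i <- which(vapply(roster, `[[`, TRUE, "treated"))
      aldo_i <- which(vapply(roster, `[[`, TRUE, "aldo"))
      conc_tab <- matrix(0, n_st, length(grid))
      if (length(treated_i)) {
        tab <- do.call(rbind, lapply(roster[treated_i], function(r) {
          data.frame(ka = r$pk$ka, cl = r$pk$cl, v1 = r$pk$v1,
                     q = r$pk$q %||% 0, v2 = r$pk$v2 %||% NA_real_,
                     ind_fold = r$pk$ind_fold %||% 1)
        }))
        amt <- vapply(roster[treated_i], `[[`, 0, "dose") * props$nmol_per_mg
        conc_tab[treated_i, ] <- .conc_ode_multi(
          tab, design$dose_times, amt, grid,
          induction_start = tpk$induction_start,
          induction_end = tpk$induction_end)
      }
      # UACR trajectories for all aldosterone-infused animals (days)
      uacr_tab <- matrix(NA_real_, n_st, length(design$uacr_times))
      if (length(aldo_i)) {
        pot <- vapply(roster[aldo_i], function(r) {
          if (r$treated) pdU$ic50[[st$drug]] else 1
        }, numeric(1))
        u0v <- vapply(roster[aldo_i], `[[`, 0, "u0")
        uacr_tab[aldo_i, ] <- .irm_multi(
          "uacr", kin = pdU$kin, kout = pdU$kout, imax = pdU$imax,
          pot = pot, u0 = u0v, ct = grid / 24,
          conc_mat = conc_tab[aldo_i, , drop = FALSE],
          t_out = design$uacr_times / 24)
      }
      # drug-induced serum-K+ delta for treated animals (days)
      dk_tab <- matrix(0, n_st, length(design$k_times))
      if (length(treated_i)) {
        potk <- rep(pdK$ec50[[st$drug]], length(treated_i))
        dk_tab[treated_i, ] <- .irm_multi(
          "delta", kin = pdK$kin_max, kout = pdK$kout, imax = NA,
          pot = potk, u0 = NULL, ct = grid / 24,
          conc_mat = conc_tab[treated_i, , drop = FALSE],
          t_out = design$k_times / 24)
      }
      for (a in seq_len(n_st)) {
        r <- roster[[a]]
        drug_lbl <- if (r$treated) st$drug else NA_character_
        if (r$treated) {
          rows[[length(rows) + 1L]] <- .row_block(
            r$id, design$dose_times, r$dose, 0, NA_real_, 1, 1, 1, r$dose,
            r$group, drug_lbl)
          obs_c <- conc_tab[a, match(design$pk_times, grid)]
          rows[[length(rows) + 1L]] <- .row_block(
            r$id, design$pk_times, NA_real_, NA_real_,
            .prop_noise(obs_c, truth$sigma$conc), 0, 0, 1, r$dose, r$group,
            drug_lbl)
        }
        traj <- if (r$aldo) uacr_tab[a, ] else
          rep(r$u0, length(design$uacr_times))
        rows[[length(rows) + 1L]] <- .row_block(
          r$id, design$uacr_times, NA_real_, NA_real_,
          .prop_noise(traj, truth$sigma$uacr), 0, 0, 2, r$dose, r$group,
          drug_lbl)
        kdrift <- if (r$aldo) {
          -pdK$vehicle_k_drop * design$k_times / design$t_end
        } else {
          rep(0, length(design$k_times))
        }
        kraw <- r$k0 + kdrift + dk_tab[a, ]
        rows[[length(rows) + 1L]] <- .row_block(
          r$id, design$k_times, NA_real_, NA_real_,
          .add_noise(kraw, truth$sigma$serum_k), 0, 0, 3, r$dose, r$group,
          drug_lbl)
      }
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$ID, out$TIME, -out$EVID), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "truth") <- truth
    attr(out, "seed") <- seed
    attr(out, "design") <- design
    out
  })
}

#' Generate an acute urinary Na+/K+ dataset
#'
#' Single oral dose per animal; plasma samples at 0/1/2/4/7 h (proportional
#' error, zero before dosing) and urinary Na+/K+ ratios at the urine-interval
#' midpoints 1/3/5.5 h plus a time-0 baseline (additive error).  The drug
#' drive of the Na+/K+ delta response is the free plasma concentration
#' normalised to the drug's in-vitro potency, so the EC50 truth is
#' dimensionless.  Vehicle animals have zero drug drive.
#'
#' @inheritParams generate_chronic_study
#' @param design an [acute_design()].
#' @export
generate_acute_study <- function(design = acute_design(),
                                 truth = default_truth(), seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  if (design$kind != "acute") .stopf("design must be an acute design")
  .with_seed(seed, {
    rows <- list()
    id <- 0L
    pdN <- truth$pd$nak
    mids <- design$urine_midpoints
    for (study in names(design$studies)) {
      st <- design$studies[[study]]
      props <- truth$props[[st$drug]]
      tpk <- truth$pk[[st$drug]]$acute
      arms <- c("veh", paste0("d", st$doses))
      arm_dose <- c(0, st$doses)
      for (a in seq_along(arms)) {
        arm <- arms[a]
        dose <- arm_dose[a]
        treated <- dose > 0
        group <- paste0(study, ":", arm)
        for (k in seq_len(design$n_per_group)) {
          id <- id + 1L
          drug_lbl <- if (treated) st$drug else NA_character_
          dnk <- rep(0, length(mids))
          if (treated) {
            p <- .draw_pk(tpk, truth$bsv_cv)
            if (!is.null(tpk$cl_dose)) {
              eta <- if (truth$bsv_cv[["cl"]] > 0) {
                stats::rnorm(1, 0, truth$bsv_cv[["cl"]])
              } else 0
              cdm <- cl_dose_model(theta1 = tpk$cl_dose$theta1,
                                   reference_dose = tpk$cl_dose$reference_dose,
                                   pwr = tpk$cl_dose$pwr, eta = eta)
              p$cl <- dose_dependent_clearance(cdm, dose)
            }
            pkp <- .pk_params_from_list(p)
            doses <- dose_events(0, dose, dur = tpk$dur)
            d_nmol <- doses
            d_nmol$amt <- d_nmol$amt * props$nmol_per_mg
            cfun <- function(t) .conc_analytic(pkp, d_nmol, t)
            rate <- if (tpk$dur > 0) dose / tpk$dur else 0
            rows[[length(rows) + 1L]] <- .row_block(
              id, 0, dose, rate, NA_real_, 1, 1, 1, dose, group, drug_lbl)
            obs_t <- design$plasma_times
            obs_c <- cfun(obs_t)
            rows[[length(rows) + 1L]] <- .row_block(
              id, obs_t, NA_real_, NA_real_,
              .prop_noise(obs_c, truth$sigma$conc), 0, 0, 1, dose, group,
              drug_lbl)
            # normalised free-concentration drive
            ufun <- function(t) cfun(t) * props$fu / props$ic50_invitro
            dp <- delta_irm_params(kin_max = pdN$kin_max, kout = pdN$kout,
                                   ec50 = pdN$ec50[[st$drug]])
            dnk <- simulate_delta_response(dp, ufun, mids)$delta
          }
          base <- stats::rnorm(1, pdN$baseline_mean, pdN$baseline_sd)
          nak_t <- c(0, mids)
          nak_v <- c(base, base + dnk)
          rows[[length(rows) + 1L]] <- .row_block(
            id, nak_t, NA_real_, NA_real_,
            .add_noise(nak_v, truth$sigma$nak), 0, 0, 4, dose, group,
            drug_lbl)
        }
      }
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$ID, out$TIME, -out$EVID), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "truth") <- truth
    attr(out, "seed") <- seed
    attr(out, "design") <- design
    out
  })
}
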