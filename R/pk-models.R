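#' Dose events
#'
#' Builds the event table describing oral (first-order depot) or zero-order
#' (constant-rate over a duration, emulating an observed absorption plateau)
#' dose administrations for one subject.
#'
#' @param time numeric vector, hours since first dose (>= 0).
#' @param amt numeric vector, dose amount per kg body weight (> 0). Units are
#'   nmol/kg unless a [drug_properties()] object is supplied to the consumer,
#'   in which case amounts are mg/kg and converted internally.
#' @param dur absorption duration in hours; `0` means first-order depot
#'   absorption, `> 0` means zero-order input over `dur` hours.
#' @return a `data.frame` of class `dose_events` with columns `time`, `amt`,
#'   `dur`.
#' @examples
#' dose_events(time = c(0, 10), amt = c(5, 5))
#' @export
dose_events <- function(time = numeric(), amt = numeric(), dur = 0) {
  if (length(time) != length(amt)) .stopf("time and amt must have equal length")
  dur <- rep_len(dur, length(time))
  if (any(time < 0)) .stopf("dose times must be >= 0")
  if (any(amt <= 0)) .stopf("dose amounts must be > 0")
  if (any(dur < 0)) .stopf("zero-order durations must be > 0 (or 0 for depot)")
  out <- data.frame(time = as.numeric(time), amt = as.numeric(amt),
                    dur = as.numeric(dur))
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dose_events", "data.frame")
  out
}

#' Compartmental PK parameters
#'
#' Parameter container for the one/two-compartment disposition models with
#' first-order elimination and (optionally) time-varying clearance.  Clearance
#' induction on repeated dosing is encoded as a linear ramp from `cl` to
#' `cl_induced` between `induction_start` and `induction_end` (hours); outside
#' the ramp clearance is constant.
#'
#' @param ka first-order absorption rate constant (1/h); unused for pure
#'   zero-order dosing but must be positive.
#' @param cl initial clearance (L/h/kg).
#' @param v1 central volume of distribution (L/kg).
#' @param q inter-compartmental flow (L/h/kg); `0` collapses the model to one
#'   compartment and `v2` is ignored.
#' @param v2 peripheral volume (L/kg), required when `q > 0`.
#' @param cl_induced post-induction clearance (L/h/kg); defaults to `cl`
#'   (no induction). Values above `cl` encode the loss of exposure on
#'   multiple dosing.
#' @param induction_start,induction_end hours bounding the induction ramp
#'   (defaults: day 1 to day 7).
#' @param f bioavailable fraction, fixed at 1 by default (apparent oral
#'   parameters; absolute F is not identifiable from oral data alone).
#' @return an object of class `pk_params`.
#' @seealso [clearance_at()], [conc_profile()]
#' @export
pk_params <- function(ka = 1, cl, v1, q = 0, v2 = NA_real_,
                      cl_induced = NULL, induction_start = 24,
                      induction_end = 168, f = 1) {
  cl_induced <- cl_induced %||% cl
  for (nm in c("ka", "cl", "v1", "cl_induced", "f")) {
    v <- get(nm)
    if (!.is_number(v) || v <= 0) .stopf("pk_params: %s must be a positive number", nm)
  }
  if (!.is_number(q) || q < 0) .stopf("pk_params: q must be >= 0")
  if (q > 0 && (!.is_number(v2) || v2 <= 0)) {
    .stopf("pk_params: v2 must be positive when q > 0")
  }
  if (induction_end < induction_start) {
    .stopf("pk_params: induction_end must be >= induction_start")
  }
  structure(list(ka = ka, cl = cl, v1 = v1, q = q, v2 = v2,
                 cl_induced = cl_induced,
                 induction_start = induction_start,
                 induction_end = induction_end, f = f),
            class = "pk_params")
}

#' Dose-dependent clearance power model
#'
#' Empirical covariate model `CL = theta1 * (reference_dose / dose)^pwr *
#' exp(eta)` describing a non-linear decrease of apparent clearance with dose
#' (`theta1` is the typical clearance at the reference dose; `eta` is a
#' subject-level log-scale deviation).
#'
#' @param theta1 clearance at the reference dose (L/h/kg).
#' @param reference_dose reference dose (mg/kg), 30 by default.
#' @param pwr dimensionless power exponent.
#' @param eta subject-level log-scale random effect (0 = typical subject).
#' @export
cl_dose_model <- function(theta1, reference_dose = 30, pwr = 0, eta = 0) {
  if (!.is_number(theta1) || theta1 <= 0) .stopf("theta1 must be > 0")
  if (!.is_number(reference_dose) || reference_dose <= 0) {
    .stopf("reference_dose must be > 0")
  }
  structure(list(theta1 = theta1, reference_dose = reference_dose,
                 pwr = pwr, eta = eta),
            class = "cl_dose_model")
}

#' Drug properties used for unit conversion and potency normalisation
#'
#' @param fu unbound (free) fraction in plasma, in (0, 1].
#' @param ic50_invitro in-vitro receptor potency (nM) from a serum-free
#'   functional assay.
#' @param nmol_per_mg molar conversion factor (nmol per mg of drug); required,
#'   no default.
#' @param name drug label used to match dataset `DRUG` codes.
#' @export
drug_properties <- function(fu, ic50_invitro, nmol_per_mg, name = NA_character_) {
  if (!.is_number(fu) || fu <= 0 || fu > 1) .stopf("fu must be in (0, 1]")
  if (!.is_number(ic50_invitro) || ic50_invitro <= 0) {
    .stopf("ic50_invitro must be > 0")
  }
  if (!.is_number(nmol_per_mg) || nmol_per_mg <= 0) {
    .stopf("nmol_per_mg must be > 0")
  }
  structure(list(fu = fu, ic50_invitro = ic50_invitro,
                 nmol_per_mg = nmol_per_mg, name = name),
            class = "drug_properties")
}

#' Clearance at a given time under the induction ramp
#'
#' Returns `cl` before `induction_start`, `cl_induced` after `induction_end`,
#' and the linear interpolation in between.
#'
#' @param params a [pk_params()] object.
#' @param t time in hours (vectorised), must be >= 0.
#' @export
clearance_at <- function(params, t) {
  stopifnot(inherits(params, "pk_params"))
  if (any(t < 0)) .stopf("clearance_at: t must be >= 0")
  s <- params$induction_start
  e <- params$induction_end
  if (e < s) .stopf("induction_end must be >= induction_start")
  if (e == s) {
    return(ifelse(t < s, params$cl, params$cl_induced))
  }
  frac <- pmin(pmax((t - s) / (e - s), 0), 1)
  params$cl + (params$cl_induced - params$cl) * frac
}

#' Dose-dependent clearance
#'
#' Evaluates the power model `theta1 * (reference_dose/dose)^pwr * exp(eta)`.
#'
#' @param model a [cl_dose_model()] object.
#' @param dose dose in mg/kg (> 0), vectorised.
#' @export
dose_dependent_clearance <- function(model, dose) {
  stopifnot(inherits(model, "cl_dose_model"))
  if (any(dose <= 0)) .stopf("dose must be > 0")
  model$theta1 * (model$reference_dose / dose)^model$pwr * exp(model$eta)
}

#' Plasma concentration-time profile
#'
#' Simulates the total plasma concentration profile (nM) resulting from a
#' sequence of dose events under a linear one- or two-compartment model by
#' superposition.  Time-invariant systems are evaluated with closed-form
#' solutions; profiles with an active clearance-induction ramp are integrated
#' numerically (lsoda).
#'
#' @param params a [pk_params()] object.
#' @param doses a [dose_events()] table. Amounts are nmol/kg, or mg/kg when
#'   `props` is supplied.
#' @param times strictly increasing observation times (hours, >= 0).
#' @param cl_dose optional [cl_dose_model()]; when present, each dose event
#'   decays under the clearance implied by its own dose level (requires
#'   `props` so dose levels are in mg/kg).
#' @param props optional [drug_properties()] used to convert mg/kg amounts to
#'   nmol/kg.
#' @param method `"auto"` (default: analytic when the system is
#'   time-invariant, numerical otherwise), `"analytic"` (closed forms; with an
#'   induction ramp each dose uses the clearance in force at its
#'   administration time), or `"ode"` (reference integrator).
#' @param rtol,atol integration tolerances for the ODE route.
#' @return `data.frame` of class `conc_profile` with columns `time`, `conc`.
#' @examples
#' p <- pk_params(ka = 1, cl = 0.5, v1 = 1)
#' conc_profile(p, dose_events(0, 1), times = c(0.5, 1, 2))
#' @export
conc_profile <- function(params, doses, times, cl_dose = NULL, props = NULL,
                         method = c("auto", "analytic", "ode"),
                         rtol = 1e-8, atol = 1e-12) {
  method <- match.arg(method)
  stopifnot(inherits(params, "pk_params"))
  if (!inherits(doses, "dose_events")) {
    .stopf("doses must be a dose_events() table")
  }
  if (any(times < 0)) .stopf("observation times must be >= 0")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    .stopf("observation times must be strictly increasing")
  }
  if (!is.null(cl_dose) && is.null(props)) {
    .stopf("cl_dose requires props so dose amounts are interpreted as mg/kg")
  }
  dose_mg <- NULL
  d <- doses
  if (!is.null(props)) {
    dose_mg <- d$amt
    d$amt <- d$amt * props$nmol_per_mg
  }
  time_varying <- params$cl_induced != params$cl
  use_ode <- switch(method,
                    auto = time_varying,
                    analytic = FALSE,
                    ode = TRUE)
  conc <- if (use_ode) {
    .conc_ode(params, d, times, cl_dose, dose_mg, rtol = rtol, atol = atol)
  } else {
    .conc_analytic(params, d, times, cl_dose, dose_mg)
  }
  out <- data.frame(time = times, conc = conc)
  class(out) <- c("conc_profile", "data.frame")
  out
}

#' Concentration profile as a continuous function of time
#'
#' Returns a vectorised function `C(t)` (nM, t in hours) suitable as the
#' forcing input of the indirect-response models.  Time-invariant systems are
#' evaluated exactly at every requested time; systems with an induction ramp
#' are solved once on a fine grid and interpolated linearly.
#'
#' @inheritParams conc_profile
#' @param t_max upper end of the support needed (hours); required for
#'   time-varying systems.
#' @param grid_step grid resolution (hours) for the numerically solved case.
#' @export
conc_fun <- function(params, doses, t_max = NULL, cl_dose = NULL, props = NULL,
                     grid_step = 0.25, rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(params, "pk_params"))
  time_varying <- params$cl_induced != params$cl
  dose_mg <- NULL
  d <- doses
  if (!is.null(props)) {
    dose_mg <- d$amt
    d$amt <- d$amt * props$nmol_per_mg
  }
  if (!time_varying) {
    force(d); force(dose_mg)
    return(function(t) .conc_analytic(params, d, t, cl_dose, dose_mg))
  }
  if (is.null(t_max)) .stopf("t_max is required for time-varying clearance")
  grid <- sort(unique(c(seq(0, t_max, by = grid_step), t_max, d$time)))
  cg <- .conc_ode(params, d, grid, cl_dose, dose_mg, rtol = rtol, atol = atol)
  stats::approxfun(grid, cg, rule = 2)
}

#' Area under the concentration-time curve to the last observation
#'
#' Linear trapezoidal AUC(0-last) over the observed points; no extrapolation
#' beyond the last sample.
#'
#' @param x a `conc_profile`, or a data.frame with columns `time` and `conc`,
#'   or a numeric vector of times.
#' @param conc concentrations matching `x` when `x` is a numeric vector.
#' @return exposure in nM*h.
#' @export
auc_last <- function(x, conc = NULL) {
  if (is.data.frame(x)) {
    times <- x$time
    conc <- x$conc
  } else {
    times <- x
  }
  if (length(times) < 1L) .stopf("auc_last: need at least one observation")
  if (length(times) != length(conc)) .stopf("times and concentrations differ in length")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    .stopf("auc_last: times must be strictly increasing")
  }
  if (length(times) == 1L) return(0)
  sum(diff(times) * (conc[-1L] + conc[-length(conc)]) / 2)
}
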