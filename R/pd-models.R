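# Indirect-response pharmacodynamic systems.
#
# Two turnover structures cover all three endpoints:
#   * UACR: dR/dt = Kin * [1 - Imax * C/(C + IC50)] - Kout * R, started from a
#     non-steady-state baseline uacr0 (the untreated disease trajectory rises
#     towards Kin/Kout).
#   * Delta endpoints (drug-induced serum K+ rise, acute urinary Na+/K+):
#     dD/dt = Kin_max * C/(C + EC50) - Kout * D, started from 0.
# Rates are unit-agnostic: kin/kout in 1/unit-time must match the time unit of
# the grid and of the concentration function.

#' UACR indirect-response parameters
#'
#' @param kin zero-order production rate of the response (UACR-units per unit
#'   time).
#' @param kout first-order loss rate (1/unit time).
#' @param imax maximal fractional inhibition of the input, in \[0, 1\].
#' @param ic50 total plasma concentration producing half-maximal inhibition
#'   (nM).
#' @param uacr0 initial (non-steady-state) response value, > 0.
#' @export
uacr_irm_params <- function(kin, kout, imax, ic50, uacr0) {
  for (nm in c("kin", "kout", "ic50", "uacr0")) {
    v <- get(nm)
    if (!.is_number(v) || v <= 0) .stopf("uacr_irm_params: %s must be > 0", nm)
  }
  if (!.is_number(imax) || imax < 0 || imax > 1) {
    .stopf("uacr_irm_params: imax must be in [0, 1]")
  }
  structure(list(kin = kin, kout = kout, imax = imax, ic50 = ic50,
                 uacr0 = uacr0),
            class = "uacr_irm_params")
}

#' Stimulated-input (delta) indirect-response parameters
#'
#' @param kin_max maximal drug-driven input rate (response-units per unit
#'   time).
#' @param kout first-order loss rate (1/unit time).
#' @param ec50 concentration of half-maximal input stimulation, in the units
#'   of the driving concentration (total nM for the chronic serum-K+ endpoint;
#'   dimensionless free/in-vitro-normalised drive for the acute endpoint).
#' @export
delta_irm_params <- function(kin_max, kout, ec50) {
  for (nm in c("kin_max", "kout", "ec50")) {
    v <- get(nm)
    if (!.is_number(v) || v <= 0) .stopf("delta_irm_params: %s must be > 0", nm)
  }
  structure(list(kin_max = kin_max, kout = kout, ec50 = ec50),
            class = "delta_irm_params")
}

.as_conc_fun <- function(conc) {
  if (is.function(conc)) return(conc)
  if (inherits(conc, "conc_profile") || (is.data.frame(conc) &&
      all(c("time", "conc") %in% names(conc)))) {
    return(stats::approxfun(conc$time, conc$conc, rule = 2))
  }
  .stopf("conc must be a function of time or a conc_profile")
}

.check_grid <- function(t_grid) {
  if (length(t_grid) < 1L || any(t_grid < 0)) .stopf("t_grid must be >= 0")
  if (length(t_grid) > 1L && any(diff(t_grid) <= 0)) {
    .stopf("t_grid must be strictly increasing")
  }
}

#' Simulate the UACR turnover trajectory
#'
#' Integrates `dUACR/dt = kin * (1 - imax * C/(C + ic50)) - kout * UACR` from
#' `uacr0` with an adaptive stiff-capable integrator.
#'
#' @param params a [uacr_irm_params()] object.
#' @param conc driving concentration: a vectorised function of time or a
#'   [conc_profile()] (interpolated linearly). Its time unit must match
#'   `t_grid` and the `kin`/`kout` units.
#' @param t_grid strictly increasing output times (same unit as the rates).
#' @param rtol,atol integration tolerances.
#' @return `data.frame(time, uacr)`.
#' @examples
#' p <- uacr_irm_params(kin = 2, kout = 0.1, imax = 1, ic50 = 1, uacr0 = 10)
#' simulate_uacr(p, function(t) rep(0, length(t)), t_grid = 0:10)
#' @export
simulate_uacr <- function(params, conc, t_grid, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "uacr_irm_params"))
  cfun <- .as_conc_fun(conc)
  .check_grid(t_grid)
  if (any(cfun(t_grid) < 0)) .stopf("negative concentrations are not allowed")
  rhs <- function(t, y, p) {
    cc <- cfun(t)
    inh <- 1 - params$imax * cc / (cc + params$ic50)
    list(params$kin * inh - params$kout * y)
  }
  tt <- sort(unique(c(0, t_grid)))
  sol <- deSolve::lsoda(params$uacr0, tt, rhs, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  data.frame(time = t_grid, uacr = sol[match(t_grid, sol[, 1L]), 2L])
}

#' Simulate a stimulated-input delta trajectory
#'
#' Integrates `dDelta/dt = kin_max * C/(C + ec50) - kout * Delta` from 0.
#' Serves both the chronic drug-induced serum-K+ rise and the acute urinary
#' Na+/K+ double-delta endpoint (the endpoint is set by the units and time
#' scale of the inputs).
#'
#' @inheritParams simulate_uacr
#' @param params a [delta_irm_params()] object.
#' @return `data.frame(time, delta)`.
#' @export
simulate_delta_response <- function(params, conc, t_grid, rtol = 1e-8,
                                    atol = 1e-10) {
  stopifnot(inherits(params, "delta_irm_params"))
  cfun <- .as_conc_fun(conc)
  .check_grid(t_grid)
  if (any(cfun(t_grid) < 0)) .stopf("negative concentrations are not allowed")
  rhs <- function(t, y, p) {
    cc <- cfun(t)
    list(params$kin_max * cc / (cc + params$ec50) - params$kout * y)
  }
  tt <- sort(unique(c(0, t_grid)))
  sol <- deSolve::lsoda(0, tt, rhs, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  data.frame(time = t_grid, delta = sol[match(t_grid, sol[, 1L]), 2L])
}

.norm_tv <- function(df, value_col = NULL) {
  nm <- names(df)
  if ("TIME" %in% nm && !("time" %in% nm)) df$time <- df$TIME
  if (!is.null(value_col) && value_col %in% nm) {
    df$value <- df[[value_col]]
  } else if ("DV" %in% nm && !("value" %in% nm)) {
    df$value <- as.numeric(df$DV)
  }
  if (!all(c("time", "value") %in% names(df))) {
    .stopf("expected columns time/value (or TIME/DV)")
  }
  df[, c("time", "value")]
}

#' Double-delta (baseline- and vehicle-corrected) transform
#'
#' Computes `Delta(T) = (TxT - Tx0) - (VehT - Veh0)`: the change from baseline
#' in a treated subject minus the change from baseline of the vehicle
#' reference, so every subject's time-zero response is exactly 0.  The vehicle
#' reference is interpolated linearly at subject times when needed.
#'
#' @param subject data.frame with columns `time`, `value` (or `TIME`, `DV`)
#'   for one subject, containing time 0.
#' @param vehicle data.frame `(time, value)` of vehicle means (see
#'   [vehicle_reference()]), containing time 0 and covering all subject times.
#' @return `data.frame(time, delta)`; values may be negative.
#' @export
double_delta <- function(subject, vehicle) {
  s <- .norm_tv(subject)
  v <- .norm_tv(vehicle)
  if (!any(s$time == 0)) .stopf("subject series must contain a time-0 observation")
  if (!any(v$time == 0)) .stopf("vehicle series must contain a time-0 observation")
  veh_at <- stats::approx(v$time, v$value, xout = s$time, rule = 1)$y
  if (any(is.na(veh_at))) {
    .stopf("vehicle reference does not cover all subject times")
  }
  s0 <- s$value[s$time == 0][1L]
  v0 <- v$value[v$time == 0][1L]
  data.frame(time = s$time, delta = (s$value - s0) - (veh_at - v0))
}

#' Vehicle reference series
#'
#' Per-time arithmetic mean of the supplied vehicle-animal observations,
#' pooling all animals (and studies) given.
#'
#' @param obs data.frame with columns `time`, `value` (or `TIME`, `DV`) over
#'   one or more vehicle animals; an optional `ID` column is ignored.
#' @return `data.frame(time, value)` sorted by time.
#' @export
vehicle_reference <- function(obs) {
  if (is.null(obs) || nrow(obs) == 0L) .stopf("empty vehicle observation set")
  o <- .norm_tv(obs)
  agg <- stats::aggregate(value ~ time, data = o, FUN = mean)
  agg[order(agg$time), , drop = FALSE]
}
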