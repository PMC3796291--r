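# Therapeutic-index calculus: free-fraction correction, in-vitro potency
# normalisation, TI and fold ratios, plus the table-shaped report.

#' Free (protein-binding corrected) EC50
#'
#' `fEC50 = EC50_total * fu`, converting total-plasma potency to free-drug
#' potency.
#'
#' @param ec50_total potency against total plasma concentration (nM), > 0.
#' @param fu unbound fraction, in (0, 1].
#' @return fEC50 in nM (full precision; display rounding is left to callers).
#' @export
free_ec50 <- function(ec50_total, fu) {
  if (any(ec50_total <= 0)) .stopf("ec50_total must be > 0")
  if (any(fu <= 0 | fu > 1)) .stopf("fu must be in (0, 1]")
  ec50_total * fu
}

#' In-vitro potency normalisation
#'
#' Ratio of the free in-vivo potency to the in-vitro receptor potency,
#' a dimensionless measure comparable across drugs.
#'
#' @param fec50 free EC50 (nM), > 0.
#' @param invitro_ic50 in-vitro IC50 (nM), > 0.
#' @export
potency_normalized <- function(fec50, invitro_ic50) {
  if (any(fec50 <= 0)) .stopf("fec50 must be > 0")
  if (any(invitro_ic50 <= 0)) .stopf("invitro_ic50 must be > 0")
  fec50 / invitro_ic50
}

#' Therapeutic index
#'
#' TI = (potency-normalised serum-K+ EC50) / (potency-normalised UACR EC50).
#' Because the unbound fraction and the in-vitro potency are shared within a
#' drug they cancel algebraically, so TI equals `ec50_k / ec50_uacr`; the
#' function computes both routes and asserts the identity.
#'
#' @param ec50_k total-concentration EC50 for the serum-K+ (adverse) endpoint
#'   (nM).
#' @param ec50_uacr total-concentration EC50 for UACR lowering (efficacy)
#'   (nM).
#' @param props a [drug_properties()] object for the drug.
#' @return the TI (dimensionless), with the normalised potencies attached as
#'   attribute `components`.
#' @examples
#' pf <- drug_properties(fu = 0.0038, ic50_invitro = 0.75, nmol_per_mg = 2273)
#' therapeutic_index(874, 10.4, pf)
#' @export
therapeutic_index <- function(ec50_k, ec50_uacr, props) {
  stopifnot(inherits(props, "drug_properties"))
  if (any(c(ec50_k, ec50_uacr) <= 0)) .stopf("EC50 inputs must be > 0")
  num <- potency_normalized(free_ec50(ec50_k, props$fu), props$ic50_invitro)
  den <- potency_normalized(free_ec50(ec50_uacr, props$fu), props$ic50_invitro)
  ti <- num / den
  if (!isTRUE(all.equal(ti, ec50_k / ec50_uacr, tolerance = 1e-12))) {
    .stopf("internal error: TI cancellation identity violated")
  }
  attr(ti, "components") <- c(normalized_k = num, normalized_uacr = den)
  ti
}

#' Fold difference between two positive quantities
#'
#' @param a,b positive scalars; returns `a / b`. Reports round this to the
#'   integer fold.
#' @export
fold_difference <- function(a, b) {
  if (any(b <= 0)) .stopf("denominator must be > 0")
  if (any(a <= 0)) .stopf("numerator must be > 0")
  a / b
}

#' Percentile confidence interval for a ratio from paired bootstrap replicates
#'
#' @param rep_num,rep_den paired bootstrap replicates (same resamples, equal
#'   length) of the numerator and denominator potencies.
#' @param level confidence level (default 0.95).
#' @return named vector `c(lower, upper)`.
#' @export
ti_confidence_interval <- function(rep_num, rep_den, level = 0.95) {
  if (length(rep_num) != length(rep_den)) {
    .stopf("replicate vectors must be paired (equal length)")
  }
  if (length(rep_num) < 2L) .stopf("need at least 2 paired replicates")
  r <- rep_num / rep_den
  a <- (1 - level) / 2
  q <- stats::quantile(r, probs = c(a, 1 - a), names = FALSE, type = 7)
  c(lower = q[1L], upper = q[2L])
}

#' Therapeutic-index summary table
#'
#' Assembles the table-shaped report of the chronic analysis: per drug and
#' endpoint the total-concentration potency with its CI, the free potency,
#' the in-vitro-normalised potency, and per drug the TI with its CI and the
#' cross-drug TI fold ratio (attribute `fold`).
#'
#' @param estimates data.frame with columns `drug`, `endpoint` (one of
#'   `"serum_k"`, `"uacr"`), `ec50`, and optionally `lower`, `upper`.
#' @param props named list of [drug_properties()] keyed by drug.
#' @param ti_ci optional named list per drug of `c(lower, upper)` for the TI
#'   (e.g. from [ti_confidence_interval()]).
#' @return data.frame of class `ti_table`; one row per drug-endpoint with the
#'   eight report cells.
#' @export
ti_table <- function(estimates, props, ti_ci = NULL) {
  need <- c("drug", "endpoint", "ec50")
  if (!all(need %in% names(estimates))) {
    .stopf("estimates must have columns %s", paste(need, collapse = ", "))
  }
  if (!all(estimates$endpoint %in% c("serum_k", "uacr"))) {
    .stopf("endpoint must be 'serum_k' or 'uacr'")
  }
  drugs <- unique(estimates$drug)
  rows <- lapply(drugs, function(dr) {
    e <- estimates[estimates$drug == dr, , drop = FALSE]
    pr <- props[[dr]]
    if (is.null(pr)) .stopf("no drug_properties supplied for '%s'", dr)
    ek <- e$ec50[e$endpoint == "serum_k"]
    eu <- e$ec50[e$endpoint == "uacr"]
    if (length(ek) != 1L || length(eu) != 1L) {
      .stopf("drug '%s' needs exactly one serum_k and one uacr row", dr)
    }
    ti <- as.numeric(therapeutic_index(ek, eu, pr))
    ci <- ti_ci[[dr]] %||% c(NA_real_, NA_real_)
    data.frame(
      drug = dr,
      endpoint = e$endpoint,
      ec50_total_nM = e$ec50,
      ci_lower = if ("lower" %in% names(e)) e$lower else NA_real_,
      ci_upper = if ("upper" %in% names(e)) e$upper else NA_real_,
      fec50_nM = free_ec50(e$ec50, pr$fu),
      fec50_over_invitro = potency_normalized(free_ec50(e$ec50, pr$fu),
                                              pr$ic50_invitro),
      ti = ti,
      ti_lower = ci[1L],
      ti_upper = ci[2L],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  tis <- out$ti[!duplicated(out$drug)]
  if (length(tis) == 2L) {
    attr(out, "fold") <- fold_difference(max(tis), min(tis))
  }
  class(out) <- c("ti_table", "data.frame")
  out
}
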