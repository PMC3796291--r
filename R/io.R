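# Dataset reading/writing and the end-to-end pipeline.
#
# Datasets use a NONMEM-style rectangular layout as comma-delimited text with
# a fixed dialect: header row required, decimal point, "." for missing.
# Columns: ID, TIME (hours), AMT (mg/kg), RATE (mg/kg/h; 0 or missing =
# first-order depot, > 0 = zero-order over AMT/RATE hours), DV, EVID (1 dose,
# 0 observation), MDV, CMT (1 plasma concentration nM, 2 UACR, 3 serum K+
# mmol/L, 4 urinary Na+/K+ ratio), DOSE (group dose, mg/kg), GROUP
# ("<study>:<arm>"), DRUG (drug code or missing for vehicle animals).

.DATASET_COLS <- c("ID", "TIME", "AMT", "RATE", "DV", "EVID", "MDV", "CMT",
                   "DOSE", "GROUP", "DRUG")
.NUMERIC_COLS <- c("TIME", "AMT", "RATE", "DV", "EVID", "MDV", "CMT", "DOSE")

#' Write a dataset as delimited text
#'
#' @param data dataset with exactly the canonical columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_dataset()] for the column contract.
#' @export
write_dataset <- function(data, path) {
  miss <- setdiff(.DATASET_COLS, names(data))
  if (length(miss)) .stopf("missing required column(s): %s",
                           paste(miss, collapse = ", "))
  extra <- setdiff(names(data), .DATASET_COLS)
  if (length(extra)) .stopf("unknown column(s): %s",
                            paste(extra, collapse = ", "))
  out <- data[, .DATASET_COLS]
  fmt <- function(x) {
    if (is.numeric(x)) {
      ifelse(is.na(x), ".", vapply(x, function(v) sprintf("%.15g", v), ""))
    } else {
      ifelse(is.na(x), ".", as.character(x))
    }
  }
  chr <- vapply(out, fmt, character(nrow(out)))
  utils::write.table(chr, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = .DATASET_COLS)
  invisible(path)
}

#' Read a dataset from delimited text
#'
#' Reads and validates an event/observation table written in the package's
#' fixed dialect (see [write_dataset()]).  Dose rows must carry no dependent
#' value; observation times must be non-decreasing within each subject.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  miss <- setdiff(.DATASET_COLS, names(raw))
  if (length(miss)) .stopf("missing required column(s): %s",
                           paste(miss, collapse = ", "))
  extra <- setdiff(names(raw), .DATASET_COLS)
  if (length(extra)) .stopf("unknown column(s): %s",
                            paste(extra, collapse = ", "))
  if (nrow(raw) == 0L) .stopf("dataset is empty")
  out <- raw[, .DATASET_COLS]
  for (cc in .NUMERIC_COLS) {
    v <- out[[cc]]
    v[v == "."] <- NA
    num <- suppressWarnings(as.numeric(v))
    if (any(!is.na(v) & is.na(num))) {
      .stopf("non-numeric value in column %s", cc)
    }
    out[[cc]] <- num
  }
  for (cc in c("GROUP", "DRUG")) out[[cc]][out[[cc]] == "."] <- NA
  idnum <- suppressWarnings(as.numeric(out$ID))
  if (!any(is.na(idnum))) out$ID <- idnum
  if (any(out$EVID == 1 & !is.na(out$DV))) {
    .stopf("dose rows (EVID == 1) must not carry a DV value")
  }
  for (id in unique(out$ID)) {
    tt <- out$TIME[out$ID == id]
    if (any(diff(tt) < 0)) {
      .stopf("non-monotone times within subject %s", id)
    }
  }
  out
}

#' Pipeline run configuration
#'
#' @param study `"chronic"` or `"acute"`.
#' @param seed integer seed used for every stochastic step (generation and
#'   optimizer restarts).
#' @param truth simulation truth used when generating data
#'   ([default_truth()] by default); also supplies the drug properties used
#'   in estimation and metrics.
#' @param design study design; defaults to [chronic_design()] or
#'   [acute_design()].
#' @param noise logical; `FALSE` runs the generator with all variability
#'   removed ([noise_free_truth()]).
#' @param dataset optional path to an existing dataset (skips generation).
#' @param n_boot bootstrap resamples for the TI confidence interval (0 = the
#'   cheap asymptotic fit CIs only).
#' @param n_restarts_pk,n_restarts_pd multistart counts for the two stages.
#' @param grid_step stage-2 concentration grid step (hours).
#' @export
pipeline_config <- function(study = c("chronic", "acute"), seed = 1L,
                            truth = default_truth(), design = NULL,
                            noise = TRUE, dataset = NULL, n_boot = 0,
                            n_restarts_pk = 5, n_restarts_pd = 5,
                            grid_step = 0.25) {
  study <- match.arg(study)
  design <- design %||% if (study == "chronic") chronic_design() else
    acute_design()
  drugs <- vapply(design$studies, `[[`, "", "drug")
  if (!all(drugs %in% names(truth$props))) {
    .stopf("design references drugs without properties: %s",
           paste(setdiff(drugs, names(truth$props)), collapse = ", "))
  }
  if (is.null(seed)) .stopf("a seed is required (stochastic steps must log it)")
  structure(list(study = study, seed = as.integer(seed), truth = truth,
                 design = design, noise = noise, dataset = dataset,
                 n_boot = n_boot, n_restarts_pk = n_restarts_pk,
                 n_restarts_pd = n_restarts_pd, grid_step = grid_step),
            class = "mra_config")
}

# stage-1 structures mirroring the study model choices; fixed values
# (2-cmt distribution constants, induction window, zero-order duration) come
# from the configured truth
default_structures <- function(study, truth) {
  pr <- truth$props
  if (study == "chronic") {
    pf <- truth$pk[["PF-03882845"]]$chronic
    ep <- truth$pk[["eplerenone"]]$chronic
    list(
      "PF-03882845" = pk_structure(
        n_cmt = 2, absorption = "depot",
        induction = list(start = pf$induction_start, end = pf$induction_end),
        props = pr[["PF-03882845"]],
        estimate = c("ka", "cl", "v1", "ind_fold"),
        fixed = list(q = pf$q, v2 = pf$v2)),
      "eplerenone" = pk_structure(
        n_cmt = 1, absorption = "depot",
        induction = list(start = ep$induction_start, end = ep$induction_end),
        props = pr[["eplerenone"]],
        estimate = c("ka", "cl", "v1", "ind_fold"))
    )
  } else {
    ep <- truth$pk[["eplerenone"]]$acute
    list(
      "PF-03882845" = pk_structure(
        n_cmt = 1, absorption = "depot", props = pr[["PF-03882845"]],
        estimate = c("ka", "cl", "v1")),
      "eplerenone" = pk_structure(
        n_cmt = 2, absorption = "zero_order", props = pr[["eplerenone"]],
        estimate = c("cl", "v1", "q"),
        fixed = list(ka = ep$ka, v2 = ep$v2))
    )
  }
}

#' Run the full two-stage analysis pipeline
#'
#' Executes generate (unless a dataset is supplied) -> stage-1 individual PK
#' fits -> stage-2 pooled PD fits -> therapeutic-index metrics, and returns a
#' report bundle.  Rerunning with an identical configuration reproduces the
#' report exactly; every stochastic step derives its seed from the
#' configuration seed.
#'
#' @param config an [pipeline_config()] object.
#' @return list of class `mra_report`: the dataset, `pk_fits`, `pd_fits`,
#'   `ti` (chronic) or acute potencies, provenance labels for the report
#'   cells, and the seeds/structures used.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mra_config"))
  truth <- if (config$noise) config$truth else noise_free_truth(config$truth)
  props <- truth$props
  stage_seed <- config$seed
  data <- if (!is.null(config$dataset)) {
    if (is.character(config$dataset)) read_dataset(config$dataset) else
      config$dataset
  } else if (config$study == "chronic") {
    generate_chronic_study(config$design, truth, seed = stage_seed)
  } else {
    generate_acute_study(config$design, truth, seed = stage_seed)
  }
  structures <- default_structures(config$study, truth)
  pk_fits <- fit_pk_study(data, structures,
                          n_restarts = config$n_restarts_pk,
                          seed = stage_seed + 1000L)
  pd_fits <- list()
  ti <- NULL
  acute_potencies <- NULL
  if (config$study == "chronic") {
    pd_fits$uacr <- fit_pd_pooled(data, pk_fits, "uacr", props,
                                  seed = stage_seed + 2000L,
                                  n_restarts = config$n_restarts_pd,
                                  grid_step = config$grid_step)
    pd_fits$delta_k <- fit_pd_pooled(data, pk_fits, "delta_k", props,
                                     seed = stage_seed + 3000L,
                                     n_restarts = config$n_restarts_pd,
                                     grid_step = config$grid_step)
    drugs <- sort(unique(stats::na.omit(data$DRUG)))
    grab <- function(fit, prefix, drug) {
      nm <- paste0(prefix, drug)
      ci <- fit$ci
      c(est = unname(fit$estimates[nm]),
        lo = if (is.null(ci)) NA_real_ else ci$lower[ci$param == nm],
        hi = if (is.null(ci)) NA_real_ else ci$upper[ci$param == nm])
    }
    est <- do.call(rbind, lapply(drugs, function(dr) {
      k <- grab(pd_fits$delta_k, "ec50_", dr)
      u <- grab(pd_fits$uacr, "ic50_", dr)
      data.frame(drug = dr, endpoint = c("serum_k", "uacr"),
                 ec50 = c(k[["est"]], u[["est"]]),
                 lower = c(k[["lo"]], u[["lo"]]),
                 upper = c(k[["hi"]], u[["hi"]]),
                 stringsAsFactors = FALSE)
    }))
    ti_ci <- NULL
    if (config$n_boot >= 2) {
      boot_fun <- function(d) {
        pk_b <- fit_pk_study(d, structures, n_restarts = 2,
                             seed = stage_seed + 4000L)
        fu <- fit_pd_pooled(d, pk_b, "uacr", props, n_restarts = 2,
                            seed = stage_seed + 5000L, compute_ci = FALSE,
                            grid_step = config$grid_step)
        fk <- fit_pd_pooled(d, pk_b, "delta_k", props, n_restarts = 2,
                            seed = stage_seed + 6000L, compute_ci = FALSE,
                            grid_step = config$grid_step)
        out <- c(fk$estimates[paste0("ec50_", drugs)],
                 fu$estimates[paste0("ic50_", drugs)])
        out
      }
      bt <- bootstrap_ci(boot_fun, data, n_boot = config$n_boot,
                         seed = stage_seed + 7000L)
      ti_ci <- lapply(drugs, function(dr) {
        ti_confidence_interval(bt$replicates[, paste0("ec50_", dr)],
                               bt$replicates[, paste0("ic50_", dr)])
      })
      names(ti_ci) <- drugs
    }
    ti <- ti_table(est, props, ti_ci = ti_ci)
  } else {
    pd_fits$nak <- fit_pd_pooled(data, pk_fits, "nak", props,
                                 seed = stage_seed + 2000L,
                                 n_restarts = config$n_restarts_pd,
                                 grid_step = min(config$grid_step, 0.02))
    drugs <- sort(unique(stats::na.omit(data$DRUG)))
    nm <- paste0("ec50_", drugs)
    ci <- pd_fits$nak$ci
    acute_potencies <- data.frame(
      drug = drugs,
      ec50_normalized = unname(pd_fits$nak$estimates[nm]),
      lower = if (is.null(ci)) NA_real_ else ci$lower[match(nm, ci$param)],
      upper = if (is.null(ci)) NA_real_ else ci$upper[match(nm, ci$param)],
      stringsAsFactors = FALSE)
  }
  provenance <- c(
    ec50_total_nM = "fitted", ci_lower = "fitted", ci_upper = "fitted",
    fec50_nM = "derived", fec50_over_invitro = "derived", ti = "derived",
    ti_lower = "derived", ti_upper = "derived",
    fu = "configured", ic50_invitro = "configured",
    ec50_normalized = "fitted")
  structure(list(study = config$study, seed = config$seed,
                 noise = config$noise, dataset = data,
                 structures = structures, pk_fits = pk_fits,
                 pd_fits = pd_fits, ti = ti,
                 acute_potencies = acute_potencies,
                 provenance = provenance, config = config),
            class = "mra_report")
}

.describe_structure <- function(nm, st) {
  sprintf(
    "  %s: %d-compartment, %s absorption%s; estimated per animal: %s%s",
    nm, st$n_cmt, gsub("_", "-", st$absorption),
    if (is.null(st$induction)) "" else
      sprintf(", clearance induction %g-%g h", st$induction$start,
              st$induction$end),
    paste(st$estimate, collapse = "/"),
    if (length(st$fixed)) sprintf("; fixed: %s",
      paste(sprintf("%s=%g", names(st$fixed), unlist(st$fixed)),
            collapse = ", ")) else "")
}

#' @export
print.mra_report <- function(x, ...) {
  cat(sprintf("MR-antagonist PK/PD pipeline report (%s study)\n", x$study))
  cat(sprintf("seed: %d   noise: %s   subjects: %d   records: %d\n",
              x$seed, x$noise, length(unique(x$dataset$ID)),
              nrow(x$dataset)))
  cat("PK model structures:\n")
  for (nm in names(x$structures)) {
    cat(.describe_structure(nm, x$structures[[nm]]), "\n")
  }
  cat(sprintf("stage-1 fits: %d animals, %d converged\n",
              nrow(x$pk_fits), sum(x$pk_fits$converged)))
  for (nm in names(x$pd_fits)) {
    f <- x$pd_fits[[nm]]
    cat(sprintf("stage-2 %s fit (%s, seed %d): %s\n", nm, f$rate_unit,
                f$seed, paste(sprintf("%s=%.4g", names(f$estimates),
                                      f$estimates), collapse = ", ")))
  }
  if (!is.null(x$ti)) {
    cat("therapeutic-index table:\n")
    print(as.data.frame(x$ti), digits = 3)
    cat(sprintf("TI fold ratio: %.3g\n", attr(x$ti, "fold")))
  }
  if (!is.null(x$acute_potencies)) {
    cat("acute normalised EC50s:\n")
    print(x$acute_potencies, digits = 3)
  }
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Emits the dataset, stage-1 parameter table, stage-2 estimates with CIs,
#' the metric table and a human-readable summary as plain delimited text.
#'
#' @param report an `mra_report` from [run_pipeline()].
#' @param dir output directory (created if absent).
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mra_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dataset(report$dataset, file.path(dir, "dataset.csv"))
  utils::write.csv(as.data.frame(report$pk_fits),
                   file.path(dir, "pk_fits.csv"), row.names = FALSE)
  for (nm in names(report$pd_fits)) {
    f <- report$pd_fits[[nm]]
    est <- data.frame(param = names(f$estimates), estimate = f$estimates)
    if (!is.null(f$ci)) est <- merge(est, f$ci, by = "param", sort = FALSE)
    utils::write.csv(est, file.path(dir, sprintf("pd_fit_%s.csv", nm)),
                     row.names = FALSE)
  }
  if (!is.null(report$ti)) {
    utils::write.csv(as.data.frame(report$ti), file.path(dir, "ti_table.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$acute_potencies)) {
    utils::write.csv(report$acute_potencies,
                     file.path(dir, "acute_potencies.csv"), row.names = FALSE)
  }
  con <- file(file.path(dir, "summary.txt"), "w")
  sink(con)
  on.exit({ sink(); close(con) }, add = TRUE)
  print(report)
  invisible(dir)
}
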