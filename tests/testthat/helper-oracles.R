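# Brute-force reference integrators used as independent oracles, plus shared
# fixtures.  The integrators are deliberately naive (fixed-step explicit
# schemes) and independent of the package's analytic/adaptive code paths.

# explicit fixed-step integrator for the compartmental system
# doses: data.frame(time, amt, dur); amounts in nmol/kg
euler_conc <- function(params, doses, times, h = 0.002) {
  t_end <- max(times)
  nt <- ceiling(t_end / h)
  tt <- seq(0, by = h, length.out = nt + 1)
  dep <- a1 <- a2 <- 0
  q <- if (is.na(params$q)) 0 else params$q
  v2 <- if (q > 0) params$v2 else 1
  out <- numeric(nt + 1)
  cl_t <- clearance_at(params, tt)  # vectorised once, indexed in the loop
  for (i in seq_len(nt + 1)) {
    t <- tt[i]
    # impulse doses entering exactly at t
    hit <- abs(doses$time - t) < h / 2 & doses$dur == 0
    if (any(hit)) dep <- dep + sum(params$f * doses$amt[hit])
    out[i] <- a1 / params$v1
    rate_in <- 0
    zo <- doses$dur > 0 & t >= doses$time & t < doses$time + doses$dur
    if (any(zo)) rate_in <- sum(params$f * doses$amt[zo] / doses$dur[zo])
    cl <- cl_t[i]
    d_dep <- -params$ka * dep
    d_a1 <- params$ka * dep + rate_in - (cl / params$v1) * a1 -
      (q / params$v1) * a1 + (q / v2) * a2
    d_a2 <- (q / params$v1) * a1 - (q / v2) * a2
    dep <- dep + h * d_dep
    a1 <- a1 + h * d_a1
    a2 <- a2 + h * d_a2
  }
  stats::approx(tt, out, xout = times)$y
}

# explicit fixed-step integrator for the turnover models
euler_irm <- function(kind = c("uacr", "delta"), kin, kout, imax = 1, pot,
                      y0, cfun, t_out, h = 0.002) {
  kind <- match.arg(kind)
  t_end <- max(t_out)
  nt <- ceiling(t_end / h)
  tt <- seq(0, by = h, length.out = nt + 1)
  y <- y0
  out <- numeric(nt + 1)
  for (i in seq_len(nt + 1)) {
    out[i] <- y
    cc <- cfun(tt[i])
    s <- cc / (cc + pot)
    dy <- if (kind == "uacr") kin * (1 - imax * s) - kout * y else
      kin * s - kout * y
    y <- y + h * dy
  }
  stats::approx(tt, out, xout = t_out)$y
}

# shared noise-free chronic dataset (generated once per test run)
.fixture_env <- new.env(parent = emptyenv())
nf_chronic <- function() {
  if (is.null(.fixture_env$nf_chronic)) {
    .fixture_env$nf_chronic <-
      generate_chronic_study(truth = noise_free_truth(), seed = 1)
  }
  .fixture_env$nf_chronic
}

pf_props <- function() drug_properties(fu = 0.0038, ic50_invitro = 0.75,
                                       nmol_per_mg = 2273,
                                       name = "PF-03882845")
epl_props <- function() drug_properties(fu = 0.68, ic50_invitro = 109,
                                        nmol_per_mg = 2413,
                                        name = "eplerenone")
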