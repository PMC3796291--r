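---
title: "Exposure-response modelling of MR antagonists: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exposure-response modelling of MR antagonists: models, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Mineralocorticoid-receptor (MR) antagonists lower albuminuria — measured as
the urinary albumin-to-creatinine ratio (UACR) — in aldosterone-driven renal
disease, but the same receptor blockade raises serum K⁺ and can cause
hyperkalemia. Whether a compound offers a usable safety margin is therefore a
question about the *ratio of two potencies*: the concentration needed to
raise serum K⁺ versus the concentration needed to suppress UACR. `mrapkpd`
implements the preclinical analysis chain that produces this therapeutic
index (TI) from two chronic 27-day rat studies (one per drug, here the
non-steroidal antagonist PF-03882845 and the steroidal comparator
eplerenone) and an acute urinary Na⁺/K⁺ biomarker study, together with a
synthetic-study generator that stands in for the unavailable animal data.

# Models

## Pharmacokinetics

Plasma concentration (nM) follows linear one- or two-compartment
disposition with first-order elimination. Two absorption inputs are
supported: a first-order depot (oral gavage) and a zero-order input of fixed
duration (used for eplerenone in the acute analysis, where a 1 h zero-order
input reproduces the observed time of peak concentration). All structures
share a single closed-form evaluator: the central-compartment bolus response
is a sum of exponentials $C(t) = (D/V_1)\sum_i E_i e^{-\lambda_i t}$, the
depot input is its convolution with $k_a e^{-k_a t}$, and zero-order input
is the difference of two step responses.

Repeated dosing lowers exposure for both drugs; this is encoded as
clearance induction: clearance rises from its initial value to an induced
value between day 1 and day 7 and stays constant thereafter. The shape of
the transition is not identifiable from sparse sampling, so the package uses
the simplest monotone interpolant, a linear ramp (`clearance_at()`), with
the boundary behaviour testable at `t = 0`, at the ramp midpoint, and
beyond day 7. While the ramp is active the system is a time-varying linear
ODE with no closed form; `conc_profile()` then integrates numerically
(`deSolve::lsoda`, default `rtol 1e-8`). An analytic route is still
available (`method = "analytic"`): each dose decays under the clearance in
force at its administration time (doses inside the ramp use the mid-ramp
clearance). For the study sampling schedules — day 1 samples before the ramp
starts, all later samples at least a week past any ramp-era dose, with
half-lives of a few hours — this regime approximation is numerically exact
at the sampled times (carryover across the ramp is below $10^{-10}$ of the
signal), which is why the stage-1 optimizer uses it; inside the ramp itself
it can deviate by several percent, which is why simulators and stage-2 drive
matrices use the ODE route instead.

For the acute eplerenone analysis, apparent clearance decreases with dose;
this is the empirical power model
$CL = \theta_1 (30/\text{dose})^{pwr} e^{\eta}$ with the reference dose at
30 mg/kg (`dose_dependent_clearance()`).

Doses are recorded in mg/kg; a per-drug molar conversion factor (nmol/mg)
turns them into the nmol/kg amounts that make concentrations come out in
nM. The factors are not part of the published analysis and are a required
input (`drug_properties()` has no default); the generator's truth uses
2413 nmol/mg for eplerenone (molar mass 414.5 g/mol) and an approximate
2273 nmol/mg for PF-03882845. Because the potency truths are stated on the
resulting concentration scale, this choice sets units, not conclusions.
Bioavailability is fixed at 1: only apparent oral parameters are
identifiable from oral data.

## Pharmacodynamics

Three endpoints, two turnover structures (`simulate_uacr()`,
`simulate_delta_response()`):

* **UACR** follows an indirect-response model whose production is inhibited
  by drug:
  $\frac{dR}{dt} = K_{in}\left[1 - \frac{I_{max} C}{C + IC_{50}}\right] - K_{out} R,$
  started from a per-animal, non-steady-state baseline $R(0) = UACR_0$.
  Untreated (vehicle-aldosterone) animals rise towards $K_{in}/K_{out}$;
  drug slows or prevents the rise. The drive $C$ is *total* plasma
  concentration; protein-binding correction is applied afterwards in the
  metrics layer.
* **Drug-induced serum K⁺** uses the double-delta transform
  $\Delta(T) = (Tx_T - Tx_0) - (Veh_T - Veh_0)$ — each treated animal's
  change from baseline minus the vehicle group's mean change — so
  $\Delta(0) = 0$ by construction and disease- and time-trends cancel
  (`double_delta()`, `vehicle_reference()`). The transformed endpoint
  follows a stimulated-input model
  $\frac{d\Delta}{dt} = \frac{K_{in,max} C}{C + EC_{50}} - K_{out}\Delta.$
* **Acute urinary Na⁺/K⁺** reuses the stimulated-input structure on the
  double-delta of the Na⁺/K⁺ ratio, with two differences: observations are
  timestamped at the midpoints of the urine collection intervals
  (0–2, 2–4, 4–7 h → 1, 3, 5.5 h), and the drive is the *free*
  concentration normalised to the drug's in-vitro potency
  ($C \cdot f_u / IC_{50,\text{in vitro}}$), making the estimated EC₅₀
  dimensionless and directly comparable across drugs. The vehicle reference
  pools the vehicle animals of both drug studies.

$K_{in}$, $K_{out}$ and $I_{max}$ (or $K_{in,max}$) are shared between
drugs; only the potency is drug-specific. Chronic rates are reported per
day, acute rates per hour.

# Two-stage estimation

Estimation is piece-wise, mirroring the study analysis: stage 1 fits each
animal's PK alone (`fit_pk_individual()`, `fit_pk_study()`); stage 2 fits
the pooled two-drug PD model with the individual PK parameters *fixed*
(`fit_pd_pooled()`). This two-stage scheme replaces full nonlinear
mixed-effects machinery; with 10 concentration samples per animal the
individual fits are well conditioned, and the PD stage never revisits them
(asserted in the tests). Parameters whose between-animal variability the
study design cannot resolve (the two-compartment distribution constants
`q`/`v2`, the zero-order duration) are carried into the individual fits as
fixed population values via `pk_structure()`.

Residual error is proportional for concentrations and UACR (strictly
positive, right-skewed endpoints; the UACR stage uses fixed observation
weights $1/y^2$) and additive for the delta endpoints (which can be
negative). Optimization works on log-transformed positive parameters and a
logit-transformed $I_{max}$ (bounded in $[0,1]$), with seeded multistart
(default 5 jittered launches; the replicate studies in the acceptance
checks use 2 launches for stage 1 and 3 for stage 2, which the
well-conditioned fits there do not need more of). Non-convergence is
flagged on the returned object, never silent.

Two implementation details matter for accuracy and speed:

* **Per-animal baselines are profiled.** The UACR trajectory is linear in
  $UACR_0$: $R(T) = UACR_0 e^{-K_{out}T} + K_{in}\int_0^T
  e^{-K_{out}(T-s)} I(C(s))\,ds$. For any candidate value of the shared
  parameters the weighted-least-squares baseline of each animal has a
  closed form, so ~100 baseline parameters never enter the optimizer; they
  are reported in the fit's `$baseline` table.
* **The response integral is evaluated by exact segment quadrature.** The
  drive $C(t)$ is represented piecewise-linearly on a 0.25 h grid (0.02 h
  for the 7 h acute study) solved once per fit by `lsoda`; the integral of
  the saturable drive over each segment has a closed form
  ($\int C/(C+p) = \Delta t\,[1 - \tfrac{p}{c_1-c_0}\log\tfrac{c_1+p}{c_0+p}]$),
  and the slowly varying kernel $e^{-K_{out}(T-s)}$ is taken at segment
  midpoints. This matches the simulators' piecewise-linear forcing to
  solver tolerance (noise-free round trips recover parameters to
  $\sim 10^{-5}$ relative) at a fraction of the cost of per-iteration ODE
  solves, and the objective's analytic gradient falls out of the same
  formulas.

Confidence intervals: curvature-based (asymptotic) intervals come with
every fit; `bootstrap_ci()` provides case-resampling (subjects within
group) percentile intervals, and `ti_confidence_interval()` forms the TI
interval from paired bootstrap replicates of the two potencies. The
published table reports CIs without naming a method; the bootstrap is this
package's choice.

# Therapeutic-index metrics

For each drug, `free_ec50()` multiplies the total-concentration potency by
the unbound fraction ($f_u$ = 0.0038 for PF-03882845, 0.68 for
eplerenone), `potency_normalized()` divides by the in-vitro potency
(0.75 nM and 109 nM), and `therapeutic_index()` takes the ratio of the
normalised serum-K⁺ potency to the normalised UACR potency. Within a drug
$f_u$ and the in-vitro potency cancel algebraically, so TI equals the raw
EC₅₀ ratio — the function computes both routes and asserts the identity.
`ti_table()` assembles the table-shaped report (estimates, CIs, free and
normalised potencies, TI) and attaches the cross-drug fold ratio; display
rounding is 3 significant figures, all internal arithmetic is full
precision. With the published inputs the TIs are 84.0 and 1.47 and their
ratio is 57-fold.

# The synthetic-study generator

No animal-level data are deposited, so `generate_chronic_study()` and
`generate_acute_study()` create datasets with the statistical structure the
analysis assumes, and `default_truth()` carries the study conditions:

* Design: two chronic studies of 5 groups × 11 animals (vehicle-sham,
  vehicle-aldosterone, three BID dose arms; eplerenone 15/50/450 mg/kg,
  PF-03882845 5/15/50 mg/kg), dosing at 6 am/4 pm (alternating 10 h/14 h
  intervals) for 27 days; PK samples at 1/2/4/7 h on days 1 and 26, 7 h
  post-dose on day 14, and a terminal sample 16 h after the final dose;
  UACR on days 0/14/25; serum K⁺ on days 0/14/27. The acute design doses
  once at 8 am (eplerenone 5/30/300, PF-03882845 3/10/30 mg/kg), collects
  urine over 0–2/2–4/4–7 h and plasma at 0/1/2/4/7 h.
* Published values used as truth: all four chronic potencies (10.4/671 nM
  UACR; 874/988 nM serum K⁺), both acute normalised EC₅₀s (3.10/5.92),
  $f_u$ and the in-vitro potencies.
* Artifact choices (not published; chosen once and documented here):
  turnover rates $K_{in} = 6$ UACR-units/day, $K_{out} = 0.06$/day,
  $I_{max} = 0.9$, baseline $UACR_0 \sim$ log-normal(mean 30, CV 30%) — so
  the untreated group roughly triples its UACR by day 26;
  $K_{in,max} = 0.25$ mmol/L/day and $K_{out} = 0.2$/day for serum K⁺ with
  a 0.4 mmol/L aldosterone-driven decline in vehicle animals;
  $K_{in,max} = 1.5$/h, $K_{out} = 0.35$/h and baseline 3.5 ± 0.3 for the
  acute Na⁺/K⁺ ratio; rat-plausible PK (e.g. PF-03882845 chronic:
  two-compartment, $k_a$ 1.5/h, CL 2 L/h/kg, $V_1$ 1.5 L/kg, Q 0.5,
  $V_2$ 2, 1.8-fold clearance induction; eplerenone chronic:
  one-compartment, CL 3 L/h/kg) chosen so that trough concentrations
  bracket the potency truths — the identifiability the published CIs imply;
  between-animal log-normal CVs of 25% on $k_a$, CL and $V_1$ (the
  parameters the study put population variances on); proportional residual
  CVs of 15% (concentration) and 25% (UACR); additive SDs of 0.15 mmol/L
  (serum K⁺) and 0.4 (Na⁺/K⁺ ratio); acute group size n = 6 (not stated in
  the source study).
* Aldosterone infusion is not modelled mechanistically: it is the disease
  condition ($UACR_0 < K_{in}/K_{out}$, rising trajectory) switched on for
  infused groups; sham animals stay at baseline.

What passing recovery tests on these data do and do not show: they
demonstrate that the estimation chain is consistent — it recovers the
parameters that generated data with exactly the assumed model, the assumed
error structure and the stated design. They do not validate the model
against real rats: real UACR errors are unlikely to be exactly
proportional, real clearance induction is not exactly linear-in-time, and
real baselines are not exactly log-normal.

# Numerical choices and limitations

* ODE integration: `lsoda`, `rtol 1e-8` throughout; PK systems are
  integrated piecewise between dose events (restarting at each
  discontinuity) and batched across animals.
* Drive grid: 0.25 h (chronic) / 0.02 h (acute); all dose and observation
  times fall on grid nodes, so interpolation kinks never sit inside a
  quadrature segment.
* Repeated disposition eigenvalues (a measure-zero configuration) are
  split by a $10^{-7}$ relative nudge.
* Tie-breaks: multistart jitter SD 0.4 on the transformed scale; the best
  objective wins; `nlminb` iteration cap 150.
* Degenerate inputs are rejected, not coerced: empty vehicle sets, missing
  time-0 observations, dose rows carrying observations, non-monotone
  within-subject times, under-determined fits.
* The asymptotic CIs use the curvature of the concentrated (profiled-error)
  likelihood; they ignore baseline-profiling uncertainty and are the cheap
  alternative to the bootstrap.
* Known limitations: no saturable elimination, enterohepatic
  recirculation, lag times, effect compartments or tolerance models; no
  full mixed-effects estimation (two-stage by design); eplerenone's UACR
  potency is weakly identified at the study design (its exposures sit far
  above the UACR IC₅₀ only at the top dose), which the wide published
  interval reflects and the stochastic tests reproduce.

# Reproducing the analysis

`run_pipeline(pipeline_config("chronic", seed = 1))` generates a chronic
study, runs both estimation stages and produces the TI table;
`pipeline_config("acute", ...)` does the same for the acute biomarker
study. `scripts/acceptance.R` regenerates the headline numbers (the two
TIs, and median recovered potencies across 20 seeded replicate studies at
the full design) from a single seed. Problem sizes there — 20 replicates,
2 stage-1 and 3 stage-2 multistart launches — are the package's choice of
desk-scale defaults for a laptop-class single-CPU run.
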