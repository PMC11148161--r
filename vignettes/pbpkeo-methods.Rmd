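---
title: "Methods: the osimertinib PBPK-EO model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the osimertinib PBPK-EO model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model structure and its assumptions, the parameters that matter, what
was genuinely open during the design and how each choice was made, the
numerical settings, and what the shipped tests do and do not demonstrate.

## Scope and structure

The package couples a reduced whole-body PBPK model of osimertinib — a
lipophilic (logP 5.45), very highly protein-bound (fup 0.011), basic
(pKa 9.5) covalent EGFR inhibitor — to a receptor-turnover model of EGFR
engagement in brain tissue. The clinical questions it serves are framed by
two thresholds: trough EGFR occupancy of the sensitising mutants at or
above 80% (efficacy), and a steady-state plasma trough below 711 nmol/L
(safety).

The PBPK core treats all organs as flow-limited with
tissue-composition-based partitioning except the brain, which is
permeability-limited with four sub-compartments (vascular plasma, blood
cells, interstitial, intracellular). Oral absorption is a Weibull
dissolution in the stomach (t50 = 15 min, shape 0.92, half the dose
dissolved at t50 by construction), first-order gastric emptying with mean
time 120 min, and permeability-limited uptake from a single intestinal
segment. Elimination is six-CYP hepatic metabolism (CYP1A2/2A6/2C9/2E1/
3A4/3A5 intrinsic clearances scaled bottom-up by hepatic abundance ×
microsomal protein × liver weight), intestinal CYP3A4, and renal
clearance GFR × fup. The ODE right-hand side is compiled C (28 states);
mass balance holds to machine precision and is asserted to 1e-6 in the
tests.

## Parameters, units and provenance

All drug-specific constants live in `inst/extdata/osimertinib.yaml` with
explicit unit comments; `parameter_table()` flattens them for reporting
and round-trip checks. Three groups deserve comment.

* **Measured/published drug constants** (physicochemistry, CYP and
  transporter intrinsic clearances, binding kinetics, K_BRT,p = 2.89,
  Kp scale 1.5) are stored as printed. The transwell-assay back-calculation
  is instructive: the published efflux clearances (ABCB1 73.4, BCRP 15.9
  µL/min/10⁶ cells) are reproduced by
  `CLint,u = 2·Papp,A-B·(NFR−1)·SA/(γ·cells)` with a *single* implied
  assay scale — SA 1.12 cm² (a standard 12-well insert) and 3.92 × 10⁶
  cells — for both transporters; the fixture records this as the implied
  scale, not as an author-stated value.
* **Reference-human plumbing** (organ volumes and blood flows, tissue
  composition for the partitioning equations, CYP abundances, MPPGL,
  GFR, brain sub-compartment fractions) are standard literature values
  shipped as documented fixtures. They are not the package's contribution
  and absolute accuracy is absorbed by the calibration protocol below.
* **Perpetrator records** (`inst/extdata/perpetrators.yaml`) are reduced
  one-compartment exposure models with unbound Ki / Emax–EC50 terms.
  Every entry is a literature-sourced substitute (flagged per record), so
  the exact DDI ratios inherit that uncertainty; the direction and
  monotonicity of each interaction do not.

Albumin is handled entirely through a dimensionless ratio because the
printed absolute values are internally inconsistent (0.31 g/dL in the
parameter table against 2.8–3.5 g/dL in the demographics and a 1.0–6.0
g/dL sweep range); the reference patient albumin is 3.1 g/dL.

## The plasma-protein scale factor and its orientation

`ppsf()` implements `PPSF = 1/(fup + (1 − fup)·albumin_f)`. With
`albumin_f = albumin/albumin_ref` (the *physiological* orientation) this
is algebraically the standard albumin-dilution relation: hypoalbuminemia
raises the unbound fraction. That orientation is the function's default
and is verified in the tests against the independent dilution formula
(fup 0.011 at 0.31 vs 0.45 albumin units gives PPSF ≈ 1.444, scaled fup
≈ 0.0159).

The *simulation pathway*, however, uses the reciprocal ("as printed")
orientation, set explicitly in the shipped configuration. The reason is
empirical: the published behaviour of this model — plasma trough rising
above 711 nmol/L when albumin falls ~0.65-fold, and intracranial
occupancy falling when albumin rises — is only reproducible under
restrictive hepatic clearance if lower albumin *lowers* the effective
unbound fraction. Under the physiological orientation, lower albumin
raises fup, raises clearance, and *lowers* total exposure, the opposite
of the published sweep. Both orientations are selectable and every result
records which was used; users applying the model prospectively should
prefer the physiological orientation and treat the as-printed default as
behaviour-faithful reproduction.

## The brain model and K_BRT,p

The blood–brain barrier flux is
`PS·(K_BRT,p·fu·C_vascular − C_interstitial) − CL_efflux·C_interstitial`.
K_BRT,p (2.89) is treated as the passive unbound interstitial:plasma
equilibrium partition — physically readable as ionization trapping of a
pKa-9.5 base in the slightly acidic brain compartments, which predicts a
ratio of the same magnitude. The efflux clearance is the transwell-derived
ABCB1 + BCRP intrinsic clearance scaled by a fixed cell count, with the
printed transporter concentrations used as relative activity anchors
(multiplier 1 at base). `brain_kpuu()` reports the interval-averaged
attenuation, exactly `PS/(PS + CL_efflux)` at periodic steady state and
guaranteed to lie in (0, 1]; instantaneous concentration ratios can
transiently exceed it because the brain lags plasma. The intracellular
partition is pinned so that the passive-equilibrium *total* brain:plasma
ratio equals K_BRT,p, making the volume-weighted total brain
concentration track ~2.89 × plasma at base.

## Calibration: two factors, fitted once, frozen

Absolute reference-human physiology is not recoverable from the published
text, so two — and only two — free factors absorb it: a global hepatic
CLint scale and the brain passive permeability PS. They were fitted
sequentially by monotone root finding against the published 80 mg
once-daily *population* predictions (final-interval plasma AUC
12,382 nmol·h/L; brain interstitial free trough 12.0 nmol/L) using the
Planchard-demographics population (n = 100, internal seed 20260915), then
frozen into the configuration (`hepatic_clint_scale = 1.3354`,
`brain_ps = 12.39 L/h`). No experiment re-tunes them; every validation
number downstream is therefore falsifiable. `calibrate()` re-runs the
protocol; `refit_hepatic_scale()` is the independent recovery harness
used by the synthetic-data tests.

One absorption fixture was anchored the same way the source model
describes anchoring its own absorption parameters — to the observed peak
time (~6 h): a mucosal surface-amplification factor of 3.0 on the
single-segment permeability, without which the single-dose peak falls at
16 h. It was set before, and independently of, any exposure-target
comparison.

## The occupancy model, its drive, and the locked mode

The association constants are tabulated in µM⁻¹ s⁻¹, but the printed
occupancy outcomes are not jointly consistent with that reading: with the
free interstitial drive (~0.012 µM) and s⁻¹ constants converted to hours,
the resistant C797S variant would sit near 80% occupancy, not the
published ~10%. The package therefore carries the drive and time base as
one auditable configuration pair and `select_eo_mode()` runs the deciding
experiment: mode A (free interstitial drive, s⁻¹ × 3600) versus mode B
(total-brain drive, numerals per hour). Mode B reproduces both published
findings (C797S ≈ 10%, sensitising mutants > 80%) and is locked in the
shipped configuration; every manifest records it.

Two structural facts about the printed equations are flagged rather than
"fixed". First, occupancy is exactly invariant to the initial receptor
concentration EGFR₀ (the system is linear in receptor species and the
drug is not depleted by binding), so the EGFR-T0 sweep is flat by
construction. Second, the system has no non-zero stationary point: with
finite koff, complex dissociation eventually refills the free-receptor
pool and true equilibrium occupancy is zero. The published outcomes live
on the transient quasi-plateau `kon·C/(kon·C + kdeg + koff)`
(`qss_occupancy()`), which is a valid description while koff is slow
relative to free-receptor relaxation. The oracle-agreement tests run in
that separated regime; at the printed koff = 0.001 h⁻¹ and the C797S
kon·C the 14-day trough sags to ~8.5% against the 10.4% plateau, and the
package reports the faithful ODE value. The occupancy trough is the
minimum over the final dosing interval, not the pre-dose sample, because
occupancy lags concentration.

## Virtual populations and the synthetic-data generator

`sample_population()` draws independent median-1 log-normal multipliers
(the standard exp(η) convention) on hepatic CLint (CV 40%), intestinal
permeability (20%), brain PS (25%) and ABCB1 activity (25%), plus
log-normal albumin (10%) and body weight (15%) around the demographic
means; missing demographic cells fall back to the patient means. The CVs
were chosen once so the simulated exposure spread emulates the published
34–46% CVs (the shipped settings give AUC CV ≈ 37%, trough CV ≈ 43%) —
the source populations came from a simulation platform whose variability
model is not published, so this layer is declared surrogate behaviour.
Subjects are reproducible from (seed, id).

`generate_synthetic_observed()` overlays multiplicative log-normal noise
on model predictions and stores the ground truth, supporting the
parameter-recovery experiment (n = 16 subjects, rich sampling, 20% CV
recovers the hepatic scale within 10%; the shipped run recovers it within
~1%). What these tests show: the estimation machinery is unbiased on data
generated by the model itself. What they do not show: robustness to model
misspecification, covariate structure, or real assay error, none of which
the generator emulates.

## Numerical choices

LSODA with rtol 1e-8, atol 1e-10 µM, event-based dosing (doses are `add`
events on the gastric solid state; output rows at a dose instant hold the
pre-event state), fixed 0.1 h output grid, 14-day horizons (plasma
reaches periodic steady state by ~day 6; day-13 vs day-14 troughs agree
to <1%). The Weibull dissolution hazard uses time since the most recent
dose and is capped near t = 0 where the shape < 1 form diverges.
Threshold crossings are bracketed on a grid and refined by log-bisection
to 1% relative precision; absent sign changes are reported as `NA` rather
than extrapolated. Dose linearity is exact by construction
(auto-inhibition/induction off by default) and verified to 1e-6, which
licenses dose-scaling of population predictions across arms of the same
study. Problem sizes throughout (n = 100 populations, 14-day horizons,
5–15-point sweep grids) are the study conditions of the reproduced
experiments.

## Known limitations

* The published sweep findings (ABCB1 ~2-fold and albumin ~1.6-fold
  crossings of the 80% occupancy threshold) are not reproducible under
  *any* single drive/unit convention that also reproduces C797S ≈ 10%:
  with the locked mode the mutant occupancy sits near 98% and only
  collapses below 80% at ~70-fold ABCB1 or ~9-fold albumin. The package
  computes and reports the crossings it actually finds. Relatedly, the
  brain-permeability calibration pinned by the 12 nmol/L intracranial
  target leaves the BBB passive-dominated (attenuation ≈ 0.79), so
  occupancy is intrinsically insensitive to 2-fold efflux changes — in
  agreement with the model's own sensitivity scan.
* A strictly linear model cannot reproduce sub-proportional low-dose
  population predictions; the 20 mg comparisons inherit that.
* 160 mg once daily and 80 mg twice daily exceed the 711 nmol/L plasma
  trough threshold in this implementation (as they do in the published
  exposure predictions themselves) and are flagged infeasible.
* No enterohepatic recirculation, metabolite kinetics, food effects,
  segmented intestinal transit, transporter DDI at the BBB, or
  mechanism-based inhibition. CSF is not a distinct compartment; the
  interstitial free concentration stands in for intracranial free drug.
* Perpetrator fixtures are substitutes; exact DDI ratios (especially the
  strong-inducer magnitude) carry that uncertainty.
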