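---
title: "Methods: mechanical power, FDG kinetics and lung aeration in vilipower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mechanical power, FDG kinetics and lung aeration in vilipower}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vilipower)
```

`vilipower` implements the computational core of a ventilator-induced
lung injury (VILI) imaging study design: respiratory mechanics and
mechanical power from ventilator waveforms, tissue-normalized
fluorodeoxyglucose (FDG) uptake from dynamic PET, lung aeration from
quantitative CT, and the nonparametric statistics that link them. This
vignette explains each model, the tunable parameters, the synthetic-data
generators that stand in for unreleased raw animal data, and the
numerical and design choices made where more than one convention exists.

## Respiratory mechanics

A recording is a uniform time grid of airway pressure `paw` (cmH2O),
flow (L/s, inspiration positive) and optionally esophageal pressure
`peso`. Breaths are detected at upward flow crossings of a +0.02 L/s
threshold, armed only after flow has been non-positive for 50 ms; both
numbers are arguments of `segment_breaths()` because they are
instrument-dependent, and the defaults are robust against typical
pneumotachograph noise. Volume is the per-breath trapezoidal integral
of flow, re-zeroed at each onset; no global leak correction is
attempted, so slow drift never accumulates across breaths.

Per breath, `breath_pressures()` reports the cycle maximum and mean of
`paw`, the plateau pressure as the mean over the last 100 ms of the
zero-flow end-inspiratory pause, the measured PEEP as the mean over the
last 100 ms of expiration, and the driving pressure
`dP = Pplat - PEEP` by construction. The 100 ms windows are arguments:
clinical practice ranges from point reads to 300 ms averages and no
single convention is canonical. Breaths without a pause report `Pplat`
and `dP` as missing rather than guessing from the peak. Ordering
violations caused by noise (`Ppeak < Pplat`, `Pplat < PEEP`) are
flagged, not errors.

Transpulmonary pressure is `paw - peso`. Its end-expiratory value is
frequently negative in lavage-injured lungs (the esophageal baseline
exceeds PEEP), and the transpulmonary driving pressure is defined as
the plateau-window mean of `P_trans` minus its cycle minimum. With a
constant-flow simulator the cycle minimum sits at expiration onset
(elastic recoil equal to the plateau's, minus the resistive dip), which
the tests exploit as a closed form.

`fit_equation_of_motion()` regresses `paw` on volume and flow
(multiple linear regression):

* linear: `paw = E*V + R*V' + P0`
* volume-dependent: `paw = E1*V + E2*V^2 + R*V' + P0`

The pause samples are excluded from the design matrix: with flow
pinned at zero and volume constant they are collinear with the
intercept and only dilute the fit. The percentage of volume-dependent
elastance is `%E2 = 100 * E2*VT / (E1 + E2*VT)`, a signed quantity:
negative values indicate elastance falling with volume (tidal
recruitment), positive values rising elastance (overdistension). The
offset `P0` is reported as fitted and deliberately not constrained to
the set PEEP.

## Mechanical energy and power

The mechanical energy of a breath is the numerical (trapezoidal)
integral of airway pressure over inspired volume along the inspiratory
limb — onset through end of pause — of the tidal pressure-volume loop,
converted with 1 cmH2O·L = 0.0980665 J. Mechanical power is energy
times respiratory rate.

Two pressure references are first-class, because the literature does
not agree on whether the work performed against PEEP belongs to the
tidal energy. `reference = "atmospheric"` (default) integrates the
pressure as recorded, so the PEEP-level work `PEEP*VT` is included;
`reference = "peep"` subtracts the measured PEEP first. Both are exact
conventions of the same loop; for a constant-flow breath the closed
forms are `PEEP*VT + E*VT^2/2 + R*flow*VT` and `E*VT^2/2 + R*flow*VT`
respectively. A point worth recording: the study conditions' typical
0 h values (E 57.3 cmH2O/L, R 12.4 cmH2O·s/L, RR 31, VT 6 ml/kg at
47.7 kg) reproduce a median power near 13.5 J/min under the
PEEP-referenced convention, which is why the cohort generator maps
target power to lung parameters through that convention.

The resistive energy component is the integral of the fitted resistive
pressure `R*V'` over inspired volume; the elastic component is defined
residually as `ME_total - ME_resistive`. This residual closure is a
deliberate choice: a geometric split of the loop area depends on the
model fitting the data perfectly, whereas the residual definition makes
`elastic + resistive = total` an identity, so the decomposition always
adds up — as component tables in this field do. With the atmospheric
reference the elastic component absorbs the PEEP-level work.

## FDG kinetics

The net uptake rate `Ki` comes from Patlak graphical analysis:
ordinary least squares of `C_T(t)/C_p(t)` on
`(integral of C_p)/C_p(t)` over frames whose mid-time is at or past
`t_star`. The plasma curve is interpolated piecewise-linearly and
integrated exactly. `t_star` defaults to 20 min: for the rate
constants typical of lung FDG studies the transient term
`exp(-(k2+k3)t)` has decayed below 1 % by then, and the tests verify
that later `t_star` only shrinks the residual bias. Frames are
unweighted by default (`weights = "duration"` is available); with
noiseless data the choice is irrelevant and with the frame-noise model
used here duration weighting is close to inverse-variance.

The blood fraction comes from a nonlinear least-squares fit of the
irreversible two-tissue-compartment model,
`C(t) = (1-Vb)*C_2TC(t) + Vb*C_blood(t)`, with the analytic solution
`C_2TC = K1*k3/(k2+k3) * Int(Cp) + K1*k2/(k2+k3) * exp(-(k2+k3)t) (*) Cp`
evaluated on a 0.05 min grid (a recursive trapezoid for the
exponential convolution) and averaged over frame intervals. The blood
curve is taken equal to the plasma input — no hematocrit correction —
which is the simplest defensible choice when whole-blood samples are
not modeled. The macro rate `K1*k3/(k2+k3)` from this fit cross-checks
the Patlak slope.

Tissue-fraction normalization is the study's central quantity:

```
KiS = Ki / (1 - F_gas - F_blood)
```

A voxel's measured `Ki` is diluted by the gas and blood it contains;
dividing by the tissue fraction compares regions at equal
tissue-level metabolic activity. This is also why the simulator's
default tracer curve carries `vb = 0`: on a mixed curve the Patlak
slope measures `(1-Vb)*Ki`, which is exactly the dilution the
normalization removes, and keeping the default pure makes the recovery
oracles unambiguous. `delta_kis()` is the difference of ROI medians
(second minus first scan).

## CT aeration

Gas fraction is `HU/-1000` clipped to `[0, 1]`. Aeration compartments
are hyper (< -900 HU), normal ([-900, -500)), poor ([-500, -100)) and
non-aerated (>= -100 HU), left-closed on the denser side. The
non-aerated boundary is -100 HU, the standard quantitative-CT
convention, adopted over a literal reading of inconsistent printed
ranges. Voxel mass is voxel volume x tissue fraction x 1.0 g/ml
(water-equivalent density); positive-HU voxels saturate at tissue
fraction 1 and voxels outside [-1024, 100] HU are counted but flagged
in a QC field. The partition is exhaustive and exclusive, so
compartment masses sum to the total exactly and relative masses to
100 %.

## Statistics

The statistical layer reproduces the conventions of SPSS, the software
named for the original analyses, because asymptotic p-values differ
across packages in exactly the details that matter at n = 8:

* Wilcoxon signed-rank: zero differences dropped, midranks for ties,
  tie-corrected variance, **no** continuity correction,
  `p = 2*(1 - Phi(|Z|))`. At n = 8 the minority-sign rank sums 0, 1,
  2, 3 give p = 0.0117, 0.0173, 0.0251, 0.0357 — the 0.012 / 0.017 /
  0.025 / 0.036 ladder such studies print.
* Spearman: Pearson correlation of midranks;
  `t = rho*sqrt((n-2)/(1-rho^2))` with `n-2` df, two-sided. Ranks with
  `sum(d^2) = 22` at n = 8 give rho = 0.738, p = 0.037. `|rho| = 1` is
  flagged degenerate rather than given a fake finite p.
* Median (IQR) with the SPSS weighted-average percentile (R type 6);
  the `type` argument exposes the R-default type 7 because the two
  disagree on small samples (IQR of 1..5 is 3 vs 2).
* No multiple-testing correction anywhere, matching the exploratory
  design.

## Synthetic data

The generators define the study conditions and are tested code, not
fixtures:

* `simulate_ventilation()`: volume-controlled ventilation, VT 6 ml/kg
  at 47.7 kg, I:E 1:1, flow 35 L/min, PEEP 5 cmH2O, 100 Hz; constant
  flow, then a pause filling the rest of the inspiratory time, then
  passive exponential expiration. Airway pressure is computed from the
  equation of motion applied to the *discrete* trapezoidal volume of
  the sampled flow, so noiseless recordings are fit exactly —
  regression recovery is then a true oracle, not a tolerance game. The
  sampled flow is shaped so its trapezoid reaches VT exactly at the
  pause, and the expiratory samples are rescaled so the volume trace
  closes at zero (otherwise the flow discontinuity leaks half a sample
  of volume per cycle). The expiratory time constant is `R/E1` capped
  at one-eighth of the expiratory time so exhalation completes within
  the cycle; only the inspiratory limb enters the energy integral, so
  the cap does not touch any measured quantity except keeping the
  measured PEEP clean of trapped-gas pressure.
* `simulate_tracer()`: Feng-model plasma input (A1 = 851.1,
  lambda1 = -4.13, A2 = 20.8, lambda2 = -0.12, A3 = 21.9,
  lambda3 = -0.01, minute scale) over a 75 min schedule with short
  early frames; tissue frames from the same analytic 2TC solution the
  fitter uses (a deliberate inverse-crime design for exact recovery
  tests); Gaussian frame noise with SD proportional to
  `1/sqrt(duration)`.
* `simulate_ct()`: truncated Gaussians per compartment (means
  -950/-700/-300/0 HU, SD 30), with per-compartment voxel counts
  solved so the expected compartment *mass* fractions equal the
  request — mass per voxel differs between compartments, so drawing
  counts from the mass fractions directly would bias the recovery.
* `simulate_cohort()`: a Gaussian copula links per-animal median power
  and the KiS increase at a target Spearman correlation (0.74, n = 8 by
  default), with `rho_P = 2*sin(pi*rho_S/6)`; the KiS increase is
  log-normal (median 0.0184 min^-1) so every animal's second scan
  exceeds its first, reproducing the all-positive paired
  configuration; power marginal normal with median 13.5, IQR 4.9
  J/min. The finite-sample expectation of the sample Spearman rho,
  `E[r_S] = 6/(pi(n+1)) * (asin(rho) + (n-2)asin(rho/2))`, is exposed
  as `expected_spearman()` and is the reference the recovery tests
  compare against — at n = 8 it is noticeably below the population
  value (0.675 vs 0.74). Each animal also receives lung parameters
  solved from its target power (PEEP-referenced closed form), so the
  waveform path of the pipeline reproduces the copula's power ranks.

What the generators deliberately do not emulate: cardiogenic
oscillations, ventilator trigger artifacts, leak and drift, PET
reconstruction noise correlations and partial-volume effects,
anatomical CT structure, and between-variable physiological couplings
other than the single power-inflammation link. Passing recovery tests
therefore demonstrate correctness of the estimators on clean forward
models, not robustness to every artifact of real recordings.

## Problem sizes and determinism

The shipped tests and the acceptance script use 100 Hz recordings of
2-10 breaths, 35-frame tracer studies, one million voxels for the CT
recovery, and 100-500 seeded replicates for the Monte-Carlo checks;
these sizes keep every oracle's sampling error an order of magnitude
below its tolerance. Every stochastic path takes an explicit seed and
is bit-reproducible; `run_pipeline()` writes result CSVs rounded to 10
significant digits so reruns are byte-identical, plus a JSON manifest
with an MD5 hash of the effective configuration.

## Known limitations

* Breath detection assumes flow crosses the threshold once per cycle;
  pressure-support or spontaneous efforts would need different logic.
* `Pplat` requires an end-inspiratory pause; none of the estimators
  invent one.
* The Patlak and 2TC paths assume an irreversible tracer over the scan
  window; k4 > 0 would bias `Ki` downward.
* The equality of blood and plasma activity ignores hematocrit and
  red-cell tracer handling.
* Aeration masses assume water-equivalent tissue density; contrast
  agents or calcification violate it (flagged by QC, not corrected).
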