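---
title: "Methods: testing linear summation of co-stimulation forces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing linear summation of co-stimulation forces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costim)
```

## The question and the procedure

When two stimulation sites — an epidural electrode over the sacral spinal
cord and a motor-point electrode in a thigh muscle — are driven together,
is the evoked isometric limb force simply the vector sum of the forces each
site evokes alone?  `costim` implements the complete statistical procedure
for answering this with blocked isometric-force data, and a synthetic
generator so the procedure can be validated end to end without animal data.

The pipeline is: (1) force traces are demeaned by the 400 ms pre-stimulus
baseline and averaged over a 200 ms window starting 300 ms after onset to
give one 3-D force vector per trial; (2) trials with magnitude at or below
0.03 N are discarded (directions of near-zero vectors are unreliable);
(3) each co-stimulation trial is paired with the *same-block* individual
responses of its two constituent conditions, whose vector sum is the
linear prediction; (4) prediction, magnitude, direction and relative
errors are contrasted between spinal/muscle and muscle/muscle
co-stimulation in mixed-effects models; (5) a case-level bootstrap asks
whether the observed errors exceed what pure trial-to-trial variability
would produce under exact summation.

Coordinates are body-referenced: +x rostral, +y dorsal, +z lateral; the
sagittal plane is x–y, flexion forces point rostral–dorsal, extension
forces caudal–ventral.

## The synthetic generator

Each site is a `recruitment_model()`: magnitude follows a sigmoid
$f(a) = F_{max}/(1+e^{-(a-a_{50})/k})$ of current $a$ (µA), which is
non-decreasing; direction lives in the sagittal plane and rotates along a
normalized sigmoid schedule across the amplitude grid.  Spinal defaults
(grid 160–440 µA, $F_{max}$ = 3 N) rotate from 70° (flexion) steeply
around 300 µA; muscle defaults (600–1440 µA, $F_{max}$ = 1.2 N) stay near
−120° (extension).  The *total* rotation is not set directly: it is
calibrated by root-finding so the noiseless curve's circular angular
deviation equals 47.6° (spinal) and 2.7° (muscle) — the level of
direction dispersion characteristic of each site class.  With the default
schedules this yields ≈ −118° of spinal and ≈ 7.4° of muscle rotation.
The steep spinal schedule concentrates directions at the flexion and
extension ends, which is what makes a 47.6° dispersion attainable within
a ~120° rotation.

Trial-to-trial noise (`noise_model()`) has two parts, matching how
variability is summarized in this preparation: additive Gaussian noise on
the magnitude, truncated at zero by inverse-CDF sampling so magnitudes
stay non-negative without re-draws, and a Gaussian rotation of the
direction *within the sagittal plane*.  We deliberately place the
direction noise in-plane rather than about a random 3-D axis: dispersion
is measured on sagittal-plane angles, and an arbitrary-axis rotation of
SD $\sigma$ would project to a sagittal circular SD systematically below
$\sigma$, so the configured parameter would not be recoverable from the
quantity the analysis actually computes.  Defaults are 0.47 N / 20.7°
(spinal) and 0.04 N / 1.0° (muscle).  Note that the circular SD of a
wrapped Gaussian with $\sigma$ = 20.7° is ≈ 20.4°, so recovered spinal
direction dispersions sit ~1.5% below the nominal parameter; this is a
property of the circular statistic, not an implementation bias.

Co-stimulation responses are the exact component-wise sum of two fresh
individual draws unless an `interaction_model()` injects a departure:
a multiplicative gain $(1+\varepsilon)$ on the sum, or saturation of the
summed magnitude at $F_{sat}$.  The interaction applies to spinal/muscle
pairs only — muscle/muscle pairs are the linear control in the study
design.  Traces (`simulate_trace()`) rise to the trial's plateau vector as
a first-order exponential ($\tau$ = 50 ms by default); real traces show a
fast rise and plateau but do not constrain the kinetics, so $\tau$, the
trace noise SD and the baseline offset are exposed, documented
placeholders.  With $\tau$ = 50 ms the 300–500 ms window recovers the
plateau to < 0.1%.

`simulate_experiment()` reproduces the session design: a recruitment-curve
phase (every grid amplitude of every site, alone), then randomized blocks
containing each selected amplitude alone plus all pairs, 45 s between
trials, spinal trains of 600 ms (15 ms period, 0.2 ms pulses) and muscle
trains of 520 ms (13 ms period, 0.12 ms pulses).  Fatigue, when enabled,
subtracts `drift × elapsed-minutes` from the noiseless magnitude (floored
at zero).  One seeded RNG stream drives the whole run, drawn sequentially
in trial order; identical configuration and seed give byte-identical
tables (tested).  We chose a single stream over per-trial substreams
because nothing is generated in parallel and sequential draws keep the
generator trivially auditable.

What the generator does *not* emulate: biophysics of recruitment (axon
collision, afferent integration), EMG, limb dynamics, across-subject
heterogeneity of recruitment curves (all simulated subjects share the
site models; only noise differs), and any magnitude-dependence of the
noise.  Passing tests therefore validate the *statistical machinery* —
they cannot certify how real spinal responses behave.

## Numerical and procedural choices

- **Half-open windows** `[start, end)` everywhere (baseline, extraction,
  50 ms sub-windows) so tiling windows never double-count a boundary
  sample; the duration-weighted mean of the tiles provably equals the
  whole-span mean, and this identity is tested.
- **Strict inequality** for the 0.03 N filter ("greater than").
- **Non-uniform sampling is rejected**, not resampled: silently
  interpolating a transducer stream can hide acquisition faults.
- **Clamped dot products** to [−1, 1] before `acos` in the direction
  error, so numerically collinear vectors give 0° or 180° rather than NaN.
  Zero-magnitude vectors yield `NA` with a warning and are excluded from
  direction models.
- **Magnitude errors** are stored signed (observed − predicted) but
  modeled as absolute values; comparing signed errors across types would
  conflate bias direction with size.
- **Pairing rule**: individual responses come from the same block as the
  co-stimulation trial; multiple same-block repeats are vector-averaged
  to minimize single-trial noise in the prediction.
- **Dispersion statistics** use sagittal-plane angles (how directions are
  displayed and summarized in this preparation); the full 3-D angle is
  used for the direction error between two specific vectors.
- **Bootstrap interval**: percentile 2.5/97.5, two-sided; observed and
  predicted draws are paired by draw index.  With several real
  co-stimulation trials per case their errors are averaged before the
  comparison.
- **Fatigue screen**: ordinary least squares of spinal magnitude on time
  in minutes (time is the independent variable), exclusion iff slope < 0
  and two-sided p < .01 — the closest reading of a "significant decrease".
  Identical timestamps leave the regression undefined; the case is kept
  with a warning.
- **Log-transform gate**: "as necessary" is operationalized as a
  Shapiro–Wilk test (α = .05) on the untransformed model's residuals
  (subsampled to 4999 if larger); the gate is overridable
  (`transform = "none"`/`"log"`).  Non-positive responses are dropped
  before a log transform, with a message, rather than offset.
- **Mixed-model p-values** default to Satterthwaite degrees of freedom
  (`lmerTest`), with Wald z available.  At six subjects the Satterthwaite
  test on the random-intercept fit is well calibrated (type-I ≈ 0.05,
  verified by simulation in the test suite); fitting the full
  random-slope structure to slope-free data is markedly conservative
  (type-I ≈ 0.01), so calibration checks match the fitted to the
  generating structure.  On non-convergence of the random-slope model the
  fit falls back to a random intercept and says so.

## Bootstrap coverage regime

The percentile interval is built from resamples of a finite pool of
individual repeats, and its frequency calibration depends on the study
conditions.  Two effects matter.  First, with only 4 repeats per site
(the eligibility floor) the empirical distribution is a coarse proxy for
the true response distribution and the interval *undercovers*
(~0.81–0.90 in direct simulation).  Second, when a case has $k$ real
co-stimulation trials, their mean error concentrates as $k$ grows while
the interval describes single-draw errors, so coverage climbs towards 1.
The package's coverage study (`simulate_costim_case()`, used by the test
suite and `analysis/05_bootstrap.R`) therefore runs the regime in which
the nominal 95% statement is meaningful: 16 individual repeats per site
and one co-stimulation trial per case, where each case's observed error
and each bootstrap draw follow the same distribution.  Both departures
are properties of the published procedure itself and are worth keeping in
mind when interpreting case counts near the eligibility floor.

## Problem sizes

The test suite and drivers use sizes chosen to keep Monte-Carlo error
well inside the asserted tolerances: 500 repeated trials for variability
recovery (3 Monte-Carlo SEs), 200 cases × 5000 draws for bootstrap
coverage, 500 simulated datasets for mixed-model type-I calibration,
1000 random vector pairs for oracle equivalence at 1e-12 relative
tolerance, and a 6-subject × 4-block default experiment (576 trials).

## Known limitations

- The trace model's rise kinetics and noise floor are placeholders; real
  transducer data should be validated against the trace-schema checks
  before trusting windowed analyses.
- Angular deviation is computed in the sagittal plane; strongly
  out-of-plane forces would need a spherical dispersion statistic, which
  is out of scope.
- The generator's subjects are exchangeable; between-animal variance in
  the *mean* error enters only through the noise realizations, so random
  slope variances estimated on synthetic data are typically near zero
  (and the fitter tolerates the resulting singular fits).
- Fatigue is screened only through the spinal magnitudes, mirroring the
  procedure it implements; muscle fatigue is assumed negligible.
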