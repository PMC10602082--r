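# costim

Do forces evoked by *combined* epidural spinal cord and intramuscular
stimulation equal the **linear vector sum** of the forces each site evokes
alone?  That question decides how hard it is to build co-stimulation
controllers for restoring movement after spinal cord injury: if responses
superpose, the response to any amplitude pair can be predicted from two
recruitment curves.

`costim` implements the full analysis pipeline for this question, driven by
a synthetic-data generator that emulates the blocked isometric-force
experiment in the anesthetized rat hindlimb (a 6-axis transducer at the
ankle, epidural stimulation over the S1 segment, motor-point stimulation of
two thigh muscles).  It is aimed at researchers designing or re-analyzing
multi-site stimulation experiments who need the statistical machinery —
not the hardware control — of such a study.

## The model and statistics

For a co-stimulation trial of sites *a* and *b*, the observed force vector
**F**<sub>ab</sub> is compared with the prediction
**F̂** = **F**<sub>a</sub> + **F**<sub>b</sub>, where **F**<sub>a</sub>,
**F**<sub>b</sub> are the (block-matched, averaged) individual responses.
The package computes:

- **prediction error** ‖**F**<sub>ab</sub> − **F̂**‖₂ (N), **magnitude
  error** ‖**F**<sub>ab</sub>‖ − ‖**F̂**‖ (signed, N), **direction error**
  ∠(**F**<sub>ab</sub>, **F̂**) (degrees), and the **relative error**
  100·‖**F**<sub>ab</sub> − **F̂**‖ / ‖**F**<sub>ab</sub>‖;
- a **combined R²** pooling residual and total sums of squares across the
  three force axes (each axis centered by its own mean);
- the circular **angular deviation** s = √(2(1−R)) (R the mean resultant
  length) for the direction dispersion of recruitment curves, contrasted
  between spinal and muscle sites with Welch's t test;
- **linear mixed models** (maximum likelihood, by-subject random intercept
  and slope, optional log transform and magnitude-nuisance covariate) for
  the error-by-co-stimulation-type contrasts, plus a windowed (50 ms)
  time-course analysis and an early (100–300 ms) vs late (300–500 ms)
  contrast;
- a **bootstrap null**: for each amplitude pair with ≥ 4 repeats of each
  individual condition (and no significant fatigue decline, p < .01 by
  regression of spinal magnitude on time), 5000 resampled "observed" sums
  and 5000 independently resampled "predicted" sums give the distribution
  of prediction errors expected under *exact* linear summation with the
  observed trial-to-trial variability; the case's actual mean error is
  compared to the 95% percentile interval.

The generator reproduces the study's structure: sigmoid magnitude
recruitment, sagittal direction rotation with amplitude (calibrated so the
noiseless spinal curve has 47.6° angular deviation and the muscle curve
2.7°), across-trial variability with spinal ≫ muscle (0.47 N / 20.7° vs
0.04 N / 1.0°), randomized blocks over all amplitude combinations, 45 s
inter-trial intervals, optional fatigue drift, optional injected
nonlinear interaction, and full transducer traces (400 ms baseline,
first-order rise, 600/520 ms spinal/muscle trains).

## Worked example

```r
library(costim)
cfg <- generator_config(n_subjects = 6, n_blocks = 4, seed = 101)
trials <- simulate_experiment(cfg)$trials
errors <- build_error_records(trials)
tapply(errors$prediction_error_N, errors$type, median)
#> muscle/muscle spinal/muscle
#>    0.06249...      1.16637...
fit <- fit_error_model(errors, response = "prediction_error_N")
fit$coefficients[2, c("estimate", "se", "p")]
#>   estimate         se            p
#>   2.829...   0.0853...  9.3...e-100   (log scale)
```

Muscle/muscle co-stimulation sums almost perfectly (median error 0.06 N,
5% of the co-stimulation magnitude; combined R² 0.86 in this run), while
spinal/muscle errors are an order of magnitude larger — and the mixed model
calls that difference decisively.  The resampling analysis then shows the
large spinal/muscle errors are exactly what linear summation *with the
spinal site's trial-to-trial variability* produces: in the run above all
44 eligible spinal/muscle cases fall inside their 95% bootstrap intervals
(`analysis/05_bootstrap.R`), so the data give no evidence of a true
nonlinear interaction.

The `analysis/` directory holds the numbered stage drivers
(`01_simulate.R` … `05_bootstrap.R`); each prints its findings and writes
its tables under `results/`.

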