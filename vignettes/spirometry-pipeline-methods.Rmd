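---
title: "Estimating spirometric indices from wearable tracheal sound and chest motion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating spirometric indices from wearable tracheal sound and chest motion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiropatch)
```

## The problem

Clinical spirometry measures forced vital capacity (FVC, L), forced
expiratory volume in one second (FEV1, L) and peak expiratory flow
(PEF, L/s) from a maximal forced exhalation into a mouthpiece. A
skin-conformal patch worn over the suprasternal notch records two
surrogate signals instead: tracheal breathing sounds (a microphone) and
chest-wall motion (a tri-axial accelerometer). `spiropatch` implements
the full analysis chain that turns such recordings into spirometric
estimates:

1. **Respiratory phase detection** — condition both channels, find
   breath-related extrema, and segment valid inspiration/expiration
   cycles.
2. **Feature extraction** — a fixed 185-dimensional acoustic + kinematic
   descriptor per breath cycle.
3. **Screening** — Boruta all-relevant selection against permuted shadow
   features, run separately per sensing modality and spirometric index.
4. **Estimation** — elastic-net regression (OLS as baseline) with
   demographic covariates, evaluated by leave-one-subject-out
   cross-validation (LOSO-CV) with strictly in-fold tuning and
   standardization, aggregated to subject-level RMSE/MAE.
5. **Mode comparison** — a random-intercept linear mixed model contrasts
   subject-level errors between the two guided maneuvers (low-effort
   vs. forceful breathing).

No public recordings accompany this problem, so the package ships a
synthetic-data module that generates multimodal sessions with ground
truth annotations and cohorts with planted statistical structure. Every
pipeline stage is exercised against those generators.

## Phase detection

The acoustic channel is band-passed 50–1000 Hz (2nd-order Butterworth,
zero-phase forward–backward filtering). Tracheal sound energy (TSEng) is
the natural log of the moving variance of the filtered audio over a
20 ms centered window (shrinking at the edges; variances floored at
`1e-12` before the log, so silence maps to a finite floor rather than an
error). The TSEng track is low-passed at 2 Hz, smoothed with 0.5 s
moving-median and moving-average windows, and resampled to a common
20 Hz envelope grid. The IMU Z axis follows the analogous path with a
5 Hz low-pass.

Extrema of both envelopes are detected by topographic prominence with a
minimum spacing of 1.5 s and a prominence threshold of 20% of the
envelope's interquartile range. IMU minima that align with a TSEng
minimum within ±1 s become inspiration onsets; IMU maxima become
expiration onsets (a `strict_expiration` flag additionally requires
acoustic confirmation for expirations; off by default, since airflow
sound alone already corroborates inspirations and the maxima are the
more robust IMU feature). A valid cycle is the consecutive pattern
inspiration → expiration → inspiration, the closing inspiration marking
the end of expiration; sessions with fewer than three valid cycles are
excluded, mirroring the three-acceptable-maneuver rule of spirometry
guidelines.

Numerical choices worth stating explicitly:

* **Zero-phase filtering** extends the signal by odd reflection sized
  from the slowest filter pole before the forward–backward pass, so the
  operator commutes with time reversal to ~1e-12 and has no phase lag at
  cycle boundaries.
* **TSEng decimation**: the 2 Hz low-pass is applied after decimating
  the full-rate log-variance track to 200 Hz. A 2nd-order Butterworth
  at 2 Hz over 8 kHz would have a normalized cutoff of 5e-4 and is
  numerically fragile; the 20 ms variance window itself is the
  anti-alias stage.
* **Smoothing windows** (0.5 s median and mean) are long enough to
  suppress sub-breath ripple on the 20 Hz grid and short relative to
  the shortest cycles (~2.7 s).
* **IQR stage**: the prominence threshold is computed on the
  conditioned (smoothed, resampled) envelope, because detection operates
  on that signal.
* **Ties** in the spacing rule keep the higher-prominence peak, then
  the earlier one. Association is nearest-first greedy, one TSEng
  minimum per IMU minimum, ties to the earlier IMU time.

## The 185-feature inventory

Per valid cycle, in a fixed documented order
(`feature_inventory()`):

| block | count |
|---|---|
| 13 MFCCs × {static, Δ, ΔΔ} × {mean, SD} × {inspiration, expiration} | 156 |
| IMU range (3 axes × {peak-to-peak, P95–P5}) × 2 phases | 12 |
| envelope/timing: per phase duration, TSEng mean/SD/max/area, audio RMS, zero-crossing rate (7 × 2), plus cycle duration, inspiratory duty fraction, expiratory/inspiratory TSEng area ratio | 17 |

MFCCs use 25 ms frames with a 10 ms hop, Hamming window, an HTK-scale
26-filter triangular mel bank to half the sampling rate, floored log
energies, and an orthonormal type-II cosine transform keeping c0–c12
(c1–c13 available by flag). Deltas are the standard regression
derivative with half-width K = 2 and replicated edge frames; the SD uses
the n−1 denominator and is 0 for single-frame segments. Quantiles are
linear-interpolation (type 7).

Only the total feature count and the MFCC/IMU-range blocks are externally
constrained; the 17 envelope/timing descriptors are this package's
completion of the inventory, chosen as the most conventional breath
descriptors, and are versioned in code. The grouping used by the
modality-wise screen assigns them to the acoustic group (they are
computed on the sound-energy-segmented cycle), giving 173 acoustic and
12 IMU features.

## Screening and estimation

`run_boruta()` follows the original all-relevant algorithm: per
iteration every candidate column is duplicated and row-permuted
("shadows"), a random-forest regression (ranger, out-of-bag permutation
importance, single-threaded and seeded for determinism) scores all
columns, and a feature scores a *hit* if it strictly beats the maximum
shadow importance. Accumulated hits are tested two-sided against
Binomial(iterations, ½) with Bonferroni correction over the currently
undecided features; significantly many hits confirm, significantly few
reject (rejected features leave the design). Survivors are tentative and
resolved by policy (reject by default). Regression forests are used
throughout because the outcomes are continuous. The screen runs once per
modality × index (6 runs) on the full table — a pre-CV application whose
optimism is acknowledged and is further constrained downstream by
regularization.

The elastic net minimizes

$$\frac{1}{2n}\lVert y - \beta_0 - X\beta \rVert_2^2 +
  \lambda\left(\alpha\lVert\beta\rVert_1 +
  \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\right)$$

by cyclic coordinate descent with soft-thresholding, in Gram
("covariance-updating") space with warm starts along a 50-point
log-spaced λ path and active-set iteration between full
Karush–Kuhn–Tucker sweeps. Predictors are standardized internally with
training-fold statistics (population SD; constant columns get a unit SD
surrogate and a forced zero coefficient); the intercept is unpenalized;
coefficients are returned on the original scale. The λ path starts at
the data-driven null threshold `max|X'y|/(n·α)` and descends to 1e-4 of
it when rows exceed predictors and 1e-2 otherwise (tiny penalties are
ill-conditioned in the weakly determined case). Convergence is a 1e-7
bound on the maximum coefficient change, with a periodic exact residual
refresh to cancel floating-point drift; non-convergence is an error,
never silent. At α = 1 the solutions agree with glmnet to machine
precision; at mixed α glmnet's internal response scaling leads it to a
slightly different point, and the test suite checks that our solution
attains at least as low a value of the objective above.

LOSO-CV holds out all rows of one subject per fold. Hyperparameters
(α ∈ {0.1, …, 1.0}, λ on the path) are tuned by an inner
leave-one-*training*-subject-out grid search minimizing subject-level
RMSE — the inner resampling unit matches the outer unit of
exchangeability — with ties resolved toward larger λ, then larger α
(sparser models). Demographic covariates (age, sex coded male = 1, BMI,
ethnicity one-hot against a Caucasian reference) enter every model and
are penalized alongside the features by default
(`unpenalized_covariates` inverts this). Subject-level RMSE and MAE are
averaged unweighted across subjects; the training-stage summary refits
the tuned procedure on all rows and predicts all rows. Reference targets
repeat the subject's single spirometer-derived value across that
subject's breath rows, following spirometry's best-of-session
convention.

Mode comparison fits `rmse ~ mode + (1 | subject)` by maximum
likelihood (lme4) on subject-level RMSE pooled across modes — partially
crossed designs are supported — and tests the mode effect with a
likelihood-ratio test against the no-mode model at α = 0.05. ML (not
REML) keeps the two models nested for the LRT. The error report flags
each LOSO RMSE against the spirometry repeatability limits of 0.15 L
(FVC, FEV1) and 0.67 L/s (PEF).

## The synthetic-data module

The generators define the study conditions for every test; they are
deterministic functions of their configuration and seed.

**Cohort.** Demographics and reference spirometry are drawn from
truncated normals calibrated to a healthy adult cohort: age 30.3 ± 6.7 y,
BMI 23.9 ± 3.3 kg/m², FVC 4.0 ± 1.1 L, FEV1 3.2 ± 0.7 L, PEF
6.9 ± 1.7 L/s, 44.4% male, ethnicity {Asian 33.3%, Caucasian 44.4%,
Southeast Asian 5.6%, Other 16.7%}. Truncation bounds (age ≥ 18,
BMI ≥ 15, volumes/flows ≥ 0.5) prevent nonphysical draws; the location
parameter of each truncated normal is solved (uniroot) so the
*truncated* mean equals the target mean — naive truncation would bias
mean age upward by ~0.5 y and break the calibration contract. FEV1 is
drawn jointly with FVC (correlation 0.9, the physiological coupling)
and clipped to FEV1 ≤ FVC; with that correlation the clip moves the
FEV1 mean by <0.02 L.

**Timelines.** Cycles are contiguous: the expiration interval runs from
the expiration onset to the *next* inhalation onset, comprising the
audible exhalation plus a silent relaxation tail — exactly the
convention the detector uses to close a cycle. Default durations
(seconds, truncated normal): low-effort inspiration 2.5 ± 0.4, audible
expiration 3.5 ± 0.5, tail 1.2 ± 0.2; forceful 1.8 ± 0.3, 1.2 ± 0.2,
1.0 ± 0.2. Only the ordering (forceful shorter) is contractual. The
recording opens on the dying tail of a previous unannotated exhalation
and closes on the onset of a next inhalation at the last `cycle_end`,
so the first and last annotated events are interior extrema rather than
edge artifacts — recordings start and stop mid-breathing, as a worn
patch's would.

**Audio.** Band-limited Gaussian noise (50–1000 Hz with extra 800–1000 Hz
energy, the tracheal band) amplitude-modulated by a smooth
per-phase sin² envelope; expiration peaks 1.5× inspiration, forceful 4×
low-effort, white sensor noise at a configurable SNR (20 dB default)
relative to in-cycle signal RMS. The base amplitude (0.03 full scale)
keeps even forceful maneuvers within 16-bit PCM range. No generative
amplitude or SNR figures exist to copy for this device class; these
defaults are the package's own, exposed in `simulation_config()`, and
only orderings are asserted in tests.

**IMU.** The Z axis interpolates cosine ramps between breath events —
every anchor has zero slope, so minima fall exactly on inspiration
onsets and maxima on expiration onsets — plus sinusoidal baseline
drift, white noise at the same SNR, and optional exponentially decaying
artifact spikes (off by default). X/Y carry attenuated copies plus
independent noise.

**Feature cohorts.** `simulate_feature_cohort()` bypasses the signal
stages: standard-normal features with a per-subject random intercept
(SD 0.3) for within-subject correlation, and an outcome
`y = intercept + Σ βx + subject effect + noise` with a named sparse β.
With zero noise the planted coefficients are exactly recoverable by
least squares, which the tests assert.

**What the simulator does not emulate:** adventitious sounds (wheeze,
crackle), mouth-radiated turbulence spectra, posture and ambient noise,
device coupling physics, or disease-altered mechanics. Passing tests
demonstrate that the pipeline recovers structure it is designed to
exploit from signals that contain it — not clinical performance on
human data.

## Test and simulation scales

Statistical checks run at sizes chosen to keep the suite fast while
leaving comfortable margins: cohort calibration at n = 10,000 (3
standard errors), segmentation recall/precision over 20 seeded sessions
of 5 cycles at 20 dB SNR with a 20 → 10 → 0 dB degradation sweep,
elastic-net support recovery over 20 seeded cohorts of 50 subjects × 5
breaths at a planted R² ≈ 0.8, Boruta calibration over 20 seeded
60-row × 50-feature designs, and the mixed-model type-I rate over 1000
null replicates of a 20-subject crossed design — a moderate size where
the likelihood-ratio χ² asymptotics are expected to hold.

## Known limitations

* Boruta, as defined — hits against the maximum shadow importance,
  binomial test on a fixed dataset — cannot distinguish a strong
  *chance* correlation in a small sample from weak real signal: with 60
  rows and 50 noise features the largest chance |r| is ≈ 0.35, and a
  feature carrying it beats the per-iteration shadow maximum often
  enough to be confirmed. On such designs the procedure confirms 1–3
  noise features per dataset on average. This is a property of the
  algorithm at that sample size (an independent reimplementation with a
  different importance measure reproduces it), not of this
  implementation; the suite documents it rather than masking it.
* The 17 envelope/timing features are a reasoned completion of an
  externally fixed 185-feature total whose full composition is not
  public; results attached to those columns should be read accordingly.
* The mixed model uses a random intercept only; random slopes are not
  identifiable at the intended cohort sizes.
* Elastic-net λ values follow the `(1−α)/2` ridge convention and are
  not numerically comparable to conventions that omit the ½.
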