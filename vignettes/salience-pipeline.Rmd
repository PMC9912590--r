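---
title: "Sensory salience processing in naturalistic gaze data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensory salience processing in naturalistic gaze data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazesal)
```

## The analysis this package implements

`gazesal` implements an end-to-end analysis of how low-level sensory
salience shapes visual attention while people watch naturalistic video,
and how that relationship differs between autistic (ASD) and neurotypical
(TD) viewers. The pipeline has five stages:

1. **Event detection** — raw binocular gaze streams (120 or 300 Hz remote
   eye trackers, a 345 × 259 mm display viewed from 650 mm) are reduced to
   fixations by a velocity-threshold (I-VT) algorithm.
2. **Frame features** — every video frame is converted into three aligned
   grids: *physical salience* (spectral-residual analysis), *motion
   salience* (Gaussian-mixture background subtraction), and *relative
   luminance* (Rec.709 on linearized RGB).
3. **Scene pipeline** — videos are segmented at camera cuts into scenes
   (human vs. non-human category), each analysed over its first 5000 ms;
   feature maps and area-of-interest (AOI) masks are sampled at fixation
   centroids.
4. **Pupillometry** — pupil traces are cleaned, standardized by the
   participant's mean diameter, aggregated per fixation with a 200–400 ms
   latency shift, and decomposed over scene time into an early (PR1) and a
   late (PR2) component via PCA with varimax rotation. The pupillary
   response is used as a proxy of phasic locus coeruleus–norepinephrine
   activity.
5. **Inference** — linear mixed models with crossed random intercepts for
   participant and scene, Satterthwaite F-tests, standardized coefficients,
   FDR adjustment, marginal contrasts, likelihood-ratio model comparison,
   and simulation-based power.

Because the cohort data this design targets are not redistributable, the
package ships a first-class synthetic-data generator that emulates all four
inputs — videos, AOI masks, gaze/pupil streams, and cohort tables — with
known ground truth, so every stage is testable without any download.

## Event detection

The detector follows the conventional I-VT chain. Binocular samples are
combined by a validity-aware mean (both eyes when valid, the valid eye
otherwise). Angles are computed from metric on-screen displacement by the
arctangent subtense at the viewing distance, so the full 345 mm screen
width subtends `2·atan(172.5/650)` ≈ 29.7°.

Parameters and their defaults:

| parameter | default | role |
|---|---|---|
| velocity threshold | 20 °/s | fixation (strictly below) vs. saccade |
| minimum duration | 100 ms | fixations must be strictly longer |
| maximum RMS dispersion | 1° | within-fixation stability (strictly below) |
| merge radius | 0.5° | consecutive fixations closer than this merge |
| interpolation cap | 100 ms | longest linearly filled gap |
| interpolation displacement | 1° | largest flank separation for filling |
| temporal smoothing window | 20 samples | centred window |
| spatial smoothing scale | 8 mm | excursion scale removed by smoothing |

Two choices here were genuinely open and are worth recording:

* **The smoothing kernel.** The smoothing stage is specified by a temporal
  window (20 samples) and a spatial scale (8 mm) without naming a kernel.
  We implement it as a joint (bilateral-style) filter: each sample is
  replaced by the mean of the window samples lying within 8 mm of it.
  Sub-scale jitter is averaged away while displacements beyond the scale —
  saccade end points — are excluded from the window, so event boundaries
  are not smeared. A plain moving average would drag positions across
  saccades and systematically bias onset estimates. Temporal and spatial
  criteria are applied jointly (the order question does not arise).
* **Velocity estimation.** Velocity is the angular displacement between
  consecutive samples divided by the sampling interval, without additional
  Savitzky–Golay differentiation — the simplest estimator consistent with
  a per-sample threshold rule.

Threshold comparisons are strict in the directions the rules are stated
("less than 1°", "longer than 100 ms", "less than 0.5°"), which pins down
behaviour exactly at the boundary values; the test suite sweeps each
boundary.

The detector's accuracy contract — planted fixation counts recovered
exactly and onsets within one sample on noise-free streams at both 120 and
300 Hz — is assessed on the unsmoothed path (`smooth = FALSE`): smoothing
exists for noisy traces, and on a noise-free stream it can only displace
estimates near saccade landings. Jittered and blink-interrupted streams are
tested separately with smoothing enabled.

## Frame features

**Physical salience** uses the spectral-residual method: grayscale frames
are downscaled to a 64-pixel working width (the method's canonical scale),
Fourier transformed, and the log-amplitude spectrum is compared with its
3 × 3 local mean; the residual is recombined with the original phase,
inverse transformed, squared, Gaussian smoothed (σ = 2.5 on the working
grid) and min–max normalized. Numerical choices: the log-amplitude uses
`log(1 + A)` so that exact spectrum zeros (common in synthetic imagery) do
not produce unbounded residuals; the unit phasor is defined as zero where a
frequency carries no energy; and both the 3 × 3 local mean and the
post-smoothing operate on the periodic DFT grid (circular boundary). With
these conventions the operator is exactly equivariant under circular shifts
and right-angle rotations, and a constant frame maps to an all-zero grid.
The implementation matches an independently coded dense-FFT oracle to
1e-6 on random frames.

**Motion salience** uses an adaptive per-pixel mixture of K = 5 Gaussians
with learning rate α = 0.002, match threshold 2.5 SD, background weight
fraction 0.9 and initial SD 15 (on the 0–255 intensity scale) — the common
defaults of this background-subtraction family; only α is prescribed by
the analysis design. A pixel is foreground when it matches no component of
the top-ranked background set. The model is reset at every scene cut so
foreground evidence never leaks across scenes. Ghosting — a region marked
salient at the *initial* location of an object present in the first frame —
is inherent to the method at this learning rate and visible in synthetic
tests that initialize on a frame containing the moving object.

**Luminance** linearizes sRGB channels with the piecewise transfer function
(threshold 0.04045; configurable to a pure power law) and combines them as
`L = 0.2126 R + 0.7152 G + 0.0722 B`. The local map is a Gaussian blur with
σ = 10 px (interpreted in full-frame pixels) and kernel extent 10% of the
frame size, using reflective padding, which conserves the spatial mean; the
global value is the unblurred mean.

## Scene pipeline

Scenes are delimited by manifest cut points and analysed over
`[0, min(duration, 5000)]` ms. Fixations belong to the scene containing
their onset; a fixation straddling a cut is truncated at the cut. Feature
values at a fixation are the grid value at the centroid pixel of the
temporally nearest frame — a point lookup, not a neighbourhood statistic
(bilinear sampling is available behind a flag); off-screen centroids are
missing. AOI hits test centroid membership in the mask of the nearest
frame; scenes without masks (non-human) yield missing flags rather than
errors. Age-restricted scenes carry a record flag consumed as a covariate
or filter downstream.

## Pupillometry

Cleaning follows standard pupillometric practice: diameters outside
1–9 mm are removed, dilation-speed outliers are rejected by a
median-absolute-deviation rule (multiplier 16) on sample-to-sample speed,
interior gaps up to 250 ms are linearly interpolated, and a 3-sample median
smooth is applied; traces losing more than 90% of samples are flagged
unusable. Standardization divides by the participant's mean diameter, so
traces are dimensionless with mean 1 and the response measure is scale
invariant.

The per-fixation response window is `[onset + 200, offset + 400]` ms,
reading the stated 200–400 ms latency range as bracketing the fixation
span; a fixed 300 ms lag is available as an alternative
(`fixed_lag = 300`). For the temporal decomposition, responses are binned
into 20 × 250 ms bins over the 5000 ms window (a bin width fine enough to
separate sub-second dynamics while keeping most participant × scene cells
occupied), averaged per participant × scene × bin, mean-imputed for missing
bins (decomposition only), and the first two principal components are
varimax-rotated. The rotation is computed on variance-scaled loadings and
applied to the orthonormal basis, so the returned loading vectors stay
exactly orthogonal. The component whose absolute-loading centroid falls
earlier in scene time is PR1 (early), the other PR2 (late); per-fixation
weighted responses multiply the response by the loading at the fixation's
bin.

## Inference

Continuous outcomes and predictors are z-scored on the analysis sample and
two-level factors are deviation-coded (+0.5 for ASD and for human scenes),
so fixed effects are standardized betas and main effects are averages over
the other factor's levels. Models carry crossed random intercepts for
participant and scene, REML estimation (ML for comparisons), a 3rd-degree
polynomial of time-in-scene that is dropped automatically when PR1/PR2
enter the fixed effects, and a human-scene filter for face-gaze models.
Fitting, Satterthwaite F-tests and marginal means delegate to `lme4`,
`lmerTest` and `emmeans`; the module owns the standardization, coding,
model construction and result schema. The face-gaze outcome is the
per-fixation on-face indicator aggregated to a participant × scene ×
time-bin proportion and modelled linearly, matching the proportion-of-gazes
operationalization. Group matching is greedy 1:1 nearest-neighbour without
replacement on z-scored variables with a 0.4 SD per-variable caliper.
Missing symptom covariates are imputed by group-wise predictive mean
matching (the imputation method was an open choice; predictive mean
matching keeps imputed values in the observed support). FDR adjustment is
Benjamini–Hochberg within a family of analyses.

Power is estimated by simulation from a fitted template: the target fixed
effect is forced to the planted value, outcomes are simulated with the
estimated variance components, each replicate is refitted and tested at
the Satterthwaite level, and the binomial 95% CI is reported.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

* **Geometry** — 345 × 259 mm display at 650 mm, 120 or 300 Hz.
* **Fixation plans** — durations 200–600 ms, 20–40 ms saccade gaps, landing
  targets split between the face region (40% in human scenes, shifted by
  the planted group effect), the static salient patch (20%), and random
  locations; consecutive centroids at least 1.5° apart so planted events
  stay individually recoverable under the 0.5° merge rule.
* **Streams** — within-fixation jitter SD 2 px (about 0.05°; within-fixation
  noise of real trackers is not characterised in the source design, so this
  is a free parameter), linear saccades completing within 30 ms, blink
  runs covering ~5% of time, pupil baseline ~3.6 mm with gamma-function
  impulse responses (the standard pupillometry convention; n = 10.1,
  t_max = 930 ms) at fixation onsets delayed by 300 ms, plus a step-shaped
  alternative for latency tests.
* **Videos** — uniform background with one static high-contrast checker
  patch and one moving patch per scene, nested rectangular AOIs (eyes and
  mouth inside face inside body) for human scenes, rendered as PNG-able
  arrays at a 96-pixel working width with a recorded screen mapping.
* **Cohorts** — ASD/TD groups with age 6–30 y, perceptual IQ ~N(103, 17),
  symptom scores with planted group differences, missing covariate cells
  MCAR, a planted group shift in face-gaze probability (−0.12 by default)
  and a planted group × category pupil-gain interaction (0.3 by default,
  oriented so ASD responses are larger for non-human and smaller for human
  scenes).
* **Record-level simulator** — `simulate_fixation_records()` draws analysis
  tables directly from the mixed-model structure (random intercept SDs
  0.4/0.3, residual 0.85, variances summing to ≈1 so planted coefficients
  are standardized betas). The model-stage simulations use it so that
  hundreds of replicates fit in minutes on one core.

What the generator does *not* emulate: photorealistic content, semantic
salience, smooth pursuit, audio, luminance-driven pupil reflexes, site
effects beyond participant intercepts, or covariance between covariates
and gaze behaviour. Passing tests therefore demonstrate algorithmic
correctness and statistical calibration under the planted model — not that
real recordings satisfy those assumptions.

## Validation sizes and numerical conventions

The validation suite uses scaled-down problem sizes chosen to exercise the
statistics at desk scale: interaction-recovery at n = 40/40 participants ×
20 scenes × 5 fixations (10 replicates), null calibration over 200
simulated cohorts of n = 20/20 × 10 scenes, and power curves with 200
simulation iterations on an n = 12/12 template. At these sizes the planted
+0.3 interaction is recovered with |bias| < 0.05, the group-term type-I
error stays within 0.05 ± 0.02, and power rises monotonically over planted
effects {0, 0.1, 0.3}. Boundary behaviour (velocity, duration, dispersion,
merge, interpolation) is pinned by fine parameter sweeps around each
printed threshold.

Degenerate inputs are handled by convention rather than error where a
convention is defensible: constant frames normalize to all-zero salience,
all-missing streams yield empty event sequences, non-human scenes yield
missing AOI flags, and singular mixed-model fits are flagged (degrees of
freedom withheld) rather than silently accepted.

## Known limitations

* The event detector does not classify smooth pursuit; slow drift below
  20 °/s is counted as fixation, as in any plain I-VT scheme.
* Motion salience is binary per pixel (foreground membership); graded
  foreground probability would need a different mixture readout.
* The face-gaze model is linear on proportions; a logistic link would be
  the natural alternative if cell sizes were very small.
* Satterthwaite approximations are delegated to `lmerTest`; no independent
  degrees-of-freedom implementation is shipped. The delegation is backed by
  algebraic identities (F = t² in balanced designs) and bound checks in the
  test suite.
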