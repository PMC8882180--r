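---
title: "Methods: from prefrontal optical signals to impairment classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from prefrontal optical signals to impairment classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsimpair)
```

## The problem and the design

Acute THC intoxication impairs cognition and driving, but neither THC
metabolite levels nor field sobriety testing separate the *impaired* state
from mere exposure: metabolites linger for weeks in regular users, and
sobriety examinations misclassify a substantial fraction of sober
participants. The hypothesis this pipeline operationalizes is neural: during
a working-memory task (2-back vs 0-back), acute impairment raises the
task-evoked oxygenated-hemoglobin (HbO) response across the prefrontal
cortex, measurable with a forehead-mounted fNIRS probe, and that signature
supports per-scan classification.

The study design the synthetic generator emulates is a double-blind
cross-over: each participant completes a THC visit and a placebo visit at
least a week apart, with three 6-minute fNIRS scans per visit (pre-dose,
~100 min and ~200 min post-dose — the first post-dose scan sits near the
median peak of oral THC absorption), heart rate and a 0–100 self-rating of
"high" (Drug Effects Questionnaire) sampled roughly every 20 minutes over
[−20, 240] minutes.

Ground truth impairment is deliberately *not* a drug assay. A post-dose
scan counts as impaired only when two independent determinations agree: a
clinical consensus rating, and an algorithm requiring both self-rated high
above 50/100 and a heart-rate rise of at least 10 bpm over pre-dose
baseline near the scan. Scans where the two disagree are *discordant* and
excluded from classifier construction; post-placebo scans are the negative
class; concordant-unimpaired THC scans form an all-negative hold-out set.

## The forward model in the synthetic cohort

Real recordings are not distributable, so the generator is a first-class
module: it fixes the statistical structure the analysis assumes, and every
downstream stage is tested against it.

Per scan, clean HbO per channel is

  beta * (HRF ⊛ boxcar of the 2-back blocks) + drift + physiology,

with a double-gamma hemodynamic response (peak 6 s, undershoot 16 s, ratio
1/6) scaled so one isolated 30-s block response peaks at 1 — the amplitude
`beta` (µM) is therefore the peak block response. The 6-minute run holds
twelve alternating 30-s blocks, 0-back first, six per condition. The text
the schedule comes from admits a six-total reading as well; six per
condition is the one that fills the stated 6-minute run. Noise comprises
per-channel white noise, a random per-channel linear drift, and three
sinusoids shared across channels with scan-level random phases — cardiac
(~1.1 Hz), respiratory (~0.25 Hz) and Mayer waves (~0.1 Hz). The shared
physiology is what gives channels their common variance, so connectivity
windows have realistic structure. HbR is generated as −1/3 of the clean
HbO plus independent noise; it is carried through conversion and I/O but
not analyzed, matching the HbO-only outcome.

Latent truth: each participant becomes impaired on the THC visit with
probability 80/137 (the study's concordant-impaired fraction). Impairment
expresses at scan 2 only, scan 3 only, or both scans with probabilities
proportional to the study's observed 39/20/24 split, raising the expressed
scans' amplitude from `beta_base` (0.2 µM) to `beta_base + delta_beta`
(0.5 µM). Vitals follow ramp-then-decay trajectories (tachycardia peaking
+25 bpm at 60 min; DEQ-high peaking ~75 at 100 min for impaired vs ~25 for
not-impaired participants, both with between-subject spread); placebo
visits are flat plus noise. A simulated consensus rating flips the latent
scan-level truth with 10% probability, which is what produces discordant
scans. The defaults put the single-sample SNR of the impairment effect
near 1 (`delta_beta` = `sigma_white` = 0.3 µM); averaging over blocks and
ROI channels is what makes the effect recoverable, as in real block
designs.

Randomness is split into named substreams (assignment, fNIRS, vitals)
derived from the master seed, so regeneration is exact and changing vitals
parameters cannot perturb the optical series.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: motion artifacts and optode-coupling drifts,
heteroscedastic or heavy-tailed noise, spatially graded (non-global) ROI
responses, habituation across blocks, between-visit probe placement
differences, and any true connectivity reorganization beyond what shared
physiology and common task drive induce. Classifier performance on this
synthetic cohort is a *correctness* check of the pipeline under its own
assumptions, not an estimate of field performance.

## Preprocessing choices

Raw intensities map to optical density as `OD = −ln(I/Ī)` against the
channel's temporal mean, then per channel a 2×2 modified Beer–Lambert
system is inverted with standard tabulated extinction coefficients for
HbO/HbR at 760/850 nm, a differential pathlength factor of 6.0 at both
wavelengths, and 3 cm source–detector separation for every channel (the
physical separations ranged 2.5–3 cm but are not published per channel;
all three quantities are arguments). Band-pass filtering is a 3rd-order
Butterworth applied forward–backward (zero phase, so extremum timing
features are not shifted) over 0.01–0.5 Hz after linear detrending; at the
7.81 Hz sampling rate this suppresses the cardiac band by ~99% and passes
0.05 Hz at ~99.5%. Filtering is optional in the wiring because the
amplitude-recovery contract (noise-free pipeline recovers `beta` within
1%) is defined on the unfiltered path: a 0.01 Hz high-pass necessarily
biases a 60-s-periodic block response slightly.

Epoching takes each 2-back onset over [0, 40] s — deliberately reaching
10 s into the following 0-back block, as the late feature segments
require — subtracts the mean over [−2, 0) s, averages channels within each
ROI and then epochs within the scan. Blocks whose epoch or baseline falls
outside the record are dropped and counted; with the default schedule the
sixth 2-back block (onset 330 s) is always dropped, leaving five averaged
blocks. Features are computed on the block-averaged response (per-block
feature extraction followed by averaging is the alternative reading; block
averaging first is the convention adopted here).

## Feature conventions

All segment windows are half-open `[a, b)` seconds, mapped to sample
indices `floor(a·fs) … floor(b·fs)−1`, so the eight 5-s segments partition
0–40 s without overlap. Slope is the least-squares line over [5, 15) s.
Skewness and kurtosis are plain sample moments over [0, 15) s, kurtosis
*non-excess* (a constant window returns 0 for both rather than NaN). AUCs
integrate the piecewise-linear interpolant over exact second boundaries
[0, 15] and [15, 40], so a constant c yields exactly 15c and 25c. An
*extremum* is a turning point — a sign change of the zero-skipping first
difference — with optional prominence filtering (default 0); when fewer
than two turning points exist (monotone or constant input) the fallback is
the global maximum then the global minimum, which keeps the feature map
total. Mean/SD "after the first extremum" use samples strictly after it
(SD 0 when fewer than two remain). Feature names
(`MPFC_seg_mean_0_5`, …) are a stable public contract.

## Connectivity and the recurrent model

Connectivity is computed on the continuous (optionally band-passed) HbO
record, not on block averages: windows of 300 samples (~38 s) advanced by
100 samples give `floor((T−300)/100)+1 = 26` windows for a 2811-sample
scan, each summarized by the strict upper triangle of the 20×20 Pearson
matrix in row-major order (190 values). Zero-variance channels yield
correlation 0 plus a degeneracy flag rather than an error. Correlations
enter the model raw; no Fisher z-transform (whether the original analysis
transformed them is unstated, and the recurrent network is scale-free in
its input range).

The recurrent classifier reads the stated "5 hidden layers with 128, 64,
32, and 16 nodes" as four tanh encoder layers plus the 64-unit tanh
recurrent layer (the reading that makes the two statements consistent).
Each window vector is encoded, folded into the recurrent state, and mapped
to a per-window probability by an affine layer with logistic squashing;
the scan-level probability is the mean over windows (last-window and max
aggregation are switches). Training minimizes scan-level cross-entropy
with full-batch Adam (default 80 epochs at learning rate 0.01) from a
seeded Glorot initialization; the gradient is analytic
(backpropagation-through-time, verified against central finite differences
to 1e-5) and training is fully deterministic given the seed. The network
is small enough (~33k parameters) that no accelerator is relevant.

The ensemble is a stack: within each training set, internal grouped
3-fold splits produce an out-of-split RNN probability for every training
scan; that probability joins the 95 temporal features as a 96th predictor
for the gradient-boosted trees (200 trees, depth 3, learning rate 0.1,
logistic objective — the library is named in the source work, the
hyperparameters are not). At prediction time the RNN runs first, then the
GBT. The description "boosting to iteratively fit the RNN" is
under-specified; this single-pass stack is the documented primary
behavior.

## Evaluation protocol

Cross-validation is stratified by scan label *and grouped by participant*:
a subject's scans never straddle train and test. The source text does not
state the grouping, but without it the split leaks within-subject signal
(a participant's pre- and post-dose scans share idiosyncratic anatomy and
physiology), so grouping is the defensible default here. Per-fold class
counts deviate from proportional by at most one group. Metrics are pooled
over folds (micro-average) with per-fold values kept alongside; the
null-information rate is the majority-class proportion, and pooled correct
counts are tested against it with the exact one-tailed binomial tail.
Model selection minimizes mean FPR/TNR across folds — since
FPR/TNR = FPR/(1−FPR) is increasing, this is argmin FPR — with ties broken
by accuracy then candidate id. The hold-out evaluator refuses any
participant overlap with training and, on the all-negative
not-clearly-impaired set, reports the accuracy = 1 − FPR pair.

## Group statistics

For each participant the *peak-dose* scan is the post-dose scan with the
higher DEQ-high at the vitals sample nearest the scan midpoint (ties to
scan 2); only participants with both a pre-dose and a peak-dose
timecourse enter, and exclusions are counted. At each of the 313
block-relative samples a paired t-test of peak − pre is computed per ROI,
with Benjamini–Hochberg applied *within each ROI across timepoints* at
q = 0.05 (the pooled-across-ROI family is the other defensible reading;
the per-ROI family matches per-panel significance traces and is
switchable). Zero-variance timepoints get p = 1 with a flag. Because BH
controls the false discovery rate, not the family-wise error, each null
ROI family still has roughly a q-level chance of showing at least one
significant timepoint; occasional placebo-group "hits" in a single ROI are
therefore expected sampling behavior, not a pipeline defect.

## Problem sizes and numerical tolerances

The shipped tests and the acceptance script run the pipeline at sizes
chosen to exercise every code path while staying desk-scale: 75
participants (450 scans, ~200 classifier scans) for the cross-validated
classification runs, 40 matched pairs for the group-statistics recovery,
single-repeat 5-fold CV. Oracle-equivalence checks hold to 1e-10 (feature
moments, MBLL round trip) and 1e-12 (windowed correlations, binomial
tails); amplitude recovery on noise-free input holds to 1%. Because the
real cohort is unavailable, the study's headline classification numbers
(76.4% accuracy, 69.8% PPV, 10.0% FPR, AUC 0.83) are not reproduction
targets: on the synthetic cohort the task is as separable as its SNR and
averaging make it, and the pipeline's cross-validated performance there
reflects the generator's conditions, not the clinical difficulty of the
original data.

## Known limitations

The consensus-rating process is simulated as a noisy flip of latent truth;
the real rating embodies clinical judgment no simulation captures. The
intoxication algorithm's exact published thresholds are not available; the
50/100 DEQ cut is anchored in the source text, the 10 bpm criterion is a
conventional choice, and both are arguments recorded with results. The
probe geometry is metadata only — no optode-space forward model is solved,
and channel positions beyond ROI membership are unused. SNIRF/HDF5 I/O is
not provided; scans exchange as wide CSV plus a JSON sidecar, which
round-trips all metadata and events losslessly.
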