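---
title: "Methods: tactile-mat center-of-pressure estimation in copmat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tactile-mat center-of-pressure estimation in copmat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The body center of pressure (CoP) — the point of application of the resultant
vertical ground reaction force — is the standard quantity for assessing
standing balance. Force plates measure it accurately but are expensive and
stationary. `copmat` implements an estimation system built around a low-cost
piezoresistive pressure mat: four 32 x 32 sensing modules tiled into a
64 x 64 grid covering 80 cm (anteroposterior, AP) x 60 cm (mediolateral, ML),
read at ~14 Hz, optionally fused with lower-limb joint kinematics derived
from a calibrated stereo pair of RGB cameras at 30 Hz. A 1000 Hz reference
CoP stream (in practice from force plates) provides training labels.

Because suitable human recordings contain personal data and are generally not
shareable, the package is synthetic-data-driven: a seeded simulator generates
cohorts, trials, raw sensor streams, and analytic ground truth, and every
downstream component is developed and tested against it.

## Synthetic cohorts and trials

`make_cohort()` draws subjects from normal distributions typical of a young
healthy cohort (age 22.7 +/- 1.6 y, height 171.6 +/- 7.8 cm, weight
73.4 +/- 13.5 kg, roughly 15:8 male:female), truncated to positive values.
Segment lengths, foot dimensions, lean mass, and waist-hip ratio derive from
height/weight/gender through standard anthropometric ratios with individual
variation.

Four balance protocols are simulated (`protocol_spec()`), 90 s each with the
middle 80 s analysed:

* **one-leg stance** and **tandem stance** (static): the body CoP follows
  Gaussian white noise low-passed at 1 Hz. The sway SDs — one-leg 8 mm ML /
  10 mm AP, tandem 12 mm ML / 6 mm AP — are package choices at clinically
  plausible magnitudes; the underlying study protocols specify none.
* **squat** (dynamic): one repetition per 3 s. A deterministic AP
  oscillation (default 100 mm peak-to-peak at 1/3 Hz, a typical anterior shift for a deep squat and comfortably larger than static sway excursions) is phase-locked to the
  squat depth, and the total vertical load is modulated +/-15% by the
  vertical acceleration surrogate.
* **walking-in-place** (dynamic): the load share of the left foot follows
  `0.5 + 0.45 sin(2 pi f t)` at a default cadence f = 1 Hz (a package
  choice; "self-selected pace" is otherwise unconstrained), producing large
  ML excursions between the feet. Because CoP is load-share weighted, the
  time-average CoP sits exactly at the stance midpoint — one of the analytic
  anchors used in tests.

Ground truth is the load-weighted centroid of the per-foot CoPs at 1000 Hz —
exact by construction, which is what makes end-to-end accuracy bounds
testable.

**Pressure rendering.** Each foot is a truncated anisotropic Gaussian blob
(sigma = foot length / 4.5 along AP, foot width / 3.5 along ML, truncated at
2.2 sigma with the edge value subtracted so the field is continuous) centred
on that foot's instantaneous CoP and scaled by its instantaneous load. The
kgf-to-kPa scale is fixed so a 73 kg reference subject in double stance peaks
at ~60% of the 14 kPa sensor saturation; single-leg protocols may saturate,
which clips the blob top symmetrically and therefore does not bias the
centroid. The discretised, truncated blob keeps the stitched frame's
pressure-weighted centroid within a small fraction of a cell pitch of the
analytic CoP, and total rendered pressure is exactly proportional to load
(the conservation invariant).

**Sensor defect model** (`noise_model()`), applied in order: response
nonlinearity `measured = 14 (true/14)^gamma` kPa; per-module gain and
baseline offset plus slow drift; salt-and-pepper cell noise; whole-frame
drops. `default_sensor_defects()` (gamma 0.7, gains in 0.8–1.2, sparse
salt-and-pepper, 2% drops) defines the "noisy sensor" condition used in the
model benchmarks. Stream starts are jittered uniformly within one device
frame interval to emulate manual triggering.

**Skeleton.** A 33-landmark skeleton (the common full-body pose topology) is
posed per frame: hips track the body CoP, legs are solved by two-segment
inverse kinematics (knees bow forward), squats drive knee/hip flexion
phase-locked to the AP oscillation, and walking lifts the unloaded foot.
Both camera views are exact pinhole projections plus optional Gaussian pixel
noise; points behind a camera are flagged invalid.

What the simulator does **not** model: soft-tissue and silicone-mat
mechanics, sensor creep/hysteresis, realistic gait variability, pose-
estimator failure modes (it only reproduces the 33-keypoint output
contract), and correlated anthropometrics. Tests passing on this data
demonstrate the pipeline's correctness and the architecture ordering under
controlled distortions — not clinical accuracy on humans.

## Tactile preprocessing

The chain in `preprocess_tactile()` follows the acquisition design:

1. **Stitching**: four 32 x 32 modules into the 64 x 64 frame
   (`stitch_modules()`).
2. **Baseline correction**: the per-cell mean of 20 no-load frames is
   subtracted and negative values clipped.
3. **Thresholding**: cells below a noise floor are zeroed. The design only
   says "a certain threshold"; the default is 2% of the post-correction
   full scale, configurable.
4. **Min-max normalization and 8-bit quantization**: one min/max pair over
   the whole collected dataset maps values to [0,1], then x255 and
   rounding. The constants are stored on the sequence for inversion and for
   reuse at inference.
5. **Denoising**: the validated denoiser of the original acquisition stack
   is not public; the package uses a 3 x 3 median filter with edge
   replication — the standard salt-and-pepper remedy — implemented as a
   19-exchange sorting network and verified against a brute-force oracle.
6. **Drop filling**: missing frames are rebuilt by per-cell linear
   interpolation between surviving neighbours (exact for signals linear in
   time); leading/trailing gaps take the nearest frame.

**WMA CoP.** The weighted-mean approach computes, per axis, the pressure-
weighted mean of 1-based cell indices times the cell pitch. For a
non-square mat the printed form of this formula pairs the ML coordinate
with the 80 cm *length* although ML physically spans the 60 cm *width*;
whether that pairing is intentional is not decidable from the text. The
package default maps ML to the width axis and AP to the length axis;
`strict_eq1 = TRUE` reproduces the literal printed pairing. A cell-center
`(i - 0.5) x pitch` variant is available via the geometry. An all-zero
frame yields a typed no-load marker rather than NaN coordinates; callers
decide whether to skip or hold the last value.

## Stereo kinematics

Projection matrices are `P = K [R | t]`. Per-point triangulation
(`triangulate_dlt()`) solves the homogeneous DLT system by the smallest
right singular vector and reports the RMS reprojection residual; the batched
track path (`triangulate_tracks()`) solves the equivalent inhomogeneous
normal equations vectorised over all frames and keypoints (Cramer's rule on
the 3 x 3 system), and the two are cross-checked in tests. A keypoint
invalid in either view is not triangulated.

3D tracks are gap-filled (linear, with a 10-frame cap before the track is
flagged) and filtered with a zero-phase fourth-order Butterworth low-pass at
2 Hz. Joint angles use the clamped dot-product formula at vertex joints;
since the source names the joints but not the vertex triplets, the package
declares: hip = angle(shoulder–hip–knee), knee = angle(hip–knee–ankle),
ankle = angle(knee–ankle–foot tip), configurable through `pose_landmarks`.
Angular velocity and acceleration are central differences (one-sided at the
ends), computed after synchronization at the 14 Hz rate, giving the
18-feature block (3 joints x 2 legs x angle/velocity/acceleration) in a
fixed documented column order.

## Synchronization and the trial container

The 1000 Hz reference CoP is zero-phase Butterworth-filtered at 10 Hz; a
Welch PSD (Hann window, segment length 1024, 50% overlap) verifies that
essentially all spectral energy sits below 7 Hz, so resampling to 14 Hz is
alias-free. The 14 Hz reference grid is anchored at the start of the middle
analysis window (a symmetric [5 s, 85 s] trim of the 90 s trial) and all
modalities are linearly interpolated onto it (frames per cell, categorical
payloads nearest-neighbour). With manual triggering, the cross-device
alignment uncertainty is bounded by half of each sampling interval,
`(1/14 + 1/30)/2 ~ 52 ms` (`sync_mismatch_bound()`).

Zero-phase filtering deserves a note: naive forward–backward filtering
leaves large startup transients on short or offset signals, so the package
extends signals by odd reflection and initialises each IIR pass with
constant-history initial conditions; DC gain is then 1 to ~1e-10 and
symmetric features keep their sample location.

Each synchronized trial is consolidated into a single-file `trial_record`
container (quantized frames stored as raw bytes, WMA CoP, reference CoP,
angular features, subject characteristics, experimental settings, unit and
schema-version attributes) with an exact write–read round trip. The
container uses native R serialization; the schema mirrors the one-file-per-
trial layout of the acquisition design.

## The CoP regressors

All four benchmark architectures share a template implemented by a compact
neural-network engine written for this package (double precision,
BLAS-backed matrix maths, C++ im2col/col2im kernels, full analytic
backpropagation verified against numerical differentiation):

* **Encoder** over each 64 x 64 frame (values scaled to [0,1]):
  * `cnn2d` — strided 3-stage convolution stack (all downsampling by
    stride, no pooling anywhere);
  * `resnet` — the same stem plus identity-shortcut residual blocks, with
    stride-2 convolutions for all downsampling and zero pooling layers;
  * `none` — the frame is flattened to 4096 features (the baseline that
    isolates the value of spatial feature extraction).
* **First-stage fusion**: the per-frame WMA CoP (2 features) and, in the WA
  input condition, the 18 angular features are concatenated to the frame
  encoding.
* **Decoder**: LSTM or Bi-LSTM over the window; bidirectionality doubles
  the per-frame output width.
* **Second-stage fusion**: static features — weight, gender, lean mass,
  upper/lower limb length, waist–hip ratio, protocol one-hot, sensor width
  and length — are concatenated to each frame's decoder output.
* **Head**: fully connected layers to the per-frame (ML, AP) CoP in mm.

Training minimises the MSE (mm^2) with Adam and a StepLR schedule
(`gamma^floor(epoch/step)`), on overlapping windows cut within trials.
Supervision is per frame across the window (the alternative, supervising
only the final frame, discards most of the signal at these window lengths).
Continuous inputs are z-scored with training-fold statistics only; the
output bias is initialised at the training-mean CoP, which removes the long
plateau Adam would otherwise spend finding the operating point. Determinism
is by construction: all randomness flows through seeds derived from one
master seed.

**Desk-scale sizes.** The engine is CPU-only, so the default sizes are
deliberately small: encoder channels 6/12/18 with the residual blocks
placed after the resolution has dropped to 8 x 8 and 4 x 4, encoder feature
size 32, hidden size 32, one recurrent layer, 12-frame windows
(~0.86 s at 14 Hz), 10 epochs of 96 sampled windows at an initial Adam
learning rate of 1e-2 (halved every 4 epochs). The rate was chosen by a
convergence check — at 5e-3 the same budget leaves the training loss an
order of magnitude above its floor — not by peeking at held-out data. Larger, deeper
configurations (wider channels, more blocks, hidden 128) are a constructor
argument away; the architecture contracts (stride-only downsampling,
residual shortcuts, fusion stages) are independent of size. Hyperparameter
search (`grid_search()`) applies an identical grid to every architecture
with an inner held-out subject, scoring validation RMSE; diverging
combinations score `Inf` rather than aborting the search.

## Evaluation protocol

Validation is leave-one-subject-out: every subject serves once as the
validation set. Metrics per direction: RMSE (mm), NRMSE (RMSE over the
ground-truth range, percent), and R^2. The normalization scope of NRMSE is
ambiguous in general (per subject vs pooled); the package computes it per
validation subject per direction per stratum, which reproduces the
mean-(SD)-across-subjects table shape, and concatenates a subject's trials
within a stratum before computing metrics (per-trial averaging is available
by evaluating trials separately). Strata: overall, static (one-leg,
tandem), dynamic (squat, walking-in-place), and each protocol. Constant
ground truth makes NRMSE/R^2 undefined; these return typed `NA`s, never
silent zeros.

The two-way repeated-measures ANOVA (factors Model x Input Condition,
subjects as blocks) is computed from explicit sums-of-squares
decomposition; each effect is tested against its own effect-by-subject
interaction. No sphericity correction is asserted as primary; uncorrected
p-values are reported with Greenhouse–Geisser epsilons and corrected
p-values alongside. The implementation is verified to 1e-9 against R's
`aov()` error-stratum decomposition on random balanced designs.

## The desk-scale experiment

`run_experiment()` reproduces the study design end to end: simulate a
cohort, preprocess and synchronize every trial, train each architecture
under both input conditions per LOOCV fold, and emit the summary tables,
ANOVA, stabilograms, RMSE boxplots and error-versus-position figures. Desk
defaults are 8 subjects x 8 trials (4 protocols x 2 repetitions), 30 s
trials with a 20 s analysis window, and the short training schedule above —
sizes chosen so a full comparison runs on one CPU in minutes;
`paper_scale = TRUE` restores the 23-subject, 90 s design.
`benchmark_models()` runs the core ordering comparison (ResNet-Bi-LSTM
versus the flattened Bi-LSTM baseline versus raw WMA, and WA versus OT)
under the nonlinear default sensor.

What that benchmark shows: under a gamma-compressed sensor with module gain
spread, the WMA centroid is systematically biased, a learned model that
sees the raw images can correct the distortion, and compact spatial
encodings generalise better across held-out subjects than flattened pixels.
It is a directional, seed-majority check of the expected ordering — not a
reproduction of human-cohort error magnitudes, which require the original
(non-public) recordings.

## Known limitations

* Foot placement is deterministic per protocol (mat-centred stances), and
  the rendered pressure field is a nearly linear functional of the CoP. A
  consequence, visible in the benchmark, is that the flattened-pixel
  Bi-LSTM baseline can reach the error floor and is not reliably beaten by
  the convolutional encoders on this synthetic data: the cross-subject
  placement and foot-shape variability that makes spatial abstraction pay
  off on real recordings is absent. The learned-model-versus-WMA ordering
  and the WA-versus-OT ablation direction are robust; the
  ResNet-versus-flatten ordering on synthetic data is not.
* The simulator's sway and gait models are phenomenological; no
  biomechanically validated gait dynamics.
* The trial container is native R serialization, not a cross-language
  binary format; exchange with other stacks goes through the documented
  accessors.
* The NN engine is single-threaded CPU code aimed at desk-scale studies; it
  is not an optimisation target for large cohorts.
* Camera calibration is taken as given (parameters in, no checkerboard
  solver), and 2D pose estimation itself is out of scope — only its output
  contract is modelled.
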