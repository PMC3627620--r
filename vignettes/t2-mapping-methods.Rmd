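---
title: "Models and methods behind cmrT2map"
author: "cmrT2map authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cmrT2map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrT2map)
```

# The measurement and its failure modes

T2-prepared mapping acquires a small number of single-shot images, each
preceded by a T2-preparation block of duration $\tau$ that leaves the
longitudinal magnetization at

$$ M(\tau) = M_0 \, e^{-\tau/T_2}, $$

and fits the two-parameter mono-exponential pixel-wise across preparation
times (defaults 0, 24, 55 ms, three images, one shot every fourth heartbeat
of a 12-beat scan, a 150 ms acquisition window per shot in mid-diastole,
2.7 x 2.1 mm pixels). Healthy myocardium sits near 50 ms; edema raises T2 by
roughly 20 ms, so a threshold of 70 ms is a natural screen for focal
abnormality — and also the level that mapping artifacts must not reach in
healthy tissue. The package simulates, with known ground truth, the three
mechanisms that push healthy myocardium toward that level: partial volume
with blood (T2 ≈ 200 ms) and pericardial fat (≈ 80 ms), residual in-plane
diastolic motion between the single-shot images, and the transient readout.

Everything below is a design decision of this package; where the underlying
acquisition protocol leaves a quantity unspecified (readout flip angle and
TR of the mapping sequence, the inline fitting algorithm, the phantom's T1),
the default is an explicit, configurable assumption.

# Signal model and readout transients

`t2prep_signal()` is the pure preparation model. The recorded image
intensity of a homogeneous region, however, is the signal of the k-space
*center* line of the transient single-shot readout (low-frequency dominance
approximation; no full image-encoding simulation is attempted, so ghosting
and banding are out of scope). `readout_effective_signal()` iterates the
Bloch equations over the pulse train:

* **FLASH (spoiled gradient echo), centric ordering** — ideal spoiling
  (transverse magnetization zeroed each TR), per-TR flip $\alpha$ (default
  15°, TR 2.8 ms); the center line is the *first* line, so a single fresh
  shot records $M_\mathrm{prep}\sin\alpha$ essentially unbiased.
* **Balanced SSFP, linear ordering** — an $\alpha/2$ catalyzation pulse and
  alternating $\pm\alpha$ pulses (default 70°); the center line is the
  *middle* line, by which time the magnetization has partly relaxed toward
  the bSSFP steady state. Because that steady state is a nonzero,
  $T_2/T_1$-weighted attractor, the prep-time contrast acquires a positive
  offset and the two-parameter fit overestimates T2.

A single-shot center-line model with fresh magnetization every shot can
only produce overestimation (any transient is an affine map toward a
non-negative steady state, i.e. a positive offset in the decay), yet FLASH
maps are observed to read *below* a spin-echo reference. The package
therefore models the shot train (`effective_prep_signals()`): shots are
played every `scan_time_beats / n_preps` heartbeats, prep times in
increasing order, and the longitudinal magnetization recovers with T1 for
the remaining fraction of those beats — generally incompletely. Later
(longer-prep) shots therefore start slightly saturated, the apparent decay
steepens, and the FLASH fit lands a little *below* truth. With the default
protocol a T1 = 1000 / T2 = 62 ms tissue fits to 60.8 (FLASH-centric),
62.0 (ideal) and 68.7 ms (SSFP-linear) — the characteristic ordering
FLASH < reference < SSFP of phantom validations, produced entirely by
standard physics rather than by a fitted correction. The `"ideal"` readout
bypasses all of this and records the prepared magnetization itself; it is
the truth channel used in tests.

# The digital phantom

`phantom_spec()` describes a single 2D short-axis slice: a myocardial
annulus (endo 20 mm, epi 28 mm by default) around a blood pool, optional
sector lesions (edema, with an optional hypointense microvascular-
obstruction core inside), an optional pericardial fat arc, and a background
of air. Wall thickness may vary with angle: a cosine modulation thins the
wall to `thin_thickness_mm` at `thin_angle_deg` (anteroseptal by default),
emulating the 2–8 mm range of normal thin walls. Default tissue properties
(`tissue_properties()`): myocardium T1 1000 / T2 50 / PD 0.7, blood
1600 / 200 / 1.0, fat 260 / 80 / 0.9, edema 1200 / 73 / 0.75, MVO core
1100 / 60 / 0.45.

**Partial volume** is rendered by subgrid oversampling (default 8 x 8
subpixels per pixel), each subpixel classified geometrically and averaged
into per-pixel tissue fractions that sum to one exactly. Oversampling was
chosen over analytic area integrals because it is geometry-agnostic
(lesions, fat arcs and angular thinning come for free); against a dense
64 x analytic rasterization oracle the per-pixel fractions agree to within
the one-subpixel boundary band.

**Motion** is rigid in-plane translation per single-shot image — the
correction such sequences apply is in-plane, and residual through-plane
motion is out of scope. Each image's displacement is the motion profile
sampled at that image's k-space-center time (which depends on the
trajectory: first line for centric, middle line for linear); the default
profile is a linear drift reaching `motion_amplitude_mm` across the shots'
center times. The amplitude is interpreted as the *residual* motion that
survives the scanner's correction, which is why the cohort experiment fits
uncorrected series: correcting simulated rigid motion with the matched
rigid estimator would cancel the very mechanism under study.

**Noise** is Rician (magnitude of a complex Gaussian), the physical model
for magnitude MR images; a Gaussian option exists for analytic checks.
`noise_sigma` is expressed relative to a proton density of 1. Because a
transient readout attenuates all recorded signals by a roughly common
factor while a scanner renormalizes its receiver gain, the simulator
rescales the per-tissue recorded signals so the brightest tissue at prep 0
equals its proton density before noise is added (fitted T2 is invariant to
this common scaling; the ideal readout is left on the physical
magnetization scale). Noise is applied last under a caller-supplied seed,
and the session RNG state is restored afterwards; the noiseless component
is seed-independent.

**Cine stacks** (`make_cine()`) sample one RR interval (default 1000 ms):
a half-sine systolic contraction of the endocardial radius over the first
35% of the cycle, then a diastolic translation drift that ramps linearly
across the acquisition window placed in mid-diastole, reaching exactly
`motion_amplitude_mm`. Frame intensity is the proton-density-weighted
mixture (bright blood over intermediate myocardium, the bSSFP cine
appearance).

# Fitting

`fit_t2_map()` defaults to unweighted least squares on the log-signal:
closed-form, exact on noiseless mono-exponential data, and with three
points and two parameters there is little to gain from iteration. A
vectorized Gauss-Newton refinement in the signal domain (`method = "nls"`)
is provided for noise-robustness comparisons; the two agree to < 0.1 ms on
noiseless single-tissue data (mixed voxels are non-exponential, so the two
objectives legitimately differ there). Pixels with a non-positive signal at
any prep time are invalid — a classification, not an error; air pixels
eliminate themselves this way or via the noise floor, and no background
mask is applied before fitting. Fits above the ceiling (default 300 ms,
safely above blood) or with non-decaying signals are clamped to the ceiling
and flagged. The multi-echo reference (`fit_t2_multiecho()`) fits
$A e^{-TE/T_2} + C$ by Levenberg-Marquardt, initialized from a log-linear
fit with an offset guess and restarted from a T2 grid (10–240 ms) on
non-convergence; the default echo grid is 32 echoes equally spaced
7–224 ms.

# Motion correction

`motion_correct()` registers each image to the reference by rigid in-plane
translation: images are intensity-normalized (so prep-time contrast does
not bias the metric) and lightly smoothed, a coarse integer-shift grid
seeds a Nelder-Mead refinement of the mean-squares metric, and the
correction is applied by bilinear resampling. One numerical subtlety is
worth recording: evaluating the metric with bilinear-interpolated shifts
biases the optimum *away* from zero, because fractional-shift interpolation
smooths the moving image and smoothing itself lowers the mean-squares cost
between images of different contrast. The metric therefore shifts the
moving image in the Fourier domain (a phase ramp — unitary, hence no
shift-dependent smoothing). On synthetic series the estimator recovers
known translations to a few hundredths of a pixel, comfortably inside the
half-pixel contract, and a non-converged registration passes the image
through unchanged and flags it. Translation is the matched model for the
simulator's motion; deformable registration of real data is out of scope.

# Segmentation and ROI statistics

`segment_myocardium()` labels pixels whose *center* lies between the
endocardial and epicardial contours (no fractional pixel weighting —
partial volume is studied through the simulator, not the mask). Short-axis
slices are divided into six 60° AHA sectors clockwise from the anterior RV
insertion: anterior, anteroseptal, inferoseptal, inferior, inferolateral,
anterolateral. Four-chamber views have no canonical AHA sectors, so the
package uses an explicit convention: six wall territories (basal/mid/apical
septal and lateral) from the fractional position along a user-supplied
base-to-apex axis (thirds) and the side of that axis. Pixel coordinates are
1-based (row, column), the R convention, throughout.

`roi_stats()` reports per-segment mean/SD over valid pixels, the global
slice value as the pixel-wise mean over all labeled valid pixels (not the
mean of segment means), each segment's absolute deviation from the global
value, and flags any segment (or the global value) at or above the
threshold — exactly the `>= 70 ms` rule, boundary inclusive.
`edema_vs_remote()` removes MVO-core pixels from the edema ROI before any
statistic (they appear in neither group), requires disjoint ROIs, and
summarizes the contrast with a Welch two-sample t.

# Motion metrics

`mmode_projection()` samples every cine frame along a fixed ray (bilinear
interpolation) into a distance-time image and tracks the outer wall edge as
the first half-maximum crossing of the Gaussian-smoothed profile (sigma
1 pixel). `diastolic_motion()` is the range of that track inside the
acquisition window. `wall_thickness()` localizes the two wall edges along a
chord as the two strongest gradient maxima of the smoothed profile
(equivalent to half-amplitude crossings for smoothed steps) with subpixel
parabolic refinement; its default smoothing is sigma 0.5 pixel because a
1-pixel kernel merges the edges of a 2 mm wall at millimetric pixel sizes —
the thin end of the range the tool exists to measure. Diastole is known
from the simulation ground truth; for real cine input the window is
user-supplied, and no automatic mid-diastole detection is attempted.

# Agreement statistics

`bland_altman()` reports bias and limits of agreement (bias ± 1.96 x sample
SD of the paired differences). `cov_interscan()` implements the interscan
coefficient of variation as the SD of the between-visit difference divided
by the mean of the measurement; "the mean" is read as the pooled mean of
both visits (the per-visit-1 alternative is switchable), which makes the
statistic invariant to common rescaling. `tolerance_interval()` covers a
stated fraction of a normal population: with known parameters it is exactly
mean ± z·SD with z the (1+coverage)/2 quantile; from a sample it uses the
Howe/Wald-Wolfowitz approximation with the exact chi-square quantile,

$$ k = z_{(1+P)/2} \sqrt{\frac{\nu\,(1 + 1/n)}{\chi^2_{1-\gamma,\,\nu}}}, $$

accurate to better than 1% for n ≥ 10; exact small-n tables are not
implemented. Monte-Carlo calibration (10,000 samples of n = 69) puts the
fraction of 90%-coverage intervals that truly capture ≥ 90% of the mass at
about 95%, as the 95% confidence level demands — this is what
`scripts/acceptance.R` recomputes. `paired_compare()` wraps the paired t
machinery and reports zero-variance differences as the degenerate boundary
case rather than erroring. `t2_bias_regression()` is a plain multiple
linear regression of segmental T2 on wall thickness, motion and their
interaction, provided to check the sign pattern of the mechanism; mixed
models across repeated sequences are deliberately out of scope. No p-value
adjustment is applied across segments.

# Experiment designs and problem sizes

`run_experiment()` drives five reproducible designs from one config, all
randomness flowing from a single root seed through per-subject/per-visit
substreams; re-running a config reproduces byte-identical CSV summaries.
The cohort designs use 64 x 64-pixel slices and 24 subjects whose
thin-sector thickness spans 2–8 mm and whose residual motion spans
0–5.2 mm, with the two covariates crossed through a seeded permutation so
they are not confounded; Rician noise sigma is 0.02 of unit proton density.
These sizes keep a full cohort under a minute on one core while leaving
every mechanism measurable. The resolution comparison (2.7 x 2.1 vs
2.2 x 1.8 mm presets) holds motion at zero so it isolates the
partial-volume mechanism. In the cohort the thin-sector bias correlates
negatively with wall thickness and positively with motion, and thin mobile
sectors cross the 70 ms flag while thick static walls do not — the
qualitative pattern the package exists to reproduce.

# What the phantom does and does not show

The generator emulates the geometry, contrast, partial-volume mixing,
inter-shot motion and noise statistics of T2-prepared cardiac acquisitions,
with exact ground truth. It does not simulate k-space artifacts
(off-resonance banding, ghosting), through-plane motion, B1 or slice-profile
effects, T2-preparation pulse imperfections, 3D anatomy, or physiological
between-visit variability; the interscan CoV of the simulation therefore
reflects noise and motion realizations only and is smaller than CoV values
measured across real repeated examinations. Passing tests demonstrate the
mechanisms and the correctness of the estimators on data satisfying the
model's assumptions — not the clinical accuracy of any particular scanner's
implementation.
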