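---
title: "Measuring anguilliform swimming from silhouette video: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring anguilliform swimming from silhouette video: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimkin)
```

## The measurement problem

Anguilliform swimmers (eels, lampreys) propel themselves with a lateral
wave that travels from head to tail while growing in amplitude. A swimming
trial filmed from above as a dark-on-light (or laser-lit light-on-dark)
silhouette carries everything needed to characterize that wave: from each
frame one can extract the body **midline**, express its lateral motion as
an excursion field $h(s, t)$ over arc position $s \in [0, 1]$ (0 = snout,
1 = tail tip, in body lengths, BL) and time, and summarize the trial by

* swimming speed $U$ (BL s⁻¹), net centroid displacement along the heading
  per unit time;
* tail-beat frequency $f$ (Hz);
* body wavelength $\lambda$ (BL) and its reciprocal, the number of
  simultaneous waves on the body;
* maximum peak-to-peak amplitude $A_{pp}$ (BL) and the caudal/rostral
  amplitude ratio of the envelope;
* wave propagation speed $V$ (BL s⁻¹), equal to $\lambda f$ for a pure
  traveling wave;
* the efficiency surrogates **Strouhal number** $St = 2 f A / U$ and
  **stride length** $U/f$ (BL per tail beat).

This package implements the full chain — segmentation, midline tracking,
wave-parameter estimation, efficiency indices — together with the group
statistics used in spinal-cord-injury recovery studies, where cohorts of
spinal-transected animals (with a known percent of regenerated
reticulospinal axons) are compared with sham-operated controls. Because
such studies rarely deposit raw video, the package also contains a
synthetic swimmer generator that produces silhouette stacks with exact
ground truth, so every stage is testable end to end.

## The synthetic swimmer

The generator prescribes the lateral wave in the body frame,

$$h(s, t) = A(s)\,\sin\!\big(2\pi(s/\lambda - f t)\big),
  \qquad A(s) = \frac{A_{pp}}{2}\, r^{\,s - 1},$$

where $r \ge 1$ is the caudal/rostral amplitude ratio, so $A(1)/A(0) = r$
and the phase speed is exactly $\lambda f$. The geometric (exponential)
envelope is a modeling choice: recovery studies report a single
caudal/rostral ratio rather than an envelope shape, and a one-parameter
log-linear family is the simplest curve consistent with that statistic.
The along-body coordinate is obtained by integrating
$dx = \sqrt{1 - (\partial h/\partial s)^2}\,ds$, which makes $s$ true arc
length: the generated body is inextensible, and wavelengths measured along
the body agree with the prescribed $\lambda$. The centroid advances along
the heading at exactly $U$ BL s⁻¹. There is no fluid–structure coupling:
the analysis pipeline only consumes kinematics, so a purely kinematic
model is sufficient and keeps every parameter independently controllable.

Defaults are the group means reported for larval lampreys: sham controls
$\lambda = 0.79$, $A_{pp} = 0.16$, $f = 3.6$, $U = 1.83$, $r = 4.8$;
5th-gill transected $0.53, 0.11, 4.1, 1.12, 1.7$; mid-body transected
$0.61, 0.13, 3.7, 1.12, 1.9$ (BL, BL, Hz, BL s⁻¹). Two bookkeeping
conventions matter and are used consistently:

* **Amplitudes are peak-to-peak.** The sinusoid half-amplitude is
  $A_{pp}/2$; generated and reported quantities share the convention.
* **Group frequencies are in Hz.** (The source tables print frequency
  with a "BL" unit label, evidently typographical.)

The renderer turns midlines into 8-bit silhouette frames by stamping
disks along a finely resampled midline, with a half-width profile that is
blunt at the snout, constant at mid-body (default maximum half-width
0.04 BL) and tapers to a point at the tail. An optional follow camera
keeps the image window centered on the body and records per-frame integer
origins so global pixel coordinates stay consistent. Frames can be
written as multi-page TIFF or numbered PNG with a JSON sidecar.

A virtual cohort draws per-individual parameters from truncated normal
distributions at the group means/SDs (truncated at physical bounds),
per-trial values around the individual's (SD = half the group SD by
default — the studies publish no within-individual variance, so this is a
package choice, exposed as `within_sd_frac`), and a uniform percent axon
regeneration on 33.3–84.2% for transected animals (missing for sham, as
controls have no lesion to regenerate across). Only the published
transected-combined speed (1.12 ± 0.35 BL s⁻¹) exists, so both transected
groups share it. All draws come from one seeded RNG stream in a
documented order, making cohorts bit-for-bit reproducible. Sample sizes
default to the study design (3 sham, 11 fifth-gill, 3 mid-body); trials
per individual default to 3 — the number of analyzed swim sequences per
animal is not published, so this is a configurable package default, not a
study fact.

## Midline tracking

Each frame is thresholded (Otsu by default; the polarity is chosen
automatically by taking the minority intensity class as the swimmer),
reduced to its largest connected component, and hole-filled. The
centerline is computed by Zhang–Suen thinning followed by the longest
geodesic path between skeleton pixels, which doubles as spur pruning; a
path covering less than 80% of the skeleton, or shorter than
$2\sqrt{\text{area}}$, is rejected as "ambiguous centerline" (branched or
non-elongated object). Because thinning erodes the rounded tips, both path
ends are extended along their local tangents to the mask boundary.

Two refinements matter for accuracy:

* the raw path is smoothed with cubic smoothing splines in
  $x(u), y(u)$ (fixed `spar = 0.4`, identical for every frame and
  treatment — treatment-blind processing), resampled uniformly in arc
  length to `n_points = 100` (≥ 50 samples per wave at
  $\lambda \approx 0.5$ BL);
* each resampled point is then slid to the **midpoint of the transverse
  foreground run** along the local normal. Thinning-based skeletons cut
  corners where the bend radius approaches the body half-width (at
  $\lambda \approx 0.5$ BL and $A_{pp} \approx 0.13$ BL the mid-body bend
  radius is only ~3 half-widths), which attenuates the measured wave by
  several percent; the transverse-center correction removes that bias and
  is sub-pixel. A second light spline pass and arc-length resampling
  follow.

Head and tail are identified from the physics of anguilliform swimming:
amplitude grows caudally, so the end with the smaller lateral-excursion
variance over time is the head. If the variance ratio between candidate
ends is below 1.2 the orientation is reported as ambiguous rather than
guessed — a deliberate failure mode for uniform-envelope motion. This is
robust to the erratic paths of spinal-transected swimmers, unlike
heuristics based on motion direction.

Image coordinates follow the usual row-down convention; all kinematics
are computed after converting to a right-handed frame internally, so the
sign of $h$ is consistent ("positive to the swimmer's left").

## Wave-parameter estimation

**Excursion field.** The heading is the principal axis of the centroid
track over the whole clip (the steady-state framing makes a single global
heading appropriate), signed by net displacement; $h(s_i, t_j)$ is the
signed perpendicular distance from the heading line through the mean
centroid, divided by the measured body length.

**Steady-state filter.** Cycles are delimited by successive upward zero
crossings of the tail excursion; a trial passes if every cycle-averaged
centroid speed is within 15% of the clip mean (the criterion in the
source studies is stated only qualitatively; 15% is the package default,
configurable and echoed into every run log). Zero crossings use a
Schmitt trigger: a crossing counts only when the signal swings from below
$-\delta$ to above $+\delta$ with $\delta$ = 20% of the oscillation
amplitude, which makes cycle detection immune to tracking ripple.

**Frequency** is the reciprocal mean period between same-sign zero
crossings (upward and downward pooled), with crossing times interpolated
linearly. For the few-cycle clips typical of swim trials this is unbiased
where a coarse spectral peak is not. The tail station is $s = 0.95$, not
1.0: the extreme tip is the least reliable sample of an extracted
midline.

**Amplitude.** At every station the peak-to-peak excursion is computed
per cycle and averaged. The per-cycle value is taken from a low-order
Fourier reconstruction of that cycle (fundamental plus two overtones)
rather than from raw sample extremes: extremes of noisy series are biased
upward by measurement ripple, while the reconstruction is exact for
sinusoids and still captures skewed waveforms. $A_{pp}$ is the maximum of
the envelope; because the outermost samples carry spline-end artifacts,
the tail value is extrapolated log-linearly from stations
$s \in [0.30, 0.975]$ — a window spanning several body-wave periods, so
wavelength-locked measurement ripple averages out of both the fitted
slope and level. The amplitude ratio is measured between stations
0.05 and 0.95 (operationalizing "head" and "tail") and raised to the
power $1/0.9$, i.e. extrapolated to the full body under the log-linear
envelope model, so it is a true caudal/rostral ratio.

**Wavelength** is twice the mean arc-length spacing between adjacent
prominence-filtered extrema of $h(s)$ per frame, averaged over frames.
Extremum prominence must exceed 20% of the local half-amplitude (rejects
noise wiggles without suppressing the quiet head region); positions are
refined by parabolic interpolation; a light Gaussian smoothing along the
body (SD = 2 samples, ~2% of body length) precedes detection, and
spacings outside 0.5–1.5× the median are discarded (a missed extremum
would otherwise double one spacing, a split one halve it). When no frame
shows two interior extrema but the body does oscillate — wavelengths near
or above one body length — the estimator falls back to fitting a single
sinusoid in $s$ (after dividing out the envelope) and flags the value as
fit-based.

**Wave speed** comes from complex demodulation: the phase of the
tail-beat-frequency component of $h(s_i, \cdot)$, computed over a whole
number of cycles at 14 stations in $[0.3, 0.95]$, is unwrapped and
regressed on $s$; $V = -2\pi f / \text{slope}$. A fit $R^2 < 0.9$ or a
near-zero slope (standing wave) is an explicit "incoherent wave" error.
On clean input $V$ agrees with $\lambda f$ within a few tenths of a
percent, and the ratio $V/(\hat\lambda \hat f)$ is reported with every
trial as an internal consistency check.

## Efficiency surrogates

$St = 2 f A / U$ with $A$ the *maximum amplitude*. Amplitudes here are
recorded peak-to-peak, which makes the convention inside $St$ ambiguous;
the package resolves it by internal consistency. With $A = A_{pp}/2$
(half peak-to-peak), healthy-control group means give
$St = 2 \cdot 3.6 \cdot 0.08 / 1.83 = 0.315$ — inside the 0.25–0.35 band
where oscillating propulsors are most efficient, exactly where those
animals are reported to sit. The literal peak-to-peak reading doubles it
to 0.63, contradicting that classification. Half peak-to-peak is
therefore the default, and `amplitude = "pp"` exposes the alternative.
The optimal band is inclusive at both endpoints. Stride length is $U/f$.
Percent axon regeneration is $100 \times$ (labeled axons counted 1.0 mm
distal to the transection) / (labeled axons 1.0–1.5 mm proximal); only
this final ratio is implemented — axon counting from micrographs is out
of scope.

## Statistics

The battery mirrors the analysis of treatment-comparison studies:

* **One-way ANOVA** across treatments per response, with **Holm–Šidák**
  step-down post hoc pairwise comparisons (pooled-variance $t$ with the
  ANOVA error df; the $i$-th smallest of $m$ p-values adjusted as
  $1 - (1-p)^{m-i+1}$ with monotonicity enforced). ANOVA and post hoc
  tests run on **individual means**: trials of one animal are not
  independent, and the source studies do not state their unit of
  analysis, so the package picks the conservative one and documents it.
* **Parametric-assumption diagnostics** (Shapiro–Wilk per group, Levene)
  are advisory: they are reported with pass/fail flags but never switch
  the test automatically.
* **Regressions** of each response on percent regeneration use
  individual means of transected animals only (sham animals carry no
  regeneration value).
* The **mixed model** `speed ~ frequency * regeneration` with a random
  intercept per individual is fitted by REML via `nlme` — deliberately
  the same engine such studies use — on *trials*, since absorbing
  within-individual correlation is its purpose. Fixed-effect p-values
  are Wald $t$-tests from the single fit. If every individual has one
  trial the random intercept is unidentifiable and the function falls
  back to OLS with an explicit warning record.

## What the tests do and do not show

The test suite calibrates every stage against ground truth the package
itself generates:

* full-pipeline recovery (generate → render → track → extract) of
  $\lambda, f, A_{pp}, U$ within 2% noise-free and 5% at 0.005 BL midline
  noise, over a 3×3×3×3 grid spanning the published group means
  (amplitude ratio fixed at 2, mid-range of the published 1.7–4.8), at
  250 fps, 2 s clips — the problem size chosen to resolve ≥ 7 tail-beat
  cycles while keeping the grid affordable;
* ANOVA type-I error within 5% ± 1.5% and Holm–Šidák family-wise error
  ≤ 5% over 2000 null replicates; mixed-model recovery of a 0.30
  frequency slope (and non-significant regeneration terms) in ≥ 90% of
  300 replicates of an 11-individual × 6-trial design with
  individual-intercept SD 0.1 and residual SD 0.1 (the residual SD is a
  package choice; the design mirrors the published finding pattern that
  speed depends on tail-beat frequency but not on regeneration);
* exact agreement of ANOVA/OLS with hand-coded sums-of-squares and
  normal-equations oracles, and of the Holm–Šidák adjustment with its
  closed form.

Synthetic silhouettes are clean: single animal, rigid width profile,
constant illumination, no shadows, glare, water-surface refraction or
occlusion, and a strictly periodic wave. Passing these tests therefore
demonstrates the *estimators* are accurate on well-segmented silhouettes
of steadily swimming animals; it does not certify segmentation on natural
footage, multi-animal scenes, or strongly aperiodic swimming. The
steady-state filter is the guard: trials that fail it are excluded from
kinematic averaging, exactly as unsteady sequences are excluded in the
laboratory workflow.

## Numerical choices and degenerate inputs

* Sampling adequacy: the generator requires a frame rate of at least
  10× the wave frequency and errors otherwise, naming the bound.
* Wave steepness: $|\partial h/\partial s| \ge 1$ is unrealizable for an
  inextensible body; the generator rejects such parameter combinations.
* A blank frame is "no swimmer detected"; a disk is "ambiguous
  centerline"; a uniform envelope is "orientation ambiguous"; a straight
  body is "wave not resolved"; a station-holding oscillation is "no net
  travel"; fewer than two cycles is "insufficient cycles". Errors are
  raised early and verbatim rather than degraded into numbers.
* All estimators are invariant (≤ 1–2%) under rigid rotation and
  translation of the input and under doubling of the pixel scale, and
  frequency estimates at 250 and 1000 fps agree within 1%.

## Worked example

```{r example, eval = FALSE}
library(swimkin)

## a healthy-control swimmer, 2 s at 250 fps
p <- swimmer_params()            # sham defaults
sq <- generate_midline_sequence(p, frame_rate_hz = 250, n_frames = 500)
stack <- render_frames(sq, render_spec(follow = TRUE))
tracked <- track_frames(stack)
wave_kinematics(tracked)

## a full virtual study
cfg <- run_config(out_dir = tempfile("study"), seed = 1)
res <- run_pipeline(cfg)
res$stats
```

## Known limitations

* The tracker assumes one animal filling a useful fraction of the frame;
  there is no multi-animal assignment, occlusion handling, or background
  subtraction for natural scenes.
* The amplitude-ratio and tail-amplitude corrections assume a locally
  log-linear envelope; envelopes with interior maxima are summarized by
  the envelope's maximum but their ratio statistic loses meaning.
* `waves_per_body` is defined as $1/\lambda$. For the healthy-control
  wavelength 0.79 BL this gives 1.27, while visual crest counts reported
  for such animals are nearer 1.2 — counting visible crests and inverting
  the wavelength are close but not identical operations; the package
  defines the reproducible one.
* Exact coefficient values of published mixed-model tables cannot be
  reproduced without the undeposited raw data; the statistics are instead
  validated by simulation calibration and closed-form oracles.
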