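---
title: "Simulating Cartesian view-sharing versus golden-angle radial time-resolved MRA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating Cartesian view-sharing versus golden-angle radial time-resolved MRA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`grasptwist` is a desk-scale simulation laboratory for comparing two
families of time-resolved contrast-enhanced MR angiography (CE-trMRA)
acquisitions on the same known ground truth:

* **Cartesian view sharing** (TWIST-style): the central 25% of
  phase-encode lines is re-acquired every frame, while the periphery is
  split into three interleaved subsets of which one is refreshed per
  frame; a frame borrows the other two subsets from preceding frames.
* **Golden-angle radial** (GRASP-style): spokes through the k-space
  centre advance by 111.24611° each repetition; thirteen consecutive
  spokes are grouped into one frame and reconstructed by
  density-compensated gridding.

Because clinical comparisons of these sequences rest on patient data with
no ground truth, the package replaces the patient with a dynamic digital
phantom whose geometry, bolus kinetics, motion and noise are exactly
known, and implements the image-quality metrics used in such studies:
20–80% vessel sharpness, bolus FWHM and maximum upslope, subtraction SNR,
plus paired t-tests and Fleiss' kappa for reader tables.

## The dynamic phantom

The scene contains three aorta-like discs — ascending (AA), descending
(DA) and abdominal (AbA) aorta cross-sections — with radii 16, 15 and
12 mm (half of typical adult diameters). Enhancement follows a unit-peak
gamma variate,

$$g(t) = \left(\frac{t-t_0}{t_p}\right)^{\alpha}
         \exp\!\left[\alpha\left(1-\frac{t-t_0}{t_p}\right)\right],
  \qquad t > t_0,$$

the standard first-pass bolus model; it peaks at exactly 1 at
$t_0 + t_p$. A recirculation plateau
$f_r\,(1-e^{-(t-t_0)/3t_p})$ with $f_r = 0.15$ reproduces the persistent
late-frame signal seen clinically. The AA bolus arrives first (default
$t_0 = 9$ s, $\alpha = 3$, $t_p = 7$ s), DA and AbA follow 2 and 4 s
later with slightly longer rise times. With a 1.8 s frame interval the
first three frames are always pre-bolus, as the subtraction-SNR metric
requires.

Vessel boundaries are rendered with a radial error-function profile
$\Phi((R - r)/\sigma)$, i.e. a step edge under Gaussian blur with
$\sigma = 2$ mm by default. This gives the 20–80% rise distance the
closed form $2\sigma\,\Phi^{-1}(0.8) \approx 1.6832\,\sigma$, so the
sharpness metric can be validated against an exact value. (For a disc
with $R \gg \sigma$ the erf profile and a true 2-D convolution agree to
well below the metric's resolution; the erf form is used directly.)

Respiration is modelled as rigid in-plane sinusoidal translation,
default period 4 s with head–foot amplitude 2–4 mm across subjects —
the scale of reported aortic respiratory displacement. Noise is i.i.d.
Gaussian per voxel per frame. The default `noise_sigma = 5` a.u. (against
a baseline of 100 and peak enhancement of 350–400) places the
reconstructed subtraction-SNR values in the range of diagnostic CE-MRA
(tens to low hundreds); the gridding reconstruction has no denoising, so
the measurement noise must represent the *post-reconstruction* regime of
the clinical images being emulated.

Crucially, the phantom exposes `scene(t)`, the continuous noise-free
scene at any time, so the samplers can evaluate k-space at per-line and
per-spoke timestamps; enhancement and motion *during* the acquisition of
a single frame corrupt its k-space exactly as in a real scanner.

## Acquisition models

The simulation is 2D+time: one "star" of the stack-of-stars, one
phase-encode plane of the Cartesian sequence. Slice-direction encoding
enters only through the timing arithmetic: the temporal resolution of a
stack-of-stars frame is `spokes_per_frame × n_partitions × TR`, which for
13 spokes, 53 partitions and TR 2.6 ms gives 1.79 s ≈ 1.8 s. Accordingly,
the per-spoke (and per-line) repeat time in the 2-D simulation is the
frame window divided by the spokes (lines) per frame, so that one frame's
acquisition spans its full temporal footprint — this is what makes the
two schemes differ under motion.

* **Radial:** spoke $i$ has angle $(i \cdot 111.24611°) \bmod 180°$
  (spokes are full diameters), 2× readout oversampling, and holds the
  exact 2-D DFT of `scene(t_i)` along its diameter (direct summation,
  verified against a brute-force oracle to $10^{-6}$ relative).
* **Cartesian:** the acquired band is the central
  `round(N · 1.56/2.89)` phase-encode lines, emulating the anisotropic
  acquired resolution of the clinical protocol (2.89 × 1.56 mm²) by
  zero-filling; 25% of the band forms the centre block, the periphery is
  split into every-third-line subsets; frame $k$ acquires the centre and
  subset $k \bmod 3$, each line holding a row of the DFT of the scene at
  that line's timestamp.

Measurement noise is added in k-space as complex Gaussian noise scaled so
that a fully sampled reconstruction carries the configured image-domain
noise level.

## Reconstruction

**View sharing:** frame $k$ combines its own centre block with the most
recent copy of each periphery subset; missing data at the sequence start
are zero-filled. Image = magnitude of the inverse FFT. One frame's
periphery therefore persists in the following two frames — the temporal
footprint of a view-shared frame spans three frame periods, which the
test suite asserts directly by perturbing one frame's data.

**Gridding:** per 13-spoke frame, density compensation followed by
convolution gridding with a width-4 Kaiser–Bessel kernel onto a 1.5×
oversampled grid (Beatty β), inverse FFT, deapodization, magnitude.

The density compensation deserves a note. The starting weights are the
polar area elements: a ramp $|k|$ with per-spoke azimuthal extents taken
from the actual angular gaps, because golden-angle gaps vary by up to the
golden ratio and a mean-gap ramp alone breaks the 2% reconstruction
contract on a fully sampled star. The plain gap-aware ramp still sits at
the edge of that contract — residual quadrature error of
spoke-constrained sampling, not of the kernel — so the weights inside the
Nyquist-sampled core ($|k| \le 1/\Delta\theta$) are refined by a
Pipe–Menon-style multiplicative iteration whose target is the gridded
density of a fully sampled Cartesian disc; ten iterations bring the fully
sampled reconstruction comfortably under 1% NRMSE (the acceptance script
reports the value it achieves). Outside the core the azimuthal density is
genuinely deficient and the area weights are kept: matching the Cartesian
target there, or capping the ramp at the spoke-count plateau, apodizes
the frame and inflates measured edge widths by a factor of about two.
`dcf_iters = 0` recovers the plain ramp.

**What is deliberately absent:** the clinical GRASP reconstruction is an
inline compressed-sensing algorithm with unpublished regularisation;
only its geometry-driven effects (streaks, sharpness) are reproduced by
gridding. Two consequences are documented rather than hidden:

* The simulated radial series has *lower* SNR than the Cartesian one
  (ramp weighting amplifies high-frequency noise; CS denoising would
  reverse this). The clinical finding of higher GRASP SNR is therefore
  not expected to reproduce here, and SNR direction is excluded from the
  directional suite.
* CS temporal regularisation — one driver of the clinically observed
  FWHM difference — is absent.

## Metrics

ROI curves are mean intensities over pixel-centre-in-disc ROIs.
Preprocessing interpolates ×10 and smooths with a centred moving
average, then min–max normalises. The interpolant is the
shape-preserving monotone cubic (Fritsch–Carlson, `pchip`): linear
interpolation clips the peak between frames and a natural spline rings
below the pre-bolus baseline, and either bias — a shifted half-maximum
level — costs a multiple of the 1% recovery budget for short boluses;
the monotone cubic keeps the noise-free recovery error near or below 1%
across arrival phases for boluses with FWHM ≥ 6 s (the acceptance script
reports the grid's worst and mean error). A genuine sampling
limit remains: a bolus with FWHM 4.2 s is sampled ~2.4 times per width at
1.8 s frames and aliases — no interpolant recovers its width to 1% at
all arrival phases.

`preprocess_curve()` defaults to a 5-sample (0.9 s) window. The
*pipeline* (`compute_metrics()`) smooths over two frame periods instead:
undersampled radial frames carry a few-percent frame-to-frame
fluctuation of the ROI mean (the streak pattern of the other enhancing
vessels rotates with the golden angle), and a smoother shorter than one
frame period cannot suppress it; the biased maximum of a fluctuating
curve otherwise systematically narrows the measured radial FWHM. Both
schemes use the identical estimator, so comparisons are unaffected by the
common broadening this induces (a boxcar of width $\tau$ adds roughly
$2\ln 2\,\tau^2/(3\,\mathrm{FWHM})$, ~0.3 s here).

FWHM is the time between the first upward and last downward crossing of
half maximum around the global peak (linear interpolation on the dense
grid); a curve that never returns below half maximum — e.g. a strong
recirculation plateau — is flagged as an error rather than truncated.
Max slope is the steepest forward difference on the upslope. Min–max
normalisation was chosen over baseline-relative normalisation (the
clinical description does not specify; min–max is scale-free and robust
to baseline offset).

Vessel sharpness follows the 20–80% construction: thresholds at 20% and
80% of the profile's absolute intensity range, edge anchored at the
steepest gradient, crossings found walking outward, $d = |x_{80} -
x_{20}|$, $vs = 1/d$. The construction is affine-invariant and satisfies
$vs \cdot d = 1$ exactly. Two robustness layers serve the pipeline:
the anchor search can be restricted to a window around the known wall
position of the profile line (±9 mm), and the pipeline reports the
median over the three frames centred on the bolus peak — an automated
stand-in for a reader choosing the frame where the wall is best seen,
since a single frame's profile can be ruined by a streak crossing it
(the measured rise distance can jump severalfold between adjacent
frames).

Subtraction SNR uses frames 2 and 3 (both pre-bolus; frame 1 is
excluded): $\hat\sigma = \mathrm{sd}(\text{frame}_3 -
\text{frame}_2)/\sqrt{2}$ over the ROI, and SNR is the peak-frame ROI
mean over $\hat\sigma$. The $\sqrt{2}$ follows from the difference of two
i.i.d. noise realisations; noiseless input is flagged rather than
returning infinity.

The peak frame is automated as the frame nearest the smoothed curve's
maximum (never earlier than frame 4).

## Statistics

Quantitative metrics are compared with a paired t-test computed from
first principles ($t = \bar d / (s_d/\sqrt{n})$, two-sided p from the
Student-t distribution); *paired* because the study design is an
intra-individual cross-over — both sequences are acquired in the same
subject. Reader agreement tables use Fleiss' kappa in its defining form
(per-subject agreement, marginal chance agreement). The multilevel
proportional-odds models used for reader scores in clinical work are
out of scope: they are off-the-shelf ordinal regressions on data that
cannot be simulated here, and the package deliberately restricts itself
to statistics that are fully specified and testable.

## The cohort study and what it can show

`run_study()` simulates a seeded cohort (default 10 subjects, 128×128
matrix, 40 frames of 1.8 s ≈ 72 s) with subject-to-subject variability
in arrival time (±1.5 s), respiratory period (3.5–5 s), phase and
amplitude (2–4 mm head–foot). Both schemes sample the identical
continuous scene. Four directional findings are aggregated:

1. radial vessel sharpness above Cartesian at all three ROIs
   (per subject);
2. Cartesian mean FWHM at or below radial (per subject) — the expected
   direction because the Cartesian centre block is acquired in ~1.0 s of
   the 1.98 s frame, a shorter temporal footprint than the radial frame's
   full 1.8 s;
3. similar maximum upslope between schemes (median relative
   difference);
4. radial background streak energy above Cartesian (per subject).

Sharpness and streak direction reproduce robustly, and the
max-slope similarity also reproduces once curves are smoothed over two
frame periods. The FWHM *direction*, however, is only partially
reproduced at desk scale, and the mechanism is instructive: with
13-spoke single-coil 2-D gridding, streaks from the *earlier-enhancing*
AA cross the DA region; the DA curve's peak is raised by a few percent
while its baseline is not, which narrows the measured radial FWHM by a
few tenths of a second — an effect larger than the ~0.1 s
temporal-footprint systematic it competes with. Clinically this
cross-contamination is diluted by 3-D encoding, coil arrays and CS
regularisation, none of which exist in this deliberately transparent
reconstruction. The package reports these aggregates as computed; the
vignette records why the desk-scale study is expected to agree with
clinical findings on sharpness, slopes and streaks but not reliably on
FWHM direction.

A note on what passing tests show about real data: the phantom has
piecewise-constant vessels with analytic edges, rigid global motion and
white noise. It validates the *mechanics* of sampling, reconstruction
and metrology; it does not model flow, dissection lumina,
through-plane motion, coil shading or vendor filtering, so effect sizes
measured here do not transfer to patients — only directions and
mechanisms do.

## Numerical choices and degenerate inputs

* Golden angle fixed at 111.24611° ($180°/\varphi^2$); spokes are
  diameters over $[0°, 180°)$.
* Gridding: Kaiser–Bessel width 4, oversampling 1.5, Beatty β; samples
  wrap periodically at grid edges; deapodization by the kernel's
  analytic transform.
* Ties and degenerate cases are errors, not silent numbers: constant
  curves (normalisation), flat profiles (no edge), profiles not reaching
  both thresholds, noiseless subtraction SNR, zero-variance paired
  differences, single-category rating tables.
* All randomness flows from explicit integer seeds; a phantom plus its
  two acquisitions is bit-reproducible from its configuration.
* Problem sizes used in the shipped tests: 32×32 scenes for oracle
  checks, 64×64 single-vessel phantoms for estimator checks, the
  128×128 × 40-frame 10-subject cohort for the directional suite.

## Serialisation

Image series travel as 4-D NIfTI (pixel spacing in mm, frame interval in
s, conventional `(x, y, z, t)` on disk, `(t, y, x)` in memory) with a
JSON sidecar for exact frame times and provenance; phantom configurations
as YAML; ROI/profile definitions as JSON; metric reports as CSV/JSON;
reader scores as long-format CSV. Every writer has a reader and a
round-trip test.
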