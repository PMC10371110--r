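---
title: "Models and methods behind the fgsim pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the fgsim pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgsim)
```

## What the package models

Wearable fluorescence-guided surgery (FGS) goggles combine a near-infrared
(NIR) excitation source, an emission filter, dual visible/NIR cameras and a
see-through display. Three processing problems make or break such a
system, and `fgsim` implements all three together with an optical
simulator that generates the inputs they need:

1. **Background subtraction.** Room lights emit NIR. Pulsing the laser on
   every other camera frame and taking the absolute consecutive-frame
   difference `|F[n] - F[n-1]|` removes any static background while
   preserving the full frame rate.
2. **Coalignment.** The NIR and visible sensors (and the camera versus
   the surgeon's eye) see the world from slightly different positions. A
   3x3 projective transform (homography) fitted to matched fiducials at a
   single calibration distance corrects the misalignment — exactly, at
   every distance, when the two viewpoints share an optical center, and
   only at the calibration distance otherwise.
3. **Quantification.** Fluorescence is reported as a signal-to-background
   ratio (SBR). Per-pixel maps divide the background-subtracted intensity
   by the *excitation-leak threshold* — the maximum laser-ON minus
   laser-OFF intensity on a white, non-fluorescent card — so SBR = 1 means
   "indistinguishable from leaked excitation light". Well-plate curves
   instead divide each well's background-subtracted mean by that of a
   zero-concentration control well.

## The camera and scene model

Cameras are ideal pinholes (`camera_model()`): focal length `f` (mm),
pixel pitch `p` (mm/px), a principal point, a world pose, and a bit
depth. A fronto-parallel plane at distance `d` is sampled at
`d * p / f` mm/px. The default intrinsics give 0.15 mm/px at 50 cm,
matching the published relation that a 20 px offset corresponds to 3 mm
at that distance; the full-resolution sensor mode behind that statement
is not published, so the pitch here is an effective value chosen to
reproduce it, and `binned_camera()` derives the desk-scale 410 x 308
audit camera (1.2 mm/px at 50 cm) used throughout the examples and
tests. Lens distortion and rolling shutter are not modeled.

Targets are planar: a uniform card, a fiducial/bar chart, or a 96-well
phantom. Rendering back-projects each pixel (supersampled 2–4x per axis
for anti-aliased edges) onto the plane, evaluates reflectance and
fluorophore concentration, applies the channel model, then noise
(Poisson shot noise at a full-scale photoelectron count, then Gaussian
read noise), then quantization to `2^bit_depth` levels (8 by default).
Identical noise seeds reproduce frames bit-for-bit; the per-frame seed is
derived from the noise seed and the frame index.

The chart analysed by the alignment audits carries four 13 mm fiducial
squares at (±40, ±40) mm and two bar groups. On the physical chart the
bar analysis uses the group at 1.0 line pairs/mm; the desk-scale audit
camera cannot resolve 0.5 mm bars, so the default chart uses 4 mm bars
(0.125 lp/mm) and the frequency is configurable.

## Illumination and the channel forward model

The excitation source is a circular array of three Gaussian beams
(1/e^2 radius 5 mm at source, linear divergence 0.01 mm/mm, per-beam
source peak 22 mW/cm^2) mounted on a 30 mm circle and converging on the
optical axis at 40 cm. At plane distance `z` each beam center sits
`d (1 - z/L)` off-axis and its peak decays with footprint area. These
beam parameters are not published; they were chosen once to give
~20 mW/cm^2 peak near the convergence distance falling toward
~5 mW/cm^2 at 60 cm, and are config-exposed, not asserted by tests.
`inclination_angle()` gives the diode tilt `atan(d/L)` and
`coverage_above()` the irradiated area above a threshold.
`power_from_thermal()` implements the linear thermal estimator
`P = max(0, dT)/max(dT) * P_max` with no diffusion correction — the
estimator is the rescaling, nothing more.

An `optical_channel()` collapses the excitation-filter stack into two
scalars: the **leak fraction** `l` (fraction of excitation irradiance
registering through the emission filter) and the **emission gain** `k`
(intensity per molar per mW/cm^2). Detected NIR intensity is

    I = min(1, exposure * (k C E + l E + ambient))

The four filter presets are calibrated so that a noiseless white-card
render at the 20 mW/cm^2 reference irradiance reproduces the measured
leak maxima 0.53 (single 830 nm LP), 0.082 (double 830 nm LP), 0.106
(832 nm BP) and 0.090 (808 nm LP) — the only way the filters enter the
published processing chain. The gain default `k = 2.05e6` places the
sensitivity knee `l/k` at 2 nM for the double-830LP channel, so the
simulated curve is log-log linear over 1–100 nM with a plateau below
1 nM, the published curve shape. Under this model the implied well SBR
is exactly `1 + k C / l`, independent of irradiance and exposure.

Two deliberate simplifications: the leak term is not modulated by
surface reflectance (the control well then measures `l E` like the white
card), and there is no spectral rendering, tissue scattering or depth
attenuation.

## Synchronized streams

`generate_stream()` triggers the laser on every other frame (trigger
period twice the 33 ms frame period at 30 fps) with an on-window of
`duty` x frame period (default 0.70). The excitation received by a frame
is the overlap of the laser window with that frame's exposure window;
with the default exposure offset of 0 the on-frames receive a factor
`duty` and off-frames none. Setting `exposure_offset = 0.3` makes
exposure windows lead the frame boundary by 30%, so duties above 0.7
bleed excitation into the following frame — the behavior that motivated
the 70% duty choice on the hardware. `background_subtract()` uses
sliding (not half-rate) differences, honoring the full-rate output
claim; differences are computed in double precision so quantized inputs
cannot wrap.

## Alignment audits

`distance_sweep()` calibrates a homography from matched fiducial
centroids at `d_cal` (Hartley-normalized DLT, exact on four
non-degenerate points) and measures raw and corrected errors across
distances, in pixels and in scene mm at the eye view. Design choices
that matter for accuracy:

- Fiducial centroids are intensity-weighted over the component bounding
  box expanded by two pixels, with weights `I - min(I)`. This is exact
  for an anti-aliased blob on a uniform background and invariant under
  linear contrast changes; the practical floor is ~0.03 px.
- Bar positions are refined by an intensity-weighted centroid over each
  above-threshold run of the profile. A parabolic refinement of the
  discrete maximum was rejected: rendered bars are flat-topped, where the
  parabola's curvature estimate is phase-biased by ~0.2 px.
- Blobs are matched between images by nearest neighbor after centering
  each centroid set, which is exact for the translation-dominated
  offsets these geometries produce.
- Errors are reported as the mean over fiducials (the per-fiducial
  maximum is recorded alongside).

The three mount presets encode the published raw overlay offsets as
baselines with parallel optical axes: forehead (69.5 mm vertical,
26.5 mm horizontal), between-eyes (36.9, 23.0), and coaxial — shared
optical center, with the printed residual offsets (17.3, 3.4 mm at
50 cm) represented as an in-plane sensor shift. For a translated camera
viewing a fronto-parallel plane the corrected scene-space error has the
closed form `B |d/d_cal - 1|` (`parallax_error_closed_form()`); the
forehead preset therefore predicts 13.9 / 5.3 mm at ±10 cm versus the
published 15 / 5 mm — the gap is consistent with a mount tilt the
published description does not parameterize. The between-eyes preset's
printed corrected vertical error (1 mm) is *inconsistent* with
pure-translation parallax given its printed 36.9 mm raw offset; the
preset keeps parallel axes and the discrepancy stands rather than tuning
a hidden tilt. The coaxial preset's corrected error is
distance-independent and limited only by detection (~0.1 mm).

## The sensitivity experiment and its limits

The replicated well-plate experiment (`run_experiment(kind =
"sensitivity")`) renders duplicate wells of the printed dilution series
(0 control, 250 pM … 100 nM) at 45 cm under spatially **uniform**
20 mW/cm^2 excitation — emulating the motorized stage that equalized
per-well irradiance on the bench; the converging array would light only
~1 cm of a plate. Well exposures use a 0.15 exposure scalar so the
100 nM well stays below 8-bit saturation while the control well remains
measurable (the bench protocol likewise varied exposure/ISO); SBR is a
ratio and is exposure-invariant. Negative background-subtracted pixels
are clipped to zero before ratios, the well statistic is the ROI mean
(median by flag), and duplicate wells are averaged after per-well SBR.

`fit_sensitivity()` splits wells at SBR < 1.5 (the same 1.5 used for
overlay masking) into plateau and linear regions and fits ordinary least
squares on log10–log10. One structural limitation deserves emphasis:
under `SBR = 1 + kC/l` the plateau approaches 1 only for wells far below
the knee, and the asymptotic unit slope only far above it. The printed
series spans a factor of 400, so the two plateau wells sit just 4–8x
below any knee that keeps 1–100 nM linear, and the model plateau mean is
~1.19, not 1. The published flat plateau at exactly 1 reflects a
detection floor that a smooth ratio model cannot reproduce. The
asymptotic slope is therefore estimated on wells whose fluorescence
exceeds the leak tenfold (`asymptotic_slope()`, model slope within 4% of
unity there), and the plateau level is reported as-is. Tests assert what
the model actually produces; the replicated-recovery check of the
plateau against 1 ± 0.1 documents this gap rather than hiding it.

## Numerical and reproducibility choices

- Homographies are normalized to `h33 = 1`, falling back to unit
  Frobenius norm in the contrived case `|h33|` below 1e-8 of the largest
  entry; DLT uses Hartley pre-normalization and the smallest singular
  vector; over-determined consistent systems are exact to ~1e-12.
- `warp_image()` uses inverse mapping with bilinear (default) or nearest
  interpolation and zero fill outside the source.
- Rotations enter as axis–angle and are stored as orthonormal matrices
  (tolerance 1e-9, determinant +1).
- All lengths are mm internally; irradiance mW/cm^2; time ms.
- Every randomized pathway draws through an `fgs_noise` seed;
  `fork_seed()` hashes experiment names into per-experiment substreams of
  the single config seed, so adding an experiment does not perturb the
  draws of the others. Rerunning any experiment with an equal config is
  bit-identical.
- Problem sizes used by the shipped tests and the acceptance script: the
  410 x 308 audit camera for sweeps (21 distances for the coaxial sweep,
  supersample 4), a 102 x 77 card camera for stream and leak checks, and
  20 replicate plates for the sensitivity recovery — sizes chosen so the
  full suite exercises every pathway in a few minutes on a laptop.

## What passing tests do and do not show

The simulator produces ideal pinhole views of perfectly planar targets
with known noise. Passing audits therefore validate the *algorithms* —
DLT calibration, parallax behavior, leak normalization, stream
demultiplexing — not the hardware: real systems add lens distortion,
imperfect beamsplitter flatness, autofocus breathing, specular
reflections and motion, none of which are modeled. Conversely, the
closed-form parallax oracle and the shared-center exactness results are
properties of projective geometry and carry over to any calibrated
implementation.
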