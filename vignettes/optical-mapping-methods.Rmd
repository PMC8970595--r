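---
title: "Methods: signal conditioning and parameter maps for low-cost cardiac optical mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal conditioning and parameter maps for low-cost cardiac optical mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Optical mapping images cardiac electrical activity by staining a
Langendorff-perfused heart with a voltage-sensitive dye (such as
di-4-ANEPPS) and filming it at high frame rates. Each pixel's intensity
trace is a fractional-fluorescence copy of the local action potential
(AP), with two complications that drive everything in this package:

* **Inverted polarity and small amplitude.** At red emission
  wavelengths the dye darkens on depolarization, and a full AP moves
  the signal by only a few percent of the baseline fluorescence
  (`amplitude_fraction`, default 0.08).
* **Severe noise.** With an industrial CMOS camera at 977 frames/s and
  200x200 pixels over a ~7 mm mouse heart, the raw per-pixel
  signal-to-noise ratio is near 0.5 — the AP is buried in sensor
  noise and only becomes measurable after aggressive conditioning.

The package implements the complete chain from the raw movie to the
physiological quantities a cardiac electrophysiologist reports:
activation (isochrone) maps, APD80 maps, conduction-velocity (CV)
vector fields with longitudinal/transversal axis speeds, and
rate-dependence (restitution) curves.

## The synthetic study scenarios

Because no public recordings accompany this class of camera rig, the
package ships a simulator (`simulate_recording()`, `scenario()`) whose
output has exact, analytic ground truth. It emulates, rather than
solves, cardiac physics:

* **Wavefront:** a point-paced elliptical wave. In fiber coordinates
  the activation delay is `T = sqrt((u/v_long)^2 + (w/v_trans)^2)`.
  This is the far-field shape of anisotropic conduction from a point
  source; it deliberately omits wavefront curvature effects on speed,
  boundary effects, and heterogeneous fiber fields.
* **AP waveform:** rest at 0, a 2 ms smoothstep upstroke (mouse-scale;
  whole-heart activation takes ~10 ms), then exponential
  repolarization with `tau = APD80 / ln 5`, which places the
  80%-repolarization crossing at `APD80` by construction. Restitution
  is linear in pacing cycle length (PCL): the mouse template loses
  19 ms of APD80 from PCL 150 ms to PCL 80 ms, and "drug mode" adds a
  fixed +19 ms increment (a transient-outward K+ blocker effect).
* **Camera:** vignetted baseline (radial cosine falloff, 30% at the
  corners, reproducing the uneven illumination that masking must
  handle), additive white gaussian sensor noise, optional linear
  drift, 10-bit quantization, and the dye's polarity inversion.

Scenario defaults are the study conditions themselves: mouse —
200x200 px, 977 FPS, 2 s, PCL 150 ms, `v_long/v_trans` = 0.51/0.29 m/s
at PCL 150 (linearly interpolated to 0.47/0.25 m/s at PCL 90), raw-SNR
calibration 0.5; rat — APD80 60 ms, raw SNR 1.4. Quantities the
source experiments do not pin down are explicit package defaults, not
inferences: absolute mouse APD80 (40 ms at PCL 150; rodent-typical),
rat velocities (0.60/0.35 m/s), pixel pitch (0.035 mm/px, i.e. a 7 mm
field of view), baseline 600 counts, fiber angle 30 degrees.

The noise SD is not hand-tuned: `noise_sd_for_snr()` solves it in
closed form from the target raw SNR, `sigma = B_mask * dF/F * RMS(V) /
SNR_target`, where `RMS(V)` is the root-mean-square of the normalized
waveform over one cycle and `B_mask` the mean baseline over the
intensity-masked region.

What passing on these movies does **not** show: robustness to motion
artifact (the emulated preparations are mechanically uncoupled),
photobleaching beyond linear drift, arrhythmic or alternans rhythms
(the conditioning chain assumes strict pacing periodicity), or
reentrant propagation geometries.

## Signal conditioning

`condition_recording()` applies, in order:

1. **Spatial gaussian binning** (`spatial_gaussian_filter()`): each
   frame is convolved with a normalized 5x5 gaussian. The window size
   is a camera-class setting; the gaussian's SD is not separately
   specified anywhere authoritative, so the package sets
   `sigma = (window - 1) / 4` (kernel truncated at two sigma) and makes
   it configurable. Boundaries are reflective — zero padding would dim
   the frame edge and leak into the intensity mask. For white noise
   this step divides the noise SD by ~3.48.
2. **Beat segmentation** (`segment_beats()`): onsets come from the
   spatially averaged global signal — the strongest derivative
   extreme fixes the pacing phase and polarity, candidates at strides
   of one PCL are refined within +/-2 frames. Alignment is by
   stimulus-period stride, not cross-correlation; for paced rhythms
   the stride is exact and refinement only absorbs frame quantization.
   Each window opens 10% of a cycle before the onset so the earliest
   pixels keep their full upstrokes (clamped so beat 1 is never lost).
3. **Ensemble averaging** (`ensemble_average()`): every complete beat
   inside the 2 s window (13 beats at PCL 150) is averaged per pixel,
   for a further sqrt(13) noise reduction.
4. **Resting level** (`estimate_resting_level()`): the trace is
   smoothed with a 1-D gaussian (sigma 7 ms, truncated at 4 sigma; 57
   taps at 977 FPS) and averaged over the diastolic window — the
   trailing 20% of the cycle, just before the next upstroke. The
   smoothed-trace *minimum* was considered and rejected: on noisy
   traces a minimum estimator is biased low by construction.
5. **Normalization/polarity** (`normalize_invert()`): flips the dye
   polarity and rescales each pixel to resting 0, peak 1. Zero-range
   pixels are flagged dead and excluded, never raised as errors.

### SNR definition

`compute_snr()` returns the ratio of RMS signal amplitude to RMS
noise, with noise evaluated at resting potential (the pooled diastolic
windows). The amplitude is noise-power corrected:

`A = sqrt(max(mean((x - rest)^2, beat) - mean((x - rest)^2, diastole), 0))`

The correction matters: an uncorrected beat-window RMS contains the
noise power and can never fall below the noise RMS, so the ratio could
never be less than one — yet raw rodent recordings of this class
genuinely sit near SNR 0.5. Only an amplitude that excludes the noise
power measures the AP itself. After conditioning the correction is
negligible (noise is ~13x smaller), and a noise-free trace returns the
sentinel `Inf`.

With this definition the conditioning chain multiplies SNR by
~3.48 * sqrt(13) ~ 12.5: the mouse scenario goes from 0.5 to ~6.4,
inside the reported 16 +/- 10 band for conditioned recordings; the rat
scenario from 1.4 to ~15.

### Masking

`build_mask()` keeps a pixel iff conditioned SNR >= `snr_cutoff`
(default 2), mean intensity >= `intensity_cutoff` (scenario default
80% of the central baseline) and below the saturation bound (top 1% of
the dynamic range). This reproduces the semi-automatic SNR/intensity
cutoff masking used in practice; an empty mask warns instead of
failing.

## Parameter maps

* **Activation** (`detect_activation()`): maximum first difference of
  the upstroke-positive trace, refined by parabolic interpolation,
  ties to the earliest sample. The max-derivative marker is the
  standard choice in this software ecosystem; a 50%-amplitude marker
  was evaluated and is not the default. On noiseless movies the map
  matches ground truth to well under a frame; at raw SNR 0.5 after
  conditioning the per-pixel error is ~0.15 ms.
* **APD80** (`compute_apd80()`): amplitude is the post-activation peak
  (3-frame running mean, to tame single-sample peak noise) above the
  resting level; APD80 runs from the activation time to the first
  *sustained* crossing below `rest + 0.2 * amplitude`, linearly
  interpolated. The sustain rule (default 2 ms) exists because a
  literal first-sample crossing is biased early on noisy traces — at
  the mouse scenario's conditioned noise a first-crossing rule reads
  ~2.5 ms short, while a long 5 ms debounce reads ~6 ms long; 2 ms
  balances the two (~+1.4 ms residual). APD starts at the
  max-derivative time, not the upstroke midpoint or peak, matching the
  motivation that noise corrupts the apparent resting potential (which
  is why the resting level is filtered first). Non-repolarizing pixels
  are flagged, not errors.
* **Outlier exclusion** (`exclude_outliers_iqr()`): Tukey fences
  `Q1 - 1.5 IQR`, `Q3 + 1.5 IQR`, single pass, quartiles by linear
  interpolation between order statistics (`quantile()` type 7 — the
  dominant convention in scientific software; Tukey hinges would change
  the worked example `{10,11,12,12,13,50} -> [9, 15]`). Fewer than 4
  values pass through unchanged; a zero IQR excludes nothing.
* **Conduction velocity** (`fit_cv_bayly()`): for every defined pixel
  a quadratic surface `T(x, y)` is least-squares fitted over a 7x7
  neighborhood in physical coordinates and the velocity is the
  gradient inverse `v = grad T / |grad T|^2` at the centre, in cm/s.
  Pixels whose full window is defined share one pseudo-inverse
  (vectorized); mask-boundary pixels get individual fits if at least 6
  defined neighbors remain and the design is non-singular. Fits with
  residual RMS > 2 ms are dropped. On any polynomial surface of degree
  <= 2 the estimator is exact to numerical precision.
* **Axis CV** (`extract_axis_cv()`): vectors whose direction lies
  within +/-15 degrees of the fiber axis (or its opposite — waves
  propagate outward both ways from a central pacing site) average into
  the longitudinal CV; likewise the perpendicular for transversal. The
  average is 20% trimmed: gradient inversion has a heavy right tail
  under noise, and a plain mean can be destroyed by a single
  near-zero-gradient fit.
* **Restitution** (`build_restitution()`): per-PCL summaries
  aggregate into a PCL-sorted table of mean APD80 and axis CVs.

### Why the activation map is smoothed before the CV fit

`analyze_conditioned()` passes the activation map through a mask-aware
normalized 5x5 gaussian (`smooth_map()`) before `fit_cv_bayly()`, while
APD continues to use the raw per-pixel activation times. The reason is
a bias, not cosmetics: activation-marker jitter enters the speed
through `1 / |grad T|`, a convex function, so zero-mean timing noise
inflates speeds (by ~11% on the longitudinal axis of the mouse scenario
if left untreated — the jitter is spatially correlated at the fit
window's own scale, so the fit cannot average it away). Smoothing the
isochrones suppresses the jitter at its source; in the interior a
gaussian leaves the gradient of any quadratic surface unchanged, so the
estimator's exactness class is unaffected. With smoothing plus the
trimmed sector mean, recovered axis speeds sit within ~2 cm/s of truth
at raw SNR 0.5.

## Numerical choices and degenerate inputs

* All conditioning runs in floating point; integers exist only in the
  OMR1 container (uint16 little-endian samples, 44-byte header).
* Reflective boundaries everywhere a kernel meets an edge (space and
  time), with scatter-side accumulation where reflected indices
  coincide.
* Ties in activation detection resolve to the earliest sample; a flat
  derivative denominator falls back to the unrefined peak.
* Dead pixels, unrepolarized pixels, empty masks and empty axis
  sectors are flagged (NA + classed warning); malformed arguments,
  unreadable files and impossible geometry raise classed errors
  (`omapr_argument_error`, `omapr_format_error`, ...).
* Every random quantity flows from one integer seed; the pipeline
  fans it out per stage (`seed * 100 + stage`) and equal seeds give
  byte-identical summaries.

## Problem sizes used in the shipped checks

The validation experiments run the full-scale study conditions:
200x200 pixels, 977 FPS, 2 s movies (1954 frames), five seeded
replicates for the recovery statistics, plus single runs at PCL 80 and
90 ms for restitution and one rat-calibration run. Unit tests exercise
the same code paths on reduced fields (24-60 px, 0.4-0.8 s), which
keeps the default suite fast while the acceptance checks retain the
full geometry.

## Known limitations

* The OMR1 container is self-defined; it does not read any vendor's
  proprietary stream, and TIFF/HDF5 import is out of scope.
* The simulator is kinematic. It cannot probe source-sink effects,
  curvature-dependent CV, or tissue heterogeneity, so recovery results
  bound algorithmic error only, not physiological model error.
* Long-APD templates (rat, 60 ms at PCL 150) leave a small exponential
  tail in the diastolic window; the resting level is then slightly
  overestimated and APD80 reads a few percent short. Shortening the
  diastolic fraction trades this against noise-estimate variance.
* Beat segmentation assumes strictly periodic pacing; irregular
  rhythms need a different alignment strategy (out of scope).
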