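---
title: "Thermographic hen detection: model, parameters and design"
author: "hentherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermographic hen detection: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hentherm)
```

## The problem and the sensing model

Sanitary treatments of poultry housing (for instance ozone treatments that
reduce atmospheric ammonia and bacterial load) are toxic to the animals, so
they may only run when the treated room is empty. The sensor modelled here
answers one question per short monitoring slot: *is at least one hen on the
floor under the camera?* The input is an 8-bit grey-scale thermographic
frame (nominally 320 × 240 pixels) from a ceiling-mounted infrared camera
pointing straight down; warm bodies appear as bright regions on a cooler
floor.

Two physical facts shape the design. First, an uncooled microbolometer
camera has excellent *relative* sensitivity (about 0.04 °C) but poor
*absolute* accuracy (±2 °C, plus periodic internal recalibration jumps).
Absolute thresholds are therefore useless; the detector re-estimates the
floor temperature from every frame's own histogram and thresholds
*relative* to it. Second, a hen's thermal imprint is not a solid object of
fixed shape — feathers insulate, the bird deforms, and at low contrast
only parts of the body clear any threshold. A single rigid criterion is
brittle, so the detector combines shape evidence (template matching) with
a shape-free fallback (total warm area).

## The per-frame pipeline

For a frame with calibration $t(\ell) = t_0 + \ell \cdot \delta$ (default
$t_0 = 0$ °C, $\delta = 0.1$ °C per grey level, which makes a 1 °C shift
exactly 10 levels):

1. **Histogram.** Exact counts of grey levels 0–255.
2. **Floor estimate.** The floor dominates the image, so a location
   statistic of the histogram estimates its temperature. The default is
   the *mode* (tie-break: lowest level); a count-weighted *trimmed mean*
   over the central 80% of the mass is available for comparison. For the
   near-normal histogram of an empty floor the two coincide; the mode
   stays robust when hens occupy a sizeable image fraction.
3. **Background Color Threshold.** $\mathrm{BCT} =
   \mathrm{level}(T_{floor} + \Delta t)$ with $\Delta t > 0$
   (default 1 °C; 2 and 3 °C are the other calibrated operating points).
   A BCT that saturates at 255 makes detection impossible: the frame is
   processed anyway and the condition is recorded as a warning, so one hot
   frame cannot halt a monitoring run.
4. **Binarization.** Strictly above threshold: pixel > BCT. Strictness
   matters only at exact equality, but fixing it makes results
   reproducible bit for bit.
5. **Particle filter.** Morphological opening with a disc (radius 1 by
   default) removes speckle; 8-connected components smaller than
   `minParticleArea` (default 30 px) are dropped. The filter is
   idempotent and never adds foreground.
6. **Colored Pixels.** CP = number of foreground pixels left.
7. **Pattern recognition.** Normalized cross-correlation of a binary hen
   template against the filtered mask (the 0/1 values are treated as
   intensities), evaluated at every placement where the template fits
   entirely inside the frame, over a rotation grid. The score
   $R \in [-1, 1]$ is invariant to affine intensity maps of the image;
   windows with constant content score 0 by convention, so blank regions
   can never match.
8. **Decision.** $\mathrm{HD} = 1$ if the best score reaches the
   acceptance threshold, else if $\mathrm{CP} > \mathrm{CPT}$ (strictly),
   else 0.

Slots aggregate frames with any-frame-positive logic (one frame per
2-second slot is the operational default — the point of the design is that
one thermographic image suffices for a decision), and every slot appends
one record to a TSV log: slot start/end timestamps, the decision, CP, the
BCT used, and the set-up echo (shift, template, best score, warnings).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `shift` | 1 °C | floor-to-foreground contrast threshold |
| `template` | ellipse 135 × 63 px | full-body hen shape at 1 °C shift |
| `nccThreshold` | 0.5 | minimum accepted match score |
| `cpt` | 1736 px | fallback warm-area threshold (one hen's imprint) |
| `minParticleArea` | 30 px | particle filter area cut |
| `openingRadius` | 1 px | particle filter opening disc |
| `floorMethod` | `"mode"` | floor statistic |
| `slotSeconds` | 2 s | monitoring slot duration |
| `angles` | 0–165° by 15° | rotation grid (0–345° for triangles) |

The template dimensions and the CPT are *calibrated* quantities: at a 1 °C
shift the measured single-hen particles have equivalent-ellipse axes close
to 135 × 63 pixels (area ≈ 6680 px, comfortably above the CPT), while at
2–3 °C only the head remains visible and head-scale triangles (35 × 16,
18 × 12) describe the particles. `calibrateTemplate()` reproduces that
procedure on annotated frames: segmentation at the chosen shift, the
largest particle per frame taken as the hen, equivalent-ellipse axes
(shift 1 °C) or oriented-rectangle sides (larger shifts) accumulated, and
per-feature mean, SE, Student-t 95% CI and one-sample t-test reported; the
template is built from the means rounded to whole pixels.

The NCC acceptance threshold and the rotation step are not calibrated
quantities; 0.5 and 15° are package defaults, chosen so that a planted
elliptical hen rotated up to half a grid step from the nearest angle still
scores far above threshold (typically > 0.85), while compact non-hen
blobs of comparable area (discs, bars, patches) stay well below
(≤ ≈ 0.35). Both are configuration-exposed and echoed in every log record.

## Numerical choices

* **Equivalent ellipse.** Axis lengths are $4\sqrt{\lambda_{1,2}}$ of the
  pixel-coordinate covariance matrix, with a $+1/12$ unit-square variance
  correction so that degenerate one-pixel-wide components keep a positive
  minor axis. For rasterized ellipses with axes in [10, 150] px under
  arbitrary rotation the recovered axes stay within 5% of truth (verified
  by simulation before freezing the tolerance).
* **Oriented rectangle.** The bounding extent of a component along its
  principal axes (max − min + 1 per axis) — a bounding-box reading of
  "long and short side", not the moments-equivalent rectangle.
* **Connectivity.** 8-connected components throughout, so diagonal blob
  boundaries are not split (implemented in compiled code; the interface's
  own labeling routine is 4-connected).
* **NCC implementation.** The cross term is computed by FFT and the
  window statistics by integral images, giving exact-to-rounding
  agreement (≤ 10⁻⁸ observed ≈ 10⁻¹³) with a direct per-window
  evaluation at a fraction of the cost; the raw correlation primitive is
  direct summation in C++ and is tested against a quadruple-loop oracle
  for exact integer equality. Ties in the rotation/placement search break
  toward the lowest angle, then the lowest (row, col), so matching is
  deterministic.
* **Rounding.** Reported percentages round half away from zero to one
  decimal; calibrated template dimensions round to the nearest pixel.
  Full precision is kept internally.
* **Degenerate inputs.** Constant templates are rejected (undefined NCC);
  constant image windows score 0; a blank mask yields `found = FALSE`
  with score 0; empty frame sources produce a valid header-only log;
  frames that fail to decode mark their slot with an error flag and the
  run continues.

## The synthetic scene generator

No thermographic recordings are distributed with the package, so every
claim about the detector is exercised on synthetic scenes
(`sceneConfig()`), built to emulate the documented study conditions:

* floor at 8 °C (the field average; the operating range 5–13 °C is covered
  by tests), with independent per-pixel Gaussian noise of 0.04 °C — the
  camera's sensitivity figure;
* hens as rotated filled ellipses with mean axes 135 × 63 px (per-hen
  jitter SD 4 px), body contrast drawn uniformly from 1–4 °C above the
  floor, with a 12 px-radius head disc 1 °C hotter than the body placed
  inside one end of the body ellipse. This reproduces the two observed
  regimes: at a 1 °C shift the whole body binarizes; at 3 °C only the
  head survives;
* artifacts per frame: foot imprints (two +0.5 °C discs, radius 3–5 px,
  probability 0.10), an egg laid on the floor (radius 8–12 px at hen body
  temperature, probability 0.05), and a warm floor patch (+1.5 °C, radius
  8–16 px, probability 0.05). Rates are modelling choices — residual-heat
  marks are occasional, not dominant — and each class is individually
  switchable;
* optionally a per-sequence constant temperature offset (SD 2 °C),
  emulating absolute-accuracy error; the relative thresholding makes
  detections invariant to it, which the tests assert.

Rendering is deterministic in `(seed, slot)`: every slot draws from its own
derived stream, so any frame of a long sequence can be regenerated in
isolation, bit-identically.

**What passing synthetic tests does and does not show.** The generator
produces ideal ellipse-plus-disc bodies on a stationary flat floor. It
omits feather-texture gradients, partial occlusion and contact between
birds, motion blur, perspective distortion at the frame edge, reflections
and emissivity effects, and any behavioural correlation between slots.
Accuracy measured on it (the 1000-slot benchmark: sensitivity and
specificity both above 95%) validates the *pipeline logic and its
thresholds under the modelled conditions*; it is not a field-accuracy
claim. The residual misses in the benchmark are informative nonetheless:
they are hens whose body contrast falls within about 0.1 °C of the 1 °C
shift, where binarization catches only noise-scattered fragments — the
same marginal-contrast failure mode described for the physical sensor.

## Design decisions in open territory

* **Matching on the binary mask, not the grey frame.** The pipeline order
  puts pattern recognition after binarization; matching the mask makes
  the match score independent of the hen's absolute contrast and lets one
  template serve all shifts.
* **Valid-mode placements only.** Windows that extend past the frame edge
  have ill-defined statistics; hens at the edge are covered by the CP
  fallback instead.
* **Largest-particle rule in calibration.** In a controlled single-hen
  frame the hen is assumed to be the biggest warm object; smaller
  particles are artifacts. Calibration scenes in the tests use a clearly
  visible body contrast (2.5 °C), emulating the controlled set-up in
  which such data are collected — geometry calibration at marginal
  contrast is not meaningful, because the measured particle is then a
  noise-fragmented subset of the body.
* **Triangle pose.** Isosceles, apex up, base at the bottom; the rotation
  search makes the choice immaterial to matching.
* **Frame storage.** 8-bit grey PNG and uncompressed 8-bit BMP, with the
  calibration supplied in configuration rather than embedded in files; a
  `YYYYMMDD-HHMMSS` filename pattern carries timestamps.
* **Problem sizes in the checks.** The benchmark uses 1000 slots at 50%
  occupancy, calibration recovery uses 3 × 50 frames, and oracle
  comparisons use 100 random 16 × 16 / 5 × 5 cases — sizes at which the
  binomial noise on a 95% rate is about ±1.5 percentage points, small
  against the margins being asserted.

## Known limitations

* One scalar floor temperature per frame: spatially varying backgrounds
  (sunlit patches, heated equipment) are not modelled — a warm patch
  larger than the CPT would be a false positive.
* No scale search: a template of fixed size cannot follow chicks, other
  breeds, or camera-height changes without re-calibration.
* One detection suffices: the sensor reports presence, not a count or
  positions of multiple hens.
* The decision is per-slot with no temporal smoothing; a hen crossing a
  slot boundary is simply detected in both slots.
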