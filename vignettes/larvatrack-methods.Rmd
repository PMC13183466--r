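---
title: "Quantifying optogenetically evoked larval contraction and fatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying optogenetically evoked larval contraction and fatigue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvatrack)
```

## The assay and what the package computes

In the motor-performance assay this package analyzes, a third-instar
*Drosophila* larva expressing channelrhodopsin-2 in its motor neurons crawls
freely on an agar plate while blue LEDs drive cyclic body-wall contraction: a
10 s unstimulated baseline, then 2 s of illumination alternating with 1 s of
rest for 20 minutes. A monochrome camera records the scene at 10 frames per
second through a long-pass filter that blocks the blue light; a small red
indicator LED inside the field of view mirrors the stimulus state so that
each frame can be labelled on/off after the fact.

The measurement of interest is the larva's outline perimeter. Contraction
shortens the body, so the perimeter drops while the stimulus is on and
recovers while it is off; of the available blob measurements (area,
perimeter, centroid displacement) the perimeter tracks contraction most
reliably and is least disturbed by rearing. The package converts a recording
into:

1. a per-frame binary mask of the larva (`segment_frame()`),
2. a per-frame perimeter/area/centroid trace (`track_single()`),
3. a per-frame stimulus state decoded from the indicator ROI
   (`decode_led_status()`),
4. a normalized perimeter trace (`normalize_trace()`), and
5. per-cycle contraction metrics and fatigue statistics (`cycle_metrics()`,
   `fatigue_comparison()`, `two_group_test()`).

A companion module quantifies presynaptic mitochondrial content from
two-channel fluorescence stacks (`mitochondrial_content()`), and a phantom
generator (`render_phantom()`, `render_bouton_pair()`) produces synthetic
inputs with analytic ground truth so that every stage can be validated
without recorded animals.

## Segmentation

The segmentation chain is deliberately plain, mirroring a standard
ImageJ-style recipe, with the published defaults:

* **Gaussian blur**, radius 1. Image tools disagree about what "radius"
  means; here the kernel standard deviation equals the radius
  (`sigma = radius`), stated once and fixed. Radius 0 disables the step.
* **Rolling-ball background subtraction**, radius 50 px. Implemented as a
  grayscale morphological opening with a flat disc structuring element; for
  the default dark-larva polarity the opening is applied to the photometric
  inverse (equivalently, a closing of the original), so the larva survives
  as a bright residual. Filter windows are clamped to the frame, so borders
  are not dragged toward zero; on a pure illumination ramp the residual is
  zero away from an edge band of the ball radius. We do not attempt
  bit-for-bit parity with ImageJ's sliding-paraboloid refinement; the
  morphological definition is the documented behavior and the test oracle.
* **Otsu threshold** on a 256-bin histogram regardless of input bit depth
  (wider ranges are scaled onto the bins and the threshold mapped back);
  ties are broken toward the lowest maximizing threshold. Because the
  residual after background subtraction is object-bright in both polarities,
  the final binarization always keeps the bright class. The threshold is
  computed per frame by default; a config flag freezes the first frame's
  threshold instead, since neither mode is canonical and recordings vary in
  illumination stability.

A frame that contains no object after background subtraction (a constant
residual) yields an empty mask rather than an error; the tracker marks such
frames invalid.

## Tracking and the perimeter estimator

Masks are labelled with 8-connectivity — a strongly contracted larva can thin
to diagonal pixel runs that 4-connectivity would fragment. Per frame, the
components inside the area gates are candidates; the tracked object is the
candidate nearest the previous valid centroid (largest candidate on the
first valid frame), and a nearest candidate farther than `max_jump` marks
the frame invalid rather than letting the track teleport. Invalid frames
carry missing values, never zeros, and `step_distance` bridges them from the
last valid centroid.

The perimeter estimator traces the outer contour (Moore-neighbor tracing
with Jacob's stopping criterion) and sums chain steps with the corrected
weights 0.948 per orthogonal and 1.340 per diagonal step. The naive
1/&radic;2 weighting systematically overestimates digitized smooth contours
— on digital disks of radius 10–50 it runs about 5% above 2&pi;r, which
would swamp contraction amplitudes of a few percent — while the corrected
weights keep the error below 1%. Conventions worth knowing: an axis-aligned
w&times;h rectangle measures 0.948(2(w+h)&minus;4); a one-pixel-wide arm is
traversed on both sides and counts twice; an isolated pixel returns the
fixed constant 1. Accuracy is asserted against analytic shapes, not against
any particular tracker plugin whose internals are unpublished.

## Stimulus decoding and the cycle grid

The indicator-ROI mean is averaged per frame; a frame is "on" when the mean
strictly exceeds the threshold (a boundary value counts as off — arbitrary
but fixed). Auto-thresholding clusters the trace into two plateaus with a
deterministic 1-D two-means (centers seeded at the extremes) and takes the
plateau midpoint; it refuses traces whose plateau separation is less than
four within-plateau standard deviations, the signature of an indicator that
never blinked, and asks for a manual threshold.

The protocol's cycle grid places cycle *k* at
`[delay + (k-1)(on+off), delay + k(on+off))`, split into on- then
off-window; only complete cycles count. The default protocol is 10 s delay
plus 1200 s of stimulation (total 1210 s), which yields exactly 400 complete
2 s/1 s cycles, so "the last 10 cycles" are 391–400. Because the delay is
program-side while the video starts asynchronously, `align_status()`
measures the lag between the nominal first on-time and the first decoded
on-frame and shifts the grid by it (a flag disables the compensation); a lag
exceeding one full cycle is treated as a protocol/video mismatch. Frame
timestamps are `frame / fps` with frame 0 at *t* = 0, windows are half-open
so every frame belongs to exactly one window, and the nominal 10 fps can be
overridden with a measured rate.

Two scalar conveniences expose the protocol arithmetic: `duty_cycle()`
(2 s/1 s &rarr; 66.67%, reported as 67) and `metabolic_load()`, the assay
duty cycle relative to the ~78% endogenous duty cycle of larval motor
neurons during fictive locomotion (67/78 &rarr; 86%).

## Normalization and cycle metrics

The baseline is the mean perimeter over the 2 s immediately before the first
decoded illumination; the whole trace is divided by that window **mean**
(dividing by per-frame window values would be the other reading of
"divided by the 0–2 s window values"; the window-mean reading is the one
consistent with describing traces as "normalized to the average perimeter
value" and is what is implemented). Scale invariance is exact: multiplying a
raw trace by any positive constant leaves everything downstream unchanged.

Per cycle, `rest_value` is the mean normalized perimeter over the trailing
half of the *preceding* off-window — the off phase is when the larva
relaxes, and no published per-cycle "rest" definition exists, so the window
fraction is a documented knob (default 0.5); cycle 1 uses the pre-stimulus
baseline, i.e. rest 1.0. "Maximum contraction" is the *minimum* normalized
perimeter within the on-window, making amplitudes positive for contracting
larvae. Missing frames are linearly interpolated only inside cycle windows
and only across gaps of at most 3 frames; longer gaps flag the cycle rather
than invent data. Fatigue is summarized per animal as the mean amplitude of
the first *k* versus the final *k* complete cycles (*k* = 3 by default), and
groups are compared with a two-sided, equal-variance Student's t-test on the
per-animal values (Welch behind a flag; per-animal rather than pooled,
matching a reading in which each point in a group comparison is one larva).
Zero-variance degenerate inputs are handled explicitly: equal constant
groups give p = 1, a constant shift gives the p &rarr; 0 limit clamped to
the smallest positive double.

## The phantom generator

`render_phantom()` emulates the recording geometry rather than larval
biology: a dark ellipse (default semi-axes 30 &times; 10 px, intensity 60)
on a brighter background (180) with a linear 20-gray-level shading, a
blinking indicator dot, optional centroid drift, and additive Gaussian noise
clipped to the 8-bit range. The major axis relaxes exponentially toward
`a0(1 - contraction_fraction)` while the stimulus is on and back toward `a0`
while off; the paper-style response is immediate and sustained, but no
functional form is published, so the time constant is an explicit parameter
(default 0.2 s). An optional `contraction_decline` scales the contraction
down linearly over the protocol's cycles to emulate fatigue. Ground truth
uses Ramanujan's second approximation for the ellipse perimeter, whose error
is orders of magnitude below pixel-level tolerances. All randomness flows
through the single seed, so an identical spec renders a bit-identical video.

What the phantom does **not** emulate — and therefore what passing tests do
not show about real data: peristaltic waves and posture changes (the body is
always a perfect ellipse), rearing, occlusions, reflections, camera gain
drift, and multi-animal scenes. The phantom validates the pipeline's
arithmetic, not its robustness to every behavior of a real larva; the
published recipe itself notes that segmentation parameters must be tuned per
recording.

`render_bouton_pair()` plays the same role for the mitochondrial module:
disk-shaped boutons over a uniform background in two registered channels,
with above-background intensities `cyto_level` and `mito_level`, so the
programmed content ratio `mito/cyto` is known exactly. Stacks carry three
identical pre-noise slices (confocal series in this preparation span 3–5
sections) so the average projection is exercised.

## Mitochondrial content

Multi-slice stacks are collapsed by average projection. Fluorescence is
measured as (mean over the union of bouton-ROI pixels) minus (mean over
background ROIs placed adjacent to the terminal), per channel, and content
is the mitochondrial over cytosolic background-subtracted ratio — invariant
to any gain applied equally to both channels. Pixel membership in polygon
ROIs follows the center-point, even-odd rule. Pooling bouton ROIs as a pixel
union is the default (the published description is ambiguous between
pooling and per-ROI averaging; the alternative sits behind `per_roi =
TRUE`). Avoiding fluorescent aggregates is the user's responsibility via ROI
placement. `percent_reduction()` compares group mean contents as
`100(1 - test/control)`.

## Problem sizes used in the tests

The validation suite chooses sizes that keep the full suite around a minute
while still exercising every code path: module tests use 64&times;96-px
phantoms with a 21 s protocol and a 20-px rolling ball; the end-to-end
amplitude-recovery check runs the full image pipeline on 60 s, 600-frame
phantoms at the published 120&times;160-ish scale with the 50-px ball, both
noiseless and at 5 gray levels of noise. The fatigue-power analysis (ten
stable versus nine declining animals, 50 cycles, 100 replicates) runs on
analytic truth traces with 0.5 px of measurement jitter and 10% inter-animal
variability in contraction fraction — rendering 1,900 videos would test the
renderer, not the statistics, and the rendered path is already covered by
the amplitude-recovery check. Between-animal variability (CV 10%) and the
30% programmed decline were fixed when the generator was written.

## Numerical conventions and edge cases

* Frame indices are 0-based in all outputs (ImageJ-style tools are 1-based);
  times are seconds at 3 decimals in CSVs.
* Grayscale conversion of RGB input uses Rec. 601 luminance weights.
* Otsu on a constant image is an error; `segment_frame()` converts the
  specific case "nothing left after background subtraction" into an empty
  mask instead.
* The rolling ball must fit inside the frame; a larger ball errors.
* An all-invalid tracking sequence warns and returns an all-invalid trace.
* `write_pipeline_config()` / `read_pipeline_config()` round-trip the full
  configuration through YAML losslessly; the run log records the package
  version, an md5 of the serialized config, and the seed.

## Known limitations

Single-animal tracking only — no identity management when larvae touch or
multiple animals are present. No skeleton or midline analysis, so rearing is
neither detected nor modeled. AVI containers are not read directly; videos
are exchanged as numbered PNG/TIFF frame directories. The rolling-ball step
is a morphological opening, not ImageJ's paraboloid variant, so tuned
ImageJ thresholds may not transfer exactly. Statistics stop at the two-group
t-test; multiple-genotype corrections and mixed models are out of scope.
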