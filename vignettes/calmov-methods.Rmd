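---
title: "Methods: how calmov processes calcium imaging movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how calmov processes calcium imaging movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calmov)
```

calmov is a pipeline for extracting cellular activity from single-plane
functional imaging recordings: nuclear-localized calcium indicators give
well-separated, roughly circular objects whose mean intensity tracks
intracellular calcium, and the package's job is to go from a raw movie to
per-cell ΔF/F traces, ternary event flags and stimulus-response classes.
This vignette explains each stage's model, its assumptions, the tunable
parameters, and the design decisions taken where the problem admitted
several reasonable answers.

## Coordinates and containers

All pixel coordinates are 0-based with x = column (rightward) and y = row
(downward), origin at the top-left — the convention of ImageJ, whose `.roi`
and `.zip` files are the package's ROI interchange format. Pixel `(x, y)`
occupies the unit square `[x, x+1] × [y, y+1]`; a pixel belongs to a region
when its *centre* `(x + 0.5, y + 0.5)` lies inside (even-odd rule for
polygons). Boundary-tracing of label masks emits vertices on pixel corners,
so rasterizing a traced polygon recovers the original pixel set exactly for
hole-free 4-connected labels; holes inside a label are ignored (nuclei are
convex-ish — a documented limitation).

Stacks are `[row, col, frame]` double arrays with a declared storage dtype
(`uint8`, `uint16`, `float32`). TIFF reading goes through the `tiff`
package; writing uses the package's own minimal baseline-TIFF writer
(little-endian, uncompressed, one strip per page) because ΔF/F stacks
contain negative float values, which must round-trip bit-exactly.

## Rigid motion correction

The model is a per-frame integer translation against a *fixed* reference
frame. Fixed-reference matching (rather than frame-to-previous-frame) avoids
accumulation of small errors into drift over a recording; the cost is that
the scene must stay recognisably similar to the reference, which holds for
the minutes-long single-plane recordings this package targets.

The similarity metric is the normalized (zero-mean, unit-norm)
cross-correlation between a template — by default the central 50% of the
reference frame — and the correspondingly offset window of each frame,
searched exhaustively over offsets within `max_shift` (default 20 px) whose
window stays inside the frame. NCC is invariant to affine intensity changes,
so slow bleaching does not bias the match. Ties are broken deterministically
(smallest `|dx| + |dy|`, then smallest `dy`, then `dx`) so results are
reproducible across platforms. Only integer shifts are estimated and applied
(no subpixel interpolation, rotation or scaling): values are moved, never
resampled, so ΔF/F statistics are untouched. Exposed borders are filled with
a constant (default 0) rather than wrapped or reflected, so baseline windows
are never contaminated by content from the opposite edge; ROIs hugging the
border of a jittery recording are the user's responsibility.

## Cell detection

`segment_stack_to_rois()` composes four steps:

* **Projection** (`sum` by default, also `max`/`mean`) collapses time;
  sums are held in doubles so they cannot overflow.
* **Rolling-ball background subtraction** (default radius 20 px) estimates
  the smooth background as the grayscale opening of the image with a
  non-flat, spherical-cap structuring element (the classic rolling-ball
  formulation) and subtracts it, clipping at 0. A flat image maps to zeros;
  a gentle intensity ramp is removed up to a curvature-limited residual of
  about `radius × slope² / 2`. Borders use edge replication.
* **Threshold**: Otsu on the image's own range by default, or a fixed value.
* **Watershed split + area filter**: when enabled (default), touching
  objects are split by marker-based watershed on the Euclidean distance
  transform. Seeds are local maxima of the distance map, greedily thinned to
  a minimum separation of `sqrt(min_area / π)` (strongest first, raster
  order on ties) — the seeding rule is fixed here purely for determinism,
  since any reasonable variant works on nucleus-like blobs. Components with
  area outside `[min_area, max_area]` (defaults 20 and 400 px²) are
  discarded, and surviving labels are renumbered in raster order of their
  first pixel, making the whole stage deterministic.

Learned segmenters are deliberately not reimplemented: any external tool
that produces a label image enters the pipeline through
`label_mask_to_rois()`, which converts each label into a polygon ROI by
boundary tracing. Default area bounds and the Otsu default are package
choices; recordings with very large somata or dim nuclei will need them
adjusted.

## ΔF/F and traces

ΔF/F is computed **per pixel** before any ROI averaging:
`F0(p)` is the mean (optionally median) of pixel `p` over a user-defined
baseline window, and the output is `(F − F0) / max(F0, ε)` as a float32
stack. The floor `ε` (default `10⁻⁶ × max(stack)`) exists because background
subtraction produces exact zeros in `F0`; it keeps the division finite while
scaling with the data, which also preserves the transform's invariance to
multiplying the whole stack by a positive constant. The pipeline order is
pinned as convert-then-extract (the image is converted, then ROI means are
taken); the reverse order gives different numbers whenever `F0` varies
across a ROI's pixels, and a regression test fixes the chosen order.

ROI traces are the arithmetic mean over the ROI's interior pixels per frame.
Replicate acquisitions of the same field are averaged elementwise
(`average_replicates()`), requiring identical ROI sets and provenance
labels. Smoothing is a truncated (±4σ) normalized Gaussian kernel with
symmetric (reflect) padding; σ is in frames, default 1 — strong enough to
suppress shot-like noise at ~1 Hz sampling while blurring minute-scale
transients negligibly. σ = 0 disables smoothing exactly.

## Event detection

The detector maintains a *filtered* copy of the trace, initialised to the
first `lag` samples. For each later frame, with μ and σ the mean and
**population** SD (divide by `lag`; the choice shifts borderline flags and
is therefore fixed and documented) of the filtered values over the trailing
`lag` frames:

* if `|x_t − μ| > threshold × σ`, the frame is flagged `sign(x_t − μ)` and
  the filtered value becomes
  `influence × x_t + (1 − influence) × filtered[t−1]`;
* otherwise the flag is 0 and the filtered value is `x_t`.

A zero-σ window with `x_t ≠ μ` flags by sign. The first `lag` frames are
defined as 0 rather than NA so exports stay numeric. `influence` (default
0.5) controls how much flagged excursions contaminate the running
statistics: 0 freezes them during an event, 1 reduces the detector to a
plain rolling z-score. The exact update rule above is the package's
normative definition, and the test suite holds the implementation equal to
an independently written reference implementation of the same rule on a
thousand random traces.

Epoch classification scores the flags inside
`[epoch_start, epoch_start + response_window)` (default: the whole epoch)
against either `k` consecutive matching-direction flags — `k = 3` for the
minute-scale light protocol — or at least `k` matching flags within any
`m`-frame window (`2` of `5` for brief pulse stimuli). ROIs are then
labelled `OFF`, `ON`, `OFF_ON` or `NONE` by their responsiveness to the
designated light-extinction and light-return epochs.

## The synthetic generator, and what passing tests mean

`render_movie()` renders each cell as a 2-D Gaussian spot (σ = radius/2)
whose brightness follows a simulated trace: baseline 1 plus a
double-exponential transient `(1 − e^{−t/rise}) · e^{−t/decay}`, rescaled to
unit peak, at each class-appropriate epoch onset, so `amplitude` is the peak
ΔF/F of the transient. Defaults — rise 1 frame, decay 15 frames at 1 Hz-like
sampling — give a time-to-peak of ~2.8 frames, matching the sub-second-to-
seconds onset and multi-second decay of fast nuclear calcium indicators.
Movies add a single global integer shift per frame (matching the rigid model
being tested) and white Gaussian pixel noise (default SD 5 counts = 10% of
the default transient amplitude of 50 counts). Default trace-level
conditions are amplitude 0.5 against noise SD 0.1, i.e. events at five times
the noise floor.

The generator intentionally omits photobleaching, neuropil contamination,
Poisson shot noise, scanning artifacts and non-rigid deformation. Passing
the recovery tests therefore demonstrates that the algorithms are
implemented correctly and behave as designed under their stated model — not
that the defaults are optimal for any particular microscope; real recordings
with strong bleaching need detrending upstream, and non-rigid motion is out
of scope.

Recovery benchmarks run the *full* processing path, including the default
σ = 1 smoothing before detection, because detection is specified to operate
on smoothed data. Two numerical consequences are worth knowing. First,
without smoothing, a single sub-threshold frame during a transient inserts
the full transient value into the detector's window (non-flagged samples
enter at full weight), inflating the window SD and often breaking the
3-consecutive run — raw-trace recovery drops to roughly 75% at the 5×-noise
operating point. Second, smoothing correlates neighbouring noise samples,
so spurious 3-consecutive runs become the dominant error mode for
non-responsive traces; at σ = 1 their rate is 2–4%, which is why the NONE
class sits closest to the 95% recovery bound while the responsive classes
sit at 97–100%.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale problem sizes
chosen as the package's own benchmark conditions: 1000 random traces of
length 300 for the detector-equivalence check; a 64×64 × 100-frame movie
with shifts in ±5 for motion recovery; 200 traces per class for
classification recovery; 100 planted disks at SNR 5 on a 300×300 field for
segmentation; 500 random fixtures for format round-trips; and a
96×96 × 180-frame, 12-cell movie for the end-to-end determinism check.
Everything is seeded; rendered movies, traces and exports are bit-identical
across runs with the same seed, and the CSV writers serialize doubles with
`%.17g` so export → read → export reproduces files byte-for-byte.

Other fixed numerical choices: ImageJ ROI files are written in the classic
integer-coordinate layout (fractional vertices are rounded on write; the
package's own contour tracer only emits integers); Otsu thresholds are
computed on the image rescaled to its own range with 256 levels; the NCC
denominator treats zero-variance windows as score 0; and `estimate_shifts`
forces no shift for the reference frame only through the tie-break order,
not by special-casing.

## Known limitations

Single-plane recordings only (no volumetric registration or 3-D
segmentation); integer-pixel rigid motion only; no bleach detrending,
neuropil decontamination or spike deconvolution; ROI groups are decided by
centroid containment, not area overlap, which can misassign a sprawling ROI
whose centroid falls outside the drawn polygon; and the ImageJ ROI reader
supports the polygon, rectangle, oval and point subtypes, rejecting
composite and line ROIs with their subtype code.
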