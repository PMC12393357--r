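# calmov

Scriptable analysis of single-plane calcium imaging movies — the kind of
recording produced by nuclear-localized GCaMP in larval zebrafish, cytosolic
GCaMP in *Drosophila* antennal lobes, or GCaMP6s in mouse visual cortex. The
package turns a raw multipage TIFF into per-cell ΔF/F traces, ternary event
flags and stimulus-response classes, entirely from R (or a thin command-line
front end), with ImageJ-compatible ROI files at the interchange points.

## What it computes

Given a time series of frames `F(t, p)` the pipeline performs:

1. **Rigid motion correction.** Each frame's integer shift `(dx, dy)` is the
   argmax of the normalized cross-correlation between a template cut from a
   fixed reference frame and the correspondingly offset window, searched
   exhaustively within a radius (ties broken toward the smallest shift).
2. **Cell detection.** Intensity projection across frames (sum by default),
   rolling-ball background subtraction (grayscale opening with a spherical
   structuring element, default radius 20 px), binary threshold (Otsu by
   default), marker-based watershed on the distance transform to split
   touching nuclei, and an object-area filter. External segmenters (e.g.
   learned models) can be plugged in through a label-mask adapter
   (`label_mask_to_rois()`) instead.
3. **ΔF/F conversion, per pixel.** With `F0(p)` the mean of pixel `p` over a
   user-defined baseline window,
   `ΔF/F(t, p) = (F(t, p) − F0(p)) / max(F0(p), ε)`,
   written as a 32-bit float stack. Traces are then the mean ΔF/F over each
   ROI's pixels, optionally averaged across replicate acquisitions and
   smoothed with a truncated Gaussian kernel.
4. **Peak detection.** A sliding-window z-score detector: for each frame past
   a trailing window of `lag` frames, a deviation of more than
   `threshold × SD(window)` from the window mean flags the frame `+1`
   (significant increase) or `−1` (significant decrease), else `0`; flagged
   samples update the running window only with weight `influence`. Typical
   operating point: `lag = 30`, `threshold = 3`.
5. **Response classification.** A ROI is responsive in a stimulus epoch if
   its flags satisfy a criterion within the epoch — `k` consecutive matching
   flags (`k = 3` for minute-scale light steps) or `k` of any `m` frames
   (`2` of `5` for brief acoustic pulses) — and is labelled
   `OFF` / `ON` / `OFF_ON` / `NONE` by its responsiveness to the
   light-extinction and light-return epochs.
6. **Export.** Two CSV files per recording (signal = ΔF/F, peaks = −1/0/1)
   with columns `Name, ROI, X, Y, Groups, Filter, Detection.Method,
   F1 … Fn`; numbers are serialized with full round-trip precision so the
   files are byte-stable.

A seeded synthetic-movie generator (`scene_spec()`, `render_movie()`) renders
Gaussian-spot cells with double-exponential stimulus-locked transients, rigid
jitter and additive noise, and returns the ground truth alongside — every
stage above is testable against planted truth without microscopy data.

## Worked example

```r
library(calmov)

# a 3-minute, 1 Hz light ON/OFF/ON assay with 12 planted cells
sim <- render_movie(scene_preset("visual", seed = 7, n_cells = 12,
                                 field = c(96, 96)))
sim$stack
#> <calmov_stack 'synthetic': 180 frame(s) of 96x96, float32>

res <- register(sim$stack, registration_params(max_shift = 6))
head(res$shifts, 3)
#>   frame dx dy     score
#> 1     1  0  0 1.0000000
#> 2     2 -1  2 0.7733402
#> 3     3  0  1 0.7893771

rois <- segment_stack_to_rois(res$stack,
                              segmentation_params(min_area = 8, max_area = 300))
length(rois)
#> [1] 12

dff    <- convert_stack_to_dff(res$stack, dff_params(1, 60))
traces <- gaussian_smooth(extract_traces(dff, rois), sigma = 1)
peaks  <- detect_peaks_traces(traces, peak_params(lag = 30, threshold = 3,
                                                  influence = 0.5))

epochs <- epoch_set(c("ON1", "OFF", "ON2"), c(1, 61, 121), c(61, 121, 181))
crit   <- response_criteria("consecutive", k = 3, direction = "increase")
types  <- vapply(seq_along(rois), function(i) {
  r <- classify_epoch_response(peaks$flags[i, ], epochs, crit)
  label_response_type(r[["OFF"]], r[["ON2"]])
}, "")
table(types)
#> types
#>   NONE    OFF OFF_ON     ON
#>      3      3      3      3      # matches the planted classes exactly

export_data(cell_manager(rois), traces, peaks, "fish01")
#> writes fish01_signal.csv and fish01_peaks.csv
```

The estimated shifts are the planted jitter; the twelve detected ROIs land on
the twelve planted cells; the recovered response table equals the planted
3/3/3/3 class mix; and the peak ΔF/F of an OFF cell during the OFF epoch is
0.497 against a planted transient amplitude of 0.5.

The same flow is available from a shell via `inst/cli/calmov.R`
(`simulate`, `register`, `segment`, `dff`, `extract`, `smooth`, `detect`,
`classify`, `group`, `export`, and `run` for a whole YAML-configured
pipeline).

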