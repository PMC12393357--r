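# Synthetic nuclear-GCaMP-style movies and traces with ground truth.

RESPONSE_CLASSES <- c("NONE", "OFF", "ON", "OFF_ON")

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# Onset frames for a response class, derived from epoch labels: OFF classes
# fire at the start of every "OFF*" epoch; ON classes at the start of every
# "ON*" epoch that is not the first frame of the recording (the stimulus is
# already on at acquisition start).
class_onsets <- function(class, epochs) {
  off <- epochs$start[startsWith(epochs$label, "OFF")]
  on <- epochs$start[startsWith(epochs$label, "ON") & epochs$start > 1]
  switch(class,
         NONE = integer(0),
         OFF = off,
         ON = on,
         OFF_ON = sort(c(off, on)),
         stop("invalid response class: ", class))
}

# Double-exponential transient normalized to unit peak.
transient_shape <- function(t, rise, decay) {
  s <- (1 - exp(-t / rise)) * exp(-t / decay)
  tpk <- rise * log(1 + decay / rise)
  s / ((1 - exp(-tpk / rise)) * exp(-tpk / decay))
}

#' Simulate a single DF/F-like trace
#'
#' The trace is a constant baseline plus one unit-peak double-exponential
#' transient (`(1 - exp(-t/rise)) * exp(-t/decay)`, rescaled to peak at
#' `amplitude`) at each class-appropriate epoch onset, plus Gaussian noise.
#' Fully reproducible under a fixed seed.
#'
#' @param class `"NONE"`, `"OFF"`, `"ON"` or `"OFF_ON"`.
#' @param epochs an [epoch_set()]; OFF classes fire at `OFF*` epoch starts,
#'   ON classes at non-initial `ON*` epoch starts.
#' @param amplitude transient peak height (default 0.5, i.e. 5x the default
#'   noise SD).
#' @param rise,decay transient time constants in frames (defaults 1 and 15,
#'   nuclear-indicator-like at ~1 Hz sampling).
#' @param noise_sd additive Gaussian noise SD (default 0.1).
#' @param n_frames trace length.
#' @param baseline baseline level (default 1).
#' @param seed optional RNG seed (the caller's RNG state is restored).
#' @return list with `trace` (numeric vector) and `onsets` (event frames).
#' @export
simulate_trace <- function(class, epochs, amplitude = 0.5, rise = 1,
                           decay = 15, noise_sd = 0.1, n_frames,
                           baseline = 1, seed = NULL) {
  class <- match.arg(class, RESPONSE_CLASSES)
  stopifnot(amplitude >= 0, rise > 0, decay > 0, noise_sd >= 0, n_frames >= 1)
  if (max(epochs$end) - 1 > n_frames) stop("epochs extend beyond n_frames")
  onsets <- class_onsets(class, epochs)
  trace <- rep(baseline, n_frames)
  for (o in onsets) {
    t <- seq_len(n_frames) - o
    add <- ifelse(t >= 0, amplitude * transient_shape(pmax(t, 0), rise, decay), 0)
    trace <- trace + add
  }
  if (noise_sd > 0) {
    trace <- trace + with_seed(seed, stats::rnorm(n_frames, 0, noise_sd))
  }
  list(trace = trace, onsets = onsets)
}

#' Synthetic scene specification
#'
#' Describes a field of circular cells rendered as 2-D Gaussian spots
#' (`sigma = radius / 2`) whose brightness follows a simulated per-cell
#' trace, plus per-frame global rigid jitter and additive pixel noise. The
#' seed fully determines the rendered movie.
#'
#' @param field `c(height, width)` in pixels.
#' @param n_cells number of cells.
#' @param radius_range min/max cell radius in pixels.
#' @param min_separation minimum centre-to-centre distance in pixels.
#' @param baseline_intensity resting spot peak intensity (arbitrary counts).
#' @param amplitude transient peak as a multiple of baseline (default 0.5).
#' @param rise,decay transient time constants in frames.
#' @param noise_sd additive pixel noise SD in counts (default 5, i.e. 10
#'   percent of the default transient amplitude in counts).
#' @param jitter maximum absolute per-frame rigid shift in pixels.
#' @param epochs an [epoch_set()] defining the stimulus protocol.
#' @param n_frames movie length.
#' @param classes per-cell response classes (recycled to `n_cells`).
#' @param seed RNG seed.
#' @return a list of class `calmov_scenespec`.
#' @export
scene_spec <- function(field = c(128, 128), n_cells = 24,
                       radius_range = c(3, 5), min_separation = 12,
                       baseline_intensity = 100, amplitude = 0.5,
                       rise = 1, decay = 15, noise_sd = 5, jitter = 3,
                       epochs = epoch_set(c("ON1", "OFF", "ON2"),
                                          c(1, 61, 121), c(61, 121, 181)),
                       n_frames = 180,
                       classes = RESPONSE_CLASSES, seed = 1) {
  stopifnot(length(field) == 2, all(field >= 8), n_cells >= 1,
            length(radius_range) == 2, radius_range[1] > 0,
            radius_range[2] >= radius_range[1],
            min_separation >= 0, baseline_intensity > 0, amplitude >= 0,
            noise_sd >= 0, jitter >= 0, n_frames >= 1)
  if (max(epochs$end) - 1 > n_frames) stop("epochs extend beyond n_frames")
  classes <- rep(as.character(classes), length.out = n_cells)
  if (!all(classes %in% RESPONSE_CLASSES))
    stop("classes must be in {", paste(RESPONSE_CLASSES, collapse = ", "), "}")
  structure(list(field = as.integer(field), n_cells = as.integer(n_cells),
                 radius_range = radius_range,
                 min_separation = min_separation,
                 baseline_intensity = baseline_intensity,
                 amplitude = amplitude, rise = rise, decay = decay,
                 noise_sd = noise_sd, jitter = as.integer(jitter),
                 epochs = epochs, n_frames = as.integer(n_frames),
                 classes = classes, seed = seed),
            class = "calmov_scenespec")
}

#' Scene presets
#'
#' `"visual"`: 3-minute, 1 Hz light ON / OFF / ON protocol (one minute per
#' epoch) with a balanced mix of NONE/OFF/ON/OFF_ON cells. `"acoustic"`:
#' five stimulus pulses 30 s apart after a 30 s lead-in; responsive cells
#' fire at every pulse onset.
#'
#' @param name `"visual"` or `"acoustic"`.
#' @param seed RNG seed.
#' @param ... overrides passed to [scene_spec()].
#' @return a [scene_spec()].
#' @export
scene_preset <- function(name = c("visual", "acoustic"), seed = 1, ...) {
  name <- match.arg(name)
  args <- switch(name,
    visual = list(
      epochs = epoch_set(c("ON1", "OFF", "ON2"), c(1, 61, 121),
                         c(61, 121, 181)),
      n_frames = 180, classes = RESPONSE_CLASSES),
    acoustic = list(
      epochs = epoch_set(c("PRE", paste0("ON", 1:5)),
                         c(1, 31, 61, 91, 121, 151),
                         c(31, 61, 91, 121, 151, 181)),
      n_frames = 180, classes = c("ON", "NONE")))
  args$seed <- seed
  do.call(scene_spec, utils::modifyList(args, list(...)))
}

#' Render a synthetic movie with ground truth
#'
#' Cells are placed with rejection sampling under the minimum-separation
#' constraint, rendered as Gaussian spots scaled each frame by their
#' simulated trace, globally shifted by the per-frame jitter (frame 1 is the
#' unshifted reference), and corrupted with additive Gaussian pixel noise.
#'
#' @param spec a [scene_spec()].
#' @return list with `stack` (a float32 [image_stack()]) and `truth`: cell
#'   `centers` (x, y), `radii`, `masks` (per-cell true disc pixels), `shifts`
#'   (per-frame dx, dy), `classes`, `onsets`, `traces` (noise-free per-cell
#'   trace matrix).
#' @export
render_movie <- function(spec) {
  stopifnot(inherits(spec, "calmov_scenespec"))
  with_seed(spec$seed, {
    h <- spec$field[1]; w <- spec$field[2]
    rmax <- spec$radius_range[2]
    # placement
    centers <- matrix(NA_real_, spec$n_cells, 2)
    radii <- numeric(spec$n_cells)
    tries <- 0L
    placed <- 0L
    while (placed < spec$n_cells) {
      tries <- tries + 1L
      if (tries > 200L * spec$n_cells)
        stop("cannot place ", spec$n_cells, " cells with separation ",
             spec$min_separation, " in a ", h, "x", w, " field")
      r <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      cx <- stats::runif(1, rmax + 1, w - rmax - 1)
      cy <- stats::runif(1, rmax + 1, h - rmax - 1)
      if (placed == 0 ||
          all((centers[seq_len(placed), 1] - cx)^2 +
              (centers[seq_len(placed), 2] - cy)^2 >= spec$min_separation^2)) {
        placed <- placed + 1L
        centers[placed, ] <- c(cx, cy)
        radii[placed] <- r
      }
    }
    # per-cell noise-free traces
    traces <- matrix(NA_real_, spec$n_cells, spec$n_frames)
    onsets <- vector("list", spec$n_cells)
    for (i in seq_len(spec$n_cells)) {
      sim <- simulate_trace(spec$classes[i], spec$epochs,
                            amplitude = spec$amplitude, rise = spec$rise,
                            decay = spec$decay, noise_sd = 0,
                            n_frames = spec$n_frames, baseline = 1)
      traces[i, ] <- sim$trace
      onsets[[i]] <- sim$onsets
    }
    # Gaussian spot profile per cell (pixels x cells), and true disc masks
    px_x <- rep(seq_len(w) - 0.5, each = h)   # pixel centres, 0-based coords
    px_y <- rep(seq_len(h) - 0.5, times = w)
    spots <- matrix(0, h * w, spec$n_cells)
    masks <- vector("list", spec$n_cells)
    for (i in seq_len(spec$n_cells)) {
      d2 <- (px_x - centers[i, 1])^2 + (px_y - centers[i, 2])^2
      sg <- radii[i] / 2
      spots[, i] <- spec$baseline_intensity * exp(-d2 / (2 * sg^2))
      inside <- which(d2 <= radii[i]^2)
      masks[[i]] <- cbind(row = (inside - 1L) %% h + 1L,
                          col = (inside - 1L) %/% h + 1L)
    }
    flat <- spots %*% traces  # pixels x frames
    dx <- c(0L, sample(-spec$jitter:spec$jitter, spec$n_frames - 1, TRUE))
    dy <- c(0L, sample(-spec$jitter:spec$jitter, spec$n_frames - 1, TRUE))
    frames <- array(NA_real_, c(h, w, spec$n_frames))
    for (t in seq_len(spec$n_frames)) {
      f <- matrix(flat[, t], h, w)
      if (dx[t] != 0 || dy[t] != 0) f <- translate_matrix(f, dx[t], dy[t], 0)
      frames[, , t] <- f
    }
    if (spec$noise_sd > 0) {
      frames <- frames + stats::rnorm(length(frames), 0, spec$noise_sd)
    }
    stack <- image_stack(frames, name = "synthetic", dtype = "float32")
    truth <- list(centers = centers, radii = radii, masks = masks,
                  shifts = data.frame(frame = seq_len(spec$n_frames),
                                      dx = dx, dy = dy),
                  classes = spec$classes, onsets = onsets, traces = traces)
    list(stack = stack, truth = truth)
  })
}
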