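#' Peak-detector parameters
#'
#' Parameters of the sliding-window z-score detector: a trailing window of
#' `lag` frames supplies the running mean and standard deviation, `threshold`
#' is the significance level in multiples of the window SD, and `influence`
#' in `[0, 1]` is the weight given to flagged samples when updating the
#' running (filtered) copy of the trace — 0 freezes the window statistics
#' during an event, 1 lets events pass straight through.
#'
#' @param lag trailing window length in frames (>= 2; 30 for the 1 Hz visual
#'   assay, 10 or 5 for faster protocols).
#' @param threshold multiple of the window SD (> 0; default 3).
#' @param influence weight in `[0, 1]` applied to flagged samples
#'   (default 0.5).
#' @return a list of class `calmov_peakparams`.
#' @export
peak_params <- function(lag = 30, threshold = 3, influence = 0.5) {
  stopifnot(lag >= 2, threshold > 0, influence >= 0, influence <= 1)
  structure(list(lag = as.integer(lag), threshold = threshold,
                 influence = influence),
            class = "calmov_peakparams")
}

peak_method_label <- function(params) {
  sprintf("sliding_window(lag=%d,threshold=%g,influence=%g)",
          params$lag, params$threshold, params$influence)
}

#' Sliding-window z-score peak detection
#'
#' Maintains a filtered copy of the trace, initialised to the first `lag`
#' samples. For each frame `t` past the window, with `mu` and `sigma` the
#' mean and population SD of the filtered values over the preceding `lag`
#' frames: if `|x_t - mu| > threshold * sigma` the frame is flagged with
#' `sign(x_t - mu)` (+1 significant increase, -1 significant decrease) and
#' the filtered value becomes
#' `influence * x_t + (1 - influence) * filtered[t - 1]`; otherwise the flag
#' is 0 and the filtered value is `x_t`. A zero-SD window with `x_t != mu`
#' flags by sign. The first `lag` frames are defined as 0 (no detection is
#' possible there), keeping exports numeric.
#'
#' @param trace numeric vector, length > `lag`.
#' @param params a [peak_params()].
#' @return an object of class `calmov_peaks`: list with `flags` (integers in
#'   `{-1, 0, 1}`, same length as the trace), `params` and
#'   `detection_method`.
#' @export
detect_peaks <- function(trace, params = peak_params()) {
  stopifnot(inherits(params, "calmov_peakparams"))
  n <- length(trace)
  lag <- params$lag
  if (n <= lag) stop("trace must be longer than lag (need length > ", lag, ")")
  flags <- integer(n)
  filtered <- as.numeric(trace)
  thr <- params$threshold
  infl <- params$influence
  for (t in (lag + 1):n) {
    win <- filtered[(t - lag):(t - 1)]
    mu <- mean(win)
    sigma <- sqrt(max(mean(win * win) - mu * mu, 0))
    dev <- trace[t] - mu
    if (abs(dev) > thr * sigma) {
      flags[t] <- if (dev > 0) 1L else -1L
      filtered[t] <- infl * trace[t] + (1 - infl) * filtered[t - 1]
    } else {
      flags[t] <- 0L
      filtered[t] <- trace[t]
    }
  }
  structure(list(flags = flags, params = params,
                 detection_method = peak_method_label(params)),
            class = "calmov_peaks")
}

#' Detect peaks for every ROI of a trace matrix
#'
#' @param traces a [trace_matrix()].
#' @param params a [peak_params()].
#' @return an object of class `calmov_peakset`: list with `flags` (ROI x
#'   frame integer matrix), `roi_names`, `params`, `detection_method`.
#' @export
detect_peaks_traces <- function(traces, params = peak_params()) {
  stopifnot(inherits(traces, "calmov_traces"))
  flags <- matrix(0L, nrow(traces$values), ncol(traces$values))
  for (i in seq_len(nrow(traces$values))) {
    flags[i, ] <- detect_peaks(traces$values[i, ], params)$flags
  }
  structure(list(flags = flags, roi_names = traces$roi_names, params = params,
                 detection_method = peak_method_label(params)),
            class = "calmov_peakset")
}

#' Stimulus epochs
#'
#' Ordered, non-overlapping half-open frame intervals `[start, end)` (1-based
#' starts), e.g. the 3-minute visual protocol at 1 Hz: light ON frames
#' 1-60, OFF 61-120, ON again 121-180 is
#' `epoch_set(c("ON1", "OFF", "ON2"), c(1, 61, 121), c(61, 121, 181))`.
#'
#' @param label character labels; labels starting with `"OFF"` / `"ON"` mark
#'   light-extinction / light-return (or stimulus-onset) epochs for
#'   classification and simulation.
#' @param start,end 1-based half-open frame bounds, `start < end`.
#' @return a data frame of class `calmov_epochs`.
#' @export
epoch_set <- function(label, start, end) {
  stopifnot(length(label) == length(start), length(start) == length(end),
            all(start >= 1), all(end > start))
  o <- order(start)
  label <- as.character(label)[o]; start <- as.integer(start)[o]
  end <- as.integer(end)[o]
  if (length(start) > 1 && any(start[-1] < end[-length(end)]))
    stop("epochs must not overlap")
  structure(data.frame(label = label, start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("calmov_epochs", "data.frame"))
}

#' Response criteria
#'
#' How flagged frames within an epoch's response window count as a response:
#' either `k` consecutive matching flags (the visual-assay rule with `k = 3`)
#' or at least `k` matching flags within any `m`-frame window (the acoustic
#' rule with `k = 2, m = 5`).
#'
#' @param mode `"consecutive"` or `"k_of_m"`.
#' @param k minimum number of matching flags (>= 1).
#' @param m window length for `"k_of_m"` (>= k).
#' @param direction flags that count: `"increase"` (+1), `"decrease"` (-1),
#'   or `"either"` (any non-zero).
#' @return a list of class `calmov_criteria`.
#' @export
response_criteria <- function(mode = c("consecutive", "k_of_m"), k = 3,
                              m = NULL,
                              direction = c("increase", "decrease", "either")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  stopifnot(k >= 1)
  if (mode == "k_of_m") {
    if (is.null(m)) stop("k_of_m mode needs m")
    stopifnot(m >= k)
    m <- as.integer(m)
  }
  structure(list(mode = mode, k = as.integer(k), m = m,
                 direction = direction),
            class = "calmov_criteria")
}

criteria_match <- function(flags, criteria) {
  switch(criteria$direction,
         increase = flags == 1L,
         decrease = flags == -1L,
         either = flags != 0L)
}

#' Classify per-epoch responsiveness from peak flags
#'
#' An epoch is responsive iff, within
#' `[epoch_start, epoch_start + response_window)`, the flags satisfy the
#' criteria: a run of `k` consecutive matching-direction flags, or at least
#' `k` matching flags in some `m`-frame window.
#'
#' @param peaks a `calmov_peaks` object (or a plain integer flag vector).
#' @param epochs an [epoch_set()].
#' @param criteria a [response_criteria()].
#' @param response_window frames after epoch onset considered; `NULL`
#'   (default) uses the full epoch.
#' @return named logical vector, one element per epoch.
#' @export
classify_epoch_response <- function(peaks, epochs, criteria,
                                    response_window = NULL) {
  flags <- if (inherits(peaks, "calmov_peaks")) peaks$flags else as.integer(peaks)
  if (nrow(epochs) == 0) stop("empty epoch set")
  if (max(epochs$end) - 1 > length(flags))
    stop("epochs extend beyond the trace")
  res <- logical(nrow(epochs))
  for (i in seq_len(nrow(epochs))) {
    s <- epochs$start[i]
    e <- epochs$end[i] - 1L
    if (!is.null(response_window)) e <- min(e, s + response_window - 1L)
    m <- criteria_match(flags[s:e], criteria)
    res[i] <- if (criteria$mode == "consecutive") {
      r <- rle(m)
      any(r$values & r$lengths >= criteria$k)
    } else {
      len <- length(m)
      if (len <= criteria$m) {
        sum(m) >= criteria$k
      } else {
        cs <- cumsum(m)
        sums <- cs[criteria$m:len] - c(0, cs[seq_len(len - criteria$m)])
        any(sums >= criteria$k)
      }
    }
  }
  names(res) <- epochs$label
  res
}

#' Label a ROI's response type from OFF/ON epoch responsiveness
#'
#' @param off_responsive,on_responsive logical (vectorized): responsiveness
#'   of the designated light-extinction (OFF) and light-return (ON) epochs.
#' @return character vector in `{"NONE", "OFF", "ON", "OFF_ON"}`.
#' @export
label_response_type <- function(off_responsive, on_responsive) {
  stopifnot(length(off_responsive) == length(on_responsive))
  ifelse(off_responsive & on_responsive, "OFF_ON",
         ifelse(off_responsive, "OFF",
                ifelse(on_responsive, "ON", "NONE")))
}
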