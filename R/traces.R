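#' DF/F conversion parameters
#'
#' The baseline window is the inclusive 1-based frame range
#' `[baseline_start, baseline_end]`. Per pixel, `F0` is the mean (or median)
#' over the baseline frames and the output is `(F - F0) / max(F0, epsilon)`.
#' The `epsilon` floor keeps the division finite after background
#' subtraction, which creates zero-baseline pixels; it defaults to
#' `1e-6 * max(stack)`.
#'
#' @param baseline_start,baseline_end 1-based inclusive frame indices,
#'   `1 <= start <= end <= n_frames`.
#' @param epsilon positive floor for `F0`, or `NULL` for the default.
#' @param statistic baseline statistic, `"mean"` (default) or `"median"`.
#' @return a list of class `calmov_dffparams`.
#' @export
dff_params <- function(baseline_start, baseline_end, epsilon = NULL,
                       statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  stopifnot(baseline_start >= 1, baseline_end >= baseline_start)
  if (!is.null(epsilon)) stopifnot(epsilon > 0)
  structure(list(baseline_start = as.integer(baseline_start),
                 baseline_end = as.integer(baseline_end),
                 epsilon = epsilon, statistic = statistic),
            class = "calmov_dffparams")
}

#' Convert a stack to per-pixel DF/F
#'
#' Every pixel is normalized to its own baseline: `F0(p)` is the baseline
#' statistic of pixel `p` over the baseline window, and the output frame `t`
#' holds `(F(t, p) - F0(p)) / max(F0(p), epsilon)`. The result is a float32
#' stack; it is invariant to multiplying the input by any positive constant
#' (when `epsilon` scales with the stack, as the default does).
#'
#' @param stack a [image_stack()].
#' @param params a [dff_params()].
#' @return a float32 [image_stack()] of DF/F values.
#' @export
convert_stack_to_dff <- function(stack, params) {
  stopifnot(inherits(stack, "calmov_stack"), inherits(params, "calmov_dffparams"))
  fr <- stack$frames
  h <- dim(fr)[1]; w <- dim(fr)[2]; nf <- dim(fr)[3]
  if (params$baseline_end > nf) stop("baseline window outside stack")
  flat <- matrix(fr, nrow = h * w, ncol = nf)
  bl <- flat[, params$baseline_start:params$baseline_end, drop = FALSE]
  f0 <- if (params$statistic == "mean") rowMeans(bl)
        else apply(bl, 1, stats::median)
  eps <- params$epsilon %||% (1e-6 * max(fr))
  if (eps <= 0) eps <- .Machine$double.eps
  denom <- pmax(f0, eps)
  out <- (flat - f0) / denom
  image_stack(array(out, dim = c(h, w, nf)),
              frame_interval_s = stack$frame_interval_s,
              name = stack$name, dtype = "float32")
}

#' Trace matrix constructor (internal use mostly)
#'
#' Per-ROI, per-frame signal values with processing provenance. Rows follow
#' `roi_names`; `filter` and `detection_method` are always set (defaulting to
#' `"none"`).
#'
#' @param values numeric ROI x frame matrix.
#' @param roi_names character vector, one per row.
#' @param centroids numeric ROI x 2 matrix of (x, y) centroids.
#' @param source_name recording identifier.
#' @param filter,detection_method provenance labels.
#' @return an object of class `calmov_traces`.
#' @export
trace_matrix <- function(values, roi_names, centroids, source_name = "stack",
                         filter = "none", detection_method = "none") {
  values <- rbind(values)
  if (nrow(values) != length(roi_names))
    stop("values rows must match roi_names")
  if (anyNA(values)) stop("trace values must not contain missing values")
  if (anyDuplicated(roi_names)) stop("duplicate ROI names in trace matrix")
  centroids <- rbind(centroids)
  stopifnot(nrow(centroids) == length(roi_names), ncol(centroids) == 2)
  structure(list(values = values, roi_names = roi_names,
                 centroids = centroids, source_name = source_name,
                 filter = filter, detection_method = detection_method),
            class = "calmov_traces")
}

#' @export
print.calmov_traces <- function(x, ...) {
  cat(sprintf("<calmov_traces '%s': %d ROI(s) x %d frame(s), filter=%s, detection=%s>\n",
              x$source_name, nrow(x$values), ncol(x$values), x$filter,
              x$detection_method))
  invisible(x)
}

#' Extract per-ROI traces from a stack
#'
#' The signal of ROI `i` at frame `t` is the mean intensity over the ROI's
#' interior pixels (pixel centres inside the region, see [roi_pixels()]).
#' In the standard pipeline this is applied to the DF/F-converted stack
#' (convert first, then extract).
#'
#' @param stack a [image_stack()].
#' @param rois list of [roi()]s; each must cover at least one in-frame pixel.
#' @return a [trace_matrix()] with `filter = "none"`.
#' @export
extract_traces <- function(stack, rois) {
  stopifnot(inherits(stack, "calmov_stack"), length(rois) > 0)
  fr <- stack$frames
  h <- dim(fr)[1]; w <- dim(fr)[2]; nf <- dim(fr)[3]
  flat <- matrix(fr, nrow = h * w, ncol = nf)
  values <- matrix(NA_real_, length(rois), nf)
  centroids <- matrix(NA_real_, length(rois), 2)
  nms <- character(length(rois))
  for (i in seq_along(rois)) {
    r <- rois[[i]]
    px <- roi_pixels(r, c(h, w))
    if (nrow(px) == 0)
      stop("ROI '", r$name, "' has no pixels inside the frame")
    lin <- (px[, "col"] - 1L) * h + px[, "row"]
    values[i, ] <- colMeans(flat[lin, , drop = FALSE])
    centroids[i, ] <- roi_centroid(r)
    nms[i] <- r$name
  }
  trace_matrix(values, nms, centroids, source_name = stack$name)
}

#' Gaussian smoothing of traces
#'
#' Each trace is convolved with a normalized Gaussian kernel truncated at
#' `+/- 4 sigma`, with symmetric (reflect, edge repeated) padding at the
#' ends. `sigma = 0` is the identity. The trace matrix's filter label is
#' updated to `"gaussian(<sigma>)"`.
#'
#' @param traces a [trace_matrix()].
#' @param sigma kernel standard deviation in frames (>= 0; default 1).
#' @return a smoothed [trace_matrix()].
#' @export
gaussian_smooth <- function(traces, sigma = 1) {
  stopifnot(inherits(traces, "calmov_traces"))
  if (sigma < 0) stop("sigma must be >= 0")
  out <- traces
  out$filter <- sprintf("gaussian(%g)", sigma)
  if (sigma == 0) return(out)
  r <- as.integer(ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- ncol(traces$values)
  idx <- reflect_index((1 - r):(n + r), n)
  for (i in seq_len(nrow(traces$values))) {
    padded <- traces$values[i, idx]
    sm <- stats::filter(padded, k, sides = 2)
    out$values[i, ] <- as.numeric(sm[(r + 1):(r + n)])
  }
  out
}

#' Average replicate acquisitions
#'
#' Elementwise mean of several trace matrices from repeated acquisitions of
#' the same field (e.g. two recordings per animal averaged before export).
#' All matrices must share ROI names (same order), frame count and
#' provenance labels.
#'
#' @param traces_list list of [trace_matrix()] objects.
#' @return a [trace_matrix()] with `source_name` joined by `"+"`.
#' @export
average_replicates <- function(traces_list) {
  stopifnot(length(traces_list) >= 1)
  first <- traces_list[[1]]
  for (tr in traces_list[-1]) {
    if (!identical(tr$roi_names, first$roi_names))
      stop("replicates disagree in ROI names or order")
    if (ncol(tr$values) != ncol(first$values))
      stop("replicates disagree in frame count")
    if (!identical(tr$filter, first$filter) ||
        !identical(tr$detection_method, first$detection_method))
      stop("replicates carry mixed provenance labels")
  }
  vals <- Reduce(`+`, lapply(traces_list, function(tr) tr$values)) /
    length(traces_list)
  cents <- Reduce(`+`, lapply(traces_list, function(tr) tr$centroids)) /
    length(traces_list)
  trace_matrix(vals, first$roi_names, cents,
               source_name = paste(vapply(traces_list, function(tr)
                 tr$source_name, ""), collapse = "+"),
               filter = first$filter,
               detection_method = first$detection_method)
}
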