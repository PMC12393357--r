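#' Image stack container
#'
#' An image stack is a time-ordered sequence of single-channel 2-D frames with
#' a common height and width, stored as a 3-D numeric array indexed
#' `[row, col, frame]`. Pixel coordinates used throughout the package are
#' 0-based with x = column (rightward) and y = row (downward), matching the
#' ImageJ pixel convention; pixel `(x, y)` occupies the unit square
#' `[x, x + 1] x [y, y + 1]` and its centre is at `(x + 0.5, y + 0.5)`.
#'
#' @param frames a 3-D numeric array `[row, col, frame]`, a single matrix, or
#'   a list of equally sized matrices.
#' @param frame_interval_s optional seconds per frame (> 0).
#' @param name source identifier carried into trace provenance and exports.
#' @param dtype storage type used when the stack is written to disk: one of
#'   `"uint8"`, `"uint16"`, `"float32"`. Guessed from the values if omitted.
#' @return an object of class `calmov_stack` with fields `frames`,
#'   `frame_interval_s`, `name`, `dtype`.
#' @export
image_stack <- function(frames, frame_interval_s = NULL, name = "stack",
                        dtype = NULL) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) stop("all frames must share one (height, width)")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3)
    stop("frames must be a [row, col, frame] array")
  if (any(dim(frames) < 1)) stop("stack must have n_frames >= 1 and height, width >= 1")
  if (!is.numeric(frames)) stop("frames must be numeric")
  if (anyNA(frames)) stop("frames must not contain missing values")
  if (!is.null(frame_interval_s)) {
    stopifnot(is.numeric(frame_interval_s), frame_interval_s > 0)
  }
  if (is.null(dtype)) {
    dtype <- if (all(frames == round(frames)) && min(frames) >= 0) {
      if (max(frames) <= 255) "uint8" else if (max(frames) <= 65535) "uint16"
      else "float32"
    } else "float32"
  }
  dtype <- match.arg(dtype, c("uint8", "uint16", "float32"))
  structure(
    list(frames = frames, frame_interval_s = frame_interval_s,
         name = name, dtype = dtype),
    class = "calmov_stack"
  )
}

#' @export
print.calmov_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<calmov_stack '%s': %d frame(s) of %dx%d, %s", x$name, d[3],
              d[1], d[2], x$dtype))
  if (!is.null(x$frame_interval_s))
    cat(sprintf(", %.4g s/frame", x$frame_interval_s))
  cat(">\n")
  invisible(x)
}

#' @export
dim.calmov_stack <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[3]

#' Read a multipage TIFF into an image stack
#'
#' Pages are returned in file order. Integer pixel values are preserved
#' exactly; 32-bit float pages are read as stored. Multi-channel (RGB) pages
#' and files whose pages differ in shape are rejected.
#'
#' @param path path to a grayscale (single-channel) TIFF file.
#' @param name source name recorded on the stack; defaults to the file name.
#' @return a [image_stack()] object.
#' @export
read_stack <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  info <- tiff::readTIFF(path, all = TRUE, payload = FALSE)  # data frame
  if (NROW(info) == 0) stop("TIFF has zero pages: ", path)
  bits <- info$bits.per.sample
  is_float <- "sample.format" %in% names(info) &&
    any(info$sample.format == "float")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !is_float)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (!is.matrix(p))
      stop("multi-channel (RGB) TIFF is not supported; supply a grayscale stack")
  }
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1)
    stop("TIFF pages differ in shape; all frames must share one (height, width)")
  dtype <- if (is_float) "float32" else if (max(bits) <= 8) "uint8" else "uint16"
  image_stack(pages, name = name %||% basename(path), dtype = dtype)
}

#' Write an image stack to a multipage TIFF
#'
#' Frames are written as uncompressed grayscale pages, one strip per page,
#' using the stack's `dtype` (`uint8`, `uint16`, or IEEE `float32`; DF/F
#' stacks are float32). Output round-trips through [read_stack()] with exact
#' value equality (bit-identical for float32).
#'
#' @param stack a [image_stack()] object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "calmov_stack"))
  fr <- stack$frames
  if (stack$dtype != "float32") {
    lim <- if (stack$dtype == "uint8") 255 else 65535
    if (any(fr != round(fr)) || min(fr) < 0 || max(fr) > lim)
      stop("values do not fit dtype ", stack$dtype,
           "; use dtype = \"float32\"")
  }
  pages <- lapply(seq_len(dim(fr)[3]), function(t) fr[, , t])
  tiff_write_pages(pages, path, stack$dtype)
  invisible(path)
}

# Minimal baseline-TIFF writer: little-endian, uncompressed, grayscale,
# one strip per page. Exists because the installed TIFF writer cannot store
# float values outside [0, 1], which DF/F stacks require.
# `pages` is a list of numeric matrices (shapes may differ; write_stack
# enforces equal shapes, tests use unequal ones to probe the reader).
tiff_write_pages <- function(pages, path, dtype) {
  stopifnot(length(pages) >= 1)
  bps <- switch(dtype, uint8 = 8L, uint16 = 16L, float32 = 32L)
  sfmt <- if (dtype == "float32") 3L else 1L
  bytes_pp <- bps / 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), u16_le(42)), con)
  # layout: header(8) [page data][IFD] ...
  n <- length(pages)
  ifd_len <- 2 + 10 * 12 + 4
  pos <- 8
  data_off <- numeric(n); ifd_off <- numeric(n)
  for (i in seq_len(n)) {
    len <- length(pages[[i]]) * bytes_pp
    if (len %% 2 == 1) len <- len + 1
    data_off[i] <- pos
    ifd_off[i] <- pos + len
    pos <- ifd_off[i] + ifd_len
  }
  writeBin(u32_le(ifd_off[1]), con)
  entry <- function(tag, type, count, value) {
    val <- if (type == 3) c(u16_le(value), u16_le(0)) else u32_le(value)
    c(u16_le(tag), u16_le(type), u32_le(count), val)
  }
  for (i in seq_len(n)) {
    m <- pages[[i]]
    h <- nrow(m); w <- ncol(m)
    vals <- as.vector(t(m))  # row-major, top row first
    raw_data <- switch(dtype,
      uint8 = as.raw(vals),
      uint16 = writeBin(as.integer(vals), raw(), size = 2, endian = "little"),
      float32 = writeBin(as.numeric(vals), raw(), size = 4, endian = "little"))
    if (length(raw_data) %% 2 == 1) raw_data <- c(raw_data, as.raw(0))
    writeBin(raw_data, con)
    ifd <- c(
      u16_le(10),
      entry(256, 4, 1, w),                 # ImageWidth
      entry(257, 4, 1, h),                 # ImageLength
      entry(258, 3, 1, bps),               # BitsPerSample
      entry(259, 3, 1, 1),                 # Compression = none
      entry(262, 3, 1, 1),                 # Photometric = BlackIsZero
      entry(273, 4, 1, data_off[i]),       # StripOffsets
      entry(277, 3, 1, 1),                 # SamplesPerPixel
      entry(278, 4, 1, h),                 # RowsPerStrip
      entry(279, 4, 1, h * w * bytes_pp),  # StripByteCounts
      entry(339, 3, 1, sfmt),              # SampleFormat
      if (i < n) u32_le(ifd_off[i + 1]) else u32_le(0)
    )
    writeBin(ifd, con)
  }
  invisible(path)
}
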