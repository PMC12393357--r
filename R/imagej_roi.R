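# ImageJ ROI binary format ("Iout" magic, big-endian) reader/writer.
# Supported subtypes: polygon (0), rectangle (1), oval (2), point (10).
# Coordinates are stored in the classic integer layout (no sub-pixel data);
# fractional vertices are rounded on write.

IJ_TYPE <- c(polygon = 0L, rectangle = 1L, ellipse = 2L, point = 10L)
IJ_TYPE_NAMES <- c("polygon", "rect", "oval", "line", "freeline", "polyline",
                   "noRoi", "freehand", "traced", "angle", "point")

encode_imagej_roi <- function(r) {
  stopifnot(inherits(r, "calmov_roi"))
  type <- IJ_TYPE[[r$kind]]
  v <- round(r$vertices)
  if (any(v < 0)) stop("ImageJ ROI coordinates must be non-negative: ", r$name)
  left <- min(v[, 1]); top <- min(v[, 2])
  right <- max(v[, 1]); bottom <- max(v[, 2])
  has_coords <- r$kind %in% c("polygon", "point")
  n <- if (has_coords) nrow(v) else 0L
  if (r$kind == "point") { right <- right + 1; bottom <- bottom + 1 }
  hdr <- c(
    charToRaw("Iout"), u16_be(228), as.raw(c(type, 0)),
    u16_be(top), u16_be(left), u16_be(bottom), u16_be(right),
    u16_be(n),
    raw(16),            # x1, y1, x2, y2 floats (unused)
    raw(26)             # stroke/fill/subtype/options/... (defaults)
  )
  stopifnot(length(hdr) == 60)
  coords <- raw(0)
  if (has_coords) {
    xs <- v[, 1] - left; ys <- v[, 2] - top
    coords <- c(
      unlist(lapply(xs, u16_be)),
      unlist(lapply(ys, u16_be))
    )
  }
  hdr2_off <- 64 + length(coords)
  name_chars <- utf8ToInt(r$name)
  hdr2 <- c(
    raw(16),
    u32_be(hdr2_off + 64),          # name offset
    u32_be(length(name_chars)),     # name length
    raw(40)
  )
  stopifnot(length(hdr2) == 64)
  c(hdr, u32_be(hdr2_off), coords, hdr2,
    unlist(lapply(name_chars, u16_be)))
}

decode_imagej_roi <- function(bytes, default_name = "roi") {
  if (length(bytes) < 64 || rawToChar(bytes[1:4]) != "Iout")
    stop("not an ImageJ ROI file (bad magic bytes)")
  type <- as.integer(bytes[7])
  if (!type %in% IJ_TYPE) {
    tn <- if (type + 1 <= length(IJ_TYPE_NAMES)) IJ_TYPE_NAMES[type + 1]
          else "unknown"
    stop(sprintf("unsupported ImageJ ROI subtype %d (%s); supported: polygon, rect, oval, point",
                 type, tn))
  }
  kind <- names(IJ_TYPE)[match(type, IJ_TYPE)]
  top <- be_u16(bytes[9:10]); left <- be_u16(bytes[11:12])
  bottom <- be_u16(bytes[13:14]); right <- be_u16(bytes[15:16])
  n <- be_u16(bytes[17:18])
  if (kind %in% c("polygon", "point")) {
    if (n < 1) stop("ROI has zero coordinates")
    xs <- ys <- integer(n)
    off <- 64L
    for (i in seq_len(n)) xs[i] <- be_u16(bytes[off + 2 * i - 1:0])
    off <- 64L + 2L * n
    for (i in seq_len(n)) ys[i] <- be_u16(bytes[off + 2 * i - 1:0])
    verts <- cbind(x = left + xs, y = top + ys)
  } else {
    verts <- cbind(x = c(left, right, right, left),
                   y = c(top, top, bottom, bottom))
  }
  nm <- default_name
  hdr2_off <- be_u32(bytes[61:64])
  if (hdr2_off > 0 && hdr2_off + 24 <= length(bytes)) {
    name_off <- be_u32(bytes[hdr2_off + 17:20])
    name_len <- be_u32(bytes[hdr2_off + 21:24])
    if (name_off > 0 && name_len > 0 &&
        name_off + 2 * name_len <= length(bytes)) {
      codes <- vapply(seq_len(name_len), function(i)
        be_u16(bytes[name_off + 2 * i - 1:0]), 0)
      nm <- intToUtf8(codes)
    }
  }
  roi(nm, kind, verts)
}

#' Read ImageJ ROI files
#'
#' Reads a single `.roi` file or a `.zip` bundle of `.roi` files (the format
#' written by ImageJ's ROI Manager). Supported subtypes are polygon,
#' rectangle, oval and point; other subtypes are rejected with their subtype
#' code. ROI names default to the archive entry name when the file carries no
#' name; duplicate names are deduplicated by suffixing `-1`, `-2`, ...
#'
#' @param path path to a `.roi` or `.zip` file.
#' @return list of [roi()] objects, in file/entry order.
#' @export
read_imagej_rois <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  head2 <- readBin(path, "raw", n = 2)
  rois <- if (identical(head2, charToRaw("PK"))) {
    exdir <- tempfile("rois")
    dir.create(exdir)
    on.exit(unlink(exdir, recursive = TRUE))
    entries <- utils::unzip(path, exdir = exdir)
    # preserve archive entry order
    listed <- utils::unzip(path, list = TRUE)$Name
    files <- file.path(exdir, listed)
    lapply(seq_along(files), function(i) {
      decode_imagej_roi(readBin(files[i], "raw", n = file.size(files[i])),
                        default_name = sub("\\.roi$", "", basename(listed[i])))
    })
  } else {
    list(decode_imagej_roi(readBin(path, "raw", n = file.size(path)),
                           default_name = sub("\\.roi$", "", basename(path))))
  }
  nms <- vapply(rois, function(r) r$name, "")
  if (anyDuplicated(nms)) {
    for (i in seq_along(rois)) {
      if (sum(nms[seq_len(i)] == nms[i]) > 1) {
        k <- sum(nms[seq_len(i)] == nms[i]) - 1
        rois[[i]]$name <- paste0(nms[i], "-", k)
      }
    }
  }
  rois
}

#' Write ImageJ ROI files
#'
#' One ROI is written as a single `.roi` file; several ROIs produce a `.zip`
#' bundle with one entry per ROI, openable by ImageJ's ROI Manager and by
#' [read_imagej_rois()] with lossless (integer-coordinate) geometry.
#'
#' @param rois list of [roi()] objects with unique names.
#' @param path output path (`.roi` for one ROI, `.zip` for several).
#' @return the path, invisibly.
#' @export
write_imagej_rois <- function(rois, path) {
  if (length(rois) == 0) stop("no ROIs to write")
  if (inherits(rois, "calmov_roi")) rois <- list(rois)
  nms <- vapply(rois, function(r) r$name, "")
  if (anyDuplicated(nms)) stop("duplicate ROI names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  if (length(rois) == 1) {
    writeBin(encode_imagej_roi(rois[[1]]), path)
  } else {
    entries <- lapply(rois, encode_imagej_roi)
    names(entries) <- paste0(nms, ".roi")
    write_stored_zip(entries, path)
  }
  invisible(path)
}
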