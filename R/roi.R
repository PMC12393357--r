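#' Region of interest (ROI)
#'
#' A named 2-D region in pixel coordinates. Coordinates are 0-based with
#' x = column and y = row, origin top-left (ImageJ convention). For
#' `"polygon"` the vertices are the polygon outline (>= 3 vertices);
#' for `"rectangle"` and `"ellipse"` the vertices are the four corners of the
#' bounding box (the ellipse is inscribed in it); for `"point"` each vertex
#' is one selected point.
#'
#' @param name unique ROI name.
#' @param kind one of `"polygon"`, `"ellipse"`, `"rectangle"`, `"point"`.
#' @param vertices numeric matrix with columns (x, y).
#' @return an object of class `calmov_roi`.
#' @export
roi <- function(name, kind = c("polygon", "ellipse", "rectangle", "point"),
                vertices) {
  kind <- match.arg(kind)
  vertices <- rbind(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2)
    stop("vertices must be an n x 2 numeric matrix of (x, y)")
  if (nrow(vertices) < 1) stop("ROI needs at least one vertex")
  if (kind == "polygon") {
    if (nrow(vertices) < 3) stop("polygon ROI needs >= 3 vertices")
    if (abs(polygon_area(vertices[, 1], vertices[, 2])) == 0)
      stop("polygon ROI has zero area")
  }
  if (kind %in% c("rectangle", "ellipse")) {
    if (diff(range(vertices[, 1])) <= 0 || diff(range(vertices[, 2])) <= 0)
      stop(kind, " ROI has zero area")
  }
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop("ROI name must be a non-empty string")
  colnames(vertices) <- c("x", "y")
  structure(list(name = name, kind = kind, vertices = vertices),
            class = "calmov_roi")
}

#' @export
print.calmov_roi <- function(x, ...) {
  cat(sprintf("<calmov_roi '%s': %s, %d vertices, centroid (%.1f, %.1f)>\n",
              x$name, x$kind, nrow(x$vertices),
              roi_centroid(x)[1], roi_centroid(x)[2]))
  invisible(x)
}

#' ROI centroid
#'
#' Vertex mean for polygons and points; bounding-box centre for rectangles
#' and ellipses. Always lies within the vertex bounding box.
#'
#' @param r a [roi()].
#' @return numeric `(x, y)`.
#' @export
roi_centroid <- function(r) {
  v <- r$vertices
  if (r$kind %in% c("rectangle", "ellipse")) {
    c(x = mean(range(v[, 1])), y = mean(range(v[, 2])))
  } else {
    c(x = mean(v[, 1]), y = mean(v[, 2]))
  }
}

#' Interior pixels of a ROI
#'
#' A pixel belongs to the ROI if its centre `(x + 0.5, y + 0.5)` lies inside
#' the region (even-odd rule for polygons). Point ROIs select the pixel
#' containing each point. Pixels outside the frame are clipped.
#'
#' @param r a [roi()].
#' @param shape frame shape `c(height, width)`.
#' @return integer matrix of 1-based `(row, col)` pixel indices.
#' @export
roi_pixels <- function(r, shape) {
  h <- shape[1]; w <- shape[2]
  v <- r$vertices
  empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  if (r$kind == "point") {
    col <- floor(v[, 1]) + 1L
    row <- floor(v[, 2]) + 1L
    ok <- row >= 1 & row <= h & col >= 1 & col <= w
    out <- cbind(row = as.integer(row[ok]), col = as.integer(col[ok]))
    return(unique(out))
  }
  cmin <- max(1L, floor(min(v[, 1])) + 1L)
  cmax <- min(w, ceiling(max(v[, 1])))
  rmin <- max(1L, floor(min(v[, 2])) + 1L)
  rmax <- min(h, ceiling(max(v[, 2])))
  if (cmin > cmax || rmin > rmax) return(empty)
  grid <- expand.grid(row = rmin:rmax, col = cmin:cmax)
  cx <- grid$col - 0.5  # pixel centre, 0-based coords
  cy <- grid$row - 0.5
  keep <- switch(r$kind,
    polygon = ,
    rectangle = point_in_polygon(cx, cy, v[, 1], v[, 2]),
    ellipse = {
      a <- diff(range(v[, 1])) / 2
      b <- diff(range(v[, 2])) / 2
      x0 <- mean(range(v[, 1])); y0 <- mean(range(v[, 2]))
      ((cx - x0) / a)^2 + ((cy - y0) / b)^2 <= 1
    })
  if (r$kind == "rectangle") {
    # rectangle is its bounding box; include pixels whose centre is inside it
    keep <- cx > min(v[, 1]) & cx < max(v[, 1]) &
      cy > min(v[, 2]) & cy < max(v[, 2])
  }
  out <- cbind(row = as.integer(grid$row[keep]), col = as.integer(grid$col[keep]))
  out
}

# Trace the outer boundary of a 4-connected pixel set as a polygon along
# pixel edges (crack following, inside kept on the right). `member` is a
# logical matrix; the traced component is the one containing the raster-first
# (row-major) member pixel. Returns an n x 2 matrix of 0-based (x, y) corner
# coordinates. Holes are ignored (documented limitation: nuclei are
# convex-ish).
trace_boundary <- function(member) {
  h <- nrow(member); w <- ncol(member)
  inside <- function(x, y) {  # 0-based pixel (col, row)
    x >= 0 && x < w && y >= 0 && y < h && member[y + 1, x + 1]
  }
  # raster-first pixel: scan rows top to bottom, left to right
  start <- NULL
  for (r0 in seq_len(h)) {
    cc <- which(member[r0, ])
    if (length(cc) > 0) { start <- c(cc[1] - 1L, r0 - 1L); break }
  }
  if (is.null(start)) return(matrix(numeric(0), 0, 2))
  dxs <- c(1L, 0L, -1L, 0L); dys <- c(0L, 1L, 0L, -1L)  # E S W N
  px <- start[1]; py <- start[2]
  d <- 1L  # east along the top edge of the start pixel
  verts <- list(c(px, py))
  steps <- 0L; max_steps <- 4L * h * w + 8L
  repeat {
    px <- px + dxs[d]; py <- py + dys[d]
    if (px == start[1] && py == start[2]) break
    steps <- steps + 1L
    if (steps > max_steps) stop("boundary tracing failed to close")
    # ahead-left / ahead-right pixels of corner (px, py) for direction d
    lp <- switch(d, c(px, py - 1L), c(px, py), c(px - 1L, py), c(px - 1L, py - 1L))
    rp <- switch(d, c(px, py), c(px - 1L, py), c(px - 1L, py - 1L), c(px, py - 1L))
    r_in <- inside(rp[1], rp[2])
    l_in <- inside(lp[1], lp[2])
    nd <- if (r_in && l_in) (d - 2L) %% 4L + 1L      # turn left
          else if (r_in) d                            # straight
          else d %% 4L + 1L                           # turn right
    if (nd != d) {
      verts[[length(verts) + 1L]] <- c(px, py)
      d <- nd
    }
  }
  do.call(rbind, verts)
}

#' Convert a label mask to polygon ROIs
#'
#' Each positive label becomes one polygon ROI whose vertices follow the
#' outer boundary of the label's pixel set at pixel-edge resolution. Labels
#' need not be consecutive; names are `<prefix><label>` in ascending label
#' order. Rasterizing a returned ROI recovers the label's pixels exactly for
#' hole-free 4-connected labels; disjoint or diagonal fragments beyond the
#' first component are dropped (contour tolerance, documented).
#'
#' @param mask 2-D non-negative integer matrix; 0 is background.
#' @param name_prefix prefix for ROI names.
#' @return list of [roi()] objects (empty for an all-zero mask).
#' @export
label_mask_to_rois <- function(mask, name_prefix = "cell_") {
  if (!is.matrix(mask)) stop("mask must be a 2-D matrix")
  if (any(mask < 0)) stop("negative labels are not allowed")
  if (any(mask != round(mask))) stop("mask must contain integer labels")
  labs <- sort(unique(mask[mask > 0]))
  lapply(labs, function(k) {
    verts <- trace_boundary(mask == k)
    roi(paste0(name_prefix, format(k, scientific = FALSE)), "polygon", verts)
  })
}

#' Paint ROIs into a label mask
#'
#' ROI `i` (in list order) paints label `i` over its interior pixels; later
#' ROIs overwrite earlier ones where they overlap. ROIs extending beyond the
#' frame are clipped.
#'
#' @param rois list of [roi()] objects.
#' @param shape `c(height, width)` of the output mask.
#' @return integer label matrix.
#' @export
rois_to_label_mask <- function(rois, shape) {
  if (any(shape < 1)) stop("mask shape must be positive")
  mask <- matrix(0L, shape[1], shape[2])
  for (i in seq_along(rois)) {
    px <- roi_pixels(rois[[i]], shape)
    if (nrow(px) > 0) mask[px] <- i
  }
  mask
}
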