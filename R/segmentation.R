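#' Segmentation parameters
#'
#' Controls the cell-detection pipeline: intensity projection across frames,
#' rolling-ball background subtraction, binary threshold, optional
#' marker-based watershed split of touching objects, and an area filter.
#'
#' @param projection frame reduction: `"sum"`, `"max"` or `"mean"`.
#' @param rolling_ball_radius background ball radius in pixels (default 20).
#' @param threshold `"otsu"` (default) or a fixed numeric threshold.
#' @param min_area,max_area object area bounds in pixels^2.
#' @param watershed split touching objects via distance-transform watershed
#'   (default `TRUE`).
#' @return a list of class `calmov_segparams`.
#' @export
segmentation_params <- function(projection = c("sum", "max", "mean"),
                                rolling_ball_radius = 20,
                                threshold = "otsu",
                                min_area = 20, max_area = 400,
                                watershed = TRUE) {
  projection <- match.arg(projection)
  stopifnot(rolling_ball_radius > 0, min_area > 0, min_area < max_area)
  if (!(identical(threshold, "otsu") || is.numeric(threshold)))
    stop("threshold must be \"otsu\" or a numeric value")
  structure(list(projection = projection,
                 rolling_ball_radius = rolling_ball_radius,
                 threshold = threshold, min_area = min_area,
                 max_area = max_area, watershed = isTRUE(watershed)),
            class = "calmov_segparams")
}

#' Project a stack to a single image
#'
#' Pixelwise reduction across frames. Values are held in double precision
#' throughout, so sum projections cannot overflow.
#'
#' @param stack a [image_stack()].
#' @param method `"sum"`, `"max"` or `"mean"`.
#' @return a numeric matrix.
#' @export
project <- function(stack, method = c("sum", "max", "mean")) {
  method <- match.arg(method)
  fr <- stack$frames
  h <- dim(fr)[1]; w <- dim(fr)[2]; nf <- dim(fr)[3]
  flat <- matrix(fr, nrow = h * w, ncol = nf)
  out <- switch(method,
    sum = rowSums(flat),
    mean = rowMeans(flat),
    max = {
      m <- flat[, 1]
      for (t in seq_len(nf)[-1]) m <- pmax(m, flat[, t])
      m
    })
  matrix(as.numeric(out), h, w)
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grayscale opening of the image with a
#' ball-shaped (non-flat, spherical cap) structuring element of the given
#' radius, and subtracts it. The result is clipped at zero; a flat image maps
#' to all zeros. Borders are handled by edge replication.
#'
#' @param image 2-D numeric matrix.
#' @param radius ball radius in pixels (> 0).
#' @return background-subtracted matrix, same shape.
#' @export
rolling_ball_subtract <- function(image, radius) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (radius <= 0) stop("radius must be > 0")
  r <- as.integer(ceiling(radius))
  off <- expand.grid(di = -r:r, dj = -r:r)
  keep <- off$di^2 + off$dj^2 <= radius^2
  off <- off[keep, ]
  hk <- sqrt(pmax(radius^2 - off$di^2 - off$dj^2, 0))
  h <- nrow(image); w <- ncol(image)
  pad <- function(m) {
    ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
    ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
    m[ri, ci, drop = FALSE]
  }
  pim <- pad(image)
  ero <- matrix(Inf, h, w)
  for (k in seq_len(nrow(off))) {
    sub <- pim[(1:h) + r + off$di[k], (1:w) + r + off$dj[k]]
    ero <- pmin(ero, sub - hk[k])
  }
  pe <- pad(ero)
  bg <- matrix(-Inf, h, w)
  for (k in seq_len(nrow(off))) {
    sub <- pe[(1:h) + r + off$di[k], (1:w) + r + off$dj[k]]
    bg <- pmax(bg, sub + hk[k])
  }
  out <- image - bg
  out[out < 0] <- 0
  out
}

#' Threshold + watershed segmentation of a 2-D image
#'
#' Pipeline: binary threshold (Otsu by default) -> optional split of touching
#' objects by marker-based watershed (distance-transform local maxima as
#' seeds, minimum seed separation `sqrt(min_area / pi)`) -> discard
#' components with area outside `[min_area, max_area]`. Surviving labels are
#' renumbered consecutively from 1 in raster order (top-to-bottom,
#' left-to-right) of each component's first pixel. The result is fully
#' deterministic for identical input and parameters.
#'
#' @param image 2-D numeric matrix (non-constant when using Otsu).
#' @param params a [segmentation_params()].
#' @return integer label matrix (all-zero when nothing passes the filter).
#' @export
segment <- function(image, params = segmentation_params()) {
  stopifnot(is.matrix(image))
  if (identical(params$threshold, "otsu")) {
    rng <- range(image)
    if (diff(rng) == 0) stop("constant image: Otsu threshold undefined")
    x01 <- (image - rng[1]) / diff(rng)
    th <- rng[1] + EBImage::otsu(EBImage::Image(x01)) * diff(rng)
  } else {
    th <- params$threshold
  }
  mask <- image > th
  if (!any(mask)) return(matrix(0L, nrow(image), ncol(image)))
  if (params$watershed) {
    dist <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask)))
    sep <- sqrt(params$min_area / pi)
    bs <- 2L * floor(sep) + 1L
    dil <- if (bs >= 3) {
      EBImage::imageData(EBImage::dilate(EBImage::Image(dist),
                                         EBImage::makeBrush(bs, "disc")))
    } else dist
    cand <- which(dist > 0 & dist >= dil)
    # greedy non-maximum suppression: strongest first, raster order on ties
    cr <- ((cand - 1) %% nrow(image)) + 1
    cc <- ((cand - 1) %/% nrow(image)) + 1
    ord <- order(-dist[cand], cr, cc)
    kept_r <- kept_c <- numeric(0)
    for (i in ord) {
      if (length(kept_r) == 0 ||
          all((kept_r - cr[i])^2 + (kept_c - cc[i])^2 >= sep^2)) {
        kept_r <- c(kept_r, cr[i]); kept_c <- c(kept_c, cc[i])
      }
    }
    seeds <- matrix(0L, nrow(image), ncol(image))
    seeds[cbind(kept_r, kept_c)] <- seq_along(kept_r)
    labels <- EBImage::imageData(EBImage::propagate(
      EBImage::Image(dist), EBImage::Image(seeds), mask = EBImage::Image(mask)))
  } else {
    labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  }
  labels <- matrix(as.integer(round(labels)), nrow(image), ncol(image))
  areas <- tabulate(labels)
  bad <- which(areas < params$min_area | areas > params$max_area)
  if (length(bad) > 0) labels[labels %in% bad] <- 0L
  # renumber consecutively in raster order of first pixel
  scan <- as.vector(t(labels))
  present <- unique(scan[scan > 0])
  if (length(present) == 0) return(matrix(0L, nrow(image), ncol(image)))
  remap <- integer(max(present))
  remap[present] <- seq_along(present)
  out <- labels
  out[labels > 0] <- remap[labels[labels > 0]]
  out
}

#' Segment a stack into cell ROIs
#'
#' Composition of [project()], [rolling_ball_subtract()], [segment()] and
#' [label_mask_to_rois()]: the standard detection path for nuclear-localized
#' indicator movies.
#'
#' @param stack a [image_stack()].
#' @param params a [segmentation_params()].
#' @param name_prefix prefix for ROI names.
#' @return list of polygon [roi()]s (empty when nothing is detected).
#' @export
segment_stack_to_rois <- function(stack, params = segmentation_params(),
                                  name_prefix = "cell_") {
  img <- project(stack, params$projection)
  bg <- rolling_ball_subtract(img, params$rolling_ball_radius)
  labels <- segment(bg, params)
  label_mask_to_rois(labels, name_prefix)
}
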