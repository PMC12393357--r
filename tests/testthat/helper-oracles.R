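# Independent reference implementations used as oracles. These are written
# directly from the definitions, separately from the package code paths.

# Reference sliding-window z-score detector: plain transliteration of the
# update rule, using explicit sums rather than the package's vectorized
# window statistics.
ref_detect_peaks <- function(x, lag, threshold, influence) {
  n <- length(x)
  flags <- integer(n)
  filt <- numeric(n)
  for (i in 1:lag) filt[i] <- x[i]
  for (i in (lag + 1):n) {
    s1 <- 0; s2 <- 0
    for (j in (i - lag):(i - 1)) {
      s1 <- s1 + filt[j]
      s2 <- s2 + filt[j]^2
    }
    mu <- s1 / lag
    varw <- s2 / lag - mu^2
    sd <- if (varw > 0) sqrt(varw) else 0
    if (abs(x[i] - mu) > threshold * sd) {
      flags[i] <- if (x[i] > mu) 1L else -1L
      filt[i] <- influence * x[i] + (1 - influence) * filt[i - 1]
    } else {
      flags[i] <- 0L
      filt[i] <- x[i]
    }
  }
  flags
}

# Brute-force template-match oracle: double loop over all offsets, scoring
# with stats::cor, same deterministic tie-break (smallest |dx|+|dy|, then dy,
# then dx).
brute_shift <- function(frame, ref, rect, max_shift) {
  x0 <- rect[1]; y0 <- rect[2]; tw <- rect[3]; th <- rect[4]
  templ <- ref[(y0 + 1):(y0 + th), (x0 + 1):(x0 + tw)]
  h <- nrow(frame); w <- ncol(frame)
  best <- c(score = -Inf, dx = NA, dy = NA)
  for (dy in -max_shift:max_shift) {
    for (dx in -max_shift:max_shift) {
      if (x0 + dx < 0 || y0 + dy < 0 || x0 + dx + tw > w || y0 + dy + th > h)
        next
      win <- frame[(y0 + dy + 1):(y0 + dy + th), (x0 + dx + 1):(x0 + dx + tw)]
      sc <- suppressWarnings(stats::cor(as.vector(win), as.vector(templ)))
      if (is.na(sc)) sc <- 0
      better <- sc > best["score"] ||
        (sc == best["score"] &&
           (abs(dx) + abs(dy) < abs(best["dx"]) + abs(best["dy"]) ||
              (abs(dx) + abs(dy) == abs(best["dx"]) + abs(best["dy"]) &&
                 (dy < best["dy"] ||
                    (dy == best["dy"] && dx < best["dx"])))))
      if (better) best <- c(score = sc, dx = dx, dy = dy)
    }
  }
  best
}

# Independent encoder for an ImageJ point ROI at (x, y), written byte-by-byte
# from the published layout ("Iout", version, type 10 at offset 6, bounding
# box top/left/bottom/right, one relative coordinate pair).
ij_point_roi_bytes <- function(x, y) {
  b2 <- function(v) as.raw(c(v %/% 256, v %% 256))
  c(charToRaw("Iout"),
    b2(218),                 # version
    as.raw(c(10, 0)),        # type = point
    b2(y), b2(x),            # top, left
    b2(y + 1), b2(x + 1),    # bottom, right (bounding-box convention)
    b2(1),                   # n coordinates
    raw(46),                 # rest of the 64-byte header zeroed
    b2(0), b2(0))            # x - left, y - top
}

# Random ROI generators (integer coordinates, the classic format's domain)
random_polygon_roi <- function(name, lim = 50) {
  n <- sample(3:8, 1)
  ang <- sort(stats::runif(n, 0, 2 * pi))
  rad <- stats::runif(n, 3, 10)
  cx <- sample(12:(lim - 12), 1); cy <- sample(12:(lim - 12), 1)
  v <- cbind(round(cx + rad * cos(ang)), round(cy + rad * sin(ang)))
  v[v < 0] <- 0
  if (abs(calmov:::polygon_area(v[, 1], v[, 2])) == 0) {
    return(random_polygon_roi(name, lim))
  }
  roi(name, "polygon", v)
}

random_roi <- function(name, lim = 50) {
  kind <- sample(c("polygon", "rectangle", "ellipse", "point"), 1)
  if (kind == "polygon") return(random_polygon_roi(name, lim))
  if (kind == "point") {
    n <- sample(1:4, 1)
    return(roi(name, "point",
               cbind(sample(0:lim, n, TRUE), sample(0:lim, n, TRUE))))
  }
  x <- sort(sample(0:lim, 2)); y <- sort(sample(0:lim, 2))
  if (x[1] == x[2]) x[2] <- x[2] + 1
  if (y[1] == y[2]) y[2] <- y[2] + 1
  roi(name, kind, cbind(c(x[1], x[2], x[2], x[1]),
                        c(y[1], y[1], y[2], y[2])))
}

# A flat-disk scene with known centres; returns list(image, centers (x, y)).
disk_scene <- function(h, w, centers_rc, radius, intensity = 100) {
  img <- matrix(0, h, w)
  for (i in seq_len(nrow(centers_rc))) {
    for (r in max(1, centers_rc[i, 1] - radius):min(h, centers_rc[i, 1] + radius)) {
      for (cc in max(1, centers_rc[i, 2] - radius):min(w, centers_rc[i, 2] + radius)) {
        if ((r - centers_rc[i, 1])^2 + (cc - centers_rc[i, 2])^2 <= radius^2)
          img[r, cc] <- intensity
      }
    }
  }
  img
}

# Greedy centroid matching within a radius; returns number of matched pairs.
match_centroids <- function(found_xy, true_xy, max_dist = 3) {
  if (nrow(found_xy) == 0 || nrow(true_xy) == 0) return(0L)
  d <- sqrt(outer(found_xy[, 1], true_xy[, 1], "-")^2 +
              outer(found_xy[, 2], true_xy[, 2], "-")^2)
  matched <- 0L
  repeat {
    m <- which(d == min(d), arr.ind = TRUE)[1, , drop = FALSE]
    if (d[m] > max_dist) break
    matched <- matched + 1L
    d[m[1], ] <- Inf
    d[, m[2]] <- Inf
    if (all(is.infinite(d))) break
  }
  matched
}
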