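#' Registration parameters
#'
#' Parameters for rigid (integer-pixel translation) motion correction by
#' normalized cross-correlation template matching against a fixed reference
#' frame. Matching against a fixed reference (rather than the previous frame)
#' avoids drift accumulation.
#'
#' @param reference_frame 1-based index of the reference frame (default 1).
#' @param template_rect template sub-region of the reference as
#'   `c(x, y, w, h)` in 0-based pixel coordinates; `NULL` (default) uses the
#'   central 50 percent of the frame.
#' @param max_shift search radius in pixels (default 20).
#' @return a list of class `calmov_regparams`.
#' @export
registration_params <- function(reference_frame = 1, template_rect = NULL,
                                max_shift = 20) {
  stopifnot(reference_frame >= 1, max_shift >= 0)
  if (!is.null(template_rect)) {
    stopifnot(length(template_rect) == 4, template_rect[3] >= 1,
              template_rect[4] >= 1, all(template_rect[1:2] >= 0))
  }
  structure(list(reference_frame = as.integer(reference_frame),
                 template_rect = template_rect,
                 max_shift = as.integer(max_shift)),
            class = "calmov_regparams")
}

default_template_rect <- function(h, w) {
  tw <- max(1L, floor(w / 2)); th <- max(1L, floor(h / 2))
  c(floor((w - tw) / 2), floor((h - th) / 2), tw, th)
}

#' Estimate per-frame rigid shifts by template matching
#'
#' For every frame the shift `(dx, dy)` maximizing the normalized (zero-mean,
#' unit-norm) cross-correlation between the reference template and the
#' correspondingly offset frame window is found by exhaustive search over
#' offsets within `max_shift` whose window lies inside the frame. Ties are
#' broken deterministically: smallest `|dx| + |dy|`, then smallest `dy`, then
#' smallest `dx`.
#'
#' @param stack a [image_stack()].
#' @param params a [registration_params()].
#' @return data frame of class `calmov_shifts` with columns
#'   `frame, dx, dy, score` (score in `[-1, 1]`).
#' @export
estimate_shifts <- function(stack, params = registration_params()) {
  stopifnot(inherits(stack, "calmov_stack"))
  fr <- stack$frames
  h <- dim(fr)[1]; w <- dim(fr)[2]; nf <- dim(fr)[3]
  if (params$reference_frame > nf) stop("reference_frame beyond stack")
  rect <- params$template_rect %||% default_template_rect(h, w)
  x0 <- rect[1]; y0 <- rect[2]; tw <- rect[3]; th <- rect[4]
  if (x0 < 0 || y0 < 0 || x0 + tw > w || y0 + th > h)
    stop("template_rect out of frame bounds")
  rows <- (y0 + 1):(y0 + th)
  cols <- (x0 + 1):(x0 + tw)
  templ <- fr[rows, cols, params$reference_frame]
  tz <- templ - mean(templ)
  tn <- sqrt(sum(tz * tz))
  if (tn == 0) stop("template has zero intensity variance")
  ms <- params$max_shift
  grid <- expand.grid(dx = -ms:ms, dy = -ms:ms)
  valid <- x0 + grid$dx >= 0 & x0 + grid$dx + tw <= w &
    y0 + grid$dy >= 0 & y0 + grid$dy + th <= h
  grid <- grid[valid, , drop = FALSE]
  ord <- order(abs(grid$dx) + abs(grid$dy), grid$dy, grid$dx)
  grid <- grid[ord, , drop = FALSE]
  npx <- tw * th
  dx <- dy <- integer(nf); score <- numeric(nf)
  for (t in seq_len(nf)) {
    f <- fr[, , t]
    best <- -Inf; bi <- 1L
    for (k in seq_len(nrow(grid))) {
      win <- f[rows + grid$dy[k], cols + grid$dx[k]]
      s <- sum(win)
      num <- sum(win * tz)
      den2 <- sum(win * win) - s * s / npx
      sc <- if (den2 <= 0) 0 else num / (sqrt(den2) * tn)
      if (sc > best) { best <- sc; bi <- k }
    }
    dx[t] <- grid$dx[bi]; dy[t] <- grid$dy[bi]
    score[t] <- max(min(best, 1), -1)
  }
  structure(data.frame(frame = seq_len(nf), dx = dx, dy = dy, score = score),
            class = c("calmov_shifts", "data.frame"))
}

#' Apply rigid shifts to a stack
#'
#' Frame `t`, estimated as shifted by `(dx_t, dy_t)` relative to the
#' reference, is translated by `(-dx_t, -dy_t)`; pixels exposed at the
#' borders take `fill_value`. The stack dtype is promoted to float32 when
#' `fill_value` is non-integral.
#'
#' @param stack a [image_stack()].
#' @param shifts a `calmov_shifts` data frame from [estimate_shifts()].
#' @param fill_value intensity for exposed border pixels (default 0).
#' @return the registered [image_stack()].
#' @export
apply_shifts <- function(stack, shifts, fill_value = 0) {
  stopifnot(inherits(stack, "calmov_stack"))
  nf <- n_frames(stack)
  if (nrow(shifts) != nf) stop("shifts length does not match stack")
  out <- stack$frames
  for (t in seq_len(nf)) {
    if (shifts$dx[t] != 0 || shifts$dy[t] != 0) {
      out[, , t] <- translate_matrix(stack$frames[, , t],
                                     -shifts$dx[t], -shifts$dy[t], fill_value)
    } else if (fill_value != 0) {
      out[, , t] <- stack$frames[, , t]
    }
  }
  dtype <- stack$dtype
  if (fill_value != round(fill_value)) dtype <- "float32"
  image_stack(out, frame_interval_s = stack$frame_interval_s,
              name = stack$name, dtype = dtype)
}

#' Register a stack (estimate, then apply shifts)
#'
#' @inheritParams estimate_shifts
#' @param fill_value passed to [apply_shifts()].
#' @return list with elements `stack` (registered [image_stack()]) and
#'   `shifts` (`calmov_shifts`).
#' @export
register <- function(stack, params = registration_params(), fill_value = 0) {
  shifts <- estimate_shifts(stack, params)
  list(stack = apply_shifts(stack, shifts, fill_value), shifts = shifts)
}

#' Write / read a shift table as CSV
#' @param shifts a `calmov_shifts` data frame.
#' @param path CSV path (columns `frame,dx,dy,score`).
#' @return the path (write) or the table (read), invisibly for write.
#' @export
write_shifts <- function(shifts, path) {
  lines <- c("frame,dx,dy,score",
             sprintf("%d,%d,%d,%.17g", shifts$frame, shifts$dx, shifts$dy,
                     shifts$score))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_shifts
#' @export
read_shifts <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("frame", "dx", "dy", "score") %in% names(d)))
  structure(d, class = c("calmov_shifts", "data.frame"))
}
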