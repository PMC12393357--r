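# Projection, rolling-ball background subtraction, threshold + watershed

test_that("projections reduce frames as expected", {
  one <- image_stack(matrix(1:6, 2, 3))
  expect_identical(project(one, "sum"), matrix(as.numeric(1:6), 2, 3))
  expect_identical(project(one, "max"), matrix(as.numeric(1:6), 2, 3))
  two <- image_stack(array(c(rep(1, 6), rep(3, 6)), c(2, 3, 2)))
  expect_identical(project(two, "sum"), matrix(4, 2, 3))
  expect_identical(project(two, "mean"), matrix(2, 2, 3))
  expect_identical(project(two, "max"), matrix(3, 2, 3))
  expect_error(project(two, "median"))
  # no integer overflow: many bright frames
  big <- image_stack(array(65535, c(2, 2, 40)), dtype = "uint16")
  expect_identical(project(big, "sum")[1, 1], 65535 * 40)
})

test_that("max projection of a transient movie highlights cell pixels", {
  sim <- render_movie(scene_spec(field = c(48, 48), n_cells = 3,
                                 min_separation = 14, noise_sd = 0, jitter = 0,
                                 classes = "OFF", seed = 4))
  mx <- project(sim$stack, "max")
  cellpx <- do.call(rbind, sim$truth$masks)
  cells_lin <- (cellpx[, "col"] - 1) * 48 + cellpx[, "row"]
  expect_gt(mean(mx[cells_lin]), 10 * mean(mx[-cells_lin]))
})

test_that("rolling ball removes smooth background and keeps sharp features", {
  expect_identical(rolling_ball_subtract(matrix(7, 12, 12), 3),
                   matrix(0, 12, 12))
  # isolated spike on constant background survives within 10%
  img <- matrix(5, 30, 30); img[15, 15] <- 50
  out <- rolling_ball_subtract(img, 5)
  expect_gt(out[15, 15], 0.9 * 45)
  expect_lt(max(out[-((15 - 1) * 30 + 15)]), 1e-9)
  # vs an independent brute-force grayscale-opening oracle
  set.seed(9)
  small <- matrix(runif(10 * 10, 0, 10), 10, 10)
  radius <- 2.5
  oracle_open <- function(im, rad) {
    h <- nrow(im); w <- ncol(im)
    offs <- subset(expand.grid(di = -3:3, dj = -3:3), di^2 + dj^2 <= rad^2)
    offs$hk <- sqrt(rad^2 - offs$di^2 - offs$dj^2)
    at <- function(m, r, cc) m[pmin(pmax(r, 1), h), pmin(pmax(cc, 1), w)]
    ero <- matrix(NA, h, w)
    for (r in 1:h) for (cc in 1:w)
      ero[r, cc] <- min(sapply(seq_len(nrow(offs)), function(k)
        at(im, r + offs$di[k], cc + offs$dj[k]) - offs$hk[k]))
    dil <- matrix(NA, h, w)
    for (r in 1:h) for (cc in 1:w)
      dil[r, cc] <- max(sapply(seq_len(nrow(offs)), function(k)
        at(ero, r + offs$di[k], cc + offs$dj[k]) + offs$hk[k]))
    dil
  }
  bg <- oracle_open(small, radius)
  expect_equal(rolling_ball_subtract(small, radius),
               pmax(small - bg, 0), tolerance = 1e-12)
  # a gentle linear ramp is almost entirely background for an image-sized
  # ball (residual bounded by ball curvature, ~ radius * slope^2 / 2)
  ramp <- matrix(rep(seq(0, 1, length.out = 20), each = 20), 20, 20)
  res <- rolling_ball_subtract(ramp, 20)
  expect_lt(max(res), 0.1 * 1)
  expect_true(all(res >= 0))
  expect_error(rolling_ball_subtract(ramp, 0), "radius")
})

test_that("disjoint bright disks are segmented with accurate centroids", {
  centers <- cbind(c(10, 10, 30, 50, 50), c(10, 50, 30, 12, 48))
  img <- disk_scene(60, 60, centers, radius = 4)
  lab <- segment(img, segmentation_params(threshold = 50, min_area = 10,
                                          max_area = 200))
  expect_identical(max(lab), 5L)
  rois <- label_mask_to_rois(lab)
  found <- do.call(rbind, lapply(rois, roi_centroid))
  true_xy <- cbind(centers[, 2] - 0.5, centers[, 1] - 0.5)
  expect_identical(match_centroids(found, true_xy, max_dist = 1), 5L)
})

test_that("watershed splits touching disks; plain labeling does not", {
  img <- disk_scene(40, 40, cbind(c(20, 20), c(15, 25)), radius = 6)
  p_on <- segmentation_params(threshold = 50, min_area = 10, max_area = 500)
  p_off <- segmentation_params(threshold = 50, min_area = 10, max_area = 500,
                               watershed = FALSE)
  expect_identical(max(segment(img, p_on)), 2L)
  expect_identical(max(segment(img, p_off)), 1L)
  # connected-components oracle for the merged case
  cc <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(img > 50)))
  expect_true(max(cc) == 1)
})

test_that("all-background images give all-zero masks; otsu needs contrast", {
  img <- matrix(0, 20, 20)
  lab <- segment(img, segmentation_params(threshold = 10, min_area = 2,
                                          max_area = 50))
  expect_true(all(lab == 0L))
  expect_error(segment(img, segmentation_params()), "constant")
})

test_that("area filtering only removes labels and keeps areas in bounds", {
  set.seed(10)
  centers <- cbind(sample(seq(8, 72, by = 16), 4), sample(seq(8, 72, by = 16), 4))
  img <- disk_scene(80, 80, centers, radius = 3)
  img[2, 2] <- 100  # single-pixel speck, below min_area
  p <- segmentation_params(threshold = 50, min_area = 10, max_area = 100)
  lab <- segment(img, p)
  areas <- tabulate(lab)
  expect_true(all(areas >= p$min_area & areas <= p$max_area))
  p_loose <- segmentation_params(threshold = 50, min_area = 1, max_area = 1e5)
  expect_gte(max(segment(img, p_loose)), max(lab))
})

test_that("segmentation is deterministic", {
  set.seed(12)
  img <- disk_scene(50, 50, cbind(c(12, 35), c(12, 35)), radius = 5) +
    matrix(rnorm(2500, 0, 10), 50, 50)
  p <- segmentation_params(min_area = 10, max_area = 300)
  expect_identical(segment(img, p), segment(img, p))
})

test_that("segment_stack_to_rois composes the whole detection path", {
  sim <- render_movie(scene_spec(field = c(96, 96), n_cells = 8,
                                 min_separation = 16, noise_sd = 2,
                                 jitter = 0, seed = 13))
  rois <- segment_stack_to_rois(sim$stack,
                                segmentation_params(min_area = 8,
                                                    max_area = 300),
                                name_prefix = "nuc_")
  expect_length(rois, 8)
  expect_true(all(startsWith(vapply(rois, function(r) r$name, ""), "nuc_")))
  found <- do.call(rbind, lapply(rois, roi_centroid))
  expect_identical(match_centroids(found, sim$truth$centers, 3), 8L)
  # empty movie
  quiet <- image_stack(array(0, c(32, 32, 4)))
  expect_identical(segment_stack_to_rois(
    quiet, segmentation_params(threshold = 10, min_area = 2, max_area = 99)),
    list())
})
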