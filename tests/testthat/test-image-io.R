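# TIFF stack and ImageJ ROI file IO

test_that("stack round-trips preserve values exactly for every dtype", {
  set.seed(11)
  f <- withr::local_tempfile(fileext = ".tif")

  s16 <- image_stack(array(sample(0:65535, 5 * 8 * 8, TRUE), c(8, 8, 5)),
                     dtype = "uint16")
  write_stack(s16, f)
  expect_true(all(read_stack(f)$frames == s16$frames))
  expect_identical(read_stack(f)$dtype, "uint16")

  s8 <- image_stack(array(sample(0:255, 4 * 4 * 3, TRUE), c(4, 4, 3)),
                    dtype = "uint8")
  write_stack(s8, f)
  expect_true(all(read_stack(f)$frames == s8$frames))

  # float32: values written, re-read, re-written must be bit-stable
  sf <- image_stack(array(rnorm(4 * 4 * 3), c(4, 4, 3)), dtype = "float32")
  write_stack(sf, f)
  once <- read_stack(f)
  expect_equal(once$frames, sf$frames, tolerance = 1e-7)
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_stack(once, f2)
  expect_identical(read_stack(f2)$frames, once$frames)
  # negative / large values survive (no [0,1] clamping)
  neg <- image_stack(array(c(-3.5, 0, 1e6, -1e-4), c(2, 2, 1)),
                     dtype = "float32")
  write_stack(neg, f)
  expect_equal(read_stack(f)$frames, neg$frames, tolerance = 1e-3)
})

test_that("single-page files load as one-frame stacks", {
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(image_stack(matrix(1:12, 3, 4)), f)
  s <- read_stack(f)
  expect_identical(dim(s$frames), c(3L, 4L, 1L))
})

test_that("degenerate inputs are rejected", {
  f <- withr::local_tempfile(fileext = ".tif")
  # pages of differing shapes (constructed via the low-level page writer)
  calmov:::tiff_write_pages(list(matrix(1, 4, 4), matrix(1, 5, 5)), f, "uint8")
  expect_error(read_stack(f), "shape")
  expect_error(read_stack(tempfile()), "not found")
  expect_error(image_stack(array(1, c(0, 4, 1))), "frames")
  expect_error(write_stack(image_stack(matrix(c(0.5, 1, 2, 3), 2),
                                       dtype = "float32")$frames, f))
})

test_that("ImageJ ROI files round-trip geometry, kind and names", {
  r_poly <- roi("soma-1", "polygon", cbind(c(2, 10, 10, 2), c(3, 3, 8, 8)))
  r_pt <- roi("pt", "point", cbind(c(10, 4), c(20, 7)))
  r_ov <- roi("nucleus", "ellipse", cbind(c(1, 9, 9, 1), c(2, 2, 6, 6)))
  r_rc <- roi("box", "rectangle", cbind(c(0, 6, 6, 0), c(0, 0, 4, 4)))

  f1 <- withr::local_tempfile(fileext = ".roi")
  write_imagej_rois(list(r_poly), f1)
  back <- read_imagej_rois(f1)
  expect_length(back, 1)
  expect_identical(back[[1]]$kind, "polygon")
  expect_true(all(back[[1]]$vertices == r_poly$vertices))
  expect_identical(back[[1]]$name, "soma-1")

  fz <- withr::local_tempfile(fileext = ".zip")
  write_imagej_rois(list(r_poly, r_pt, r_ov, r_rc, roi("e", "point", cbind(0, 0))), fz)
  back <- read_imagej_rois(fz)
  expect_length(back, 5)
  expect_identical(vapply(back, function(r) r$name, ""),
                   c("soma-1", "pt", "nucleus", "box", "e"))
  expect_identical(vapply(back, function(r) r$kind, ""),
                   c("polygon", "point", "ellipse", "rectangle", "point"))
  for (i in 1:4) {
    expect_true(all(back[[i]]$vertices ==
                      list(r_poly, r_pt, r_ov, r_rc)[[i]]$vertices))
  }
})

test_that("a point ROI encoded by an independent writer decodes correctly", {
  f <- withr::local_tempfile(fileext = ".roi")
  writeBin(ij_point_roi_bytes(10, 20), f)
  r <- read_imagej_rois(f)[[1]]
  expect_identical(r$kind, "point")
  expect_identical(unname(r$vertices[1, ]), c(10, 20))
})

test_that("bad magic and unsupported subtypes are rejected with detail", {
  f <- withr::local_tempfile(fileext = ".roi")
  writeBin(as.raw(1:80), f)
  expect_error(read_imagej_rois(f), "magic")
  # a line ROI (type 3)
  b <- calmov:::encode_imagej_roi(roi("x", "polygon",
                                      cbind(c(0, 5, 5), c(0, 0, 5))))
  b[7] <- as.raw(3)
  writeBin(b, f)
  expect_error(read_imagej_rois(f), "subtype 3")
  expect_error(write_imagej_rois(list(), tempfile()), "no ROIs")
  expect_error(write_imagej_rois(list(roi("a", "point", cbind(1, 1)),
                                      roi("a", "point", cbind(2, 2))),
                                 tempfile()), "duplicate")
})

test_that("stack and ROI round-trips are lossless over random fixtures", {
  set.seed(99)
  f <- withr::local_tempfile(fileext = ".tif")
  for (i in 1:20) {
    nf <- sample(1:6, 1)
    h <- sample(2:12, 1); w <- sample(2:12, 1)
    s <- image_stack(array(sample(0:65535, h * w * nf, TRUE), c(h, w, nf)),
                     dtype = "uint16")
    write_stack(s, f)
    expect_true(all(read_stack(f)$frames == s$frames))
  }
  fz <- withr::local_tempfile(fileext = ".zip")
  for (i in 1:20) {
    rois <- lapply(seq_len(sample(2:6, 1)), function(k)
      random_roi(sprintf("r%d_%d", i, k)))
    write_imagej_rois(rois, fz)
    back <- read_imagej_rois(fz)
    expect_length(back, length(rois))
    for (k in seq_along(rois)) {
      expect_identical(back[[k]]$kind, rois[[k]]$kind)
      expect_identical(back[[k]]$name, rois[[k]]$name)
      expect_true(all(back[[k]]$vertices == rois[[k]]$vertices))
    }
  }
})

test_that("label masks convert to ROIs and back", {
  # single 3x3 square: rasterization covers exactly those 9 pixels
  m <- matrix(0L, 10, 10); m[3:5, 4:6] <- 1L
  rois <- label_mask_to_rois(m, "c")
  expect_length(rois, 1)
  expect_identical(rois[[1]]$name, "c1")
  px <- roi_pixels(rois[[1]], c(10, 10))
  expect_identical(nrow(px), 9L)
  # brute-force check: every pixel centre classified by even-odd rule
  v <- rois[[1]]$vertices
  for (r in 1:10) for (cc in 1:10) {
    inside <- calmov:::point_in_polygon(cc - 0.5, r - 0.5, v[, 1], v[, 2])
    expect_identical(inside, m[r, cc] == 1L)
  }

  expect_identical(label_mask_to_rois(matrix(0L, 5, 5)), list())
  expect_error(label_mask_to_rois(matrix(-1L, 2, 2)), "negative")

  # two touching labels produce disjoint rasterizations
  m2 <- matrix(0L, 8, 8)
  m2[2:5, 2:4] <- 1L; m2[2:5, 5:7] <- 2L
  rois2 <- label_mask_to_rois(m2)
  p1 <- roi_pixels(rois2[[1]], c(8, 8))
  p2 <- roi_pixels(rois2[[2]], c(8, 8))
  lin <- function(p) (p[, "col"] - 1) * 8 + p[, "row"]
  expect_length(intersect(lin(p1), lin(p2)), 0)
  expect_setequal(lin(p1), which(m2 == 1L))
  expect_setequal(lin(p2), which(m2 == 2L))
})

test_that("mask -> ROIs -> mask recovers non-overlapping rectangle partitions", {
  set.seed(3)
  for (rep in 1:5) {
    m <- matrix(0L, 20, 20)
    # non-overlapping rectangles on a grid
    m[2:6, 2:7] <- 1L; m[10:15, 3:6] <- 2L; m[4:9, 12:18] <- 3L
    rois <- label_mask_to_rois(m)
    expect_identical(rois_to_label_mask(rois, c(20, 20)), m)
  }
})

test_that("ROI painting clips and later ROIs overwrite earlier", {
  r1 <- roi("a", "rectangle", cbind(c(1, 5, 5, 1), c(1, 1, 5, 5)))
  r2 <- roi("b", "rectangle", cbind(c(3, 8, 8, 3), c(3, 3, 8, 8)))
  m <- rois_to_label_mask(list(r1, r2), c(10, 10))
  expect_identical(m[5, 5], 2L)  # overlap carries the later label
  expect_identical(m[2, 2], 1L)
  expect_identical(rois_to_label_mask(list(), c(4, 4)), matrix(0L, 4, 4))
  expect_error(rois_to_label_mask(list(r1), c(0, 5)), "positive")
})
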