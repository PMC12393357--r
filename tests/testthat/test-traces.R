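# DF/F conversion, trace extraction, smoothing, replicate averaging

test_that("DF/F follows (F - F0) / max(F0, eps) per pixel", {
  # constant stack -> all zeros
  const <- image_stack(array(42, c(3, 3, 6)))
  expect_true(all(convert_stack_to_dff(const, dff_params(1, 3))$frames == 0))
  # worked value: baseline 10,10,10,10 then 15 -> 0.5
  stk <- image_stack(array(rep(c(10, 10, 10, 10, 15), each = 4), c(2, 2, 5)))
  d <- convert_stack_to_dff(stk, dff_params(1, 4))
  expect_identical(d$frames[1, 1, 5], 0.5)
  expect_true(all(d$frames[, , 1:4] == 0))
  expect_identical(d$dtype, "float32")
  # F0 = 0 uses the epsilon floor: finite, no division error
  z <- array(0, c(1, 1, 3)); z[1, 1, 3] <- 5
  dz <- convert_stack_to_dff(image_stack(z), dff_params(1, 2, epsilon = 1e-3))
  expect_identical(dz$frames[1, 1, 3], 5 / 1e-3)
  expect_true(all(is.finite(dz$frames)))
  # invalid window
  expect_error(convert_stack_to_dff(stk, dff_params(1, 9)), "baseline")
})

test_that("DF/F baseline mean is zero and the transform is scale invariant", {
  set.seed(21)
  fr <- array(runif(6 * 6 * 30, 50, 200), c(6, 6, 30))
  st <- image_stack(fr, dtype = "float32")
  p <- dff_params(1, 10)
  d <- convert_stack_to_dff(st, p)$frames
  bl_mean <- apply(d[, , 1:10], c(1, 2), mean)
  expect_lt(max(abs(bl_mean)), 1e-6)
  for (cst in c(0.5, 3)) {
    d2 <- convert_stack_to_dff(image_stack(fr * cst, dtype = "float32"), p)$frames
    expect_equal(d2, d, tolerance = 1e-9)
  }
})

test_that("extract_traces averages pixels within each ROI", {
  fr <- array(0, c(4, 4, 3))
  fr[, , 1] <- matrix(1:16, 4, 4)
  fr[, , 2] <- 5
  fr[, , 3] <- matrix(1:16, 4, 4) * 2
  st <- image_stack(fr, name = "rec1")
  # 2x2 ROI over rows 1:2, cols 1:2 -> pixels 1,2,5,6 in frame 1
  r_sq <- roi("sq", "rectangle", cbind(c(0, 2, 2, 0), c(0, 0, 2, 2)))
  r_pt <- roi("p", "point", cbind(2, 3))  # col 3, row 4 -> value fr[4,3,]
  tr <- extract_traces(st, list(r_sq, r_pt))
  expect_equal(tr$values["sq" == tr$roi_names, ], c(mean(c(1, 2, 5, 6)), 5,
                                                    2 * mean(c(1, 2, 5, 6))))
  expect_equal(tr$values["p" == tr$roi_names, ], c(fr[4, 3, 1], 5, fr[4, 3, 3]))
  expect_identical(tr$filter, "none")
  expect_identical(tr$source_name, "rec1")
  # uniform region -> constant trace
  u <- image_stack(array(7, c(5, 5, 4)))
  tru <- extract_traces(u, list(r_sq))
  expect_true(all(tru$values == 7))
  # ROI outside the frame errors with its name
  far <- roi("lost", "point", cbind(99, 99))
  expect_error(extract_traces(st, list(far)), "lost")
})

test_that("the pipeline order is convert-then-extract (pinned)", {
  # heterogeneous F0 across pixels makes the two orders differ
  fr <- array(0, c(1, 2, 3))
  fr[1, 1, ] <- c(10, 10, 20)   # dF/F: 0, 0, 1
  fr[1, 2, ] <- c(40, 40, 50)   # dF/F: 0, 0, 0.25
  st <- image_stack(fr)
  r <- roi("both", "rectangle", cbind(c(0, 2, 2, 0), c(0, 0, 1, 1)))
  p <- dff_params(1, 2)
  convert_first <- extract_traces(convert_stack_to_dff(st, p), list(r))$values[1, ]
  expect_equal(convert_first, c(0, 0, mean(c(1, 0.25))))
  # extract-then-convert would instead give (F=35 vs F0=25) -> 0.4
  raw_mean <- extract_traces(st, list(r))$values[1, ]
  extract_first <- (raw_mean - mean(raw_mean[1:2])) / mean(raw_mean[1:2])
  expect_false(isTRUE(all.equal(convert_first[3], extract_first[3])))
})

test_that("gaussian smoothing is a normalized, label-updating filter", {
  set.seed(22)
  v <- matrix(rnorm(2 * 200), 2, 200)
  tr <- trace_matrix(v, c("a", "b"), cbind(c(0, 1), c(0, 1)))
  expect_identical(gaussian_smooth(tr, 0)$values, v)
  expect_identical(gaussian_smooth(tr, 0)$filter, "gaussian(0)")
  # constant trace unchanged for any sigma
  cst <- trace_matrix(matrix(3, 1, 50), "c", cbind(0, 0))
  expect_equal(gaussian_smooth(cst, 4)$values, matrix(3, 1, 50),
               tolerance = 1e-12)
  # unit impulse -> sampled Gaussian kernel, sum 1
  imp <- matrix(0, 1, 101); imp[1, 51] <- 1
  sm <- gaussian_smooth(trace_matrix(imp, "i", cbind(0, 0)), 2)$values[1, ]
  kern <- dnorm(-8:8, sd = 2); kern <- kern / sum(kern)
  expect_equal(sm[(51 - 8):(51 + 8)], kern, tolerance = 1e-9)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  # mean preservation on a long stationary trace
  expect_equal(mean(gaussian_smooth(tr, 3)$values[1, ]), mean(v[1, ]),
               tolerance = 1e-3 * abs(mean(v[1, ])) + 1e-3)
  expect_error(gaussian_smooth(tr, -1), "sigma")
})

test_that("replicate averaging is an elementwise mean with strict checks", {
  m1 <- trace_matrix(matrix(0, 2, 5), c("a", "b"), cbind(c(1, 2), c(1, 2)),
                     source_name = "acq1")
  m2 <- trace_matrix(matrix(2, 2, 5), c("a", "b"), cbind(c(1, 2), c(1, 2)),
                     source_name = "acq2")
  avg <- average_replicates(list(m1, m2))
  expect_true(all(avg$values == 1))
  expect_identical(avg$source_name, "acq1+acq2")
  expect_identical(average_replicates(list(m1, m1))$values, m1$values)
  bad_order <- trace_matrix(matrix(2, 2, 5), c("b", "a"),
                            cbind(c(1, 2), c(1, 2)))
  expect_error(average_replicates(list(m1, bad_order)), "ROI names")
  short <- trace_matrix(matrix(2, 2, 4), c("a", "b"), cbind(c(1, 2), c(1, 2)))
  expect_error(average_replicates(list(m1, short)), "frame count")
  smoothed <- gaussian_smooth(m2, 1)
  expect_error(average_replicates(list(m1, smoothed)), "provenance")
})
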