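test_that("background estimation matches per-pixel statistics", {
  stack <- array(7, dim = c(4, 4, 5))
  expect_equal(estimate_background(stack, "median"), matrix(7, 4, 4))
  # alternating 0 / 100 frames, max
  stack <- array(0, dim = c(3, 3, 6))
  stack[, , c(2, 4, 6)] <- 100
  expect_equal(estimate_background(stack, "max"), matrix(100, 3, 3))
  # moving dark blob over a bright field: median recovers the field
  stack <- array(200, dim = c(10, 10, 11))
  for (i in 1:11) stack[i %% 10 + 1, 5, i] <- 0   # blob transits
  expect_equal(estimate_background(stack, "median"), matrix(200, 10, 10))
  # random stacks vs a per-pixel sort oracle
  set.seed(42)
  stack <- array(sample(0:255, 5 * 5 * 9, TRUE), dim = c(5, 5, 9))
  med <- apply(stack, c(1, 2), function(v) median(v))
  expect_equal(estimate_background(stack, "median"), med)
  expect_warning(estimate_background(stack, "median", window = 3),
                 "single-frame")
})

test_that("centroid is the pixel-coordinate mean of the foreground", {
  m <- matrix(FALSE, 21, 21)
  m[ellipse_mask(21, c(11, 11), 5, 5)] <- TRUE
  expect_equal(centroid(m), c(11, 11))
  m2 <- matrix(FALSE, 5, 5); m2[1, 1] <- TRUE; m2[5, 3] <- TRUE
  expect_equal(centroid(m2), c(3, 2))
  # direct-sum oracle on a random mask, with pixel scaling
  set.seed(7)
  m3 <- matrix(runif(100) < 0.3, 10, 10)
  idx <- which(m3, arr.ind = TRUE)
  expect_equal(centroid(m3, pixel_scale = 0.05),
               c(mean(idx[, 1]), mean(idx[, 2])) * 0.05)
})

test_that("radial profile matches the per-ray scan oracle", {
  m <- ellipse_mask(41, c(21, 21), 15, 6)
  prof <- radial_profile(m, c(21, 21), angular_step = 10)
  oracle <- brute_radial_profile(m, c(21, 21), angular_step = 10)
  expect_equal(prof$radius, oracle$radius)
  # centered disk: constant profile within a pixel
  d <- ellipse_mask(41, c(21, 21), 12, 12)
  pd <- radial_profile(d, c(21, 21), angular_step = 15)
  expect_true(all(abs(pd$radius - 12) <= 1))
  # ellipse maxima at the major-axis angles
  imax <- which.max(prof$radius)
  expect_true(prof$angle[imax] %in% c(0, 180))
  # random blob mask
  set.seed(11)
  rb <- matrix(runif(900) < 0.2, 30, 30)
  expect_equal(radial_profile(rb, c(15, 15), 30)$radius,
               brute_radial_profile(rb, c(15, 15), 30)$radius)
})

test_that("length from profile sums the two opposite maxima", {
  m <- ellipse_mask(61, c(31, 31), 25, 10)
  prof <- radial_profile(m, c(31, 31), angular_step = 2)
  lf <- length_from_profile(prof)
  expect_true(lf$valid)
  expect_equal(lf$length, 50, tolerance = 0.03)
  expect_equal(abs(lf$theta1 - lf$theta2), 180)
  # constant profile -> invalid
  flat <- tibble::tibble(angle = seq(0, 358, 2), radius = 5)
  expect_false(length_from_profile(flat)$valid)
})

test_that("length from profile is rotation-invariant within a step", {
  lens <- sapply(c(0, 0.4, 0.9, 1.4), function(ang) {
    m <- ellipse_mask(61, c(31, 31), 20, 8, angle = ang)
    lf <- length_from_profile(radial_profile(m, c(31, 31), 2))
    lf$length
  })
  expect_lt(max(lens) - min(lens), 2.5)
})

test_that("segment_frame finds the blob and flags hopeless frames", {
  set.seed(3)
  bg <- matrix(0.75, 80, 80)
  frame <- bg + matrix(rnorm(6400, 0, 0.01), 80, 80)
  frame[ellipse_mask(80, c(40, 42), 12, 5)] <-
    frame[ellipse_mask(80, c(40, 42), 12, 5)] - 0.45
  sf <- segment_frame(frame, bg, segmentation_params())
  expect_true(sf$valid)
  cpx <- centroid(sf$mask)
  expect_lt(sqrt(sum((cpx - c(40, 42))^2)), 2)
  # mask area tracks the drawn area; the low maximum-entropy threshold
  # keeps part of the blur skirt, so agreement is coarse, not exact
  expect_lt(abs(sf$area - sum(ellipse_mask(80, c(40, 42), 12, 5))) /
              sum(ellipse_mask(80, c(40, 42), 12, 5)), 1.0)
  # pure-noise frame -> invalid, not an error
  noise <- bg + matrix(rnorm(6400, 0, 0.01), 80, 80)
  expect_false(segment_frame(noise, bg, segmentation_params())$valid)
  # identical frame and background -> invalid
  expect_false(segment_frame(bg, bg, segmentation_params())$valid)
})

test_that("circularity filter rejects stringy dust next to the cell", {
  set.seed(4)
  bg <- matrix(0.75, 80, 80)
  frame <- bg + matrix(rnorm(6400, 0, 0.005), 80, 80)
  blob <- ellipse_mask(80, c(30, 30), 10, 6)
  frame[blob] <- frame[blob] - 0.45
  frame[60:78, 60] <- frame[60:78, 60] - 0.45   # 1 px wide streak
  sf <- segment_frame(frame, bg, segmentation_params(circularity_min = 0.3))
  expect_true(sf$valid)
  cpx <- centroid(sf$mask)
  expect_lt(sqrt(sum((cpx - c(30, 30))^2)), 2.5)
})

test_that("segment_frame is translation-equivariant", {
  set.seed(5)
  base <- matrix(0.75, 90, 90) + matrix(rnorm(8100, 0, 0.008), 90, 90)
  blob <- ellipse_mask(90, c(35, 40), 11, 5)
  f1 <- base; f1[blob] <- f1[blob] - 0.45
  # shift frame and background by (7, -4)
  sh <- function(m, di, dj) {
    out <- matrix(median(m), nrow(m), ncol(m))
    si <- (1 + max(0, di)):(nrow(m) + min(0, di))
    sj <- (1 + max(0, dj)):(ncol(m) + min(0, dj))
    out[si, sj] <- m[si - di, sj - dj]
    out
  }
  bg <- matrix(0.75, 90, 90)
  c1 <- centroid(segment_frame(f1, bg, segmentation_params())$mask)
  c2 <- centroid(segment_frame(sh(f1, 7, -4), sh(bg, 7, -4),
                               segmentation_params())$mask)
  expect_equal(c2 - c1, c(7, -4), tolerance = 0.15)
})

test_that("segment_stack assembles a track with invalid frames flagged", {
  set.seed(6)
  n <- 12
  # the cell must keep moving, or the per-pixel median background would
  # absorb it
  stack <- array(0.75 + rnorm(60 * 60 * n, 0, 0.008), dim = c(60, 60, n))
  for (i in 1:n) {
    if (i == 5) next  # frame 5: cell missing
    b <- ellipse_mask(60, c(14 + 3 * i, 30), 6, 3)
    stack[, , i][b] <- stack[, , i][b] - 0.45
  }
  tr <- segment_stack(stack, segmentation_params(background_window = n),
                      fps = 2, pixel_scale = 0.05)
  expect_s3_class(tr, "tbl_df")
  expect_false(tr$valid[5])
  expect_true(all(tr$valid[-5]))
  expect_equal(diff(tr$x[1:2]), 3 * 0.05, tolerance = 0.3)
})
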