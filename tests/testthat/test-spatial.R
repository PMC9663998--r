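track_from_points <- function(x, y, fps = 2) {
  tr <- tibble::tibble(frame = seq_along(x), t = (seq_along(x) - 1) / fps,
                       x = x, y = y)
  attr(tr, "fps") <- fps
  tr
}

test_that("density maps integrate to exactly 1", {
  # all mass in one cell
  tr <- track_from_points(rep(0.01, 50), rep(0.01, 50))
  dm <- occupancy_density(tr)
  cell_area <- attr(dm, "cell_area")
  expect_equal(max(dm$density), 1 / cell_area)
  expect_equal(sum(dm$density) * cell_area, 1, tolerance = 1e-9)
  # uniform occupancy: density 1/36 per mm^2
  g <- expand.grid(x = seq(-2.95, 2.95, length.out = 56),
                   y = seq(-2.95, 2.95, length.out = 56))
  dmu <- occupancy_density(track_from_points(g$x, g$y))
  expect_equal(unique(round(dmu$density, 9)), round(1 / 36, 9))
  # random tracks always integrate to 1 (property, 10 seeds)
  for (s in 1:10) {
    set.seed(s)
    tr2 <- track_from_points(runif(500, -3, 3), runif(500, -3, 3))
    dm2 <- occupancy_density(tr2)
    expect_equal(sum(dm2$density) * attr(dm2, "cell_area"), 1,
                 tolerance = 1e-9)
  }
})

test_that("out-of-field positions are dropped and counted", {
  tr <- track_from_points(c(0, 0, 10), c(0, 0, 10))
  dm <- occupancy_density(tr)
  expect_equal(attr(dm, "n_dropped"), 1)
  expect_equal(sum(dm$n), 2)
})

test_that("presence frequency is time over area, excluding adhesion", {
  geom <- chamber_geometry(inner_disk = TRUE)
  cres <- crescent_mask(geom)
  tips <- cres$tips
  # 60 s parked on a crescent tip at 2 fps
  tr <- track_from_points(rep(tips[1, 1], 120), rep(tips[1, 2], 120))
  expect_equal(presence_frequency(tr, cres), 60 / cres$area)
  # a region never visited
  other <- region_complement(cres, geom)
  expect_equal(presence_frequency(tr, other), 0)
  # adhesion frames excluded
  adh <- tibble::tibble(start = 0, duration = 30)
  expect_equal(presence_frequency(tr, cres, adh), 30 / cres$area)
  # additivity over disjoint regions: total time is conserved
  expect_equal(presence_frequency(tr, cres) * cres$area +
                 presence_frequency(tr, other) * other$area, 60)
})

test_that("adhesion detection respects the duration cutoff", {
  fps <- 2
  stay <- function(n, x0, y0, jitter = 0.01, seed = 1) {
    set.seed(seed)
    cbind(x0 + rnorm(n, 0, jitter), y0 + rnorm(n, 0, jitter))
  }
  move <- function(n, from, speed = 0.5) {
    cbind(from[1] + speed * (1:n) / fps, rep(from[2], n))
  }
  a <- stay(60, 0, 0)                       # 30 s stationary
  b <- move(40, c(0.2, 0))
  c_ <- stay(18, 4, 0, seed = 2)            # 9 s only
  pts <- rbind(a, b, c_)
  tr <- track_from_points(pts[, 1], pts[, 2], fps = fps)
  ev <- detect_adhesions(tr)
  expect_equal(nrow(ev), 1)
  expect_gte(ev$duration, 29)
  expect_lt(sqrt(ev$x^2 + ev$y^2), 0.05)
  # track shorter than the cutoff: empty result
  expect_equal(nrow(detect_adhesions(track_from_points(1:5 * 0, 1:5 * 0))), 0)
})

test_that("adhesion detection reproduces simulator ground truth", {
  matched <- 0; total <- 0
  for (s in 1:5) {
    bp <- structured_behavior_params()
    rec <- simulate_behavior(bp, chamber_geometry(inner_disk = TRUE),
                             duration = 4000, fps = 4, seed = s)
    truth <- attr(rec, "adhesion_truth")
    truth <- truth[truth$duration >= 12, ]
    ev <- detect_adhesions(rec, min_duration = 10)
    total <- total + nrow(truth)
    for (k in seq_len(nrow(truth))) {
      iou <- sapply(seq_len(nrow(ev)), function(j) {
        a0 <- truth$start[k]; a1 <- a0 + truth$duration[k]
        b0 <- ev$start[j]; b1 <- b0 + ev$duration[j]
        inter <- max(0, min(a1, b1) - max(a0, b0))
        inter / (max(a1, b1) - min(a0, b0))
      })
      if (length(iou) && max(iou) >= 0.8) matched <- matched + 1
    }
  }
  expect_gt(total, 10)
  expect_gte(matched / total, 0.9)
})

test_that("Welch test from summaries reproduces the printed p-values", {
  # identical groups: t = 0, p = 1
  eq <- welch_t_test(5, 1, 10, 5, 1, 10)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  # crescent vs other presence frequencies
  w1 <- welch_t_test(614.9, 136.6, 12, 43.4, 11.1, 12)
  expect_equal(w1$p, 0.0015, tolerance = 0.35)
  expect_lt(w1$p, 0.01)
  # adhering times: not significant
  w2 <- welch_t_test(603.0, 209.2, 18, 411.2, 187.1, 13)
  expect_equal(w2$p, 0.50, tolerance = 0.02)
})

test_that("summary-based Welch agrees with t.test on raw samples", {
  set.seed(17)
  a <- rnorm(14, 10, 3); b <- rnorm(9, 7, 5)
  raw <- welch_t_test_samples(a, b)
  summ <- welch_t_test(mean(a), sd(a), length(a), mean(b), sd(b), length(b),
                       dispersion = "sd")
  expect_equal(summ$t, raw$t, tolerance = 1e-12)
  expect_equal(summ$df, raw$df, tolerance = 1e-12)
  expect_equal(summ$p, raw$p, tolerance = 1e-12)
  # equal dispersions and n: Student df = 2n - 2 exactly
  st <- welch_t_test(3, 1.2, 8, 2, 1.2, 8)
  expect_equal(st$df, 14)
})
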