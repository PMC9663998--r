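norm_track <- function(l, s, fps = 10) {
  tr <- tibble::tibble(l_norm = l, s_norm = s)
  attr(tr, "fps") <- fps
  tr
}

test_that("state classification follows the speed and length cuts", {
  tr <- norm_track(c(1.0, 0.5, 1.5, 1.0, NA), c(1.0, 0.05, 0.1, 0.2, 0.3))
  out <- classify_states(tr)
  expect_equal(out$label,
               c("cone", "droplet", "trumpet", "transition", "invalid"))
})

test_that("state frequencies count non-transition frames and sum to 1", {
  labs <- c("cone", "cone", "trumpet", "droplet", "transition", "invalid",
            rep("cone", 4))
  sf <- state_frequencies(labs)
  expect_equal(sum(sf$fraction), 1)
  expect_equal(sf$fraction[sf$state == "cone"], 6 / 8)
  expect_equal(sf$fraction[sf$state == "droplet"], 1 / 8)
  all_cone <- state_frequencies(rep("cone", 10))
  expect_equal(all_cone$fraction, c(0, 1, 0))
})

test_that("transition vectors are central differences, antisymmetric in time", {
  n <- 61
  tr <- norm_track(seq(1, 2, length.out = n), seq(0, 1, length.out = n),
                   fps = 1)
  v <- transition_vectors(tr, half_window = 0)
  a <- 1 / (n - 1); b <- 1 / (n - 1)
  expect_equal(v$dl[5], 2 * a)
  expect_equal(v$ds[30], 2 * b)
  # constant series -> zero vectors
  v0 <- transition_vectors(norm_track(rep(1, 30), rep(1, 30)), half_window = 0)
  expect_true(all(v0$dl[2:29] == 0))
  # reversing time negates the (inner) vectors
  tr_rev <- norm_track(rev(tr$l_norm), rev(tr$s_norm), fps = 1)
  v_rev <- transition_vectors(tr_rev, half_window = 0)
  expect_equal(v_rev$dl[2:(n - 1)], -rev(v$dl[2:(n - 1)]))
})

test_that("gridded vector field takes per-cell medians and drops rare cells", {
  tr <- norm_track(rep(1.05, 3), rep(0.55, 3))
  tr$dl <- c(1, 3, 2); tr$ds <- c(0, 0, 0)
  g <- grid_vector_field(tr, min_occupancy = 0)
  expect_equal(nrow(g), 1)
  expect_equal(g$dl_med, 2)
  expect_equal(g$l_mid, 1.05)
  # a single stray point among 10^4: occupancy 0.01% < 0.05% cutoff
  set.seed(12)
  n <- 10000
  tr2 <- norm_track(c(rep(1.01, n - 1), 3.55), c(rep(1.01, n - 1), 3.55))
  tr2$dl <- rnorm(n); tr2$ds <- rnorm(n)
  g2 <- grid_vector_field(tr2, min_occupancy = 5e-4)
  expect_false(any(g2$l_mid > 3))
  # against a binning + sort oracle
  set.seed(13)
  tr3 <- norm_track(runif(500, 0, 2), runif(500, 0, 2))
  tr3$dl <- rnorm(500); tr3$ds <- rnorm(500)
  g3 <- grid_vector_field(tr3, min_occupancy = 0)
  cell <- function(v) floor(v / 0.1)
  for (k in sample(nrow(g3), 5)) {
    sel <- cell(tr3$l_norm) == cell(g3$l_mid[k] - 0.05 + 1e-9) &
      cell(tr3$s_norm) == cell(g3$s_mid[k] - 0.05 + 1e-9)
    expect_equal(g3$dl_med[k], median(tr3$dl[sel]))
  }
})

test_that("opposed traversals of one path cancel in the median field", {
  # forward then backward along the same state-field path (identical
  # support so the two passes bin into identical cells)
  lf <- seq(1, 1.5, by = 0.01)
  sf <- seq(1, 0.2, length.out = 51)
  l <- c(lf, rev(lf))
  s <- c(sf, rev(sf))
  tr <- norm_track(l, s, fps = 1)
  v <- transition_vectors(tr, half_window = 0)
  g <- grid_vector_field(v, min_occupancy = 0)
  # interior cells cancel exactly; the two turnaround cells carry
  # unbalanced endpoint counts and are excluded
  interior <- g$l_mid > 1.05 & g$l_mid < 1.45
  expect_true(all(abs(g$dl_med[interior]) < 1e-12))
})

test_that("transition-period margins mask each state's own side", {
  fps <- 1
  labs <- c(rep("cone", 100), rep("trumpet", 100))
  steady <- exclude_transition_periods(labs, fps,
                                       margins = c(droplet = 15, cone = 60,
                                                   trumpet = 30))
  expect_true(all(!steady[41:100]))   # last 60 s of the cone run
  expect_true(all(steady[1:40]))
  expect_true(all(!steady[101:130]))  # first 30 s of the trumpet run
  expect_true(all(steady[131:200]))
  # no switches -> nothing masked; boundary margins truncate gracefully
  expect_true(all(exclude_transition_periods(rep("cone", 50), fps)))
  short <- exclude_transition_periods(c(rep("cone", 5), rep("trumpet", 5)),
                                      fps)
  expect_equal(sum(short), 0)  # everything within a margin
})

test_that("clustering splits well-separated state blobs correctly", {
  set.seed(14)
  n <- 150
  blobs <- rbind(
    cbind(rnorm(n, 1.0, 0.05), rnorm(n, 1.0, 0.05)),   # cone
    cbind(rnorm(n, 0.5, 0.04), rnorm(n, 0.1, 0.03)),   # droplet
    cbind(rnorm(n, 1.5, 0.05), rnorm(n, 0.15, 0.03)))  # trumpet
  truth <- rep(c("cone", "droplet", "trumpet"), each = n)
  tr <- norm_track(blobs[, 1], blobs[, 2])
  cl <- cluster_states(tr, k = 3, downsample = 1)
  expect_equal(cl$cluster_state, truth)
  # k = 1: everything in one cluster
  cl1 <- cluster_states(tr, k = 1, downsample = 1)
  expect_equal(length(unique(cl1$cluster)), 1)
  expect_error(cluster_states(tr[1:15, ], k = 3, downsample = 10), "fewer")
})

test_that("cluster labels are stable under point order and phase", {
  set.seed(15)
  n <- 400
  tr <- norm_track(
    c(rnorm(n, 1, 0.05), rnorm(n, 0.5, 0.05), rnorm(n, 1.5, 0.05)),
    c(rnorm(n, 1, 0.05), rnorm(n, 0.1, 0.03), rnorm(n, 0.15, 0.03)))
  c1 <- cluster_states(tr, downsample = 10, phase = 1)
  c2 <- cluster_states(tr, downsample = 10, phase = 2)
  # same per-blob composition despite different sampled points
  f1 <- table(c1$cluster_state) / nrow(c1)
  f2 <- table(c2$cluster_state) / nrow(c2)
  expect_equal(as.numeric(f1), as.numeric(f2), tolerance = 0.08)
  perm <- sample(nrow(tr))
  c3 <- cluster_states(norm_track(tr$l_norm[perm], tr$s_norm[perm]),
                       downsample = 1)
  c4 <- cluster_states(tr, downsample = 1)
  expect_equal(sort(table(c3$cluster_state)), sort(table(c4$cluster_state)))
})

test_that("clustering of simulated steady states matches rule labels", {
  # droplet dwells are enriched so all three states have steady frames,
  # mirroring the stimulus-triggered droplet recordings used for the
  # computational classification
  bp <- behavior_params(dwell_mean_droplet = 40, dwell_mean_cone = 60,
                        dwell_mean_trumpet = 90)
  rec <- simulate_behavior(bp, duration = 10000, fps = 2, seed = 21)
  tr <- instantaneous_speed(rec)
  tr$valid <- TRUE
  tr <- smooth_track(tr)
  tr <- normalize_track(tr)
  tr <- classify_states(tr)
  steady <- exclude_transition_periods(tr, 2)
  pts <- tr[steady, ]
  cl <- cluster_states(pts, downsample = 10)
  rule <- pts$label[seq(1, nrow(pts), by = 10)][seq_len(nrow(cl))]
  agree <- mean(cl$cluster_state == rule)
  expect_gte(agree, 0.85)
})
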