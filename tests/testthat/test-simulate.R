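test_that("length relaxes in closed form after a state switch", {
  # noiseless droplet-to-cone trace: at t0 + tau the length equals
  # L_droplet + (1 - exp(-1)) (L_cone - L_droplet)
  p <- behavior_params()
  tr <- simulate_deformation_trace("droplet_to_cone", p, noise_sd = 0,
                                   fps = 10, seed = 1)
  tau <- p$tau_droplet_to_cone
  Ld <- p$target_length[["droplet"]]; Lc <- p$target_length[["cone"]]
  i <- which.min(abs(tr$time - tau))
  expect_equal(tr$length[i], Ld + (1 - exp(-1)) * (Lc - Ld),
               tolerance = 1e-9)
})

test_that("recordings are reproducible and confined to the chamber", {
  geom <- chamber_geometry(inner_disk = TRUE)
  r1 <- simulate_behavior(duration = 300, fps = 5, seed = 42,
                          geometry = geom)
  r2 <- simulate_behavior(duration = 300, fps = 5, seed = 42,
                          geometry = geom)
  expect_identical(r1, r2)
  r3 <- simulate_behavior(duration = 300, fps = 5, seed = 43,
                          geometry = geom)
  expect_false(identical(r1$x, r3$x))
  # hard confinement: never outside the outer wall or inside the disk
  expect_true(all(in_free_area(r1$true_x, r1$true_y, geom, margin = -1e-9)))
})

test_that("per-frame series are aligned and states well-formed", {
  rec <- simulate_behavior(duration = 600, fps = 5, seed = 7)
  expect_equal(nrow(rec), 3000)
  expect_true(all(rec$state %in% c("droplet", "cone", "trumpet")))
  expect_true(all(diff(rec$t) > 0))
  expect_true(all(rec$true_length > 0))
  # contraction is the only length discontinuity: outside droplet entries
  # the series moves slowly
  dl <- abs(diff(rec$true_length))
  jumps <- which(dl > 0.05)
  if (length(jumps))
    expect_true(all(rec$state[jumps + 1] == "droplet"))
})

test_that("trumpet orbits have the configured diameter", {
  rec <- simulate_behavior(duration = 120, fps = 10, seed = 5,
                           fixed_state = "trumpet")
  laps <- extract_laps(rec)
  expect_gt(max(laps$lap), 3)
  d <- lap_diameters(laps)
  expect_equal(mean(d$diameter), 1.4, tolerance = 0.02)
})

test_that("occupancy converges to the analytic stationary distribution", {
  # chi-square test of simulated state occupancy against the
  # semi-Markov stationary distribution (visit rate x mean dwell),
  # across seeds; expect no rejections at alpha = 0.01 beyond chance
  pi0 <- stationary_occupancy(behavior_params())
  expect_equal(sum(pi0), 1)
  rejected <- 0
  for (s in 1:8) {
    rec <- simulate_behavior(duration = 30000, fps = 2, seed = s)
    # thin to roughly independent samples (state correlation ~ minutes)
    st <- rec$state[seq(1, nrow(rec), by = 240)]
    obs <- table(factor(st, levels = c("droplet", "cone", "trumpet")))
    ht <- suppressWarnings(chisq.test(obs, p = pi0))
    if (ht$p.value < 0.01) rejected <- rejected + 1
  }
  expect_lte(rejected, 1)
})

test_that("crescent geometry places tips near the closest approach", {
  geom <- chamber_geometry(inner_disk = TRUE)
  tips <- crescent_tips(geom)
  expect_equal(dim(tips), c(2, 2))
  # tips are symmetric about the x axis and lie in the gap channel
  expect_equal(tips[1, 1], tips[2, 1])
  expect_equal(tips[1, 2], -tips[2, 2])
  r <- sqrt(rowSums(tips^2))
  expect_true(all(r < geom$outer_radius))
  expect_true(all(in_free_area(tips[, 1], tips[, 2], geom)))
  # crescent mask area by grid integration vs Monte-Carlo
  cres <- crescent_mask(geom)
  set.seed(1)
  px <- runif(2e5, -2.5, 2.5); py <- runif(2e5, -2.5, 2.5)
  mc <- mean(cres$contains(px, py)) * 25
  expect_equal(cres$area, mc, tolerance = 0.05)
  # a point far from both tips is outside
  expect_false(cres$contains(-2, 0))
  expect_true(cres$contains(tips[1, 1], tips[1, 2]))
})

test_that("structured chambers bias adhesion into the crescents", {
  bp <- structured_behavior_params()
  geom <- chamber_geometry(inner_disk = TRUE)
  rec <- simulate_behavior(bp, geom, duration = 6000, fps = 4, seed = 3)
  at <- attr(rec, "adhesion_truth")
  expect_gt(nrow(at), 3)
  cres <- crescent_mask(geom)
  # event density (events per mm^2) higher inside the crescents
  dens_in <- sum(at$in_crescent) / cres$area
  dens_out <- (sum(!at$in_crescent)) / (free_area(geom) - cres$area)
  expect_gt(dens_in, dens_out)
})

test_that("deformation traces follow their model curves exactly", {
  p <- behavior_params()
  tr <- simulate_deformation_trace("trumpet_to_droplet", p, noise_sd = 0,
                                   fps = 2000, seed = 1)
  amp <- (p$target_length[["trumpet"]] - p$target_length[["droplet"]]) /
    p$target_length[["droplet"]]
  B1 <- amp * p$contraction_B1; B2 <- amp * p$contraction_B2
  i40 <- which.min(abs(tr$time - 40))
  expect_equal(tr$epsilon[i40],
               B1 * exp(-40 / p$contraction_tau1) +
                 B2 * exp(-40 / p$contraction_tau2), tolerance = 1e-12)
  expect_error(simulate_deformation_trace("trumpet_to_droplet", fps = 100),
               "2000")
  expect_error(simulate_deformation_trace("droplet_to_cone", noise_sd = -1),
               "noise_sd")
})

test_that("speed-length coupling is continuous piecewise power law", {
  p <- behavior_params()
  l <- c(0.9, 1, 1.1, 1.25, 1.3, 1.45)
  s <- speed_length_coupling(l, p)
  expect_equal(s[1:2], c(1, 1))
  expect_equal(s[3], 1.1^-6.3)
  expect_equal(s[4], 1.25^-6.3)
  expect_equal(s[5], 1.25^-6.3 * (1.3 / 1.25)^0.2)
  # continuity at the breakpoint
  expect_equal(speed_length_coupling(1.25 + 1e-12, p),
               speed_length_coupling(1.25, p), tolerance = 1e-9)
})
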