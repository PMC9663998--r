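test_that("deformation rate is the relative length change", {
  dr <- deformation_rate(rep(0.5, 10), L0 = 0.5)
  expect_true(all(dr$epsilon == 0))
  expect_equal(deformation_rate(0.75, 0.5)$epsilon, 0.5)
  # round-trip with the trace generator
  tr <- simulate_deformation_trace("droplet_to_trumpet", noise_sd = 0,
                                   fps = 10, seed = 1)
  dr2 <- deformation_rate(tr$length, attr(tr, "L0"), times = tr$time)
  expect_equal(dr2$epsilon, tr$epsilon, tolerance = 1e-12)
})

test_that("elongation start detection finds the line crossing", {
  # piecewise-linear flat-then-ramp: exact breakpoint
  x <- c(rep(2, 120), 2 + 0.05 * (1:200))
  s <- detect_start_elongation_cross(x, fps = 10)
  expect_equal(as.integer(s), 120, tolerance = 1)
  # noisy ramps: within 2 s of the true start, 50 seeds
  errs <- sapply(1:50, function(k) {
    set.seed(k)
    xn <- c(rep(0, 150), 0.06 * (1:300)) + rnorm(450, 0, 0.02)
    sk <- detect_start_elongation_cross(xn, fps = 10)
    abs(attr(sk, "time") - 14.9)
  })
  expect_lt(mean(errs), 2)
  # monotone line: no slope change to find
  expect_error(detect_start_elongation_cross(seq(0, 10, 0.01), fps = 10),
               "slope change")
})

test_that("post-contraction start is the first length minimum", {
  v <- c(5, 3, 1, 0.5, 0.8, 2, 3)
  expect_equal(detect_start_post_contraction(v, fps = 1), 4)
  # plateau minimum: first minimizing index
  v2 <- c(3, 1, 1, 1, 2)
  expect_equal(detect_start_post_contraction(v2, fps = 1), 2)
  # search window truncates
  v3 <- c(5, 4, 3, 2, 1, 0.5, 6)
  expect_equal(detect_start_post_contraction(v3, fps = 1, search_window = 3), 4)
})

test_that("noiseless elongation fits recover tau to 4 significant digits", {
  for (kd in c("droplet_to_cone", "droplet_to_trumpet", "cone_to_trumpet")) {
    p <- behavior_params()
    tau_true <- switch(kd, droplet_to_cone = p$tau_droplet_to_cone,
                       droplet_to_trumpet = p$tau_droplet_to_trumpet,
                       cone_to_trumpet = p$tau_cone_to_trumpet)
    f <- fit_elongation(simulate_deformation_trace(kd, noise_sd = 0,
                                                   fps = 10, seed = 1))
    expect_equal(f$tau, tau_true, tolerance = 1e-4)
  }
  # flat trace: amplitude degenerate
  flat <- deformation_rate(rep(0.5, 100), 0.5, times = seq(-2, 7.9, 0.1))
  expect_error(fit_elongation(flat), "degenerate")
})

test_that("tau recovery from noisy traces is accurate on average", {
  taus <- sapply(1:20, function(s)
    fit_elongation(simulate_deformation_trace("droplet_to_cone",
                                              noise_sd = 0.02, fps = 10,
                                              seed = s))$tau)
  expect_lt(abs(mean(taus) - 16.2) / 16.2, 0.05)
  expect_lt(mean(abs(taus - 16.2)) / 16.2, 0.10)
})

test_that("elongation fits are invariant to uniform length rescaling", {
  tr <- simulate_deformation_trace("cone_to_trumpet", noise_sd = 0.01,
                                   fps = 10, seed = 3)
  f1 <- fit_elongation(tr)
  # epsilon is dimensionless: scaling all lengths leaves it unchanged
  tr2 <- deformation_rate(tr$length * 3.7, attr(tr, "L0") * 3.7,
                          times = tr$time)
  f2 <- fit_elongation(tr2)
  expect_equal(f1$tau, f2$tau, tolerance = 1e-6)
})

test_that("two-mode contraction fit recovers both time scales", {
  f <- fit_contraction(simulate_deformation_trace("trumpet_to_droplet",
                                                  noise_sd = 0, fps = 2000,
                                                  seed = 1))
  expect_equal(f$tau1, 2.1, tolerance = 1e-3)
  expect_equal(f$tau2, 15.6, tolerance = 1e-3)
  expect_lt(f$tau1, f$tau2)
  # noisy: median tau2 within 10% across 20 seeds
  t2s <- sapply(1:20, function(s)
    fit_contraction(simulate_deformation_trace("trumpet_to_droplet",
                                               noise_sd = 0.02, fps = 2000,
                                               seed = s))$tau2)
  expect_lt(abs(median(t2s) - 15.6) / 15.6, 0.10)
})

test_that("two-mode residual never exceeds the single-mode residual", {
  # genuinely single-exponential input: nested models
  tt <- seq(0, 50, 0.5)
  tr <- deformation_rate(0.25 * (1 + 2 * exp(-tt / 8)), 0.25, times = tt)
  f <- suppressWarnings(fit_contraction(tr))
  expect_lte(f$rss, f$single$rss + 1e-12)
  # and on noisy two-mode traces
  for (s in 1:5) {
    tr2 <- simulate_deformation_trace("trumpet_to_droplet", noise_sd = 0.02,
                                      fps = 2000, seed = s)
    f2 <- fit_contraction(tr2)
    expect_lte(f2$rss, f2$single$rss + 1e-12)
  }
})

test_that("power-law fits recover the piecewise exponents", {
  # exact power-law data
  l <- seq(1, 1.45, by = 0.001)
  s <- ifelse(l <= 1.25, l^-6.3, 1.25^-6.3 * (l / 1.25)^0.2)
  pf <- fit_power_laws(l, s)
  td <- tidy(pf)
  expect_equal(td$exponent[1], -6.3, tolerance = 1e-6)
  expect_equal(td$exponent[2], 0.2, tolerance = 1e-6)
  # constant speed: exponent 0
  pf0 <- fit_power_laws(seq(1, 1.4, 0.01), rep(2, 41))
  expect_equal(tidy(pf0)$exponent[1], 0)
})

test_that("tidy and glance methods expose fit summaries", {
  f <- fit_elongation(simulate_deformation_trace("droplet_to_cone",
                                                 noise_sd = 0.01, fps = 10,
                                                 seed = 2))
  td <- generics::tidy(f)
  expect_equal(td$term[1:2], c("A", "tau"))
  expect_true(all(is.finite(td$estimate)))
  gl <- generics::glance(f)
  expect_true(gl$rss >= 0)
  fc <- fit_contraction(simulate_deformation_trace("trumpet_to_droplet",
                                                   noise_sd = 0.01,
                                                   fps = 2000, seed = 2))
  expect_equal(generics::tidy(fc)$term, c("B1", "tau1", "B2", "tau2"))
  expect_gte(generics::glance(fc)$tau_ratio, 1.5)
})
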