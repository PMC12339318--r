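test_that("single-exponential phasors trace the universal semicircle", {
  expect_equal(unname(single_exp_phasor(0)), cbind(1, 0), ignore_attr = TRUE)

  # omega*tau = 1 lands at (0.5, 0.5); tau = 1/(2 pi 76 MHz) ~ 2094.15 ps
  tau_unit <- 1e12 / phasor_omega()
  expect_equal(tau_unit, 2094.15, tolerance = 1e-5)
  p <- single_exp_phasor(tau_unit)
  expect_equal(unname(p[1, ]), c(0.5, 0.5), tolerance = 1e-12)

  # every lifetime in [0, 1e4] ps lies on the circle centered (0.5, 0), r = 1/2
  taus <- seq(0, 1e4, length.out = 501)
  gs <- single_exp_phasor(taus)
  radii <- sqrt((gs[, "G"] - 0.5)^2 + gs[, "S"]^2)
  expect_lt(max(abs(radii - 0.5)), 1e-12)

  # long-lifetime limit approaches (0, 0)
  far <- single_exp_phasor(1e9)
  expect_lt(sqrt(sum(far^2)), 1e-3)

  expect_error(single_exp_phasor(-5), "non-negative")
})

test_that("the discrete transform matches the analytic form and is intensity-invariant", {
  # delta decay: all counts at (essentially) t = 0 -> (G, S) = (1, 0)
  h <- numeric(2048); h[1] <- 500
  gs <- phasor_transform(h, bin_width_ps = 0.001)
  expect_lt(max(abs(unname(gs) - c(1, 0))), 1e-5)

  # noiseless monoexponentials, fine bins, window >= 10 tau: within 1e-3
  for (tau in c(200, 500, 1000, 1300)) {
    cfg <- cfg_fine()
    mu <- expected_decay(mixture(tau, 1), cfg, 1e6)
    gs <- phasor_transform(mu, bin_width_ps = cfg$bin_width_ps)
    th <- single_exp_phasor(tau)
    expect_lt(abs(gs["G"] - th[1, "G"]), 1e-3)
    expect_lt(abs(gs["S"] - th[1, "S"]), 1e-3)
  }

  # nearly flat decay over the window (tau >> window) heads toward (0, 0)
  cfg <- cfg_fine()
  mu <- expected_decay(mixture(1e7, 1), cfg, 1e6)
  gs <- phasor_transform(mu, bin_width_ps = cfg$bin_width_ps)
  expect_lt(abs(gs["G"]), 0.01)

  # multiplying a decay by any positive constant leaves (G, S) unchanged
  cfg <- cfg_small()
  mu <- expected_decay(mixture_cancerous(), cfg, 4e3)
  g1 <- phasor_transform(mu, bin_width_ps = cfg$bin_width_ps)
  for (c in c(1e-3, 7, 1e5)) {
    expect_equal(phasor_transform(mu * c, bin_width_ps = cfg$bin_width_ps),
                 g1, tolerance = 1e-14)
  }

  expect_error(phasor_transform(numeric(16), bin_width_ps = 50), "zero total")
})

test_that("mixture phasors lie on the chord at intensity-fraction weights", {
  cfg <- cfg_fine()
  taus <- c(500, 2500)
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1, 0.05, 0.95)
    mix <- mixture(taus, c(a, 1 - a))
    gs_mix <- phasor_transform(expected_decay(mix, cfg, 1e6),
                               bin_width_ps = cfg$bin_width_ps)
    # discrete component phasors and discrete intensity fractions
    d1 <- expected_decay(mixture(taus[1], 1), cfg, 1)
    d2 <- expected_decay(mixture(taus[2], 1), cfg, 1)
    g1 <- phasor_transform(d1, bin_width_ps = cfg$bin_width_ps)
    g2 <- phasor_transform(d2, bin_width_ps = cfg$bin_width_ps)
    # intensity fractions: a_i * integral of exp(-t/tau_i) over the window
    w1 <- a * sum(exp(-bin_centers_ps(cfg) / taus[1]))
    w2 <- (1 - a) * sum(exp(-bin_centers_ps(cfg) / taus[2]))
    f1 <- w1 / (w1 + w2)
    expect_lt(max(abs(gs_mix - (f1 * g1 + (1 - f1) * g2))), 1e-6)
    # and against the closed-form chord (continuous fractions a_i tau_i)
    th <- single_exp_phasor(taus)
    fc <- a * taus[1] / (a * taus[1] + (1 - a) * taus[2])
    chord <- fc * th[1, ] + (1 - fc) * th[2, ]
    expect_lt(max(abs(gs_mix - chord)), 1e-3)
  }
})

test_that("phase and modulation lifetimes invert the phasor position", {
  tl <- phasor_to_lifetime(0.5, 0.5)
  expect_equal(unname(tl[1, "tau_phase_ps"]), 2094.15, tolerance = 1e-5)
  expect_equal(unname(tl[1, "tau_mod_ps"]), 2094.15, tolerance = 1e-5)

  # on-circle points: the two lifetimes agree
  for (tau in c(100, 900, 2200, 5000)) {
    p <- single_exp_phasor(tau)
    tl <- phasor_to_lifetime(p[1, "G"], p[1, "S"])
    expect_equal(unname(tl[1, "tau_phase_ps"]), tau, tolerance = 1e-9)
    expect_equal(unname(tl[1, "tau_mod_ps"]), tau, tolerance = 1e-9)
  }

  # inside-circle mixture points: tau_phase < tau_mod
  th <- single_exp_phasor(c(400, 3000))
  set.seed(8)
  for (i in 1:20) {
    f <- runif(1, 0.1, 0.9)
    p <- f * th[1, ] + (1 - f) * th[2, ]
    tl <- phasor_to_lifetime(p["G"], p["S"])
    expect_lt(tl[1, "tau_phase_ps"], tl[1, "tau_mod_ps"])
  }

  expect_error(phasor_to_lifetime(-0.1, 0.5), "G <= 0")
})

test_that("calibration maps a reference onto its theoretical phasor", {
  cfg <- cfg_small(c(6, 6))
  cube <- simulate_cube(layout_uniform("cancerous", c(6, 6)),
                        default_region_specs(5e4), cfg, seed = 4)
  pm <- phasor_transform(cube)

  # identity when the reference already sits at its theoretical point
  th <- single_exp_phasor(1500)
  pm_id <- calibrate_phasor(pm, th[1, ], 1500)
  expect_equal(pm_id$G, pm$G, tolerance = 1e-12)
  expect_equal(pm_id$modulation_correction, 1, tolerance = 1e-12)
  expect_true(pm_id$calibrated)

  # a coarse-binned monoexponential, calibrated against its own known
  # lifetime, lands on the universal circle within 1e-3
  mono <- simulate_cube(layout_uniform("cancerous", c(6, 6)),
                        list(cancerous = region_spec(
                          "cancerous", mixture(1200, 1), 1e6)),
                        cfg, seed = 6)
  pmm <- phasor_transform(mono)
  ref <- c(mean(pmm$G), mean(pmm$S))
  cal <- calibrate_phasor(pmm, ref, 1200)
  ctr <- c(mean(cal$G), mean(cal$S))
  expect_lt(max(abs(ctr - single_exp_phasor(1200)[1, ])), 1e-3)
  expect_gt(cal$modulation_correction, 0)

  expect_error(calibrate_phasor(pm, c(0, 0), 1000), "zero modulus")
})

test_that("phasor clustering recovers lifetime populations in descending order", {
  cfg <- acquisition_config(image_size = c(30, 30))
  specs <- list(
    peritumoral = region_spec("peritumoral", mixture(500, 1), 3000),
    necrotic    = region_spec("necrotic", mixture(1500, 1), 3000),
    cancerous   = region_spec("cancerous", mixture(3000, 1), 3000))
  lay <- layout_bands(c("peritumoral", "necrotic", "cancerous"), c(30, 30))
  cube <- simulate_cube(lay, specs, cfg, seed = 12)
  pm <- phasor_transform(cube)
  img <- fit_cube(cube, fit_background = FALSE)

  expect_error(cluster_phasor(pm, k = 1e6, seed = 1), "exceeds")

  one <- cluster_phasor(pm, k = 1, seed = 1)
  expect_equal(unique(na.omit(as.vector(one$labels))), 1L)

  cl <- cluster_phasor(pm, k = 3, seed = 1, image = img)
  # descending cluster mean lifetimes (cluster 1 = longest)
  expect_equal(order(cl$cluster_mean_tau_m_ps, decreasing = TRUE), 1:3)
  # recovery of the ground-truth bands
  ari <- mclust::adjustedRandIndex(as.vector(cl$labels), as.vector(lay))
  expect_gte(ari, 0.95)
})

test_that("segmentation images color clusters distinctly on black background", {
  labels <- matrix(NA_integer_, 4, 6)
  labels[, 1:2] <- 1L; labels[, 3:4] <- 2L; labels[1:2, 5:6] <- 3L
  cl <- structure(list(labels = labels, centers = matrix(0, 3, 2),
                       cluster_mean_tau_m_ps = c(3, 2, 1), k = 3),
                  class = "phasor_clusters")
  img <- segment_image(cl)
  expect_equal(dim(img), c(4, 6, 3))
  cols <- unique(apply(matrix(img, ncol = 3), 1, paste, collapse = ","))
  expect_equal(length(cols), 4)  # 3 cluster colors + black
  expect_equal(img[3, 5, ], c(0, 0, 0))  # unmasked -> black

  one <- structure(list(labels = matrix(1L, 2, 2),
                        centers = matrix(0, 1, 2),
                        cluster_mean_tau_m_ps = 1, k = 1),
                   class = "phasor_clusters")
  im1 <- segment_image(one)
  expect_equal(length(unique(apply(matrix(im1, ncol = 3), 1,
                                   paste, collapse = ","))), 1)
})
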