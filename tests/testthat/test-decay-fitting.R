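test_that("mean lifetime is the amplitude-weighted convex combination", {
  expect_equal(mean_lifetime(biexp_params(1, 2000, 0, 1000)), 2000)
  expect_equal(mean_lifetime(biexp_params(0.5, 1000, 0.5, 3000)), 2000)
  expect_equal(mean_lifetime(biexp_params(0.2, 600, 0.8, 2600)), 2200)

  # convexity property over random parameter draws
  set.seed(1)
  for (i in 1:50) {
    a <- runif(2); tau <- sort(runif(2, 100, 5000))
    p <- biexp_params(a[1], tau[1], a[2], tau[2])
    tm <- mean_lifetime(p)
    expect_gte(tm, tau[1]); expect_lte(tm, tau[2])
  }
  # canonical ordering is enforced by swap
  p <- biexp_params(0.3, 2400, 0.7, 800)
  expect_lte(p$tau1_ps, p$tau2_ps)
  expect_equal(mean_lifetime(p), mean_lifetime(biexp_params(0.7, 800, 0.3, 2400)))
  expect_error(biexp_params(0, 1000, 0, 2000))
})

test_that("noiseless biexponential decays are recovered within 1%", {
  cfg <- cfg_small()
  truth <- mixture(c(800, 2400), c(0.3, 0.7))
  mu <- expected_decay(truth, cfg, 1e5)
  fr <- fit_pixel(mu, bin_width_ps = cfg$bin_width_ps)
  expect_true(fr$converged)
  expect_equal(fr$params$tau1_ps, 800, tolerance = 0.01)
  expect_equal(fr$params$tau2_ps, 2400, tolerance = 0.01)
  expect_equal(fr$tau_m_ps, 1920, tolerance = 0.01)

  # intensity scale equivariance: scaling counts leaves lifetimes unchanged
  fr10 <- fit_pixel(mu * 10, bin_width_ps = cfg$bin_width_ps)
  expect_equal(fr10$tau_m_ps, fr$tau_m_ps, tolerance = 1e-6)
  expect_equal(fr10$params$a2 / fr$params$a2, 10, tolerance = 1e-3)

  # swap-canonicalization: exchanging the components in the init changes nothing
  fra <- fit_pixel(mu, bin_width_ps = cfg$bin_width_ps,
                   init = biexp_params(0.5, 600, 0.5, 3000))
  frb <- fit_pixel(mu, bin_width_ps = cfg$bin_width_ps,
                   init = biexp_params(0.5, 3000, 0.5, 600))
  expect_equal(fra$tau_m_ps, frb$tau_m_ps, tolerance = 1e-6)
})

test_that("fits under a measured instrument response recover the decay", {
  cfg <- cfg_small()
  truth <- mixture(c(800, 2400), c(0.3, 0.7))
  mu <- expected_decay(truth, cfg, 1e5, irf_fwhm_ps = 400)
  irf <- flimpipe:::gaussian_irf_kernel(400, cfg$bin_width_ps)
  fr <- fit_pixel(mu, bin_width_ps = cfg$bin_width_ps, irf = irf)
  expect_true(fr$converged)
  expect_equal(fr$tau_m_ps, 1920, tolerance = 0.02)
})

test_that("dim pixels are masked rather than fitted", {
  cfg <- cfg_small()
  fr <- fit_pixel(numeric(cfg$n_bins), bin_width_ps = cfg$bin_width_ps)
  expect_true(fr$masked)
  expect_false(fr$converged)
  expect_true(is.na(fr$tau_m_ps))
  # just below vs just above the photon threshold
  mu <- expected_decay(mixture(1500, 1), cfg, 99)
  expect_true(fit_pixel(round(mu), bin_width_ps = cfg$bin_width_ps,
                        threshold = 100)$masked)
  mu <- expected_decay(mixture(1500, 1), cfg, 5000)
  expect_false(fit_pixel(round(mu), bin_width_ps = cfg$bin_width_ps)$masked)
})

test_that("cube fitting maps regions, masks zeros and tightens with photons", {
  cfg <- cfg_small()
  specs <- default_region_specs(4000)
  lay <- layout_halfplane("cancerous", "peritumoral", c(12, 12))
  cube <- simulate_cube(lay, specs, cfg, seed = 5)
  img <- fit_cube(cube)
  expect_true(all(img$mask))
  expect_equal(dim(img$tau_m_map), c(12, 12))
  expect_equal(img$intensity_map, apply(cube$counts, c(2, 3), sum))

  # region separation: means differ by far more than 1000 ps by design
  mc <- mean(img$tau_m_map[lay == "cancerous"])
  mp <- mean(img$tau_m_map[lay == "peritumoral"])
  expect_gt(mc - mp, 1000)

  # all-zero cube -> fully masked image
  zero <- simulate_cube(layout_uniform("background", c(4, 4)),
                        specs, cfg, seed = 1)
  imgz <- fit_cube(zero)
  expect_false(any(imgz$mask))
  expect_equal(nrow(imgz$fits), 0)

  # estimator variance shrinks as the photon budget grows
  sd_at <- function(photons, seed) {
    sp <- default_region_specs(photons)
    cb <- simulate_cube(layout_uniform("cancerous", c(10, 10)), sp, cfg, seed)
    sd(fit_cube(cb)$tau_m_map)
  }
  expect_lt(sd_at(1e4, 3), sd_at(1e3, 3))
})

test_that("spatial binning pools k x k neighborhoods before fitting", {
  cfg <- cfg_small()
  cube <- simulate_cube(layout_uniform("cancerous", c(8, 8)),
                        default_region_specs(500), cfg, seed = 2)
  b <- bin_cube(cube, 2)
  expect_equal(dim(b$counts), c(cfg$n_bins, 4, 4))
  expect_equal(sum(b$counts), sum(cube$counts))
  expect_equal(b$counts[, 1, 1],
               cube$counts[, 1, 1] + cube$counts[, 2, 1] +
                 cube$counts[, 1, 2] + cube$counts[, 2, 2])
  img <- fit_cube(cube, binning = 2)
  expect_equal(dim(img$tau_m_map), c(4, 4))
})

test_that("lifetime histograms cover the display range and clamp outliers", {
  mk_img <- function(vals) {
    m <- matrix(vals, nrow = 2)
    structure(list(tau_m_map = m, intensity_map = m * 0 + 1,
                   mask = !is.na(m),
                   fits = data.frame()), class = "lifetime_image")
  }
  h <- lifetime_histogram(mk_img(rep(1500, 4)), c(500, 3500), 30)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(sum(h$counts), 4)

  # out-of-range values accumulate in the edge bins
  h2 <- lifetime_histogram(mk_img(c(100, 200, 4000, 9000)), c(500, 3500), 30)
  expect_equal(h2$counts[1], 2)
  expect_equal(h2$counts[30], 2)

  # empty mask -> empty-histogram signal
  h3 <- lifetime_histogram(mk_img(rep(NA_real_, 4)))
  expect_true(h3$empty)

  # two-region synthetic cube yields a bimodal histogram near 900 / 2200 ps
  cfg <- cfg_small()
  cube <- simulate_cube(layout_halfplane("cancerous", "peritumoral", c(12, 12)),
                        default_region_specs(5000), cfg, seed = 9)
  h4 <- lifetime_histogram(fit_cube(cube), c(500, 3500), 30)
  lo <- h4$mids_ps < 1500; hi <- !lo
  expect_gt(max(h4$counts[lo]), 0)
  expect_gt(max(h4$counts[hi]), 0)
  expect_lt(abs(h4$mids_ps[lo][which.max(h4$counts[lo])] - 900), 400)
  expect_lt(abs(h4$mids_ps[hi][which.max(h4$counts[hi])] - 2200), 400)
})

test_that("recovered lifetimes stay within 5% across the 700-2500 ps range", {
  cfg <- cfg_small()
  set.seed(101)
  for (tm_true in c(700, 1600, 2500)) {
    a2 <- (tm_true - 600) / 2000
    mix <- mixture(c(600, 2600), c(1 - a2, a2))
    mu <- expected_decay(mix, cfg, 1e4)
    tm <- replicate(30, fit_pixel(rpois(length(mu), mu),
                                  bin_width_ps = cfg$bin_width_ps)$tau_m_ps)
    expect_lt(abs(median(tm) - tm_true) / tm_true, 0.05)
  }
})
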