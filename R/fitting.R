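#' Biexponential decay parameters
#'
#' Canonical container for the four parameters of the per-pixel decay model
#' I(t) = a1 exp(-t/tau1) + a2 exp(-t/tau2). Components are stored in
#' canonical order tau1 <= tau2 (swapped on construction if needed).
#'
#' @param a1,a2 non-negative amplitudes (a1 + a2 > 0).
#' @param tau1_ps,tau2_ps positive component lifetimes, ps.
#' @return A `biexp_params` object.
#' @export
biexp_params <- function(a1, tau1_ps, a2, tau2_ps) {
  stopifnot(a1 >= 0, a2 >= 0, a1 + a2 > 0, tau1_ps > 0, tau2_ps > 0)
  if (tau1_ps > tau2_ps) {
    tmp <- c(a1, tau1_ps); a1 <- a2; tau1_ps <- tau2_ps
    a2 <- tmp[1]; tau2_ps <- tmp[2]
  }
  structure(list(a1 = a1, tau1_ps = tau1_ps, a2 = a2, tau2_ps = tau2_ps),
            class = "biexp_params")
}

#' Amplitude-weighted mean lifetime
#'
#' The mean lifetime tau_m = (a1 tau1 + a2 tau2) / (a1 + a2), the per-pixel
#' summary rendered in pseudo-colored lifetime images. It is a convex
#' combination of the component lifetimes, so it always lies between them.
#'
#' @param params a [biexp_params()].
#' @return Mean lifetime in ps.
#' @examples
#' mean_lifetime(biexp_params(0.2, 600, 0.8, 2600))  # 2200
#' @export
mean_lifetime <- function(params) {
  stopifnot(inherits(params, "biexp_params"))
  if (params$a1 + params$a2 <= 0) stop("undefined mean: a1 + a2 = 0")
  (params$a1 * params$tau1_ps + params$a2 * params$tau2_ps) /
    (params$a1 + params$a2)
}

# model and analytic jacobian on the raw-count scale;
# p = (a1, tau1, a2, tau2, bg), t in ps
biexp_model <- function(p, t) {
  p[5] + p[1] * exp(-t / p[2]) + p[3] * exp(-t / p[4])
}

biexp_jacobian <- function(p, t) {
  e1 <- exp(-t / p[2]); e2 <- exp(-t / p[4])
  cbind(e1, p[1] * t * e1 / p[2]^2, e2, p[3] * t * e2 / p[4]^2, 1)
}

default_fit_bounds <- function() {
  list(lower = c(a1 = 0, tau1 = 50, a2 = 0, tau2 = 50, bg = 0),
       upper = c(a1 = Inf, tau1 = 1e4, a2 = Inf, tau2 = 1e4, bg = Inf))
}

#' Fit a biexponential decay to one pixel's histogram
#'
#' Weighted least squares (Neyman weights, var ~ max(counts, 1)) with
#' Levenberg-Marquardt, fitting amplitudes a1, a2, lifetimes tau1, tau2 and a
#' constant background. Initialization is method-of-moments: the empirical
#' mean photon delay seeds tau1 at 0.5x and tau2 at 1.5x, with equal
#' amplitudes. After convergence the components are swapped into canonical
#' tau1 <= tau2 order, so the fit is invariant to exchanging the two
#' components' initialization.
#'
#' Pixels with fewer than `threshold` photons carry too little information
#' for a 5-parameter fit and are reported as masked, not fitted.
#'
#' @param decay a [decay_histogram()], or a numeric count vector (then
#'   `bin_width_ps` must be given).
#' @param bin_width_ps bin width in ps when `decay` is a bare vector.
#' @param irf optional instrument-response histogram (numeric vector, same
#'   binning); the model is convolved with it before comparison.
#' @param init optional [biexp_params()] starting point.
#' @param bounds list with `lower`/`upper` vectors over
#'   (a1, tau1, a2, tau2, bg); defaults cover 50-10000 ps.
#' @param threshold minimum total photon count for fitting (default 100).
#' @param fit_background fit a constant offset (default TRUE); set FALSE to
#'   pin the background at 0.
#' @return A `fit_result`: `params`, `tau_m_ps`, `background`,
#'   `reduced_chi_square`, `converged`, `n_photons`, `masked`.
#' @export
fit_pixel <- function(decay, bin_width_ps = NULL, irf = NULL, init = NULL,
                      bounds = default_fit_bounds(), threshold = 100,
                      fit_background = TRUE) {
  if (inherits(decay, "decay_histogram")) {
    counts <- decay$counts
    bin_width_ps <- decay$bin_width_ps
  } else {
    counts <- as.numeric(decay)
    if (is.null(bin_width_ps)) stop("bin_width_ps required for a bare vector")
  }
  n <- length(counts)
  n_photons <- sum(counts)
  if (n_photons < threshold) {
    return(structure(list(params = NULL, tau_m_ps = NA_real_,
                          background = NA_real_,
                          reduced_chi_square = NA_real_, converged = FALSE,
                          n_photons = n_photons, masked = TRUE),
                     class = "fit_result"))
  }
  t <- (seq_len(n) - 0.5) * bin_width_ps
  w <- 1 / sqrt(pmax(counts, 1))

  if (!is.null(irf)) {
    irf <- irf / sum(irf)
    i0 <- which.max(irf)  # IRF peak defines t = 0 of the decay
    predict_fn <- function(p) {
      full <- stats::convolve(biexp_model(p, t) - p[5], rev(irf),
                              type = "open")
      full[i0:(i0 + n - 1)] + p[5]
    }
    jac_fn <- NULL  # numeric jacobian under convolution
  } else {
    predict_fn <- function(p) biexp_model(p, t)
    jac_fn <- function(p) -w * biexp_jacobian(p, t)
  }

  if (is.null(init)) {
    tbar <- sum(t * counts) / n_photons
    tau1_0 <- max(bounds$lower[2], min(0.5 * tbar, bounds$upper[2]))
    tau2_0 <- max(bounds$lower[4], min(1.5 * tbar, bounds$upper[4]))
    s12 <- sum(exp(-t / tau1_0)) + sum(exp(-t / tau2_0))
    a0 <- n_photons / s12
    p0 <- c(a0, tau1_0, a0, tau2_0, 0)
  } else {
    p0 <- c(init$a1, init$tau1_ps, init$a2, init$tau2_ps, 0)
  }
  lower <- bounds$lower; upper <- bounds$upper
  if (!fit_background) upper[5] <- 1e-12

  fit <- minpack.lm::nls.lm(
    par = p0,
    lower = lower, upper = upper,
    fn = function(p) w * (counts - predict_fn(p)),
    jac = jac_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200))

  p <- fit$par
  params <- biexp_params(p[1], p[2], p[3], p[4])
  dof <- max(n - length(p0), 1)
  structure(list(params = params,
                 tau_m_ps = mean_lifetime(params),
                 background = p[5],
                 reduced_chi_square = fit$deviance / dof,
                 converged = fit$info %in% 1:3,
                 n_photons = n_photons, masked = FALSE),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (x$masked) {
    cat(sprintf("fit_result: masked (%.0f photons below threshold)\n",
                x$n_photons))
  } else {
    cat(sprintf(
      "fit_result: tau_m %.1f ps (a1 %.3g tau1 %.1f | a2 %.3g tau2 %.1f), chi2_red %.3f, %s\n",
      x$tau_m_ps, x$params$a1, x$params$tau1_ps, x$params$a2,
      x$params$tau2_ps, x$reduced_chi_square,
      if (x$converged) "converged" else "NOT converged"))
  }
  invisible(x)
}

#' Spatially bin a cube (sum of k x k neighborhoods)
#'
#' Optional pre-fit binning that trades resolution for photons per pixel.
#'
#' @param cube a `tcspc_cube`.
#' @param k integer binning factor; trailing rows/cols not filling a full
#'   k x k block are dropped.
#' @return A binned `tcspc_cube`.
#' @export
bin_cube <- function(cube, k) {
  stopifnot(inherits(cube, "tcspc_cube"), k >= 1)
  k <- as.integer(k)
  if (k == 1L) return(cube)
  d <- dim(cube$counts)
  nr <- d[2] %/% k; nc <- d[3] %/% k
  out <- array(0, dim = c(d[1], nr, nc))
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      block <- cube$counts[, ((r - 1) * k + 1):(r * k),
                           ((c - 1) * k + 1):(c * k), drop = FALSE]
      out[, r, c] <- rowSums(block, dims = 1)
    }
  }
  layout <- cube$layout[seq(1, nr * k, by = k), seq(1, nc * k, by = k),
                        drop = FALSE]
  cfg <- cube$config; cfg$image_size <- c(nr, nc)
  structure(list(counts = out, config = cfg, layout = layout),
            class = "tcspc_cube")
}

#' Fit every pixel of a TCSPC cube
#'
#' Applies [fit_pixel()] across the image and assembles the mean-lifetime
#' map, the intensity (total counts) map and the analyzed-pixel mask.
#'
#' @param cube a `tcspc_cube` (from [simulate_cube()] or [read_cube()]).
#' @param threshold minimum photons per pixel (default 100); dimmer pixels
#'   are masked out.
#' @param irf optional instrument-response vector passed to [fit_pixel()].
#' @param binning optional k x k pre-fit spatial binning (default 1 = off).
#' @param fit_background forwarded to [fit_pixel()].
#' @return A `lifetime_image`: `tau_m_map`, `intensity_map`, `mask`
#'   (matrices), plus a per-pixel `fits` data.frame with columns row, col,
#'   a1, tau1_ps, a2, tau2_ps, tau_m_ps, bg, chi2_red, n_photons, converged.
#' @export
fit_cube <- function(cube, threshold = 100, irf = NULL, binning = 1,
                     fit_background = TRUE) {
  stopifnot(inherits(cube, "tcspc_cube"))
  if (is.null(cube$config)) stop("cube is missing acquisition metadata")
  if (binning > 1) cube <- bin_cube(cube, binning)
  d <- dim(cube$counts)
  nr <- d[2]; nc <- d[3]
  bw <- cube$config$bin_width_ps
  tau_m <- matrix(NA_real_, nr, nc)
  intensity <- matrix(0, nr, nc)
  mask <- matrix(FALSE, nr, nc)
  rows <- vector("list", nr * nc)
  i <- 0L
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      counts <- cube$counts[, r, c]
      intensity[r, c] <- sum(counts)
      fr <- fit_pixel(counts, bin_width_ps = bw, irf = irf,
                      threshold = threshold,
                      fit_background = fit_background)
      if (!fr$masked) {
        tau_m[r, c] <- fr$tau_m_ps
        mask[r, c] <- TRUE
        i <- i + 1L
        rows[[i]] <- data.frame(
          row = r, col = c, a1 = fr$params$a1, tau1_ps = fr$params$tau1_ps,
          a2 = fr$params$a2, tau2_ps = fr$params$tau2_ps,
          tau_m_ps = fr$tau_m_ps, bg = fr$background,
          chi2_red = fr$reduced_chi_square, n_photons = fr$n_photons,
          converged = fr$converged)
      }
    }
  }
  fits <- if (i > 0) do.call(rbind, rows[seq_len(i)]) else
    data.frame(row = integer(), col = integer(), a1 = numeric(),
               tau1_ps = numeric(), a2 = numeric(), tau2_ps = numeric(),
               tau_m_ps = numeric(), bg = numeric(), chi2_red = numeric(),
               n_photons = numeric(), converged = logical())
  structure(list(tau_m_map = tau_m, intensity_map = intensity, mask = mask,
                 fits = fits, config = cube$config, layout = cube$layout),
            class = "lifetime_image")
}

#' @export
print.lifetime_image <- function(x, ...) {
  cat(sprintf(
    "lifetime_image: %dx%d, %d/%d pixels fitted, mean tau_m %.1f ps\n",
    nrow(x$tau_m_map), ncol(x$tau_m_map), sum(x$mask), length(x$mask),
    mean(x$tau_m_map[x$mask])))
  invisible(x)
}

#' Lifetime distribution histogram
#'
#' Pixel counts per mean-lifetime bin over the display range (default
#' 500-3500 ps, the range used for pseudo-colored rendering). Values outside
#' the range are clamped into the edge bins, matching how the rendering
#' saturates; the unclamped values stay available in the image's `fits`
#' table.
#'
#' @param image a `lifetime_image`.
#' @param range `c(low, high)` display range in ps, low < high.
#' @param n_bins number of histogram bins (default 30).
#' @return List with `breaks_ps`, `mids_ps`, `counts`.
#' @export
lifetime_histogram <- function(image, range = c(500, 3500), n_bins = 30) {
  stopifnot(inherits(image, "lifetime_image"), range[1] < range[2])
  vals <- image$tau_m_map[image$mask]
  if (length(vals) == 0)
    return(list(breaks_ps = seq(range[1], range[2], length.out = n_bins + 1),
                mids_ps = NULL, counts = integer(n_bins), empty = TRUE))
  vals <- pmin(pmax(vals, range[1]), range[2])
  breaks <- seq(range[1], range[2], length.out = n_bins + 1)
  idx <- findInterval(vals, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  list(breaks_ps = breaks, mids_ps = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
       counts = counts, empty = FALSE)
}
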