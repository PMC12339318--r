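#' Fluorophore lifetime mixture
#'
#' A discrete mixture of mono-exponential fluorescence decay components, the
#' generative side of the biexponential model
#' I(t) = a1 exp(-t/tau1) + a2 exp(-t/tau2) (any number of components is
#' allowed; the analysis pipeline fits two).
#'
#' @param lifetimes_ps component lifetimes in picoseconds, all > 0.
#' @param fractions amplitude fractions a_i, non-negative, summing to 1.
#' @return An object of class `flim_mixture`.
#' @examples
#' mixture(c(600, 2600), c(0.2, 0.8))
#' @export
mixture <- function(lifetimes_ps, fractions) {
  if (length(lifetimes_ps) != length(fractions) || length(fractions) == 0L)
    stop("lifetimes and fractions must be non-empty and of equal length")
  if (any(!is.finite(lifetimes_ps)) || any(lifetimes_ps <= 0))
    stop("all component lifetimes must be positive")
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("amplitude fractions must be non-negative and sum to 1")
  structure(list(lifetimes_ps = as.numeric(lifetimes_ps),
                 fractions = as.numeric(fractions)),
            class = "flim_mixture")
}

#' Default tissue mixtures
#'
#' Two-component eosin-like mixtures over tau = (600, 2600) ps whose
#' amplitude-weighted mean lifetimes are 2200 ps (cancerous) and 900 ps
#' (peritumoral), inside the 2000-2500 ps and 500-1000 ps ranges the two
#' tissue classes exhibit.
#'
#' @return A `flim_mixture`.
#' @export
mixture_cancerous <- function() mixture(c(600, 2600), c(0.20, 0.80))

#' @rdname mixture_cancerous
#' @export
mixture_peritumoral <- function() mixture(c(600, 2600), c(0.85, 0.15))

#' Amplitude-weighted mean lifetime of a mixture
#'
#' @param mix a [mixture()].
#' @return Mean lifetime sum(a_i tau_i) / sum(a_i) in ps.
#' @export
mixture_mean_lifetime <- function(mix) {
  stopifnot(inherits(mix, "flim_mixture"))
  sum(mix$fractions * mix$lifetimes_ps) / sum(mix$fractions)
}

gaussian_irf_kernel <- function(fwhm_ps, bin_width_ps, center_ps = NULL) {
  sigma <- fwhm_ps / (2 * sqrt(2 * log(2)))
  half <- ceiling(4 * sigma / bin_width_ps)
  t <- (-half:half) * bin_width_ps
  k <- exp(-t^2 / (2 * sigma^2))
  k / sum(k)
}

#' Expected (noise-free) TCSPC decay histogram
#'
#' Evaluates the mixture decay sum(a_i exp(-t/tau_i)) at the bin centers of an
#' acquisition window and scales it so the bins sum to `total_photons`.
#' Optionally convolves with a Gaussian instrument response and/or adds the
#' wrapped contribution of preceding laser pulses (incomplete decay).
#'
#' @param mix a [mixture()].
#' @param config an [acquisition_config()].
#' @param total_photons expected total photon count (>= 0).
#' @param irf_fwhm_ps Gaussian IRF full width at half maximum in ps; 0
#'   (default) means an ideal delta response.
#' @param wrap if `TRUE`, photons from previous pulses wrap into the window
#'   (geometric-series factor 1/(1 - exp(-T/tau)) per component). Default off.
#' @return Numeric vector of expected counts per bin, summing to
#'   `total_photons`.
#' @export
expected_decay <- function(mix, config, total_photons,
                           irf_fwhm_ps = 0, wrap = FALSE) {
  stopifnot(inherits(mix, "flim_mixture"),
            inherits(config, "acquisition_config"),
            length(total_photons) == 1L, total_photons >= 0)
  t <- bin_centers_ps(config)
  period_ps <- 1e12 / config$rep_rate_hz
  shape <- numeric(config$n_bins)
  for (i in seq_along(mix$lifetimes_ps)) {
    tau <- mix$lifetimes_ps[i]
    comp <- mix$fractions[i] * exp(-t / tau)
    if (wrap) comp <- comp / (1 - exp(-period_ps / tau))
    shape <- shape + comp
  }
  if (irf_fwhm_ps > 0) {
    k <- gaussian_irf_kernel(irf_fwhm_ps, config$bin_width_ps)
    half <- (length(k) - 1L) / 2L
    full <- stats::convolve(shape, rev(k), type = "open")
    shape <- full[(half + 1L):(half + config$n_bins)]
    shape[shape < 0] <- 0  # convolution round-off
  }
  s <- sum(shape)
  if (s == 0) return(shape)
  shape * (total_photons / s)
}

# Deterministic per-pixel child seed below 2^31, independent of loop order.
pixel_seed <- function(root_seed, index) {
  as.integer((as.double(root_seed %% 2147483647L) * 48271 + index * 69621) %%
               2147483647)
}

#' Simulate one pixel's TCSPC histogram
#'
#' Draws independent Poisson counts per time bin around the expected decay.
#'
#' @inheritParams expected_decay
#' @param photons expected total photon count for the pixel.
#' @param seed integer seed; the same seed reproduces the same histogram.
#' @return A `decay_histogram`: list with integer `counts`, `bin_width_ps`
#'   and `t0_offset_ps`.
#' @export
simulate_pixel <- function(mix, config, photons, seed,
                           irf_fwhm_ps = 0, wrap = FALSE) {
  mu <- expected_decay(mix, config, photons, irf_fwhm_ps, wrap)
  set.seed(seed)
  counts <- stats::rpois(length(mu), mu)
  decay_histogram(counts, config$bin_width_ps)
}

#' Construct a decay histogram
#'
#' @param counts non-negative integer counts per time bin.
#' @param bin_width_ps bin width in ps.
#' @param t0_offset_ps time of the leading bin edge, ps (default 0).
#' @return A `decay_histogram` object.
#' @export
decay_histogram <- function(counts, bin_width_ps, t0_offset_ps = 0) {
  stopifnot(bin_width_ps > 0, all(counts >= 0))
  structure(list(counts = as.numeric(counts),
                 bin_width_ps = bin_width_ps,
                 t0_offset_ps = t0_offset_ps),
            class = "decay_histogram")
}

#' Tissue region specification
#'
#' Binds a region label (peritumoral, cancerous, background, necrotic) to the
#' lifetime mixture and mean photon budget its pixels are simulated with.
#' `background` and `necrotic` default to low-photon pixels so that intensity
#' masking is exercised.
#'
#' @param label one of `"peritumoral"`, `"cancerous"`, `"background"`,
#'   `"necrotic"`.
#' @param mix a [mixture()].
#' @param photons_per_pixel Poisson mean of the per-pixel photon count (> 0
#'   unless label is background).
#' @return A `region_spec` object.
#' @export
region_spec <- function(label, mix, photons_per_pixel) {
  label <- match.arg(label, c("peritumoral", "cancerous", "background",
                              "necrotic"))
  stopifnot(inherits(mix, "flim_mixture"), photons_per_pixel >= 0)
  structure(list(label = label, mix = mix,
                 photons_per_pixel = photons_per_pixel),
            class = "region_spec")
}

#' Default specifications for the synthetic two-class study
#'
#' Cancerous and peritumoral regions use the default mixtures over
#' tau = (600, 2600) ps; necrotic pixels carry 30 expected photons (below the
#' 100-count fitting threshold) and background pixels none.
#'
#' @param photons_per_pixel photon budget for the two tissue classes
#'   (default 5000).
#' @return Named list of [region_spec()] objects.
#' @export
default_region_specs <- function(photons_per_pixel = 5000) {
  list(
    cancerous   = region_spec("cancerous", mixture_cancerous(),
                              photons_per_pixel),
    peritumoral = region_spec("peritumoral", mixture_peritumoral(),
                              photons_per_pixel),
    necrotic    = region_spec("necrotic", mixture_peritumoral(), 30),
    background  = region_spec("background", mixture_peritumoral(), 0)
  )
}

#' Tissue layouts
#'
#' A layout is a character matrix of region labels, one per pixel.
#' `layout_uniform` fills the frame with one label; `layout_halfplane` splits
#' it into a top and a bottom half; `layout_bands` divides it into equal-width
#' vertical bands (used for multi-population phasor tests).
#'
#' @param label,top,bottom,labels region label(s).
#' @param size integer `c(rows, cols)`.
#' @return Character matrix of labels.
#' @export
layout_uniform <- function(label, size) {
  matrix(label, nrow = size[1], ncol = size[2])
}

#' @rdname layout_uniform
#' @export
layout_halfplane <- function(top, bottom, size) {
  m <- matrix(bottom, nrow = size[1], ncol = size[2])
  m[seq_len(floor(size[1] / 2)), ] <- top
  m
}

#' @rdname layout_uniform
#' @export
layout_bands <- function(labels, size) {
  edges <- round(seq(0, size[2], length.out = length(labels) + 1))
  m <- matrix(labels[1], nrow = size[1], ncol = size[2])
  for (i in seq_along(labels)) {
    cols <- (edges[i] + 1):edges[i + 1]
    m[, cols] <- labels[i]
  }
  m
}

#' Simulate a TCSPC image cube
#'
#' Generates a full time-binned photon-count cube: each pixel's histogram is
#' Poisson noise around the expected decay of its region's mixture. Child
#' random streams are derived per pixel index from the root seed, so the
#' result does not depend on pixel iteration order.
#'
#' @param layout character matrix of region labels (see [layout_uniform()]).
#' @param specs named list of [region_spec()], one per label present.
#' @param config an [acquisition_config()]; its `image_size` is overridden by
#'   the layout dimensions.
#' @param seed root integer seed.
#' @param irf_fwhm_ps,wrap forwarded to [expected_decay()].
#' @return A `tcspc_cube`: list with `counts` (array time x row x col),
#'   `config`, `layout`.
#' @export
simulate_cube <- function(layout, specs, config, seed,
                          irf_fwhm_ps = 0, wrap = FALSE) {
  stopifnot(is.matrix(layout), inherits(config, "acquisition_config"))
  labels <- unique(as.vector(layout))
  missing <- setdiff(labels, names(specs))
  if (length(missing))
    stop("no region_spec for label(s): ", paste(missing, collapse = ", "))
  config$image_size <- dim(layout)
  nr <- nrow(layout); nc <- ncol(layout)
  mu_by_label <- lapply(specs[labels], function(sp)
    expected_decay(sp$mix, config, sp$photons_per_pixel, irf_fwhm_ps, wrap))
  counts <- array(0, dim = c(config$n_bins, nr, nc))
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      mu <- mu_by_label[[layout[r, c]]]
      if (sum(mu) == 0) next
      set.seed(pixel_seed(seed, (r - 1L) * nc + c))
      counts[, r, c] <- stats::rpois(length(mu), mu)
    }
  }
  structure(list(counts = counts, config = config, layout = layout),
            class = "tcspc_cube")
}

#' @export
print.tcspc_cube <- function(x, ...) {
  cat(sprintf("TCSPC cube: %d bins x %d x %d pixels, %.0f total photons\n",
              dim(x$counts)[1], dim(x$counts)[2], dim(x$counts)[3],
              sum(x$counts)))
  invisible(x)
}

#' Simulate a clinical indicator column with a target correlation
#'
#' Builds one synthetic laboratory-indicator column as a linear transform of
#' the supplied lifetime ratios plus Gaussian noise, with the slope calibrated
#' so that the population Pearson correlation with the ratios equals
#' `target_r`:
#' slope = sign(r) * noise_sd * |r| / (sd(ratios) * sqrt(1 - r^2)).
#'
#' @param ratios numeric vector of per-sample lifetime ratios (>= 3 values).
#' @param target_r desired Pearson correlation in `[-1, 1]`.
#' @param noise_sd standard deviation of the additive Gaussian noise; must be
#'   0 when `|target_r| = 1` (exact affine relation) and positive otherwise.
#' @param seed integer seed.
#' @param intercept,unit_scale affine placement of the indicator column
#'   (defaults give values on a bilirubin-like scale).
#' @return A data.frame with columns `lifetime_ratio` and `indicator`.
#' @export
simulate_clinical_table <- function(ratios, target_r, noise_sd, seed,
                                    intercept = 20, unit_scale = 1) {
  if (length(ratios) < 3) stop("need at least 3 ratios")
  if (abs(target_r) > 1) stop("target_r must lie in [-1, 1]")
  sx <- stats::sd(ratios)
  if (sx == 0) stop("ratios must not be constant")
  if (abs(target_r) == 1) {
    if (noise_sd != 0)
      stop("|target_r| = 1 requires noise_sd = 0")
    y <- intercept + unit_scale * sign(target_r) * ratios
  } else {
    if (noise_sd <= 0)
      stop("noise_sd must be positive for |target_r| < 1")
    slope <- sign(target_r) * noise_sd * abs(target_r) /
      (sx * sqrt(1 - target_r^2))
    set.seed(seed)
    y <- intercept + unit_scale *
      (slope * ratios + stats::rnorm(length(ratios), 0, noise_sd))
  }
  data.frame(lifetime_ratio = ratios, indicator = y)
}
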