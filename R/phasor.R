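#' Angular frequency of the phasor transform
#'
#' omega = 2 pi f with f the laser repetition frequency (76 MHz by default,
#' harmonic n multiplies it inside the transform).
#'
#' @param rep_rate_hz repetition frequency in Hz.
#' @return omega in rad/s.
#' @export
phasor_omega <- function(rep_rate_hz = 76e6) 2 * pi * rep_rate_hz

#' Phasor transform of decay data
#'
#' Maps each decay histogram to frequency-domain coordinates
#' G = sum I(t) cos(n w t) / sum I(t) and S = sum I(t) sin(n w t) / sum I(t),
#' the discrete (bin-center, rectangle-rule) form of the cosine/sine
#' transforms of the decay. G is the horizontal and S the vertical phasor
#' coordinate. The transform is invariant to overall intensity scaling; a
#' pixel with zero total counts has no phasor and is masked.
#'
#' @param x a `tcspc_cube`, a [decay_histogram()], or a numeric count vector
#'   (then `bin_width_ps` is required).
#' @param n harmonic order (default 1).
#' @param omega fundamental angular frequency rad/s; defaults to
#'   `phasor_omega(rep_rate)` of the cube's metadata, or 76 MHz for bare
#'   histograms.
#' @param bin_width_ps bin width when `x` is a bare vector.
#' @return For a cube: a `phasor_map` with matrices `G`, `S`, logical `mask`,
#'   and fields `harmonic`, `omega`, `calibrated`. For a single histogram: a
#'   named vector `c(G =, S =)`.
#' @export
phasor_transform <- function(x, n = 1, omega = NULL, bin_width_ps = NULL) {
  stopifnot(n >= 1)
  if (inherits(x, "tcspc_cube")) {
    if (is.null(omega)) omega <- phasor_omega(x$config$rep_rate_hz)
    t_s <- bin_centers_ps(x$config) * 1e-12
    co <- cos(n * omega * t_s); si <- sin(n * omega * t_s)
    d <- dim(x$counts)
    flat <- matrix(x$counts, nrow = d[1])  # bins x pixels
    tot <- colSums(flat)
    G <- S <- rep(NA_real_, length(tot))
    ok <- tot > 0
    G[ok] <- colSums(flat[, ok, drop = FALSE] * co) / tot[ok]
    S[ok] <- colSums(flat[, ok, drop = FALSE] * si) / tot[ok]
    structure(list(G = matrix(G, d[2], d[3]), S = matrix(S, d[2], d[3]),
                   mask = matrix(ok, d[2], d[3]), harmonic = n,
                   omega = omega, calibrated = FALSE),
              class = "phasor_map")
  } else {
    if (inherits(x, "decay_histogram")) {
      counts <- x$counts; bin_width_ps <- x$bin_width_ps
    } else {
      counts <- as.numeric(x)
      if (is.null(bin_width_ps))
        stop("bin_width_ps required for a bare vector")
    }
    if (sum(counts) <= 0) stop("zero total counts: phasor undefined")
    if (is.null(omega)) omega <- phasor_omega()
    t_s <- (seq_along(counts) - 0.5) * bin_width_ps * 1e-12
    c(G = sum(counts * cos(n * omega * t_s)) / sum(counts),
      S = sum(counts * sin(n * omega * t_s)) / sum(counts))
  }
}

#' Closed-form phasor of a single-exponential decay
#'
#' For a mono-exponential lifetime tau the transform integrates analytically
#' to G = 1 / (1 + (n w tau)^2), S = n w tau / (1 + (n w tau)^2). These
#' points trace the universal semicircle of radius 1/2 centered at (0.5, 0):
#' tau = 0 maps to (1, 0) and tau -> Inf to (0, 0); mixtures fall inside on
#' chords.
#'
#' @param tau_ps lifetime(s) in ps, >= 0 (vectorized).
#' @param n harmonic order.
#' @param omega fundamental angular frequency rad/s (default 2 pi 76 MHz).
#' @return Matrix with columns `G` and `S`, one row per lifetime.
#' @examples
#' single_exp_phasor(0)          # (1, 0)
#' single_exp_phasor(1 / phasor_omega() * 1e12)  # (0.5, 0.5): w tau = 1
#' @export
single_exp_phasor <- function(tau_ps, n = 1, omega = phasor_omega()) {
  if (any(tau_ps < 0)) stop("lifetime must be non-negative")
  wt <- n * omega * tau_ps * 1e-12
  cbind(G = 1 / (1 + wt^2), S = wt / (1 + wt^2))
}

#' Calibrate a phasor map against a reference of known lifetime
#'
#' Finite bins and instrument response rotate and demodulate measured
#' phasors away from their theoretical positions. Calibration applies the
#' complex rotation/scaling that carries the measured reference phasor onto
#' the closed-form phasor of its known lifetime, and applies the same
#' correction to every pixel.
#'
#' @param map a `phasor_map`.
#' @param reference_measured measured `c(G, S)` of the reference.
#' @param reference_lifetime_ps the reference fluorophore's true lifetime.
#' @return The calibrated `phasor_map` (`calibrated = TRUE`, with
#'   `phase_correction` in radians and `modulation_correction` recorded).
#' @export
calibrate_phasor <- function(map, reference_measured, reference_lifetime_ps) {
  stopifnot(inherits(map, "phasor_map"))
  z_ref <- complex(real = reference_measured[1],
                   imaginary = reference_measured[2])
  if (Mod(z_ref) == 0) stop("reference phasor has zero modulus")
  th <- single_exp_phasor(reference_lifetime_ps, map$harmonic, map$omega)
  z_th <- complex(real = th[1, "G"], imaginary = th[1, "S"])
  corr <- z_th / z_ref
  z <- complex(real = map$G, imaginary = map$S) * corr
  map$G <- matrix(Re(z), nrow(map$G), ncol(map$G))
  map$S <- matrix(Im(z), nrow(map$S), ncol(map$S))
  map$phase_correction <- Arg(corr)
  map$modulation_correction <- Mod(corr)
  map$calibrated <- TRUE
  map
}

#' Phase and modulation lifetimes of a phasor point
#'
#' Inverts a phasor position back to lifetimes: the phase lifetime
#' tau_phase = S / (G n w) and the modulation lifetime
#' tau_mod = (1/(n w)) sqrt(1/(G^2 + S^2) - 1). The two agree exactly on the
#' universal semicircle (single-exponential decays); for mixtures inside the
#' circle tau_phase < tau_mod.
#'
#' @param G,S phasor coordinates (vectorized).
#' @param n harmonic order.
#' @param omega fundamental angular frequency rad/s.
#' @return Matrix with columns `tau_phase_ps`, `tau_mod_ps`.
#' @export
phasor_to_lifetime <- function(G, S, n = 1, omega = phasor_omega()) {
  if (any(G <= 0)) stop("phase lifetime undefined for G <= 0")
  m2 <- G^2 + S^2
  if (any(m2 <= 0 | m2 > 1 + 1e-12))
    stop("modulation lifetime requires G^2 + S^2 in (0, 1]")
  nw <- n * omega
  cbind(tau_phase_ps = S / (G * nw) * 1e12,
        tau_mod_ps = sqrt(pmax(1 / m2 - 1, 0)) / nw * 1e12)
}

#' Cluster pixels in phasor space
#'
#' Partitions masked-in pixels by (G, S) position with seeded k-means
#' (multiple restarts, deterministic for a fixed seed). Pixels with similar
#' decay composition cluster at the same phasor location, so the clusters
#' recover lifetime populations without curve fitting. Clusters are
#' relabeled in descending order of mean lifetime (cluster 1 = longest),
#' taken from the paired `lifetime_image` when given and from the centers'
#' phase lifetime otherwise.
#'
#' @param map a `phasor_map`.
#' @param k number of clusters (default 3).
#' @param seed integer seed for the k-means initialization.
#' @param image optional paired `lifetime_image` supplying per-pixel tau_m.
#' @return A `phasor_clusters` object: `labels` matrix (NA outside the
#'   mask), `centers` (k x 2, G/S), `cluster_mean_tau_m_ps` (descending),
#'   `k`.
#' @export
cluster_phasor <- function(map, k = 3, seed = 1, image = NULL) {
  stopifnot(inherits(map, "phasor_map"), k >= 1)
  idx <- which(map$mask)
  if (length(idx) < k) stop("k exceeds the number of masked-in pixels")
  X <- cbind(map$G[idx], map$S[idx])
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = 10, iter.max = 100)
  # mean tau_m per cluster, for the descending relabeling
  if (!is.null(image)) {
    tau <- image$tau_m_map[idx]
    mean_tau <- vapply(seq_len(k), function(j)
      mean(tau[km$cluster == j], na.rm = TRUE), numeric(1))
  } else {
    mean_tau <- vapply(seq_len(k), function(j) {
      ctr <- km$centers[j, ]
      phasor_to_lifetime(max(ctr[1], 1e-9), max(ctr[2], 0),
                         map$harmonic, map$omega)[1, "tau_phase_ps"]
    }, numeric(1))
  }
  ord <- order(mean_tau, decreasing = TRUE)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- matrix(NA_integer_, nrow(map$G), ncol(map$G))
  labels[idx] <- relabel[km$cluster]
  structure(list(labels = labels, centers = km$centers[ord, , drop = FALSE],
                 cluster_mean_tau_m_ps = mean_tau[ord], k = k),
            class = "phasor_clusters")
}

#' Pseudo-colored segmentation image from phasor clusters
#'
#' One distinct color per cluster; pixels outside the mask are black.
#'
#' @param clusters a `phasor_clusters` object.
#' @param palette optional vector of k colors (any R color spec); defaults
#'   to evenly spaced hues.
#' @return An rows x cols x 3 RGB array in `[0, 1]`.
#' @export
segment_image <- function(clusters, palette = NULL) {
  stopifnot(inherits(clusters, "phasor_clusters"))
  k <- clusters$k
  if (is.null(palette)) palette <- grDevices::rainbow(k)
  stopifnot(length(palette) == k)
  rgb <- t(grDevices::col2rgb(palette)) / 255
  d <- dim(clusters$labels)
  img <- array(0, dim = c(d[1], d[2], 3))
  for (j in seq_len(k)) {
    sel <- !is.na(clusters$labels) & clusters$labels == j
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[sel] <- rgb[j, ch]; img[, , ch] <- plane
    }
  }
  img
}
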