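#' TCSPC acquisition configuration
#'
#' Describes the timing geometry of a time-correlated single photon counting
#' (TCSPC) acquisition: how many time bins the laser period is divided into,
#' their width, the laser repetition rate and the image size.
#'
#' The default time window spans exactly one laser period at 76 MHz
#' (1/76e6 s ~ 13.16 ns) divided into 256 bins of ~51.4 ps, the usual TCSPC
#' arrangement when no explicit gate is stated.
#'
#' @param n_bins number of time bins (positive integer).
#' @param bin_width_ps bin width in picoseconds. Default: one laser period
#'   divided by `n_bins`.
#' @param rep_rate_hz laser repetition frequency in Hz (default 76 MHz).
#' @param image_size integer vector `c(rows, cols)` (default 256 x 256).
#' @return An object of class `acquisition_config`.
#' @examples
#' cfg <- acquisition_config(image_size = c(64, 64))
#' cfg$bin_width_ps * cfg$n_bins  # one 76 MHz period, in ps
#' @export
acquisition_config <- function(n_bins = 256L, bin_width_ps = NULL,
                               rep_rate_hz = 76e6,
                               image_size = c(256L, 256L)) {
  n_bins <- as.integer(n_bins)
  stopifnot(length(n_bins) == 1L, n_bins > 0L,
            length(rep_rate_hz) == 1L, rep_rate_hz > 0,
            length(image_size) == 2L, all(image_size >= 1))
  period_ps <- 1e12 / rep_rate_hz
  if (is.null(bin_width_ps)) bin_width_ps <- period_ps / n_bins
  stopifnot(bin_width_ps > 0)
  if (n_bins * bin_width_ps > period_ps * (1 + 1e-9))
    stop("time window (n_bins * bin_width_ps) exceeds the laser period")
  structure(list(n_bins = n_bins,
                 bin_width_ps = bin_width_ps,
                 rep_rate_hz = rep_rate_hz,
                 image_size = as.integer(image_size)),
            class = "acquisition_config")
}

#' Time-bin centers of an acquisition window
#'
#' @param config an [acquisition_config()].
#' @return Numeric vector of bin-center times in picoseconds.
#' @export
bin_centers_ps <- function(config) {
  stopifnot(inherits(config, "acquisition_config"))
  (seq_len(config$n_bins) - 0.5) * config$bin_width_ps
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf("TCSPC acquisition: %d bins x %.2f ps (window %.2f ns), %g MHz, image %dx%d\n",
              x$n_bins, x$bin_width_ps, x$n_bins * x$bin_width_ps / 1e3,
              x$rep_rate_hz / 1e6, x$image_size[1], x$image_size[2]))
  invisible(x)
}
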