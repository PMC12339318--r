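# Shared fixtures: small acquisition geometries so the suite stays fast
# while exercising the full 256-bin default timing.

cfg_small <- function(size = c(12, 12)) acquisition_config(image_size = size)

# fine-grained single-pixel geometry for analytic phasor checks
cfg_fine <- function(n_bins = 4096L, window_ps = NULL) {
  if (is.null(window_ps)) window_ps <- 1e12 / 76e6
  acquisition_config(n_bins = n_bins, bin_width_ps = window_ps / n_bins,
                     image_size = c(1, 1))
}
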