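#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic two-class FLIM study.
#
# Three cancerous and three peritumoral 48x48 TCSPC cubes (256 bins over one
# 76 MHz period, 5000 expected photons/pixel, the default tissue mixtures over
# tau = (600, 2600) ps), plus a half-plane composite for phasor segmentation
# and a three-band single-lifetime cube for cluster validation. Cubes land in
# results/cubes/ as multi-page TIFF + JSON sidecars.

library(flimpipe)

seed <- 7
size <- c(48, 48)
out <- "results/cubes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- acquisition_config(image_size = size)
specs <- default_region_specs(photons_per_pixel = 5000)

for (region in c("cancerous", "peritumoral")) {
  for (i in 1:3) {
    cube <- simulate_cube(layout_uniform(region, size), specs, cfg,
                          seed = seed + 100 * match(region, c("cancerous",
                                                              "peritumoral")) + i)
    f <- file.path(out, sprintf("study_%s_%d.tif", region, i))
    write_cube(cube, f)
    cat(sprintf("%s: %.0f photons total\n", f, sum(cube$counts)))
  }
}

comp <- simulate_cube(layout_halfplane("cancerous", "peritumoral", size),
                      specs, cfg, seed = seed)
write_cube(comp, file.path(out, "composite_halfplane.tif"))

bands <- simulate_cube(
  layout_bands(c("peritumoral", "necrotic", "cancerous"), size),
  list(peritumoral = region_spec("peritumoral", mixture(500, 1), 3000),
       necrotic    = region_spec("necrotic", mixture(1500, 1), 3000),
       cancerous   = region_spec("cancerous", mixture(3000, 1), 3000)),
  cfg, seed = seed + 1)
write_cube(bands, file.path(out, "bands_three_lifetimes.tif"))
# ground-truth band labels for later cluster validation
write.csv(data.frame(which(bands$layout == bands$layout, arr.ind = TRUE),
                     label = as.vector(bands$layout)),
          file.path(out, "bands_labels.csv"), row.names = FALSE)

cat("simulated", length(list.files(out, pattern = "[.]tif$")), "cubes ->", out, "\n")
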