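#' Write a TCSPC cube to multi-page TIFF with a JSON sidecar
#'
#' One 32-bit TIFF page per time bin. TIFF samples are stored in `[0, 1]`,
#' so counts are divided by a power-of-two scale (recorded in the sidecar)
#' chosen large enough that the integer counts round-trip exactly. The
#' sidecar `<path>.json` carries the timing metadata (`bin_width_ps`,
#' `rep_rate_hz`, `count_scale`) without which a cube cannot be interpreted.
#'
#' @param cube a `tcspc_cube`.
#' @param path output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "tcspc_cube"))
  mx <- max(cube$counts)
  scale <- 2^max(ceiling(log2(mx + 1)), 1)
  pages <- lapply(seq_len(dim(cube$counts)[1]),
                  function(i) cube$counts[i, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  jsonlite::write_json(
    list(bin_width_ps = cube$config$bin_width_ps,
         rep_rate_hz = cube$config$rep_rate_hz,
         n_bins = cube$config$n_bins,
         count_scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a TCSPC cube written by [write_cube()]
#'
#' Timing metadata is mandatory: a TIFF without its sidecar (or with a
#' sidecar missing `bin_width_ps`/`rep_rate_hz`) is rejected rather than
#' silently defaulted.
#'
#' @param path path to the multi-page TIFF.
#' @return A `tcspc_cube`.
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing metadata sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("bin_width_ps", "rep_rate_hz", "count_scale"))
    if (is.null(meta[[f]]))
      stop("sidecar missing required field: ", f)
  pages <- tiff::readTIFF(path, all = TRUE)
  n_bins <- length(pages)
  d <- dim(pages[[1]])
  counts <- array(0, dim = c(n_bins, d[1], d[2]))
  for (i in seq_len(n_bins))
    counts[i, , ] <- round(pages[[i]] * meta$count_scale)
  cfg <- acquisition_config(n_bins = n_bins,
                            bin_width_ps = meta$bin_width_ps,
                            rep_rate_hz = meta$rep_rate_hz,
                            image_size = d)
  structure(list(counts = counts, config = cfg, layout = NULL),
            class = "tcspc_cube")
}

#' Render a mean-lifetime map as a pseudo-colored RGB image
#'
#' Lifetimes are mapped over the display range (default 500-3500 ps) with a
#' piecewise-linear blue -> green -> red ramp (shortest lifetimes blue,
#' longest red), clamped at the range edges; masked-out pixels are black.
#'
#' @param image a `lifetime_image`.
#' @param range `c(low, high)` ps, low < high.
#' @param intensity_weighted multiply brightness by relative intensity.
#' @return rows x cols x 3 RGB array in `[0, 1]`.
#' @export
render_lifetime_image <- function(image, range = c(500, 3500),
                                  intensity_weighted = FALSE) {
  stopifnot(inherits(image, "lifetime_image"))
  if (range[1] >= range[2]) stop("invalid display range: low >= high")
  f <- (image$tau_m_map - range[1]) / (range[2] - range[1])
  f <- pmin(pmax(f, 0), 1)
  r <- pmax(2 * f - 1, 0)
  b <- pmax(1 - 2 * f, 0)
  g <- 1 - r - b
  out <- array(0, dim = c(nrow(f), ncol(f), 3))
  w <- if (intensity_weighted) {
    mi <- max(image$intensity_map)
    if (mi > 0) image$intensity_map / mi else 1
  } else 1
  out[, , 1] <- ifelse(image$mask, r * w, 0)
  out[, , 2] <- ifelse(image$mask, g * w, 0)
  out[, , 3] <- ifelse(image$mask, b * w, 0)
  out[is.na(out)] <- 0
  out
}

#' Write a lifetime image's maps and per-pixel fit table
#'
#' Writes `<prefix>_tau_m.tif` and `<prefix>_intensity.tif` (32-bit TIFF,
#' values scaled into `[0, 1]` by the recorded scales in
#' `<prefix>_maps.json`), the per-pixel fit table `<prefix>_fits.csv`
#' (unclamped lifetimes), and the pseudo-colored `<prefix>_render.png`.
#'
#' @param image a `lifetime_image`.
#' @param prefix output path prefix.
#' @param range rendering range in ps.
#' @return Character vector of the files written, invisibly.
#' @export
write_lifetime_image <- function(image, prefix, range = c(500, 3500)) {
  stopifnot(inherits(image, "lifetime_image"))
  tau_scale <- 2^14  # > 10000 ps fit bound
  int_scale <- 2^max(ceiling(log2(max(image$intensity_map) + 1)), 1)
  tau <- image$tau_m_map / tau_scale
  tau[is.na(tau)] <- 0
  files <- c(tau = paste0(prefix, "_tau_m.tif"),
             intensity = paste0(prefix, "_intensity.tif"),
             meta = paste0(prefix, "_maps.json"),
             fits = paste0(prefix, "_fits.csv"),
             render = paste0(prefix, "_render.png"))
  tiff::writeTIFF(tau, files[["tau"]], bits.per.sample = 32)
  tiff::writeTIFF(image$intensity_map / int_scale, files[["intensity"]],
                  bits.per.sample = 32)
  jsonlite::write_json(list(tau_scale_ps = tau_scale,
                            intensity_scale = int_scale),
                       files[["meta"]], auto_unbox = TRUE, digits = NA)
  utils::write.csv(image$fits, files[["fits"]], row.names = FALSE)
  png::writePNG(render_lifetime_image(image, range), files[["render"]])
  invisible(files)
}

#' Write per-pixel phasor coordinates and a phasor-density plot
#'
#' @param map a `phasor_map`.
#' @param prefix output path prefix; writes `<prefix>_phasor.csv`
#'   (row, col, G, S) and `<prefix>_phasor.png` (2-D density over the
#'   universal semicircle).
#' @param grid density-image resolution (default 256).
#' @return Files written, invisibly.
#' @export
write_phasor <- function(map, prefix, grid = 256) {
  stopifnot(inherits(map, "phasor_map"))
  idx <- which(map$mask, arr.ind = TRUE)
  df <- data.frame(row = idx[, 1], col = idx[, 2],
                   G = map$G[idx], S = map$S[idx])
  csv <- paste0(prefix, "_phasor.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  gx <- pmin(pmax(ceiling(df$G * grid), 1), grid)
  gy <- pmin(pmax(ceiling(df$S * 2 * grid * 0.55 / 1.1), 1), grid %/% 2)
  dens <- matrix(0, grid %/% 2, grid)
  for (i in seq_along(gx))
    dens[gy[i], gx[i]] <- dens[gy[i], gx[i]] + 1
  dens <- dens[rev(seq_len(nrow(dens))), ]  # S increases upward
  img <- 1 - dens / max(dens, 1)
  pngf <- paste0(prefix, "_phasor.png")
  png::writePNG(img, pngf)
  invisible(c(csv = csv, png = pngf))
}

#' Configuration for the synthetic end-to-end pipeline
#'
#' @param out_dir output directory.
#' @param seed root seed.
#' @param image_size per-region image size (default 64 x 64).
#' @param photons_per_pixel expected photons per pixel (default 5000).
#' @param n_images_per_region images per tissue class (default 3; with four
#'   quadrants each this yields 12 quadrant means per group).
#' @param threshold minimum photons per fitted pixel.
#' @param k phasor clusters.
#' @param range rendering range in ps.
#' @return A named list.
#' @export
pipeline_config <- function(out_dir, seed = 7, image_size = c(64, 64),
                            photons_per_pixel = 5000,
                            n_images_per_region = 3, threshold = 100,
                            k = 2, range = c(500, 3500)) {
  stopifnot(range[1] < range[2])
  list(out_dir = out_dir, seed = seed, image_size = image_size,
       photons_per_pixel = photons_per_pixel,
       n_images_per_region = n_images_per_region, threshold = threshold,
       k = k, range = range)
}

#' Run the full synthetic study pipeline
#'
#' Simulate -> fit -> phasor/segmentation -> quadrant statistics ->
#' normalization -> clinical correlation, writing every stage product plus a
#' run manifest. Deterministic: the same config (including seed) reproduces
#' identical CSV outputs.
#'
#' Products under `config$out_dir`: per-image fit outputs (see
#' [write_lifetime_image()]), `measurements.csv`, `normalized.csv`,
#' `ratios.csv`, `group_stats.json` (t-test and box summaries),
#' `correlations.csv` (packaged patient table), phasor CSV/PNG and
#' `segmentation.png` for the first image pair, and `manifest.json`.
#'
#' @param config list from [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  t_start <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- acquisition_config(image_size = config$image_size)
  specs <- default_region_specs(config$photons_per_pixel)
  regions <- c("peritumoral", "cancerous")
  measurements <- list()
  outputs <- character()
  timings <- list()
  first_images <- list()

  for (region in regions) {
    for (i in seq_len(config$n_images_per_region)) {
      t0 <- Sys.time()
      seed_i <- config$seed + 1000L * match(region, regions) + i
      layout <- layout_uniform(region, config$image_size)
      cube <- simulate_cube(layout, specs, cfg, seed = seed_i)
      img <- fit_cube(cube, threshold = config$threshold)
      prefix <- file.path(config$out_dir, sprintf("%s_%d", region, i))
      outputs <- c(outputs, write_lifetime_image(img, prefix, config$range))
      measurements[[paste(region, i)]] <-
        measure_quadrants(img, sample_id = sprintf("S%d", i),
                          region = region)
      if (i == 1) first_images[[region]] <- img
      timings[[sprintf("fit_%s_%d", region, i)]] <-
        as.numeric(difftime(Sys.time(), t0, units = "secs"))
    }
  }

  meas <- do.call(rbind, measurements)
  f <- file.path(config$out_dir, "measurements.csv")
  utils::write.csv(meas, f, row.names = FALSE); outputs <- c(outputs, f)

  norm <- normalize_to_peritumoral(meas)
  f <- file.path(config$out_dir, "normalized.csv")
  utils::write.csv(norm, f, row.names = FALSE); outputs <- c(outputs, f)

  ratios <- lifetime_ratios(meas)
  f <- file.path(config$out_dir, "ratios.csv")
  utils::write.csv(ratios, f, row.names = FALSE); outputs <- c(outputs, f)

  canc <- meas$mean_tau_m_ps[meas$region == "cancerous"]
  peri <- meas$mean_tau_m_ps[meas$region == "peritumoral"]
  tt <- two_sample_ttest(canc, peri)
  stats_out <- list(t = tt$t, p = tt$p, df = tt$df,
                    cancerous = boxplot_summary(canc),
                    peritumoral = boxplot_summary(peri))
  f <- file.path(config$out_dir, "group_stats.json")
  jsonlite::write_json(stats_out, f, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, f)

  clin <- hcc_clinical_table()
  f <- file.path(config$out_dir, "correlations.csv")
  utils::write.csv(correlate_table(clin), f, row.names = FALSE)
  outputs <- c(outputs, f)

  t0 <- Sys.time()
  # phasor segmentation on a two-class composite of the first image pair
  comp_layout <- layout_halfplane("cancerous", "peritumoral",
                                  config$image_size)
  comp <- simulate_cube(comp_layout, specs, cfg, seed = config$seed)
  comp_img <- fit_cube(comp, threshold = config$threshold)
  pm <- phasor_transform(comp)
  outputs <- c(outputs, write_phasor(pm, file.path(config$out_dir, "composite")))
  cl <- cluster_phasor(pm, k = config$k, seed = config$seed, image = comp_img)
  f <- file.path(config$out_dir, "segmentation.png")
  png::writePNG(segment_image(cl), f); outputs <- c(outputs, f)
  timings$phasor <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  manifest <- list(
    config = config,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("flimpipe")),
    outputs = unname(outputs),
    cluster_mean_tau_m_ps = cl$cluster_mean_tau_m_ps,
    ttest = list(t = tt$t, p = tt$p),
    timings_s = timings,
    total_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
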