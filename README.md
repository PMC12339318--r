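# flimpipe

Quantitative analysis of fluorescence lifetime imaging microscopy (FLIM) data
from stained tissue sections, built around the workflow used to separate
hepatocellular-carcinoma (HCC) tissue from the surrounding peritumoral tissue
on ordinary H&E-stained slides. H&E morphology alone is qualitative; the
eosin fluorescence *lifetime*, mapped per pixel by time-correlated single
photon counting (TCSPC), adds a quantitative signature: cancerous regions
show mean lifetimes around 2000–2500 ps while peritumoral tissue sits near
500–1000 ps. The package is aimed at microscopists and image analysts who
want that full pipeline — simulation, per-pixel decay fitting, phasor
analysis, and the downstream region statistics — as tested, scriptable R.

Because no public FLIM dataset accompanies this kind of study, the package
includes a first-class synthetic-data module that generates TCSPC image
cubes with known lifetime-component mixtures, so every stage of the analysis
is testable end to end.

## The model

Each pixel of a TCSPC acquisition is a histogram of photon arrival times
over one laser period (76 MHz repetition rate, 256 bins by default). The
decay is modeled as a biexponential,

    I(t) = a1 exp(-t/τ1) + a2 exp(-t/τ2),

fitted per pixel by weighted least squares (Neyman weights,
Levenberg–Marquardt, optional IRF convolution and constant background), and
summarized by the amplitude-weighted mean lifetime

    τm = (a1 τ1 + a2 τ2) / (a1 + a2),

which is rendered over a 500–3500 ps blue→green→red ramp. The
frequency-domain view maps each pixel to phasor coordinates at harmonic n
and angular frequency ω = 2πf:

    G = Σ I(t) cos(nωt) / Σ I(t),   S = Σ I(t) sin(nωt) / Σ I(t).

Single-exponential decays fall on the universal semicircle of radius 1/2
centered at (0.5, 0) — G = 1/(1+(nωτ)²), S = nωτ/(1+(nωτ)²) — and mixtures
fall inside it on chords; seeded k-means on (G, S) segments the image into
lifetime populations without curve fitting. Region statistics follow the
histopathology workflow: clockwise quadrant splitting, pooled-variance
Student t-tests between tissue classes, per-sample normalization to the
peritumoral mean (the cancerous/peritumoral lifetime ratio), and Pearson
correlation of those ratios against clinical laboratory indicators.

## Worked example

```r
library(flimpipe)

cfg   <- acquisition_config(image_size = c(48, 48))   # 256 bins, 76 MHz
specs <- default_region_specs(photons_per_pixel = 5000)
cube  <- simulate_cube(layout_uniform("cancerous", c(48, 48)), specs, cfg, seed = 107)
img   <- fit_cube(cube, threshold = 100)
img
#> lifetime_image: 48x48, 2304/2304 pixels fitted, mean tau_m 2145.6 ps

pm <- phasor_transform(cube)        # (G, S) per pixel at n = 1, 76 MHz
cl <- cluster_phasor(pm, k = 2, seed = 7, image = img)

res <- correlate_table(hcc_clinical_table())
res[res$indicator == "total_bilirubin_umol_l", ]
#>                indicator         r r_2dp n
#> 2 total_bilirubin_umol_l 0.7914209  0.79 4
```

The fitted mean of 2145.6 ps sits inside the 2000–2500 ps range expected
for the cancerous mixture (true τm 2200 ps at a = 0.20/0.80 over 600/2600
ps); the 0.79 correlation is the lifetime-ratio vs total-bilirubin entry of
the packaged four-patient clinical table.

The `analysis/` directory holds the full study as five numbered drivers —
`01_simulate.R` (simulate cubes to multi-page TIFF), `02_fit_lifetimes.R`,
`03_phasor_segmentation.R`, `04_region_statistics.R`,
`05_clinical_correlation.R` — each writing its tables and images under
`results/`. Run them in order from the repository root.

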