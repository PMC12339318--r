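#!/usr/bin/env Rscript
# Stage 4: region statistics over the quadrant measurements.
#
# Pooled-variance Student t-test of the 12 cancerous vs 12 peritumoral
# quadrant means, box-plot summaries, per-sample normalization to the
# peritumoral mean (peritumoral group mean = 1 by construction) and the
# resulting cancerous/peritumoral lifetime ratios.

library(flimpipe)

out <- "results/stats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
meas <- read.csv("results/fits/measurements.csv")

canc <- meas$mean_tau_m_ps[meas$region == "cancerous"]
peri <- meas$mean_tau_m_ps[meas$region == "peritumoral"]
tt <- two_sample_ttest(canc, peri)
cat(sprintf("cancerous   (n=%d): mean %.1f ps, median %.1f ps\n",
            length(canc), mean(canc), boxplot_summary(canc)$median))
cat(sprintf("peritumoral (n=%d): mean %.1f ps, median %.1f ps\n",
            length(peri), mean(peri), boxplot_summary(peri)$median))
cat(sprintf("Student t-test: t = %.2f, two-sided p = %.3g %s\n", tt$t, tt$p,
            if (tt$p < 1e-4) "(**** p < 0.0001)" else ""))

jsonlite::write_json(
  list(t = tt$t, p = tt$p, df = tt$df,
       cancerous = boxplot_summary(canc),
       peritumoral = boxplot_summary(peri)),
  file.path(out, "group_stats.json"), auto_unbox = TRUE, digits = NA)

norm <- normalize_to_peritumoral(meas)
write.csv(norm, file.path(out, "normalized.csv"), row.names = FALSE)
ratios <- lifetime_ratios(meas)
write.csv(ratios, file.path(out, "ratios.csv"), row.names = FALSE)
cat("per-sample cancerous/peritumoral ratios:",
    paste(sprintf("%s %.2f", ratios$sample_id, ratios$lifetime_ratio),
          collapse = ", "), "\n")
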