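#!/usr/bin/env Rscript
# Telomere above-background scoring: segment the telomere marker channel
# in 3D, measure the mean sensor intensity per telomere, and report the
# fraction above the diffuse nucleoplasmic background (mean + 2 SD).

suppressPackageStartupMessages(library(rloopquant))
dir.create("results", showWarnings = FALSE)

ts <- simulate_telomere_scene(n_telomeres = 100, n_with_sensor = 32,
                              sensor_contrast = 10,
                              noise = noise_model(0, 1, FALSE), seed = 1)
obj <- segment_marker_foci(ts$marker, nucleus = ts$nucleus_roi)
res <- fraction_above_background(obj, ts$sensor, ts$background_roi, k_sd = 2)

out <- res$objects
out$voxels <- NULL
write.csv(out, "results/telomere_objects.csv", row.names = FALSE)
write.csv(data.frame(n_telomeres = res$n_total, n_above = res$n_above,
                     fraction = res$fraction, bg_mean = res$bg_mean,
                     bg_sd = res$bg_sd, k_sd = 2),
          "results/telomere_fraction.csv", row.names = FALSE)
cat(sprintf("segmented %d telomeres; %d (%.0f%%) carry sensor signal above background (bg %.1f +/- %.2f, threshold mean + 2 SD)\n",
            res$n_total, res$n_above, 100 * res$fraction,
            res$bg_mean, res$bg_sd))
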