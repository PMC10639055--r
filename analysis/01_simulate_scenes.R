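#!/usr/bin/env Rscript
# Generate the synthetic datasets the downstream analyses run on: a 3D
# nuclear foci scene, a FRAP experiment, and a two-channel locus time
# lapse. Images go to scratch/ (large, regenerable); ground truth and
# summaries go to results/.

suppressPackageStartupMessages(library(rloopquant))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)
seed <- 1L

cfg <- scene_config(n_foci = 20L, seed = seed)  # 30 x 256 x 256 default
sc <- simulate_nucleus_scene(cfg)
write_stack(sc$stack, "scratch/scene_seed1.tif")
write_rois(list(cfg$nucleus, shrink_polygon(cfg$nucleus, 6)),
           "scratch/scene_seed1_rois.yml")
write.csv(sc$truth, "results/scene_seed1_truth.csv", row.names = FALSE)
cat(sprintf("scene: %d foci, peak %d-%d photons, stack %s\n",
            nrow(sc$truth), round(min(sc$truth$peak_photons)),
            round(max(sc$truth$peak_photons)),
            paste(dim(sc$stack$data), collapse = "x")))

frap_cfg <- frap_sim_config(fractions = frap_components_for_times(1.5, 8.1),
                            seed = seed)
frap <- simulate_frap_experiment(frap_cfg)
exp_df <- data.frame(time_s = frap$experiment$times_s,
                     roi = frap$experiment$roi_series,
                     background = frap$experiment$background_series,
                     reference = frap$experiment$reference_series)
write.csv(exp_df, "results/frap_seed1_raw.csv", row.names = FALSE)
cat(sprintf("FRAP: %d frames at %.1f s, true t50 %.2f s, t80 %.2f s\n",
            nrow(exp_df), frap_cfg$dt_s, frap$truth$t50_s, frap$truth$t80_s))

loc <- simulate_locus_timelapse(burst_period_s = 45, burst_duration_s = 20,
                                n_frames = 75, dt_s = 8, seed = seed)
write_stack(loc$stack, "scratch/locus_seed1.tif")
write.csv(loc$truth$bursts, "results/locus_seed1_bursts.csv",
          row.names = FALSE)
cat(sprintf("locus: %d frames at %d s, %d true bursts of %d s every %d s\n",
            75, 8, nrow(loc$truth$bursts), 20, 45))
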