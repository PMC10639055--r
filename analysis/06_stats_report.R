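#!/usr/bin/env Rscript
# Foci-count statistics as used for the cell-population experiments:
# per-cell spot counts under control and transcription-inhibited
# conditions, Mann-Whitney U for independent groups, paired t for the
# same cells before/after, and the box-plot summary table.

suppressPackageStartupMessages(library(rloopquant))
dir.create("results", showWarnings = FALSE)

count_cell <- function(n_foci, seed) {
  cfg <- scene_config(image_shape = c(z = 10L, y = 96L, x = 96L),
                      n_foci = n_foci, seed = seed)
  sc <- simulate_nucleus_scene(cfg)
  nrow(detect_spots(sc$stack, nucleus = shrink_polygon(cfg$nucleus, 6)))
}

# independent groups: control cells vs cells with ~50% fewer foci
set.seed(1)
n_cells <- 12L
ctrl_truth <- pmax(4L, rpois(n_cells, 20))
trt_truth <- pmax(2L, rpois(n_cells, 10))
ctrl <- vapply(seq_len(n_cells), function(i) count_cell(ctrl_truth[i], 500L + i), 0L)
trt <- vapply(seq_len(n_cells), function(i) count_cell(trt_truth[i], 600L + i), 0L)

mw <- mann_whitney_u(ctrl, trt)
summary_tab <- summarize_counts(list(control = ctrl, treated = trt))
write.csv(summary_tab, "results/foci_count_summary.csv", row.names = FALSE)

# paired design: the same cells before and after treatment
after_truth <- pmax(2L, round(ctrl_truth * 0.5))
after <- vapply(seq_len(n_cells), function(i) count_cell(after_truth[i], 700L + i), 0L)
pt <- paired_t(ctrl, after)

stats_tab <- data.frame(
  test = c("mann_whitney_u", "paired_t"),
  comparison = c("control vs treated (independent cells)",
                 "same cells before vs after treatment"),
  statistic = c(mw$U, pt$t),
  p = c(mw$p, pt$p),
  mark = significance_marks(c(mw$p, pt$p)),
  n1 = c(length(ctrl), n_cells),
  n2 = c(length(trt), n_cells),
  method = c(mw$method, "paired t"))
write.csv(stats_tab, "results/foci_count_tests.csv", row.names = FALSE)

print(summary_tab, row.names = FALSE, digits = 3)
print(stats_tab[, c("test", "statistic", "p", "mark")], row.names = FALSE,
      digits = 3)
cat(sprintf("treated cells show %.0f%% of the control foci count (medians %g vs %g)\n",
            100 * median(trt) / median(ctrl), median(trt), median(ctrl)))
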