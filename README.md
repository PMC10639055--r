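# rloopquant

Quantitative analysis of live-cell R-loop imaging with a
hybrid-binding-domain (HBD) fluorescent sensor. R-loops — three-stranded
structures of an RNA:DNA hybrid plus the displaced DNA strand — form and
resolve co-transcriptionally; a genetically encoded sensor built from
tandem RNase H1 hybrid-binding domains makes them visible as discrete
nuclear foci in live cells. This package implements the measurement side
of that experiment for microscopists and image analysts: detecting and
counting sensor foci in 3D, extracting binding kinetics from FRAP, scoring
telomeres for sensor accumulation, and following sensor intensity at a
single gene locus through time. A synthetic-microscopy generator with full
ground truth makes the whole pipeline testable without any external data.

## What it computes

* **Foci detection** — per-slice à-trous (undecimated) wavelet
  decomposition with the B3-spline kernel; a voxel is kept when its detail
  coefficient exceeds a sensitivity-mapped robust threshold at every
  enabled scale (defaults: scale 2 → 60, scale 3 → 130); 26-connected 3D
  grouping, a 2–50 voxel size filter, and restriction to a nuclear polygon
  ROI. A projection-based Otsu counter handles DAPI/γH2AX-style
  per-nucleus counts.
* **FRAP kinetics** — double normalization
  `N(t) = (x(t) − x(t₀⁺)) / (x̄_pre − x(t₀⁺))` with background subtraction
  and reference-based correction for acquisition photobleaching; recovery
  half-times read from the curve (t50, t80) with linear interpolation;
  plateau; fast/slow population classification; and fold-over-reference
  ratios `t_pop / mean(t_ref)` against diffusing or binding-dead controls.
* **Telomere scoring** — 3D segmentation of the telomere-marker channel;
  a telomere counts as R-loop-positive when its mean sensor intensity
  exceeds the nucleoplasmic background by > 2 SD.
* **Locus tracking** — intensity-weighted center-of-intensity tracking of
  a marker spot with shell-background-subtracted sensor readout, burst
  (fluctuation-cycle) detection, and Welch t-tests of the response to
  transcription inhibition.
* **Statistics** — Mann–Whitney U (exact by enumeration for small
  samples), paired and Welch t-tests, `*`/`**`/`***` significance marks,
  and box-plot summary tables.

## Worked example

Simulate a nuclear scene, detect its foci, and measure FRAP kinetics for a
population whose true recovery crosses 50%/80% at 1.5 s / 8.1 s:

```r
library(rloopquant)

cfg <- scene_config(image_shape = c(z = 10, y = 96, x = 96),
                    n_foci = 20, seed = 1)
scene <- simulate_nucleus_scene(cfg)
spots <- detect_spots(scene$stack, nucleus = shrink_polygon(cfg$nucleus, 6))
nrow(spots)
#> [1] 20

frap <- simulate_frap_experiment(frap_sim_config(
  fractions = frap_components_for_times(1.5, 8.1), seed = 1))
curve <- normalize_frap(frap$experiment)
c(t50 = time_to_fraction(curve, 0.5), t80 = time_to_fraction(curve, 0.8))
#>      t50      t80
#> 1.500589 8.188962

fold_over_reference(8.1, c(2.4, 2.1))   # fast telomeric over the mutants
#> [1] 3.6
```

All 20 simulated foci are recovered; the measured half-times agree with
the population's true crossing times to within a fraction of a frame; and
the recovery-time fold of the fast telomeric population over the mean of
the two binding-dead mutants is 3.6 — a diffusion-corrected turnover
measure.

## Analysis workflow

The `analysis/` directory holds the numbered drivers that chain the
package end to end, each writing tables under `results/` (images under
`scratch/`):

| script | what it does |
|---|---|
| `01_simulate_scenes.R` | generate the reference scene, FRAP series and locus time lapse |
| `02_detect_spots.R` | wavelet detection + recall/precision vs ground truth |
| `03_frap_kinetics.R` | seven FRAP populations, kinetic table, folds, fast-vs-slow p-curve |
| `04_telomere_fraction.R` | telomere segmentation and above-background fraction |
| `05_locus_tracking.R` | locus track, burst period, transcription-inhibition response |
| `06_stats_report.R` | per-cell foci-count statistics and summary tables |

Run them in order with `Rscript analysis/01_simulate_scenes.R` etc.

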