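---
title: "Quantifying R-loop sensor imaging: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying R-loop sensor imaging: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rloopquant)
```

# Scope

`rloopquant` quantifies live-cell fluorescence imaging of R-loops labelled
with a hybrid-binding-domain (HBD) sensor. Four measurements drive the
package: (i) counting and characterizing discrete sensor foci in 3D
z-stacks; (ii) FRAP recovery kinetics of sensor populations at nucleoli and
telomeres; (iii) the fraction of telomeres carrying sensor signal above the
diffuse nucleoplasmic background; and (iv) sensor intensity at a single
tracked gene locus through time, including its response to transcription
inhibition. Because the underlying microscopy data are not deposited, every
stage is exercised against a synthetic-scene generator with complete ground
truth; this vignette records what that generator emulates, what it does
not, and the numerical decisions inside each analysis.

# Foci detection by undecimated wavelets

## The transform

Each z-slice is decomposed with the à-trous (undecimated) wavelet transform
using the B3-spline kernel $(1,4,6,4,1)/16$, applied separably with tap
spacing doubling at each scale and mirror boundaries. Detail plane $j$ is
the difference of successive smooths, so the input equals the sum of all
detail planes plus the residual smooth exactly (the telescoping identity,
asserted to $10^{-9}$ relative error in the tests). Scale $j$ responds to
structures of roughly $2^j - 1$ px: scale 2 ≈ 3 px and scale 3 ≈ 7 px at
0.16 µm pixels, matching diffraction-limited foci.

## Thresholds and the sensitivity convention

A voxel enters the detection mask when its detail coefficient exceeds a
per-scale threshold at *every* enabled scale (default scales 2 and 3; the
intersection suppresses structures supported at only one scale). The
threshold follows the sensitivity convention

$$\tau_j = \frac{100}{s_j} \cdot 3\,\hat\sigma_j,$$

so sensitivity $s_j = 100$ is a 3σ-equivalent robust cut and larger
sensitivities keep more voxels. The defaults — scale 1 disabled, scale 2 at
60, scale 3 at 130, component size 2–50 voxels, 2D planes grouped in 3D —
are the settings used for sensor foci in the source analyses. Two
refinements matter in practice:

* **Variance stabilization.** Shot noise makes bright nuclear interiors
  noisier than dim extranuclear regions, so a single threshold per scale is
  only meaningful after the Anscombe transform $2\sqrt{x + 3/8}$, which
  `detect_spots()` applies before decomposition (intensity statistics are
  always measured on the original voxels). Read noise at the default level
  (3 e⁻ against shot noise of ≥10 e⁻) perturbs the stabilized variance by
  only a few percent, so the plain Anscombe transform suffices.
* **Noise estimation.** $\hat\sigma_j$ is *not* the MAD of detail plane $j$
  itself: coarse detail planes are dominated by real structure (the nuclear
  rim, the diffuse plateau), which inflates their MAD several-fold and
  masks dim foci. Instead the image noise is estimated once, robustly, from
  the first detail plane pooled over slices, and propagated to scale $j$
  through the kernel's exact white-noise standard-deviation fractions
  (0.891, 0.201, 0.086, … in 2D, computed from the impulse response). The
  estimate is floored at the shot-noise level of the stabilized counts so
  that quantization ripple in noise-free synthetic images cannot masquerade
  as the noise floor. The exported `threshold_details()` keeps the plain
  per-plane MAD rule for direct 2D use.

Masked voxels are grouped by 26-connectivity (anisotropic voxels, 0.16 vs
0.32 µm, make diagonal z-contact common), components outside 2–50 voxels
are discarded, and — when a nuclear polygon is supplied — spots whose
intensity-weighted centroid falls outside it in x–y or z are removed. The
size filter is applied to the grouped 3D component. One useful side effect:
a sharp nuclear rim produces a single connected supra-threshold band around
the whole perimeter, which the 50-voxel cap removes wholesale. Detection
ROIs should still be drawn a few pixels inside the apparent rim (the
`shrink_polygon()` helper mimics this), as a human analyst does when
outlining nuclei on the sensor accumulation.

A single bright voxel over a realistic noisy background masks only itself
and is rejected by the minimum size of 2 — the camera-spike case the filter
exists for. On a mathematically flat, noise-free background the same
impulse instead produces an amplitude-independent 3×3 supra-threshold
footprint of the B3 kernel; this degenerate case does not occur in images
with photon noise.

The γH2AX-style counter (`count_foci_per_nucleus()`) is a separate, simpler
path: nuclei by global Otsu on the nuclear-stain maximum-intensity
projection with hole filling and a minimum-area filter; foci by per-nucleus
Otsu on the masked foci-stain pixels; components with area strictly greater
than 3 px counted.

# FRAP normalization and kinetics

Three series are measured per frame: the bleach-ROI mean, the extracellular
background mean, and the reference (labelled nucleus excluding the bleach
ROI). After background subtraction, the reference corrects acquisition
photobleaching via $c(t) = \overline{r}_\text{pre}/r(t)$, and the corrected
ROI series is scaled so the pre-bleach mean is exactly 1 and the first
post-bleach value exactly 0 (double normalization). Both anchors hold by
construction on every input, and for a noise-free simulated experiment with
per-frame bleaching up to 0.5% the normalized curve reproduces the
generator's true recovery to better than $10^{-6}$ — the correction cancels
the generator's decay exactly.

Kinetic parameters are read from the curve, not fitted: `time_to_fraction()`
returns the first post-bleach time at which the curve reaches the fraction
(relative to the pre-bleach level 1.0, not the plateau), with linear
interpolation between the bracketing frames; `plateau()` is the mean of the
last 10 frames. Optional moving-average smoothing is off by default —
recovery times in the tests are accurate to ≈0.01 s without it at the
default noise, and smoothing biases fast crossings late. A curve is *fast*
when t80 exists and is ≤ 36 s (the short-protocol post-bleach window of
5 pre + 120 post frames at 0.3 s); otherwise *slow* — which also captures
curves that plateau below 80%, such as a 65% plateau population. Folds over
a reference population divide a recovery time by the arithmetic mean of the
reference times; for telomeric populations the reference is the mean of the
two binding-dead sensor mutants, for nucleolar foci the diffuse nucleolar
sensor. This is the unique simple reference choice that reproduces all six
published fold values from the published times. Display rounding is
half-up at the printed precision; comparisons use the full-precision value.

Frame registration is translation-only integer-pixel cross-correlation
against the first pre-bleach frame (sub-pixel alignment is unnecessary for
ROI means). Pointwise comparisons between curve groups use two-sided Welch
t-tests at each frame — the unequal-variance form is used everywhere a
two-sample t-test is called for, since the variance assumption is otherwise
unstated.

# Telomere scoring and locus tracking

Telomeres are segmented by running the same wavelet detector on the marker
channel; each retained component keeps its voxel set, over which the mean
sensor intensity is measured. A telomere is *above background* when its
mean exceeds the nucleoplasmic background mean by more than `k_sd` = 2
background SDs. Strict mean-exceedance (`k_sd` = 0) would flag ~50% of null
telomeres, so a margin is necessary; 2 SD bounds the null fraction near 2%
and is exposed in configuration.

Single-locus tracking uses a background-subtracted intensity-weighted 3D
centroid of the marker within a search box around the previous position (a
deliberate simplification of Gaussian spot fitting — exact on symmetric
spots, and adequate because the readout is a sphere mean, not a
localization). The sensor readout is the mean in a 3-px sphere at the
tracked position minus the median of a 2–4 px shell, which absorbs slow
photobleaching. Fluctuation cycles are local maxima of the (optionally
smoothed) sensor series with prominence ≥ 0.5 series-SD; the median
inter-peak interval is the period. Responses to treatment are Welch t-tests
of the pre-treatment per-cell values against each post-treatment time
point.

# Statistical tests

Mann–Whitney U is computed from midranks; the two-sided p-value is exact
(from the null permutation distribution of U) when the smaller sample has
at most 8 values and there are no ties, and otherwise uses the normal
approximation with tie-corrected variance and no continuity correction.
The exact path is verified against full enumeration of all rank
assignments. Paired and two-sample t-tests wrap the standard
implementations with explicit handling of degenerate (zero-variance)
inputs: identical paired samples give p = 1 by convention; constant nonzero
differences are flagged and reported as p → 0. Significance marks follow
strict inequalities: `n.s.` at p ≥ 0.05, then `*`, `**`, `***` at 0.05,
0.01, 0.001. Summary tables report n, mean, SD, median and the two centre
quartiles using the linear-interpolation (type-7) rule.

# The synthetic generator

The generator emulates the acquisition this pipeline targets: 16-bit
z-stacks with 0.16 µm pixels and 0.32 µm z-steps; FRAP time-lapses of 5
pre-bleach and 120 post-bleach frames at 0.3 s (long protocol: 2 s frames
over 126 s) with a 25-px bleach ROI; locus series at 8–10 s or 10 min
frames.

**Scenes.** A polygonal nucleus carries a diffuse sensor level (default 100
photons) over an extranuclear floor (10), with optionally elevated
nucleolar polygons (150); the template is smoothed by the lateral PSF width
(a hard step is optically impossible). Foci are anisotropic Gaussians — PSF
σ 0.11 µm lateral / 0.30 µm axial, plus a heterogeneous intrinsic radius
drawn from U(0, 0.10) µm in quadrature — with peak amplitudes drawn from
U(120, 400) photons, i.e. SNR ≈ 11–38 against the diffuse-background noise.
Placement is uniform inside the nucleus with ≥ 8 px mutual separation and
≥ 10 px clearance from the rim so that each focus' PSF support lies in the
nucleoplasm. The camera chain is fixed as Poisson shot noise → Gaussian
read noise (σ = 3, photon-equivalent) → gain (1) → integer quantization, so
variance-based assertions are closed-form. One seed drives all randomness;
identical seeds give voxel-identical stacks.

**FRAP.** Recovery is a sum of exponential exchange components plus an
immobile fraction — a reaction-dominant binding model with no explicit
spatial diffusion, sufficient because the measured quantities are
times-to-fraction and plateaus. Since a single exponential fixes
t80/t50 = ln 5/ln 2 ≈ 2.32, populations with larger published ratios are
simulated with `frap_components_for_times()`, which solves a two-component
mixture whose noise-free curve crosses 50%/80% exactly at the published
times. Raw series are constructed so that the double normalization is the
exact inverse of the generator: fluorescent levels decay by
$(1-\beta)^\text{frame}$, the ROI follows
$\text{floor} + (1-\text{floor})R(t)$ after the bleach, and background is
constant. Shot noise on an ROI *mean* over $n$ pixels is simulated as
Poisson on the summed photons divided by $n$.

**Locus.** A static marker spot plus a sensor spot whose amplitude follows
deterministic on/off bursts (onsets every period, starting one period in).
After a treatment time, bursting stops and the amplitude decays
exponentially with τ = 360 s, placing the signal at background roughly 30
minutes after treatment.

**What the generator does not emulate** — and what passing tests therefore
do not show about real data: cell movement and focus drift (registration is
tested on constructed shifts only), sensor exchange between foci and the
diffuse pool, nonuniform illumination, EMCCD excess noise, chromatic shift
between channels, out-of-focus haze, and biological variation in focus
counts beyond the configured ranges. Detection scores on synthetic scenes
(recall/precision against ground truth) bound performance under the stated
SNR, not under real-microscope artifacts.

# Problem sizes and reproducibility

The test-suite and acceptance runs use 96×96×10 scenes (50 scenes × 20 foci
for detection fidelity), FRAP cohorts matching the published experiment
counts (25/14/37/22/16/13/8), 200 experiments for rate-recovery sweeps, and
10,000 replicates for null-size checks — sizes chosen so a full run
completes in well under a minute per stage on one core while keeping every
stochastic assertion inside 3-SE bands. `scripts/acceptance.R` recomputes
all headline quantities from scratch with a single `--seed`; every
simulation derives its stream from that seed, so runs are exactly
reproducible.

# Known limitations

* The sensitivity-to-threshold mapping is a documented convention, not a
  published formula; the values 60/130 are honoured under this mapping.
* Whether the original size filter acted on 2D or 3D components is not
  documented; 3D-component filtering is implemented, which makes very
  bright, very large foci (supra-threshold support > 50 voxels) rejectable
  by the upper bound.
* Fast/slow population assignment uses an explicit t80 cutoff (36 s); the
  original assignment criterion is not documented.
* The tracker carries the last position forward when the marker vanishes
  and flags the frame, rather than re-detecting globally.
* `fraction_above_background()` depends on a user-chosen (or helper-found)
  nucleoplasmic background region; a poorly placed region biases the
  threshold.
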