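---
title: "Quantifying FP-labeled genomic loci: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying FP-labeled genomic loci: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locusfoci)
```

# The measurement problem

Heterologous DNA-binding fluorescent protein (FP) systems — LacI/LacO,
ParB1/ParS1, ParB2/ParS2 — make a genomic locus visible as a
diffraction-limited focus inside a nucleus.  Whether such a system is usable
at a given locus comes down to two efficacy metrics, and once two loci (or
two alleles) are labeled in different colors, a third measurement becomes the
scientific payload:

1. **Per-spot signal-to-noise ratio (SNR)** — how bright a focus is relative
   to the diffuse background of unbound FP in the same nucleus.
2. **Labeling efficiency** — the fraction of nuclei in which a focus is
   detectable at all.
3. **Inter-locus 3D distance** — the Euclidean separation, in nanometres, of
   a green and a red focus marking two tagged positions (an
   enhancer–promoter pair in *cis*, or homologous alleles in *trans*).

`locusfoci` implements all three procedures with fixed, documented
geometries, a statistics layer for group comparison, and a synthetic-imaging
module that generates multi-channel Z-stacks with a complete ground-truth
manifest, so every stage of the pipeline is testable without microscopy
data.

# The SNR statistic

For a seed voxel (a manually picked or automatically detected focus), the
procedure is:

1. extract a 40 × 40 pixel, 13-slice ROI centred on the seed
   (`extractRoi()`);
2. select the Z plane with maximal pixel-intensity skewness
   (`maxSkewSlice()`) — a diffraction-limited focus adds a heavy right tail
   to the intensity histogram of its central plane, so skewness is a robust
   focus-plane indicator;
3. locate the maximum-intensity pixel in that plane;
4. delete (set to zero) a 14 × 14 pixel box centred on the maximum, then
   compute the mean and sample SD (n − 1 denominator) of the strictly
   positive pixels of the 28 × 28 box with the same centre;
5. report `SNR = (max − mean) / SD`.

```{r snr-example}
a <- array(0, c(13, 64, 64))
board <- outer(0:63, 0:63, function(y, x) ifelse((y + x) %% 2 == 0, 90, 110))
for (z in 1:13) a[z, , ] <- board
a[7, 33, 33] <- 400
computeSnr(voxelStack(a), list(z = 6, y = 32, x = 32))[
  c("skew_slice", "max_intensity", "background_mean", "background_sd", "snr")]
```

Numerical conventions, chosen once and applied everywhere:

* **0-based, half-open geometry.** A size-40 window around seed index `s`
  covers `[s − 20, s + 20)`, placing the seed at local index 20; the even
  deletion/background boxes centre on the max pixel the same way
  (`[c − 7, c + 7)`, `[c − 14, c + 14)`).  Half-open windows keep every box
  exactly its nominal size and compose without off-by-one drift.
* **Skewness** is the population (1/n) Fisher–Pearson moment form
  `m3 / m2^1.5`, the convention of ImageJ's "Skewness" measurement; a
  zero-variance plane scores 0, and slice ties resolve to the lowest index.
* **Deletion as zeroing.** The 14 × 14 box is zeroed and zero-valued pixels
  excluded from the background statistics.  A consequence worth knowing:
  genuinely zero-valued background pixels are excluded too.  On offset-free
  synthetic data with a dark background this can exhaust the background
  (fewer than 10 positive pixels), which raises an explicit error rather
  than returning a meaningless SD.
* **Border handling.** Seeds closer than 20 px to an XY border are rejected
  ("border seed"); Z windows truncate at stack boundaries and the actual
  depth is recorded.  The 13-slice window is centred on the seed slice.

The estimator is validated against the analytic companion `expectedSnr()`
(peak amplitude over the per-voxel background noise SD).  Because the
statistic uses the *maximum* pixel, it inherits an upward extreme-value bias
at low SNR that disappears as the true peak dominates the noise; the test
suite budgets 25% agreement across the SNR 5–50 range and verifies strict
monotonicity in spot amplitude.

# Labeling efficiency

Z-stacks are divided into consecutive 10-slice substacks (plus a remainder
substack when the depth is not divisible by 10), each substack is
MAX-projected, and each projection contributes one data point: the fraction
of its nuclei showing a detectable focus (`labelingEfficiency()`).

Nucleus identification on the DAPI projection is automated
(`segmentNuclei()`: Gaussian smoothing, Otsu threshold, hole filling,
distance-transform watershed, minimum-area filter — all via EBImage).  The
spot-positive call, which was a manual judgement in the original workflow,
is replaced by an explicit rule (`scoreSpotPositive()`): a nucleus is
positive iff its brightest in-mask pixel reaches
`median + kSigma × MAD` of its own pixel distribution.  Per-nucleus robust
statistics make the rule insensitive to nucleus-to-nucleus variation in
diffuse FP background; the MAD is floored at one count so blank nuclei can
never score positive.  `kSigma` defaults to 6 — high enough that the
maximum of several thousand projected noise pixels stays below threshold,
low enough that a focus several hundred counts above background always
clears it — and is recorded in every output row.  Any automated `kSigma`
reproduces the shape of the manual procedure, not its exact counts; the
validation experiments therefore test recovery of a *known* labeling
probability rather than agreement with a human rater.

# Dual-color 3D distances

`distancePipeline()` composes the measurement chain: green seeds → 15-slice
40 × 40 ROIs in both channels → per-channel focus localization → pairing
with exclusion rules → nm conversion → Euclidean distance → 750 nm filter.

Two detectors are implemented:

* **Object counting** (`detectObjectCounter()`, the presented default):
  threshold at 0.7 × the substack's global maximum, 26-connected components
  of at least 20 voxels, intensity-weighted centroid of the component
  containing the global-maximum voxel.  The threshold fraction applies to
  the global substack maximum, not a per-slice maximum: volume thresholding
  operates on the whole 3D object, while locating the brightest slice only
  identifies the focus's central plane.  The "approximate volume" of 20
  voxels is implemented as a minimum object size — the only volume-shaped
  parameter such a filter exposes.  Both the weighted centroid and the
  26-connectivity choice are recorded in the output.
* **Difference of Gaussians** (`detectDog()`, the concordance alternative):
  σ₁ = diameter/(2√3) with diameter 11 px, σ₂ = 1.6 σ₁, axial sigmas divided
  by the voxel aspect dz/dx, sub-pixel refinement by a per-axis 3-point
  quadratic fit.  The automatic response threshold is a robust floor
  (median + 5 × MAD) followed by an iterative Otsu raise: images of FP-laden
  nuclei always contain weak structural band-pass maxima at the
  nuclear-background rim, and the raise separates focus-like maxima from
  them whenever the two populations are clearly bimodal (upper class mean at
  least 1.5 × the lower).  The 1.5 guard deliberately refuses to split
  near-equal maxima, so sister-chromatid doublets stay on the same side of
  the threshold.  Seed finding on full stacks consequently presumes
  spot-bearing images; on a field with no true foci the rim maxima have no
  contrasting class and survive.

Pairing is conservative, mirroring a manual exclusion step: a group (nucleus
label when a mask is available, seed-ROI otherwise) yields a distance only
when it contains exactly one green and one red candidate.  Two or more
candidates of a colour (replicated sister chromatids) exclude the group as
`two_green`/`two_red`; a missing colour excludes it as `missing_partner`;
nothing is silently nearest-matched.  Distances are computed in nm from
sub-voxel centroids — coordinates are never rounded back to the voxel grid —
and the 750 nm threshold is applied strictly (`kept ⇔ distance < 750`),
flagging rather than deleting, with every exclusion logged once with its
reason.

Voxel calibration defaults to (dz, dy, dx) = (200, 65, 65) nm — typical
Airyscan sampling with a 63×/NA 1.4 objective and 2× zoom — and every
distance computation reads the calibration from the stack or configuration;
nothing is hard-coded to a pixel size.

# Group statistics

The comparison layer mirrors standard practice for these experiments:
pooled-variance Student's t for two groups (`studentT()`), one-way ANOVA
(`oneWayAnova()`) followed by Tukey's multiple comparisons at α = 0.05
(`tukeyHsd()`) for more, Tukey box summaries (`tukeyBox()`), and fold change
of group means (`foldChange()`, max/min).

* The Tukey–Kramer form `q = |mᵢ − mⱼ| / √(MSW/2 · (1/nᵢ + 1/nⱼ))` handles
  the unbalanced group sizes these experiments produce; adjusted p-values
  come from the studentized range distribution (`ptukey`) with k groups and
  the within-group degrees of freedom, and the test suite checks them
  against an independent numeric-integration CDF and against
  `stats::TukeyHSD`.
* One subtlety: the Tukey-adjusted p of a contrast is guaranteed to exceed
  the unadjusted p *computed with the same pooled error estimate*
  (q = √2·t at df_within).  It can fall below a two-group Student's t p for
  the same pair, because that t uses only the two groups' own variances;
  the property tests assert the well-defined form.
* Box quartiles use linear interpolation (type 7), the default of the usual
  plotting software, with whiskers at the most extreme data values within
  1.5 × IQR — whiskers are always actual observations, never fence values.

```{r stats-example}
tukeyHsd(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))$pairwise
```

# The synthetic-imaging model

`generateField()` renders what the quantification layer needs to see and no
more:

* **Nuclei** are non-overlapping spheres placed by rejection sampling (1000
  attempts per nucleus, then an error), XY-contained, Z-clipped when deeper
  than the stack — optical sections through epithelia are routinely thinner
  than the nuclei they cut.  Radius defaults to 1800 ± 120 nm.
* **Diffuse nuclear FP background** (default 100 ± 10 counts nucleus-to-
  nucleus, over 20 counts of cytoplasm) models unbound FP, the dominant
  noise source these labeling systems fight.  The "dapi" channel renders
  filled nuclei at 120 counts for segmentation.
* **Foci** are anisotropic 3D Gaussians (σ_lat 130 nm, σ_ax 350 nm —
  a diffraction-limited confocal PSF), amplitude 300 counts by default,
  placed uniformly inside the nucleus at least one PSF sigma from every
  stack border.  Labeling is Bernoulli per nucleus (default p = 0.3, the
  order of the efficiencies these systems achieve); in dual-label mode each
  labeled nucleus gets a green/red pair separated by a configurable draw.
* **Sister-chromatid doublets** duplicate the foci of a labeled nucleus at a
  500 nm offset with probability `doubletProb`.  The offset direction is
  lateral (in-plane) by default rather than uniformly 3D: at 500 nm an
  axially oriented doublet lies below the axial resolution (σ_ax ≈ 350 nm)
  and renders as a single focus — invisible to any two-spot exclusion rule,
  manual or automated — so the default produces the resolvable doublets the
  exclusion rule is designed to catch.  `doubletOrientation = "isotropic"`
  restores the uniform draw.
* **Noise** is per-voxel Poisson resampling of expected counts plus Gaussian
  read noise (default sd 3) plus a constant offset (default 10), rounded and
  clipped to 16-bit with clipping counted.

Reproducibility: one root seed; per-stage and per-channel streams are
derived by fixed offsets, so adding a channel never perturbs the draws of
existing channels, and an identical configuration yields bit-identical
stacks and truth.

What the simulator does *not* emulate — and what passing tests therefore do
not show about real data: chromatin motion and polymer physics, optical
aberrations and depth-dependent attenuation, chromatic misregistration
between channels (synthetic channels are co-registered by construction),
non-spherical or crowded epithelial nucleus shapes, and autofluorescent
debris.  Recovery of a known simulated separation bounds the *procedural*
error of the pipeline, not the biological measurement error of a real
microscope.

# Validation experiments and problem sizes

Four exported drivers define the package's acceptance-grade checks; the
sizes quoted are the defaults used by `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R`:

* `distanceRecoveryExperiment()` — true separations {260, 400, 600} nm, 9
  dual-label fields of 16 nuclei each per separation (≥ 100 kept pairs per
  separation), amplitude-to-noise ≈ 28; the median absolute recovery error
  must stay within one lateral voxel (65 nm) and the group medians must
  order correctly.
* `doubletExclusionExperiment()` — 4 fields at `doubletProb = 0.5`; every
  ground-truth doublet nucleus must be excluded and contribute no distance.
* `efficiencyExperiment()` — 9 fields × 60 nuclei at p = 0.3 (540 nuclei);
  the pooled spot-positive ratio must land inside the 95% binomial
  confidence band of 0.3.
* `nullAnovaExperiment()` — 2000 replicates of 3 equal normal groups of 30;
  the ANOVA rejection rate must sit at 5% ± 1.5% and the Tukey family-wise
  error at or below the same band.

These sizes were chosen as the smallest designs that give the quoted checks
statistical teeth (binomial CI width, ≥ 100 pairs per condition, Monte Carlo
error of a 5% rate at 2000 replicates ≈ 0.5%).

# Known limitations

* The SNR background statistics are 2D (max-skew plane only), by
  construction of the procedure; there is no 3D background option.
* The 28 × 28 background box assumes the nucleus extends that far around the
  focus; on nuclei smaller than ~ 1 µm radius the box mixes nuclear and
  cytoplasmic pixels and inflates the background SD.
* Automated seed finding assumes spot-bearing stacks (see the DoG threshold
  note above); fields known to be unlabeled should be quantified through
  the efficiency chain, not the seed finder.
* Labeling efficiency counts a nucleus once per projection it appears in;
  nuclei spanning substack boundaries are counted in each, exactly as the
  per-projection data points are defined.
* `pairSpots()` with multiple red candidates and no mask excludes the ROI
  rather than choosing the nearest red — a deliberate policy, not a
  reconstruction of how any particular manual analysis resolved such cases.
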