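# locusfoci

Image quantification for fluorescently labeled genomic loci in 3D confocal
stacks of *Drosophila* imaginal discs (and comparable tissue), aimed at
groups using heterologous DNA-binding FP systems — LacI/LacO, ParB1/ParS1,
ParB2/ParS2 — to mark tagged loci as nuclear foci.  The package answers the
three questions such experiments turn on:

* **How bright is a focus?** Per-spot signal-to-noise ratio on the
  maximum-skewness plane of a fixed 40 × 40 px, 13-slice ROI:
  `SNR = (I_max − μ_bg) / σ_bg`, with the background taken from a 28 × 28
  box around the maximum after deleting a 14 × 14 box at its centre.
* **How often does labeling work?** Labeling efficiency — the fraction of
  spot-positive nuclei — scored per 10-slice MAX projection, with automated
  DAPI nucleus segmentation and an explicit per-nucleus
  `median + kσ · MAD` spot-positive rule.
* **How far apart are two labeled loci?** Dual-color 3D localization
  (threshold/volume object counting at 0.7 × max with a ≥ 20-voxel size
  filter, or a difference-of-Gaussians detector with sub-pixel refinement),
  conservative green/red pairing that excludes replicated sister chromatids
  (`two_green` / `two_red`), Euclidean distance in nm
  `d = √(Δx² + Δy² + Δz²)`, and a strict 750 nm filter against pairs
  spanning neighbouring nuclei.

A group-statistics layer (pooled Student's *t*, one-way ANOVA with
Tukey–Kramer multiple comparisons at α = 0.05, Tukey box summaries, fold
change of means) and a synthetic-imaging module — spherical nuclei with
diffuse nuclear FP background, anisotropic Gaussian PSF foci, Poisson +
read noise, and a full ground-truth manifest — complete the pipeline, so
every stage is validated end to end without microscopy data.

## Worked example

Simulate a dual-label field with a known 400 nm green–red separation, then
recover the distance distribution blind:

```r
library(locusfoci)

cfg <- simulationConfig(nNuclei = 12L, stackDims = c(20L, 400L, 400L),
  labelingProb = 1, dualLabel = TRUE,
  pairSeparation = list(type = "fixed", value = 400),
  channels = c("green", "red"), seed = 42L)
field <- generateField(cfg)
field$truth
#> GroundTruth: 12 nuclei, 28 spots, 12 labeled pairs

dl <- distancePipeline(field$stacks$green, field$stacks$red)
summary(dl$records$distance_nm[dl$records$kept])
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   372.7   386.8   400.4   395.2   407.6   412.1
table(dl$exclusions$reason)
#> missing_partner       two_green
#>               1               4
```

The recovered median (400.4 nm) sits on the configured truth; the 28 spots
include two sister-chromatid doublet nuclei (the default
`doubletProb = 0.1` fired twice here), and each doublet is excluded as
`two_green` rather than contributing a spurious distance.  Per-spot SNR and
labeling efficiency run the same way:

```r
seeds <- findSeeds(field$stacks$green)
snr <- batchSnr(field$stacks$green, seeds)
eff <- labelingEfficiency(fpStack, dapiStack)   # needs a "dapi" channel
```

and `tukeyHsd(list(distal = ..., proximal = ...))` compares measurement
groups with adjusted p-values.  `runPipeline(cfg, outDir)` orchestrates the
whole chain and writes TIFFs, CSV tables and JSON manifests;
`inst/cli/locusfoci.R` exposes the same stages as a command-line tool
(`simulate`, `snr`, `efficiency`, `distance`, `stats`, `run`).

See the vignette (`vignettes/locus-labeling-quantification.Rmd`) for the
models, parameter defaults, numerical conventions, and the design decisions
behind them.

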