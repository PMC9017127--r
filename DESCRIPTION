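Package: locusfoci
Title: Quantification of Fluorescently Labeled Genomic Loci in 3D Microscopy Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify fluorescent protein (FP) labeling of genomic loci
    in 3D confocal stacks of Drosophila imaginal discs: per-spot signal-to-noise
    ratio on the maximum-skewness plane of a fixed-geometry ROI, labeling
    efficiency from 10-slice maximum projections, dual-color 3D focus
    localization (threshold/volume object counting and difference-of-Gaussians
    with sub-pixel refinement), nanometre-scale inter-locus distance
    distributions with sister-chromatid exclusion rules, and a group-comparison
    layer (Student's t, one-way ANOVA with Tukey's multiple comparisons, Tukey
    box summaries, fold change of means). Includes a synthetic multi-channel
    stack simulator with anisotropic PSF, Poisson plus Gaussian read noise and a
    complete ground-truth manifest, so every stage is testable without
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
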