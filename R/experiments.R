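# Validation experiments: end-to-end study designs run against the simulator's
# ground truth.  These drive the package's own acceptance checks and are
# exported so the same designs can be re-run and extended by users.

.expSeed <- function(seed, k) (abs(as.integer(seed)) %% 100000L) * 1000L + k

#' Distance-recovery experiment on dual-label fields
#'
#' Simulates dual-label fields at fixed true green/red separations, runs the
#' full distance pipeline (automatic seed finding, 15-slice ROIs,
#' object-counter centroids, pairing, 750 nm filter) and compares recovered
#' distances with the configured truth.
#'
#' @param separations true pair separations in nm.
#' @param fieldsPerSeparation simulated fields per separation.
#' @param nNuclei nuclei per field.
#' @param seed root seed.
#' @return \code{list(summary, distances)}: \code{summary} has one row per
#'   separation (\code{separation_nm, n_pairs, median_recovered_nm,
#'   median_abs_error_nm}); \code{distances} the kept distances per
#'   separation.
#' @export
distanceRecoveryExperiment <- function(separations = c(260, 400, 600),
                                       fieldsPerSeparation = 9L,
                                       nNuclei = 16L, seed = 1L) {
  distances <- list()
  rows <- list()
  for (si in seq_along(separations)) {
    sep <- separations[si]
    d <- c()
    for (fi in seq_len(fieldsPerSeparation)) {
      cfg <- simulationConfig(nNuclei = nNuclei,
        stackDims = c(20L, 400L, 400L), nucleusRadiusNm = c(1800, 120),
        labelingProb = 1, doubletProb = 0, dualLabel = TRUE,
        pairSeparation = list(type = "fixed", value = sep),
        channels = c("green", "red"),
        seed = .expSeed(seed, si * 100L + fi))
      f <- generateField(cfg)
      dl <- suppressWarnings(
        distancePipeline(f$stacks$green, f$stacks$red))
      d <- c(d, dl$records$distance_nm[dl$records$kept])
    }
    distances[[as.character(sep)]] <- d
    rows[[si]] <- data.frame(separation_nm = sep, n_pairs = length(d),
                             median_recovered_nm = stats::median(d),
                             median_abs_error_nm = stats::median(abs(d - sep)))
  }
  list(summary = do.call(rbind, rows), distances = distances)
}

#' Sister-chromatid exclusion experiment
#'
#' Simulates dual-label fields with a configurable doublet probability and
#' checks, against ground truth, that every doublet nucleus whose foci were
#' seeded is excluded as \code{two_green}/\code{two_red} and contributes no
#' distance record.
#'
#' @param nFields simulated fields.
#' @param doubletProb per-labeled-nucleus doublet probability.
#' @param nNuclei nuclei per field.
#' @param seed root seed.
#' @return one-row data.frame: \code{n_doublet_nuclei, n_flagged,
#'   n_doublet_in_records}.
#' @export
doubletExclusionExperiment <- function(nFields = 4L, doubletProb = 0.5,
                                       nNuclei = 14L, seed = 1L) {
  nDoublet <- nFlagged <- nLeaked <- 0L
  for (fi in seq_len(nFields)) {
    cfg <- simulationConfig(nNuclei = nNuclei, stackDims = c(20L, 400L, 400L),
      nucleusRadiusNm = c(1800, 120), labelingProb = 1,
      doubletProb = doubletProb, dualLabel = TRUE,
      pairSeparation = list(type = "fixed", value = 400),
      channels = c("green", "red"), seed = .expSeed(seed, 500L + fi))
    f <- generateField(cfg)
    seeds <- findSeeds(f$stacks$green)
    dl <- suppressWarnings(distancePipeline(f$stacks$green, f$stacks$red,
                                            seeds = seeds))
    sp <- truthSpots(f$truth)
    doubletNuc <- unique(sp$nucleus_id[sp$is_doublet_member])
    vs <- f$stacks$green@voxelSize
    nuc <- truthNuclei(f$truth)
    seedNuc <- vapply(seq_len(nrow(seeds)), function(i) {
      p <- c(seeds$x[i] * vs[3], seeds$y[i] * vs[2], seeds$z[i] * vs[1])
      nuc$id[which.min((nuc$x_nm - p[1])^2 + (nuc$y_nm - p[2])^2 +
                       (nuc$z_nm - p[3])^2)]
    }, numeric(1))
    exclRoi <- as.integer(sub("roi_", "",
      dl$exclusions$group_id[dl$exclusions$reason %in%
                               c("two_green", "two_red")]))
    recRoi <- as.integer(sub("roi_", "", dl$records$group_id))
    nDoublet <- nDoublet + length(doubletNuc)
    nFlagged <- nFlagged + sum(doubletNuc %in% seedNuc[exclRoi])
    nLeaked <- nLeaked + sum(seedNuc[recRoi] %in% doubletNuc)
  }
  data.frame(n_doublet_nuclei = nDoublet, n_flagged = nFlagged,
             n_doublet_in_records = nLeaked)
}

#' Labeling-efficiency recovery experiment
#'
#' Simulates fields of nuclei labeled with probability \code{p} and
#' high-amplitude foci, runs the projection/segmentation/scoring chain and
#' pools the spot-positive ratio over all projections.
#'
#' @param nFields simulated fields.
#' @param nNucleiPerField nuclei per field.
#' @param p true labeling probability.
#' @param seed root seed.
#' @return one-row data.frame: \code{n_nuclei, n_positive, pooled_ratio, p}.
#' @export
efficiencyExperiment <- function(nFields = 9L, nNucleiPerField = 60L,
                                 p = 0.3, seed = 1L) {
  tot <- c(pos = 0, n = 0)
  for (fi in seq_len(nFields)) {
    cfg <- simulationConfig(nNuclei = nNucleiPerField,
      stackDims = c(10L, 400L, 400L), nucleusRadiusNm = c(900, 60),
      labelingProb = p, doubletProb = 0, spotAmplitude = 500,
      channels = c("green", "dapi"), seed = .expSeed(seed, 700L + fi))
    f <- generateField(cfg)
    eff <- suppressWarnings(labelingEfficiency(f$stacks$green,
                                               f$stacks$dapi))
    tot <- tot + c(sum(eff$n_spot_positive), sum(eff$n_nuclei))
  }
  data.frame(n_nuclei = tot[["n"]], n_positive = tot[["pos"]],
             pooled_ratio = tot[["pos"]] / tot[["n"]], p = p)
}

#' Null-simulation calibration of the ANOVA/Tukey layer
#'
#' Draws \code{nReps} replicates of k equal normal groups and records how
#' often the one-way ANOVA rejects at \code{alpha} and how often any Tukey
#' pair is declared significant (family-wise error).
#'
#' @param nReps replicates.
#' @param k groups per replicate.
#' @param n observations per group.
#' @param alpha significance level.
#' @param seed root seed.
#' @return one-row data.frame: \code{anova_rejection_rate, tukey_fwer,
#'   n_reps}.
#' @export
nullAnovaExperiment <- function(nReps = 2000L, k = 3L, n = 30L,
                                alpha = 0.05, seed = 1L) {
  set.seed(.expSeed(seed, 900L))
  rejA <- rejT <- 0L
  for (r in seq_len(nReps)) {
    g <- lapply(seq_len(k), function(i) stats::rnorm(n))
    names(g) <- paste0("g", seq_len(k))
    res <- tukeyHsd(g, alpha = alpha)
    if (res$p < alpha) rejA <- rejA + 1L
    if (any(res$pairwise$p_adjusted < alpha)) rejT <- rejT + 1L
  }
  data.frame(anova_rejection_rate = rejA / nReps, tukey_fwer = rejT / nReps,
             n_reps = nReps)
}
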