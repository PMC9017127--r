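# File formats and orchestration: one channel per multi-page TIFF (plane
# order = z ascending), CSV seed/result tables (0-based voxel coordinates,
# distances in nm), JSON config and ground-truth manifests.

#' Read a single-channel multi-page TIFF as a VoxelStack
#'
#' Planes are taken as Z ascending.  Calibration comes from \code{voxelSize}
#' (the run configuration); when absent, package defaults are used with a
#' warning.  RGB-interleaved files are rejected: one channel per file.
#'
#' @param path TIFF file path.
#' @param voxelSize \code{c(dz, dy, dx)} nm, or NULL for the default
#'   (200, 65, 65) with a warning.
#' @param channel channel name to record.
#' @return A \linkS4class{VoxelStack}.
#' @export
readStack <- function(path, voxelSize = NULL, channel = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!length(pages)) stop("zero planes in ", path)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("one channel per file: ", path, " has interleaved samples")
  d <- dim(pages[[1]])
  if (any(vapply(pages, function(p) any(dim(p) != d), logical(1))))
    stop("mixed plane dimensions in ", path)
  a <- array(0, c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) a[i, , ] <- pages[[i]]
  if (is.null(voxelSize)) {
    warning("no voxel calibration given for ", path,
            "; using default (200, 65, 65) nm")
    voxelSize <- c(200, 65, 65)
  }
  voxelStack(a, voxelSize, channel)
}

#' Write a VoxelStack to a 16-bit multi-page TIFF
#'
#' Planes are written Z ascending; values are rounded and clipped to the
#' 16-bit range.  Round-trips exactly through \code{\link{readStack}} for
#' integer-valued stacks.
#'
#' @param stack a \linkS4class{VoxelStack}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "VoxelStack"))
  a <- pmin(pmax(round(stack@intensities), 0), 65535)
  pages <- lapply(seq_len(dim(a)[1]), function(i) a[i, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read / write spot seed tables
#'
#' CSV with header \code{channel,z,y,x}; coordinates are 0-based voxel
#' indices.
#'
#' @param path CSV path.
#' @param seeds data.frame with columns \code{channel, z, y, x}.
#' @return \code{readSeeds}: the seeds data.frame.
#' @export
readSeeds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "z", "y", "x")
  if (!all(need %in% names(df)))
    stop("seed file must have columns: ", paste(need, collapse = ", "))
  df[need]
}

#' @rdname readSeeds
#' @export
writeSeeds <- function(seeds, path) {
  utils::write.csv(seeds[c("channel", "z", "y", "x")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write / read a ground-truth manifest as JSON
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param path JSON path.
#' @param voxelSize calibration recorded in the manifest.
#' @return \code{readGroundTruth}: a \linkS4class{GroundTruth}.
#' @export
writeGroundTruth <- function(truth, path, voxelSize = c(200, 65, 65)) {
  jsonlite::write_json(list(voxel_size_nm = voxelSize,
                            nuclei = truth@nuclei, spots = truth@spots,
                            pair_distances = truth@pairDistances),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  asdf <- function(x, proto) if (is.data.frame(x) && nrow(x)) x else proto
  groundTruth(
    asdf(j$nuclei, data.frame(id = integer(), x_nm = numeric(),
                              y_nm = numeric(), z_nm = numeric(),
                              radius_nm = numeric())),
    asdf(j$spots, data.frame(nucleus_id = integer(), channel = character(),
                             x_nm = numeric(), y_nm = numeric(),
                             z_nm = numeric(), amplitude = numeric(),
                             is_doublet_member = logical())),
    asdf(j$pair_distances,
         data.frame(nucleus_id = integer(), distance_nm = numeric())))
}

.configToList <- function(config) {
  sl <- slotNames(class(config))
  out <- lapply(sl, function(s) slot(config, s))
  names(out) <- sl
  out
}

#' Run the full analysis pipeline on a simulated field
#'
#' Simulates a field from \code{config}, writes the per-channel TIFFs and the
#' ground-truth/config manifests to \code{outDir}, then runs seed finding,
#' per-spot SNR, labeling efficiency (when a "dapi" channel is present) and,
#' in dual-label mode, the green/red distance pipeline; each table is written
#' as CSV.  Deterministic for a fixed config seed: running twice produces
#' byte-identical outputs.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param outDir output directory (created if needed).
#' @param kSigma efficiency spot-positive stringency.
#' @param thresholdNm distance filter in nm.
#' @return Invisibly, a list with elements \code{stacks, truth, seeds, snr,
#'   efficiency, distances, exclusions} (the non-applicable ones NULL).
#' @export
runPipeline <- function(config, outDir, kSigma = 6, thresholdNm = 750) {
  stopifnot(is(config, "SimulationConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  field <- generateField(config)
  jsonlite::write_json(.configToList(config),
                       file.path(outDir, "config.json"),
                       digits = NA, auto_unbox = TRUE)
  writeGroundTruth(field$truth, file.path(outDir, "ground_truth.json"),
                   config@voxelSize)
  for (ch in names(field$stacks))
    writeStack(field$stacks[[ch]], file.path(outDir, paste0(ch, ".tif")))

  fpChans <- setdiff(config@channels, "dapi")
  out <- list(stacks = field$stacks, truth = field$truth, seeds = NULL,
              snr = NULL, efficiency = NULL, distances = NULL,
              exclusions = NULL)

  primary <- if ("green" %in% fpChans) "green" else fpChans[1]
  if (length(fpChans)) {
    seeds <- findSeeds(field$stacks[[primary]])
    out$seeds <- seeds
    writeSeeds(seeds, file.path(outDir, "seeds.csv"))
    snr <- suppressWarnings(batchSnr(field$stacks[[primary]], seeds))
    out$snr <- snr
    utils::write.csv(snr, file.path(outDir, "snr.csv"), row.names = FALSE)
  }
  if ("dapi" %in% config@channels && length(fpChans)) {
    eff <- suppressWarnings(labelingEfficiency(field$stacks[[primary]],
                                               field$stacks[["dapi"]],
                                               kSigma = kSigma))
    out$efficiency <- eff
    utils::write.csv(eff, file.path(outDir, "efficiency.csv"),
                     row.names = FALSE)
  }
  if (config@dualLabel) {
    dl <- suppressWarnings(distancePipeline(field$stacks[["green"]],
                                            field$stacks[["red"]],
                                            thresholdNm = thresholdNm))
    out$distances <- dl$records
    out$exclusions <- dl$exclusions
    utils::write.csv(dl$records, file.path(outDir, "distances.csv"),
                     row.names = FALSE)
    utils::write.csv(dl$exclusions, file.path(outDir, "exclusions.csv"),
                     row.names = FALSE)
  }
  invisible(out)
}
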