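# Dual-color 3D inter-locus distances: centroid pairing, voxel-to-nm
# conversion, Euclidean distance, sister-chromatid exclusion and the 750 nm
# neighbouring-nucleus filter.

#' Convert voxel coordinates to nanometres
#'
#' Componentwise multiplication by the voxel calibration; axis order is
#' converted from \code{(cz, cy, cx)} voxels to \code{(x, y, z)} nm for the
#' distance formula.
#'
#' @param coord numeric \code{c(cz, cy, cx)} (sub-voxel, 0-based) or a matrix
#'   with those three columns.
#' @param voxelSize \code{c(dz, dy, dx)} in nm, strictly positive.
#' @return \code{c(x, y, z)} in nm (or a matrix of such rows).
#' @examples
#' voxelToNm(c(10, 10, 10), c(200, 65, 65))  # 650 650 2000
#' @export
voxelToNm <- function(coord, voxelSize = c(200, 65, 65)) {
  if (any(voxelSize <= 0)) stop("voxelSize must be strictly positive")
  if (is.matrix(coord)) {
    out <- cbind(x = coord[, 3] * voxelSize[3], y = coord[, 2] * voxelSize[2],
                 z = coord[, 1] * voxelSize[1])
    return(out)
  }
  c(x = coord[3] * voxelSize[3], y = coord[2] * voxelSize[2],
    z = coord[1] * voxelSize[1])
}

#' @describeIn voxelToNm Inverse conversion: \code{c(x, y, z)} nm to
#'   \code{c(cz, cy, cx)} voxels.
#' @export
nmToVoxel <- function(coord, voxelSize = c(200, 65, 65)) {
  if (any(voxelSize <= 0)) stop("voxelSize must be strictly positive")
  c(cz = coord[3] / voxelSize[1], cy = coord[2] / voxelSize[2],
    cx = coord[1] / voxelSize[3])
}

#' 3D Euclidean distance
#'
#' \eqn{\sqrt{\Delta x^2 + \Delta y^2 + \Delta z^2}} between two points in nm.
#'
#' @param p1,p2 numeric length-3 points (same axis order).
#' @return distance in nm.
#' @export
euclidean3d <- function(p1, p2) sqrt(sum((p1 - p2)^2))

#' Pair green and red focus candidates within groups
#'
#' A group (nucleus label or ROI id) with exactly one green and one red
#' candidate yields a pair; groups with two or more candidates of either
#' colour are excluded (reasons \code{two_green} / \code{two_red}: likely
#' replicated sister chromatids), and groups missing a colour are excluded
#' (\code{missing_partner}).
#'
#' @param green,red data.frames of centroids with columns \code{group_id, cz,
#'   cy, cx} (sub-voxel parent-frame voxels).
#' @return \code{list(pairs, exclusions)}: \code{pairs} has one row per kept
#'   group with the two centroids side by side; \code{exclusions} has
#'   \code{group_id, reason}.
#' @export
pairSpots <- function(green, red) {
  groups <- union(green$group_id, red$group_id)
  pairs <- list()
  excl <- list()
  for (g in groups) {
    gi <- green[green$group_id == g, , drop = FALSE]
    ri <- red[red$group_id == g, , drop = FALSE]
    if (nrow(gi) >= 2L) {
      excl[[length(excl) + 1L]] <- data.frame(group_id = g,
                                              reason = "two_green")
    } else if (nrow(ri) >= 2L) {
      excl[[length(excl) + 1L]] <- data.frame(group_id = g,
                                              reason = "two_red")
    } else if (nrow(gi) == 0L || nrow(ri) == 0L) {
      excl[[length(excl) + 1L]] <- data.frame(group_id = g,
                                              reason = "missing_partner")
    } else {
      pairs[[length(pairs) + 1L]] <- data.frame(
        group_id = g, g_cz = gi$cz, g_cy = gi$cy, g_cx = gi$cx,
        r_cz = ri$cz, r_cy = ri$cy, r_cx = ri$cx)
    }
  }
  emptyPairs <- data.frame(group_id = character(), g_cz = numeric(),
                           g_cy = numeric(), g_cx = numeric(),
                           r_cz = numeric(), r_cy = numeric(),
                           r_cx = numeric())
  emptyExcl <- data.frame(group_id = character(), reason = character())
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else emptyPairs,
       exclusions = if (length(excl)) do.call(rbind, excl) else emptyExcl)
}

#' Flag distances below the nucleus-spanning threshold
#'
#' Sets \code{kept = distance_nm < thresholdNm} (strictly below) on every
#' record; nothing is deleted, and over-threshold records are logged as
#' exclusions with reason \code{over_threshold}.  The default 750 nm removes
#' focus pairs spanning neighbouring nuclei.
#'
#' @param records data.frame with columns \code{group_id, distance_nm}.
#' @param thresholdNm filter threshold in nm (> 0).
#' @return \code{list(records, exclusions)}: records gain \code{kept} and
#'   \code{threshold_nm} columns.
#' @export
filterDistances <- function(records, thresholdNm = 750) {
  if (thresholdNm <= 0) stop("thresholdNm must be > 0")
  records$kept <- records$distance_nm < thresholdNm
  records$threshold_nm <- rep(thresholdNm, nrow(records))
  over <- records$group_id[!records$kept]
  excl <- data.frame(group_id = as.character(over),
                     reason = rep("over_threshold", length(over)))
  list(records = records, exclusions = excl)
}

# nucleus label under a seed, from an integer label mask (y, x)
.seedGroup <- function(seed, mask) {
  if (is.null(mask)) return(NA_integer_)
  mask[seed$y + 1L, seed$x + 1L]
}

#' End-to-end dual-color distance pipeline
#'
#' Composes the analysis chain: green seeds (given, or found with the DoG
#' detector), per-seed 15-slice ROI extraction in both channels, per-channel
#' focus candidate detection, pairing with the sister-chromatid exclusion
#' rules, nm conversion, 3D distance, and the distance-threshold filter.
#' Grouping is per nucleus when a label mask is supplied, per seed-ROI
#' otherwise; per-ROI failures are logged, never fatal.  The presented
#' centroids come from the object-counting detector by default; \code{"dog"}
#' is a flagged alternative.
#'
#' @param greenStack,redStack co-registered \linkS4class{VoxelStack}s.
#' @param seeds optional data.frame \code{(z, y, x)} of green seeds; found
#'   automatically when \code{NULL}.
#' @param mask optional integer nucleus label matrix (y, x) for grouping.
#' @param detector \code{"object_counter"} (default) or \code{"dog"}.
#' @param nSlices,xySize ROI geometry (defaults 15, 40).
#' @param thresholdFrac,minVolume object-counter parameters (defaults 0.7, 20).
#' @param dogDiameter DoG spot diameter in pixels (default 11).
#' @param thresholdNm distance filter (default 750 nm).
#' @return \code{list(records, exclusions)}; \code{records} columns:
#'   \code{group_id, gx, gy, gz, rx, ry, rz} (nm), \code{distance_nm, kept,
#'   threshold_nm, detector}.
#' @export
distancePipeline <- function(greenStack, redStack, seeds = NULL, mask = NULL,
                             detector = c("object_counter", "dog"),
                             nSlices = 15L, xySize = 40L,
                             thresholdFrac = 0.7, minVolume = 20L,
                             dogDiameter = 11, thresholdNm = 750) {
  detector <- match.arg(detector)
  stopifnot(is(greenStack, "VoxelStack"), is(redStack, "VoxelStack"))
  vs <- greenStack@voxelSize
  if (is.null(seeds)) seeds <- findSeeds(greenStack, diameterPx = dogDiameter)
  emptyRec <- data.frame(group_id = character(), gx = numeric(),
                         gy = numeric(), gz = numeric(), rx = numeric(),
                         ry = numeric(), rz = numeric(),
                         distance_nm = numeric(), kept = logical(),
                         threshold_nm = numeric(), detector = character())
  exclusions <- data.frame(group_id = character(), reason = character())
  if (!nrow(seeds)) return(list(records = emptyRec, exclusions = exclusions))

  roiCandidates <- function(stack, seed, ch) {
    roi <- extractRoi(stack, seed, xySize = xySize, nSlices = nSlices)
    if (detector == "object_counter") {
      cc <- objectComponents(roi$substack, thresholdFrac, minVolume,
                             origin = roi$box$origin)
    } else {
      cc <- detectDog(roi$substack, diameterPx = dogDiameter,
                      origin = roi$box$origin, channel = ch)
    }
    cc
  }

  # group seeds by nucleus when a mask is given, else each seed is its own ROI
  groupIds <- vapply(seq_len(nrow(seeds)), function(i) {
    g <- .seedGroup(list(y = seeds$y[i], x = seeds$x[i]), mask)
    if (is.na(g)) paste0("roi_", i) else paste0("nucleus_", g)
  }, character(1))

  records <- list()
  for (g in unique(groupIds)) {
    rows <- which(groupIds == g)
    if (length(rows) > 1L) {
      # two green seeds in one nucleus: replicated sister chromatids
      exclusions <- rbind(exclusions,
                          data.frame(group_id = g, reason = "two_green"))
      next
    }
    i <- rows[1L]
    seed <- list(z = seeds$z[i], y = seeds$y[i], x = seeds$x[i])
    res <- tryCatch({
      gc <- suppressWarnings(roiCandidates(greenStack, seed, "green"))
      rc <- suppressWarnings(roiCandidates(redStack, seed, "red"))
      if (nrow(gc) >= 2L) data.frame(group_id = g, reason = "two_green")
      else if (nrow(rc) >= 2L) data.frame(group_id = g, reason = "two_red")
      else if (nrow(gc) == 0L || nrow(rc) == 0L)
        data.frame(group_id = g, reason = "missing_partner")
      else {
        gp <- voxelToNm(c(gc$cz, gc$cy, gc$cx), vs)
        rp <- voxelToNm(c(rc$cz, rc$cy, rc$cx), vs)
        data.frame(group_id = g, gx = gp[1], gy = gp[2], gz = gp[3],
                   rx = rp[1], ry = rp[2], rz = rp[3],
                   distance_nm = euclidean3d(gp, rp))
      }
    }, error = function(e) {
      warning("group ", g, " skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(res)) next
    if ("reason" %in% names(res)) exclusions <- rbind(exclusions, res)
    else records[[length(records) + 1L]] <- res
  }

  if (!length(records)) return(list(records = emptyRec,
                                    exclusions = exclusions))
  records <- do.call(rbind, records)
  flt <- filterDistances(records, thresholdNm)
  flt$records$detector <- detector
  list(records = flt$records,
       exclusions = rbind(exclusions, flt$exclusions))
}
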