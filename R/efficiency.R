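# Labeling efficiency: fraction of nuclei showing a detectable focus,
# computed per 10-slice maximum projection of the Z-stack.

#' Split a stack into consecutive Z substacks
#'
#' Consecutive non-overlapping groups of \code{groupSize} slices, plus one
#' remainder group if the depth is not divisible by \code{groupSize} (a
#' depth-25 stack yields groups of 10, 10 and 5 slices).
#'
#' @param stack a \linkS4class{VoxelStack}.
#' @param groupSize slices per group (>= 1, default 10).
#' @return list of \linkS4class{VoxelStack} substacks, each carrying
#'   attributes \code{zStart}/\code{zEnd} (0-based, half-open).
#' @export
splitSubstacks <- function(stack, groupSize = 10L) {
  stopifnot(is(stack, "VoxelStack"))
  if (groupSize < 1L) stop("groupSize must be >= 1")
  nz <- dim(stack@intensities)[1]
  starts <- seq(0L, nz - 1L, by = groupSize)
  lapply(starts, function(z0) {
    z1 <- min(nz, z0 + groupSize)
    sub <- voxelStack(stack@intensities[(z0 + 1L):z1, , , drop = FALSE],
                      stack@voxelSize, stack@channel)
    attr(sub, "zStart") <- z0
    attr(sub, "zEnd") <- z1
    sub
  })
}

#' Maximum-intensity Z projection
#'
#' @param substack a \linkS4class{VoxelStack} or 3D \code{(z, y, x)} array.
#' @return numeric matrix (y, x): per-pixel maximum over Z.
#' @export
maxProject <- function(substack) {
  a <- if (is(substack, "VoxelStack")) substack@intensities else substack
  Reduce(pmax, lapply(seq_len(dim(a)[1]), function(i) a[i, , ]))
}

#' Segment nuclei in a DAPI projection
#'
#' Smoothed Otsu foreground, hole filling, and a distance-transform watershed
#' to split touching nuclei; objects below \code{minArea} pixels are removed
#' and labels renumbered consecutively.  Deterministic.
#'
#' @param projection numeric matrix (a DAPI maximum projection).
#' @param blurSigma Gaussian smoothing sigma in pixels.
#' @param minArea minimum nucleus area in pixels.
#' @param tolerance watershed tolerance (in distance-map units).
#' @return integer label matrix (0 = background); all-zero with a warning if
#'   no foreground is found.
#' @export
segmentNuclei <- function(projection, blurSigma = 2, minArea = 150L,
                          tolerance = 1) {
  mx <- max(projection)
  lab <- matrix(0L, nrow(projection), ncol(projection))
  if (mx <= 0) {
    warning("no foreground in projection: empty mask")
    return(lab)
  }
  img <- EBImage::Image(projection / mx)
  img <- EBImage::gblur(img, sigma = blurSigma)
  th <- EBImage::otsu(img)
  bw <- EBImage::fillHull(img > th)
  if (!any(bw > 0)) {
    warning("no foreground in projection: empty mask")
    return(lab)
  }
  ws <- EBImage::watershed(EBImage::distmap(bw), tolerance = tolerance)
  lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(projection))
  counts <- tabulate(lab)
  small <- which(counts < minArea)
  if (length(small)) lab[lab %in% small] <- 0L
  old <- sort(unique(lab[lab > 0L]))
  if (length(old)) lab[] <- match(lab, old, nomatch = 0L)
  lab
}

#' Score each nucleus as spot-positive or not
#'
#' A nucleus is spot-positive iff its maximum in-mask pixel reaches the robust
#' background of its own pixel distribution: \code{median + kSigma * MAD}
#' (MAD floored at one count).  This is an explicit automated stand-in for a
#' manual per-nucleus call; \code{kSigma} is surfaced and recorded.
#'
#' @param projection FP-channel maximum projection (matrix, same shape as
#'   \code{mask}).
#' @param mask integer label matrix from \code{\link{segmentNuclei}}.
#' @param kSigma detection stringency in robust SDs (default 6).
#' @return named logical vector, one element per nucleus label.
#' @export
scoreSpotPositive <- function(projection, mask, kSigma = 6) {
  stopifnot(all(dim(projection) == dim(mask)))
  labels <- sort(unique(mask[mask > 0L]))
  out <- vapply(labels, function(l) {
    px <- projection[mask == l]
    md <- stats::mad(px)
    max(px) >= stats::median(px) + kSigma * max(md, 1)
  }, logical(1))
  names(out) <- labels
  out
}

#' Labeling efficiency per 10-slice maximum projection
#'
#' Composes \code{\link{splitSubstacks}}, \code{\link{maxProject}},
#' \code{\link{segmentNuclei}} (on the DAPI channel) and
#' \code{\link{scoreSpotPositive}} (on the FP channel); each projection yields
#' one data point.  Projections with zero segmented nuclei are dropped with a
#' warning.
#'
#' @param fpStack FP-channel \linkS4class{VoxelStack}.
#' @param dapiStack DAPI-channel \linkS4class{VoxelStack}, same dimensions.
#' @param groupSize slices per substack (default 10).
#' @param kSigma spot-positive stringency (see \code{\link{scoreSpotPositive}}).
#' @param minArea minimum nucleus area for segmentation.
#' @return data.frame: \code{substack_index} (1-based), \code{z_start, z_end}
#'   (0-based half-open), \code{n_nuclei, n_spot_positive, ratio, k_sigma}.
#' @export
labelingEfficiency <- function(fpStack, dapiStack, groupSize = 10L,
                               kSigma = 6, minArea = 150L) {
  stopifnot(all(dim(fpStack@intensities) == dim(dapiStack@intensities)))
  fps <- splitSubstacks(fpStack, groupSize)
  dps <- splitSubstacks(dapiStack, groupSize)
  rows <- lapply(seq_along(fps), function(i) {
    mask <- segmentNuclei(maxProject(dps[[i]]), minArea = minArea)
    n <- max(mask)
    if (n == 0L) {
      warning("substack ", i, " dropped: no nuclei segmented")
      return(NULL)
    }
    pos <- scoreSpotPositive(maxProject(fps[[i]]), mask, kSigma = kSigma)
    data.frame(substack_index = i, z_start = attr(fps[[i]], "zStart"),
               z_end = attr(fps[[i]], "zEnd"), n_nuclei = n,
               n_spot_positive = sum(pos), ratio = sum(pos) / n,
               k_sigma = kSigma)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(substack_index = integer(), z_start = integer(),
                      z_end = integer(), n_nuclei = integer(),
                      n_spot_positive = integer(), ratio = numeric(),
                      k_sigma = numeric()))
  do.call(rbind, rows)
}
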