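# Fixed-geometry ROI extraction and the max-skewness slice rule.
#
# All seed/box coordinates are 0-based (z, y, x) voxel indices; boxes are
# half-open: a size-40 window around seed index s covers [s - 20, s + 20),
# putting the seed at local index 20.

#' Extract a fixed-geometry ROI substack around a spot seed
#'
#' Cuts an \code{xySize x xySize} XY window centred on the seed (half-open:
#' \code{[s - xySize/2, s + xySize/2)}) and a Z window of \code{nSlices}
#' centred on the seed slice, truncated at the stack Z boundaries.  Seeds
#' closer than \code{xySize/2} to an XY border are rejected.
#'
#' @param stack a \linkS4class{VoxelStack}.
#' @param seed named numeric/list with 0-based voxel indices \code{z, y, x}.
#' @param xySize even XY window size in pixels (default 40).
#' @param nSlices Z window depth; odd, or equal to the stack depth.
#' @return \code{list(substack = VoxelStack, box = list(origin, size))} with
#'   \code{origin}/\code{size} as 0-based \code{(z, y, x)} triples; the
#'   substack is a copy, never a view.
#' @examples
#' st <- voxelStack(array(0, c(15, 256, 256)))
#' extractRoi(st, list(z = 7, y = 100, x = 100), 40, 13)$box
#' @export
extractRoi <- function(stack, seed, xySize = 40L, nSlices = 13L) {
  stopifnot(is(stack, "VoxelStack"))
  d <- dim(stack@intensities)
  z <- as.integer(seed$z); y <- as.integer(seed$y); x <- as.integer(seed$x)
  if (z < 0 || z >= d[1] || y < 0 || y >= d[2] || x < 0 || x >= d[3])
    stop("seed lies outside the stack")
  if (xySize %% 2L != 0L) stop("xySize must be even")
  if (nSlices %% 2L == 0L && nSlices != d[1])
    stop("nSlices must be odd or equal to the stack depth")
  h <- xySize %/% 2L
  if (y < h || y > d[2] - h - 1L || x < h || x > d[3] - h - 1L)
    stop("border seed: seed closer than ", h, " pixels to an XY border")
  hz <- (nSlices - 1L) %/% 2L
  z0 <- max(0L, z - hz)
  z1 <- min(d[1], z - hz + nSlices)    # exclusive
  sub <- stack@intensities[(z0 + 1L):z1, (y - h + 1L):(y + h),
                           (x - h + 1L):(x + h), drop = FALSE]
  list(substack = voxelStack(sub, stack@voxelSize, stack@channel),
       box = list(origin = c(z = z0, y = y - h, x = x - h),
                  size = c(z = z1 - z0, y = xySize, x = xySize),
                  parentDims = d,
                  seed = list(z = z, y = y, x = x)))
}

#' Population skewness of a 2D intensity plane
#'
#' Fisher-Pearson moment skewness \eqn{m_3 / m_2^{3/2}} with population
#' (1/n) moments over all pixels, the convention of ImageJ's "Skewness"
#' measurement.  Returns 0 for a zero-variance plane.
#'
#' @param plane numeric matrix.
#' @return skewness (dimensionless).
#' @examples
#' sliceSkewness(matrix(c(0, 0, 0, 9), 2))
#' @export
sliceSkewness <- function(plane) {
  x <- as.numeric(plane)
  if (!length(x)) stop("plane must be non-empty")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 == 0) return(0)
  mean((x - mu)^3) / m2^1.5
}

#' Index of the maximum-skewness slice of a substack
#'
#' The Z plane with the largest pixel-intensity skewness marks the central
#' plane of a diffraction-limited focus (a focus adds a heavy right tail).
#' Ties resolve to the lowest index.
#'
#' @param substack a \linkS4class{VoxelStack} or 3D array.
#' @return 0-based local slice index.
#' @export
maxSkewSlice <- function(substack) {
  a <- if (is(substack, "VoxelStack")) substack@intensities else substack
  if (dim(a)[1] < 1L) stop("substack must have at least one slice")
  sk <- vapply(seq_len(dim(a)[1]), function(i) sliceSkewness(a[i, , ]),
               numeric(1))
  which.max(sk) - 1L
}
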