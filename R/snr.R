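# Per-spot signal-to-noise ratio on the max-skewness plane of a
# 40 x 40 x 13 ROI: SNR = (MAX intensity - background mean) / background SD,
# background taken from a 28 x 28 box around the max after deleting a
# 14 x 14 box (deleted pixels are zeroed and zeros excluded, so genuinely
# zero-valued background pixels are excluded too -- documented behaviour).

#' Compute the per-spot SNR statistic
#'
#' Pipeline: extract a \code{xySize x xySize x nSlices} ROI around the seed;
#' pick the maximum-skewness slice; locate the maximum intensity pixel in that
#' slice; zero a \code{deleteBox x deleteBox} box centred on it; over the
#' \code{bgBox x bgBox} box with the same centre (clipped to the ROI), compute
#' the mean and sample SD of the strictly positive pixels; SNR is
#' \code{(max - mean) / sd}.  Even boxes centre with the same half-open
#' convention as ROIs (\code{[c - 7, c + 7)}, \code{[c - 14, c + 14)}).
#'
#' @param stack a \linkS4class{VoxelStack}.
#' @param seed list/named vector with 0-based voxel indices \code{z, y, x};
#'   must be at least \code{xySize/2} pixels from the XY borders.
#' @param xySize,nSlices ROI geometry (defaults 40, 13).
#' @param deleteBox,bgBox deletion and background box sizes (defaults 14, 28).
#' @return One-row data.frame: \code{seed_z, seed_y, seed_x, skew_slice}
#'   (local 0-based), \code{max_intensity, max_y, max_x} (local),
#'   \code{background_mean, background_sd, n_background_pixels, snr}.
#' @examples
#' a <- array(100, c(13, 44, 44)); a[7, 23, 23] <- 400; a[7, 10, 10] <- 90
#' computeSnr(voxelStack(a), list(z = 6, y = 22, x = 22))
#' @export
computeSnr <- function(stack, seed, xySize = 40L, nSlices = 13L,
                       deleteBox = 14L, bgBox = 28L) {
  roi <- extractRoi(stack, seed, xySize = xySize, nSlices = nSlices)
  a <- roi$substack@intensities
  ks <- maxSkewSlice(a)
  plane <- a[ks + 1L, , ]
  mi <- which.max(plane)                      # first max, column-major
  my <- (mi - 1L) %% nrow(plane)              # 0-based local y
  mx <- (mi - 1L) %/% nrow(plane)             # 0-based local x
  maxInt <- plane[mi]
  hd <- deleteBox %/% 2L
  hb <- bgBox %/% 2L
  clip <- function(v) pmin(pmax(v, 0L), xySize - 1L)
  delY <- clip(my - hd):clip(my + hd - 1L)
  delX <- clip(mx - hd):clip(mx + hd - 1L)
  plane[delY + 1L, delX + 1L] <- 0
  bgY <- clip(my - hb):clip(my + hb - 1L)
  bgX <- clip(mx - hb):clip(mx + hb - 1L)
  bg <- plane[bgY + 1L, bgX + 1L]
  bg <- bg[bg > 0]
  if (length(bg) < 10L)
    stop("background exhausted: fewer than 10 positive background pixels")
  bsd <- stats::sd(bg)
  if (bsd == 0) stop("degenerate background: zero background SD")
  bm <- mean(bg)
  data.frame(seed_z = as.integer(seed$z), seed_y = as.integer(seed$y),
             seed_x = as.integer(seed$x), skew_slice = ks,
             max_intensity = maxInt, max_y = my, max_x = mx,
             background_mean = bm, background_sd = bsd,
             n_background_pixels = length(bg),
             snr = (maxInt - bm) / bsd)
}

#' SNR for a batch of seeds
#'
#' Applies \code{\link{computeSnr}} to each seed; per-seed failures (border
#' seeds, degenerate backgrounds) are reported as warnings and skipped, never
#' fatal.
#'
#' @param stack a \linkS4class{VoxelStack}.
#' @param seeds data.frame with columns \code{z, y, x} (0-based voxels).
#' @param ... passed to \code{\link{computeSnr}}.
#' @return data.frame with one row per successful seed (possibly empty).
#' @export
batchSnr <- function(stack, seeds, ...) {
  rows <- lapply(seq_len(nrow(seeds)), function(i) {
    tryCatch(
      computeSnr(stack, list(z = seeds$z[i], y = seeds$y[i], x = seeds$x[i]),
                 ...),
      error = function(e) {
        warning("seed (", seeds$z[i], ",", seeds$y[i], ",", seeds$x[i],
                ") skipped: ", conditionMessage(e), call. = FALSE)
        NULL
      })
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(seed_z = integer(), seed_y = integer(),
                      seed_x = integer(), skew_slice = integer(),
                      max_intensity = numeric(), max_y = integer(),
                      max_x = integer(), background_mean = numeric(),
                      background_sd = numeric(),
                      n_background_pixels = integer(), snr = numeric()))
  do.call(rbind, rows)
}
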