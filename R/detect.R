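# 3D focus detection: threshold/volume object counting with 26-connectivity
# and intensity-weighted centroids, and a difference-of-Gaussians detector
# with sub-pixel quadratic refinement.

# separable 1D convolution along one axis of a 3D array, edge-replicated,
# done as a banded-matrix product so BLAS carries the inner loop
.convAxis <- function(a, k, axis) {
  d <- dim(a)
  r <- (length(k) - 1L) %/% 2L
  n <- d[axis]
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmin(pmax(i + (-r:r), 1L), n)
    for (t in seq_along(j)) K[i, j[t]] <- K[i, j[t]] + k[t]
  }
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(a, perm)
  dm <- dim(m)
  aperm(array(K %*% matrix(m, nrow = dm[1]), dm), order(perm))
}

# 3D Gaussian smoothing with per-axis sigmas (z, y, x), in voxel units
.gaussSmooth3d <- function(a, sigma) {
  for (axis in 1:3) {
    s <- sigma[axis]
    if (s < 0.15 || dim(a)[axis] == 1L) next
    r <- max(1L, ceiling(3.5 * s))
    k <- stats::dnorm(-r:r, sd = s)
    a <- .convAxis(a, k / sum(k), axis)
  }
  a
}

# 26-connected components of a logical 3D mask; returns a list of
# linear-index vectors, one per component.
.connectedComponents26 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(list())
  coords <- arrayInd(idx, d)
  candPos <- array(0L, d)
  candPos[idx] <- seq_along(idx)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  compOf <- integer(length(idx))
  comp <- 0L
  for (s in seq_along(idx)) {
    if (compOf[s] != 0L) next
    comp <- comp + 1L
    compOf[s] <- comp
    queue <- s
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      nb <- cbind(coords[cur, 1L] + offs[, 1L], coords[cur, 2L] + offs[, 2L],
                  coords[cur, 3L] + offs[, 3L])
      keep <- nb[, 1L] >= 1L & nb[, 1L] <= d[1] &
              nb[, 2L] >= 1L & nb[, 2L] <= d[2] &
              nb[, 3L] >= 1L & nb[, 3L] <= d[3]
      if (!any(keep)) next
      nb <- nb[keep, , drop = FALSE]
      p <- candPos[nb[, 1L] + (nb[, 2L] - 1L) * d[1] +
                   (nb[, 3L] - 1L) * d[1] * d[2]]
      p <- p[p > 0L]
      p <- p[compOf[p] == 0L]
      if (length(p)) {
        compOf[p] <- comp
        queue <- c(queue, p)
      }
    }
  }
  split(idx, compOf)
}

#' All above-threshold objects in a substack
#'
#' Thresholds the substack at \code{thresholdFrac} times its global maximum,
#' labels 26-connected components of voxels at or above the threshold,
#' discards components smaller than \code{minVolume} voxels, and reports the
#' intensity-weighted centroid of each survivor.  Used by
#' \code{\link{detectObjectCounter}} (which keeps the component containing the
#' global-maximum voxel) and by the pairing stage to count focus candidates
#' per ROI.
#'
#' @param substack a \linkS4class{VoxelStack} or 3D array.
#' @param thresholdFrac threshold as a fraction of the global max, in (0, 1].
#' @param minVolume minimum object size in voxels (>= 1).
#' @param origin 0-based \code{(z, y, x)} of the substack in its parent stack;
#'   centroids are reported in the parent frame.
#' @return data.frame with one row per surviving component: \code{cz, cy, cx}
#'   (sub-voxel, parent frame), \code{voxel_count}, \code{threshold_used},
#'   \code{contains_max}.
#' @export
objectComponents <- function(substack, thresholdFrac = 0.7, minVolume = 20L,
                             origin = c(0L, 0L, 0L)) {
  a <- if (is(substack, "VoxelStack")) substack@intensities else substack
  if (thresholdFrac <= 0 || thresholdFrac > 1)
    stop("thresholdFrac must be in (0, 1]")
  if (minVolume < 1L) stop("minVolume must be >= 1")
  empty <- data.frame(cz = numeric(), cy = numeric(), cx = numeric(),
                      voxel_count = integer(), threshold_used = numeric(),
                      contains_max = logical())
  mx <- max(a)
  if (mx <= 0) {
    warning("all-zero substack: no objects")
    return(empty)
  }
  thr <- thresholdFrac * mx
  comps <- .connectedComponents26(a >= thr)
  maxIdx <- which.max(a)
  d <- dim(a)
  rows <- lapply(comps, function(lin) {
    if (length(lin) < minVolume) return(NULL)
    co <- arrayInd(lin, d) - 1L           # 0-based (z, y, x)
    w <- a[lin]
    data.frame(cz = sum(w * co[, 1]) / sum(w) + origin[1],
               cy = sum(w * co[, 2]) / sum(w) + origin[2],
               cx = sum(w * co[, 3]) / sum(w) + origin[3],
               voxel_count = length(lin), threshold_used = thr,
               contains_max = maxIdx %in% lin)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Localize a focus by threshold/volume object counting
#'
#' The 3D object-counting procedure: threshold at \code{thresholdFrac} of the
#' substack's global maximum intensity, keep 26-connected components of at
#' least \code{minVolume} voxels, and return the intensity-weighted centroid
#' of the component containing the global-maximum voxel.  Returns \code{NULL}
#' if that component was discarded by the volume filter or the substack is
#' empty.
#'
#' @inheritParams objectComponents
#' @param channel channel name recorded in the result.
#' @return One-row data.frame \code{(channel, detector, cz, cy, cx,
#'   voxel_count, threshold_used)} with parent-frame sub-voxel coordinates, or
#'   \code{NULL}.
#' @export
detectObjectCounter <- function(substack, thresholdFrac = 0.7,
                                minVolume = 20L, origin = c(0L, 0L, 0L),
                                channel = NA_character_) {
  comps <- objectComponents(substack, thresholdFrac, minVolume, origin)
  hit <- comps[comps$contains_max, , drop = FALSE]
  if (!nrow(hit)) return(NULL)
  data.frame(channel = channel, detector = "object_counter",
             cz = hit$cz[1], cy = hit$cy[1], cx = hit$cx[1],
             voxel_count = hit$voxel_count[1],
             threshold_used = hit$threshold_used[1])
}

# strict-plateau local maxima of a 3D response above `thr`
.localMaxima3d <- function(resp, thr) {
  d <- dim(resp)
  ok <- resp > thr
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    sh <- array(-Inf, d)
    src <- list(z = max(1, 1 + dz):min(d[1], d[1] + dz),
                y = max(1, 1 + dy):min(d[2], d[2] + dy),
                x = max(1, 1 + dx):min(d[3], d[3] + dx))
    dst <- list(z = src$z - dz, y = src$y - dy, x = src$x - dx)
    sh[dst$z, dst$y, dst$x] <- resp[src$z, src$y, src$x]
    ok <- ok & (resp >= sh)
  }
  which(ok)
}

# Exact 1D Otsu split of a value vector: the threshold maximizing
# between-class variance over all candidate cuts.  Used to separate
# focus-like maxima from the weaker structural maxima every nucleus-bearing
# image produces (nuclear-rim band-pass response).
.otsuSplit1d <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n < 2L) return(-Inf)
  csum <- cumsum(v)
  total <- csum[n]
  i <- seq_len(n - 1L)
  w0 <- i / n
  m0 <- csum[i] / i
  m1 <- (total - csum[i]) / (n - i)
  bc <- w0 * (1 - w0) * (m0 - m1)^2
  best <- which.max(bc)
  (v[best] + v[best + 1L]) / 2
}

.quadraticOffset <- function(fm, f0, fp) {
  den <- fm - 2 * f0 + fp
  if (!is.finite(den) || abs(den) < 1e-12) return(0)
  max(-0.5, min(0.5, 0.5 * (fm - fp) / den))
}

#' Difference-of-Gaussians focus detection with sub-pixel refinement
#'
#' Band-pass DoG response with \eqn{\sigma_1 = d / (2\sqrt{3})} and
#' \eqn{\sigma_2 = 1.6 \sigma_1} (lateral, in pixels; axial sigmas divided by
#' the voxel aspect \code{dz/dx}), local maxima above an automatic threshold,
#' and a 3-point quadratic fit per axis around each maximum.  Detections
#' closer than half the spot diameter keep only the strongest.  Results are
#' sorted by response, descending.
#'
#' The automatic threshold has two stages.  A robust floor,
#' median + \code{kMad} x MAD of the response, removes flat-background noise
#' maxima.  Images of FP-labeled nuclei additionally produce weak structural
#' maxima wherever the band-pass meets the diffuse nuclear-background rim;
#' when the surviving maxima are clearly bimodal (the upper Otsu class sits
#' at least \code{gapRatio} times above the lower) the threshold is raised to
#' the Otsu split, separating focus-like maxima from rim responses.  The
#' guard keeps near-equal maxima -- for example sister-chromatid doublets --
#' on the same side of the threshold.
#'
#' @inheritParams detectObjectCounter
#' @param diameterPx estimated spot diameter in (lateral) pixels.
#' @param voxelAspect \code{dz/dx}; taken from the stack calibration when
#'   \code{substack} is a \linkS4class{VoxelStack}.
#' @param kMad robustness factor of the automatic threshold floor.
#' @param gapRatio minimum upper/lower Otsu-class mean ratio for the bimodal
#'   raise to apply.
#' @param threshold absolute response threshold overriding the automatic one.
#' @return data.frame \code{(channel, detector, cz, cy, cx, voxel_count,
#'   threshold_used, response)}, possibly empty; coordinates sub-voxel in the
#'   parent frame.
#' @export
detectDog <- function(substack, diameterPx = 11, voxelAspect = NULL,
                      kMad = 5, gapRatio = 1.5, threshold = NULL,
                      origin = c(0L, 0L, 0L), channel = NA_character_) {
  if (diameterPx <= 0) stop("diameterPx must be > 0")
  if (is(substack, "VoxelStack")) {
    if (is.null(voxelAspect))
      voxelAspect <- substack@voxelSize[1] / substack@voxelSize[3]
    if (is.na(channel)) channel <- substack@channel
    a <- substack@intensities
  } else a <- substack
  if (is.null(voxelAspect)) voxelAspect <- 1
  empty <- data.frame(channel = character(), detector = character(),
                      cz = numeric(), cy = numeric(), cx = numeric(),
                      voxel_count = integer(), threshold_used = numeric(),
                      response = numeric())
  if (max(a) <= 0) return(empty)
  s1 <- diameterPx / (2 * sqrt(3))
  s2 <- 1.6 * s1
  resp <- .gaussSmooth3d(a, c(s1 / voxelAspect, s1, s1)) -
          .gaussSmooth3d(a, c(s2 / voxelAspect, s2, s2))
  if (is.null(threshold)) {
    threshold <- stats::median(resp) + kMad * stats::mad(resp)
    rv <- resp[.localMaxima3d(resp, threshold)]
    # raise through successive Otsu cuts while the classes stay well
    # separated; stops before splitting near-equal maxima (doublets)
    while (length(rv) >= 2L) {
      cut <- .otsuSplit1d(rv)
      lower <- rv[rv <= cut]
      upper <- rv[rv > cut]
      if (!length(lower) || !length(upper) ||
          mean(upper) < gapRatio * max(mean(lower), 1e-12)) break
      threshold <- cut
      rv <- upper
    }
  }
  peaks <- .localMaxima3d(resp, threshold)
  if (!length(peaks)) return(empty)
  d <- dim(resp)
  co <- arrayInd(peaks, d)
  r <- resp[peaks]
  o <- order(-r, peaks)
  co <- co[o, , drop = FALSE]
  r <- r[o]
  # suppress plateau duplicates / split maxima within half a spot diameter
  minSep <- diameterPx / 2
  keep <- logical(length(r))
  for (i in seq_along(r)) {
    if (!i %in% which(keep) && i > 1 && any(keep)) {
      kc <- co[keep, , drop = FALSE]
      dd <- sqrt(((co[i, 1] - kc[, 1]) * voxelAspect)^2 +
                 (co[i, 2] - kc[, 2])^2 + (co[i, 3] - kc[, 3])^2)
      if (any(dd < minSep)) next
    }
    keep[i] <- TRUE
  }
  co <- co[keep, , drop = FALSE]
  r <- r[keep]
  rows <- lapply(seq_along(r), function(i) {
    p <- co[i, ]
    delta <- numeric(3)
    for (axis in 1:3) {
      if (p[axis] > 1L && p[axis] < d[axis]) {
        pm <- p; pm[axis] <- pm[axis] - 1L
        pp <- p; pp[axis] <- pp[axis] + 1L
        delta[axis] <- .quadraticOffset(resp[pm[1], pm[2], pm[3]],
                                        resp[p[1], p[2], p[3]],
                                        resp[pp[1], pp[2], pp[3]])
      }
    }
    data.frame(channel = channel, detector = "dog",
               cz = p[1] - 1 + delta[1] + origin[1],
               cy = p[2] - 1 + delta[2] + origin[2],
               cx = p[3] - 1 + delta[3] + origin[3],
               voxel_count = NA_integer_, threshold_used = threshold,
               response = r[i])
  })
  do.call(rbind, rows)
}

#' Find spot seeds across a full stack
#'
#' Runs the DoG detector over the whole stack and converts detections to
#' integer voxel seeds, dropping seeds too close to an XY border to support
#' the fixed-geometry ROIs downstream.  Deterministic.
#'
#' @param stack a \linkS4class{VoxelStack}.
#' @param channel channel name carried by the seeds (default: the stack's).
#' @param diameterPx estimated spot diameter in pixels.
#' @param kMad automatic-threshold robustness factor.
#' @param xyMargin minimum seed distance from an XY border in pixels
#'   (half the downstream ROI size).
#' @return data.frame \code{(channel, z, y, x)} of 0-based voxel seeds.
#' @export
findSeeds <- function(stack, channel = NULL, diameterPx = 11, kMad = 5,
                      xyMargin = 20L) {
  stopifnot(is(stack, "VoxelStack"))
  if (is.null(channel)) channel <- stack@channel
  det <- detectDog(stack, diameterPx = diameterPx, kMad = kMad,
                   channel = channel)
  if (!nrow(det))
    return(data.frame(channel = character(), z = integer(), y = integer(),
                      x = integer()))
  d <- dim(stack@intensities)
  z <- as.integer(round(det$cz)); y <- as.integer(round(det$cy))
  x <- as.integer(round(det$cx))
  ok <- y >= xyMargin & y <= d[2] - xyMargin - 1L &
        x >= xyMargin & x <= d[3] - xyMargin - 1L &
        z >= 0L & z <= d[1] - 1L
  data.frame(channel = channel, z = z[ok], y = y[ok], x = x[ok])
}
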