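# Synthetic 3D microscopy fields: spherical nuclei with diffuse nuclear FP
# background and diffraction-limited Gaussian foci, plus a camera noise model.
#
# Coordinate convention: a (0-based) voxel index v along an axis samples the
# field at v * voxelSize nm, so continuous voxel coordinates convert to nm by
# componentwise multiplication (see voxelToNm).

.chanIndex <- function(channel, channels) {
  fixed <- c(green = 1L, red = 2L, dapi = 3L)
  if (channel %in% names(fixed)) return(unname(fixed[channel]))
  3L + match(channel, setdiff(channels, names(fixed)))
}

.fieldExtent <- function(config) {
  # nm positions of the last voxel center along (z, y, x)
  (config@stackDims - 1L) * config@voxelSize
}

.unitVector3 <- function(lateral = FALSE) {
  if (lateral) {
    a <- stats::runif(1, 0, 2 * pi)
    c(cos(a), sin(a), 0)
  } else {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n < 1e-12) c(1, 0, 0) else v / n
  }
}

.uniformInSphere <- function(radius) {
  radius * stats::runif(1)^(1 / 3) * .unitVector3()
}

# Place non-overlapping spherical nuclei by rejection sampling (max 1000
# attempts per nucleus).  XY containment is enforced; in Z a nucleus larger
# than the stack depth is centred and clipped, mimicking optical sections
# through tissue thicker than the acquired stack.
.placeNuclei <- function(config) {
  n <- config@nNuclei
  out <- data.frame(id = integer(), x_nm = numeric(), y_nm = numeric(),
                    z_nm = numeric(), radius_nm = numeric())
  if (n == 0L) return(out)
  ext <- .fieldExtent(config)   # (z, y, x) nm
  set.seed(config@seed + 1000L)
  rmean <- config@nucleusRadiusNm[1]
  rsd <- config@nucleusRadiusNm[2]
  for (i in seq_len(n)) {
    r <- max(0.4 * rmean, stats::rnorm(1, rmean, rsd))
    if (2 * r > ext[3])
      stop("x dimension too small to contain a nucleus of radius ", round(r),
           " nm")
    if (2 * r > ext[2])
      stop("y dimension too small to contain a nucleus of radius ", round(r),
           " nm")
    rz <- min(r, ext[1] / 2)
    ok <- FALSE
    for (attempt in seq_len(1000L)) {
      cx <- stats::runif(1, r, ext[3] - r)
      cy <- stats::runif(1, r, ext[2] - r)
      cz <- if (ext[1] / 2 <= rz) ext[1] / 2 else stats::runif(1, rz, ext[1] - rz)
      if (nrow(out)) {
        d <- sqrt((out$x_nm - cx)^2 + (out$y_nm - cy)^2 + (out$z_nm - cz)^2)
        if (any(d < out$radius_nm + r)) next
      }
      out <- rbind(out, data.frame(id = i, x_nm = cx, y_nm = cy, z_nm = cz,
                                   radius_nm = r))
      ok <- TRUE
      break
    }
    if (!ok)
      stop("failed to place nucleus ", i, " after 1000 attempts; ",
           "reduce nNuclei or nucleusRadiusNm")
  }
  out
}

# Add `value` inside the sphere (center in nm, x/y/z) of `radius` to a raw
# (z, y, x) array.
.addSphere <- function(arr, center, radius, value, voxelSize) {
  d <- dim(arr)
  ctr <- c(center[3], center[2], center[1])            # to (z, y, x) nm
  lo <- pmax(1L, floor(ctr / voxelSize - radius / voxelSize) + 1L)
  hi <- pmin(d, ceiling(ctr / voxelSize + radius / voxelSize) + 1L)
  if (any(lo > hi)) return(arr)
  zz <- ((lo[1]:hi[1]) - 1L) * voxelSize[1] - ctr[1]
  yy <- ((lo[2]:hi[2]) - 1L) * voxelSize[2] - ctr[2]
  xx <- ((lo[3]:hi[3]) - 1L) * voxelSize[3] - ctr[3]
  d2 <- outer(outer(zz^2, yy^2, "+"), xx^2, "+")
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + value * (d2 <= radius^2)
  arr
}

.renderSpotArray <- function(arr, centerNm, amplitude, sigmaLat, sigmaAx,
                             voxelSize) {
  if (amplitude == 0) return(arr)
  d <- dim(arr)
  ctr <- c(centerNm[3], centerNm[2], centerNm[1])      # (z, y, x) nm
  sig <- c(sigmaAx, sigmaLat, sigmaLat)
  lo <- pmax(1L, floor((ctr - 4.5 * sig) / voxelSize) + 1L)
  hi <- pmin(d, ceiling((ctr + 4.5 * sig) / voxelSize) + 1L)
  if (any(lo > hi)) return(arr)
  gz <- exp(-(((lo[1]:hi[1]) - 1L) * voxelSize[1] - ctr[1])^2 / (2 * sig[1]^2))
  gy <- exp(-(((lo[2]:hi[2]) - 1L) * voxelSize[2] - ctr[2])^2 / (2 * sig[2]^2))
  gx <- exp(-(((lo[3]:hi[3]) - 1L) * voxelSize[3] - ctr[3])^2 / (2 * sig[3]^2))
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] +
    amplitude * (gz %o% gy %o% gx)
  arr
}

#' Render a diffraction-limited focus into a stack
#'
#' Adds an anisotropic 3D Gaussian, evaluated at voxel centers, to the stack.
#' The total added signal approximates
#' \eqn{A (2\pi)^{3/2} \sigma_{lat}^2 \sigma_{ax} / (dx\, dy\, dz)}.
#'
#' @param stack a \linkS4class{VoxelStack}.
#' @param centerNm focus center, \code{c(x, y, z)} in nm; must lie inside the
#'   stack (voxel-center extent).
#' @param amplitude peak counts added at the center.
#' @param sigmaLatNm,sigmaAxNm lateral / axial Gaussian sigma in nm (> 0).
#' @return The stack with the focus added.
#' @export
renderSpot <- function(stack, centerNm, amplitude, sigmaLatNm = 130,
                       sigmaAxNm = 350) {
  stopifnot(is(stack, "VoxelStack"))
  if (sigmaLatNm <= 0 || sigmaAxNm <= 0)
    stop("spot sigmas must be strictly positive")
  if (amplitude < 0) stop("amplitude must be >= 0")
  ext <- (dim(stack@intensities) - 1L) * stack@voxelSize   # (z, y, x)
  if (centerNm[1] < 0 || centerNm[1] > ext[3] ||
      centerNm[2] < 0 || centerNm[2] > ext[2] ||
      centerNm[3] < 0 || centerNm[3] > ext[1])
    stop("spot center lies outside the stack")
  stack@intensities <- .renderSpotArray(stack@intensities, centerNm, amplitude,
                                        sigmaLatNm, sigmaAxNm, stack@voxelSize)
  stack
}

#' Apply the camera noise model to a stack
#'
#' Per-voxel Poisson resampling of the expected counts (if enabled), plus
#' Gaussian read noise, plus a constant offset; the result is rounded and
#' clipped to the 16-bit range.  With every component disabled the stack is
#' returned unchanged (exact identity).  Clipped voxels are counted and
#' reported via \code{message()}.
#'
#' @param stack a \linkS4class{VoxelStack} of expected counts.
#' @param poisson logical, enable shot noise.
#' @param readSd Gaussian read-noise sd in counts (>= 0).
#' @param offset constant offset in counts.
#' @param seed RNG seed; identical seeds give identical stacks.
#' @return A \linkS4class{VoxelStack} of observed counts.
#' @export
applyNoise <- function(stack, poisson = TRUE, readSd = 0, offset = 0,
                       seed = 1L) {
  stopifnot(is(stack, "VoxelStack"))
  if (readSd < 0) stop("readSd must be >= 0")
  if (!poisson && readSd == 0 && offset == 0) return(stack)
  v <- as.numeric(stack@intensities)
  set.seed(as.integer(seed))
  if (poisson) v <- stats::rpois(length(v), v)
  if (readSd > 0) v <- v + stats::rnorm(length(v), 0, readSd)
  v <- round(v + offset)
  nclip <- sum(v < 0 | v > 65535)
  if (nclip > 0)
    message(nclip, " voxel(s) clipped to the 16-bit range")
  v <- pmin(pmax(v, 0), 65535)
  stack@intensities <- array(v, dim(stack@intensities))
  stack
}

#' Analytic SNR of a configured simulation
#'
#' Companion oracle for estimator validation: peak amplitude divided by the
#' per-voxel background noise sd.  With Poisson noise enabled the background
#' variance is the shot-noise variance at the mean nuclear background plus the
#' read-noise variance; otherwise it is the read-noise variance alone.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return Expected SNR (dimensionless).
#' @export
expectedSnr <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  if (config@spotAmplitude == 0) return(0)
  v <- config@noiseReadSd^2
  if (config@noisePoisson) v <- v + config@nuclearBackground[1]
  if (v == 0) stop("SNR undefined: zero background variance with noise disabled")
  config@spotAmplitude / sqrt(v)
}

# Draw a spot position uniformly inside a sphere of radius maxR around the
# nucleus center, rejecting positions outside the interior box [lo, hi]
# (x, y, z margins from the stack borders).
.drawSpotInNucleus <- function(center, maxR, lo, hi) {
  maxR <- max(maxR, 1)
  for (i in seq_len(200L)) {
    p <- center + .uniformInSphere(maxR)
    if (all(p >= lo) && all(p <= hi)) return(p)
  }
  pmin(pmax(center, lo), hi)
}

.drawPairSeparation <- function(spec) {
  switch(spec$type,
         fixed = spec$value,
         normal = max(0, stats::rnorm(1, spec$mean, spec$sd)),
         uniform = stats::runif(1, spec$min, spec$max))
}

#' Generate a synthetic multi-channel field with ground truth
#'
#' Places non-overlapping spherical nuclei, renders the requested channels
#' ("dapi" as filled nuclei; FP channels as diffuse nuclear background plus
#' diffraction-limited foci), applies the noise model, and emits a
#' \linkS4class{GroundTruth} manifest.  In single-label mode each FP channel
#' labels each nucleus independently with probability \code{labelingProb}, and
#' a labeled nucleus carries a sister-chromatid doublet with probability
#' \code{doubletProb}.  In dual-label mode (\code{dualLabel = TRUE}) each
#' labeled nucleus carries one green and one red focus separated by a draw
#' from \code{pairSeparation}; a doublet duplicates both foci with the same
#' sister offset.
#'
#' The simulation is deterministic for a fixed seed; per-stage and per-channel
#' RNG streams are derived from the root seed by fixed offsets, so adding a
#' channel never perturbs the draws of existing channels.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return \code{list(stacks = named list of VoxelStack, truth = GroundTruth)}.
#' @examples
#' f <- generateField(simulationConfig(nNuclei = 3L,
#'   stackDims = c(10L, 96L, 96L), nucleusRadiusNm = c(900, 50), seed = 4L))
#' f$truth
#' @export
generateField <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  nuclei <- .placeNuclei(config)
  d <- config@stackDims
  vs <- config@voxelSize
  ext <- .fieldExtent(config)
  # interior-only spot placement: at least one PSF sigma from every border
  zmargin <- min(config@spotSigmaAxialNm, ext[1] / 2)
  spotLo <- c(config@spotSigmaLateralNm, config@spotSigmaLateralNm, zmargin)
  spotHi <- c(ext[3] - config@spotSigmaLateralNm,
              ext[2] - config@spotSigmaLateralNm, ext[1] - zmargin)
  chans <- config@channels
  fpChans <- setdiff(chans, "dapi")

  # diffuse backgrounds
  arrays <- list()
  for (ch in chans) {
    a <- array(config@cytoplasmBackground, d)
    if (ch == "dapi") {
      for (i in seq_len(nrow(nuclei)))
        a <- .addSphere(a, c(nuclei$x_nm[i], nuclei$y_nm[i], nuclei$z_nm[i]),
                        nuclei$radius_nm[i], config@dapiIntensity, vs)
    } else if (nrow(nuclei)) {
      set.seed(config@seed + 3000L + 17L * .chanIndex(ch, chans))
      lev <- pmax(0, stats::rnorm(nrow(nuclei), config@nuclearBackground[1],
                                  config@nuclearBackground[2]))
      for (i in seq_len(nrow(nuclei)))
        a <- .addSphere(a, c(nuclei$x_nm[i], nuclei$y_nm[i], nuclei$z_nm[i]),
                        nuclei$radius_nm[i], lev[i], vs)
    }
    arrays[[ch]] <- a
  }

  spots <- data.frame(nucleus_id = integer(), channel = character(),
                      x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
                      amplitude = numeric(), is_doublet_member = logical())
  pairs <- data.frame(nucleus_id = integer(), distance_nm = numeric())

  addSpot <- function(nid, ch, p, doubletMember) {
    spots[nrow(spots) + 1L, ] <<- list(nid, ch, p[1], p[2], p[3],
                                       config@spotAmplitude, doubletMember)
    arrays[[ch]] <<- .renderSpotArray(arrays[[ch]], p, config@spotAmplitude,
                                      config@spotSigmaLateralNm,
                                      config@spotSigmaAxialNm, vs)
  }

  if (config@dualLabel) {
    if (!all(c("green", "red") %in% chans))
      stop("dual-label mode requires 'green' and 'red' channels")
    set.seed(config@seed + 2000L)
    for (i in seq_len(nrow(nuclei))) {
      if (stats::runif(1) >= config@labelingProb) next
      ctr <- c(nuclei$x_nm[i], nuclei$y_nm[i], nuclei$z_nm[i])
      sep <- .drawPairSeparation(config@pairSeparation)
      isDoublet <- stats::runif(1) < config@doubletProb
      margin <- sep + if (isDoublet) config@doubletSeparationNm else 0
      g <- .drawSpotInNucleus(ctr, nuclei$radius_nm[i] - margin,
                              spotLo, spotHi)
      dir <- .unitVector3()
      r <- g + sep * dir
      for (k in seq_len(50L)) {
        if (r[3] >= zmargin && r[3] <= ext[1] - zmargin) break
        dir <- .unitVector3()
        r <- g + sep * dir
      }
      addSpot(nuclei$id[i], "green", g, FALSE)
      addSpot(nuclei$id[i], "red", r, FALSE)
      pairs[nrow(pairs) + 1L, ] <- list(nuclei$id[i], sqrt(sum((g - r)^2)))
      if (isDoublet) {
        off <- config@doubletSeparationNm *
          .unitVector3(lateral = config@doubletOrientation == "lateral")
        addSpot(nuclei$id[i], "green", g + off, TRUE)
        addSpot(nuclei$id[i], "red", r + off, TRUE)
      }
    }
  } else {
    for (ch in fpChans) {
      set.seed(config@seed + 2000L + 13L * .chanIndex(ch, chans))
      for (i in seq_len(nrow(nuclei))) {
        if (stats::runif(1) >= config@labelingProb) next
        ctr <- c(nuclei$x_nm[i], nuclei$y_nm[i], nuclei$z_nm[i])
        isDoublet <- stats::runif(1) < config@doubletProb
        margin <- if (isDoublet) config@doubletSeparationNm else 0
        p <- .drawSpotInNucleus(ctr, nuclei$radius_nm[i] - margin,
                                spotLo, spotHi)
        addSpot(nuclei$id[i], ch, p, FALSE)
        if (isDoublet) {
          off <- config@doubletSeparationNm *
            .unitVector3(lateral = config@doubletOrientation == "lateral")
          addSpot(nuclei$id[i], ch, p + off, TRUE)
        }
      }
    }
  }

  stacks <- list()
  for (ch in chans) {
    st <- voxelStack(arrays[[ch]], vs, ch)
    stacks[[ch]] <- applyNoise(st, poisson = config@noisePoisson,
                               readSd = config@noiseReadSd,
                               offset = config@noiseOffset,
                               seed = config@seed + 4000L +
                                 .chanIndex(ch, chans))
  }
  list(stacks = stacks, truth = groundTruth(nuclei, spots, pairs))
}
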