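#' @import methods
NULL

#' VoxelStack: a calibrated 3D intensity grid for one channel
#'
#' A single-channel Z-stack stored as a numeric array indexed \code{(z, y, x)}
#' together with its physical voxel calibration in nanometres.  All voxel
#' indices exposed by this package are 0-based and intervals are half-open,
#' matching the coordinate conventions of the detection and distance layers;
#' a continuous voxel coordinate \code{c} along an axis corresponds to
#' \code{c * voxelSize} nanometres.
#'
#' @slot intensities numeric array, \code{dim = c(nz, ny, nx)}, all values
#'   finite and non-negative (16-bit unsigned range after noise application).
#' @slot voxelSize named numeric, \code{c(dz, dy, dx)} in nm, strictly positive.
#' @slot channel character scalar channel name (e.g. "green", "red", "dapi").
#' @export
setClass("VoxelStack",
  representation(intensities = "array", voxelSize = "numeric",
                 channel = "character"),
  validity = function(object) {
    msg <- character()
    a <- object@intensities
    if (length(dim(a)) != 3L)
      msg <- c(msg, "intensities must be a 3D (z, y, x) array")
    else if (any(dim(a) < 1L))
      msg <- c(msg, "all three dimensions must be >= 1")
    if (anyNA(a) || any(!is.finite(a)))
      msg <- c(msg, "intensities must be finite")
    else if (any(a < 0))
      msg <- c(msg, "intensities must be non-negative")
    else if (any(a > 65535))
      msg <- c(msg, "intensities exceed the 16-bit range")
    vs <- object@voxelSize
    if (length(vs) != 3L || any(!is.finite(vs)) || any(vs <= 0))
      msg <- c(msg, "voxelSize must be three strictly positive values (dz, dy, dx)")
    if (length(object@channel) != 1L)
      msg <- c(msg, "channel must be a single string")
    if (length(msg)) msg else TRUE
  })

#' Construct a VoxelStack
#'
#' @param intensities 3D numeric array indexed \code{(z, y, x)}.
#' @param voxelSize numeric length-3 \code{c(dz, dy, dx)} in nm.
#' @param channel channel name.
#' @return A \linkS4class{VoxelStack}.
#' @examples
#' vs <- voxelStack(array(0, c(3, 8, 8)), c(200, 65, 65), "green")
#' dim(intensities(vs))
#' @export
voxelStack <- function(intensities, voxelSize = c(200, 65, 65),
                       channel = "unknown") {
  vs <- as.numeric(voxelSize)
  names(vs) <- c("dz", "dy", "dx")
  new("VoxelStack", intensities = intensities, voxelSize = vs,
      channel = as.character(channel))
}

#' @describeIn voxelStack Intensity array accessor.
#' @param x,object a \code{VoxelStack}.
#' @export
intensities <- function(x) x@intensities

#' @describeIn voxelStack Voxel calibration accessor, \code{c(dz, dy, dx)} nm.
#' @export
voxelSize <- function(x) x@voxelSize

#' @describeIn voxelStack Channel name accessor.
#' @export
channelName <- function(x) x@channel

setMethod("show", "VoxelStack", function(object) {
  d <- dim(object@intensities)
  cat(sprintf(
    "VoxelStack '%s': %d x %d x %d (z, y, x), voxel %g x %g x %g nm, range [%g, %g]\n",
    object@channel, d[1], d[2], d[3],
    object@voxelSize[1], object@voxelSize[2], object@voxelSize[3],
    min(object@intensities), max(object@intensities)))
})

#' SimulationConfig: parameters of the synthetic imaging field
#'
#' Describes one simulated field of spherical nuclei with diffuse nuclear FP
#' background and diffraction-limited foci, imaged with an anisotropic Gaussian
#' PSF and a Poisson + Gaussian read-noise camera model.  Defaults describe the
#' regime the quantification layer is designed for: Airyscan-like sampling
#' (65 nm lateral, 200 nm axial), diffraction-limited foci
#' (sigma 130 nm lateral / 350 nm axial), diffuse nuclear FP background of
#' 100 counts over 20 counts of cytoplasm, and shot noise plus a 3-count read
#' noise.
#'
#' @slot stackDims integer \code{c(nz, ny, nx)}.
#' @slot voxelSize numeric \code{c(dz, dy, dx)} nm.
#' @slot nNuclei number of nuclei to place (non-overlapping spheres).
#' @slot nucleusRadiusNm \code{c(mean, sd)} of the nucleus radius in nm.
#' @slot nuclearBackground \code{c(mean, sd)}: diffuse in-nucleus FP level in
#'   counts; the sd is the nucleus-to-nucleus variation of the level.
#' @slot cytoplasmBackground constant out-of-nucleus level in counts.
#' @slot dapiIntensity added in-nucleus level for the "dapi" channel.
#' @slot spotAmplitude peak focus counts above local background.
#' @slot spotSigmaLateralNm,spotSigmaAxialNm PSF sigmas in nm.
#' @slot labelingProb probability that a nucleus carries a focus, per channel.
#' @slot doubletProb probability that a labeled nucleus carries a sister-pair
#'   (two same-channel foci).
#' @slot doubletSeparationNm separation of the two sister foci.
#' @slot doubletOrientation "lateral" (in the XY plane, default) or
#'   "isotropic" (uniform 3D direction).
#' @slot dualLabel logical; if TRUE every labeled nucleus carries one green and
#'   one red focus separated by a draw from \code{pairSeparation}.
#' @slot pairSeparation list: \code{list(type = "fixed", value = nm)},
#'   \code{list(type = "normal", mean =, sd =)} or
#'   \code{list(type = "uniform", min =, max =)}.
#' @slot noisePoisson logical: per-voxel Poisson resampling of expected counts.
#' @slot noiseReadSd Gaussian read noise sd in counts (>= 0).
#' @slot noiseOffset constant camera offset in counts.
#' @slot channels channels to render; "dapi" renders filled nuclei.
#' @slot seed integer root RNG seed; per-stage/per-channel streams are derived
#'   from it by fixed offsets.
#' @export
setClass("SimulationConfig",
  representation(stackDims = "integer", voxelSize = "numeric",
    nNuclei = "integer", nucleusRadiusNm = "numeric",
    nuclearBackground = "numeric", cytoplasmBackground = "numeric",
    dapiIntensity = "numeric", spotAmplitude = "numeric",
    spotSigmaLateralNm = "numeric", spotSigmaAxialNm = "numeric",
    labelingProb = "numeric", doubletProb = "numeric",
    doubletSeparationNm = "numeric", doubletOrientation = "character",
    dualLabel = "logical", pairSeparation = "list",
    noisePoisson = "logical", noiseReadSd = "numeric",
    noiseOffset = "numeric", channels = "character", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@stackDims) != 3L || any(object@stackDims < 1L))
      msg <- c(msg, "stackDims must be three positive integers (nz, ny, nx)")
    if (any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be strictly positive")
    if (object@nNuclei < 0L)
      msg <- c(msg, "nNuclei must be >= 0")
    if (object@labelingProb < 0 || object@labelingProb > 1)
      msg <- c(msg, "labelingProb must be in [0, 1]")
    if (object@doubletProb < 0 || object@doubletProb > 1)
      msg <- c(msg, "doubletProb must be in [0, 1]")
    if (object@spotSigmaLateralNm <= 0 || object@spotSigmaAxialNm <= 0)
      msg <- c(msg, "spot sigmas must be > 0")
    if (object@spotAmplitude < 0)
      msg <- c(msg, "spotAmplitude must be >= 0")
    if (object@noiseReadSd < 0)
      msg <- c(msg, "noiseReadSd must be >= 0")
    if (!object@doubletOrientation %in% c("lateral", "isotropic"))
      msg <- c(msg, "doubletOrientation must be 'lateral' or 'isotropic'")
    if (is.null(object@pairSeparation$type) ||
        !object@pairSeparation$type %in% c("fixed", "normal", "uniform"))
      msg <- c(msg, "pairSeparation$type must be 'fixed', 'normal' or 'uniform'")
    if (length(msg)) msg else TRUE
  })

#' Build a simulation configuration
#'
#' See \linkS4class{SimulationConfig} for the meaning of each parameter.
#'
#' @param stackDims \code{c(nz, ny, nx)}.
#' @param voxelSize \code{c(dz, dy, dx)} nm.
#' @param nNuclei number of nuclei.
#' @param nucleusRadiusNm \code{c(mean, sd)} nm.
#' @param nuclearBackground \code{c(mean, sd)} counts.
#' @param cytoplasmBackground counts.
#' @param dapiIntensity counts.
#' @param spotAmplitude peak counts above local background.
#' @param spotSigmaLateralNm,spotSigmaAxialNm PSF sigmas, nm.
#' @param labelingProb per-channel labeling probability.
#' @param doubletProb sister-pair probability for a labeled nucleus.
#' @param doubletSeparationNm sister separation, nm.
#' @param doubletOrientation "lateral" or "isotropic".
#' @param dualLabel render a green/red pair per labeled nucleus.
#' @param pairSeparation list describing the green-red separation draw.
#' @param noisePoisson,noiseReadSd,noiseOffset camera noise model.
#' @param channels channels to render.
#' @param seed root RNG seed.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nNuclei = 4L, stackDims = c(10L, 128L, 128L))
#' cfg
#' @export
simulationConfig <- function(stackDims = c(20L, 256L, 256L),
    voxelSize = c(200, 65, 65), nNuclei = 15L,
    nucleusRadiusNm = c(1800, 120), nuclearBackground = c(100, 10),
    cytoplasmBackground = 20, dapiIntensity = 120, spotAmplitude = 300,
    spotSigmaLateralNm = 130, spotSigmaAxialNm = 350, labelingProb = 0.3,
    doubletProb = 0.1, doubletSeparationNm = 500,
    doubletOrientation = "lateral", dualLabel = FALSE,
    pairSeparation = list(type = "fixed", value = 400),
    noisePoisson = TRUE, noiseReadSd = 3, noiseOffset = 10,
    channels = c("green", "dapi"), seed = 1L) {
  new("SimulationConfig",
      stackDims = as.integer(stackDims), voxelSize = as.numeric(voxelSize),
      nNuclei = as.integer(nNuclei),
      nucleusRadiusNm = as.numeric(nucleusRadiusNm),
      nuclearBackground = as.numeric(nuclearBackground),
      cytoplasmBackground = as.numeric(cytoplasmBackground),
      dapiIntensity = as.numeric(dapiIntensity),
      spotAmplitude = as.numeric(spotAmplitude),
      spotSigmaLateralNm = as.numeric(spotSigmaLateralNm),
      spotSigmaAxialNm = as.numeric(spotSigmaAxialNm),
      labelingProb = as.numeric(labelingProb),
      doubletProb = as.numeric(doubletProb),
      doubletSeparationNm = as.numeric(doubletSeparationNm),
      doubletOrientation = doubletOrientation, dualLabel = dualLabel,
      pairSeparation = pairSeparation, noisePoisson = noisePoisson,
      noiseReadSd = as.numeric(noiseReadSd),
      noiseOffset = as.numeric(noiseOffset),
      channels = channels, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    paste0("SimulationConfig: %d nuclei in %d x %d x %d stack, channels [%s],\n",
           "  p(label) = %g, p(doublet) = %g, dual-label = %s, seed = %d\n"),
    object@nNuclei, object@stackDims[1], object@stackDims[2],
    object@stackDims[3], paste(object@channels, collapse = ", "),
    object@labelingProb, object@doubletProb, object@dualLabel, object@seed))
})

#' GroundTruth: simulator manifest of true nuclei, foci and pair distances
#'
#' @slot nuclei data.frame with columns \code{id, x_nm, y_nm, z_nm, radius_nm}.
#' @slot spots data.frame with columns \code{nucleus_id, channel, x_nm, y_nm,
#'   z_nm, amplitude, is_doublet_member}.
#' @slot pairDistances data.frame with columns \code{nucleus_id, distance_nm}
#'   (dual-label mode; one row per labeled nucleus, the Euclidean distance of
#'   its primary green/red focus pair).
#' @export
setClass("GroundTruth",
  representation(nuclei = "data.frame", spots = "data.frame",
                 pairDistances = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@spots) &&
        !all(object@spots$nucleus_id %in% object@nuclei$id))
      msg <- c(msg, "every spot's nucleus_id must exist in nuclei")
    if (nrow(object@spots)) {
      ni <- match(object@spots$nucleus_id, object@nuclei$id)
      d <- sqrt((object@spots$x_nm - object@nuclei$x_nm[ni])^2 +
                (object@spots$y_nm - object@nuclei$y_nm[ni])^2 +
                (object@spots$z_nm - object@nuclei$z_nm[ni])^2)
      if (any(d > object@nuclei$radius_nm[ni] + 1e-6))
        msg <- c(msg, "every spot center must lie inside its nucleus sphere")
    }
    if (length(msg)) msg else TRUE
  })

groundTruth <- function(nuclei, spots, pairDistances) {
  new("GroundTruth", nuclei = nuclei, spots = spots,
      pairDistances = pairDistances)
}

#' @describeIn GroundTruth-class Nucleus table accessor.
#' @param x a \code{GroundTruth}.
#' @export
truthNuclei <- function(x) x@nuclei

#' @describeIn GroundTruth-class Spot table accessor.
#' @export
truthSpots <- function(x) x@spots

#' @describeIn GroundTruth-class Pair-distance table accessor.
#' @export
truthPairDistances <- function(x) x@pairDistances

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d nuclei, %d spots, %d labeled pairs\n",
              nrow(object@nuclei), nrow(object@spots),
              nrow(object@pairDistances)))
})
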