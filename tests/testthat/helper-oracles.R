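# Independent oracles and fixture builders used across the suite.
# Every oracle here is deliberately implemented differently from the package
# code path it checks.

# Brute-force object-counter oracle: threshold at frac * max, connect
# candidates by iterative minimum-label propagation over pairwise Chebyshev
# adjacency (no BFS/queue), keep components >= minVol, return the weighted
# centroid of the component containing the global-max voxel (0-based z, y, x),
# or NULL.
oracleObjectCounter <- function(a, frac = 0.7, minVol = 20L) {
  mx <- max(a)
  if (mx <= 0) return(NULL)
  thr <- frac * mx
  cand <- which(a >= thr)
  if (!length(cand)) return(NULL)
  d <- dim(a)
  co <- arrayInd(cand, d)
  lab <- seq_along(cand)
  repeat {
    changed <- FALSE
    for (i in seq_along(cand)) {
      nb <- which(abs(co[, 1] - co[i, 1]) <= 1L &
                  abs(co[, 2] - co[i, 2]) <= 1L &
                  abs(co[, 3] - co[i, 3]) <= 1L)
      m <- min(lab[nb])
      if (any(lab[nb] != m)) {
        lab[nb] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  maxIdx <- which.max(a)
  hit <- lab[match(maxIdx, cand)]
  members <- cand[lab == hit]
  if (length(members) < minVol) return(NULL)
  mco <- arrayInd(members, d) - 1L
  w <- a[members]
  c(cz = sum(w * mco[, 1]) / sum(w), cy = sum(w * mco[, 2]) / sum(w),
    cx = sum(w * mco[, 3]) / sum(w), n = length(members))
}

# Studentized range CDF by direct numeric integration:
# F(q; k, df) = Int_0^inf f_df(s) * k * Int phi(z) [Phi(z) - Phi(z - q s)]^(k-1) dz ds
# with s distributed as sqrt(chisq_df / df).
oraclePtukey <- function(q, k, df) {
  inner <- function(s) {
    vapply(s, function(si) {
      stats::integrate(function(z)
        k * stats::dnorm(z) *
          pmax(stats::pnorm(z) - stats::pnorm(z - q * si), 0)^(k - 1),
        -8, 8, rel.tol = 1e-9)$value
    }, numeric(1))
  }
  fs <- function(s)   # density of sqrt(chisq_df / df), in log scale
    exp(log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
        (df - 1) * log(pmax(s, 1e-300)) - df * s^2 / 2)
  stats::integrate(function(s) fs(s) * inner(s), 0, Inf,
                   rel.tol = 1e-7)$value
}

# 40 x 40 x 13 checkerboard fixture for the SNR arithmetic oracle: a 90/110
# alternating background everywhere and a single 400-count pixel at the seed.
makeCheckerboardStack <- function(maxValue = 400) {
  a <- array(0, c(13, 64, 64))
  board <- outer(0:63, 0:63, function(y, x) ifelse((y + x) %% 2 == 0, 90, 110))
  for (z in 1:13) a[z, , ] <- board
  a[7, 33, 33] <- maxValue
  voxelStack(a)
}

# a single noisy ROI-sized stack with one rendered spot at a known sub-voxel
# center; returns the stack and the true center in voxel units (z, y, x)
makeSpotRoi <- function(seedOffset, amplitude = 300, background = 100,
                        readSd = 3, poisson = TRUE, dims = c(15L, 40L, 40L),
                        voxelSize = c(200, 65, 65)) {
  set.seed(9000 + seedOffset)
  ctrVox <- c((dims[1] - 1) / 2 + runif(1, -0.5, 0.5),
              (dims[2] - 1) / 2 + runif(1, -0.5, 0.5),
              (dims[3] - 1) / 2 + runif(1, -0.5, 0.5))
  st <- voxelStack(array(background, dims), voxelSize)
  st <- renderSpot(st, c(ctrVox[3] * voxelSize[3], ctrVox[2] * voxelSize[2],
                         ctrVox[1] * voxelSize[1]), amplitude)
  st <- applyNoise(st, poisson = poisson, readSd = readSd, offset = 0,
                   seed = 9000 + seedOffset)
  list(stack = st, center = ctrVox)
}

# nearest ground-truth spot distance (nm) for a voxel-coordinate point
nearestTruthSpot <- function(spots, voxPoint, voxelSize) {
  p <- c(voxPoint[3] * voxelSize[3], voxPoint[2] * voxelSize[2],
         voxPoint[1] * voxelSize[1])
  min(sqrt((spots$x_nm - p[1])^2 + (spots$y_nm - p[2])^2 +
           (spots$z_nm - p[3])^2))
}

# map each seed to the id of the nearest ground-truth nucleus
seedNucleusIds <- function(seeds, nuclei, voxelSize) {
  vapply(seq_len(nrow(seeds)), function(i) {
    p <- c(seeds$x[i] * voxelSize[3], seeds$y[i] * voxelSize[2],
           seeds$z[i] * voxelSize[1])
    nuclei$id[which.min(sqrt((nuclei$x_nm - p[1])^2 + (nuclei$y_nm - p[2])^2 +
                             (nuclei$z_nm - p[3])^2))]
  }, numeric(1))
}

# standard dual-label field used by the distance tests
dualLabelConfig <- function(seed, nNuclei = 16L, separation = 400,
                            doubletProb = 0) {
  simulationConfig(nNuclei = nNuclei, stackDims = c(20L, 400L, 400L),
    nucleusRadiusNm = c(1800, 120), labelingProb = 1,
    doubletProb = doubletProb, dualLabel = TRUE,
    pairSeparation = list(type = "fixed", value = separation),
    channels = c("green", "red"), seed = seed)
}
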