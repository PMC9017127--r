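test_that("object counting matches symmetric block fixtures", {
  a <- array(0, c(9, 40, 40))
  a[4:6, 19:21, 19:21] <- 100
  r <- detectObjectCounter(voxelStack(a))
  expect_equal(r$voxel_count, 27)
  expect_equal(c(r$cz, r$cy, r$cx), c(4, 19, 19))   # block center, 0-based
  expect_equal(r$threshold_used, 70)

  small <- array(0, c(9, 40, 40))
  small[4:5, 19:20, 19:20] <- 100                   # 8 voxels < 20
  expect_null(detectObjectCounter(voxelStack(small)))

  two <- array(0, c(9, 40, 40))
  two[4:6, 5:7, 5:7] <- 100
  two[4:6, 30:32, 30:32] <- 80                      # above 0.7 * 100 = 70
  comps <- objectComponents(two)
  expect_equal(nrow(comps), 2)
  r2 <- detectObjectCounter(voxelStack(two))
  expect_equal(c(r2$cy, r2$cx), c(5, 5))            # the 100-block wins
  # oracle agrees on the two-block instance
  o <- oracleObjectCounter(two)
  expect_equal(c(r2$cz, r2$cy, r2$cx), unname(o[1:3]), tolerance = 1e-12)

  expect_warning(expect_null(detectObjectCounter(array(0, c(5, 10, 10)))),
                 "all-zero")
})

test_that("object counting equals the brute-force flood-fill oracle on
           randomized instances", {
  for (i in 1:100) {
    set.seed(1300 + i)
    a <- array(rpois(9 * 40 * 40, 30), c(9, 40, 40))
    if (i %% 10 != 0) {   # most instances carry a real blob
      st <- voxelStack(array(0, c(9, 40, 40)))
      ctr <- c(runif(1, 8, 32) * 65, runif(1, 8, 32) * 65, runif(1, 2, 6) * 200)
      a <- a + intensities(renderSpot(st, ctr, runif(1, 120, 300)))
    }
    got <- detectObjectCounter(voxelStack(a))
    want <- oracleObjectCounter(a)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_false(is.null(got))
      expect_equal(c(got$cz, got$cy, got$cx), unname(want[1:3]),
                   tolerance = 1e-9)
      expect_equal(got$voxel_count, unname(want["n"]))
    }
  }
})

test_that("DoG detects nothing in empty substacks and localizes single
           spots to sub-voxel accuracy", {
  expect_equal(nrow(detectDog(array(0, c(9, 40, 40)))), 0)

  # symmetric spot at a voxel center, isotropic sd 2 px
  a <- array(0, c(15, 40, 40))
  st <- renderSpot(voxelStack(a, c(65, 65, 65)), c(20 * 65, 19 * 65, 7 * 65),
                   100, sigmaLatNm = 130, sigmaAxNm = 130)
  d <- detectDog(st, diameterPx = 2 * sqrt(3) * 2)
  expect_equal(nrow(d), 1)
  expect_equal(c(d$cz, d$cy, d$cx), c(7, 19, 20), tolerance = 0.1)

  # sub-voxel lateral center (y, x) = (18.70, 20.30)
  a2 <- voxelStack(array(0, c(15, 40, 40)))
  a2 <- renderSpot(a2, c(20.30 * 65, 18.70 * 65, 7 * 200), 100)
  d2 <- detectDog(a2, diameterPx = 11)
  expect_equal(nrow(d2), 1)
  expect_lt(abs(d2$cy - 18.70), 0.25)
  expect_lt(abs(d2$cx - 20.30), 0.25)
  # oracle: intensity-weighted centroid of voxels above half max
  aa <- intensities(a2)
  idx <- which(aa >= max(aa) / 2)
  co <- arrayInd(idx, dim(aa)) - 1L
  w <- aa[idx]
  expect_lt(abs(d2$cy - sum(w * co[, 2]) / sum(w)), 0.25)
  expect_lt(abs(d2$cx - sum(w * co[, 3]) / sum(w)), 0.25)
})

test_that("both detectors recover simulated spot positions within their
           accuracy budgets over 200 noisy ROIs", {
  errOc <- errDogLat <- rep(NA_real_, 200)
  for (i in 1:200) {
    roi <- makeSpotRoi(i, amplitude = 300, readSd = 10, poisson = FALSE,
                       background = 100)
    oc <- detectObjectCounter(roi$stack)
    if (!is.null(oc))
      errOc[i] <- sqrt((oc$cz - roi$center[1])^2 +
                       (oc$cy - roi$center[2])^2 + (oc$cx - roi$center[3])^2)
    dg <- detectDog(roi$stack, diameterPx = 11)
    if (nrow(dg))
      errDogLat[i] <- sqrt((dg$cy[1] - roi$center[2])^2 +
                           (dg$cx[1] - roi$center[3])^2)
  }
  expect_gt(sum(!is.na(errOc)), 180)
  expect_gt(sum(!is.na(errDogLat)), 180)
  expect_lt(median(errOc, na.rm = TRUE), 1)
  expect_lt(median(errDogLat, na.rm = TRUE), 0.5)
})

test_that("pairwise distances agree between detectors within one voxel
           diagonal", {
  vs <- c(200, 65, 65)
  diagNm <- sqrt(sum(vs^2))
  diffs <- c()
  for (i in 1:30) {
    g <- makeSpotRoi(4000 + i)
    r <- makeSpotRoi(6000 + i)
    ocG <- detectObjectCounter(g$stack); ocR <- detectObjectCounter(r$stack)
    dgG <- detectDog(g$stack); dgR <- detectDog(r$stack)
    if (is.null(ocG) || is.null(ocR) || !nrow(dgG) || !nrow(dgR)) next
    dOc <- euclidean3d(voxelToNm(c(ocG$cz, ocG$cy, ocG$cx), vs),
                       voxelToNm(c(ocR$cz, ocR$cy, ocR$cx), vs))
    dDg <- euclidean3d(voxelToNm(c(dgG$cz[1], dgG$cy[1], dgG$cx[1]), vs),
                       voxelToNm(c(dgR$cz[1], dgR$cy[1], dgR$cx[1]), vs))
    diffs <- c(diffs, abs(dOc - dDg))
  }
  expect_gt(length(diffs), 20)
  expect_true(all(diffs < diagNm))
})

test_that("findSeeds recovers one seed per labeled nucleus on a bright
           field and carries the channel name", {
  cfg <- simulationConfig(nNuclei = 10L, stackDims = c(16L, 300L, 300L),
                          nucleusRadiusNm = c(1400, 80), labelingProb = 1,
                          doubletProb = 0, channels = c("green"), seed = 55L)
  f <- generateField(cfg)
  seeds <- findSeeds(f$stacks$green)
  sp <- truthSpots(f$truth)
  vs <- voxelSize(f$stacks$green)
  # seeds away from the 20 px XY margin are exhaustively matched to truth
  interior <- sp[sp$x_nm >= 20 * 65 & sp$x_nm <= 279 * 65 &
                 sp$y_nm >= 20 * 65 & sp$y_nm <= 279 * 65, ]
  expect_gte(nrow(seeds), nrow(interior) - 1)
  expect_lte(nrow(seeds), nrow(sp))
  for (i in seq_len(nrow(seeds))) {
    err <- nearestTruthSpot(sp, c(seeds$z[i], seeds$y[i], seeds$x[i]), vs)
    expect_lt(err, 2 * sqrt(sum(vs^2)))      # within 2 voxels of a true spot
  }
  expect_true(all(seeds$channel == "green"))
  expect_equal(nrow(findSeeds(voxelStack(array(7, c(8, 64, 64))))), 0)
})
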