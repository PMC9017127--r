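test_that("an empty field is pure background with empty truth", {
  cfg <- simulationConfig(nNuclei = 0L, stackDims = c(6L, 64L, 64L),
                          noisePoisson = FALSE, noiseReadSd = 0,
                          noiseOffset = 0, channels = c("green", "dapi"))
  f <- generateField(cfg)
  expect_equal(nrow(truthNuclei(f$truth)), 0)
  expect_equal(nrow(truthSpots(f$truth)), 0)
  expect_true(all(intensities(f$stacks$green) == 20))
})

test_that("labeling probabilities are honoured exactly at p = 1 and p = 0", {
  cfg <- simulationConfig(nNuclei = 50L, stackDims = c(8L, 500L, 500L),
                          nucleusRadiusNm = c(600, 40), labelingProb = 1,
                          doubletProb = 0, channels = "green", seed = 2L)
  f <- generateField(cfg)
  sp <- truthSpots(f$truth)
  expect_equal(nrow(sp), 50)
  expect_equal(max(table(sp$nucleus_id)), 1)   # no nucleus with two foci
  cfg0 <- simulationConfig(nNuclei = 20L, stackDims = c(8L, 300L, 300L),
                           nucleusRadiusNm = c(600, 40), labelingProb = 0,
                           channels = "green", seed = 2L)
  expect_equal(nrow(truthSpots(generateField(cfg0)$truth)), 0)
})

test_that("dual-label pair distances equal the configured separation and the
           recomputed Euclidean distance of the emitted centers", {
  f <- generateField(dualLabelConfig(seed = 7L, nNuclei = 10L,
                                     separation = 400))
  pd <- truthPairDistances(f$truth)
  expect_gt(nrow(pd), 0)
  expect_true(all(abs(pd$distance_nm - 400) < 1e-6))
  sp <- truthSpots(f$truth)
  for (nid in pd$nucleus_id) {
    g <- sp[sp$nucleus_id == nid & sp$channel == "green" &
            !sp$is_doublet_member, ]
    r <- sp[sp$nucleus_id == nid & sp$channel == "red" &
            !sp$is_doublet_member, ]
    d <- sqrt((g$x_nm - r$x_nm)^2 + (g$y_nm - r$y_nm)^2 + (g$z_nm - r$z_nm)^2)
    expect_equal(d, pd$distance_nm[pd$nucleus_id == nid], tolerance = 1e-9)
  }
})

test_that("renderSpot adds a unit-peak Gaussian and conserves its analytic
           integral", {
  st <- voxelStack(array(0, c(15, 64, 64)))
  expect_identical(intensities(renderSpot(st, c(2000, 2000, 1400), 0)),
                   intensities(st))
  # peak at a voxel center reads back the amplitude
  s2 <- renderSpot(st, c(30 * 65, 28 * 65, 7 * 200), 100)
  expect_equal(max(intensities(s2)), 100, tolerance = 1e-9)
  peak <- arrayInd(which.max(intensities(s2)), dim(intensities(s2))) - 1L
  expect_equal(as.integer(peak), c(7L, 28L, 30L))
  # total added signal matches the closed-form Gaussian integral
  added <- sum(intensities(s2))
  analytic <- 100 * (2 * pi)^1.5 * 130^2 * 350 / (65 * 65 * 200)
  expect_equal(added, analytic, tolerance = 0.005)
  expect_error(renderSpot(st, c(2000, 2000, 1400), 10, sigmaLatNm = 0),
               "sigma")
  expect_error(renderSpot(st, c(-100, 2000, 1400), 10), "outside")
})

test_that("field intensity is conserved without noise", {
  base <- list(nNuclei = 6L, stackDims = c(14L, 220L, 220L),
               nucleusRadiusNm = c(1200, 80), labelingProb = 1,
               doubletProb = 0, noisePoisson = FALSE, noiseReadSd = 0,
               noiseOffset = 0, channels = "green", seed = 12L)
  fSpots <- generateField(do.call(simulationConfig, base))
  fBlank <- generateField(do.call(simulationConfig,
                                  c(base[-which(names(base) == "seed")],
                                    spotAmplitude = 0, seed = 12L)))
  sp <- truthSpots(fSpots$truth)
  expect_equal(nrow(sp), 6)
  added <- sum(intensities(fSpots$stacks$green)) -
           sum(intensities(fBlank$stacks$green))
  # analytic integral of each Gaussian over the stack box (voxel-sum form)
  axisMass <- function(c, sigma, size, n) {
    sigma * sqrt(2 * pi) / size *
      (pnorm((n - 0.5) * size, c, sigma) - pnorm(-0.5 * size, c, sigma))
  }
  analytic <- sum(vapply(seq_len(nrow(sp)), function(i) {
    300 * axisMass(sp$x_nm[i], 130, 65, 220) *
          axisMass(sp$y_nm[i], 130, 65, 220) *
          axisMass(sp$z_nm[i], 350, 200, 14)
  }, numeric(1)))
  expect_equal(added, analytic, tolerance = 0.005)
})

test_that("applyNoise reproduces Poisson moments, is seed-deterministic, and
           disabled noise is the identity", {
  st <- voxelStack(array(1000, c(10, 100, 100)))
  expect_identical(applyNoise(st, poisson = FALSE, readSd = 0, offset = 0),
                   st)
  n1 <- applyNoise(st, poisson = TRUE, readSd = 0, offset = 0, seed = 42L)
  v <- as.numeric(intensities(n1))
  expect_equal(mean(v), 1000, tolerance = 0.01)
  expect_equal(var(v), 1000, tolerance = 0.05)
  n2 <- applyNoise(st, poisson = TRUE, readSd = 0, offset = 0, seed = 42L)
  expect_identical(intensities(n1), intensities(n2))
  expect_error(applyNoise(st, readSd = -1), "readSd")
})

test_that("expectedSnr follows the shot/read-noise formula", {
  expect_equal(expectedSnr(simulationConfig(spotAmplitude = 0)), 0)
  expect_equal(expectedSnr(simulationConfig(spotAmplitude = 300,
    noisePoisson = FALSE, noiseReadSd = 10)), 30)
  expect_equal(expectedSnr(simulationConfig(spotAmplitude = 200,
    nuclearBackground = c(100, 0), noisePoisson = TRUE, noiseReadSd = 0)), 20)
  expect_error(expectedSnr(simulationConfig(noisePoisson = FALSE,
                                            noiseReadSd = 0)), "undefined")
})

test_that("identical configs give bit-identical stacks and truth", {
  cfg <- simulationConfig(nNuclei = 5L, stackDims = c(10L, 160L, 160L),
                          nucleusRadiusNm = c(1000, 60),
                          channels = c("green", "dapi"), seed = 31L)
  f1 <- generateField(cfg)
  f2 <- generateField(cfg)
  expect_identical(intensities(f1$stacks$green),
                   intensities(f2$stacks$green))
  expect_identical(intensities(f1$stacks$dapi), intensities(f2$stacks$dapi))
  expect_identical(truthSpots(f1$truth), truthSpots(f2$truth))
})

test_that("adding a channel does not perturb the draws of existing channels", {
  base <- list(nNuclei = 5L, stackDims = c(10L, 160L, 160L),
               nucleusRadiusNm = c(1000, 60), labelingProb = 1, seed = 31L)
  f1 <- generateField(do.call(simulationConfig, c(base,
                                                  list(channels = "green"))))
  f2 <- generateField(do.call(simulationConfig,
                              c(base, list(channels = c("green", "dapi")))))
  expect_identical(intensities(f1$stacks$green),
                   intensities(f2$stacks$green))
})

test_that("labeled fraction converges to p over 500 nuclei", {
  cfg <- simulationConfig(nNuclei = 500L, stackDims = c(6L, 600L, 600L),
                          nucleusRadiusNm = c(450, 30), labelingProb = 0.3,
                          doubletProb = 0, channels = "green", seed = 77L)
  f <- generateField(cfg)
  frac <- length(unique(truthSpots(f$truth)$nucleus_id)) / 500
  ci <- 1.96 * sqrt(0.3 * 0.7 / 500)
  expect_gt(frac, 0.3 - ci)
  expect_lt(frac, 0.3 + ci)
})

test_that("spot centers keep their margin from the stack borders", {
  f <- generateField(simulationConfig(nNuclei = 30L,
    stackDims = c(12L, 300L, 300L), nucleusRadiusNm = c(900, 60),
    labelingProb = 1, channels = "green", seed = 8L))
  sp <- truthSpots(f$truth)
  expect_true(all(sp$x_nm >= 130 & sp$x_nm <= 299 * 65 - 130))
  expect_true(all(sp$y_nm >= 130 & sp$y_nm <= 299 * 65 - 130))
  expect_true(all(sp$z_nm >= 0 & sp$z_nm <= 11 * 200))
})

test_that("a stack too small for a nucleus fails naming the dimension", {
  expect_error(generateField(simulationConfig(nNuclei = 1L,
    stackDims = c(10L, 20L, 200L), nucleusRadiusNm = c(1800, 0))),
    "y dimension")
  expect_error(generateField(simulationConfig(nNuclei = 1L,
    stackDims = c(10L, 200L, 20L), nucleusRadiusNm = c(1800, 0))),
    "x dimension")
})
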