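test_that("voxel/nm conversion is componentwise and invertible", {
  expect_equal(unname(voxelToNm(c(0, 0, 0))), c(0, 0, 0))
  expect_equal(unname(voxelToNm(c(10, 10, 10), c(200, 65, 65))),
               c(650, 650, 2000))
  p <- c(3.25, 17.5, 22.75)
  expect_equal(unname(nmToVoxel(voxelToNm(p, c(200, 65, 65)),
                                c(200, 65, 65))), p)
  expect_error(voxelToNm(c(1, 1, 1), c(0, 65, 65)), "positive")
})

test_that("euclidean3d satisfies the metric axioms", {
  expect_equal(euclidean3d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean3d(c(0, 0, 0), c(300, 400, 0)), 500)
  expect_equal(euclidean3d(voxelToNm(c(10, 10, 10), c(200, 65, 65)),
                           voxelToNm(c(10, 14, 13), c(200, 65, 65))), 325)
  set.seed(17)
  for (i in 1:50) {
    p <- rnorm(3, 0, 500); q <- rnorm(3, 0, 500); r <- rnorm(3, 0, 500)
    expect_equal(euclidean3d(p, q), euclidean3d(q, p))
    expect_gte(euclidean3d(p, q) + 1e-9, 0)
    expect_lte(euclidean3d(p, r), euclidean3d(p, q) + euclidean3d(q, r) + 1e-9)
    expect_equal(euclidean3d(p, p), 0)
  }
})

test_that("pairing applies the sister-chromatid exclusion rules", {
  g1 <- data.frame(group_id = "n1", cz = 5, cy = 10, cx = 10)
  r1 <- data.frame(group_id = "n1", cz = 5, cy = 12, cx = 11)
  p <- pairSpots(g1, r1)
  expect_equal(nrow(p$pairs), 1)
  expect_equal(nrow(p$exclusions), 0)

  g2 <- rbind(g1, data.frame(group_id = "n1", cz = 6, cy = 20, cx = 20))
  p2 <- pairSpots(g2, r1)
  expect_equal(nrow(p2$pairs), 0)
  expect_equal(p2$exclusions$reason, "two_green")

  p3 <- pairSpots(g1, r1[0, ])
  expect_equal(p3$exclusions$reason, "missing_partner")
  p4 <- pairSpots(g1, rbind(r1, r1))
  expect_equal(p4$exclusions$reason, "two_red")
})

test_that("the 750 nm filter keeps strictly-below distances and logs the
           rest", {
  rec <- data.frame(group_id = paste0("n", 1:4),
                    distance_nm = c(300, 749.9, 750, 900))
  f <- filterDistances(rec)
  expect_equal(f$records$kept, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(f$exclusions$reason, rep("over_threshold", 2))
  expect_equal(sum(f$records$kept) + nrow(f$exclusions), nrow(rec))
  expect_true(all(filterDistances(rec, Inf)$records$kept))
  expect_equal(nrow(filterDistances(rec[0, ])$records), 0)
  expect_error(filterDistances(rec, -1), "thresholdNm")
})

test_that("recovered distances are invariant to an integer-voxel rigid
           translation of both channels", {
  base <- array(100, c(15, 80, 80))
  mk <- function(shift) {
    g <- voxelStack(base); r <- voxelStack(base)
    centers <- list(c(30, 30, 7), c(55, 50, 6))     # (x, y, z) voxels
    for (c0 in centers) {
      gc <- c0 + shift
      g <- renderSpot(g, c(gc[1] * 65, gc[2] * 65, gc[3] * 200), 300)
      r <- renderSpot(r, c((gc[1] + 3) * 65, (gc[2] + 2) * 65, gc[3] * 200),
                      300)
    }
    seeds <- data.frame(channel = "green", z = sapply(centers, `[`, 3),
                        y = sapply(centers, `[`, 2) + shift[2],
                        x = sapply(centers, `[`, 1) + shift[1])
    seeds$z <- seeds$z + shift[3]
    distancePipeline(g, r, seeds = seeds)$records$distance_nm
  }
  d0 <- mk(c(0, 0, 0))
  d1 <- mk(c(2, -3, 1))
  expect_equal(length(d0), 2)
  expect_equal(d0, d1, tolerance = 1e-6)
})

test_that("the pipeline recovers a known separation end to end and excludes
           doublet nuclei", {
  f <- generateField(dualLabelConfig(seed = 301L, nNuclei = 12L,
                                     separation = 400))
  dl <- distancePipeline(f$stacks$green, f$stacks$red)
  expect_gt(sum(dl$records$kept), 6)
  d <- dl$records$distance_nm[dl$records$kept]
  expect_lt(abs(median(d) - 400), sqrt(sum(c(200, 65, 65)^2)))

  fd <- generateField(dualLabelConfig(seed = 302L, nNuclei = 12L,
                                      separation = 400, doubletProb = 0.6))
  seeds <- findSeeds(fd$stacks$green)
  dld <- distancePipeline(fd$stacks$green, fd$stacks$red, seeds = seeds)
  sp <- truthSpots(fd$truth)
  doubletNuc <- unique(sp$nucleus_id[sp$is_doublet_member])
  vs <- voxelSize(fd$stacks$green)
  seedNuc <- seedNucleusIds(seeds, truthNuclei(fd$truth), vs)
  exclRoi <- as.integer(sub("roi_", "",
    dld$exclusions$group_id[dld$exclusions$reason %in%
                              c("two_green", "two_red")]))
  expect_true(all(doubletNuc %in% seedNuc[exclRoi]))
  recRoi <- as.integer(sub("roi_", "", dld$records$group_id))
  expect_false(any(seedNuc[recRoi] %in% doubletNuc))
})

test_that("empty stacks yield empty records without error", {
  e <- voxelStack(array(0, c(15, 80, 80)))
  dl <- distancePipeline(e, e)
  expect_equal(nrow(dl$records), 0)
})

test_that("nucleus-mask grouping flags two seeds in one nucleus", {
  base <- array(100, c(15, 80, 80))
  g <- voxelStack(base); r <- voxelStack(base)
  g <- renderSpot(g, c(30 * 65, 30 * 65, 7 * 200), 300)
  g <- renderSpot(g, c(36 * 65, 31 * 65, 7 * 200), 300)
  r <- renderSpot(r, c(33 * 65, 30 * 65, 7 * 200), 300)
  mask <- matrix(0L, 80, 80)
  mask[20:45, 20:45] <- 1L
  seeds <- data.frame(channel = "green", z = c(7, 7), y = c(30, 31),
                      x = c(30, 36))
  dl <- distancePipeline(g, r, seeds = seeds, mask = mask)
  expect_equal(nrow(dl$records), 0)
  expect_equal(dl$exclusions$reason, "two_green")
  expect_equal(dl$exclusions$group_id, "nucleus_1")
})
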