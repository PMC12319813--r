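test_that("ROI statistics match hand values and the sort-based oracle", {
  asMap <- function(v) array(v, c(length(v), 1, 1))
  lab <- function(v) array(1L, c(length(v), 1, 1))
  s1 <- roiStatistics(asMap(c(1, 2, 3)), lab(1:3), 1)
  expect_equal(s1[["median"]], 2)
  s2 <- roiStatistics(asMap(c(1, 2, 3, 4)), lab(1:4), 1)
  expect_equal(s2[["iqr"]], 1.5)            # type-7 quantiles by hand
  s3 <- roiStatistics(asMap(c(-1, 0, 1)), lab(1:3), 1)
  expect_equal(s3[["skewness"]], 0)
  # random ROIs against the definitional oracle
  set.seed(4)
  for (n in c(11, 500, 4321)) {
    v <- rnorm(n)^3
    st <- roiStatistics(asMap(v), lab(v), 1)
    expect_equal(st[["median"]], quantileOracle(v, 0.5), tolerance = 1e-12)
    expect_equal(st[["iqr"]],
                 quantileOracle(v, 0.75) - quantileOracle(v, 0.25),
                 tolerance = 1e-12)
    expect_equal(st[["skewness"]], skewnessOracle(v), tolerance = 1e-12)
  }
  # invalid voxels excluded and counted; degenerate cases
  sNA <- roiStatistics(asMap(c(1, 2, NaN, 3)), lab(1:4), 1)
  expect_equal(attr(sNA, "nInvalid"), 1)
  expect_equal(sNA[["median"]], 2)
  expect_true(is.na(roiStatistics(asMap(5), lab(1), 1)[["skewness"]]))
  expect_error(roiStatistics(asMap(1:3), lab(1:3), 9), "empty")
})

test_that("box erosion matches the definitional oracle", {
  cube <- array(FALSE, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
  er <- erodeMask(cube)
  expect_equal(sum(er), 1)
  expect_true(er[3, 3, 3])
  big <- array(TRUE, c(5, 5, 5))
  er2 <- erodeMask(big, n = 2)
  expect_equal(which(er2), which(array(seq_len(125), c(5, 5, 5)) == 63))
  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_error(erodeMask(single, roi = "SNc"), "SNc")
  set.seed(5)
  for (i in 1:5) {
    m <- array(runif(6 * 7 * 5) < 0.8, c(6, 7, 5))
    if (!any(erodeOracle(m))) next
    expect_identical(erodeMask(m), erodeOracle(m))
  }
})

test_that("spatial gradients are recovered exactly on noiseless fields", {
  spec <- voxelPhantomSpec(c(26, 26, 26), 1, c(12, 12, 12), c(8, 7, 6),
                           c(2, -1, 0.5), meanTruth = 10, noiseSd = 0)
  ph <- generateVoxelPhantom(spec, seed = 1)
  er <- erodeMask(ph$labels == 1L)
  fit <- fitSpatialGradient(ph$map, er, ph$affine, hemisphere = "left")
  expect_equal(unname(fit@gradient), c(2, -1, 0.5), tolerance = 1e-10)
  expect_equal(fit@p0, 10, tolerance = 1e-8)
  expect_lt(fit@rmse, 1e-10)
  # constant field
  spec0 <- voxelPhantomSpec(c(20, 20, 20), 1, c(9, 9, 9), c(5, 5, 5),
                            c(0, 0, 0), meanTruth = 3, noiseSd = 0)
  ph0 <- generateVoxelPhantom(spec0, seed = 1)
  f0 <- fitSpatialGradient(ph0$map, ph0$labels == 1L, ph0$affine, "left")
  expect_equal(unname(f0@gradient), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(f0@p0, 3, tolerance = 1e-12)
})

test_that("gradient fit is invariant to rigid translation", {
  base <- voxelPhantomSpec(c(30, 30, 30), 1, c(10, 10, 14), c(6, 6, 6),
                           c(1.5, -0.5, 1), meanTruth = 8, noiseSd = 0)
  shifted <- voxelPhantomSpec(c(30, 30, 30), 1, c(10, 17, 14), c(6, 6, 6),
                              c(1.5, -0.5, 1), meanTruth = 8, noiseSd = 0)
  f1 <- fitSpatialGradient(generateVoxelPhantom(base, 1)$map,
                           generateVoxelPhantom(base, 1)$labels == 1L,
                           generateVoxelPhantom(base, 1)$affine, "left")
  f2 <- fitSpatialGradient(generateVoxelPhantom(shifted, 1)$map,
                           generateVoxelPhantom(shifted, 1)$labels == 1L,
                           generateVoxelPhantom(shifted, 1)$affine, "left")
  expect_equal(f1@gradient, f2@gradient, tolerance = 1e-10)
})

test_that("right-hemisphere x flip makes lateral-medial gradients poolable", {
  # a left-hemisphere ROI (negative x) and its mirror with mirrored field
  spec <- voxelPhantomSpec(c(20, 20, 20), 1, c(9, 9, 9), c(5, 5, 5),
                           c(1, 0, 0), meanTruth = 10, noiseSd = 0)
  ph <- generateVoxelPhantom(spec, seed = 1)
  mask <- ph$labels == 1L
  affL <- ph$affine; affL[1, 4] <- -25   # place ROI at negative x
  fL <- fitSpatialGradient(ph$map, mask, affL)
  expect_equal(fL@hemisphere, "left")
  # mirror: flip the array and field along x, place at positive x
  mapR <- ph$map[dim(ph$map)[1]:1, , ]
  maskR <- mask[dim(mask)[1]:1, , ]
  affR <- ph$affine; affR[1, 4] <- 6
  fR <- fitSpatialGradient(mapR, maskR, affR)
  expect_equal(fR@hemisphere, "right")
  expect_equal(fR@gradient[["LM"]], fL@gradient[["LM"]], tolerance = 1e-10)
})

test_that("degenerate planar masks flag the missing direction", {
  m <- array(FALSE, c(6, 6, 6)); m[2:5, 2:5, 3] <- TRUE
  map <- array(1, c(6, 6, 6))
  expect_warning(fit <- fitSpatialGradient(map, m, diag(4), "left"), "IS")
  expect_true(is.na(fit@gradient[["IS"]]))
  expect_false(is.na(fit@gradient[["LM"]]))
  tiny <- array(FALSE, c(6, 6, 6)); tiny[1:7] <- TRUE
  expect_error(fitSpatialGradient(map, array(FALSE, c(6, 6, 6)), diag(4)),
               "at least 8")
})

test_that("volume metrics follow the percentage-change identity", {
  lab <- array(0L, c(10, 10, 10)); lab[1:50] <- 1L
  icv <- array(TRUE, c(10, 10, 10))
  vm <- volumeMetrics(lab, 1, icv, voxelVolume = 1,
                      populationValues = rep(50 / 1000, 5))
  expect_equal(vm$vRoi, 0.05)
  expect_equal(vm$vPct, 0)
  vm2 <- volumeMetrics(lab, 1, icv, populationValues = rep(50 / 1100, 5))
  expect_equal(vm2$vPct, 10)
  expect_error(volumeMetrics(lab, 7, icv), "absent")
  # cohort mean of percentage change is zero by construction
  set.seed(6)
  v <- runif(40, 0.01, 0.05)
  expect_lt(abs(mean(volumePercentChange(v))), 1e-10)
})

test_that("label combination behaves as a set union", {
  lab <- array(0L, c(6, 6, 6))
  lab[1:20] <- 31L; lab[21:50] <- 32L; lab[51:60] <- 7L
  merged <- combineLabels(lab, c(31, 32), 30)
  expect_equal(sum(merged == 30L), 50)
  expect_equal(sum(merged == 7L), 10)
  # statistics over the merged label equal statistics over the union
  map <- array(rnorm(216), c(6, 6, 6))
  su <- roiStatistics(map, merged, 30)
  expect_equal(su[["median"]], median(map[lab %in% c(31, 32)]))
  # voxel counts conserved for disjoint parts
  expect_equal(sum(merged == 30L), sum(lab == 31L) + sum(lab == 32L))
  expect_error(combineLabels(lab, c(31, 32), 7), "collides")
  expect_error(combineLabels(lab, c(98, 99), 100), "none of the labels")
  expect_error(combineLabels(lab, integer(0), 5), "empty")
})
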