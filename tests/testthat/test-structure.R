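test_that("slice clustering separates constant regions and orders labels", {
  sl <- matrix(400, 30, 30)
  sl[, 11:20] <- 600; sl[, 21:30] <- 800
  cl <- clusterSlice(sl, k = 3, seed = 0)
  expect_equal(cl$centers, c(400, 600, 800), tolerance = 1e-9)
  expect_true(all(cl$labels[, 1:10] == 1))
  expect_true(all(cl$labels[, 11:20] == 2))
  expect_true(all(cl$labels[, 21:30] == 3))

  expect_error(clusterSlice(matrix(5, 10, 10), k = 3), "distinct values")

  ## phantom slice: cluster means land near the regional truths
  ph <- genCTPhantom(shape = c(64, 64, 6), seed = 1,
                     params = ctPhantomParams(timepointsH = 500))
  z <- 3
  cal <- truthCalibrate(ph$series[[1]], ph$truth)
  sl2 <- intensities(cal)[, , z]; m2 <- tissueMask(ph$truth)[, , z]
  cl2 <- clusterSlice(sl2, m2, k = 3, seed = 0)
  ## top cluster tracks the IFM; the two sub-clusters below it jointly
  ## cover the fascicles (their pooled mean tracks the fascicle truth)
  expect_lt(abs(max(cl2$centers) - 795), 10)
  lower <- sl2[m2][cl2$labels[m2] < 3]
  expect_lt(abs(mean(lower) - 603), 10)
})

test_that("label ordering is invariant to clustering initialization", {
  ph <- genCTPhantom(shape = c(48, 48, 4), seed = 2)
  cal <- truthCalibrate(ph$series[[length(ph$series)]], ph$truth)
  sl <- intensities(cal)[, , 2]; m <- tissueMask(ph$truth)[, , 2]
  a <- clusterSlice(sl, m, k = 3, seed = 1)
  b <- clusterSlice(sl, m, k = 3, seed = 99)
  expect_false(is.unsorted(a$centers, strictly = TRUE))
  expect_equal(a$centers, b$centers, tolerance = 1e-6)
  expect_equal(a$labels, b$labels)
})

test_that("fascicle segmentation reaches the phantom Dice targets", {
  ## noiseless two-level phantom: set difference against cluster 3 is exact
  ph0 <- genCTPhantom(shape = c(64, 64, 8), seed = 3,
                      params = ctPhantomParams(noiseSdHU = 0,
                                               timepointsH = 500))
  cal0 <- truthCalibrate(ph0$series[[1]], ph0$truth)
  m0 <- suppressWarnings(segmentFascicles(cal0, tissueMask(ph0$truth)))
  expect_gte(diceCoefficient(fascicleMask(m0), fascicleMask(ph0$truth)), 0.99)
  expect_identical(fascicleMask(m0) | ifmMask(m0), tissueMask(ph0$truth))
  expect_false(any(fascicleMask(m0) & ifmMask(m0)))

  ## realistic noise: Dice >= 0.90 across seeds
  dices <- vapply(1:3, function(s) {
    ph <- genCTPhantom(shape = c(64, 64, 8), seed = s,
                       params = ctPhantomParams(timepointsH = 72))
    cal <- truthCalibrate(ph$series[[1]], ph$truth)
    mk <- segmentFascicles(cal, tissueMask(ph$truth), seed = s)
    diceCoefficient(fascicleMask(mk), fascicleMask(ph$truth))
  }, 0)
  expect_true(all(dices >= 0.90))

  ## pure-IFM attenuation everywhere: empty fascicle mask with a warning
  ph1 <- genCTPhantom(shape = c(48, 48, 4), seed = 4,
                      params = ctPhantomParams(muFascicleHU = 795,
                                               muIfmHU = 795, noiseSdHU = 0,
                                               timepointsH = 500))
  cal1 <- truthCalibrate(ph1$series[[1]], ph1$truth)
  expect_warning(m1 <- segmentFascicles(cal1, tissueMask(ph1$truth)),
                 "empty fascicle|reducing")
  expect_equal(sum(fascicleMask(m1)), 0)
})

test_that("fascicle segmentation is equivariant under positive affine maps", {
  ph <- genCTPhantom(shape = c(48, 48, 6), seed = 5)
  cal <- truthCalibrate(ph$series[[length(ph$series)]], ph$truth)
  m1 <- segmentFascicles(cal, tissueMask(ph$truth), seed = 1)
  aff <- cal
  aff@intensities <- 2.5 * cal@intensities + 120
  m2 <- segmentFascicles(aff, tissueMask(ph$truth), seed = 1)
  expect_identical(fascicleMask(m1), fascicleMask(m2))
})

test_that("region statistics handle constants, single voxels and contrast", {
  v <- new("CTVolume", intensities = array(519, c(6, 6, 2)),
           voxelSizeUm = 16.99, calibrated = TRUE, waterROI = integer(0),
           airROI = integer(0), timepointH = 8, agent = "Ta2O5-cNP",
           bathHU = NA_real_)
  m <- array(TRUE, c(6, 6, 2))
  st <- roiStats(v, list(roi = m))
  expect_equal(st$meanHU, 519)
  expect_equal(st$sdHU, 0)

  one <- array(FALSE, c(6, 6, 2)); one[3, 3, 1] <- TRUE
  st1 <- roiStats(v, list(single = one))
  expect_true(st1$sdUndefined)
  expect_true(is.na(st1$sdHU))
  expect_error(roiStats(v, list(none = array(FALSE, c(6, 6, 2)))), "empty")

  fs <- data.frame(meanHU = 603); is <- data.frame(meanHU = 795)
  rc <- regionContrast(fs, is)
  expect_equal(rc$differenceHU, 192)
  rc2 <- regionContrast(data.frame(meanHU = 519), data.frame(meanHU = 696))
  expect_equal(rc2$differenceHU, 177)
  eq <- regionContrast(data.frame(meanHU = 700), data.frame(meanHU = 700))
  expect_equal(eq$differenceHU, 0)
  expect_equal(eq$ratio, 1)
  expect_error(regionContrast(data.frame(meanHU = -1),
                              data.frame(meanHU = 5)), "positive")
})

test_that("IFM reads brighter than fascicles whenever the generator says so", {
  for (s in 1:3) {
    ph <- genCTPhantom(shape = c(48, 48, 6), seed = s)
    cal <- truthCalibrate(ph$series[[length(ph$series)]], ph$truth)
    st <- roiStats(cal, list(fascicle = fascicleMask(ph$truth),
                             ifm = ifmMask(ph$truth)))
    expect_gt(st$meanHU[st$region == "ifm"],
              st$meanHU[st$region == "fascicle"])
  }
})

test_that("slice averaging reduces depth by the grouping factor", {
  ph <- genCTPhantom(shape = c(24, 24, 20), seed = 6)
  av <- averageSlices(ph$native, every = 10)
  expect_equal(dim(av)[3], 2)
  expect_equal(av[1, 1, 1],
               mean(intensities(ph$native)[1, 1, 1:10]), tolerance = 1e-9)
})
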