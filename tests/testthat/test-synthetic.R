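test_that("degenerate relaxation truth yields a constant hold stress", {
  tr <- defaultMechTruth(A1 = 0, A2 = 0, sigmaEq = 2)
  g <- genTensileTest(tr, quickProtocol("control"))
  an <- analyzeTensileTest(g$test)
  hold <- segmentSliceForTest(g$test, "hold8")
  expect_lt(diff(range(hold$stress)), 1e-9)
  expect_true(an$relaxation@degenerate)
  expect_equal(an$relaxation@sigmaEq, 2, tolerance = 1e-9)
})

test_that("trace generation is a pure function of (truth, protocol, seed)", {
  a <- genTensileTest(noiseSd = 0.05, seed = 42,
                      protocol = quickProtocol("damaged"))
  b <- genTensileTest(noiseSd = 0.05, seed = 42,
                      protocol = quickProtocol("damaged"))
  expect_identical(traceData(a$test), traceData(b$test))
  c <- genTensileTest(noiseSd = 0.05, seed = 43,
                      protocol = quickProtocol("damaged"))
  expect_false(identical(traceData(a$test)$force, traceData(c$test)$force))
})

test_that("control protocol produces no overstrain segments, damaged does", {
  ctrl <- genTensileTest(protocol = quickProtocol("control"))$test
  dam <- genTensileTest(protocol = quickProtocol("damaged"))$test
  expect_false(any(grepl("ramp16|_post", segmentMap(ctrl)$label)))
  expect_true(all(c("ramp16", "hold2s", "return", "rezero_post",
                    "ramp8_post", "hold8_post") %in% segmentMap(dam)$label))
})

test_that("diffusion generator matches the closed form", {
  expect_equal(partition(genDiffusionSeries(1, 1, 1)), 1 - exp(-1),
               tolerance = 1e-12)
  expect_equal(partition(genDiffusionSeries(1, 1, 100)), 1, tolerance = 1e-4)
  tp <- agentTimepoints("Ta2O5-cNP")
  ds <- genDiffusionSeries(2.49, 5.38, tp)
  expect_equal(partition(ds), 2.49 * (1 - exp(-tp / 5.38)), tolerance = 1e-12)
  expect_error(genDiffusionSeries(-1, 1, 1), "positive")
  expect_error(genDiffusionSeries(1, 0, 1), "positive")
})

test_that("single-fascicle noiseless phantom has exactly two tissue levels", {
  ph <- genCTPhantom(shape = c(48, 48, 8), seed = 1, maxFascicles = 1,
                     params = ctPhantomParams(noiseSdHU = 0,
                                              timepointsH = 500))
  v <- intensities(truthCalibrate(ph$series[[1]], ph$truth))
  lv <- sort(unique(round(v[tissueMask(ph$truth)], 6)))
  expect_equal(length(lv), 2)
  expect_equal(lv, c(603, 795), tolerance = 1e-6)
})

test_that("phantom masks partition the tissue and ROI means hit the truth", {
  ph <- genCTPhantom(shape = c(64, 64, 24), seed = 7)
  tm <- tissueMask(ph$truth)
  expect_identical(fascicleMask(ph$truth) | ifmMask(ph$truth), tm)
  expect_false(any(fascicleMask(ph$truth) & ifmMask(ph$truth)))
  late <- truthCalibrate(ph$series[[length(ph$series)]], ph$truth)
  st <- roiStats(late, list(fascicle = fascicleMask(ph$truth),
                            ifm = ifmMask(ph$truth)))
  up <- 1 - exp(-72 / ph$truth@tauTrueH)
  muF <- 60 + (603 - 60) * up; muI <- 60 + (795 - 60) * up
  sdN <- ph$truth@noiseSdHU
  expect_lt(abs(st$meanHU[st$region == "fascicle"] - muF),
            3 * sdN / sqrt(st$voxelCount[st$region == "fascicle"]))
  expect_lt(abs(st$meanHU[st$region == "ifm"] - muI),
            3 * sdN / sqrt(st$voxelCount[st$region == "ifm"]))
})

test_that("phantom generation is deterministic under seed", {
  a <- genCTPhantom(shape = c(32, 32, 8), seed = 3)
  b <- genCTPhantom(shape = c(32, 32, 8), seed = 3)
  expect_identical(intensities(a$native), intensities(b$native))
  expect_identical(intensities(a$series[[2]]), intensities(b$series[[2]]))
  expect_identical(fascicleMask(a$truth), fascicleMask(b$truth))
})

test_that("phantom rejects voxel sizes too coarse for the fascicle range", {
  expect_error(genCTPhantom(shape = c(32, 32, 4), voxelUm = 400, seed = 1),
               "too coarse")
})

test_that("null cohorts pair identically and cohorts are seed-deterministic", {
  nullCo <- genCohort(3, damageEffect = defaultDamageEffect(
    d = 0, residualStrain = 0), seed = 8, precondBlocks = 0,
    mechNoiseSd = 0, partitionNoiseSd = 0)
  gt <- nullCo@groundTruth$mechParams
  dE <- gt$E[gt$group == "control"] - gt$E[gt$group == "damaged"]
  expect_equal(dE, rep(0, 3))

  a <- genCohort(2, seed = 9, precondBlocks = 0)
  b <- genCohort(2, seed = 9, precondBlocks = 0)
  expect_identical(studyDesign(a), studyDesign(b))
  expect_identical(traceData(a@mech[[1]]), traceData(b@mech[[1]]))
  expect_identical(partition(a@diffusion[[1]]), partition(b@diffusion[[1]]))
})

test_that("cohort pairs are complete within ligament", {
  co <- genCohort(4, seed = 10, precondBlocks = 0)
  tb <- studyDesign(co)
  expect_equal(nrow(tb), 8)
  for (lg in unique(tb$ligamentId))
    expect_setequal(tb$group[tb$ligamentId == lg], c("control", "damaged"))
  expect_equal(length(co@diffusion), 8 * 2)  # both agents per subsample
})
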