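test_that("elliptical area matches closed form and quadrature", {
  expect_equal(ellipticalArea(4, 3), pi * 3, tolerance = 1e-9)
  expect_equal(ellipticalArea(2.5, 2.5), pi * 2.5^2 / 4, tolerance = 1e-12)
  ## quadrature oracle: area of (x/a)^2 + (y/b)^2 <= 1 by integration
  for (w in c(1, 2.7, 5)) for (th in c(1, 3.3, 5)) {
    a <- w / 2; b <- th / 2
    quad <- stats::integrate(function(x) 2 * b * sqrt(pmax(0, 1 - (x / a)^2)),
                             -a, a, rel.tol = 1e-12)$value
    expect_equal(ellipticalArea(w, th), quad, tolerance = 1e-9)
  }
  expect_error(ellipticalArea(-1, 2), "positive")
})

test_that("zero-load length crossing is located and interpolated", {
  ## stress exactly at preload on one sample
  s <- data.frame(length = c(20, 20.5, 21), stress = c(0, 0.05, 0.1))
  expect_equal(findZeroLoadLength(s), 20.5)
  ## linear 0 -> 0.1 MPa over 20 -> 21 mm crosses at the midpoint
  s2 <- data.frame(length = c(20, 21), stress = c(0, 0.1))
  expect_equal(findZeroLoadLength(s2), 20.5)
  expect_error(findZeroLoadLength(data.frame(length = 1:3, stress = 0)),
               "never reached")
  ## generator oracle: recovered within one sample spacing
  g <- genTensileTest(protocol = quickProtocol("control"))
  L0 <- zeroLoadLength(g$test)
  expect_lt(abs(L0 - 19.6), 19.6 * 0.005 / 200)
})

test_that("Young's modulus fit recovers exact and generated slopes", {
  ramp <- data.frame(strain = seq(0, 0.08, 1e-4))
  ramp$stress <- 50 * ramp$strain
  m <- suppressWarnings(computeYoungModulus(ramp))  # zero-residual fit
  expect_equal(m@E, 50, tolerance = 1e-12)
  expect_equal(m@rSquared, 1, tolerance = 1e-12)

  g <- genTensileTest(protocol = quickProtocol("control"))
  an <- analyzeTensileTest(g$test)
  expect_lt(abs(an$modulus@E - 70.10) / 70.10, 0.02)

  set.seed(1)
  noise <- data.frame(strain = seq(0.03, 0.09, 1e-4))
  noise$stress <- rnorm(nrow(noise))
  mn <- computeYoungModulus(noise)
  expect_lt(mn@rSquared, 0.05)
  expect_true(mn@lowQuality)
  expect_error(computeYoungModulus(ramp[1:5, ], window = c(0, 1e-9)), "<10")
})

test_that("relaxation fit recovers the healthy-group truth and flags degenerates", {
  g <- genTensileTest(protocol = quickProtocol("control"))
  hold <- segmentSliceForTest(g$test, "hold8")
  fit <- fitRelaxation(hold)
  tr <- g$truth
  expect_lt(abs(fit@sigmaEq - tr@sigmaEq) / tr@sigmaEq, 1e-3)
  expect_lt(abs(fit@A1 - tr@A1) / tr@A1, 1e-3)
  expect_lt(abs(fit@theta1 - tr@theta1) / tr@theta1, 1e-3)
  expect_lt(abs(fit@A2 - tr@A2) / tr@A2, 1e-3)
  expect_lt(abs(fit@theta2 - tr@theta2) / tr@theta2, 1e-3)
  expect_equal(fit@ratioPE, 1.80, tolerance = 1e-3)

  const <- data.frame(tSeg = seq(0.1, 600, 0.1), stress = 2)
  dg <- fitRelaxation(const)
  expect_true(dg@degenerate)
  expect_equal(dg@sigmaEq, 2)
  expect_equal(dg@A1 + dg@A2, 0)
  expect_equal(dg@ratioPE, 1)

  ## single-exponential input: A2 ~ 0, slow time constant unidentifiable
  t <- seq(0.1, 600, 0.1)
  single <- data.frame(tSeg = t, stress = 1.5 + 0.9 * exp(-t / 3))
  sf <- fitRelaxation(single)
  expect_lt(sf@A2, 1e-3)
  expect_true(sf@theta2Unidentifiable)
})

test_that("relaxation fit is equivariant under uniform stress scaling", {
  g <- genTensileTest(protocol = quickProtocol("control"), noiseSd = 0.02,
                      seed = 3)
  hold <- segmentSliceForTest(g$test, "hold8")
  f1 <- fitRelaxation(hold)
  hold2 <- hold; hold2$stress <- 3.7 * hold$stress
  f2 <- fitRelaxation(hold2)
  expect_equal(f2@sigmaEq / f1@sigmaEq, 3.7, tolerance = 1e-6)
  expect_equal(f2@A1 / f1@A1, 3.7, tolerance = 1e-4)
  expect_equal(f2@A2 / f1@A2, 3.7, tolerance = 1e-4)
  expect_equal(f2@theta1, f1@theta1, tolerance = 1e-5)
  expect_equal(f2@theta2, f1@theta2, tolerance = 1e-5)
  expect_equal(f2@ratioPE, f1@ratioPE, tolerance = 1e-6)
  expect_gte(f1@ratioPE, 1)
})

test_that("phase shift is recovered exactly and is shift/offset invariant", {
  f <- 0.1
  t <- seq(0, 100, 0.01)
  seg <- data.frame(tSeg = t,
                    strain = 0.08 + 0.005 * sin(2 * pi * f * t),
                    stress = 2 + 0.35 * sin(2 * pi * f * t - 4.13 * pi / 180))
  fit <- fitSinusoidPhase(seg, f)
  expect_equal(fit@gammaDeg, 4.13, tolerance = 1e-6)

  ## elastic limit: stress proportional to strain has zero lag
  seg0 <- seg; seg0$stress <- 40 * seg0$strain
  expect_equal(fitSinusoidPhase(seg0, f)@gammaDeg, 0, tolerance = 1e-9)

  ## time-origin shift and stress offset leave the phase unchanged
  segS <- seg; segS$tSeg <- segS$tSeg + 12.34; segS$stress <- segS$stress + 5
  expect_equal(fitSinusoidPhase(segS, f)@gammaDeg, fit@gammaDeg,
               tolerance = 1e-9)
  expect_error(fitSinusoidPhase(seg[t < 20, ], f), "cycles")
})

test_that("phase recovery stays within 0.2 degrees at 5% amplitude noise", {
  f <- 0.5; t <- seq(0, 20, 0.01)  # 10 cycles
  amp <- 0.35
  errs <- vapply(seq_len(100), function(s) {
    set.seed(s)
    seg <- data.frame(
      tSeg = t, strain = 0.08 + 0.005 * sin(2 * pi * f * t),
      stress = 2 + amp * sin(2 * pi * f * t - 3.27 * pi / 180) +
        rnorm(length(t), 0, 0.05 * amp))
    abs(fitSinusoidPhase(seg, f)@gammaDeg - 3.27)
  }, 0)
  expect_lt(median(errs), 0.2)
  expect_lt(unname(quantile(errs, 0.9)), 0.2)
})

test_that("yield detection finds bilinear kinks and flags linear ramps", {
  eps <- seq(0.08, 0.16, 2e-4)
  bil <- data.frame(strain = eps,
                    stress = ifelse(eps <= 0.12, 70 * eps,
                                    70 * 0.12 + 35 * (eps - 0.12)))
  y <- detectYield(bil, ELinear = 70)
  expect_false(y$noYield)
  expect_equal(y$yieldStrain, 0.12, tolerance = 1e-6)
  expect_equal(y$yieldStress, 70 * 0.12, tolerance = 1e-4)

  lin <- data.frame(strain = eps, stress = 70 * eps)
  expect_true(detectYield(lin, ELinear = 70)$noYield)

  g <- genTensileTest(protocol = quickProtocol("damaged"))
  an <- analyzeTensileTest(g$test)
  expect_lt(abs(an$damage@yieldStrain - g$truth@yieldStrain), 0.01)
  expect_lt(abs(an$damage@yieldStress - g$truth@yieldStress) /
              g$truth@yieldStress, 0.01)
})

test_that("damage parameters follow their definitions and vanish for identity", {
  mk <- function(se, a1, a2) new("RelaxationFit", sigmaEq = se, A1 = a1,
                                 theta1 = 2, A2 = a2, theta2 = 100,
                                 ratioPE = (se + a1 + a2) / se, rmse = 0,
                                 degenerate = FALSE,
                                 theta2Unidentifiable = FALSE)
  pre <- mk(3, 1.2, 0.8)   # peak 5.0
  post <- mk(0.5, 0.25, 0.15)  # peak 0.9
  dm <- damageParameters(pre, post, 20.0, 20.8)
  expect_equal(dm@DSigma, 1 - 0.9 / 5.0, tolerance = 1e-12)  # 0.82
  expect_equal(dm@lambdaEpsilon, 0.04, tolerance = 1e-12)

  same <- damageParameters(pre, pre, 20.0, 20.0)
  expect_equal(same@DSigma, 0)
  expect_equal(same@DEpsilon, 0)
  expect_equal(same@lambdaEpsilon, 0)
})

test_that("full zero-noise analysis recovers every generator parameter to 1e-3", {
  g <- genTensileTest(protocol = quickProtocol("damaged"))
  an <- analyzeTensileTest(g$test)
  tr <- g$truth; d <- tr@damageFraction
  relErr <- function(est, tru) abs(est - tru) / abs(tru)
  expect_lt(relErr(an$modulus@E, tr@E), 1e-3)
  expect_lt(relErr(an$relaxation@sigmaEq, tr@sigmaEq), 1e-3)
  expect_lt(relErr(an$relaxation@theta2, tr@theta2), 1e-3)
  for (f in names(an$sinusoid))
    expect_lt(relErr(an$sinusoid[[f]]@gammaDeg, tr@gammaDeg[[f]]), 1e-3)
  expect_lt(relErr(an$damage@DSigma, d), 1e-3)
  expect_lt(relErr(an$damage@DEpsilon, d), 1e-3)
  expect_lt(relErr(an$damage@lambdaEpsilon, tr@residualStrain), 1e-3)
  expect_lt(relErr(an$post$modulus@E, (1 - d) * tr@E), 1e-3)
})
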