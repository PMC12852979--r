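test_that("signed-rank p-values match enumeration oracles for small n", {
  ## all-positive n = 6, no ties: p = 2/64
  w <- wilcoxonSignedRank(11:16, rep(10, 6))
  expect_equal(w$pValue, 2 / 64)
  expect_true(w$exact)

  ## antisymmetric pairs: symmetric null is indistinguishable, p = 1
  w2 <- suppressWarnings(wilcoxonSignedRank(c(1, -1, 2.5, -2.5), 0))
  expect_equal(w2$pValue, 1)

  ## random pairs (with occasional ties) equal brute-force enumeration
  set.seed(11)
  for (n in c(5, 7, 9, 11)) {
    d <- round(rnorm(n), 1)  # rounding forces ties
    d[d == 0] <- 0.05
    ours <- wilcoxonSignedRank(d, 0)
    expect_equal(ours$pValue, bruteWilcoxonP(d), tolerance = 1e-12,
                 info = paste("n =", n))
  }

  ## tie-free case also agrees with the standard exact implementation
  set.seed(12)
  x <- rnorm(11); y <- rnorm(11)
  expect_equal(wilcoxonSignedRank(x, y)$pValue,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)

  expect_error(wilcoxonSignedRank(rep(3, 4), rep(3, 4)), "zero")
  expect_warning(wilcoxonSignedRank(1:3, 0), "underpowered")
})

test_that("zero differences are dropped before ranking", {
  d <- c(0, 0, 1, 2, -3, 4, 5)
  w <- wilcoxonSignedRank(d, 0)
  expect_equal(w$n, 5)
  expect_equal(w$pValue, bruteWilcoxonP(d), tolerance = 1e-12)
})

test_that("spearman matches monotone limits and the permutation oracle", {
  x <- c(1, 3, 4, 7, 9, 12)
  expect_equal(spearmanCorrelation(x, x^3 + 2)$rho, 1)
  expect_equal(spearmanCorrelation(x, -sqrt(x))$rho, -1)

  set.seed(13)
  a <- rnorm(7); b <- rnorm(7)
  s <- spearmanCorrelation(a, b)
  expect_true(s$exact)
  expect_equal(s$pValue, bruteSpearmanP(a, b), tolerance = 1e-12)
  ref <- cor.test(a, b, method = "spearman", exact = TRUE)
  expect_equal(s$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(s$pValue, ref$p.value, tolerance = 1e-12)

  expect_error(spearmanCorrelation(rep(1, 6), rnorm(6)), "constant")
  expect_error(spearmanCorrelation(1:3, 1:3), "n >= 4")
})

test_that("spearman is invariant to strictly monotone transforms", {
  set.seed(14)
  x <- runif(9); y <- rnorm(9)
  base <- spearmanCorrelation(x, y)
  tr <- spearmanCorrelation(exp(3 * x), y^3 + 5 * y)  # y^3+5y is monotone
  expect_equal(tr$rho, base$rho, tolerance = 1e-12)
  expect_equal(tr$pValue, base$pValue, tolerance = 1e-12)
})

test_that("correlation screen pools correctly and flags engineered links", {
  ## cohort where iodixanol Pmax is a monotone function of the 0.1 Hz phase
  set.seed(15)
  n <- 20
  gamma01 <- runif(n, 3, 5)
  biomech <- data.frame(
    sampleId = sprintf("S%02d", 1:n),
    group = rep(c("control", "damaged"), each = n / 2),
    gamma0.1 = gamma01,
    E = rnorm(n, 70, 10),
    DSigma = c(rep(NA, n / 2), runif(n / 2, 0.6, 0.9)))
  cect <- data.frame(
    sampleId = rep(biomech$sampleId, 2),
    agent = rep(c("iodixanol", "Ta2O5-cNP"), each = n),
    Pmax = c(1.5 - 0.2 * gamma01 + rnorm(n, 0, 0.01), rnorm(n, 2.5, 0.5)),
    tauH = c(rnorm(n, 0.8, 0.1), rnorm(n, 5.4, 1)))
  out <- correlationScreen(biomech, cect)
  hit <- out[out$parameter == "gamma0.1" & out$cectParameter == "Pmax" &
               out$agent == "iodixanol", ]
  expect_true(hit$significant)
  expect_lt(hit$rho, -0.9)
  ## damage parameters are screened damaged-only
  dmg <- out[out$parameter == "DSigma", ]
  expect_true(all(dmg$pooling == "damaged-only"))
  expect_true(all(dmg$n == n / 2))
  othr <- out[out$parameter == "E", ]
  expect_true(all(othr$pooling == "pooled"))

  expect_error(correlationScreen(biomech, cect[0, ]), "common sample ids")
})

test_that("null cells of the screen are not systematically significant", {
  set.seed(16)
  hits <- replicate(30, {
    n <- 22
    biomech <- data.frame(sampleId = sprintf("S%02d", 1:n),
                          group = rep(c("control", "damaged"), n / 2),
                          E = rnorm(n, 70, 20))
    cect <- data.frame(sampleId = biomech$sampleId, agent = "iodixanol",
                       Pmax = rnorm(n, 0.8, 0.1), tauH = rnorm(n, 0.8, 0.2))
    out <- correlationScreen(biomech, cect)
    mean(out$significant)
  })
  expect_lte(mean(hits), 0.10)  # nominal 5% per cell, generous margin
})
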