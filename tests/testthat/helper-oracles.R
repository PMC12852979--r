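## Independent oracles and fixture builders used across the suite.

## Brute-force exact Wilcoxon signed-rank p by enumerating all 2^n sign
## assignments (independent of the package's DP implementation).
bruteWilcoxonP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- as.vector(signs %*% r)
  min(1, 2 * min(mean(Wall <= W + 1e-9), mean(Wall >= W - 1e-9)))
}

## Brute-force exact Spearman p over all n! permutations of y.
bruteSpearmanP <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  perms <- ligamentCECT:::allPermutations(length(y))
  rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
  mean(abs(rhos) >= abs(rho) - 1e-12)
}

## Per-slice erosion of a 3D mask with a disc (matches the shrink applied by
## segmentTissue, so truth can be shrink-corrected before Dice).
erodeMask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  br <- EBImage::makeBrush(2 * radius + 1, "disc")
  out <- array(FALSE, dim(mask))
  for (z in seq_len(dim(mask)[3]))
    out[, , z] <- EBImage::erode(mask[, , z] + 0, br) > 0
  out
}

## Calibrate a phantom volume with the generator's exact raw mapping
## (isolates region statistics from water/air ROI sampling noise).
truthCalibrate <- function(volume, truth) {
  v <- (ligamentCECT::intensities(volume) - truth@rawIntercept) / truth@rawSlope
  out <- volume
  out@intensities <- v
  out@calibrated <- TRUE
  out
}

## Short protocols for tests that do not need preconditioning.
quickProtocol <- function(group) defaultProtocol(group, precondBlocks = 0)

## Extract one labeled stress-strain segment of a test (time rebased).
segmentSliceForTest <- function(test, label) {
  sss <- toStressStrain(test, zeroLoadLength(test))
  ligamentCECT:::segmentSlice(sss, test, label)
}
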