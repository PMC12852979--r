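#' Calibrate a CT volume to Hounsfield units
#'
#' Applies the linear map sending the water-tube ROI mean to 0 HU and the
#' air ROI mean to -1000 HU voxelwise, and sets the calibrated flag.
#'
#' @param volume a [CTVolume-class] with non-empty `waterROI` and `airROI`.
#' @return the calibrated [CTVolume-class].
#' @export
huCalibrate <- function(volume) {
  stopIfNot(length(volume@waterROI) > 0 && length(volume@airROI) > 0,
            "water and air reference ROIs must be defined")
  v <- intensities(volume)
  mw <- mean(v[volume@waterROI]); ma <- mean(v[volume@airROI])
  stopIfNot(abs(mw - ma) > 1e-9, "degenerate calibration: water mean equals air mean")
  hu <- (v - mw) * 1000 / (mw - ma)
  out <- volume
  out@intensities <- hu
  out@calibrated <- TRUE
  validObject(out)
  out
}

## Deterministic two-means intensity split: k-means centres estimated on a
## subsample, all voxels assigned to the nearest centre.
kmeansAssign <- function(values, k, seed = 0, nstart = 10, maxSample = 2e5) {
  u <- unique(values)
  stopIfNot(length(u) >= k, "fewer distinct values (%d) than k = %d",
            length(u), k)
  withSeed(seed, {
    train <- if (length(values) > maxSample) sample(values, maxSample) else values
    km <- kmeans(train, centers = k, nstart = nstart, iter.max = 100)
  })
  centers <- sort(as.vector(km$centers))
  lab <- max.col(-abs(outer(values, centers, "-")), ties.method = "first")
  list(labels = lab, centers = centers)
}

#' Segment tissue from background by intensity clustering
#'
#' k-means (k = 2) over voxel intensities of the full volume; the tissue is
#' the higher-mean cluster. Per-slice post-processing mirrors the standard
#' recipe: morphological closing then opening with a disk (radius
#' `smoothRadius` pixels), boundary shrinking by `shrink` pixels and removal
#' of connected components smaller than `minArea` pixels. A known reference
#' region (e.g. the water tube) can be excluded up front.
#'
#' @param volume a calibrated [CTVolume-class].
#' @param smoothRadius disk radius (pixels) for closing/opening; 0 disables.
#' @param shrink boundary erosion (pixels); 0 disables.
#' @param minArea minimum connected-component area per slice (pixels).
#' @param exclude optional logical array of voxels to exclude (defaults to
#'   the volume's water ROI bounding cylinder when present).
#' @param seed clustering seed (recorded for determinism).
#' @return logical tissue mask array.
#' @export
segmentTissue <- function(volume, smoothRadius = 10, shrink = 10,
                          minArea = 2000, exclude = NULL, seed = 0) {
  stopIfNot(isCalibrated(volume), "volume must be HU-calibrated first")
  v <- intensities(volume)
  km <- kmeansAssign(as.vector(v), 2, seed = seed)
  mask <- array(km$labels == which.max(km$centers), dim = dim(v))
  if (is.null(exclude) && length(volume@waterROI)) {
    ## exclude the full extent (all z) of the water ROI footprint
    idx <- arrayInd(volume@waterROI, dim(v))
    foot <- matrix(FALSE, dim(v)[1], dim(v)[2])
    foot[unique(idx[, 1:2, drop = FALSE])] <- TRUE
    foot <- EBImage::dilate(foot + 0, EBImage::makeBrush(9, "disc"))
    exclude <- array(rep(foot > 0, dim(v)[3]), dim = dim(v))
  }
  if (!is.null(exclude)) mask[exclude] <- FALSE
  brush <- if (smoothRadius > 0)
    EBImage::makeBrush(2 * smoothRadius + 1, "disc") else NULL
  shrinkBrush <- if (shrink > 0)
    EBImage::makeBrush(2 * shrink + 1, "disc") else NULL
  for (z in seq_len(dim(v)[3])) {
    m <- mask[, , z] + 0
    if (!is.null(brush)) {
      m <- EBImage::closing(m, brush)
      m <- EBImage::opening(m, brush)
    }
    if (!is.null(shrinkBrush)) m <- EBImage::erode(m, shrinkBrush)
    if (minArea > 0 && any(m > 0)) {
      lbl <- EBImage::bwlabel(m)
      sizes <- tabulate(lbl[lbl > 0])
      keep <- which(sizes >= minArea)
      m <- array(as.numeric(lbl %in% keep), dim = dim(lbl))
    }
    mask[, , z] <- m > 0
  }
  stopIfNot(any(mask), "empty tissue mask after filtering")
  mask
}

#' Bulk contrast-agent partition across an immersion time series
#'
#' `partition(t) = (mean HU of tissue at t - mean HU of native tissue) /
#' bath HU`, with the bath attenuation referenced to water (0 HU after
#' calibration) so that the bath itself has partition 1. The native-scan
#' subtraction isolates contrast-induced attenuation and can be disabled.
#'
#' @param native the native (pre-immersion) calibrated [CTVolume-class].
#' @param series list of calibrated timepoint [CTVolume-class] objects.
#' @param masks a single logical tissue mask applied to all scans, or a list
#'   of per-timepoint masks parallel to `series`.
#' @param nativeMask mask for the native scan; defaults to `masks` when a
#'   single mask is given, else to the first per-timepoint mask.
#' @param subtractNative subtract the native tissue mean (default TRUE).
#' @param sampleId identifier carried on the result.
#' @return a [DiffusionSeries-class] ordered by timepoint.
#' @export
bulkPartition <- function(native, series, masks, nativeMask = NULL,
                          subtractNative = TRUE, sampleId = "S1") {
  bath <- bathHU(native)
  if (is.na(bath)) bath <- bathHU(series[[1]])
  stopIfNot(is.finite(bath) && bath > 0, "bath attenuation must be positive")
  stopIfNot(isCalibrated(native) &&
              all(vapply(series, isCalibrated, TRUE)),
            "all volumes must be HU-calibrated")
  single <- !is.list(masks)
  if (is.null(nativeMask)) nativeMask <- if (single) masks else masks[[1]]
  tp <- vapply(series, timepoint, 0)
  o <- order(tp)
  nativeMean <- if (subtractNative)
    mean(intensities(native)[nativeMask]) else 0
  part <- vapply(o, function(i) {
    m <- if (single) masks else masks[[i]]
    (mean(intensities(series[[i]])[m]) - nativeMean) / bath
  }, 0)
  new("DiffusionSeries", timepointsH = tp[o], partition = part,
      agent = agent(series[[1]]), sampleId = sampleId)
}

#' Fit the first-order exponential uptake model
#'
#' Nonlinear least squares for `partition(t) = Pmax (1 - exp(-t / tau))`.
#' Initial values: `Pmax0` is the last (largest-t) partition and `tau0` the
#' earliest time at which the series reaches 63.2% of `Pmax0` (linearly
#' interpolated); both parameters are bounded positive and a small grid of
#' fallback tau starts guards against non-convergence.
#'
#' @param series a [DiffusionSeries-class] with at least 3 timepoints.
#' @return a [PartitionFit-class]. At the fitted tau the model evaluates to
#'   `(1 - exp(-1)) = 63.2%` of Pmax by construction.
#' @export
fitUptake <- function(series) {
  t <- timepoints(series); y <- partition(series)
  stopIfNot(length(t) >= 3, "need >= 3 timepoints (got %d)", length(t))
  Pm0 <- max(y[length(y)], 1e-6)
  thr <- 0.632 * Pm0
  tau0 <- if (any(y >= thr)) {
    i <- which(y >= thr)[1]
    if (i == 1) t[1] else
      t[i - 1] + (thr - y[i - 1]) * (t[i] - t[i - 1]) / (y[i] - y[i - 1])
  } else max(t)
  tau0 <- max(tau0, min(t) / 10)
  dat <- data.frame(t = t, y = y)
  best <- NULL; tried <- character(0)
  for (ta in unique(c(tau0, 0.5, 2, 8, 24))) {
    tried <- c(tried, sprintf("tau0=%.3g", ta))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ pm * (1 - exp(-t / tau)), data = dat,
                        start = list(pm = Pm0, tau = ta),
                        lower = c(pm = 1e-12, tau = 1e-12),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      ssr <- sum(resid(fit)^2)
      if (is.null(best) || ssr < best$ssr - 1e-18) best <- list(fit = fit, ssr = ssr)
      if (ssr < 1e-20 * length(y)) break
    }
  }
  stopIfNot(!is.null(best), "uptake fit did not converge (starts tried: %s)",
            paste(tried, collapse = "; "))
  cf <- coef(best$fit)
  new("PartitionFit", Pmax = unname(cf["pm"]), tauH = unname(cf["tau"]),
      rmse = rmseOf(y, fitted(best$fit)), nPoints = length(t))
}

#' Worst-case bath dilution error
#'
#' With a bath of `ratio` times the sample volume, tissue uptake at a given
#' partition depletes the bath concentration by at most `partition / ratio`
#' (mass balance); at the standard 100x bath this is negligible.
#'
#' @param partition achieved tissue partition (fraction).
#' @param bathToSampleVolumeRatio bath-to-sample volume ratio (default 100).
#' @return worst-case relative bath-concentration depletion.
#' @export
dilutionError <- function(partition, bathToSampleVolumeRatio = 100) {
  stopIfNot(all(bathToSampleVolumeRatio > 0), "volume ratio must be positive")
  partition / bathToSampleVolumeRatio
}
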