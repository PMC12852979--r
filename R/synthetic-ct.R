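#' Parameter set for the CT phantom generator
#'
#' Defaults emulate the nanoparticle-agent study conditions: equilibrium
#' attenuation 603 HU in fascicles and 795 HU in the interfascicular matrix,
#' reconstruction noise sd 22 HU, bulk uptake Pmax 2.49 with tau 5.38 h at
#' the nanoparticle timepoints, a 60 HU native soft-tissue baseline, and a
#' known linear raw reconstruction scale (raw = 0.5 * HU + 600) so that HU
#' calibration from the water/air references can be exercised.
#'
#' @param muFascicleHU,muIfmHU equilibrium regional attenuations (HU).
#' @param noiseSdHU additive Gaussian noise sd (HU).
#' @param Pmax,tauH bulk uptake truth (partition fraction, hours).
#' @param timepointsH immersion timepoints (hours).
#' @param baselineHU native soft-tissue attenuation (HU).
#' @param rawSlope,rawIntercept linear map from HU to the emitted raw scale.
#' @return named list of parameters for [genCTPhantom()].
#' @export
ctPhantomParams <- function(muFascicleHU = 603, muIfmHU = 795,
                            noiseSdHU = 22, Pmax = 2.49, tauH = 5.38,
                            timepointsH = agentTimepoints("Ta2O5-cNP"),
                            baselineHU = 60, rawSlope = 0.5,
                            rawIntercept = 600) {
  list(muFascicleHU = muFascicleHU, muIfmHU = muIfmHU, noiseSdHU = noiseSdHU,
       Pmax = Pmax, tauH = tauH, timepointsH = timepointsH,
       baselineHU = baselineHU, rawSlope = rawSlope,
       rawIntercept = rawIntercept)
}

## Rejection-sampled circle packing inside a disc: fascicle centres/radii in
## voxel units, >= `gap` voxels of interfascicular matrix between circles.
packFascicles <- function(rt, voxelUm, maxFascicles, gap = 1,
                          diamRangeUm = c(50, 500), attempts = 4000) {
  dmin <- max(diamRangeUm[1], 3 * voxelUm)  # >= 3 voxels across
  stopIfNot(dmin <= diamRangeUm[2],
            "voxel size %.3g um too coarse for fascicles <= %g um",
            voxelUm, diamRangeUm[2])
  ## place larger fascicles first (dense packings need the big disks early,
  ## as in real cross-sections where fascicles dominate over the thin IFM)
  diams <- sort(runif(attempts %/% 8, dmin, diamRangeUm[2]), decreasing = TRUE)
  cy <- numeric(0); cx <- numeric(0); cr <- numeric(0)
  for (dm in diams) {
    if (length(cr) >= maxFascicles) break
    r <- dm / 2 / voxelUm
    if (r + gap >= rt) next
    for (k in seq_len(60)) {
      rho <- sqrt(runif(1)) * (rt - r - gap)
      th <- runif(1, 0, 2 * pi)
      y <- rho * sin(th); x <- rho * cos(th)
      if (!length(cr) || all((cy - y)^2 + (cx - x)^2 >= (cr + r + gap)^2)) {
        cy <- c(cy, y); cx <- c(cx, x); cr <- c(cr, r)
        break
      }
    }
  }
  stopIfNot(length(cr) > 0, "no fascicle fits the phantom cross-section")
  list(y = cy, x = cx, r = cr)
}

#' Generate a micro-CT phantom time series with ground truth
#'
#' Builds a cylindrical tissue sample whose cross-section is tiled with
#' quasi-circular fascicles (diameters sampled between 50 and 500 um,
#' clipped to at least 3 voxels) embedded in interfascicular matrix, extruded
#' along the z (fascicle) axis, in an air background with a water-tube
#' reference cylinder. The native volume sits at a soft-tissue baseline; each
#' immersion timepoint adds regional uptake
#' `delta(t) = (mu_region - baseline) * (1 - exp(-t / tauH))`, larger in the
#' IFM than in fascicles for the nanoparticle agent. Volumes are emitted on a
#' known raw linear scale (uncalibrated) with additive Gaussian noise.
#'
#' The implied bath attenuation (stored in each volume and in the truth) is
#' the area-weighted equilibrium tissue gain divided by `Pmax`, so the bulk
#' partition of the phantom converges to `Pmax` by construction.
#'
#' @param shape volume dimensions `c(ny, nx, nz)`; slice k is `[, , k]`.
#' @param voxelUm isotropic voxel size in micrometres.
#' @param params parameter list from [ctPhantomParams()].
#' @param seed RNG seed; the phantom is a pure function of (params, seed).
#' @param maxFascicles cap on the number of packed fascicles (e.g. 1 for a
#'   single-fascicle phantom).
#' @param agent agent label stored on the volumes.
#' @return list with `native` (a [CTVolume-class]), `series` (list of
#'   [CTVolume-class] per timepoint) and `truth` (a [CTGroundTruth-class]).
#' @export
genCTPhantom <- function(shape = c(96, 96, 48), voxelUm = 16.99,
                         params = ctPhantomParams(), seed = NULL,
                         maxFascicles = Inf, agent = "Ta2O5-cNP") {
  ny <- shape[1]; nx <- shape[2]; nz <- shape[3]
  withSeed(seed, {
    rt <- 0.30 * min(ny, nx)
    ctrY <- 0.52 * ny; ctrX <- 0.40 * nx
    rw <- 0.09 * min(ny, nx)
    tubeY <- 0.22 * ny; tubeX <- 0.82 * nx
    pk <- packFascicles(rt, voxelUm, maxFascicles)

    Y <- matrix(seq_len(ny), ny, nx)
    X <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    tissue2d <- (Y - ctrY)^2 + (X - ctrX)^2 <= rt^2
    tube2d <- (Y - tubeY)^2 + (X - tubeX)^2 <= rw^2
    fasc2d <- matrix(FALSE, ny, nx)
    for (i in seq_along(pk$r))
      fasc2d <- fasc2d |
        ((Y - (ctrY + pk$y[i]))^2 + (X - (ctrX + pk$x[i]))^2 <= pk$r[i]^2)
    fasc2d <- fasc2d & tissue2d
    ifm2d <- tissue2d & !fasc2d

    rep3 <- function(m) array(m, dim = c(ny, nx, nz))
    tissueMask <- rep3(tissue2d); fascMask <- rep3(fasc2d)
    ifmMask <- rep3(ifm2d); tubeMask <- rep3(tube2d)

    ## reference ROIs: tube core (half radius, middle z) and an air corner
    core2d <- (Y - tubeY)^2 + (X - tubeX)^2 <= (rw / 2)^2
    zMid <- seq(max(1, round(nz / 4)), round(3 * nz / 4))
    coreMask <- array(FALSE, dim = c(ny, nx, nz))
    coreMask[, , zMid] <- core2d
    airMask <- array(FALSE, dim = c(ny, nx, nz))
    airMask[seq_len(max(4, round(ny / 12))), seq_len(max(4, round(nx / 12))), zMid] <- TRUE
    waterROI <- which(coreMask); airROI <- which(airMask)

    ampF <- params$muFascicleHU - params$baselineHU
    ampI <- params$muIfmHU - params$baselineHU
    nF <- sum(fasc2d); nI <- sum(ifm2d)
    bulkAmp <- (nF * ampF + nI * ampI) / (nF + nI)
    bath <- bulkAmp / params$Pmax

    toRaw <- function(hu) params$rawSlope * hu + params$rawIntercept
    mkVolume <- function(tH) {
      up <- if (is.na(tH)) 0 else 1 - exp(-tH / params$tauH)
      hu <- array(-1000, dim = c(ny, nx, nz))
      hu[tubeMask] <- 0
      hu[fascMask] <- params$baselineHU + ampF * up
      hu[ifmMask] <- params$baselineHU + ampI * up
      raw <- toRaw(hu)
      if (params$noiseSdHU > 0)
        raw <- raw + rnorm(length(raw), 0,
                           params$rawSlope * params$noiseSdHU)
      new("CTVolume", intensities = array(raw, dim = c(ny, nx, nz)),
          voxelSizeUm = voxelUm, calibrated = FALSE, waterROI = waterROI,
          airROI = airROI, timepointH = tH, agent = agent, bathHU = bath)
    }
    native <- mkVolume(NA_real_)
    series <- lapply(params$timepointsH, mkVolume)
    truth <- new("CTGroundTruth", fascicleMask = fascMask, ifmMask = ifmMask,
                 tissueMask = tissueMask, tubeMask = tubeMask,
                 muFascicleHU = params$muFascicleHU,
                 muIfmHU = params$muIfmHU, noiseSdHU = params$noiseSdHU,
                 PmaxTrue = params$Pmax, tauTrueH = params$tauH,
                 timepointsH = params$timepointsH,
                 baselineHU = params$baselineHU, bathHU = bath,
                 rawSlope = params$rawSlope,
                 rawIntercept = params$rawIntercept)
    list(native = native, series = series, truth = truth)
  })
}
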