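## Forward model for tensile-test traces. Strain is machine strain relative
## to the zero-load length, which is *defined* (as on the instrument) as the
## length at a 0.05 MPa preload. The ramp model therefore carries a toe
## offset eps0 chosen so that stress at zero strain equals the preload; the
## post-damage curve, scaled by (1 - d), gets its own offset so that the
## redetermined zero-load length is exactly L0 * (1 + residualStrain).

toeOffset <- function(E, preload, etoe) {
  a <- 2 * preload / E
  (a + sqrt(a^2 + 4 * a * etoe)) / 2
}

## Quadratic toe from -eps0 (slack, zero stress) blending into slope E at
## strain etoe; sigma(0) = preload by construction of eps0.
rampShape <- function(eps, E, eps0, etoe = 0.02) {
  s <- numeric(length(eps))
  q <- eps > -eps0 & eps < etoe
  s[q] <- E * (eps[q] + eps0)^2 / (2 * (etoe + eps0))
  l <- eps >= etoe
  s[l] <- E * (etoe + eps0) / 2 + E * (eps[l] - etoe)
  s
}

#' Generate a synthetic tensile test with known ground truth
#'
#' Emulates the full measurement sequence of [defaultProtocol()]. The
#' relaxation hold follows `sigma(t) = sigmaEq + A1 exp(-t/theta1) +
#' A2 exp(-t/theta2)` from the ramp end; the strain ramp has a quadratic toe
#' over the first 2% strain followed by slope E; sinusoidal stress lags
#' strain by the truth's per-frequency phase shift; the 16% overstrain ramp
#' is bilinear with the tangent modulus dropping to 30% of E beyond the
#' yield strain; post-damage stress is scaled by `(1 - damageFraction)` and
#' the zero-load length shifted by `residualStrain`. Additive Gaussian noise
#' of sd `noiseSd` (MPa) is applied to stress before conversion to force.
#'
#' The returned truth has `yieldStress` completed from the curve
#' (`E * (yieldStrain - (0.02 - eps0)/2)`, the stress of the toe+linear ramp
#' at the yield strain).
#'
#' @param truth a [MechGroundTruth-class]; see [defaultMechTruth()].
#' @param protocol protocol description from [defaultProtocol()]; its group
#'   decides whether overstrain/post-damage segments are generated.
#' @param noiseSd stress noise sd in MPa.
#' @param seed RNG seed (traces are identical under the same seed).
#' @param geometry named numeric `width`, `thickness`, `clampLength` in mm.
#' @param sampleId sample identifier.
#' @return list with `test` (a [TensileTest-class]) and `truth` (the
#'   completed [MechGroundTruth-class]).
#' @export
genTensileTest <- function(truth = defaultMechTruth(),
                           protocol = defaultProtocol("control"),
                           noiseSd = 0, seed = NULL,
                           geometry = c(width = 5.4, thickness = 2.7,
                                        clampLength = 19.6),
                           sampleId = "S1") {
  group <- protocol$group
  stopIfNot(group %in% c("control", "damaged"),
            "protocol group must be control or damaged")
  E <- truth@E; etoe <- 0.02
  p <- protocol$preloadMPa
  eps0 <- toeOffset(E, p, etoe)
  d <- if (group == "damaged") truth@damageFraction else 0
  Epost <- (1 - d) * E
  eps0post <- toeOffset(Epost, p, etoe)
  lam <- truth@residualStrain
  L0 <- unname(geometry["clampLength"])
  L0post <- L0 * (1 + lam)
  area <- ellipticalArea(geometry["width"], geometry["thickness"])
  ey <- truth@yieldStrain
  yStress <- rampShape(ey, E, eps0, etoe)
  truth@yieldStress <- unname(yStress)
  postYieldSlope <- 0.3 * E

  rates <- protocol$rates
  segs <- list()
  addSeg <- function(label, dur, rate, strainFn, stressFn, post = FALSE) {
    n <- max(2L, round(dur * rate))
    t <- seq(0, dur, length.out = n + 1L)[-1L]  # local time, excl. boundary
    segs[[length(segs) + 1L]] <<- list(label = label, dur = dur, t = t,
                                       strain = strainFn(t),
                                       stress = stressFn(t), post = post)
  }
  sigRamp <- function(eps) rampShape(eps, E, eps0, etoe)
  sigPost <- function(eps) (1 - d) * rampShape(eps, Epost / (1 - d), eps0post, etoe)
  ## (Epost/(1-d) = E; shape uses slope E then scale (1-d) => slope Epost.)

  triangle <- function(t, lo, hi, rate) {
    per <- 2 * (hi - lo) / rate
    ph <- t %% per
    ifelse(ph <= per / 2, lo + rate * ph, hi - rate * (ph - per / 2))
  }

  ## -- preconditioning: blocks of 10 cycles 0 -> 6% at 2%/s
  if (protocol$precondBlocks > 0) {
    durP <- protocol$precondBlocks * protocol$precondCycles *
      2 * protocol$precondStrain / protocol$precondRate
    addSeg("preconditioning", durP, rates["precond"],
           function(t) triangle(t, 0, protocol$precondStrain, protocol$precondRate),
           function(t) sigRamp(triangle(t, 0, protocol$precondStrain,
                                        protocol$precondRate)))
  }
  ## -- re-zeroing ramp: -0.5% -> 2% -> -0.5% at 0.5%/s; preload crossing at 0
  rzLo <- -0.005; rzHi <- protocol$rezeroStrain; rzRate <- protocol$rezeroRate
  durRz <- 2 * (rzHi - rzLo) / rzRate
  addSeg("rezero", durRz, rates["rezero"],
         function(t) triangle(t, rzLo, rzHi, rzRate),
         function(t) sigRamp(triangle(t, rzLo, rzHi, rzRate)))
  ## -- 8% ramp at 8%/s
  rampTo <- protocol$rampStrain; rr <- protocol$rampRate
  addSeg("ramp8", rampTo / rr, rates["ramp"],
         function(t) rr * t, function(t) sigRamp(rr * t))
  ## -- 600 s relaxation hold
  sigHold <- function(t, scale = 1)
    scale * (truth@sigmaEq + truth@A1 * exp(-t / truth@theta1) +
               truth@A2 * exp(-t / truth@theta2))
  addSeg("hold8", protocol$holdS, rates["hold"],
         function(t) rep(rampTo, length(t)), function(t) sigHold(t))
  ## -- sinusoids
  amp <- protocol$sinAmplitude
  for (f in protocol$frequenciesHz) {
    g <- truth@gammaDeg[as.character(f)] * pi / 180
    dur <- sinusoidCycles(protocol, f) / f
    addSeg(paste0("sinusoid@", f), dur, rates["sinusoid"],
           local({f0 <- f; function(t) rampTo + amp * sin(2 * pi * f0 * t)}),
           local({f0 <- f; g0 <- g
                  function(t) truth@sigmaEq + E * amp * sin(2 * pi * f0 * t - g0)}))
  }

  if (group == "damaged") {
    over <- protocol$overStrain
    sig16 <- function(eps) ifelse(eps <= ey, sigRamp(eps),
                                  yStress + postYieldSlope * (eps - ey))
    ## continue from 8% to 16% at 8%/s
    addSeg("ramp16", (over - rampTo) / rr, rates["ramp"],
           function(t) rampTo + rr * t, function(t) sig16(rampTo + rr * t))
    sigTop <- sig16(over)
    addSeg("hold2s", protocol$overHoldS, rates["hold"] * 10,
           function(t) rep(over, length(t)),
           function(t) rep(sigTop, length(t)))
    ## return to the original length; stress unloads with slope E, floored at 0
    addSeg("return", over / rr, rates["return."],
           function(t) over - rr * t,
           function(t) pmax(0, sigTop - E * (rr * t)))
    ## post-damage segments in strain relative to the new zero-load length
    addSeg("rezero_post", durRz, rates["rezero"],
           function(t) triangle(t, rzLo, rzHi, rzRate),
           function(t) sigPost(triangle(t, rzLo, rzHi, rzRate)), post = TRUE)
    addSeg("ramp8_post", rampTo / rr, rates["ramp"],
           function(t) rr * t, function(t) sigPost(rr * t), post = TRUE)
    addSeg("hold8_post", protocol$holdS, rates["hold"],
           function(t) rep(rampTo, length(t)),
           function(t) sigHold(t, scale = 1 - d), post = TRUE)
    for (f in protocol$frequenciesHz) {
      g <- truth@gammaDeg[as.character(f)] * pi / 180
      dur <- sinusoidCycles(protocol, f) / f
      addSeg(paste0("sinusoid_post@", f), dur, rates["sinusoid"],
             local({f0 <- f; function(t) rampTo + amp * sin(2 * pi * f0 * t)}),
             local({f0 <- f; g0 <- g
                    function(t) (1 - d) * (truth@sigmaEq +
                      E * amp * sin(2 * pi * f0 * t - g0))}),
             post = TRUE)
    }
  }

  ## assemble global time axis and the segment map
  t0 <- 0; rows <- vector("list", length(segs)); smap <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    tg <- t0 + s$t
    L <- if (s$post) L0post * (1 + s$strain) else L0 * (1 + s$strain)
    rows[[i]] <- data.frame(time = tg, displacement = L - L0, stress = s$stress)
    ## tStart is the segment boundary (ramp end for holds); the first segment
    ## starts at its first sample so the map stays inside the time range.
    smap[[i]] <- data.frame(label = s$label,
                            tStart = if (i == 1L) tg[1] else t0,
                            tEnd = t0 + s$dur)
    t0 <- t0 + s$dur
  }
  tr <- do.call(rbind, rows)
  if (noiseSd > 0)
    tr$stress <- withSeed(seed, tr$stress + rnorm(nrow(tr), 0, noiseSd))
  tr$force <- tr$stress * area
  tr$stress <- NULL
  test <- new("TensileTest", trace = tr, segments = do.call(rbind, smap),
              geometry = c(width = unname(geometry["width"]),
                           thickness = unname(geometry["thickness"]),
                           clampLength = L0),
              sampleId = sampleId, group = group)
  validObject(test)
  list(test = test, truth = truth)
}

#' Generate a synthetic bulk-uptake diffusion series
#'
#' `partition(t) = Pmax * (1 - exp(-t / tauH)) + noise`.
#'
#' @param Pmax equilibrium partition (> 0).
#' @param tauH diffusion time constant in hours (> 0).
#' @param timepointsH positive immersion timepoints; see [agentTimepoints()].
#' @param noiseSd additive Gaussian noise sd on partition.
#' @param seed RNG seed.
#' @param agent,sampleId metadata carried on the result.
#' @return a [DiffusionSeries-class].
#' @export
genDiffusionSeries <- function(Pmax, tauH,
                               timepointsH = agentTimepoints("iodixanol"),
                               noiseSd = 0, seed = NULL,
                               agent = "iodixanol", sampleId = "S1") {
  stopIfNot(Pmax > 0, "Pmax must be positive")
  stopIfNot(tauH > 0, "tauH must be positive")
  stopIfNot(all(timepointsH > 0), "timepoints must be positive")
  part <- Pmax * (1 - exp(-timepointsH / tauH))
  if (noiseSd > 0)
    part <- withSeed(seed, part + rnorm(length(part), 0, noiseSd))
  new("DiffusionSeries", timepointsH = timepointsH, partition = part,
      agent = agent, sampleId = sampleId)
}
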