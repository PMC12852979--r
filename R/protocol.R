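## Protocol constants of the tensile-testing and immersion schedules.

#' Default tensile-testing protocol
#'
#' Encodes the measurement sequence: five preconditioning blocks of ten
#' loading cycles to 6% strain at 2%/s, a slow re-zeroing ramp used to find
#' the zero-load length at a 0.05 MPa preload, an 8% strain ramp at 8%/s
#' followed by a 600 s relaxation hold, and sinusoidal loading of 0.5% strain
#' amplitude at 0.1, 0.5, 1 and 2 Hz. The damaged variant appends a 16%
#' overstrain ramp, a 2 s hold, return to the original length, and a repeat
#' of re-zeroing, ramp, hold and sinusoids.
#'
#' Sampling rates are per-segment: ramps 500 Hz, holds 10 Hz, sinusoids
#' 100 Hz (at least 50 samples per cycle at 2 Hz), re-zeroing 200 Hz and
#' preconditioning 20 Hz.
#'
#' @param group `"control"` or `"damaged"`.
#' @param frequenciesHz sinusoid frequencies (Hz).
#' @param nCycles minimum sinusoid cycles per frequency.
#' @param sinusoidWindowS minimum dwell per frequency in seconds; the cycle
#'   count per frequency is `max(nCycles, ceiling(sinusoidWindowS * f))`, so
#'   every frequency contributes a comparable number of samples to the
#'   phase-shift fit.
#' @param precondBlocks preconditioning blocks (10 cycles each); set to 0 to
#'   omit preconditioning from generated traces.
#' @param holdS relaxation hold duration, seconds.
#' @return list describing the protocol, consumed by [genTensileTest()].
#' @export
defaultProtocol <- function(group = c("control", "damaged"),
                            frequenciesHz = c(0.1, 0.5, 1, 2),
                            nCycles = 10, sinusoidWindowS = 80,
                            precondBlocks = 5, holdS = 600) {
  group <- match.arg(group)
  list(group = group, frequenciesHz = frequenciesHz, nCycles = nCycles,
       sinusoidWindowS = sinusoidWindowS,
       precondBlocks = precondBlocks, precondCycles = 10,
       precondStrain = 0.06, precondRate = 0.02,
       rezeroStrain = 0.02, rezeroRate = 0.005,
       rampStrain = 0.08, rampRate = 0.08, holdS = holdS,
       sinAmplitude = 0.005,
       overStrain = 0.16, overHoldS = 2,
       preloadMPa = 0.05,
       rates = c(ramp = 500, hold = 20, sinusoid = 100, rezero = 200,
                 precond = 20, return. = 100))
}

## Cycles generated at frequency f: at least nCycles, and enough to fill the
## per-frequency dwell window.
sinusoidCycles <- function(protocol, f) {
  w <- if (!is.null(protocol$sinusoidWindowS)) protocol$sinusoidWindowS else 0
  max(protocol$nCycles, ceiling(w * f))
}

#' Default mechanical ground truth (healthy-group study conditions)
#'
#' @param ... named slot overrides (e.g. `E = 50`, `damageFraction = 0`).
#' @return a [MechGroundTruth-class] object.
#' @export
defaultMechTruth <- function(...) {
  ratioPE <- 1.80
  A1 <- 0.88; A2 <- 0.49
  obj <- new("MechGroundTruth",
             E = 70.10, sigmaEq = (A1 + A2) / (ratioPE - 1),
             A1 = A1, theta1 = 2.56, A2 = A2, theta2 = 137.18,
             gammaDeg = c("0.1" = 4.13, "0.5" = 3.27, "1" = 3.08, "2" = 2.95),
             yieldStrain = 0.12, yieldStress = NA_real_,
             damageFraction = 1 - 22.13 / 70.10, residualStrain = 0.04)
  ov <- list(...)
  for (nm in names(ov)) slot(obj, nm) <- ov[[nm]]
  validObject(obj)
  obj
}

#' Default immersion timepoints per contrast agent
#'
#' Iodixanol: 0.75, 1.5, 3, 5, 8, 22 h. Ta2O5-cNP: 3, 8, 22, 46, 72 h.
#'
#' @param agent `"iodixanol"` or `"Ta2O5-cNP"`.
#' @return numeric vector of hours.
#' @export
agentTimepoints <- function(agent = c("iodixanol", "Ta2O5-cNP")) {
  agent <- match.arg(agent)
  if (agent == "iodixanol") c(0.75, 1.5, 3, 5, 8, 22) else c(3, 8, 22, 46, 72)
}

#' Default uptake truth per contrast agent
#'
#' Equilibrium partition and diffusion time constant typical of the two
#' agents: iodixanol Pmax 0.81, tau 0.82 h; Ta2O5-cNP Pmax 2.49, tau 5.38 h
#' (between-sample sds 0.06/0.20 and 0.90/1.36 respectively).
#'
#' @param agent `"iodixanol"` or `"Ta2O5-cNP"`.
#' @return list with `Pmax`, `tauH` and their between-sample sds.
#' @export
agentUptakeTruth <- function(agent = c("iodixanol", "Ta2O5-cNP")) {
  agent <- match.arg(agent)
  if (agent == "iodixanol")
    list(Pmax = 0.81, tauH = 0.82, PmaxSd = 0.06, tauSd = 0.20)
  else
    list(Pmax = 2.49, tauH = 5.38, PmaxSd = 0.90, tauSd = 1.36)
}
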