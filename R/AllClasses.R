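## Central S4 containers. Heavy data (traces, volumes) live in TensileTest /
## CTVolume; per-analysis results are small value classes with validity checks.

#' TensileTest: a raw mechanical test trace with protocol annotations
#'
#' Holds the device trace (time, displacement, force), the ordered protocol
#' segment map, the sample geometry, and group membership. The trace is kept
#' in instrument units (s, mm, N); stress/strain conversion happens in the
#' analysis layer via [toStressStrain()].
#'
#' @slot trace data.frame with columns `time` (s, strictly increasing),
#'   `displacement` (mm, relative to the clamp-to-clamp mounting length) and
#'   `force` (N).
#' @slot segments data.frame with columns `label`, `tStart`, `tEnd`: ordered,
#'   non-overlapping intervals within the time range. Labels follow the
#'   protocol: `preconditioning`, `rezero`, `ramp8`, `hold8`, `sinusoid@f`,
#'   and for the damaged group additionally `ramp16`, `hold2s`, `return`,
#'   `rezero_post`, `ramp8_post`, `hold8_post`, `sinusoid_post@f`.
#' @slot geometry named numeric: `width` (mm), `thickness` (mm),
#'   `clampLength` (mm); all positive. Cross-section is treated as elliptical.
#' @slot sampleId character scalar.
#' @slot group `"control"` or `"damaged"`; damaged-group tests must contain
#'   the 16% overstrain and post-damage segments, control tests must not.
#'
#' @export
setClass("TensileTest",
  representation(trace = "data.frame", segments = "data.frame",
                 geometry = "numeric", sampleId = "character",
                 group = "character"))

setValidity("TensileTest", function(object) {
  tr <- object@trace
  if (!all(c("time", "displacement", "force") %in% names(tr)))
    return("trace must have columns time, displacement, force")
  dt <- diff(tr$time)
  if (length(dt) && any(dt <= 0)) {
    i <- which(dt <= 0)[1]
    return(sprintf("time not strictly increasing at row %d", i + 1L))
  }
  g <- object@geometry
  if (!all(c("width", "thickness", "clampLength") %in% names(g)))
    return("geometry must name width, thickness, clampLength")
  if (any(g[c("width", "thickness", "clampLength")] <= 0))
    return("geometry values must be positive")
  sg <- object@segments
  if (nrow(sg)) {
    if (any(sg$tStart > sg$tEnd)) return("segment with tStart > tEnd")
    o <- order(sg$tStart)
    if (any(sg$tStart[o][-1] < sg$tEnd[o][-nrow(sg)] - 1e-9))
      return("segment intervals overlap")
    if (min(sg$tStart) < min(tr$time) - 1e-9 ||
        max(sg$tEnd) > max(tr$time) + 1e-9)
      return("segment intervals outside trace time range")
  }
  if (!object@group %in% c("control", "damaged"))
    return("group must be 'control' or 'damaged'")
  post <- grepl("^(ramp16|hold2s|return|rezero_post|ramp8_post|hold8_post|sinusoid_post)",
                sg$label)
  if (object@group == "damaged" && !any(post))
    return("damaged-group test lacks overstrain/post-damage segments")
  if (object@group == "control" && any(post))
    return("control test contains post-damage segments")
  TRUE
})

#' CTVolume: a 3D micro-CT attenuation grid with acquisition metadata
#'
#' @slot intensities 3D numeric array indexed `[y, x, z]`; `z` is the slicing
#'   axis along the fascicle direction (slice k is `intensities[, , k]`).
#' @slot voxelSizeUm isotropic voxel size in micrometres (default 16.99).
#' @slot calibrated logical; `TRUE` once mapped to Hounsfield units.
#' @slot waterROI,airROI integer linear indices of the water-tube and air
#'   reference regions used for HU calibration.
#' @slot timepointH immersion time in hours; `NA` for the native
#'   (pre-immersion) scan.
#' @slot agent `"iodixanol"`, `"Ta2O5-cNP"` or `"none"`.
#' @slot bathHU attenuation of the contrast-agent bath in HU (`NA` if unknown).
#'
#' @export
setClass("CTVolume",
  representation(intensities = "array", voxelSizeUm = "numeric",
                 calibrated = "logical", waterROI = "integer",
                 airROI = "integer", timepointH = "numeric",
                 agent = "character", bathHU = "numeric"))

setValidity("CTVolume", function(object) {
  if (length(dim(object@intensities)) != 3L) return("intensities must be 3D")
  if (object@voxelSizeUm <= 0) return("voxelSizeUm must be positive")
  if (!object@agent %in% c("iodixanol", "Ta2O5-cNP", "none"))
    return("unknown agent")
  n <- length(object@intensities)
  if (length(object@waterROI) && (min(object@waterROI) < 1 || max(object@waterROI) > n))
    return("waterROI indices out of range")
  if (length(object@airROI) && (min(object@airROI) < 1 || max(object@airROI) > n))
    return("airROI indices out of range")
  if (isTRUE(object@calibrated) && length(object@waterROI)) {
    mw <- mean(object@intensities[object@waterROI])
    if (abs(mw) > 15) return(sprintf(
      "calibrated volume has water ROI mean %.1f HU (outside [-15, 15])", mw))
  }
  TRUE
})

#' DiffusionSeries: bulk contrast-agent partition versus immersion time
#'
#' Partition is tissue attenuation gain normalized to bath attenuation
#' (1.0 = bath concentration); cationic agents may exceed 1.
#'
#' @slot timepointsH strictly increasing positive hours.
#' @slot partition dimensionless partition per timepoint.
#' @slot agent contrast agent name.
#' @slot sampleId sample identifier.
#' @export
setClass("DiffusionSeries",
  representation(timepointsH = "numeric", partition = "numeric",
                 agent = "character", sampleId = "character"))

setValidity("DiffusionSeries", function(object) {
  t <- object@timepointsH
  if (length(t) != length(object@partition))
    return("timepointsH and partition lengths differ")
  if (length(t) && (any(t <= 0) || any(diff(t) <= 0)))
    return("timepoints must be strictly increasing and positive")
  if (any(!is.finite(object@partition))) return("non-finite partition values")
  TRUE
})

#' PartitionFit: first-order exponential uptake fit
#'
#' Model: partition(t) = Pmax * (1 - exp(-t / tau)); tau is the time to reach
#' 63.2% of the equilibrium partition Pmax.
#'
#' @slot Pmax equilibrium partition (> 0).
#' @slot tauH diffusion time constant in hours (> 0).
#' @slot rmse root-mean-square residual of the fit.
#' @slot nPoints number of timepoints fitted.
#' @export
setClass("PartitionFit",
  representation(Pmax = "numeric", tauH = "numeric", rmse = "numeric",
                 nPoints = "integer"))

setValidity("PartitionFit", function(object) {
  if (object@Pmax <= 0) return("Pmax must be positive")
  if (object@tauH <= 0) return("tauH must be positive")
  TRUE
})

#' RelaxationFit: two-exponential (Prony) stress-relaxation parameters
#'
#' Model: sigma(t) = sigmaEq + A1 exp(-t/theta1) + A2 exp(-t/theta2), t = 0 at
#' the end of the strain ramp; theta1 < theta2 (fast vs slow term).
#'
#' @slot sigmaEq equilibrium stress, MPa.
#' @slot A1,theta1 fast-relaxation amplitude (MPa) and time constant (s).
#' @slot A2,theta2 slow-relaxation amplitude (MPa) and time constant (s).
#' @slot ratioPE peak-to-equilibrium stress ratio (sigmaEq+A1+A2)/sigmaEq.
#' @slot rmse fit residual RMS, MPa.
#' @slot degenerate TRUE when the trace carried no decay (amplitudes ~ 0 and
#'   time constants left at initializer defaults).
#' @slot theta2Unidentifiable TRUE when A2 ~ 0 so theta2 is unconstrained.
#' @export
setClass("RelaxationFit",
  representation(sigmaEq = "numeric", A1 = "numeric", theta1 = "numeric",
                 A2 = "numeric", theta2 = "numeric", ratioPE = "numeric",
                 rmse = "numeric", degenerate = "logical",
                 theta2Unidentifiable = "logical"))

setValidity("RelaxationFit", function(object) {
  if (object@A1 < 0 || object@A2 < 0) return("amplitudes must be >= 0")
  if (!object@degenerate && object@theta1 >= object@theta2)
    return("theta1 must be < theta2")
  if (object@ratioPE < 1 - 1e-9) return("ratioPE must be >= 1")
  TRUE
})

#' SinusoidFit: dynamic (sinusoidal) test fit at one frequency
#'
#' @slot frequencyHz loading frequency.
#' @slot stressAmplitude fitted stress amplitude, MPa.
#' @slot gammaDeg phase shift of stress behind strain, degrees, in (-90, 90).
#' @slot rSquared coefficient of determination of the stress fit.
#' @export
setClass("SinusoidFit",
  representation(frequencyHz = "numeric", stressAmplitude = "numeric",
                 gammaDeg = "numeric", rSquared = "numeric"))

setValidity("SinusoidFit", function(object) {
  if (abs(object@gammaDeg) >= 90) return("gammaDeg must lie in (-90, 90)")
  if (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9)
    return("rSquared outside [0, 1]")
  TRUE
})

#' ModulusResult: linear-region Young's modulus
#'
#' @slot E modulus in MPa (least-squares slope of stress vs strain).
#' @slot fitWindow strain interval used, e.g. c(0.04, 0.08).
#' @slot rSquared fit quality.
#' @slot lowQuality TRUE when rSquared < 0.5 (no meaningful linear response).
#' @export
setClass("ModulusResult",
  representation(E = "numeric", fitWindow = "numeric", rSquared = "numeric",
                 lowQuality = "logical"))

#' DamageMetrics: pre/post overstrain damage parameters
#'
#' D_sigma = 1 - sigma_peak,post / sigma_peak,pre;
#' D_epsilon = 1 - sigma_eq,post / sigma_eq,pre;
#' lambda_epsilon = residual strain, the relative increase in zero-load length.
#'
#' @slot DSigma,DEpsilon normalized stress reductions, in [0, 1].
#' @slot lambdaEpsilon residual strain (>= 0).
#' @slot yieldStrain,yieldStress yield point from the 16% overstrain ramp
#'   (NA when no yield was detected).
#' @slot noYield TRUE when the tangent modulus never dropped below threshold.
#' @export
setClass("DamageMetrics",
  representation(DSigma = "numeric", DEpsilon = "numeric",
                 lambdaEpsilon = "numeric", yieldStrain = "numeric",
                 yieldStress = "numeric", noYield = "logical"))

setValidity("DamageMetrics", function(object) {
  chk <- function(x) is.na(x) || (x >= -1e-9 && x <= 1 + 1e-9)
  if (!chk(object@DSigma) || !chk(object@DEpsilon))
    return("DSigma/DEpsilon outside [0, 1]")
  if (!is.na(object@lambdaEpsilon) && object@lambdaEpsilon < -1e-9)
    return("lambdaEpsilon must be >= 0")
  if (!is.na(object@yieldStrain) &&
      (object@yieldStrain <= 0 || object@yieldStrain >= 0.16))
    return("yieldStrain must lie in (0, 0.16)")
  TRUE
})

#' SegmentationMasks: tissue / fascicle / interfascicular-matrix label volumes
#'
#' @slot tissue,fascicle,ifm logical arrays of identical dimension; fascicle
#'   and ifm are disjoint subsets of tissue with fascicle + ifm = tissue.
#' @slot clusterMeansHU ordered (ascending) cluster mean attenuations.
#' @slot provenance `"clustered"` or `"manualROI"`.
#' @export
setClass("SegmentationMasks",
  representation(tissue = "array", fascicle = "array", ifm = "array",
                 clusterMeansHU = "numeric", provenance = "character"))

setValidity("SegmentationMasks", function(object) {
  d <- dim(object@tissue)
  if (!identical(d, dim(object@fascicle)) || !identical(d, dim(object@ifm)))
    return("mask dimensions differ")
  if (any(object@fascicle & object@ifm)) return("fascicle and ifm overlap")
  if (any((object@fascicle | object@ifm) & !object@tissue))
    return("fascicle/ifm outside tissue")
  if (is.unsorted(object@clusterMeansHU, strictly = TRUE))
    return("cluster means must be strictly increasing")
  if (!object@provenance %in% c("clustered", "manualROI"))
    return("unknown provenance")
  TRUE
})

#' MechGroundTruth: generator truth for one mechanical test
#'
#' Defaults are the healthy-group study conditions: E = 70.10 MPa, fast/slow
#' relaxation (A1, theta1, A2, theta2) = (0.88 MPa, 2.56 s, 0.49 MPa,
#' 137.18 s), sigmaEq chosen so the peak/equilibrium ratio is 1.80, phase
#' shifts (4.13, 3.27, 3.08, 2.95) degrees at (0.1, 0.5, 1, 2) Hz, yield
#' strain 0.12, damage fraction 1 - 22.13/70.10 and residual strain 0.04.
#'
#' @slot E Young's modulus, MPa.
#' @slot sigmaEq equilibrium relaxation stress, MPa.
#' @slot A1,theta1,A2,theta2 Prony amplitudes (MPa) and time constants (s),
#'   theta1 < theta2.
#' @slot gammaDeg named phase shift (degrees) per frequency "0.1","0.5","1","2".
#' @slot yieldStrain strain at yield on the 16% overstrain ramp.
#' @slot yieldStress stress at yield, MPa; NA means "derive from the curve"
#'   (the generator fills it in and returns the completed truth).
#' @slot damageFraction d in [0, 1): post-damage stress is scaled by (1 - d).
#' @slot residualStrain relative increase of the zero-load length after damage.
#' @export
setClass("MechGroundTruth",
  representation(E = "numeric", sigmaEq = "numeric", A1 = "numeric",
                 theta1 = "numeric", A2 = "numeric", theta2 = "numeric",
                 gammaDeg = "numeric", yieldStrain = "numeric",
                 yieldStress = "numeric", damageFraction = "numeric",
                 residualStrain = "numeric"))

setValidity("MechGroundTruth", function(object) {
  if (object@E < 0 || object@A1 < 0 || object@A2 < 0 || object@sigmaEq < 0)
    return("moduli and amplitudes must be >= 0")
  if (object@theta1 >= object@theta2) return("theta1 must be < theta2")
  if (any(object@gammaDeg <= 0 | object@gammaDeg >= 90))
    return("gammaDeg must lie in (0, 90)")
  if (object@damageFraction < 0 || object@damageFraction >= 1)
    return("damageFraction must lie in [0, 1)")
  if (object@residualStrain < 0) return("residualStrain must be >= 0")
  TRUE
})

#' CTGroundTruth: generator truth for a phantom micro-CT time series
#'
#' Regional attenuations default to the study conditions at diffusion
#' equilibrium: 603 HU in fascicles, 795 HU in the interfascicular matrix,
#' noise sd 22 HU, with nanoparticle-like uptake kinetics.
#'
#' @slot fascicleMask,ifmMask,tissueMask,tubeMask logical label volumes;
#'   fascicle and IFM are disjoint and their union is the tissue.
#' @slot muFascicleHU,muIfmHU equilibrium regional attenuations, HU.
#' @slot noiseSdHU additive Gaussian noise sd, HU.
#' @slot PmaxTrue,tauTrueH bulk uptake truth (partition fraction, hours).
#' @slot timepointsH immersion timepoints, hours.
#' @slot baselineHU native soft-tissue attenuation, HU.
#' @slot bathHU bath attenuation implied by PmaxTrue and the regional
#'   amplitudes, HU.
#' @slot rawSlope,rawIntercept linear map from HU to the raw reconstruction
#'   scale the phantom is emitted on (raw = slope * HU + intercept).
#' @export
setClass("CTGroundTruth",
  representation(fascicleMask = "array", ifmMask = "array",
                 tissueMask = "array", tubeMask = "array",
                 muFascicleHU = "numeric", muIfmHU = "numeric",
                 noiseSdHU = "numeric", PmaxTrue = "numeric",
                 tauTrueH = "numeric", timepointsH = "numeric",
                 baselineHU = "numeric", bathHU = "numeric",
                 rawSlope = "numeric", rawIntercept = "numeric"))

setValidity("CTGroundTruth", function(object) {
  if (any(object@fascicleMask & object@ifmMask))
    return("fascicle and IFM masks overlap")
  if (!identical((object@fascicleMask | object@ifmMask), object@tissueMask))
    return("fascicle and IFM masks must partition the tissue")
  if (object@PmaxTrue <= 0 || object@tauTrueH <= 0)
    return("PmaxTrue and tauTrueH must be positive")
  TRUE
})

#' StudyTable: a paired control/damaged cohort with attached data
#'
#' @slot table data.frame keyed by ligament x group with one row per
#'   subsample: `ligamentId`, `sampleId`, `group`, `ligamentType`, `excluded`.
#' @slot mech named list of [TensileTest] by sampleId.
#' @slot diffusion named list of [DiffusionSeries] by "sampleId.agent".
#' @slot groundTruth list of generator truths (empty for real data).
#' @export
setClass("StudyTable",
  representation(table = "data.frame", mech = "list", diffusion = "list",
                 groundTruth = "list"))

setValidity("StudyTable", function(object) {
  tb <- object@table
  need <- c("ligamentId", "sampleId", "group")
  if (!all(need %in% names(tb)))
    return("table must have ligamentId, sampleId, group")
  sp <- split(tb$group, tb$ligamentId)
  ok <- vapply(sp, function(g) setequal(g, c("control", "damaged")), TRUE)
  if ("excluded" %in% names(tb)) {
    excl <- vapply(split(tb$excluded, tb$ligamentId), any, TRUE)
    ok <- ok | excl
  }
  if (!all(ok))
    return(sprintf("incomplete unexcluded pair for ligament %s",
                   names(sp)[!ok][1]))
  TRUE
})
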