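#' @name accessors
#' @title Accessors for ligamentCECT data classes
#' @description Slot accessors; user code should use these rather than `@`.
#' @param object an object of the documented class
#' @param x an object of the documented class
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("sampleGroup", function(object) standardGeneric("sampleGroup"))
#' @rdname accessors
#' @export
setGeneric("traceData", function(object) standardGeneric("traceData"))
#' @rdname accessors
#' @export
setGeneric("segmentMap", function(object) standardGeneric("segmentMap"))
#' @rdname accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("isCalibrated", function(object) standardGeneric("isCalibrated"))
#' @rdname accessors
#' @export
setGeneric("timepoint", function(object) standardGeneric("timepoint"))
#' @rdname accessors
#' @export
setGeneric("agent", function(object) standardGeneric("agent"))
#' @rdname accessors
#' @export
setGeneric("bathHU", function(object) standardGeneric("bathHU"))
#' @rdname accessors
#' @export
setGeneric("timepoints", function(object) standardGeneric("timepoints"))
#' @rdname accessors
#' @export
setGeneric("partition", function(object) standardGeneric("partition"))
#' @rdname accessors
#' @export
setGeneric("studyDesign", function(object) standardGeneric("studyDesign"))
#' @rdname accessors
#' @export
setGeneric("tissueMask", function(object) standardGeneric("tissueMask"))
#' @rdname accessors
#' @export
setGeneric("fascicleMask", function(object) standardGeneric("fascicleMask"))
#' @rdname accessors
#' @export
setGeneric("ifmMask", function(object) standardGeneric("ifmMask"))

setMethod("sampleId", "TensileTest", function(object) object@sampleId)
setMethod("sampleId", "DiffusionSeries", function(object) object@sampleId)
setMethod("sampleGroup", "TensileTest", function(object) object@group)
setMethod("traceData", "TensileTest", function(object) object@trace)
setMethod("segmentMap", "TensileTest", function(object) object@segments)
setMethod("geometry", "TensileTest", function(object) object@geometry)

setMethod("intensities", "CTVolume", function(object) object@intensities)
setMethod("voxelSize", "CTVolume", function(object) object@voxelSizeUm)
setMethod("isCalibrated", "CTVolume", function(object) object@calibrated)
setMethod("timepoint", "CTVolume", function(object) object@timepointH)
setMethod("agent", "CTVolume", function(object) object@agent)
setMethod("agent", "DiffusionSeries", function(object) object@agent)
setMethod("bathHU", "CTVolume", function(object) object@bathHU)

setMethod("timepoints", "DiffusionSeries", function(object) object@timepointsH)
setMethod("partition", "DiffusionSeries", function(object) object@partition)

setMethod("studyDesign", "StudyTable", function(object) object@table)
setMethod("tissueMask", "SegmentationMasks", function(object) object@tissue)
setMethod("fascicleMask", "SegmentationMasks", function(object) object@fascicle)
setMethod("ifmMask", "SegmentationMasks", function(object) object@ifm)
setMethod("tissueMask", "CTGroundTruth", function(object) object@tissueMask)
setMethod("fascicleMask", "CTGroundTruth", function(object) object@fascicleMask)
setMethod("ifmMask", "CTGroundTruth", function(object) object@ifmMask)

setMethod("show", "TensileTest", function(object) {
  cat(sprintf("TensileTest '%s' (%s): %d samples, %.1f s, %d segments\n",
              object@sampleId, object@group, nrow(object@trace),
              diff(range(object@trace$time)), nrow(object@segments)))
  cat(sprintf("  geometry: width %.3g mm, thickness %.3g mm, clamp length %.3g mm\n",
              object@geometry["width"], object@geometry["thickness"],
              object@geometry["clampLength"]))
})

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@intensities)
  tp <- if (is.na(object@timepointH)) "native" else
    sprintf("%g h", object@timepointH)
  cat(sprintf("CTVolume %dx%dx%d @ %.2f um, %s, agent %s, %s\n",
              d[1], d[2], d[3], object@voxelSizeUm, tp, object@agent,
              if (object@calibrated) "calibrated (HU)" else "raw"))
})

setMethod("show", "DiffusionSeries", function(object) {
  cat(sprintf("DiffusionSeries '%s' (%s): %d timepoints, partition %.3g..%.3g\n",
              object@sampleId, object@agent, length(object@timepointsH),
              min(object@partition), max(object@partition)))
})

setMethod("show", "PartitionFit", function(object) {
  cat(sprintf("PartitionFit: Pmax = %.4g, tau = %.4g h (rmse %.3g, n = %d)\n",
              object@Pmax, object@tauH, object@rmse, object@nPoints))
})

setMethod("show", "RelaxationFit", function(object) {
  cat(sprintf(
    "RelaxationFit: sigmaEq %.4g MPa, A1 %.4g (theta1 %.4g s), A2 %.4g (theta2 %.4g s), ratioPE %.3f%s\n",
    object@sigmaEq, object@A1, object@theta1, object@A2, object@theta2,
    object@ratioPE,
    if (object@degenerate) " [degenerate]"
    else if (object@theta2Unidentifiable) " [theta2 unidentifiable]" else ""))
})

setMethod("show", "SinusoidFit", function(object) {
  cat(sprintf("SinusoidFit %g Hz: gamma = %.3f deg, amplitude %.4g MPa (R2 %.4f)\n",
              object@frequencyHz, object@gammaDeg, object@stressAmplitude,
              object@rSquared))
})

setMethod("show", "ModulusResult", function(object) {
  cat(sprintf("ModulusResult: E = %.4g MPa over strain [%g, %g] (R2 %.4f)%s\n",
              object@E, object@fitWindow[1], object@fitWindow[2],
              object@rSquared, if (object@lowQuality) " [low quality]" else ""))
})

setMethod("show", "DamageMetrics", function(object) {
  cat(sprintf(
    "DamageMetrics: Dsigma %.3f, Depsilon %.3f, lambdaEpsilon %.4f, yield (%.4g, %.4g MPa)%s\n",
    object@DSigma, object@DEpsilon, object@lambdaEpsilon,
    object@yieldStrain, object@yieldStress,
    if (object@noYield) " [no yield]" else ""))
})

setMethod("show", "SegmentationMasks", function(object) {
  cat(sprintf(
    "SegmentationMasks (%s): tissue %d, fascicle %d, IFM %d voxels; cluster means %s HU\n",
    object@provenance, sum(object@tissue), sum(object@fascicle),
    sum(object@ifm), paste(round(object@clusterMeansHU, 1), collapse = ", ")))
})

setMethod("show", "StudyTable", function(object) {
  tb <- object@table
  cat(sprintf("StudyTable: %d ligaments, %d subsamples (%d mech traces, %d diffusion series)\n",
              length(unique(tb$ligamentId)), nrow(tb),
              length(object@mech), length(object@diffusion)))
})
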