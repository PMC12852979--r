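## Readers/writers for on-disk artifacts. Traces and diffusion series travel
## as CSV, volumes as multipage TIFF or NIfTI-1 (each with a JSON metadata
## sidecar at <path>.json), reports as CSV + JSON. Unit conversions are
## always logged; nothing is converted silently.

unitFactors <- list(
  time = c(s = 1, ms = 1e-3, min = 60),
  displacement = c(mm = 1, um = 1e-3, m = 1e3),
  force = c(N = 1, mN = 1e-3, kN = 1e3))

sidecarPath <- function(path) paste0(path, ".json")

#' Read a tensile trace from a delimited text table
#'
#' Accepts comma- or tab-delimited files (sniffed from the header line) with
#' a header naming `time`, `displacement`, `force`. Units are configurable
#' and converted to s/mm/N with a logged message per conversion. Geometry
#' and the protocol segment map come from the arguments or, when absent,
#' from the JSON sidecar written by [writeTensileTrace()] — segment
#' boundaries are prescribed protocol times, never inferred from the signal.
#'
#' @param path CSV/TSV file.
#' @param geometry named numeric `width`, `thickness`, `clampLength` (mm).
#' @param segmentMap data.frame `label`, `tStart`, `tEnd` (s).
#' @param units named list of source units, e.g.
#'   `list(time = "s", displacement = "mm", force = "N")`.
#' @param sampleId,group metadata (defaulting to the sidecar when present).
#' @return a validated [TensileTest-class].
#' @export
readTensileTrace <- function(path, geometry = NULL, segmentMap = NULL,
                             units = list(time = "s", displacement = "mm",
                                          force = "N"),
                             sampleId = NULL, group = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tr <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("time", "displacement", "force")
  miss <- setdiff(need, names(tr))
  stopIfNot(length(miss) == 0, "missing column(s): %s",
            paste(miss, collapse = ", "))
  for (col in need) {
    u <- units[[col]]
    f <- unitFactors[[col]][u]
    stopIfNot(!is.na(f), "unknown %s unit '%s'", col, u)
    if (f != 1) {
      logConversion(col, u, names(unitFactors[[col]])[1], unname(f))
      tr[[col]] <- tr[[col]] * f
    }
  }
  bad <- which(diff(tr$time) <= 0)
  stopIfNot(length(bad) == 0,
            "time not strictly increasing at row %d",
            if (length(bad)) bad[1] + 1L else 0L)
  sc <- sidecarPath(path)
  meta <- if (file.exists(sc)) jsonlite::fromJSON(sc) else NULL
  if (is.null(geometry) && !is.null(meta)) geometry <- unlist(meta$geometry)
  if (is.null(segmentMap) && !is.null(meta)) segmentMap <- meta$segments
  if (is.null(sampleId)) sampleId <- if (!is.null(meta)) meta$sampleId else "S1"
  if (is.null(group)) group <- if (!is.null(meta)) meta$group else "control"
  stopIfNot(!is.null(geometry), "geometry required (no sidecar found)")
  stopIfNot(all(geometry[c("width", "thickness", "clampLength")] > 0),
            "geometry values must be positive")
  if (is.null(segmentMap))
    segmentMap <- data.frame(label = character(0), tStart = numeric(0),
                             tEnd = numeric(0))
  obj <- new("TensileTest", trace = tr[, need], segments = segmentMap,
             geometry = c(width = unname(geometry[["width"]]),
                          thickness = unname(geometry[["thickness"]]),
                          clampLength = unname(geometry[["clampLength"]])),
             sampleId = sampleId, group = group)
  validObject(obj)
  obj
}

#' Write a tensile trace (CSV plus JSON sidecar)
#'
#' @param test a [TensileTest-class].
#' @param path output CSV path; the segment map, geometry and metadata go to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeTensileTrace <- function(test, path) {
  utils::write.csv(traceData(test), path, row.names = FALSE)
  jsonlite::write_json(
    list(sampleId = sampleId(test), group = sampleGroup(test),
         geometry = as.list(geometry(test)),
         segments = segmentMap(test),
         units = list(time = "s", displacement = "mm", force = "N")),
    sidecarPath(path), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write a CT volume (multipage TIFF or NIfTI-1, with JSON sidecar)
#'
#' NIfTI output stores float64 voxel values exactly. TIFF output is 32-bit
#' float normalized to `[0, 1]`; the affine rescale (slope/intercept) is
#' recorded in the sidecar and undone on read, so TIFF round-trips are exact
#' to single precision (~1e-4 HU over a 2000 HU range). Slice k of the
#' array is page k of the TIFF.
#'
#' @param volume a [CTVolume-class].
#' @param path output path ending in `.tif(f)`, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  v <- intensities(volume)
  meta <- list(voxelSizeUm = voxelSize(volume),
               calibrated = isCalibrated(volume),
               timepointH = timepoint(volume), agent = agent(volume),
               bathHU = bathHU(volume), waterROI = volume@waterROI,
               airROI = volume@airROI, dim = dim(v))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    lo <- min(v); hi <- max(v)
    slope <- if (hi > lo) hi - lo else 1
    norm <- (v - lo) / slope
    pages <- lapply(seq_len(dim(v)[3]), function(z) norm[, , z])
    suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                                     compression = "none", reduce = FALSE))
    meta$scaleSlope <- slope
    meta$scaleIntercept <- lo
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(RNifti::asNifti(v, datatype = "double"), path)
  } else stop("unsupported volume format: ", path, call. = FALSE)
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a CT volume written by [writeVolume()]
#'
#' @param path `.tif(f)`, `.nii` or `.nii.gz` file with its JSON sidecar.
#' @param metadata optional named list overriding sidecar metadata fields
#'   (`voxelSizeUm`, `timepointH`, `agent`, `bathHU`, `waterROI`, `airROI`,
#'   `calibrated`).
#' @return a [CTVolume-class].
#' @export
readVolume <- function(path, metadata = NULL) {
  sc <- sidecarPath(path)
  meta <- if (file.exists(sc)) jsonlite::fromJSON(sc) else list()
  for (nm in names(metadata)) meta[[nm]] <- metadata[[nm]]
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    v <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
    for (z in seq_along(pages)) v[, , z] <- pages[[z]]
    slope <- if (!is.null(meta$scaleSlope)) meta$scaleSlope else 1
    inter <- if (!is.null(meta$scaleIntercept)) meta$scaleIntercept else 0
    if (slope != 1 || inter != 0) v <- v * slope + inter
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    v <- array(as.numeric(img), dim = dim(img)[1:3])
  } else stop("unsupported volume format: ", path, call. = FALSE)
  pick <- function(nm, dflt) if (!is.null(meta[[nm]])) meta[[nm]] else dflt
  new("CTVolume", intensities = v,
      voxelSizeUm = pick("voxelSizeUm", 16.99),
      calibrated = isTRUE(pick("calibrated", FALSE)),
      waterROI = as.integer(pick("waterROI", integer(0))),
      airROI = as.integer(pick("airROI", integer(0))),
      timepointH = as.numeric(pick("timepointH", NA_real_)),
      agent = pick("agent", "none"), bathHU = as.numeric(pick("bathHU", NA_real_)))
}

#' Read an immersion time series of CT volumes
#'
#' Volumes are returned sorted with the native scan (missing timepoint)
#' first, then by increasing immersion time. All grids must share one shape.
#'
#' @param paths character vector of volume files.
#' @param metadata optional list of per-path metadata overrides (see
#'   [readVolume()]), parallel to `paths`.
#' @return list of [CTVolume-class] objects.
#' @export
readVolumeSeries <- function(paths, metadata = NULL) {
  vols <- lapply(seq_along(paths), function(i)
    readVolume(paths[i], if (is.null(metadata)) NULL else metadata[[i]]))
  shapes <- vapply(vols, function(v) paste(dim(intensities(v)), collapse = "x"), "")
  stopIfNot(length(unique(shapes)) == 1,
            "mismatched grid shapes across timepoints: %s",
            paste(unique(shapes), collapse = " vs "))
  tp <- vapply(vols, timepoint, 0)
  vols[order(!is.na(tp), tp, na.last = FALSE)]
}

#' Write a diffusion series as CSV
#'
#' @param series a [DiffusionSeries-class].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeDiffusionSeries <- function(series, path) {
  utils::write.csv(data.frame(timepoint_h = timepoints(series),
                              partition = partition(series),
                              agent = agent(series),
                              sample_id = sampleId(series)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a diffusion series written by [writeDiffusionSeries()]
#'
#' @param path CSV with columns `timepoint_h`, `partition`, `agent`,
#'   `sample_id`.
#' @return a [DiffusionSeries-class].
#' @export
readDiffusionSeries <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  new("DiffusionSeries", timepointsH = d$timepoint_h,
      partition = d$partition, agent = d$agent[1], sampleId = d$sample_id[1])
}

#' Write the analysis report (long results table + JSON summary)
#'
#' Produces `results.csv` — one row per sample per parameter, in
#' deterministic (parameter, sample, agent) order — and `summary.json` with
#' per-group descriptive statistics and any comparison/correlation tables.
#' Rewriting the same results yields byte-identical files (no timestamps).
#'
#' @param results list with any of: `biomech` (data.frame from
#'   [biomechRow()] rows), `cect` (sampleId/agent/Pmax/tauH), `comparisons`,
#'   `correlations`, `meta`.
#' @param dir output directory (created if needed).
#' @return named character vector of written files, invisibly.
#' @export
writeReport <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- list()
  bm <- results$biomech
  if (!is.null(bm) && nrow(bm)) {
    params <- setdiff(names(bm), c("sampleId", "group"))
    for (pm in params)
      long[[length(long) + 1L]] <- data.frame(
        sampleId = bm$sampleId, group = bm$group, agent = NA_character_,
        parameter = pm, value = bm[[pm]])
  }
  ce <- results$cect
  if (!is.null(ce) && nrow(ce)) {
    for (pm in c("Pmax", "tauH"))
      long[[length(long) + 1L]] <- data.frame(
        sampleId = ce$sampleId, group = ce$group, agent = ce$agent,
        parameter = paste0(pm, ".", ce$agent), value = ce[[pm]])
  }
  long <- if (length(long)) do.call(rbind, long) else
    data.frame(sampleId = character(0), group = character(0),
               agent = character(0), parameter = character(0),
               value = numeric(0))
  long <- long[order(long$parameter, long$sampleId, long$agent,
                     method = "radix"), ]
  csv <- file.path(dir, "results.csv")
  utils::write.csv(long, csv, row.names = FALSE)

  summ <- list()
  if (nrow(long)) {
    agg <- lapply(split(long, long[c("parameter", "group")], drop = TRUE),
                  function(d) {
                    v <- d$value[!is.na(d$value)]
                    list(parameter = d$parameter[1], group = d$group[1],
                         mean = if (length(v)) mean(v) else NA,
                         sd = if (length(v) > 1) sd(v) else NA,
                         n = length(v))
                  })
    summ$groupStats <- unname(agg[order(names(agg))])
  }
  if (!is.null(results$comparisons)) summ$comparisons <- results$comparisons
  if (!is.null(results$correlations)) summ$correlations <- results$correlations
  if (!is.null(results$meta)) summ$meta <- results$meta
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, js, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(results = csv, summary = js))
}
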