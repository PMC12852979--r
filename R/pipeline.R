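#' Build a validated pipeline run configuration
#'
#' One JSON-serializable document holding every protocol constant and
#' analysis option: preload 0.05 MPa, strain levels 6/8/16%, rates 2 and
#' 8%/s, sinusoid frequencies 0.1/0.5/1/2 Hz, per-agent immersion
#' timepoints, the modulus window and yield criterion, the damage effect of
#' the simulated cohort and the run seed.
#'
#' @param seed run seed (all randomness derives from it).
#' @param outDir run directory.
#' @param nLigaments cohort size when simulating.
#' @param simulate generate a synthetic cohort (the only supported input
#'   source in this package; real data enter through the io readers and the
#'   stage functions directly).
#' @param precondBlocks preconditioning blocks per generated trace.
#' @param damageEffect see [defaultDamageEffect()].
#' @param mechNoiseSd,partitionNoiseSd simulation noise levels.
#' @param preloadMPa,modulusWindow,yieldThreshold,yieldWindow analysis
#'   options (see [analyzeTensileTest()]).
#' @param frequenciesHz sinusoid frequencies (must be a subset of the
#'   protocol's 0.1/0.5/1/2 Hz by default).
#' @param phantomDemo also run the volumetric path (phantom generation, HU
#'   calibration, tissue + fascicle segmentation, bulk partition) on one
#'   small phantom and include its regional statistics in the report.
#' @param phantomShape phantom dimensions for the demo stage.
#' @return named list of class `RunConfig`.
#' @export
runConfig <- function(seed = 1, outDir = tempfile("ligcect_run_"),
                      nLigaments = 11, simulate = TRUE, precondBlocks = 5,
                      damageEffect = defaultDamageEffect(),
                      mechNoiseSd = NULL, partitionNoiseSd = 0.03,
                      preloadMPa = 0.05, modulusWindow = c(0.04, 0.08),
                      yieldThreshold = 0.7, yieldWindow = 0.01,
                      frequenciesHz = c(0.1, 0.5, 1, 2),
                      phantomDemo = FALSE, phantomShape = c(64, 64, 24)) {
  stopIfNot(all(frequenciesHz > 0) && preloadMPa > 0 &&
              yieldThreshold > 0 && yieldWindow > 0,
            "protocol constants must be positive")
  cfg <- list(seed = as.integer(seed), outDir = outDir,
              nLigaments = nLigaments, simulate = simulate,
              precondBlocks = precondBlocks, damageEffect = damageEffect,
              mechNoiseSd = mechNoiseSd, partitionNoiseSd = partitionNoiseSd,
              preloadMPa = preloadMPa, modulusWindow = modulusWindow,
              yieldThreshold = yieldThreshold, yieldWindow = yieldWindow,
              frequenciesHz = frequenciesHz, phantomDemo = phantomDemo,
              phantomShape = phantomShape,
              timepoints = list(iodixanol = agentTimepoints("iodixanol"),
                                "Ta2O5-cNP" = agentTimepoints("Ta2O5-cNP")))
  class(cfg) <- c("RunConfig", "list")
  cfg
}

stageTry <- function(stage, sample, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed for sample '%s': %s",
                 stage, sample, conditionMessage(e)), call. = FALSE))
}

#' Paired group comparisons for a cohort's parameter tables
#'
#' Runs the exact Wilcoxon signed-rank test on control-vs-damaged pairs
#' (paired within ligament) for every biomechanical parameter and for Pmax
#' and tau of each agent. Damage-specific parameters exist only in the
#' damaged group and are skipped.
#'
#' @param biomech data.frame of [biomechRow()] rows plus `ligamentId`.
#' @param cect data.frame with `ligamentId`, `group`, `agent`, `Pmax`, `tauH`.
#' @return data.frame with `parameter`, `W`, `pValue`, `n`, `exact`.
#' @export
pairedComparisons <- function(biomech, cect = NULL) {
  out <- list()
  addTest <- function(label, ctrl, dam) {
    keep <- is.finite(ctrl) & is.finite(dam)
    if (sum(keep) < 2 || all(ctrl[keep] == dam[keep])) return()
    w <- suppressWarnings(
      wilcoxonSignedRank(ctrl[keep], dam[keep], parameter = label))
    out[[length(out) + 1L]] <<- data.frame(
      parameter = label, W = w$W, pValue = w$pValue, n = w$n, exact = w$exact)
  }
  wide <- function(d, col) {
    ctrl <- d[d$group == "control", c("ligamentId", col)]
    dam <- d[d$group == "damaged", c("ligamentId", col)]
    m <- merge(ctrl, dam, by = "ligamentId", suffixes = c(".c", ".d"))
    list(c = m[[paste0(col, ".c")]], d = m[[paste0(col, ".d")]])
  }
  params <- setdiff(names(biomech),
                    c("sampleId", "ligamentId", "group", "DSigma", "DEpsilon",
                      "lambdaEpsilon", "yieldStrain", "yieldStress"))
  for (pm in params) {
    v <- wide(biomech, pm)
    addTest(pm, v$c, v$d)
  }
  if (!is.null(cect)) {
    for (ag in unique(cect$agent)) {
      sub <- cect[cect$agent == ag, ]
      for (pm in c("Pmax", "tauH")) {
        v <- wide(sub, pm)
        addTest(paste0(pm, ".", ag), v$c, v$d)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(parameter = character(0), W = numeric(0), pValue = numeric(0),
               n = integer(0), exact = logical(0))
}

#' Run the full simulate -> mechanics -> cect -> segment -> report pipeline
#'
#' Executes every stage on a synthetic paired cohort, writes per-stage
#' outputs under the run directory and a manifest (`manifest.json`) listing
#' every written file with its MD5 checksum, the package version, the seed
#' and the config hash. Reruns with the same config produce identical
#' reports. Any stage failure aborts with the stage name and sample id.
#'
#' @param config a `RunConfig` from [runConfig()].
#' @param writeTraces also write the simulated traces/series to disk
#'   (skipped by default: the report, summary and manifest are always
#'   written).
#' @return invisible list: `cohort`, `biomech`, `cect`, `comparisons`,
#'   `correlations`, `structure` (phantom-demo region stats or NULL),
#'   `files`.
#' @export
runPipeline <- function(config = runConfig(), writeTraces = FALSE) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  stopIfNot(isTRUE(config$simulate), "only simulated cohorts are supported")

  ## -- simulate ----------------------------------------------------------
  cohort <- stageTry("simulate", "cohort", {
    mn <- config$mechNoiseSd
    if (is.null(mn)) genCohort(config$nLigaments, seed = config$seed,
                               damageEffect = config$damageEffect,
                               partitionNoiseSd = config$partitionNoiseSd,
                               precondBlocks = config$precondBlocks)
    else genCohort(config$nLigaments, seed = config$seed,
                   damageEffect = config$damageEffect,
                   mechNoiseSd = mn,
                   partitionNoiseSd = config$partitionNoiseSd,
                   precondBlocks = config$precondBlocks)
  })
  written <- character(0)
  if (writeTraces) {
    simDir <- file.path(config$outDir, "simulate")
    dir.create(simDir, showWarnings = FALSE)
    for (sid in names(cohort@mech)) {
      p <- file.path(simDir, paste0(sid, ".csv"))
      writeTensileTrace(cohort@mech[[sid]], p)
      written <- c(written, p, sidecarPath(p))
    }
    for (key in names(cohort@diffusion)) {
      p <- file.path(simDir, paste0(key, ".csv"))
      writeDiffusionSeries(cohort@diffusion[[key]], p)
      written <- c(written, p)
    }
  }
  design <- studyDesign(cohort)

  ## -- mechanics ---------------------------------------------------------
  biomech <- do.call(rbind, lapply(names(cohort@mech), function(sid)
    stageTry("mechanics", sid, {
      an <- analyzeTensileTest(cohort@mech[[sid]],
                               preloadMPa = config$preloadMPa,
                               modulusWindow = config$modulusWindow,
                               yieldThreshold = config$yieldThreshold,
                               yieldWindow = config$yieldWindow)
      row <- biomechRow(an, sid, sampleGroup(cohort@mech[[sid]]))
      row$ligamentId <- design$ligamentId[design$sampleId == sid]
      row
    })))

  ## -- cect --------------------------------------------------------------
  cect <- do.call(rbind, lapply(names(cohort@diffusion), function(key)
    stageTry("cect", key, {
      ser <- cohort@diffusion[[key]]
      fit <- fitUptake(ser)
      sid <- sampleId(ser)
      data.frame(sampleId = sid,
                 ligamentId = design$ligamentId[design$sampleId == sid],
                 group = design$group[design$sampleId == sid],
                 agent = agent(ser), Pmax = fit@Pmax, tauH = fit@tauH,
                 rmse = fit@rmse)
    })))

  ## -- segment (volumetric demo on one phantom) --------------------------
  structureStats <- NULL
  if (isTRUE(config$phantomDemo)) {
    structureStats <- stageTry("segment", "phantom", {
      ph <- genCTPhantom(shape = config$phantomShape, seed = config$seed)
      late <- huCalibrate(ph$series[[length(ph$series)]])
      masks <- segmentFascicles(late, tissueMask(ph$truth), seed = config$seed)
      st <- roiStats(late, masks)
      st$source <- "phantomDemo"
      st
    })
  }

  ## -- stats + report ----------------------------------------------------
  comparisons <- stageTry("stats", "cohort", pairedComparisons(biomech, cect))
  correlations <- stageTry("stats", "cohort", {
    bm <- biomech[, setdiff(names(biomech), "ligamentId")]
    correlationScreen(bm, cect)
  })
  files <- stageTry("report", "cohort", {
    writeReport(list(biomech = biomech[, setdiff(names(biomech), "ligamentId")],
                     cect = cect, comparisons = comparisons,
                     correlations = correlations,
                     meta = list(seed = config$seed,
                                 nLigaments = config$nLigaments)),
                config$outDir)
  })
  cfgPath <- file.path(config$outDir, "config.json")
  jsonlite::write_json(unclass(config), cfgPath, auto_unbox = TRUE, digits = NA,
                       na = "null")
  allFiles <- c(files, config = cfgPath, written)
  manifest <- list(
    package = "ligamentCECT",
    version = as.character(utils::packageVersion("ligamentCECT")),
    seed = config$seed,
    configHash = unname(tools::md5sum(cfgPath)),
    files = lapply(unname(allFiles), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  manifestPath <- file.path(config$outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(list(cohort = cohort, biomech = biomech, cect = cect,
                 comparisons = comparisons, correlations = correlations,
                 structure = structureStats,
                 files = c(allFiles, manifest = manifestPath)))
}
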