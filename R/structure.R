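#' Cluster one image slice into k attenuation groups
#'
#' k-means over the attenuation values of a slice restricted to the tissue
#' mask; labels are renumbered 1..k by ascending cluster mean, so label
#' ordering is invariant to initialization.
#'
#' @param slice numeric matrix (one z slice).
#' @param tissueMask2d logical matrix restricting the clustering.
#' @param k number of clusters (default 3).
#' @param seed clustering seed.
#' @param allowReduce when TRUE and the slice holds fewer distinct values
#'   than k, reduce k to the number of distinct values (with a warning)
#'   instead of failing; used for degenerate noiseless inputs.
#' @return list with `labels` (integer matrix, 0 outside the mask) and
#'   `centers` (ascending cluster means).
#' @export
clusterSlice <- function(slice, tissueMask2d = NULL, k = 3, seed = 0,
                         allowReduce = FALSE) {
  if (is.null(tissueMask2d)) tissueMask2d <- matrix(TRUE, nrow(slice), ncol(slice))
  vals <- slice[tissueMask2d]
  nd <- length(unique(vals))
  if (nd < k) {
    stopIfNot(allowReduce && nd >= 2,
              "slice has %d distinct values, fewer than k = %d", nd, k)
    warning(sprintf("reducing k from %d to %d distinct values", k, nd))
    k <- nd
  }
  km <- kmeansAssign(vals, k, seed = seed)
  lab <- matrix(0L, nrow(slice), ncol(slice))
  lab[tissueMask2d] <- km$labels
  list(labels = lab, centers = km$centers)
}

#' Segment fascicles from the interfascicular matrix by per-slice clustering
#'
#' Each z slice of the calibrated volume is clustered into k = 3 attenuation
#' groups within the tissue mask; the fascicle mask is the tissue minus the
#' highest-attenuation cluster (cluster 3, the nanoparticle-rich
#' interfascicular matrix), implemented as a set difference on masks. Slice
#' results are stacked into label volumes.
#'
#' @param volume a calibrated [CTVolume-class] (nanoparticle timepoint).
#' @param tissue logical tissue mask (e.g. from [segmentTissue()] or a
#'   ground-truth mask).
#' @param k number of attenuation clusters (default 3).
#' @param seed clustering seed.
#' @param maxDegenerateFrac tolerated fraction of degenerate slices.
#' @return a [SegmentationMasks-class]; `clusterMeansHU` holds the per-slice
#'   cluster means averaged over slices. A warning is issued when the
#'   fascicle mask comes out empty.
#' @export
segmentFascicles <- function(volume, tissue, k = 3, seed = 0,
                             maxDegenerateFrac = 0.1) {
  stopIfNot(isCalibrated(volume), "volume must be HU-calibrated first")
  v <- intensities(volume)
  stopIfNot(identical(dim(v), dim(tissue)), "tissue mask dimension mismatch")
  nz <- dim(v)[3]
  fasc <- array(FALSE, dim(v)); ifm <- array(FALSE, dim(v))
  centerSum <- numeric(k); centerN <- 0L
  degenerate <- integer(0)
  for (z in seq_len(nz)) {
    m2 <- tissue[, , z]
    if (!any(m2)) next
    if (length(unique(v[, , z][m2])) == 1L) {
      ## constant slice: a single attenuation group, assigned to the top
      ## cluster (no fascicle structure below it)
      ifm[, , z] <- m2
      next
    }
    cl <- tryCatch(suppressWarnings(
      clusterSlice(v[, , z], m2, k = k, seed = seed, allowReduce = TRUE)),
      error = function(e) NULL)
    if (is.null(cl)) { degenerate <- c(degenerate, z); next }
    kEff <- length(cl$centers)
    fasc[, , z] <- m2 & cl$labels < kEff   # tissue minus the top cluster
    ifm[, , z] <- m2 & cl$labels == kEff
    if (kEff == k) { centerSum <- centerSum + cl$centers; centerN <- centerN + 1L }
  }
  stopIfNot(length(degenerate) <= maxDegenerateFrac * nz,
            "clustering degenerate on %d/%d slices (slices: %s)",
            length(degenerate), nz,
            paste(head(degenerate, 20), collapse = ", "))
  if (!any(fasc)) warning("empty fascicle mask: no sub-cluster below the top attenuation group")
  centers <- if (centerN > 0) centerSum / centerN else {
    u <- sort(unique(as.vector(v[tissue])))
    u[seq_len(min(length(u), k))]
  }
  if (is.unsorted(centers, strictly = TRUE))
    centers <- centers + seq_along(centers) * 1e-9  # guard exact ties
  new("SegmentationMasks", tissue = tissue, fascicle = fasc, ifm = ifm,
      clusterMeansHU = centers, provenance = "clustered")
}

#' Attenuation statistics per labeled region
#'
#' @param volume a [CTVolume-class].
#' @param masks a [SegmentationMasks-class], a named list of logical arrays,
#'   or a path to a manual-ROI JSON sidecar (see [readManualROIs()]).
#' @return data.frame with `region`, `meanHU`, `sdHU`, `voxelCount`,
#'   `sdUndefined` (TRUE for single-voxel regions).
#' @export
roiStats <- function(volume, masks) {
  v <- intensities(volume)
  if (is(masks, "SegmentationMasks"))
    masks <- list(tissue = tissueMask(masks), fascicle = fascicleMask(masks),
                  ifm = ifmMask(masks))
  if (is.character(masks)) masks <- readManualROIs(masks, dim(v))
  stopIfNot(length(masks) > 0 && !is.null(names(masks)),
            "masks must be a named list of logical arrays")
  rows <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    n <- sum(m)
    stopIfNot(n > 0, "region '%s' is empty", nm)
    data.frame(region = nm, meanHU = mean(v[m]),
               sdHU = if (n > 1) sd(v[m]) else NA_real_,
               voxelCount = n, sdUndefined = n == 1)
  })
  do.call(rbind, rows)
}

#' Read manual regions of interest from a JSON sidecar
#'
#' Reproducible stand-in for manually selected ROIs: a JSON list of entries
#' with `label`, `slices` (1-based inclusive z range) and either `rect`
#' (`[y1, y2, x1, x2]`) or `polygon` (list of `[y, x]` vertices, tested by
#' ray casting).
#'
#' @param path JSON file path.
#' @param dims volume dimensions `c(ny, nx, nz)`.
#' @return named list of logical arrays.
#' @export
readManualROIs <- function(path, dims) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- list()
  for (e in spec) {
    m <- array(FALSE, dims)
    zr <- unlist(e$slices)
    zs <- seq(max(1, zr[1]), min(dims[3], zr[2]))
    if (!is.null(e$rect)) {
      r <- unlist(e$rect)
      m[r[1]:r[2], r[3]:r[4], zs] <- TRUE
    } else if (!is.null(e$polygon)) {
      py <- vapply(e$polygon, function(p) p[[1]], 0)
      px <- vapply(e$polygon, function(p) p[[2]], 0)
      Y <- matrix(seq_len(dims[1]), dims[1], dims[2])
      X <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
      inside <- pointInPolygon(as.vector(Y), as.vector(X), py, px)
      m2 <- matrix(inside, dims[1], dims[2])
      for (z in zs) m[, , z] <- m2
    }
    prev <- out[[e$label]]
    out[[e$label]] <- if (is.null(prev)) m else (prev | m)
  }
  out
}

## Even-odd ray casting point-in-polygon test.
pointInPolygon <- function(y, x, py, px) {
  n <- length(py)
  inside <- rep(FALSE, length(y))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Regional attenuation contrast between IFM and fascicles
#'
#' @param statsFascicle,statsIfm one-row data.frames (or rows of
#'   [roiStats()] output) with a `meanHU` column.
#' @return list with `differenceHU` (IFM - fascicle) and `ratio`
#'   (IFM / fascicle).
#' @export
regionContrast <- function(statsFascicle, statsIfm) {
  mf <- statsFascicle$meanHU; mi <- statsIfm$meanHU
  stopIfNot(length(mf) == 1 && length(mi) == 1, "need one row per region")
  stopIfNot(mf > 0, "fascicle mean attenuation must be positive for a ratio")
  list(differenceHU = mi - mf, ratio = mi / mf)
}

#' Dice overlap coefficient between two masks
#'
#' `2 |A . B| / (|A| + |B|)`; the standard segmentation-quality metric
#' against ground truth.
#'
#' @param a,b logical arrays of identical dimension.
#' @return Dice coefficient in `[0, 1]`.
#' @export
diceCoefficient <- function(a, b) {
  stopIfNot(identical(dim(a), dim(b)), "mask dimensions differ")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Average slices in groups for visualization
#'
#' Mirrors the presentation convention of averaging ~10 consecutive slices
#' (~170 um) to reduce noise in figures; statistics always use raw voxels.
#'
#' @param volume a [CTVolume-class].
#' @param every number of consecutive slices per average.
#' @return 3D array with `floor(nz / every)` averaged slices.
#' @export
averageSlices <- function(volume, every = 10) {
  v <- intensities(volume)
  nz <- dim(v)[3] %/% every
  stopIfNot(nz >= 1, "volume has fewer than %d slices", every)
  out <- array(0, c(dim(v)[1], dim(v)[2], nz))
  for (i in seq_len(nz))
    out[, , i] <- apply(v[, , ((i - 1) * every + 1):(i * every), drop = FALSE],
                        c(1, 2), mean)
  out
}
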