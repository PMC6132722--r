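# NIfTI-1 volume I/O with a JSON sidecar owning the quantitative metadata
# (VENC, timing, units, grid origin).  The sidecar is authoritative: NIfTI
# pixdim is written as a courtesy for external viewers but never trusted on
# read, avoiding scanner-private dialect issues.

.SIDEcar_SCHEMA <- 1L

.writeNiftiVolume <- function(arr, path, spacing, dtms = 1) {
  img <- RNifti::asNifti(arr)
  pd <- RNifti::pixdim(img)
  pd[seq_len(min(3L, length(pd)))] <- spacing[seq_len(min(3L, length(pd)))]
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a velocity field as NIfTI volumes plus JSON sidecar
#'
#' `writeVelocity()` stores one 4D scalar NIfTI volume per velocity
#' component (`<prefix>_vx/vy/vz.nii.gz`) plus `<prefix>_meta.json` holding
#' VENC, time stamps, spacing, origin, cycle period, units and a schema
#' version. `readVelocity()` reverses this, applying unit conversion to the
#' internal cm/s convention from the declared source unit, and validates the
#' result (consistent grids, finite values, monotone timing).
#'
#' @param field a [VelocityField4D-class]
#' @param prefix path prefix for the output files
#' @return `writeVelocity()`: invisibly, the sidecar path.
#' @export
writeVelocity <- function(field, prefix) {
  stopifnot(is(field, "VelocityField4D"))
  comps <- c("vx", "vy", "vz")
  for (i in 1:3) {
    .writeNiftiVolume(field@velocity[, , , , i, drop = TRUE],
                      sprintf("%s_%s.nii.gz", prefix, comps[i]), field@spacing)
  }
  meta <- list(schema_version = .SIDEcar_SCHEMA,
               velocity_units = "cm/s",
               venc_cms = field@venc, spacing_mm = field@spacing,
               times_ms = field@times, period_ms = field@period,
               origin_mm = field@origin, provenance = field@provenance)
  metaPath <- sprintf("%s_meta.json", prefix)
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(metaPath)
}

#' @rdname writeVelocity
#' @param paths character length-3: the x/y/z component volume files
#' @param metaPath the JSON sidecar path
#' @return `readVelocity()`: a [VelocityField4D-class]
#' @export
readVelocity <- function(paths, metaPath) {
  if (length(paths) != 3L) stopf("three component volumes required")
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  if (is.null(meta$venc_cms)) {
    stopf("sidecar %s lacks the mandatory VENC entry", metaPath)
  }
  venc <- if (is.na(meta$venc_cms %||% NA)) NA_real_ else as.numeric(meta$venc_cms)
  times <- as.numeric(meta$times_ms)
  if (is.null(times) || any(diff(times) <= 0)) {
    stopf("sidecar %s has missing or non-monotone time stamps", metaPath)
  }
  unitFactor <- switch(meta$velocity_units %||% "cm/s",
                       "cm/s" = 1, "m/s" = 100, "mm/s" = 0.1,
                       stopf("unknown velocity unit '%s' in %s",
                             meta$velocity_units, metaPath))
  vols <- lapply(paths, function(p) {
    v <- as.array(RNifti::readNifti(p))
    if (length(dim(v)) == 3L) v <- array(v, dim = c(dim(v), 1L))
    if (!all(is.finite(v))) stopf("volume %s contains NaN/Inf voxels", p)
    v
  })
  d1 <- dim(vols[[1]])
  for (i in 2:3) {
    if (!identical(dim(vols[[i]]), d1)) {
      stopf("component volume %s grid %s does not match %s",
            paths[i], paste(dim(vols[[i]]), collapse = "x"),
            paste(d1, collapse = "x"))
    }
  }
  if (length(times) != d1[4]) {
    stopf("sidecar lists %d phases but %s holds %d", length(times),
          paths[1], d1[4])
  }
  vel <- array(0, dim = c(d1, 3))
  for (i in 1:3) vel[, , , , i] <- vols[[i]] * unitFactor
  newVelocityField(vel, spacing = as.numeric(meta$spacing_mm), times = times,
                   venc = venc,
                   period = as.numeric(meta$period_ms %||% NA_real_),
                   origin = as.numeric(meta$origin_mm %||% c(0, 0, 0)),
                   provenance = as.character(meta$provenance %||% ""))
}

#' Write / read a segmentation series
#'
#' Stores the per-phase label volume as one 4D integer NIfTI plus a JSON
#' sidecar with timing and grid metadata (same conventions as
#' [writeVelocity()]).
#'
#' @param seg a [SegmentationSeries-class]
#' @param prefix path prefix
#' @export
writeSegmentation <- function(seg, prefix) {
  stopifnot(is(seg, "SegmentationSeries"))
  .writeNiftiVolume(seg@labels, sprintf("%s_mask.nii.gz", prefix), seg@spacing)
  meta <- list(schema_version = .SIDEcar_SCHEMA, spacing_mm = seg@spacing,
               times_ms = seg@times, period_ms = seg@period,
               origin_mm = seg@origin,
               labels = list(background = 0, lv = LV_LABEL, rv = RV_LABEL))
  metaPath <- sprintf("%s_mask_meta.json", prefix)
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(metaPath)
}

#' @rdname writeSegmentation
#' @param path the mask volume file
#' @param metaPath the JSON sidecar
#' @export
readSegmentation <- function(path, metaPath) {
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  lab <- RNifti::readNifti(path)
  lab <- array(as.vector(lab), dim = if (length(dim(lab)) == 3L)
    c(dim(lab), 1L) else dim(lab))
  if (!all(is.finite(lab))) stopf("mask %s contains NaN/Inf voxels", path)
  newSegmentation(lab, spacing = as.numeric(meta$spacing_mm),
                  times = as.numeric(meta$times_ms),
                  period = as.numeric(meta$period_ms %||% NA_real_),
                  origin = as.numeric(meta$origin_mm %||% c(0, 0, 0)))
}

#' Write / read great-vessel flow curves
#'
#' CSV with columns `time_ms`, `pa_flow_ml_per_s`, `ao_flow_ml_per_s`
#' (forward positive).
#'
#' @param flows a [FlowCurveSet-class]
#' @param path CSV path
#' @export
writeFlowCurves <- function(flows, path) {
  stopifnot(is(flows, "FlowCurveSet"))
  utils::write.csv(data.frame(time_ms = flows@times,
                              pa_flow_ml_per_s = flows@pa,
                              ao_flow_ml_per_s = flows@ao),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFlowCurves
#' @param period cycle duration ms (default: inferred from the time stamps)
#' @export
readFlowCurves <- function(path, period = NA_real_) {
  df <- utils::read.csv(path)
  need <- c("time_ms", "pa_flow_ml_per_s", "ao_flow_ml_per_s")
  if (!all(need %in% names(df))) {
    stopf("%s must have columns %s", path, paste(need, collapse = ", "))
  }
  if (!all(is.finite(as.matrix(df[need])))) {
    stopf("%s contains non-finite values", path)
  }
  newFlowCurves(df$time_ms, df$pa_flow_ml_per_s, df$ao_flow_ml_per_s,
                period = period)
}

#' Transfer a cine segmentation onto a 4D-flow grid
#'
#' Resamples a per-phase label series drawn on its own (typically finer,
#' shorter-cycle) cine grid onto the grid and time base of a 4D-flow
#' velocity field. Spatial resampling is nearest-neighbour (labels are
#' categorical); temporal assignment picks, for each 4D phase, the cine
#' phase nearest in fraction-of-RR units, which makes the mapping monotone
#' in time and heart-rate independent. The two grids are assumed to share a
#' world coordinate frame (origins in mm).
#'
#' @param cineSeg a [SegmentationSeries-class] on the cine grid
#' @param target a [VelocityField4D-class] (or
#'   [SegmentationSeries-class]) defining the output grid and timing
#' @return a [SegmentationSeries-class] on the target grid
#' @export
transferSegmentation <- function(cineSeg, target) {
  stopifnot(is(cineSeg, "SegmentationSeries"))
  tDim <- gridDim(target); tSp <- voxelSpacing(target)
  tOr <- gridOrigin(target); tTimes <- timeStamps(target)
  cDim <- gridDim(cineSeg); cSp <- voxelSpacing(cineSeg)
  cOr <- gridOrigin(cineSeg)

  # nearest cine voxel for every target voxel (world frame shared)
  idxAxis <- function(n, sp, or, cn, csp, cor) {
    world <- axisCoords(n, sp, or)
    i <- round((world - cor) / csp) + 1L
    i[i < 1L | i > cn] <- NA_integer_
    i
  }
  ix <- idxAxis(tDim[1], tSp[1], tOr[1], cDim[1], cSp[1], cOr[1])
  iy <- idxAxis(tDim[2], tSp[2], tOr[2], cDim[2], cSp[2], cOr[2])
  iz <- idxAxis(tDim[3], tSp[3], tOr[3], cDim[3], cSp[3], cOr[3])
  if (all(is.na(ix)) || all(is.na(iy)) || all(is.na(iz))) {
    stopf("cine and 4D fields of view do not overlap")
  }

  # nearest cine phase in fraction-of-RR units
  tFrac <- tTimes / cyclePeriod(target)
  cFrac <- cineSeg@times / cyclePeriod(cineSeg)
  phaseMap <- vapply(tFrac, function(f) which.min(abs(cFrac - f)), 0L)

  out <- array(0L, dim = c(tDim, length(tTimes)))
  IX <- ix[rep(seq_len(tDim[1]), times = tDim[2] * tDim[3])]
  IY <- iy[rep(rep(seq_len(tDim[2]), each = tDim[1]), times = tDim[3])]
  IZ <- iz[rep(seq_len(tDim[3]), each = tDim[1] * tDim[2])]
  valid <- !(is.na(IX) | is.na(IY) | is.na(IZ))
  lin <- linearIndex3(IX[valid], IY[valid], IZ[valid], cDim)
  nC3 <- prod(cDim)
  for (ph in seq_along(tTimes)) {
    vol <- integer(prod(tDim))
    vol[valid] <- cineSeg@labels[lin + (phaseMap[ph] - 1L) * nC3]
    out[, , , ph] <- vol
  }
  newSegmentation(out, spacing = tSp, times = tTimes,
                  period = cyclePeriod(target), origin = tOr)
}

.RESULT_COLUMNS <- c("subject_id", "group", "ventricle", "phase_type",
                     "peak_ke_mJ", "ke_per_sv_mJ_per_ml", "ke_per_co",
                     "ke_per_bsa", "q_per_ke", "q_per_ke_per_bsa",
                     "sd_ratio", "restrictive", "pr_ke_fraction")

#' Write per-subject result tables
#'
#' Writes the tidy results table (one row per subject x ventricle x
#' phase-type, all five indexation schemes as columns) and, optionally, a
#' cohort summary with mean and SD rows per group.
#'
#' @param results data.frame as produced by [analyzeCohort()] (columns
#'   `subject_id`, `group`, `ventricle`, `phase_type`, the indexed-KE
#'   columns, `sd_ratio`, `restrictive`, `pr_ke_fraction`)
#' @param path output CSV
#' @param summaryPath optional CSV for per-group mean/SD summary rows
#' @export
writeResults <- function(results, path, summaryPath = NULL) {
  if (nrow(results) == 0L) {
    results <- results[, intersect(.RESULT_COLUMNS, names(results)), drop = FALSE]
    empty <- as.data.frame(setNames(rep(list(logical(0)), length(.RESULT_COLUMNS)),
                                    .RESULT_COLUMNS))
    utils::write.csv(empty, path, row.names = FALSE)
    return(invisible(path))
  }
  missing <- setdiff(.RESULT_COLUMNS, names(results))
  if (length(missing)) stopf("results lack columns: %s",
                             paste(missing, collapse = ", "))
  utils::write.csv(results[, .RESULT_COLUMNS], path, row.names = FALSE)
  if (!is.null(summaryPath)) {
    num <- setdiff(.RESULT_COLUMNS,
                   c("subject_id", "group", "ventricle", "phase_type",
                     "restrictive"))
    agg <- do.call(rbind, lapply(split(results, list(results$group,
                                                     results$ventricle,
                                                     results$phase_type),
                                       drop = TRUE), function(d) {
      data.frame(group = d$group[1], ventricle = d$ventricle[1],
                 phase_type = d$phase_type[1], n = nrow(d),
                 t(vapply(num, function(cn) c(mean = mean(d[[cn]], na.rm = TRUE),
                                              sd = stats::sd(d[[cn]], na.rm = TRUE)),
                          numeric(2))))
    }))
    utils::write.csv(agg, summaryPath, row.names = FALSE)
  }
  invisible(path)
}
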