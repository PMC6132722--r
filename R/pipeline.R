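# Subject- and cohort-level orchestration: from a phantom bundle (or any
# equivalently structured set of inputs) to the per-subject result record
# and the tidy cohort table.

#' Analyze one subject
#'
#' Runs the full single-subject pipeline: optional phase preprocessing
#' (anti-aliasing then background-plane subtraction), planimetric
#' volumetry, voxel KE, per-ventricle KE curves with peak detection, all
#' indexation schemes, the systolic/diastolic ratio, regurgitation
#' measures, restrictive-physiology classification and (optionally) the
#' LCS-based PR partition at the RV diastolic KE peak.
#'
#' @param field a [VelocityField4D-class]
#' @param seg matching [SegmentationSeries-class]
#' @param flows a [FlowCurveSet-class]
#' @param subject list with `id`, `group`, `bsa` (m^2), `hr` (bpm)
#' @param preprocess `"none"` or `"full"` (unwrap with [unwrapVelocity()]
#'   then fit/subtract the background plane on an auto-derived static mask)
#' @param lcs logical; compute the PR/non-PR partition (requires `markers`)
#' @param markers orifice markers as in [partitionRV()]:
#'   `list(pa = list(center, radius), tv = list(center, radius))`
#' @param density blood density g/cm^3
#' @param ridgePct FTLE ridge percentile for the partition
#' @return list of class `subjectResult`; see [analyzeCohort()] for the
#'   tabular flattening
#' @export
analyzeSubject <- function(field, seg, flows, subject,
                           preprocess = c("none", "full"), lcs = FALSE,
                           markers = NULL, density = BLOOD_DENSITY,
                           ridgePct = 80) {
  preprocess <- match.arg(preprocess)
  if (preprocess == "full") {
    field <- unwrapVelocity(field)
    plane <- fitBackground(field)
    field <- applyBackground(field, plane)
  }
  vols <- computeVolumeCurve(seg)
  voxKe <- voxelKE(field, density)
  curves <- keCurve(voxKe, seg,
                    esPhase = c(lv = vols$lv$esPhase, rv = vols$rv$esPhase))
  regPa <- computeRegurgitation(flows, vessel = "pa")
  regAo <- computeRegurgitation(flows, vessel = "ao")
  restrictive <- classifyRestrictive(flows)

  indexed <- list()
  for (vent in c("lv", "rv")) {
    qNet <- if (vent == "lv") regAo$effectiveSv else regPa$effectiveSv
    for (phaseType in c("systole", "diastole")) {
      pk <- if (phaseType == "systole") curves[[vent]]$systolicPeak else
        curves[[vent]]$diastolicPeak
      indexed[[paste(vent, phaseType, sep = ".")]] <- indexKE(
        pk, planimetricSv = vols[[vent]]$sv, qNet = qNet,
        aorticNet = regAo$effectiveSv, bsa = subject$bsa,
        heartRate = subject$hr)
    }
  }

  partition <- NULL
  if (lcs) {
    if (is.null(markers)) stopf("LCS partition requires orifice markers")
    peak <- curves$rv$diastolicPhase
    fte <- ftleAtPhase(field, seg, phase = peak, esPhase = curves$rv$esPhase)
    nvox <- prod(gridDim(seg))
    rvMask <- seg@labels[, , , peak] == RV_LABEL
    partition <- partitionRV(fte, rvMask, markers$pa, markers$tv,
                             array(voxKe[(peak - 1) * nvox + seq_len(nvox)],
                                   dim = gridDim(seg)),
                             ridgePct = ridgePct)
  }

  structure(list(subject = subject, volumes = vols, keCurves = curves,
                 indexed = indexed,
                 sdRatio = c(lv = sdRatio(curves$lv), rv = sdRatio(curves$rv)),
                 regurgitation = regPa, aortic = regAo,
                 restrictive = as.logical(restrictive),
                 partition = partition),
            class = "subjectResult")
}

#' @export
print.subjectResult <- function(x, ...) {
  cat(sprintf("Subject %s (%s):\n", x$subject$id %||% "?", x$subject$group %||% "?"))
  for (vent in c("lv", "rv")) {
    cv <- x$keCurves[[vent]]
    cat(sprintf("  %s peak KE %.2f mJ (systole) / %.2f mJ (diastole), S/D %.2f\n",
                toupper(vent), cv$systolicPeak, cv$diastolicPeak,
                x$sdRatio[vent]))
  }
  cat(sprintf("  PR %.1f ml (%.0f%%), restrictive: %s\n",
              x$regurgitation$reverseVolume,
              x$regurgitation$regurgFractionPct %||% NA, x$restrictive))
  if (!is.null(x$partition)) print(x$partition)
  invisible(x)
}

#' Analyze a phantom bundle
#'
#' Convenience wrapper running [analyzeSubject()] on the outputs of
#' [generateVentriclePhantom()] / [generateCohort()], using the bundle's
#' orifice markers when the LCS partition is requested.
#'
#' @param bundle a `phantomBundle`
#' @param ... passed to [analyzeSubject()]
#' @export
analyzeBundle <- function(bundle, ...) {
  stopifnot(inherits(bundle, "phantomBundle"))
  subject <- bundle$subject %||% list(id = "phantom", group = "phantom",
                                      bsa = 1.9,
                                      hr = 60000 / bundle$spec@rr)
  analyzeSubject(bundle$velocity, bundle$segmentation, bundle$flows, subject,
                 markers = bundle$truth$markers, ...)
}

#' Flatten subject results into the tidy cohort table
#'
#' One row per subject x ventricle x phase-type with all indexation
#' columns, ready for [writeResults()] and the cohort statistics.
#'
#' @param results list of `subjectResult`s
#' @return data.frame with the standard result columns
#' @export
cohortTable <- function(results) {
  rows <- list()
  for (res in results) {
    for (vent in c("lv", "rv")) {
      for (phaseType in c("systole", "diastole")) {
        ix <- res$indexed[[paste(vent, phaseType, sep = ".")]]
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = res$subject$id, group = res$subject$group,
          ventricle = toupper(vent), phase_type = phaseType,
          peak_ke_mJ = ix$peakKe, ke_per_sv_mJ_per_ml = ix$kePerSv,
          ke_per_co = ix$kePerCo, ke_per_bsa = ix$kePerBsa,
          q_per_ke = ix$qPerKe, q_per_ke_per_bsa = ix$qPerKeBsa,
          sd_ratio = unname(res$sdRatio[vent]),
          restrictive = isTRUE(res$restrictive),
          pr_ke_fraction = if (vent == "rv" && !is.null(res$partition))
            res$partition$fractionPct else NA_real_)
      }
    }
  }
  do.call(rbind, rows)
}

#' Analyze a whole cohort of phantom bundles
#'
#' @param bundles list of `phantomBundle`s from [generateCohort()]
#' @param ... passed to [analyzeBundle()]
#' @return list with `results` (per-subject `subjectResult`s) and `table`
#'   (tidy data.frame from [cohortTable()])
#' @export
analyzeCohort <- function(bundles, ...) {
  results <- lapply(bundles, analyzeBundle, ...)
  list(results = results, table = cohortTable(results))
}

#' Cohort-level statistics
#'
#' Computes the standard group comparisons on a cohort table: patient vs
#' control peak KE per ventricle and phase type (Student t), S/D-ratio
#' comparison, and — within patients — the agreement (Cohen's kappa)
#' between the S/D-ratio dichotomy (ratio > 1) and restrictive physiology.
#'
#' @param tab cohort table from [analyzeCohort()]
#' @return list of statistic records
#' @export
cohortStats <- function(tab) {
  pick <- function(vent, phase, col, grp) {
    tab[[col]][tab$ventricle == vent & tab$phase_type == phase &
                 tab$group == grp]
  }
  out <- list()
  for (vent in c("LV", "RV")) {
    for (phase in c("systole", "diastole")) {
      key <- paste0(tolower(vent), ".", phase)
      out[[paste0("peakKe.", key)]] <- compareGroups(
        pick(vent, phase, "peak_ke_mJ", "patient"),
        pick(vent, phase, "peak_ke_mJ", "control"))
    }
    out[[paste0("sdRatio.", tolower(vent))]] <- compareGroups(
      pick(vent, "systole", "sd_ratio", "patient"),
      pick(vent, "systole", "sd_ratio", "control"))
  }
  pat <- tab[tab$group == "patient" & tab$ventricle == "RV" &
               tab$phase_type == "systole", ]
  if (nrow(pat)) {
    ratioHigh <- factor(pat$sd_ratio > 1, levels = c(FALSE, TRUE))
    restr <- factor(pat$restrictive, levels = c(FALSE, TRUE))
    tb <- table(ratioHigh, restr)
    out$kappaTable <- tb
    out$kappa <- cohensKappa(tb)
  }
  out
}
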