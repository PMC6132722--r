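# Voxel-wise and ventricular kinetic energy.
#
# KE of a voxel is m v^2 / 2 with m the voxel blood mass (density times
# voxel volume; blood density 1.05 g/cm^3) and v the magnitude of the
# three-directional velocity vector.  Unit bookkeeping, with velocity in
# cm/s and voxel volume in mm^3:
#   KE[mJ] = 0.5 * rho[g/cm^3] * V[mm^3] * v[cm/s]^2 * 1e-7
# e.g. one 27 mm^3 voxel at 100 cm/s and rho 1.05: 0.014175 mJ = 1.4175e-5 J.

#' Default blood density, g/cm^3
#' @export
BLOOD_DENSITY <- 1.05

#' Voxel-wise kinetic energy
#'
#' @param field a [VelocityField4D-class]
#' @param density blood density in g/cm^3
#' @return 4D array (x, y, z, phase) of per-voxel KE in mJ, with the voxel
#'   volume and density attached as attributes
#' @export
voxelKE <- function(field, density = BLOOD_DENSITY) {
  stopifnot(is(field, "VelocityField4D"))
  v2 <- field@velocity[, , , , 1]^2 + field@velocity[, , , , 2]^2 +
    field@velocity[, , , , 3]^2
  ke <- 0.5 * density * voxelVolume(field) * v2 * 1e-7
  attr(ke, "voxelVolume") <- voxelVolume(field)
  attr(ke, "density") <- density
  ke
}

.peakIn <- function(values, phases) {
  if (!length(phases)) return(list(value = NA_real_, phase = NA_integer_))
  i <- phases[which.max(values[phases])]  # which.max: earliest phase on ties
  list(value = values[i], phase = i)
}

#' Ventricular kinetic-energy curve with systolic/diastolic peaks
#'
#' Sums voxel KE within each ventricle label at every phase, then finds the
#' systolic peak (highest KE in phases `[1, esPhase]`) and diastolic peak
#' (highest KE in `(esPhase, end]`), ties broken by the earliest phase.
#' Peaks are detected on the raw phase samples; temporal interpolation is
#' only used for cohort display curves ([normalizeTime()]).
#'
#' @param voxKe voxel-KE array from [voxelKE()]
#' @param seg a [SegmentationSeries-class] on the same grid
#' @param esPhase per-ventricle end-systolic phase index; either a single
#'   index used for both ventricles, a named vector `c(lv=, rv=)`, or
#'   `NULL` to derive it from the segmentation volume curve
#' @return list per ventricle (`lv`, `rv`): `ke` (mJ per phase),
#'   `systolicPeak`, `systolicPhase`, `diastolicPeak`, `diastolicPhase`,
#'   `esPhase`; plus `times`
#' @export
keCurve <- function(voxKe, seg, esPhase = NULL) {
  stopifnot(is(seg, "SegmentationSeries"))
  d <- dim(voxKe)
  if (!identical(d, dim(seg@labels))) stopf("KE and segmentation grids differ")
  nt <- d[4]
  if (is.null(esPhase)) {
    vc <- computeVolumeCurve(seg)
    esPhase <- c(lv = vc$lv$esPhase, rv = vc$rv$esPhase)
  }
  if (length(esPhase) == 1L && is.null(names(esPhase))) {
    esPhase <- c(lv = esPhase, rv = esPhase)
  }
  out <- list(times = timeStamps(seg))
  nvox <- prod(d[1:3])
  for (vent in c("lv", "rv")) {
    lab <- if (vent == "lv") LV_LABEL else RV_LABEL
    ke <- vapply(seq_len(nt), function(ph) {
      m <- seg@labels[, , , ph] == lab
      if (!any(m)) stopf("%s label absent at phase %d", toupper(vent), ph)
      sum(voxKe[(ph - 1) * nvox + which(m)])
    }, numeric(1))
    es <- unname(esPhase[vent])
    sys <- .peakIn(ke, seq_len(es))
    dia <- .peakIn(ke, seq_len(nt)[seq_len(nt) > es])
    out[[vent]] <- list(ke = ke, systolicPeak = sys$value,
                        systolicPhase = sys$phase,
                        diastolicPeak = dia$value,
                        diastolicPhase = dia$phase, esPhase = es)
  }
  out
}

#' Systolic/diastolic peak-KE ratio
#'
#' @param curve one ventricle's entry from [keCurve()] (a list with
#'   `systolicPeak` and `diastolicPeak`), or two numbers
#' @param diastolicPeak when `curve` is given as a bare systolic peak
#' @return systolic peak / diastolic peak; `NA` when the diastolic peak is
#'   not positive
#' @export
sdRatio <- function(curve, diastolicPeak = NULL) {
  if (is.list(curve)) {
    s <- curve$systolicPeak; d <- curve$diastolicPeak
  } else {
    s <- curve; d <- diastolicPeak
  }
  if (is.na(d) || d <= 0) return(NA_real_)
  s / d
}

#' Indexed peak kinetic energy
#'
#' Computes the five indexation schemes for one ventricle and phase type:
#' absolute peak KE (mJ), KE per planimetric stroke volume (mJ/ml), KE per
#' systemic cardiac output, KE per body surface area (mJ/m^2), and the two
#' inverted flow indexations Q/KE and Q/KE/BSA, where Q is the relevant
#' vessel's net forward volume per cycle (aortic for the LV, pulmonary for
#' the RV). A KE-per-net-SV variant is also reported for the diastolic
#' PR-excluded comparison. Non-positive denominators yield `NA` (flagged
#' undefined), never zero.
#'
#' @param peakKe peak KE, mJ
#' @param planimetricSv planimetric stroke volume (EDV - ESV), ml
#' @param qNet net forward volume of the relevant vessel per cycle, ml
#' @param aorticNet net aortic volume per cycle, ml (systemic CO basis)
#' @param bsa body surface area, m^2
#' @param heartRate bpm
#' @return named list of the indexed values
#' @export
indexKE <- function(peakKe, planimetricSv, qNet, aorticNet, bsa, heartRate) {
  safeDiv <- function(num, den) {
    if (is.na(den) || den <= 0) NA_real_ else num / den
  }
  co <- if (is.na(aorticNet) || is.na(heartRate)) NA_real_ else
    aorticNet * heartRate / 1000  # l/min
  list(
    peakKe = peakKe,
    kePerSv = safeDiv(peakKe, planimetricSv),
    kePerNetSv = safeDiv(peakKe, qNet),
    kePerCo = safeDiv(peakKe, co),
    kePerBsa = safeDiv(peakKe, bsa),
    qPerKe = safeDiv(qNet, peakKe),
    qPerKeBsa = safeDiv(safeDiv(qNet, peakKe), bsa),
    systemicCo = co
  )
}

#' Time-normalized cohort curves
#'
#' Linearly interpolates each subject's KE (or KE/SV) curve onto `nPoints`
#' uniformly spaced fractions of its own cardiac cycle, so curves from
#' subjects with different heart rates can be averaged. The first point
#' corresponds to phase 0 and curve endpoints are preserved. Returns the
#' per-point cohort mean and SD.
#'
#' @param curves list of lists with `times` (ms) and `values`
#' @param nPoints number of uniform samples (default 40)
#' @return list with `fraction`, `matrix` (subjects x points), `mean`, `sd`
#' @export
normalizeTime <- function(curves, nPoints = 40L) {
  if (!length(curves)) stopf("no curves supplied")
  frac <- seq(0, 1, length.out = nPoints)
  m <- t(vapply(curves, function(cv) {
    if (length(cv$times) < 2L) stopf("need at least 2 phases per curve")
    f <- (cv$times - cv$times[1]) / (cv$times[length(cv$times)] - cv$times[1])
    stats::approx(f, cv$values, xout = frac)$y
  }, numeric(nPoints)))
  sdv <- if (nrow(m) < 2L) rep(0, nPoints) else apply(m, 2, stats::sd)
  list(fraction = frac, matrix = m, mean = colMeans(m), sd = sdv)
}
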