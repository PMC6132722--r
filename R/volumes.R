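# Planimetric ventricular volumetry from segmentation series, and
# flow-derived regurgitation measures from the pulmonary flow curve.

#' Planimetric ventricular volume curve
#'
#' Volume per phase is voxel count times voxel volume, per ventricle. EDV
#' and ESV are the maximum and minimum of the volume curve (not forced to
#' specific trigger phases, for robustness to trigger jitter), SV their
#' difference and EF = SV/EDV x 100. The end-systolic phase index (argmin
#' of the volume curve, earliest on ties) is recorded as the
#' systole/diastole boundary used downstream.
#'
#' @param seg a [SegmentationSeries-class]
#' @return list with one entry per ventricle (`lv`, `rv`), each a list with
#'   `volume` (ml per phase), `edv`, `esv`, `sv` (ml), `ef` (%), `esPhase`,
#'   plus `times` (ms)
#' @export
computeVolumeCurve <- function(seg) {
  stopifnot(is(seg, "SegmentationSeries"))
  vv <- voxelVolume(seg) / 1000  # ml per voxel
  nt <- nPhases(seg)
  out <- list(times = timeStamps(seg))
  for (vent in c("lv", "rv")) {
    lab <- if (vent == "lv") LV_LABEL else RV_LABEL
    vol <- vapply(seq_len(nt), function(ph) sum(seg@labels[, , , ph] == lab) * vv,
                  numeric(1))
    if (any(vol == 0)) stopf("%s label empty at phase %d", toupper(vent),
                             which(vol == 0)[1])
    edv <- max(vol); esv <- min(vol)
    out[[vent]] <- list(volume = vol, edv = edv, esv = esv, sv = edv - esv,
                        ef = 100 * (edv - esv) / edv,
                        esPhase = which.min(vol))
  }
  out
}

#' Regurgitation measures from a pulmonary flow curve
#'
#' Trapezoidal integration of the forward-positive flow curve over one
#' cycle: forward volume is the integral of `max(Q, 0)`, regurgitant
#' (reverse) volume that of `max(-Q, 0)`, regurgitant fraction their ratio
#' in percent, and effective stroke volume the net integral.
#'
#' @param flows a [FlowCurveSet-class], or a numeric flow vector in ml/s
#' @param times time stamps ms (required when `flows` is a bare vector)
#' @param vessel which curve to integrate when `flows` is a
#'   [FlowCurveSet-class] (`"pa"` or `"ao"`)
#' @return list with `forwardVolume`, `reverseVolume`, `effectiveSv` (ml),
#'   `regurgFractionPct` (%; `NA` with a warning attribute if the curve is
#'   all zero) and `defined`
#' @export
computeRegurgitation <- function(flows, times = NULL, vessel = "pa") {
  if (is(flows, "FlowCurveSet")) {
    times <- flows@times
    q <- slot(flows, vessel)
  } else q <- flows
  if (is.null(times) || length(times) != length(q)) {
    stopf("flow and time vectors must align")
  }
  fwd <- trapzInt(times, pmax(q, 0)) / 1000   # ml/s over ms -> ml
  rev <- trapzInt(times, pmax(-q, 0)) / 1000
  defined <- fwd > 0
  list(forwardVolume = fwd, reverseVolume = rev, effectiveSv = fwd - rev,
       regurgFractionPct = if (defined) 100 * rev / fwd else NA_real_,
       defined = defined)
}
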