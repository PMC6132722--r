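#' @import methods
NULL

#' Time-resolved three-directional velocity field
#'
#' Container for a 4D-flow velocity data set: a 5-dimensional array indexed
#' `(x, y, z, phase, component)` holding velocities in cm/s, together with the
#' voxel spacing (mm), time stamps (ms from the R-wave, covering one RR
#' interval), the velocity-encoding limit VENC (cm/s) and the cycle period.
#' World coordinates follow the package-wide convention
#' `world = origin + 0-based index * spacing`.
#'
#' @slot velocity five-dimensional numeric array, cm/s
#' @slot spacing numeric length-3, voxel spacing in mm
#' @slot times numeric, one time stamp in ms per phase, strictly increasing
#' @slot venc velocity-encoding limit in cm/s (`NA` if not applicable)
#' @slot period cycle (RR) duration in ms; defaults to
#'   `max(times) + median(diff(times))` when `NA`
#' @slot origin world coordinate of voxel (0,0,0) in mm
#' @slot provenance free-text description of where the field came from
#' @export
setClass("VelocityField4D", representation(
  velocity = "array", spacing = "numeric", times = "numeric",
  venc = "numeric", period = "numeric", origin = "numeric",
  provenance = "character"
))

setValidity("VelocityField4D", function(object) {
  d <- dim(object@velocity)
  if (length(d) != 5L) return("velocity must be a 5D array (x, y, z, phase, component)")
  if (d[5] != 3L) return("velocity must have exactly 3 components")
  if (length(object@spacing) != 3L || any(object@spacing <= 0)) {
    return("spacing must be 3 positive values (mm)")
  }
  if (length(object@times) != d[4]) return("one time stamp per phase required")
  if (any(diff(object@times) <= 0)) return("time stamps must be strictly increasing")
  if (!all(is.finite(object@velocity))) return("velocity contains non-finite values")
  if (length(object@venc) != 1L || (!is.na(object@venc) && object@venc <= 0)) {
    return("venc must be a single positive value or NA")
  }
  if (length(object@origin) != 3L) return("origin must have 3 components")
  TRUE
})

#' Construct a velocity field
#'
#' Validating constructor for [VelocityField4D-class].
#'
#' @param velocity 5D numeric array (x, y, z, phase, component), cm/s
#' @param spacing voxel spacing mm (length 3)
#' @param times phase time stamps ms, strictly increasing
#' @param venc velocity-encoding limit cm/s (`NA` if not applicable)
#' @param period cycle duration ms (`NA`: inferred downstream)
#' @param origin world coordinate of voxel (0,0,0), mm
#' @param provenance free-text description
#' @return a [VelocityField4D-class]
#' @export
newVelocityField <- function(velocity, spacing, times, venc = NA_real_,
                             period = NA_real_, origin = c(0, 0, 0),
                             provenance = "") {
  new("VelocityField4D", velocity = velocity, spacing = as.numeric(spacing),
      times = as.numeric(times), venc = as.numeric(venc),
      period = as.numeric(period), origin = as.numeric(origin),
      provenance = provenance)
}

#' Per-phase ventricular segmentation
#'
#' Voxel labels over the cardiac cycle on the same grid convention as
#' [VelocityField4D-class]. Label coding: 0 background, 1 left ventricle,
#' 2 right ventricle.
#'
#' @slot labels 4D integer array (x, y, z, phase) with values in \{0, 1, 2\}
#' @slot spacing,times,period,origin grid and timing metadata, as for
#'   [VelocityField4D-class]
#' @export
setClass("SegmentationSeries", representation(
  labels = "array", spacing = "numeric", times = "numeric",
  period = "numeric", origin = "numeric"
))

#' Label codes for the two ventricles
#' @export
LV_LABEL <- 1L
#' @rdname LV_LABEL
#' @export
RV_LABEL <- 2L

setValidity("SegmentationSeries", function(object) {
  d <- dim(object@labels)
  if (length(d) != 4L) return("labels must be a 4D array (x, y, z, phase)")
  if (length(object@times) != d[4]) return("one time stamp per phase required")
  if (any(diff(object@times) <= 0)) return("time stamps must be strictly increasing")
  if (length(object@spacing) != 3L || any(object@spacing <= 0)) {
    return("spacing must be 3 positive values (mm)")
  }
  if (!all(object@labels %in% c(0L, 1L, 2L))) {
    return("labels must be 0 (background), 1 (LV) or 2 (RV)")
  }
  for (ph in seq_len(d[4])) {
    vol <- object@labels[, , , ph]
    if (!any(vol == LV_LABEL) || !any(vol == RV_LABEL)) {
      return(sprintf("phase %d lacks LV or RV voxels", ph))
    }
  }
  TRUE
})

#' Construct a segmentation series
#'
#' Validating constructor for [SegmentationSeries-class].
#'
#' @param labels 4D array (x, y, z, phase) with values 0/1/2
#'   (background/LV/RV)
#' @param spacing,times,period,origin grid and timing metadata as for
#'   [newVelocityField()]
#' @return a [SegmentationSeries-class]
#' @export
newSegmentation <- function(labels, spacing, times, period = NA_real_,
                            origin = c(0, 0, 0)) {
  storage.mode(labels) <- "integer"
  new("SegmentationSeries", labels = labels, spacing = as.numeric(spacing),
      times = as.numeric(times), period = as.numeric(period),
      origin = as.numeric(origin))
}

#' Through-plane flow curves for the great vessels
#'
#' Pulmonary-artery and aortic flow rate versus time for one subject, on a
#' shared time base. Sign convention: antegrade (forward) flow positive.
#'
#' @slot times time stamps in ms
#' @slot pa pulmonary-artery flow in ml/s
#' @slot ao aortic flow in ml/s
#' @slot period cycle duration in ms
#' @export
setClass("FlowCurveSet", representation(
  times = "numeric", pa = "numeric", ao = "numeric", period = "numeric"
))

setValidity("FlowCurveSet", function(object) {
  n <- length(object@times)
  if (length(object@pa) != n || length(object@ao) != n) {
    return("pa and ao must match the time base")
  }
  if (any(diff(object@times) <= 0)) return("time stamps must be strictly increasing")
  if (!all(is.finite(c(object@pa, object@ao)))) return("flow values must be finite")
  TRUE
})

#' Construct a flow-curve set
#'
#' Validating constructor for [FlowCurveSet-class].
#'
#' @param times time stamps ms
#' @param pa,ao pulmonary and aortic flow, ml/s, forward positive
#' @param period cycle duration ms
#' @return a [FlowCurveSet-class]
#' @export
newFlowCurves <- function(times, pa, ao, period = NA_real_) {
  new("FlowCurveSet", times = as.numeric(times), pa = as.numeric(pa),
      ao = as.numeric(ao), period = as.numeric(period))
}

#' Flow map of advected particle seeds
#'
#' Final positions of a seed set advected through a time-resolved velocity
#' field over a signed horizon. Particles that left the blood-pool mask (or
#' the grid) are frozen at their exit position and flagged; their exit time
#' is recorded so downstream partitioning can reason about backward travel.
#'
#' @slot seeds,positions n x 3 matrices of start and end positions (mm)
#' @slot flagged logical, particle left the domain/mask before the horizon
#' @slot exitTime elapsed |time| at freezing, ms (`NA` where not flagged)
#' @slot t0,horizon,dt integration start (ms), signed horizon (ms), step (ms)
#' @slot seedDim integer dims of the seed grid (length 0 if seeds irregular)
#' @slot seedSpacing seed grid spacing in mm per axis
#' @export
setClass("FlowMap", representation(
  seeds = "matrix", positions = "matrix", flagged = "logical",
  exitTime = "numeric", t0 = "numeric", horizon = "numeric", dt = "numeric",
  seedDim = "integer", seedSpacing = "numeric"
))

setValidity("FlowMap", function(object) {
  n <- nrow(object@seeds)
  if (nrow(object@positions) != n || length(object@flagged) != n) {
    return("positions/flagged must match the seed count")
  }
  if (object@horizon == 0) return("horizon must be nonzero")
  if (any(!is.finite(object@positions[!object@flagged, ]))) {
    return("unflagged particle positions must be finite")
  }
  TRUE
})

#' Finite-time Lyapunov exponent field
#'
#' Scalar FTLE per seed of a regular seed grid,
#' \eqn{\mathrm{FTLE} = \ln\sqrt{\lambda_{max}(F^T F)} / |T|} with `F` the
#' spatial gradient of the flow map (Cauchy-Green strain). Units 1/ms.
#' Flagged seeds (particles that left the domain) hold `NA`; their exit
#' positions are retained for Lagrangian region assignment.
#'
#' @slot values FTLE array with the seed-grid dimensions, 1/ms
#' @slot direction `"forward"` or `"backward"`
#' @slot flagged logical array, seed excluded (left domain/mask)
#' @slot exitPos n x 3 matrix of exit positions for flagged seeds (mm)
#' @slot exitTime elapsed |time| to exit, ms
#' @slot seedOrigin,seedSpacing seed-grid geometry (mm)
#' @slot horizon signed integration horizon, ms
#' @export
setClass("FTLEField", representation(
  values = "array", direction = "character", flagged = "array",
  exitPos = "matrix", exitTime = "numeric",
  seedOrigin = "numeric", seedSpacing = "numeric", horizon = "numeric"
))

setValidity("FTLEField", function(object) {
  if (!identical(dim(object@values), dim(object@flagged))) {
    return("values and flagged must share dimensions")
  }
  if (!object@direction %in% c("forward", "backward")) {
    return("direction must be 'forward' or 'backward'")
  }
  vals <- object@values[!object@flagged]
  TRUE
})

#' First-order background phase model
#'
#' Per-component linear (in the three spatial voxel coordinates, constant in
#' time) model of the residual background phase offset,
#' `v_off(i,j,k) = a0 + a1*i + a2*j + a3*k` in cm/s with 0-based voxel
#' coordinates, fitted by least squares on static-tissue voxels.
#'
#' @slot coef 4 x 3 matrix; rows a0..a3, one column per velocity component
#' @slot residualRms per-component residual RMS over the static mask, cm/s
#' @slot staticMask logical 3D array of the voxels used in the fit
#' @export
setClass("BackgroundPlane", representation(
  coef = "matrix", residualRms = "numeric", staticMask = "array"
))

setValidity("BackgroundPlane", function(object) {
  if (!identical(dim(object@coef), c(4L, 3L))) return("coef must be 4 x 3")
  if (any(object@residualRms < 0)) return("residual RMS must be >= 0")
  TRUE
})

#' Specification of a synthetic ventricle phantom
#'
#' All tunable parameters of the analytic two-ventricle phantom: grid
#' geometry, timing, ellipsoidal blood-pool geometry, valve orifices, jet
#' speed envelopes, regurgitant fraction, restrictive-physiology flag,
#' background phase plane, VENC and noise. See [phantomSpec()] for defaults
#' and units.
#'
#' @slot dims,spacing,nPhases,rr grid dims (voxels), spacing (mm), phase
#'   count, RR interval (ms)
#' @slot lvCenter,lvAxes,rvCenter,rvAxes ellipsoid centers and end-diastolic
#'   semi-axes, mm
#' @slot esFraction end-systolic time as a fraction of RR
#' @slot lvEsvRatio,rvEsvRatio ESV/EDV per ventricle
#' @slot orifices named list (ao, mi, pa, tv) of lists with `center` (mm),
#'   `radius` (mm); jets extend `jetLength` mm into the ventricle along z
#' @slot jetLength jet cylinder length, mm
#' @slot jetSpeeds named peak speeds cm/s: ao, mi, pa, tv, pr
#' @slot regurgFraction pulmonary regurgitant fraction in [0, 1)
#' @slot restrictive logical; restrictive RV physiology phantom
#' @slot restrictiveSpeedFactor multiplier on diastolic jet speeds when
#'   restrictive (same regurgitant volume, lower velocity)
#' @slot lateDiastolicVolume forward PA volume in late diastole when
#'   restrictive, ml
#' @slot planeCoef 4 x 3 background-plane coefficients (cm/s and cm/s per
#'   voxel), applied via [injectPhaseArtifacts()]
#' @slot venc velocity-encoding limit, cm/s
#' @slot noiseSd additive Gaussian velocity noise SD per component, cm/s
#' @slot seed RNG seed for the noise draw
#' @export
setClass("PhantomSpec", representation(
  dims = "integer", spacing = "numeric", nPhases = "integer", rr = "numeric",
  lvCenter = "numeric", lvAxes = "numeric", rvCenter = "numeric",
  rvAxes = "numeric", esFraction = "numeric", lvEsvRatio = "numeric",
  rvEsvRatio = "numeric", orifices = "list", jetLength = "numeric",
  jetSpeeds = "numeric", regurgFraction = "numeric", restrictive = "logical",
  restrictiveSpeedFactor = "numeric", lateDiastolicVolume = "numeric",
  planeCoef = "matrix", venc = "numeric", noiseSd = "numeric", seed = "numeric"
))

setValidity("PhantomSpec", function(object) {
  if (length(object@dims) != 3L || any(object@dims < 8L)) {
    return("dims must be 3 values >= 8 voxels")
  }
  if (any(object@spacing <= 0)) return("spacing must be positive")
  if (object@nPhases < 8L) return("at least 8 time phases required")
  if (object@rr <= 0) return("RR interval must be positive")
  if (object@regurgFraction < 0 || object@regurgFraction >= 1) {
    return("regurgitant fraction must lie in [0, 1)")
  }
  if (object@esFraction <= 0.1 || object@esFraction >= 0.7) {
    return("end-systolic fraction must lie in (0.1, 0.7)")
  }
  needed <- c("ao", "mi", "pa", "tv")
  if (!all(needed %in% names(object@orifices))) {
    return("orifices must name ao, mi, pa and tv")
  }
  if (!all(c("ao", "mi", "pa", "tv", "pr") %in% names(object@jetSpeeds))) {
    return("jetSpeeds must name ao, mi, pa, tv and pr")
  }
  if (!identical(dim(object@planeCoef), c(4L, 3L))) {
    return("planeCoef must be a 4 x 3 matrix")
  }
  if (object@noiseSd < 0) return("noise SD must be >= 0")
  if (!is.na(object@venc) && object@venc <= 0) return("VENC must be positive")
  extent <- (object@dims - 1) * object@spacing
  for (nm in needed) {
    ctr <- object@orifices[[nm]]$center
    if (length(ctr) != 3L || any(ctr < 0) || any(ctr > extent)) {
      return(sprintf("orifice '%s' lies outside the grid", nm))
    }
  }
  TRUE
})

setMethod("show", "VelocityField4D", function(object) {
  d <- dim(object@velocity)
  cat(sprintf("VelocityField4D: %d x %d x %d voxels, %d phases, 3 components\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing %s mm, VENC %s cm/s, cycle %.0f ms\n",
              paste(signif(object@spacing, 3), collapse = " x "),
              ifelse(is.na(object@venc), "n/a", format(object@venc)),
              cyclePeriod(object)))
  cat(sprintf("  peak speed %.1f cm/s\n", sqrt(max(
    object@velocity[, , , , 1]^2 + object@velocity[, , , , 2]^2 +
      object@velocity[, , , , 3]^2))))
})

setMethod("show", "SegmentationSeries", function(object) {
  d <- dim(object@labels)
  cat(sprintf("SegmentationSeries: %d x %d x %d voxels, %d phases\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  LV voxels (phase 1): %d, RV voxels (phase 1): %d\n",
              sum(object@labels[, , , 1] == LV_LABEL),
              sum(object@labels[, , , 1] == RV_LABEL)))
})

setMethod("show", "FlowCurveSet", function(object) {
  cat(sprintf("FlowCurveSet: %d samples over %.0f ms\n",
              length(object@times), cyclePeriod(object)))
  cat(sprintf("  PA flow range %.1f .. %.1f ml/s; AO %.1f .. %.1f ml/s\n",
              min(object@pa), max(object@pa), min(object@ao), max(object@ao)))
})

setMethod("show", "FTLEField", function(object) {
  v <- object@values[!object@flagged]
  cat(sprintf("FTLEField (%s-time): %s seeds, %d flagged\n", object@direction,
              paste(dim(object@values), collapse = " x "), sum(object@flagged)))
  if (length(v)) cat(sprintf("  FTLE range %.3g .. %.3g per ms\n", min(v), max(v)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s voxels @ %s mm, %d phases, RR %.0f ms\n",
              paste(object@dims, collapse = " x "),
              paste(signif(object@spacing, 3), collapse = " x "),
              object@nPhases, object@rr))
  cat(sprintf("  regurgitant fraction %.2f, restrictive %s, VENC %s, noise SD %.2f cm/s\n",
              object@regurgFraction, object@restrictive,
              ifelse(is.na(object@venc), "n/a", format(object@venc)),
              object@noiseSd))
})
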