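# Analytic two-ventricle phantom.
#
# The phantom is deliberately simple so every downstream quantity has a
# closed-form ground truth: two axis-aligned ellipsoidal blood pools whose
# semi-axes breathe with a raised-cosine contraction envelope, and top-hat
# cylindrical valve jets with raised-cosine temporal speed envelopes.  Flow
# curves are the analytic time derivatives / jet envelopes, so regurgitant
# volumes and fractions are exact by construction, and the total kinetic
# energy of each ventricle is a closed-form sum over jet voxels.

#' Construct a ventricle-phantom specification
#'
#' Builds a validated [PhantomSpec-class]. Ventricle geometry is derived
#' from the requested end-diastolic volumes: each blood pool is an ellipsoid
#' with semi-axes `base * shape` where `base` is set so the analytic volume
#' matches `lvEdv`/`rvEdv`. Valve orifices are placed automatically near the
#' base (high-z pole) of each ventricle, inside the pool at every phase.
#'
#' @param dims grid size in voxels, length 3
#' @param spacing voxel spacing in mm (default 3 x 3 x 3)
#' @param nPhases reconstructed time phases over one cycle (default 40)
#' @param rr RR interval, ms
#' @param lvEdv,rvEdv end-diastolic volumes, ml
#' @param lvEsvRatio,rvEsvRatio ESV/EDV per ventricle
#' @param lvShape,rvShape relative semi-axis shape factors (x, y, z)
#' @param lvCenter,rvCenter optional explicit pool centers, mm
#' @param esFraction end-systolic time as a fraction of RR
#' @param orificeRadius requested orifice/jet radius, mm (shrunk
#'   automatically if the ventricle is too small to hold two disjoint
#'   orifices)
#' @param jetLength jet cylinder length into the ventricle, mm
#' @param jetSpeeds named peak jet speeds in cm/s (`ao`, `mi`, `pa`, `tv`,
#'   `pr`)
#' @param regurgFraction pulmonary regurgitant fraction (reverse/forward) in
#'   `[0, 1)`
#' @param restrictive logical; emulate restrictive RV physiology
#'   (early-concentrated, lower-peak diastolic jets at equal regurgitant
#'   volume, plus late-diastolic forward pulmonary flow)
#' @param restrictiveSpeedFactor diastolic speed multiplier when restrictive
#' @param lateDiastolicVolume forward PA volume in late diastole when
#'   restrictive, ml
#' @param planeCoef 4 x 3 first-order background-phase coefficients (cm/s
#'   and cm/s per voxel), rows a0..a3, one column per component
#' @param venc velocity-encoding limit, cm/s; speeds beyond it alias
#' @param noiseSd additive Gaussian noise SD per velocity component, cm/s
#' @param seed RNG seed for the noise draw (NA: use current RNG state)
#' @return a [PhantomSpec-class]
#' @export
phantomSpec <- function(dims = c(48L, 48L, 40L), spacing = c(3, 3, 3),
                        nPhases = 40L, rr = 857,
                        lvEdv = 150, lvEsvRatio = 0.46,
                        rvEdv = 200, rvEsvRatio = 0.45,
                        lvShape = c(1, 1, 1.5), rvShape = c(0.85, 1.1, 1.55),
                        lvCenter = NULL, rvCenter = NULL,
                        esFraction = 0.35, orificeRadius = 8, jetLength = 40,
                        jetSpeeds = c(ao = 100, mi = 60, pa = 70, tv = 55, pr = 95),
                        regurgFraction = 0, restrictive = FALSE,
                        restrictiveSpeedFactor = 0.6, lateDiastolicVolume = 3,
                        planeCoef = matrix(0, 4, 3), venc = 100,
                        noiseSd = 1.5, seed = NA_real_) {
  dims <- as.integer(dims)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  extent <- (dims - 1) * spacing
  axesFor <- function(edv, shape) {
    base <- (edv * 1000 / (4 / 3 * pi * prod(shape)))^(1 / 3)
    base * shape
  }
  lvAxes <- axesFor(lvEdv, lvShape)
  rvAxes <- axesFor(rvEdv, rvShape)
  lvCenter <- lvCenter %||% c(0.27 * extent[1], 0.5 * extent[2], 0.5 * extent[3])
  rvCenter <- rvCenter %||% c(0.73 * extent[1], 0.5 * extent[2], 0.5 * extent[3])
  fit <- function(ctr, axes, what) {
    if (any(ctr - axes < spacing) || any(ctr + axes > extent - spacing)) {
      stopf("%s blood pool (semi-axes %s mm) does not fit the grid; reduce its EDV",
            what, paste(signif(axes, 3), collapse = "/"))
    }
  }
  fit(lvCenter, lvAxes, "LV")
  fit(rvCenter, rvAxes, "RV")
  orifices <- .autoOrifices(lvCenter, lvAxes, lvEsvRatio,
                            rvCenter, rvAxes, rvEsvRatio, orificeRadius)
  spec <- new("PhantomSpec",
              dims = dims, spacing = as.numeric(spacing),
              nPhases = as.integer(nPhases), rr = as.numeric(rr),
              lvCenter = lvCenter, lvAxes = lvAxes,
              rvCenter = rvCenter, rvAxes = rvAxes,
              esFraction = esFraction, lvEsvRatio = lvEsvRatio,
              rvEsvRatio = rvEsvRatio, orifices = orifices,
              jetLength = jetLength, jetSpeeds = jetSpeeds,
              regurgFraction = regurgFraction, restrictive = restrictive,
              restrictiveSpeedFactor = restrictiveSpeedFactor,
              lateDiastolicVolume = lateDiastolicVolume,
              planeCoef = planeCoef, venc = as.numeric(venc),
              noiseSd = noiseSd, seed = as.numeric(seed))
  validObject(spec)
  spec
}

# Two orifices per ventricle near the basal (high-z) pole, kept inside the
# end-systolic pool and mutually disjoint.
.autoOrifices <- function(lvCenter, lvAxes, lvEsvRatio,
                          rvCenter, rvAxes, rvEsvRatio, radius) {
  place <- function(ctr, axes, esvRatio) {
    sMin <- esvRatio^(1 / 3)
    ax <- if (axes[2] >= axes[1]) 2L else 1L  # separate along the wider axis
    off <- 0.42 * axes[ax] * sMin
    rad <- min(radius, 0.60 * off)
    zTop <- ctr[3] + 0.65 * axes[3] * sMin
    mk <- function(sgn) {
      ctr2 <- ctr; ctr2[ax] <- ctr2[ax] + sgn * off
      list(center = c(ctr2[1], ctr2[2], zTop), radius = rad)
    }
    list(left = mk(-1), right = mk(1))
  }
  lv <- place(lvCenter, lvAxes, lvEsvRatio)
  rv <- place(rvCenter, rvAxes, rvEsvRatio)
  list(ao = lv$left, mi = lv$right, pa = rv$left, tv = rv$right)
}

# temporal envelopes as fractions of the RR interval; each is a unit-peak
# raised cosine with start `a` and width `w` (fractions of RR)
.phantomWindows <- function(esFraction, restrictive) {
  es <- esFraction
  dia <- 1 - es
  list(
    sys  = c(a = 0.03, w = es - 0.05),
    fill = c(a = es + 0.03 * dia, w = 0.77 * dia),
    pr   = if (restrictive) c(a = es + 0.03 * dia, w = 0.47 * dia)
           else             c(a = es + 0.03 * dia, w = 0.92 * dia),
    late = c(a = 1 - 0.12, w = 0.10)
  )
}

#' Generate a synthetic two-ventricle 4D-flow phantom
#'
#' Realizes a [PhantomSpec-class] into a velocity field, a per-phase
#' segmentation, great-vessel flow curves and a ground-truth record. The
#' velocity is nonzero only inside the blood pools (top-hat valve jets with
#' raised-cosine speed envelopes) plus optional Gaussian noise; phase
#' artifacts (background plane and aliasing above VENC) are applied last via
#' [injectPhaseArtifacts()], and the pre-artifact field is kept alongside as
#' `velocityClean` for round-trip validation.
#'
#' @param spec a [PhantomSpec-class]
#' @return a list of class `phantomBundle` with elements `spec`, `velocity`
#'   ([VelocityField4D-class], artifacts applied), `velocityClean`,
#'   `segmentation` ([SegmentationSeries-class]), `flows`
#'   ([FlowCurveSet-class]) and `truth` (see Details)
#' @details The `truth` element records, among others: the analytic total-KE
#'   curve per ventricle in mJ (`keTrue`), analytic volume curves and
#'   EDV/ESV/SV/EF, the regurgitant volume and fraction, the true diastolic
#'   peak phase, the fraction of RV KE carried by the regurgitant jet at
#'   that phase (`keFracPRPct`), per-phase jet voxel index sets for the
#'   regurgitant and tricuspid jets, orifice markers for LCS partitioning,
#'   the restrictive label and the injected plane coefficients.
#' @export
generateVentriclePhantom <- function(spec) {
  validObject(spec)
  dims <- spec@dims; sp <- spec@spacing; nt <- spec@nPhases; rr <- spec@rr
  times <- (seq_len(nt) - 1) * rr / nt
  u <- times / rr
  win <- .phantomWindows(spec@esFraction, spec@restrictive)
  envAt <- function(w, uu) raisedCosine(uu, w["a"], w["w"])
  cdfAt <- function(w, uu) raisedCosineCdf(uu, w["a"], w["w"])

  lvEdv <- 4 / 3 * pi * prod(spec@lvAxes) / 1000
  rvEdv <- 4 / 3 * pi * prod(spec@rvAxes) / 1000
  svLv <- lvEdv * (1 - spec@lvEsvRatio)
  svRv <- rvEdv * (1 - spec@rvEsvRatio)

  contraction <- cdfAt(win$sys, u) - cdfAt(win$fill, u)
  vLv <- lvEdv - svLv * contraction
  vRv <- rvEdv - svRv * contraction
  sLv <- (vLv / lvEdv)^(1 / 3)
  sRv <- (vRv / rvEdv)^(1 / 3)

  # ---- flow curves (analytic; ml/s, forward positive) --------------------
  # regurgitant volume is tied to the ejected stroke volume so restrictive
  # and non-restrictive phantoms with the same regurgitant fraction carry
  # the same regurgitant volume; the late-diastolic forward bump of the
  # restrictive phantom slightly lowers its realized regurgitant fraction
  lateVol <- if (spec@restrictive) spec@lateDiastolicVolume else 0
  forwardPa <- svRv + lateVol
  prVol <- spec@regurgFraction * svRv
  dens <- function(w, uu) 2 / (w["w"] * rr) * raisedCosine(uu, w["a"], w["w"])
  qAo <- 1000 * svLv * dens(win$sys, u)
  qPa <- 1000 * (svRv * dens(win$sys, u) - prVol * dens(win$pr, u) +
                   lateVol * dens(win$late, u))
  flows <- newFlowCurves(times, pa = qPa, ao = qAo, period = rr)

  # ---- masks -------------------------------------------------------------
  cc <- coordArrays(dims, sp)
  inEllipsoid <- function(ctr, axes, s) {
    ((cc$X - ctr[1]) / (axes[1] * s))^2 + ((cc$Y - ctr[2]) / (axes[2] * s))^2 +
      ((cc$Z - ctr[3]) / (axes[3] * s))^2 <= 1
  }
  labels <- array(0L, dim = c(dims, nt))
  lvMasks <- vector("list", nt); rvMasks <- vector("list", nt)
  for (ph in seq_len(nt)) {
    lvM <- inEllipsoid(spec@lvCenter, spec@lvAxes, sLv[ph])
    rvM <- inEllipsoid(spec@rvCenter, spec@rvAxes, sRv[ph])
    if (any(lvM & rvM)) stopf("LV and RV blood pools overlap; adjust geometry")
    vol <- array(0L, dim = dims)
    vol[lvM] <- LV_LABEL; vol[rvM] <- RV_LABEL
    labels[, , , ph] <- vol
    lvMasks[[ph]] <- lvM; rvMasks[[ph]] <- rvM
  }
  seg <- newSegmentation(labels, sp, times, period = rr)

  # ---- jets --------------------------------------------------------------
  rf <- spec@restrictiveSpeedFactor
  diaScale <- if (spec@restrictive) rf else 1
  jets <- list(
    ao = list(orifice = "ao", vent = "lv", dirZ = +1, win = win$sys,
              peak = unname(spec@jetSpeeds["ao"])),
    mi = list(orifice = "mi", vent = "lv", dirZ = -1, win = win$fill,
              peak = unname(spec@jetSpeeds["mi"])),
    pa = list(orifice = "pa", vent = "rv", dirZ = +1, win = win$sys,
              peak = unname(spec@jetSpeeds["pa"])),
    tv = list(orifice = "tv", vent = "rv", dirZ = -1, win = win$fill,
              peak = unname(spec@jetSpeeds["tv"]) * diaScale),
    pr = list(orifice = "pa", vent = "rv", dirZ = -1, win = win$pr,
              peak = if (spec@regurgFraction > 0)
                unname(spec@jetSpeeds["pr"]) * diaScale else 0),
    late = list(orifice = "pa", vent = "rv", dirZ = +1, win = win$late,
                peak = if (spec@restrictive) 15 else 0)
  )
  cylinder <- function(orf) {
    o <- spec@orifices[[orf]]
    which(((cc$X - o$center[1])^2 + (cc$Y - o$center[2])^2 <= o$radius^2) &
            cc$Z <= o$center[3] & cc$Z >= o$center[3] - spec@jetLength)
  }
  # jet voxel sets are phase-constant: cylinder clipped to the smallest
  # (end-systolic) pool, which is contained in the pool at every phase --
  # keeps each voxel's velocity history temporally smooth and the analytic
  # KE a closed form with constant voxel counts
  lvJetPool <- inEllipsoid(spec@lvCenter, spec@lvAxes, min(sLv))
  rvJetPool <- inEllipsoid(spec@rvCenter, spec@rvAxes, min(sRv))
  jetIdx <- lapply(jets, function(j) {
    cyl <- cylinder(j$orifice)
    pool <- if (j$vent == "lv") lvJetPool else rvJetPool
    cyl[pool[cyl]]
  })
  # same-window jets sharing voxels would superpose; reject
  for (i in seq_along(jets)[-1]) for (k in seq_len(i - 1)) {
    ji <- jets[[i]]; jk <- jets[[k]]
    overlapT <- ji$win["a"] < jk$win["a"] + jk$win["w"] &
      jk$win["a"] < ji$win["a"] + ji$win["w"]
    if (ji$peak > 0 && jk$peak > 0 && overlapT &&
        length(intersect(jetIdx[[i]], jetIdx[[k]]))) {
      stopf("jets '%s' and '%s' overlap in space and time; adjust orifice geometry",
            names(jets)[i], names(jets)[k])
    }
  }

  nVox3 <- prod(dims)
  vel <- array(0, dim = c(dims, nt, 3))
  voxvol <- prod(sp)
  keTrue <- matrix(0, nt, 2, dimnames = list(NULL, c("lv", "rv")))
  prVoxels <- vector("list", nt); tvVoxels <- vector("list", nt)
  for (ph in seq_len(nt)) {
    active <- list()
    for (nm in names(jets)) {
      j <- jets[[nm]]
      e <- envAt(j$win, u[ph])
      if (j$peak == 0 || e <= 0) next
      idx <- jetIdx[[nm]]
      if (!length(idx)) next
      active[[nm]] <- list(idx = idx, speed = j$peak * e, dirZ = j$dirZ,
                           vent = j$vent)
    }
    # linear index into (x,y,z,phase,component): 3D index + phase and
    # component block offsets; jets are purely z-directed (component 3)
    zCompOffset <- (ph - 1) * nVox3 + 2L * nVox3 * nt
    for (a in active) {
      vel[a$idx + zCompOffset] <- a$dirZ * a$speed
      col <- if (a$vent == "lv") 1L else 2L
      keTrue[ph, col] <- keTrue[ph, col] +
        0.5 * 1.05 * voxvol * length(a$idx) * a$speed^2 * 1e-7
    }
    prVoxels[[ph]] <- if (!is.null(active$pr)) active$pr$idx else integer(0)
    tvVoxels[[ph]] <- if (!is.null(active$tv)) active$tv$idx else integer(0)
  }

  clean <- newVelocityField(vel, sp, times, venc = spec@venc, period = rr,
                            provenance = "synthetic ventricle phantom")

  if (spec@noiseSd > 0) {
    if (!is.na(spec@seed)) set.seed(as.integer(spec@seed))
    noisy <- vel + stats::rnorm(length(vel), 0, spec@noiseSd)
    noisyField <- newVelocityField(noisy, sp, times, venc = spec@venc,
                                   period = rr,
                                   provenance = clean@provenance)
  } else noisyField <- clean

  observed <- injectPhaseArtifacts(noisyField, spec@planeCoef, spec@venc)

  esPhase <- which.min(vLv)
  diaPhases <- which(seq_len(nt) > which.min(vRv))
  keRvDia <- keTrue[diaPhases, "rv"]
  peakPhase <- if (length(diaPhases)) diaPhases[which.max(keRvDia)] else NA_integer_
  kePrPeak <- if (!is.na(peakPhase) && length(prVoxels[[peakPhase]])) {
    e <- envAt(win$pr, u[peakPhase])
    0.5 * 1.05 * voxvol * length(prVoxels[[peakPhase]]) *
      (unname(spec@jetSpeeds["pr"]) * diaScale * e)^2 * 1e-7
  } else 0
  keFracPRPct <- if (!is.na(peakPhase) && keTrue[peakPhase, "rv"] > 0) {
    100 * kePrPeak / keTrue[peakPhase, "rv"]
  } else 0

  truth <- list(
    keTrue = keTrue,
    volumeCurves = cbind(lv = vLv, rv = vRv),
    edv = c(lv = lvEdv, rv = rvEdv),
    esv = c(lv = lvEdv * spec@lvEsvRatio, rv = rvEdv * spec@rvEsvRatio),
    sv = c(lv = svLv, rv = svRv),
    prVolume = prVol, prFractionPct = 100 * prVol / forwardPa,
    forwardPaVolume = forwardPa,
    esPhase = esPhase, diastolicPeakPhase = peakPhase,
    kePrAtPeak = kePrPeak, keFracPRPct = keFracPRPct,
    restrictive = spec@restrictive, planeCoef = spec@planeCoef,
    prVoxels = prVoxels, tvVoxels = tvVoxels,
    markers = list(pa = spec@orifices$pa, tv = spec@orifices$tv),
    staticMask = {
      pool <- array(FALSE, dims)
      for (ph in seq_len(nt)) pool <- pool | (labels[, , , ph] > 0L)
      !pool
    }
  )

  structure(list(spec = spec, velocity = observed, velocityClean = clean,
                 segmentation = seg, flows = flows, truth = truth),
            class = "phantomBundle")
}

#' @export
print.phantomBundle <- function(x, ...) {
  cat("Synthetic ventricle phantom bundle\n")
  show(x$spec)
  cat(sprintf("  truth: SV %0.1f/%0.1f ml (LV/RV), PR %0.1f ml (%.0f%%), restrictive %s\n",
              x$truth$sv["lv"], x$truth$sv["rv"], x$truth$prVolume,
              x$truth$prFractionPct, x$truth$restrictive))
  invisible(x)
}

#' Inject first-order background phase and velocity aliasing
#'
#' Adds a per-component first-order phase offset
#' `a0 + a1*i + a2*j + a3*k` (0-based voxel coordinates, coefficients in
#' cm/s and cm/s per voxel) to every phase of the field, then wraps any
#' velocity with magnitude beyond VENC into `(-VENC, +VENC]` by integer
#' multiples of `2*VENC`, emulating phase-contrast aliasing.
#'
#' @param field a [VelocityField4D-class]
#' @param planeCoef 4 x 3 coefficient matrix (rows a0..a3, columns x/y/z
#'   velocity components)
#' @param venc aliasing limit in cm/s; `NA` disables wrapping
#' @return a [VelocityField4D-class]
#' @export
injectPhaseArtifacts <- function(field, planeCoef, venc = NULL) {
  stopifnot(is(field, "VelocityField4D"))
  venc <- venc %||% field@venc
  planeCoef <- as.matrix(planeCoef)
  if (!identical(dim(planeCoef), c(4L, 3L))) stopf("planeCoef must be 4 x 3")
  vel <- field@velocity
  d <- dim(vel)
  if (any(planeCoef != 0)) {
    ijk <- coordArrays(d[1:3], c(1, 1, 1))  # voxel units, 0-based
    for (comp in 1:3) {
      a <- planeCoef[, comp]
      if (all(a == 0)) next
      off <- a[1] + a[2] * ijk$X + a[3] * ijk$Y + a[4] * ijk$Z
      for (ph in seq_len(d[4])) {
        vel[, , , ph, comp] <- vel[, , , ph, comp] + off
      }
    }
  }
  if (!is.na(venc)) {
    k <- ceiling((vel - venc) / (2 * venc))
    needs <- k != 0
    if (any(needs)) vel[needs] <- vel[needs] - 2 * venc * k[needs]
  }
  outVenc <- if (!is.na(venc)) venc else field@venc
  newVelocityField(vel, field@spacing, field@times, venc = outVenc,
                   period = field@period, origin = field@origin,
                   provenance = field@provenance)
}
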