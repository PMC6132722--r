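# Lagrangian coherent structures: RK4 particle advection through the
# time-resolved velocity field, finite-time Lyapunov exponents from the
# Cauchy-Green strain of the flow map, and the Lagrangian partition of the
# right ventricle into pulmonary-regurgitation versus tricuspid-inflow
# territory at the diastolic KE peak.

# trilinear in space, linear in time, cyclic over the cardiac cycle;
# returns mm/ms
.gridVelocitySampler <- function(field) {
  vel <- field@velocity
  d <- dim(vel)
  dims <- d[1:3]; nt <- d[4]; n3 <- prod(dims)
  sp <- field@spacing; or <- field@origin
  times <- field@times; per <- cyclePeriod(field)
  function(t, P) {
    ttt <- ((t - times[1]) %% per) + times[1]
    k <- findInterval(ttt, times)
    if (k < nt) {
      k2 <- k + 1L; w <- (ttt - times[k]) / (times[k2] - times[k])
    } else {
      k2 <- 1L; w <- (ttt - times[nt]) / (times[1] + per - times[nt])
    }
    cx <- pmin(pmax((P[, 1] - or[1]) / sp[1], 0), dims[1] - 1)
    cy <- pmin(pmax((P[, 2] - or[2]) / sp[2], 0), dims[2] - 1)
    cz <- pmin(pmax((P[, 3] - or[3]) / sp[3], 0), dims[3] - 1)
    i0 <- pmin(floor(cx), dims[1] - 2); fx <- cx - i0
    j0 <- pmin(floor(cy), dims[2] - 2); fy <- cy - j0
    k0 <- pmin(floor(cz), max(dims[3] - 2, 0)); fz <- cz - k0
    out <- matrix(0, nrow(P), 3)
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      if (dz > 0 && dims[3] == 1L) next
      wgt <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
        (if (dz) fz else 1 - fz)
      lin <- (i0 + dx + 1) + dims[1] * ((j0 + dy) + dims[2] * (k0 + dz))
      for (cmp in 1:3) {
        o1 <- (k - 1L) * n3 + (cmp - 1L) * n3 * nt
        o2 <- (k2 - 1L) * n3 + (cmp - 1L) * n3 * nt
        out[, cmp] <- out[, cmp] + wgt * ((1 - w) * vel[lin + o1] + w * vel[lin + o2])
      }
    }
    out * .CMS_TO_MM_PER_MS
  }
}

# nearest-neighbour inside-mask test at the nearest phase
.maskInsideTester <- function(mask, spacing, origin, times, per) {
  dims <- dim(mask)[1:3]
  nt <- if (length(dim(mask)) == 4L) dim(mask)[4] else 1L
  n3 <- prod(dims)
  function(t, P) {
    i <- round((P[, 1] - origin[1]) / spacing[1])
    j <- round((P[, 2] - origin[2]) / spacing[2])
    k <- round((P[, 3] - origin[3]) / spacing[3])
    inb <- i >= 0 & i < dims[1] & j >= 0 & j < dims[2] & k >= 0 & k < dims[3]
    out <- logical(nrow(P))
    if (any(inb)) {
      ph <- if (nt > 1L) {
        ttt <- ((t - times[1]) %% per) + times[1]
        which.min(abs(c(times, times[1] + per) - ttt)) %% nt
      } else 1L
      if (ph == 0L) ph <- nt
      lin <- (i[inb] + 1) + dims[1] * (j[inb] + dims[2] * k[inb]) +
        (ph - 1L) * n3
      out[inb] <- mask[lin] != 0
    }
    out
  }
}

.advectImpl <- function(velFun, seeds, t0, horizon, dt, insideFun = NULL) {
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 3)
  if (horizon == 0) stopf("advection horizon must be nonzero")
  if (dt <= 0 || dt >= abs(horizon)) {
    stopf("dt must be positive and smaller than |horizon|")
  }
  n <- nrow(seeds)
  P <- seeds
  sgn <- sign(horizon)
  total <- abs(horizon)
  nFull <- floor(total / dt + 1e-12)
  steps <- rep(dt, nFull)
  if (total - nFull * dt > 1e-9 * dt) steps <- c(steps, total - nFull * dt)
  flagged <- if (!is.null(insideFun)) !insideFun(t0, P) else rep(FALSE, n)
  exitTime <- ifelse(flagged, 0, NA_real_)
  elapsed <- 0
  active <- which(!flagged)
  for (h0 in steps) {
    if (!length(active)) break
    h <- sgn * h0
    t <- t0 + sgn * elapsed
    Pa <- P[active, , drop = FALSE]
    k1 <- velFun(t, Pa)
    k2 <- velFun(t + h / 2, Pa + h / 2 * k1)
    k3 <- velFun(t + h / 2, Pa + h / 2 * k2)
    k4 <- velFun(t + h, Pa + h * k3)
    Pa <- Pa + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    P[active, ] <- Pa
    elapsed <- elapsed + h0
    if (!is.null(insideFun)) {
      inside <- insideFun(t + h, Pa)
      if (!all(inside)) {
        left <- active[!inside]
        flagged[left] <- TRUE
        exitTime[left] <- elapsed
        active <- active[inside]
      }
    }
  }
  new("FlowMap", seeds = seeds, positions = P, flagged = flagged,
      exitTime = exitTime, t0 = t0, horizon = horizon, dt = dt,
      seedDim = as.integer(attr(seeds, "seedDim") %||% integer(0)),
      seedSpacing = as.numeric(attr(seeds, "seedSpacing") %||% numeric(0)))
}

#' Regular seed grid helper
#'
#' Builds an n x 3 seed matrix over a regular grid, carrying its geometry
#' as attributes so [ftle()] can reshape the flow map.
#'
#' @param dims seed counts per axis (length 3; use 1 for a planar grid)
#' @param spacing seed spacing mm per axis
#' @param origin world position of the first seed, mm
#' @return matrix with attributes `seedDim`, `seedSpacing`, `seedOrigin`
#' @export
seedGrid <- function(dims, spacing, origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  x <- axisCoords(dims[1], spacing[1], origin[1])
  y <- axisCoords(dims[2], spacing[2], origin[2])
  z <- axisCoords(dims[3], spacing[3], origin[3])
  seeds <- cbind(rep(x, times = dims[2] * dims[3]),
                 rep(rep(y, each = dims[1]), times = dims[3]),
                 rep(z, each = dims[1] * dims[2]))
  attr(seeds, "seedDim") <- dims
  attr(seeds, "seedSpacing") <- as.numeric(spacing)
  attr(seeds, "seedOrigin") <- as.numeric(origin)
  seeds
}

#' Seed every voxel center of a field
#' @param object a [VelocityField4D-class] or [SegmentationSeries-class]
#' @return seed matrix as from [seedGrid()]
#' @export
voxelSeeds <- function(object) {
  seedGrid(gridDim(object), voxelSpacing(object), gridOrigin(object))
}

#' @rdname advect
#' @export
setMethod("advect", "VelocityField4D",
          function(field, seeds, t0, horizon, dt = NULL, bloodMask = NULL) {
  dt <- dt %||% (cyclePeriod(field) / nPhases(field) / 5)
  insideFun <- NULL
  if (!is.null(bloodMask)) {
    if (is(bloodMask, "SegmentationSeries")) {
      insideFun <- .maskInsideTester(bloodMask@labels, bloodMask@spacing,
                                     bloodMask@origin, bloodMask@times,
                                     cyclePeriod(bloodMask))
    } else {
      insideFun <- .maskInsideTester(bloodMask, field@spacing, field@origin,
                                     field@times, cyclePeriod(field))
    }
  }
  .advectImpl(.gridVelocitySampler(field), seeds, t0, horizon, dt, insideFun)
})

#' @rdname advect
#' @export
setMethod("advect", "function",
          function(field, seeds, t0, horizon, dt = NULL, bloodMask = NULL) {
  if (is.null(dt)) stopf("dt is required when advecting an analytic velocity")
  velFun <- function(t, P) field(t, P) * .CMS_TO_MM_PER_MS
  .advectImpl(velFun, seeds, t0, horizon, dt, NULL)
})

# largest eigenvalue of symmetric 2x2 / 3x3 matrices, vectorized
.lambdaMax2 <- function(a, b, c) {
  (a + c) / 2 + sqrt(((a - c) / 2)^2 + b^2)
}
.lambdaMax3 <- function(a11, a22, a33, a12, a13, a23) {
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  out <- pmax(a11, pmax(a22, a33))  # diagonal fallback
  nz <- p > .Machine$double.eps * pmax(abs(q), 1)
  nz[is.na(nz)] <- FALSE
  if (any(nz)) {
    b11 <- (a11 - q) / p; b22 <- (a22 - q) / p; b33 <- (a33 - q) / p
    b12 <- a12 / p; b13 <- a13 / p; b23 <- a23 / p
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    out[nz] <- (q + 2 * p * cos(phi))[nz]
  }
  out
}

# finite-difference gradient along one axis of a (possibly NA-holed) array;
# central where both neighbours are valid, one-sided otherwise
.gradAxis <- function(arr, axis, h) {
  d <- dim(arr)
  shiftA <- function(by) {
    out <- array(NA_real_, dim = d)
    n <- d[axis]
    src <- seq_len(n) - by
    ok <- src >= 1L & src <= n
    to <- which(ok); from <- src[ok]
    if (axis == 1) out[to, , ] <- arr[from, , ]
    if (axis == 2) out[, to, ] <- arr[, from, ]
    if (axis == 3) out[, , to] <- arr[, , from]
    out
  }
  fwd <- shiftA(-1L); bwd <- shiftA(1L)
  g <- (fwd - bwd) / (2 * h)
  oneF <- (fwd - arr) / h
  oneB <- (arr - bwd) / h
  g[is.na(g)] <- oneF[is.na(g)]
  g[is.na(g)] <- oneB[is.na(g)]
  g
}

#' Finite-time Lyapunov exponent of a flow map
#'
#' Computes the FTLE on the regular seed grid of a [FlowMap-class]:
#' spatial gradient of the final positions by central differences (one-sided
#' at borders and next to excluded seeds), Cauchy-Green tensor
#' \eqn{C = F^T F}, and \eqn{\mathrm{FTLE} = \ln\sqrt{\lambda_{max}(C)}/|T|}.
#' Planar seed grids (one seed along z) use the in-plane 2 x 2 tensor.
#' Flagged seeds are excluded (`NA`), but their exit positions and times are
#' carried along for Lagrangian region assignment in [partitionRV()].
#'
#' @param flowmap a [FlowMap-class] whose seeds came from [seedGrid()]
#' @return an [FTLEField-class] (units 1/ms)
#' @export
ftle <- function(flowmap) {
  stopifnot(is(flowmap, "FlowMap"))
  sd3 <- flowmap@seedDim
  if (length(sd3) != 3L) stopf("flow map lacks a regular seed grid")
  if (any(sd3 < 3L & sd3 != 1L)) {
    stopf("need at least 3 seeds along each non-degenerate axis for gradients")
  }
  sp <- flowmap@seedSpacing
  h <- abs(flowmap@horizon)
  planar <- sd3[3] == 1L
  pos <- flowmap@positions
  pos[flowmap@flagged, ] <- NA_real_
  comp <- lapply(1:3, function(c) array(pos[, c], dim = sd3))
  axes <- if (planar) 1:2 else 1:3
  Fg <- list()
  for (a in axes) for (c in seq_along(axes)) {
    Fg[[paste0(c, a)]] <- .gradAxis(comp[[c]], a, sp[a])
  }
  if (planar) {
    c11 <- Fg[["11"]]^2 + Fg[["21"]]^2
    c22 <- Fg[["12"]]^2 + Fg[["22"]]^2
    c12 <- Fg[["11"]] * Fg[["12"]] + Fg[["21"]] * Fg[["22"]]
    lam <- .lambdaMax2(c11, c12, c22)
  } else {
    c11 <- Fg[["11"]]^2 + Fg[["21"]]^2 + Fg[["31"]]^2
    c22 <- Fg[["12"]]^2 + Fg[["22"]]^2 + Fg[["32"]]^2
    c33 <- Fg[["13"]]^2 + Fg[["23"]]^2 + Fg[["33"]]^2
    c12 <- Fg[["11"]] * Fg[["12"]] + Fg[["21"]] * Fg[["22"]] + Fg[["31"]] * Fg[["32"]]
    c13 <- Fg[["11"]] * Fg[["13"]] + Fg[["21"]] * Fg[["23"]] + Fg[["31"]] * Fg[["33"]]
    c23 <- Fg[["12"]] * Fg[["13"]] + Fg[["22"]] * Fg[["23"]] + Fg[["32"]] * Fg[["33"]]
    lam <- .lambdaMax3(c11, c22, c33, c12, c13, c23)
  }
  vals <- 0.5 * log(pmax(lam, 1e-300)) / h
  flaggedArr <- array(flowmap@flagged, dim = sd3)
  vals[flaggedArr] <- NA_real_
  new("FTLEField", values = vals,
      direction = if (flowmap@horizon < 0) "backward" else "forward",
      flagged = flaggedArr, exitPos = flowmap@positions,
      exitTime = flowmap@exitTime,
      seedOrigin = as.numeric(attr(flowmap@seeds, "seedOrigin") %||% c(0, 0, 0)),
      seedSpacing = sp, horizon = flowmap@horizon)
}

# world positions of the seeds at given linear indices of the seed grid
.seedPositions <- function(ftleField, idx) {
  d <- dim(ftleField@values)
  ijk <- arrayInd(idx, d) - 1L
  sweep(sweep(ijk, 2, ftleField@seedSpacing, `*`), 2, ftleField@seedOrigin, `+`)
}

# layered multi-source BFS over the 6-neighbourhood, blocked by `blocked`,
# restricted to `domain`; sources is a list of index vectors, one per label
.multiSourceGrow <- function(dims, domain, blocked, sources) {
  lab <- integer(prod(dims))
  for (s in seq_along(sources)) lab[sources[[s]]] <- s
  nbOffsets <- function(idx) {
    ijk <- arrayInd(idx, dims)
    res <- list()
    for (ax in 1:3) for (dd in c(-1L, 1L)) {
      nb <- ijk
      nb[, ax] <- nb[, ax] + dd
      ok <- nb[, ax] >= 1L & nb[, ax] <= dims[ax]
      res[[length(res) + 1L]] <- cbind(from = idx[ok],
                                       to = linearIndex3(nb[ok, 1], nb[ok, 2],
                                                         nb[ok, 3], dims))
    }
    do.call(rbind, res)
  }
  frontier <- which(lab > 0L)
  while (length(frontier)) {
    e <- nbOffsets(frontier)
    cand <- e[domain[e[, "to"]] & !blocked[e[, "to"]] & lab[e[, "to"]] == 0L, ,
              drop = FALSE]
    if (!nrow(cand)) break
    # deterministic tie-break: lowest source label wins a contested voxel
    ord <- order(cand[, "to"], lab[cand[, "from"]])
    cand <- cand[ord, , drop = FALSE]
    first <- !duplicated(cand[, "to"])
    lab[cand[first, "to"]] <- lab[cand[first, "from"]]
    frontier <- unique(cand[first, "to"])
  }
  lab
}

#' Partition the right ventricle into PR and non-PR territory
#'
#' Separates, at the diastolic KE peak, the right-ventricular blood that
#' entered through the pulmonary valve (the regurgitant jet) from the rest
#' of the ventricle, using backward-time Lagrangian information: seeds whose
#' backward trajectories leave the blood pool through the pulmonary or
#' tricuspid orifice disc are assigned to that inflow directly (backward
#' travel time decides contested territory by construction), and the
#' remaining voxels are grown from those assignments through sub-ridge
#' voxels, where the ridge set is the FTLE field above a configurable
#' percentile within the RV. Unreached and ridge voxels default to the
#' non-PR side. KE bookkeeping is exactly conservative:
#' `KE(PR) + KE(non-PR) = KE(RV)`.
#'
#' @param ftleField an [FTLEField-class] computed backward in time on the
#'   full voxel grid at the diastolic-peak phase
#' @param rvMask logical 3D array: RV voxels at that phase
#' @param pulmMarker,tricMarker lists `list(center = c(x,y,z) mm, radius =
#'   mm)` describing the valve orifice discs
#' @param voxKe 3D array of per-voxel KE (mJ) at that phase
#' @param ridgePct FTLE ridge percentile within the RV (default 80)
#' @param exitRadiusFactor multiple of the orifice radius within which an
#'   exit point is attributed to that orifice (default 1.6)
#' @param mopUp logical; after the ridge-restricted growth, assign the
#'   remaining (ridge and unreached, typically near-zero-KE) voxels to the
#'   nearest grown region instead of defaulting them to non-PR. The
#'   ridge-restricted stage is monotone in `ridgePct`; the mop-up is not
#'   guaranteed to be.
#' @return list of class `rvPartition`: `labels` (0 outside RV, 1 PR, 2
#'   non-PR), `kePr`, `keNonPr`, `keRv` (mJ), `fractionPct`,
#'   `ridgeThreshold`, `nExitPa`, `nExitTv`
#' @export
partitionRV <- function(ftleField, rvMask, pulmMarker, tricMarker, voxKe,
                        ridgePct = 80, exitRadiusFactor = 1.6, mopUp = TRUE) {
  stopifnot(is(ftleField, "FTLEField"))
  dims <- dim(ftleField@values)
  if (!identical(dim(rvMask), dims) || !identical(dim(voxKe), dims)) {
    stopf("FTLE, RV mask and voxel-KE grids must agree")
  }
  sp <- ftleField@seedSpacing; orn <- ftleField@seedOrigin
  markerVoxel <- function(mk) {
    round((mk$center - orn) / sp)
  }
  for (mk in list(pulmMarker, tricMarker)) {
    mv <- markerVoxel(mk)
    if (any(mv < 0) || any(mv >= dims) ||
        !rvMask[mv[1] + 1, mv[2] + 1, mv[3] + 1]) {
      stopf("orifice marker at (%s) mm lies outside the RV mask",
            paste(signif(mk$center, 4), collapse = ", "))
    }
  }
  rv <- rvMask != 0
  vals <- ftleField@values
  inRv <- vals[rv]
  thr <- stats::quantile(inRv[!is.na(inRv)], ridgePct / 100, names = FALSE)
  ridge <- array(FALSE, dims)
  ridge[rv] <- !is.na(inRv) & inRv >= thr

  # Lagrangian assignment: blood that entered through a valve returns, under
  # backward advection, to that orifice's mouth.  A seed is attributed to an
  # orifice when its backward trajectory (i) actually travelled (stationary
  # seeds frozen by mask motion do not count), and (ii) ends laterally
  # within the orifice disc and axially at or above the valve plane (valve
  # discs sit at the basal pole, normal to z).  The lateral distance to the
  # valve axis is robust to along-axis overshoot or stalling at the mouth.
  rvIdx <- which(as.vector(rv))
  final <- ftleField@exitPos[rvIdx, , drop = FALSE]
  disp <- sqrt(rowSums((final - .seedPositions(ftleField, rvIdx))^2))
  moved <- disp > 1.5 * max(sp)
  zBand <- 2 * max(sp)
  dLat <- function(mk) sqrt((final[, 1] - mk$center[1])^2 +
                              (final[, 2] - mk$center[2])^2)
  atMouth <- function(mk) {
    moved & dLat(mk) <= exitRadiusFactor * mk$radius &
      final[, 3] >= mk$center[3] - zBand
  }
  dPa <- dLat(pulmMarker); dTv <- dLat(tricMarker)
  isPa <- atMouth(pulmMarker) & (dPa <= dTv | !atMouth(tricMarker))
  isTv <- atMouth(tricMarker) & !isPa
  srcPa <- rvIdx[isPa]
  srcTv <- rvIdx[isTv]
  lab <- .multiSourceGrow(dims, as.vector(rv), as.vector(ridge),
                          list(srcPa, srcTv))
  # mop-up: ridge and otherwise unreached voxels join the nearest grown
  # region (ties favour PR); with no PR evidence at all, PR stays empty
  if (mopUp && any(lab > 0L) && any(lab[rvIdx] == 0L)) {
    lab <- .multiSourceGrow(dims, as.vector(rv),
                            rep(FALSE, prod(dims)),
                            list(which(lab == 1L), which(lab == 2L)))
  }
  labels <- array(0L, dims)
  labels[rv] <- 2L                 # default: non-PR
  prIdx <- which(lab == 1L)
  labels[prIdx] <- 1L
  kePr <- sum(voxKe[prIdx])
  keRv <- sum(voxKe[rv])
  keNonPr <- keRv - kePr
  structure(list(labels = labels, kePr = kePr, keNonPr = keNonPr,
                 keRv = kePr + keNonPr,
                 fractionPct = if (keRv > 0) 100 * kePr / keRv else 0,
                 ridgeThreshold = thr, nExitPa = length(srcPa),
                 nExitTv = length(srcTv)),
            class = "rvPartition")
}

#' @export
print.rvPartition <- function(x, ...) {
  cat(sprintf(
    "RV partition: KE(PR) %.3f mJ, KE(non-PR) %.3f mJ (%.1f%% in PR)\n",
    x$kePr, x$keNonPr, x$fractionPct))
  invisible(x)
}

#' Diastolic-peak KE outside the regurgitant jet
#'
#' @param partition an `rvPartition` from [partitionRV()]
#' @return `KE(RV) - KE(PR)` in mJ, exact by construction
#' @export
keOutsidePR <- function(partition) {
  stopifnot(inherits(partition, "rvPartition"))
  partition$keNonPr
}

#' Backward FTLE at a given phase of a subject
#'
#' Convenience wrapper: seeds every voxel center, advects backward from the
#' requested phase over a horizon reaching back to end-systole (the inflow
#' history that shapes attracting structures at the diastolic peak), and
#' returns the FTLE field. Horizon and step are configurable.
#'
#' @param field a [VelocityField4D-class]
#' @param seg matching [SegmentationSeries-class] (blood-pool mask)
#' @param phase phase index at which structures are evaluated
#' @param esPhase end-systolic phase index (start of the backward horizon)
#' @param horizon signed horizon ms; default `-(t[phase] - t[esPhase])`
#' @param dt integration step ms; default one fifth of the phase spacing
#' @return an [FTLEField-class]
#' @export
ftleAtPhase <- function(field, seg, phase, esPhase, horizon = NULL, dt = NULL) {
  times <- timeStamps(field)
  horizon <- horizon %||% -(times[phase] - times[esPhase])
  if (horizon >= 0) stopf("phase must lie after end-systole for backward FTLE")
  dt <- dt %||% (cyclePeriod(field) / nPhases(field) / 5)
  fm <- advect(field, voxelSeeds(field), t0 = times[phase], horizon = horizon,
               dt = dt, bloodMask = seg)
  ftle(fm)
}
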