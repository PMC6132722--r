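# Phase-contrast preprocessing: first-order background phase correction and
# velocity anti-aliasing.  Recommended order on real data: unwrap first
# (aliased static voxels would corrupt the plane fit), then fit and subtract
# the background plane.

#' Derive a static-tissue mask
#'
#' Flags voxels whose speed is consistently small and temporally stable:
#' temporal SD of each velocity component below `sdThreshold` and
#' time-averaged speed below `speedThreshold`. Used as the default fitting
#' support for [fitBackground()].
#'
#' @param field a [VelocityField4D-class]
#' @param sdThreshold per-component temporal SD limit, cm/s
#' @param speedThreshold time-averaged speed limit, cm/s
#' @return logical 3D array
#' @export
staticTissueMask <- function(field, sdThreshold = 2, speedThreshold = 10) {
  d <- dim(field@velocity)
  nvox <- prod(d[1:3])
  ok <- rep(TRUE, nvox)
  meanSq <- rep(0, nvox)
  for (comp in 1:3) {
    m <- matrix(field@velocity[, , , , comp], nrow = nvox, ncol = d[4])
    mu <- rowMeans(m)
    sdv <- sqrt(pmax(rowMeans(m * m) - mu^2, 0) * d[4] / max(d[4] - 1, 1))
    ok <- ok & sdv < sdThreshold
    meanSq <- meanSq + mu^2
  }
  array(ok & sqrt(meanSq) < speedThreshold, dim = d[1:3])
}

#' Fit the first-order background phase plane
#'
#' Least-squares fit, per velocity component, of
#' `v = a0 + a1*i + a2*j + a3*k` (0-based voxel coordinates) to the
#' time-averaged velocity of static-tissue voxels. First-order means linear
#' in the three spatial coordinates and constant in time.
#'
#' @param field a [VelocityField4D-class]
#' @param staticMask logical 3D array of static-tissue voxels; `NULL` to
#'   derive one with [staticTissueMask()]
#' @return a [BackgroundPlane-class]
#' @export
fitBackground <- function(field, staticMask = NULL) {
  stopifnot(is(field, "VelocityField4D"))
  d <- dim(field@velocity)
  staticMask <- staticMask %||% staticTissueMask(field)
  if (!identical(dim(staticMask), d[1:3])) {
    stopf("static mask grid does not match the field")
  }
  idx <- which(staticMask)
  if (length(idx) < 4L) stopf("static mask needs at least 4 voxels")
  ijk <- arrayInd(idx, d[1:3]) - 1  # 0-based voxel coordinates
  X <- cbind(1, ijk)
  qrX <- qr(X)
  if (qrX$rank < 4L) {
    stopf("static mask voxels are coplanar/collinear; plane fit is degenerate")
  }
  coef <- matrix(0, 4, 3)
  rms <- numeric(3)
  nvox <- prod(d[1:3])
  for (comp in 1:3) {
    m <- matrix(field@velocity[, , , , comp], nrow = nvox, ncol = d[4])
    y <- rowMeans(m)[idx]
    beta <- qr.coef(qrX, y)
    coef[, comp] <- beta
    rms[comp] <- sqrt(mean((y - X %*% beta)^2))
  }
  new("BackgroundPlane", coef = coef, residualRms = rms,
      staticMask = staticMask)
}

#' Subtract a background phase plane
#'
#' Subtracts the fitted (or known) first-order offset from every voxel at
#' every phase, per component. Shape, spacing and timing metadata are
#' preserved exactly.
#'
#' @param field a [VelocityField4D-class]
#' @param plane a [BackgroundPlane-class] or bare 4 x 3 coefficient matrix
#' @return corrected [VelocityField4D-class]
#' @export
applyBackground <- function(field, plane) {
  stopifnot(is(field, "VelocityField4D"))
  coef <- if (is(plane, "BackgroundPlane")) plane@coef else as.matrix(plane)
  injectPhaseArtifacts(field, -coef, venc = NA_real_)
}

#' Correct velocity aliasing (phase unwrapping)
#'
#' Velocities beyond the encoding limit alias by multiples of `2*VENC`.
#' This routine restores them by temporal-spatial consistency region
#' growing. A voxel is trusted when its speed drops below `VENC/2` at some
#' phase of the cycle (pulsatile flow passes through slow phases, where
#' aliasing is impossible); for trusted voxels the cycle is walked
#' phase-by-phase from that most-trusted phase, assigning at each step the
#' wrap count `k` in `[-kMax, kMax]` that best matches the previous
#' (already-unwrapped) phase — a voxel's own velocity history is smooth
#' even across sharp jet boundaries where spatial neighbours jump. Voxels
#' that are never slow are then resolved per phase by spatial region
#' growing against the median of already-unwrapped 6-neighbours. All
#' corrections are exact multiples of `2*VENC`; unreachable voxels are
#' left unmodified and counted in the QC attributes.
#'
#' @param field a [VelocityField4D-class] with a finite VENC
#' @param kMax maximum wrap count searched (default 2)
#' @return a [VelocityField4D-class]; the object's `qc` attribute reports
#'   `unwrappedCount` (voxel-phases corrected) and `unresolvedCount`
#'   (voxel-phases no consensus could reach, left unmodified)
#' @export
unwrapVelocity <- function(field, kMax = 2L) {
  stopifnot(is(field, "VelocityField4D"))
  venc <- field@venc
  if (is.na(venc)) stopf("unwrapping requires a known VENC")
  d <- dim(field@velocity)
  nvox <- prod(d[1:3]); nt <- d[4]
  changed <- 0L; unresolved <- 0L
  vel <- field@velocity
  for (comp in 1:3) {
    v <- matrix(vel[, , , , comp], nrow = nvox, ncol = nt)
    # --- temporal walk for voxels that pass through a slow phase ---------
    minAbs <- do.call(pmin, lapply(seq_len(nt), function(p) abs(v[, p])))
    trusted <- which(minAbs < venc / 2)
    resolved <- matrix(FALSE, nvox, nt)
    if (length(trusted)) {
      startPh <- max.col(-abs(v[trusted, , drop = FALSE]), ties.method = "first")
      resolved[cbind(trusted, startPh)] <- TRUE
      for (step in seq_len(nt - 1L)) {
        cur <- (startPh + step - 1L) %% nt + 1L
        prv <- (startPh + step - 2L) %% nt + 1L
        iCur <- cbind(trusted, cur)
        k <- pmax(pmin(round((v[cbind(trusted, prv)] - v[iCur]) / (2 * venc)),
                       kMax), -kMax)
        v[iCur] <- v[iCur] + 2 * venc * k
        changed <- changed + sum(k != 0)
        resolved[iCur] <- TRUE
      }
    }
    # --- spatial consensus for voxels never trusted temporally -----------
    if (!all(resolved)) {
      dims3 <- d[1:3]
      shift <- function(arr, ax, by) {
        n <- dims3[ax]
        src <- seq_len(n) - by
        ok <- src >= 1L & src <= n
        out <- array(NA_real_, dim = dims3)
        idxTo <- which(ok); idxFrom <- src[ok]
        if (ax == 1) out[idxTo, , ] <- arr[idxFrom, , ]
        if (ax == 2) out[, idxTo, ] <- arr[, idxFrom, ]
        if (ax == 3) out[, , idxTo] <- arr[, , idxFrom]
        out
      }
      for (ph in seq_len(nt)) {
        vv <- array(v[, ph], dim = dims3)
        rr <- array(resolved[, ph], dim = dims3)
        repeat {
          nb <- vector("list", 6L); i <- 0L
          for (ax in 1:3) for (by in c(-1L, 1L)) {
            i <- i + 1L
            masked <- vv; masked[!rr] <- NA_real_
            nb[[i]] <- shift(masked, ax, by)
          }
          nbM <- do.call(cbind, lapply(nb, as.vector))
          nValid <- rowSums(!is.na(nbM))
          cand <- which(!as.vector(rr) & nValid > 0L)
          if (!length(cand)) break
          med <- apply(nbM[cand, , drop = FALSE], 1L,
                       stats::median, na.rm = TRUE)
          k <- pmax(pmin(round((med - vv[cand]) / (2 * venc)), kMax), -kMax)
          vv[cand] <- vv[cand] + 2 * venc * k
          changed <- changed + sum(k != 0)
          rr[cand] <- TRUE
        }
        v[, ph] <- as.vector(vv)
        resolved[, ph] <- as.vector(rr)
      }
    }
    unresolved <- unresolved + sum(!resolved)
    vel[, , , , comp] <- array(v, dim = c(d[1:3], nt))
  }
  out <- newVelocityField(vel, field@spacing, field@times, venc = venc,
                          period = field@period, origin = field@origin,
                          provenance = field@provenance)
  attr(out, "qc") <- list(unwrappedCount = changed,
                          unresolvedCount = unresolved)
  out
}
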