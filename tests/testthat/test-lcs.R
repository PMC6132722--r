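test_that("RK4 advection is exact for trivial fields", {
  seeds <- seedGrid(c(4, 4, 4), c(6, 6, 6), origin = c(6, 6, 6))
  zero <- uniformField(u = c(0, 0, 0))
  fmZ <- advect(zero, seeds, t0 = 0, horizon = 150, dt = 10)
  expect_equal(fmZ@positions, unclass(seeds)[, ], tolerance = 0,
               ignore_attr = TRUE)

  # constant field: displacement u * T exactly (RK4 exact for constants)
  uni <- uniformField(u = c(30, -20, 10))
  fmU <- advect(uni, seeds, t0 = 0, horizon = 150, dt = 10)
  expect_equal(fmU@positions,
               seeds + rep(c(30, -20, 10) * 0.01 * 150, each = nrow(seeds)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # backward horizon reverses it
  fmB <- advect(uni, seeds, t0 = 0, horizon = -150, dt = 10)
  expect_equal(fmB@positions,
               seeds - rep(c(30, -20, 10) * 0.01 * 150, each = nrow(seeds)),
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(advect(uni, seeds, t0 = 0, horizon = 5, dt = 10), "dt")
  expect_error(advect(uni, seeds, t0 = 0, horizon = 0, dt = 1), "nonzero")
})

test_that("RK4 self-convergence is fourth order on the double gyre", {
  vf <- function(t, P) doubleGyreVelocity(t, P)
  seeds <- seedGrid(c(9, 5, 1), c(0.2, 0.2, 1), origin = c(0.2, 0.1, 0))
  ref <- advect(vf, seeds, t0 = 0, horizon = 5, dt = 0.005)@positions
  errAt <- function(dt) {
    p <- advect(vf, seeds, t0 = 0, horizon = 5, dt = dt)@positions
    max(sqrt(rowSums((p - ref)^2)))
  }
  e <- vapply(c(0.4, 0.2, 0.1), errAt, 0)
  orders <- log2(e[-3] / e[-1])
  expect_true(all(orders > 3.5 & orders < 4.5))
})

test_that("FTLE vanishes for rigid motions", {
  # uniform translation
  seeds <- seedGrid(c(8, 8, 8), c(3, 3, 3), origin = c(6, 6, 6))
  f <- ftle(advect(uniformField(), seeds, t0 = 0, horizon = 120, dt = 10))
  expect_lt(max(abs(ftleValues(f)), na.rm = TRUE), 1e-12)

  # solid-body rotation (linear field: trilinear sampling is exact)
  n <- 12; ctr <- (n - 1) * 3 / 2; om <- 0.005
  arr <- array(0, dim = c(n, n, 3, 5, 3))
  x <- (0:(n - 1)) * 3; X <- matrix(rep(x, n), n); Y <- t(X)
  for (ph in 1:5) for (k in 1:3) {
    arr[, , k, ph, 1] <- -om * (Y - ctr) * 100
    arr[, , k, ph, 2] <- om * (X - ctr) * 100
  }
  rotFld <- newVelocityField(arr, c(3, 3, 3), (0:4) * 100, period = 500)
  sg <- seedGrid(c(7, 7, 1), c(3, 3, 3), origin = c(7.5, 7.5, 3))
  fR <- ftle(advect(rotFld, sg, t0 = 0, horizon = 200, dt = 1))
  expect_lt(max(abs(ftleValues(fR)), na.rm = TRUE), 1e-10)

  expect_error(ftle(advect(uniformField(),
                           seedGrid(c(2, 2, 2), c(3, 3, 3)),
                           t0 = 0, horizon = 100, dt = 10)), "3 seeds")
})

test_that("FTLE is invariant under a Galilean frame boost", {
  vf <- function(t, P) doubleGyreVelocity(t, P)
  u <- c(20, -10, 0)
  boosted <- function(t, P) {
    sh <- P
    sh[, 1] <- sh[, 1] - u[1] * 0.01 * t
    sh[, 2] <- sh[, 2] - u[2] * 0.01 * t
    v <- doubleGyreVelocity(t, sh)
    v[, 1] <- v[, 1] + u[1]; v[, 2] <- v[, 2] + u[2]
    v
  }
  sg <- seedGrid(c(24, 12, 1), c(2 / 23, 1 / 11, 1))
  f1 <- ftle(advect(vf, sg, t0 = 0, horizon = -8, dt = 0.05))
  f2 <- ftle(advect(boosted, sg, t0 = 0, horizon = -8, dt = 0.05))
  rel <- max(abs(ftleValues(f1) - ftleValues(f2)), na.rm = TRUE) /
    max(abs(ftleValues(f1)), na.rm = TRUE)
  expect_lt(rel, 1e-6)
})

test_that("gridded FTLE matches analytic advection of the same double gyre", {
  # the gridded route (trilinear/linear-in-time sampling of the stored
  # field) against the analytic velocity on identical seeds
  dg <- generateDoubleGyre(dims = c(96, 48), nPhases = 31)
  sI <- seedGrid(c(48, 24, 1), c(2 / 47, 1 / 23, 1),
                 origin = c(0, 0, voxelSpacing(dg)[3]))
  fG <- ftle(advect(dg, sI, t0 = 0, horizon = -10, dt = 0.05))
  sA <- seedGrid(c(48, 24, 1), c(2 / 47, 1 / 23, 1))
  fA <- ftle(advect(function(t, P) doubleGyreVelocity(t, P), sA,
                    t0 = 0, horizon = -10, dt = 0.05))
  vG <- as.vector(ftleValues(fG)); vA <- as.vector(ftleValues(fA))
  expect_gt(stats::cor(vG, vA, use = "complete.obs"), 0.995)
  ridgeIdx <- function(v, q = 0.95) {
    which(!is.na(v) & v >= stats::quantile(v, q, na.rm = TRUE))
  }
  jac <- length(intersect(ridgeIdx(vG), ridgeIdx(vA))) /
    length(union(ridgeIdx(vG), ridgeIdx(vA)))
  expect_gt(jac, 0.8)
})

test_that("RV partition recovers the regurgitant jet with exact KE bookkeeping", {
  b <- smallPhantom(regurgFraction = 0.36, noiseSd = 1.5, seed = 21)
  r <- runPartition(b)
  expect_gte(r$capture, 0.95)
  expect_lte(r$contamination, 0.05)
  expect_identical(r$partition$kePr + r$partition$keNonPr, r$partition$keRv)
  expect_equal(r$partition$fractionPct, unname(r$truthFracPct),
               tolerance = 0.07)
  expect_equal(keOutsidePR(r$partition), r$partition$keRv - r$partition$kePr)

  # no regurgitation: the PR region is empty, not an error
  b0 <- smallPhantom(regurgFraction = 0, noiseSd = 1.5, seed = 22)
  r0 <- runPartition(b0)
  expect_equal(r0$nPr, 0)
  expect_equal(r0$partition$fractionPct, 0)
  expect_equal(keOutsidePR(r0$partition), r0$partition$keRv)
})

test_that("more permissive ridges never shrink and never break the partition", {
  b <- smallPhantom(regurgFraction = 0.36, noiseSd = 1.5, seed = 23)
  # the ridge-restricted growth stage: lowering the percentile adds
  # barriers, so the PR region never grows
  sizes <- vapply(c(95, 85, 75, 65), function(p)
    runPartition(b, p, mopUp = FALSE)$nPr, 0L)
  expect_true(all(diff(sizes) <= 0))
  # the KE fraction itself is stable across percentiles with mop-up
  fr <- vapply(c(95, 80, 65), function(p)
    runPartition(b, p)$partition$fractionPct, 0)
  expect_lt(diff(range(fr)), 1)
})

test_that("orifice markers must lie inside the RV mask", {
  b <- smallPhantom(regurgFraction = 0.36, noiseSd = 0)
  vols <- computeVolumeCurve(b$segmentation)
  cur <- keCurve(voxelKE(b$velocity), b$segmentation)
  peak <- cur$rv$diastolicPhase
  fte <- ftleAtPhase(b$velocity, b$segmentation, peak, cur$rv$esPhase)
  dims <- gridDim(b$segmentation)
  rvMask <- labelData(b$segmentation)[, , , peak] == RV_LABEL
  keP <- array(0, dims)
  badMarker <- list(center = c(0, 0, 0), radius = 5)
  expect_error(partitionRV(fte, rvMask, badMarker, b$truth$markers$tv, keP),
               "outside the RV")
})
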