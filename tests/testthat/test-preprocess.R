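test_that("background plane fit recovers injected coefficients exactly on clean data", {
  b <- smallPhantom(noiseSd = 0, nPhases = 10)
  zero <- fitBackground(b$velocityClean, b$truth$staticMask)
  expect_lt(max(abs(zero@coef)), 1e-12)
  expect_lt(max(zero@residualRms), 1e-12)

  set.seed(401)
  for (rep in 1:3) {
    plane <- matrix(stats::runif(12, -5, 5), 4, 3)
    plane[2:4, ] <- plane[2:4, ] / 20  # gradients in cm/s per voxel
    art <- injectPhaseArtifacts(b$velocityClean, plane, venc = 100)
    fit <- fitBackground(art, b$truth$staticMask)
    expect_lt(max(abs(fit@coef - plane)), 1e-6)
  }
})

test_that("a degenerate static mask is rejected", {
  b <- smallPhantom(noiseSd = 0, nPhases = 10)
  m <- array(FALSE, gridDim(b$velocity))
  m[1:10, 1, 1] <- TRUE  # collinear voxels
  expect_error(fitBackground(b$velocity, m), "degenerate|coplanar")
  m2 <- array(FALSE, gridDim(b$velocity))
  m2[1, 1, 1] <- TRUE
  expect_error(fitBackground(b$velocity, m2), "at least 4")
})

test_that("plane-coefficient standard error shrinks like 1/sqrt(n)", {
  dims <- c(20, 20, 12)
  sigma <- 3
  a0True <- 2
  seCoef <- function(nVox) {
    set.seed(1000 + nVox)
    ests <- replicate(40, {
      idx <- sample(prod(dims), nVox)
      mask <- array(FALSE, dims); mask[idx] <- TRUE
      arr <- array(0, dim = c(dims, 2, 3))
      ijk <- arrayInd(idx, dims) - 1
      truthOff <- a0True + 0.05 * ijk[, 1] - 0.04 * ijk[, 2] + 0.02 * ijk[, 3]
      for (ph in 1:2) {
        vol <- array(0, dims)
        vol[idx] <- truthOff + stats::rnorm(nVox, 0, sigma)
        arr[, , , ph, 1] <- vol
      }
      fld <- newVelocityField(arr, c(3, 3, 3), c(0, 100), venc = 100,
                              period = 200)
      fitBackground(fld, mask)@coef[1, 1]
    })
    stats::sd(ests)
  }
  se <- vapply(c(60, 240, 960), seCoef, 0)
  # each quadrupling of n should roughly halve the SE
  expect_lt(se[2] / se[1], 0.75)
  expect_lt(se[3] / se[2], 0.75)
})

test_that("applying the fitted correction leaves no residual plane or static KE", {
  b <- smallPhantom(noiseSd = 0, nPhases = 10)
  plane <- matrix(c(2, 0.05, -0.03, 0.02, -1, 0.01, 0.02, -0.04,
                    0.5, -0.02, 0.01, 0.03), 4, 3)
  art <- injectPhaseArtifacts(b$velocityClean, plane, venc = 100)
  fit <- fitBackground(art, b$truth$staticMask)
  corr <- applyBackground(art, fit)
  refit <- fitBackground(corr, b$truth$staticMask)
  expect_lt(max(abs(refit@coef)), 1e-9)
  # static-tissue KE never increases under correction
  keStatic <- function(fld) {
    v2 <- velocityData(fld)[, , , , 1]^2 + velocityData(fld)[, , , , 2]^2 +
      velocityData(fld)[, , , , 3]^2
    sum(v2[rep(b$truth$staticMask, nPhases(fld))])
  }
  expect_lt(keStatic(corr), keStatic(art))
  # zero plane is the identity
  same <- applyBackground(art, matrix(0, 4, 3))
  expect_identical(velocityData(same), velocityData(art))
  # metadata preserved exactly
  expect_identical(voxelSpacing(corr), voxelSpacing(art))
  expect_identical(timeStamps(corr), timeStamps(art))
})

test_that("unwrapping is the identity on fields below VENC/2", {
  f <- uniformField(u = c(30, -20, 10))
  f@venc <- 100
  uw <- unwrapVelocity(f)
  expect_equal(velocityData(uw), velocityData(f), tolerance = 0)
})

test_that("a wrapped voxel inside a smooth ramp is restored by spatial consensus", {
  # ramp 0 -> 120 cm/s with sub-VENC increments; the top aliases to -80
  arr <- array(0, dim = c(24, 5, 5, 3, 3))
  ramp <- seq(0, 120, length.out = 24)
  for (ph in 1:3) arr[, , , ph, 1] <- ramp
  fld <- newVelocityField(arr, c(3, 3, 3), c(0, 100, 200), venc = 100,
                          period = 300)
  wrapped <- injectPhaseArtifacts(fld, matrix(0, 4, 3), venc = 100)
  expect_equal(velocityData(wrapped)[24, 3, 3, 1, 1], -80)
  uw <- unwrapVelocity(wrapped)
  expect_equal(velocityData(uw), arr, tolerance = 1e-9)
})

test_that("wrap-then-unwrap is the identity on phantom jets at 1.8x VENC", {
  b <- smallPhantom(noiseSd = 0,
                    jetSpeeds = c(ao = 100, mi = 60, pa = 70, tv = 55,
                                  pr = 180))
  expect_gt(max(abs(velocityData(b$velocity) -
                      velocityData(b$velocityClean))), 100)  # really aliased
  uw <- unwrapVelocity(b$velocity)
  expect_equal(velocityData(uw), velocityData(b$velocityClean),
               tolerance = 1e-9)
  qc <- attr(uw, "qc")
  expect_gt(qc$unwrappedCount, 0)
})

test_that("unwrap and background correction commute on mildly corrupted phantoms", {
  b <- smallPhantom(noiseSd = 0,
                    jetSpeeds = c(ao = 100, mi = 60, pa = 70, tv = 55,
                                  pr = 150))
  plane <- matrix(c(1.5, 0.02, -0.01, 0.01, -0.8, 0.01, 0.015, -0.01,
                    0.4, -0.01, 0.005, 0.02), 4, 3)
  art <- injectPhaseArtifacts(b$velocityClean, plane, venc = 100)
  a <- applyBackground(unwrapVelocity(art),
                       fitBackground(unwrapVelocity(art), b$truth$staticMask))
  bb <- unwrapVelocity(applyBackground(
    art, fitBackground(art, b$truth$staticMask)))
  expect_equal(velocityData(a), velocityData(bb), tolerance = 1e-6)
})
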