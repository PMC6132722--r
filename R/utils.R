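# Internal helpers shared across modules.
#
# Unit conventions used throughout the package (asserted at I/O):
#   positions  : mm, world coordinate = origin + 0-based voxel index * spacing
#   velocities : cm/s (1 cm/s = 0.01 mm/ms)
#   time       : ms from the R-wave
#   flow       : ml/s, antegrade (forward) positive
#   energy     : mJ at aggregation level

.CMS_TO_MM_PER_MS <- 0.01

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# trapezoidal integral of y(x); thin wrapper so the quadrature rule is one place
trapzInt <- function(x, y) {
  if (length(x) < 2L) return(0)
  pracma::trapz(x, y)
}

# raised-cosine bump of unit peak on [a, a + w], zero elsewhere
raisedCosine <- function(t, a, w) {
  u <- (t - a) / w
  out <- numeric(length(t))
  inside <- u >= 0 & u <= 1
  out[inside] <- 0.5 * (1 - cos(2 * pi * u[inside]))
  out
}

# CDF of the unit-integral raised cosine on [a, a + w]
raisedCosineCdf <- function(t, a, w) {
  u <- pmin(pmax((t - a) / w, 0), 1)
  u - sin(2 * pi * u) / (2 * pi)
}

# world coordinates of voxel centers along one axis (0-based convention)
axisCoords <- function(n, spacing, origin = 0) origin + (seq_len(n) - 1) * spacing

# 3D arrays of voxel-center world coordinates
coordArrays <- function(dims, spacing, origin = c(0, 0, 0)) {
  x <- axisCoords(dims[1], spacing[1], origin[1])
  y <- axisCoords(dims[2], spacing[2], origin[2])
  z <- axisCoords(dims[3], spacing[3], origin[3])
  list(
    X = array(rep(x, times = dims[2] * dims[3]), dim = dims),
    Y = array(rep(rep(y, each = dims[1]), times = dims[3]), dim = dims),
    Z = array(rep(z, each = dims[1] * dims[2]), dim = dims)
  )
}

# linear index into a column-major array of dimension `dims` (all 1-based)
linearIndex3 <- function(i, j, k, dims) {
  i + dims[1] * ((j - 1) + dims[2] * (k - 1))
}

assertFinite <- function(x, what) {
  if (!all(is.finite(x))) stopf("%s contains non-finite values", what)
  invisible(TRUE)
}
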