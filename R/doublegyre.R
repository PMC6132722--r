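# Periodically perturbed double gyre on [0,2] x [0,1]: the standard benchmark
# flow for validating FTLE/LCS machinery. Stream function
#   psi(x, y, t) = A sin(pi f(x, t)) sin(pi y)
#   f(x, t)      = eps sin(omega t) x^2 + (1 - 2 eps sin(omega t)) x
# so u = -d(psi)/dy, v = d(psi)/dx and the field is divergence-free by
# construction.

#' Analytic double-gyre velocity
#'
#' Evaluates the classical periodically perturbed double-gyre flow at
#' arbitrary positions and time. Nondimensional domain units are mapped onto
#' the package conventions as 1 domain unit = 1 mm and 1 time unit = 1 ms,
#' so a nondimensional speed `u` is stored/returned as `100 * u` cm/s.
#'
#' @param t time, ms
#' @param pos n x 3 matrix of positions, mm (third column ignored)
#' @param amplitude gyre strength A
#' @param epsilon perturbation amplitude of the gyre boundary
#' @param omega angular frequency of the perturbation, rad/ms
#' @return n x 3 matrix of velocities in cm/s (zero third component)
#' @export
doubleGyreVelocity <- function(t, pos, amplitude = 0.1, epsilon = 0.25,
                               omega = 2 * pi / 10) {
  x <- pos[, 1]
  y <- pos[, 2]
  st <- sin(omega * t)
  f <- epsilon * st * x^2 + (1 - 2 * epsilon * st) * x
  dfdx <- 2 * epsilon * st * x + (1 - 2 * epsilon * st)
  u <- -pi * amplitude * sin(pi * f) * cos(pi * y)
  v <- pi * amplitude * cos(pi * f) * sin(pi * y) * dfdx
  cbind(u, v, 0) / .CMS_TO_MM_PER_MS  # mm/ms -> cm/s
}

#' Gridded double-gyre velocity field
#'
#' Samples the analytic double gyre onto a regular grid over
#' \eqn{[0,2]\times[0,1]}, replicated in a thin slab along z with zero third
#' velocity component, over `nPhases` samples of one perturbation period.
#' The grid uses the package world-coordinate convention with 1 domain unit
#' mapped to 1 mm; the period is recorded in the field metadata so advection
#' wraps cyclically.
#'
#' @param amplitude,epsilon,omega flow parameters (see
#'   [doubleGyreVelocity()])
#' @param dims in-plane grid size `c(nx, ny)`; at least 32 x 16
#' @param nPhases number of time samples over one period (>= 2)
#' @param period perturbation period in ms; must equal `2*pi/omega` up to
#'   tolerance
#' @param nz slab thickness in voxels (default 3)
#' @return a [VelocityField4D-class]
#' @examples
#' fld <- generateDoubleGyre(dims = c(32, 16), nPhases = 5)
#' gridDim(fld)
#' @export
generateDoubleGyre <- function(amplitude = 0.1, epsilon = 0.25,
                               omega = 2 * pi / 10, dims = c(64, 32),
                               nPhases = 21, period = 2 * pi / omega,
                               nz = 3L) {
  if (length(dims) != 2L || any(dims < c(32, 16))) {
    stopf("double gyre requires an in-plane grid of at least 32 x 16")
  }
  if (period <= 0 || nPhases < 2L) stopf("period and phase count must be positive")
  if (abs(period - 2 * pi / omega) > 1e-9 * period) {
    stopf("period must match 2*pi/omega for a cyclic field")
  }
  nx <- as.integer(dims[1]); ny <- as.integer(dims[2]); nz <- as.integer(nz)
  sx <- 2 / (nx - 1); sy <- 1 / (ny - 1)
  # thin slab: keep z spacing comparable to in-plane spacing
  sz <- sy
  times <- seq(0, period, length.out = nPhases + 1L)[seq_len(nPhases)]
  pos <- cbind(rep(axisCoords(nx, sx), times = ny),
               rep(axisCoords(ny, sy), each = nx), 0)
  vel <- array(0, dim = c(nx, ny, nz, nPhases, 3))
  for (ph in seq_len(nPhases)) {
    v <- doubleGyreVelocity(times[ph], pos, amplitude, epsilon, omega)
    plane <- array(v[, 1:2], dim = c(nx, ny, 2))
    for (k in seq_len(nz)) {
      vel[, , k, ph, 1] <- plane[, , 1]
      vel[, , k, ph, 2] <- plane[, , 2]
    }
  }
  newVelocityField(vel, spacing = c(sx, sy, sz), times = times,
                   venc = NA_real_, period = period,
                   provenance = sprintf(
                     "double gyre A=%g eps=%g omega=%g", amplitude, epsilon,
                     omega))
}
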