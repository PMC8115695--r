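#' Time course of the reference displacement field
#'
#' `g(t) = rho * t / P + (1 - rho) * 0.5 * (1 - cos(2 pi t / P))`: a linear
#' plastic ramp superposed on raised-cosine contraction/relaxation cycles.
#' `g(0) = 0`; with `rho = 0` the field returns to zero at every period
#' boundary and peaks (at 1) mid-period; with `rho = 1` deformation
#' accumulates linearly, gaining `rho` per period.
#'
#' @param t Time(s), minutes.
#' @param params A [field_params()] (only `period` and `plastic_fraction`
#'   are used).
#' @return Numeric vector, dimensionless field scale at each `t`.
#' @export
field_time_profile <- function(t, params) {
  stopifnot(inherits(params, "field_params"))
  rho <- params$plastic_fraction
  P <- params$period
  rho * t / P + (1 - rho) * 0.5 * (1 - cos(2 * pi * t / P))
}

#' Build the tip-centred displacement field function
#'
#' Returns the field `u(x, t)` described in [field_params()]: anisotropic
#' (cosine-power in the angle to the branch axis, zero behind the tip
#' plane), exponentially decaying with distance to the tip, periodically
#' contracting/relaxing with a plastic ramp, and always pointing from the
#' material point toward the tip. This is the ground-truth deformation that
#' the synthetic scenes advect beads with, and the closed form that
#' parameter-recovery tests compare against.
#'
#' @param params A [field_params()].
#' @return A function `u(x, t)` where `x` is an `n x 3` matrix (or length-2/3
#'   vector) of positions in µm and `t` a scalar time in minutes; returns an
#'   `n x 3` matrix of displacements in µm. Total function: defined for all
#'   inputs (at the tip itself the direction is taken as `-axis`).
#' @examples
#' fp <- field_params(4, 100, 2, 60, 0.5, tip = c(0, 0), axis = c(1, 0))
#' u <- make_displacement_field(fp)
#' u(c(50, 0), 30)   # on-axis point, mid-period
#' @export
make_displacement_field <- function(params) {
  stopifnot(inherits(params, "field_params"))
  tip <- params$tip
  axis <- params$axis
  A <- params$amplitude
  lam <- params$decay_length
  k <- params$anisotropy
  force(params)

  function(x, t) {
    if (is.null(dim(x))) x <- matrix(as_xyz(x, "x"), 1L, 3L)
    stopifnot(ncol(x) == 3L, length(t) == 1L)
    d <- sweep(x, 2, tip)                 # tip -> point vectors
    r <- sqrt(rowSums(d^2))
    ct <- rep(1, nrow(x))                 # cos(theta); 1 at the tip itself
    ok <- r > 0
    ct[ok] <- (d[ok, , drop = FALSE] %*% axis) / r[ok]
    ang <- ifelse(ct > 0, ct^k, 0)        # cos^k for theta <= 90 deg, else 0
    if (k == 0) ang <- as.numeric(ct >= 0)
    mag <- A * ang * exp(-r / lam) * field_time_profile(t, params)
    e <- matrix(rep(-axis, each = nrow(x)), ncol = 3L)  # direction at tip
    e[ok, ] <- -d[ok, , drop = FALSE] / r[ok]           # unit x -> tip
    e * mag
  }
}
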