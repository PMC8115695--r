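#' Branch geometry: tip position and outward axis
#'
#' The reference frame for every deformation statistic. The tip is the
#' invasive front of an organoid branch; the axis is the outward unit vector
#' of branch elongation. Angles `theta` are measured between the tip-to-bead
#' vector and this axis, so `theta = 0` is the ECM directly in front of the
#' branch. The near field is the ECM between the tip and `near_field_um`
#' ahead of it (300 µm by convention).
#'
#' @param tip Tip position `(x, y[, z])` in µm.
#' @param axis Outward direction `(x, y[, z])`; normalized internally.
#' @param near_field_um Near-field radius in µm (default 300).
#' @return An object of class `branch_geometry`.
#' @examples
#' geo <- branch_geometry(tip = c(50, 50), axis = c(1, 0))
#' @export
branch_geometry <- function(tip, axis, near_field_um = 300) {
  tip <- as_xyz(tip, "tip")
  axis <- unit_vector(as_xyz(axis, "axis"))
  if (near_field_um <= 0) abort("`near_field_um` must be positive")
  structure(list(tip = tip, axis = axis, near_field_um = near_field_um),
            class = "branch_geometry")
}

#' @export
print.branch_geometry <- function(x, ...) {
  cat(sprintf("<branch_geometry: tip (%s) um, axis (%s), near field %g um>\n",
              paste(signif(x$tip, 4), collapse = ", "),
              paste(signif(x$axis, 3), collapse = ", "),
              x$near_field_um))
  invisible(x)
}

#' Read / write branch geometry as JSON
#'
#' @param geometry A [branch_geometry()].
#' @param path JSON file path.
#' @return `read_geometry_json()` returns a [branch_geometry()].
#' @export
write_geometry_json <- function(geometry, path) {
  jsonlite::write_json(
    list(tip = unname(geometry$tip), axis = unname(geometry$axis),
         near_field_um = geometry$near_field_um),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  branch_geometry(g$tip, g$axis, g$near_field_um %||% 300)
}

#' Parameters of the reference tip-centred displacement field
#'
#' The synthetic ECM displacement field used as ground truth throughout the
#' package. A material point at position `x` experiences
#'
#' \deqn{u(x, t) = A \cos^k\theta(x)\,[\theta \le 90^\circ]\;
#'       e^{-r(x)/\lambda}\; g(t)\; \hat e(x \to tip)}
#'
#' where `r`, `theta` are the distance and angle of `x` from the tip/axis,
#' `\hat e` points from `x` toward the tip (so positive field values are
#' contractions toward the branch), and the time course
#'
#' \deqn{g(t) = \rho\,t/P + (1 - \rho)\,\tfrac12(1 - \cos 2\pi t/P)}
#'
#' combines a linear plastic ramp (fraction `rho`) with raised-cosine
#' contraction/relaxation cycles of period `P` (fraction `1 - rho`). The
#' form reproduces the three hallmarks of tip-driven matrix deformation:
#' decay with angle, decay with distance, and periodic contraction cycles
#' with a net plastic gain of `rho * A` per period.
#'
#' @param amplitude Peak per-period displacement at the tip, µm.
#' @param decay_length Radial decay length `lambda`, µm.
#' @param anisotropy Angular exponent `k >= 0`; `k = 0` is isotropic within
#'   the forward half-space.
#' @param period Contraction/relaxation period `P`, minutes.
#' @param plastic_fraction Plastic fraction `rho` in `[0, 1]`.
#' @param tip,axis Branch geometry (see [branch_geometry()]).
#' @return An object of class `field_params`.
#' @examples
#' fp <- field_params(amplitude = 4, decay_length = 100, anisotropy = 2,
#'                    period = 60, plastic_fraction = 0.5,
#'                    tip = c(0, 50), axis = c(1, 0))
#' @export
field_params <- function(amplitude, decay_length, anisotropy = 2,
                         period = 60, plastic_fraction = 0.5,
                         tip = c(0, 0, 0), axis = c(1, 0, 0)) {
  if (decay_length <= 0) abort("`decay_length` must be > 0")
  if (period <= 0) abort("`period` must be > 0")
  if (anisotropy < 0) abort("`anisotropy` must be >= 0")
  if (plastic_fraction < 0 || plastic_fraction > 1) {
    abort("`plastic_fraction` must be in [0, 1]")
  }
  structure(
    list(amplitude = amplitude, decay_length = decay_length,
         anisotropy = anisotropy, period = period,
         plastic_fraction = plastic_fraction,
         tip = as_xyz(tip, "tip"), axis = unit_vector(as_xyz(axis, "axis"))),
    class = "field_params")
}

#' @export
print.field_params <- function(x, ...) {
  cat(sprintf(
    "<field_params: A = %g um, lambda = %g um, k = %g, P = %g min, rho = %g>\n",
    x$amplitude, x$decay_length, x$anisotropy, x$period, x$plastic_fraction))
  invisible(x)
}
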