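#' Pyramidal tip geometry for Hertz--Sneddon contact
#'
#' Describes the indenter entering the quadratic contact law
#' \deqn{F = C \tan(\theta) \frac{E_a}{1-\nu^2} \delta^2}
#' where \eqn{\theta} is the effective face half-angle of the pyramid,
#' \eqn{\nu} the Poisson ratio of the sample and \eqn{C} a dimensionless
#' geometry prefactor. The default \eqn{C = 2/\pi} is the Sneddon cone of
#' equivalent half-angle; \eqn{C = 0.7453} selects the four-sided-pyramid
#' variant. The nominal tip radius is retained as metadata only: the model
#' is the sharp-tip idealization and no blunting correction is applied.
#'
#' @param half_angle effective face half-angle of the pyramid, degrees.
#' @param radius nominal apex radius, nm (informational).
#' @param geometry_coefficient dimensionless prefactor \eqn{C} of the
#'   quadratic contact law.
#' @param poisson_ratio Poisson ratio \eqn{\nu} of the sample; 0.5 is the
#'   incompressible limit usual for hydrated biological material.
#' @return an object of class `"tip_geometry"`.
#' @examples
#' tip_geometry()                        # Sneddon cone, 20 degrees, nu = 0.5
#' tip_geometry(geometry_coefficient = 0.7453)  # four-sided pyramid
#' @export
tip_geometry <- function(half_angle = 20, radius = 10,
                         geometry_coefficient = 2 / pi,
                         poisson_ratio = 0.5) {
  stopifnot_scalar(half_angle, "half_angle", 0, 90,
                   open_lower = TRUE, open_upper = TRUE)
  stopifnot_scalar(radius, "radius", 0, Inf, open_lower = TRUE)
  stopifnot_scalar(geometry_coefficient, "geometry_coefficient", 0, Inf,
                   open_lower = TRUE)
  stopifnot_scalar(poisson_ratio, "poisson_ratio", 0, 0.5)
  structure(
    list(half_angle = half_angle, radius = radius,
         geometry_coefficient = geometry_coefficient,
         poisson_ratio = poisson_ratio),
    class = "tip_geometry")
}

# Contact-law prefactor in nN/nm^2 per MPa of modulus.
tip_prefactor <- function(tip) {
  tip$geometry_coefficient * tan(tip$half_angle * pi / 180) /
    (1 - tip$poisson_ratio^2) * .MPA_NM2_TO_NN
}

#' @export
print.tip_geometry <- function(x, ...) {
  cat(sprintf(
    "Pyramidal tip: half-angle %.1f deg, C = %.4f, nu = %.2f (radius %.0f nm)\n",
    x$half_angle, x$geometry_coefficient, x$poisson_ratio, x$radius))
  invisible(x)
}

#' Hertz--Sneddon forward model for a pyramidal tip
#'
#' Vertical force exerted by a rigid pyramid indenting an elastic
#' half-space to depth `delta`. Units are fixed across the package:
#' modulus in MPa, depth in nm, force in nN.
#'
#' @param ea apparent elastic modulus, MPa (> 0).
#' @param delta indentation depth(s), nm (>= 0); vectorized.
#' @param tip a [tip_geometry()].
#' @return force in nN, same length as `delta`.
#' @examples
#' tip <- tip_geometry()
#' hertz_pyramid_force(1000, 50, tip)  # ~772 nN
#' @export
hertz_pyramid_force <- function(ea, delta, tip = tip_geometry()) {
  stopifnot_scalar(ea, "ea", 0, Inf, open_lower = TRUE,
                   class = "cm_domain_error")
  if (!is.numeric(delta) || any(!is.finite(delta)) || any(delta < 0))
    cm_abort("'delta' must be finite and non-negative", "cm_domain_error")
  stopifnot(inherits(tip, "tip_geometry"))
  tip_prefactor(tip) * ea * delta^2
}
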