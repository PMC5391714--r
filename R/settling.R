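#' Terminal settling velocity of a pollen grain
#'
#' Stokes' law for a small sphere falling in still air:
#' \deqn{v_s = \frac{(\rho_p - \rho_a)\, g\, d^2}{18\,\eta}}
#' with grain density \eqn{\rho_p}, air density \eqn{\rho_a}, gravity
#' \eqn{g}, grain diameter \eqn{d} and dynamic viscosity \eqn{\eta}.
#' Valid in the low-Reynolds-number regime that covers pollen of the
#' major wind-pollinated crops (diameters up to a few hundred microns).
#'
#' @param diameter pollen grain diameter in micrometres; must lie in
#'   (0, 500].
#' @param constants a \code{\link{pmgf_constants}} object.
#' @return Settling velocity in m/s (strictly positive scalar).
#' @examples
#' settling_velocity(40)    # rice pollen, ~0.048 m/s
#' settling_velocity(100)   # maize pollen, ~0.30 m/s
#' @export
settling_velocity <- function(diameter, constants = pmgf_constants()) {
  diameter <- check_param(diameter, "pollen_diameter")
  d <- diameter * 1e-6
  (constants$grain_density - constants$air_density) * constants$gravity * d^2 /
    (18 * constants$viscosity)
}
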