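#' Build a pollen dispersal kernel from measurable inputs
#'
#' Constructs the wind-dispersal kernel used by the gene-flow model from
#' pollen release height, wind speed and settling velocity (itself derived
#' from pollen diameter via [settling_velocity()]).
#'
#' The kernel is a two-component inverse-Gaussian (WALD-family) mixture:
#' a wind-borne component with mean \code{drift_fraction * H * U / v_s} and
#' shape \code{shape_coef * H}, plus a calm-air component
#' (weight \code{calm_fraction}) describing pollen released during wind
#' lulls that deposits within the first decimetres of the canopy edge.
#' The mixture coefficients live in [pmgf_constants()] and were calibrated
#' once against the published rice/wheat/maize case studies (see the methods
#' vignette). The ballistic drift scale \eqn{\mu = H U / v_s} is kept as the
#' kernel's \code{mu} field.
#'
#' @param release_height pollen release height H in metres, (0, 100].
#' @param wind_speed horizontal wind speed U at canopy height in m/s, (0, 50].
#' @param settling_velocity settling velocity v_s in m/s; computed from
#'   \code{diameter} when omitted.
#' @param diameter pollen diameter in micrometres (used when
#'   \code{settling_velocity} is missing).
#' @param constants a [pmgf_constants()] object.
#' @return An object of class \code{"pmgf_kernel"}: a list with fields
#'   \code{mu} (ballistic drift scale H U / v_s, m), \code{lam}
#'   (wind-borne shape, m), \code{settling_velocity}, \code{release_height},
#'   \code{wind_speed}, and the mixture components.
#' @examples
#' k <- pmgf_kernel(release_height = 0.5, wind_speed = 1, diameter = 40)
#' k$mu                     # ~10.4 m for the rice parameter set
#' kernel_cdf(k, c(1, 10, 80))
#' @export
pmgf_kernel <- function(release_height, wind_speed, settling_velocity = NULL,
                        diameter = NULL, constants = pmgf_constants()) {
  release_height <- check_param(release_height, "release_height")
  wind_speed     <- check_param(wind_speed, "wind_speed")
  if (is.null(settling_velocity)) {
    if (is.null(diameter))
      stop("supply either settling_velocity or diameter", call. = FALSE)
    settling_velocity <- settling_velocity(diameter, constants)
  } else {
    settling_velocity <- check_positive(settling_velocity, "settling_velocity")
  }
  mu <- release_height * wind_speed / settling_velocity
  k <- list(
    mu                = mu,
    lam               = constants$shape_coef * release_height,
    settling_velocity = settling_velocity,
    release_height    = release_height,
    wind_speed        = wind_speed,
    drift_mean        = constants$drift_fraction * mu,
    calm_fraction     = constants$calm_fraction,
    calm_mean         = constants$calm_mean_frac * release_height,
    calm_shape        = constants$calm_shape_frac * release_height
  )
  stopifnot(all(vapply(k, function(v) is.finite(v) && v > 0, logical(1))))
  class(k) <- "pmgf_kernel"
  k
}

#' @export
print.pmgf_kernel <- function(x, ...) {
  cat("Pollen dispersal kernel (two-component inverse Gaussian)\n")
  cat(sprintf("  release height   %.3g m,  wind speed %.3g m/s\n",
              x$release_height, x$wind_speed))
  cat(sprintf("  settling velocity %.4g m/s\n", x$settling_velocity))
  cat(sprintf("  drift scale mu    %.4g m (wind-borne mean %.4g m, shape %.4g m)\n",
              x$mu, x$drift_mean, x$lam))
  cat(sprintf("  calm component    weight %.3g, mean %.3g m, shape %.3g m\n",
              x$calm_fraction, x$calm_mean, x$calm_shape))
  invisible(x)
}

#' Dispersal kernel density and cumulative distribution
#'
#' Evaluate the probability density (deposition per metre) or the cumulative
#' distribution \eqn{\Phi(x)} (fraction of pollen deposited within distance
#' \eqn{x}) of a [pmgf_kernel()].
#'
#' @param kernel a \code{"pmgf_kernel"} object.
#' @param x distances in metres (any numeric vector; non-positive distances
#'   give 0).
#' @param method passed to [pwald()]: \code{"closed"} (default) or
#'   \code{"simpson"}.
#' @return Numeric vector, same length as \code{x}.
#' @export
kernel_cdf <- function(kernel, x, method = c("closed", "simpson")) {
  stopifnot(inherits(kernel, "pmgf_kernel"))
  method <- match.arg(method)
  w <- kernel$calm_fraction
  w * pwald(x, kernel$calm_mean, kernel$calm_shape, method = method) +
    (1 - w) * pwald(x, kernel$drift_mean, kernel$lam, method = method)
}

#' @rdname kernel_cdf
#' @export
kernel_pdf <- function(kernel, x) {
  stopifnot(inherits(kernel, "pmgf_kernel"))
  w <- kernel$calm_fraction
  w * dwald(x, kernel$calm_mean, kernel$calm_shape) +
    (1 - w) * dwald(x, kernel$drift_mean, kernel$lam)
}
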