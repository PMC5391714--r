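#' Physical and dispersal constants
#'
#' Bundle of the physical constants used by the settling-velocity and
#' dispersal-kernel calculations, plus the calibrated coefficients of the
#' dispersal parameterization. All values can be overridden, e.g. to use a
#' measured pollen grain density instead of the default.
#'
#' @details
#' Physics (SI units):
#' \describe{
#'   \item{grain_density}{pollen grain mass density, kg/m^3 (default 1000)}
#'   \item{air_density}{air density, kg/m^3 (default 1.2)}
#'   \item{viscosity}{dynamic viscosity of air, Pa s (default 1.81e-5)}
#'   \item{gravity}{gravitational acceleration, m/s^2 (default 9.81)}
#' }
#' Dispersal parameterization (dimensionless, calibrated once against the
#' published rice/wheat/maize case studies; see the methods vignette):
#' \describe{
#'   \item{drift_fraction}{effective advective wind as a fraction of the
#'     measured canopy-top wind speed (log-profile reduction)}
#'   \item{shape_coef}{inverse-Gaussian shape parameter per metre of release
#'     height for the wind-borne component}
#'   \item{calm_fraction}{fraction of pollen released during wind lulls and
#'     deposited within the first decimetres}
#'   \item{calm_mean_frac, calm_shape_frac}{mean and shape of the calm-air
#'     component, per metre of release height}
#' }
#'
#' @param ... named overrides of any constant listed above.
#' @return A named list of class \code{"pmgf_constants"}.
#' @examples
#' pmgf_constants()
#' pmgf_constants(grain_density = 1200)
#' @export
pmgf_constants <- function(...) {
  const <- list(
    grain_density   = 1000,
    air_density     = 1.2,
    viscosity       = 1.81e-5,
    gravity         = 9.81,
    drift_fraction  = 0.7622,
    shape_coef      = 2.9989,
    calm_fraction   = 0.5020,
    calm_mean_frac  = 0.1100,
    calm_shape_frac = 29.13
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(const))
    if (length(bad))
      stop("unknown constant(s): ", paste(bad, collapse = ", "), call. = FALSE)
    for (nm in names(over)) {
      v <- over[[nm]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
        stop("constant '", nm, "' must be a single positive number", call. = FALSE)
      const[[nm]] <- as.numeric(v)
    }
  }
  if (const$grain_density <= const$air_density)
    stop("grain_density must exceed air_density", call. = FALSE)
  if (const$calm_fraction >= 1)
    stop("calm_fraction must be below 1", call. = FALSE)
  class(const) <- "pmgf_constants"
  const
}

#' @export
print.pmgf_constants <- function(x, ...) {
  cat("PMGF physical and dispersal constants\n")
  for (nm in names(x)) cat(sprintf("  %-16s %g\n", nm, x[[nm]]))
  invisible(x)
}
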