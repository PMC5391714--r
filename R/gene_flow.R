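#' Pollen-mediated gene flow model
#'
#' Constructor for the PMGF calculator. Takes the five measurable parameters
#' (or a species preset), builds the dispersal kernel and returns a model
#' object whose methods give the gene-flow frequency at any distance
#' ([frequency_at()], [predict.pmgf()]), frequency-decline curves
#' ([frequency_curve()]) and threshold isolation distances
#' ([isolation_distance()]).
#'
#' The underlying model is a pollen-competition equation: at distance
#' \eqn{x} from the donor field edge, the fraction of seeds on a recipient
#' plant sired by donor pollen is
#' \deqn{F(x) = \frac{t_B\,\delta\,D_A(x)}{\delta\,D_A(x) + D_B(x)}}
#' with outcrossing rate \eqn{t_B}, donor-recipient crossability
#' \eqn{\delta}, donor pollen dose
#' \eqn{D_A = \Phi(x+b) - \Phi(x)} (donor depth \eqn{b}, infinite by default:
#' \eqn{D_A = 1 - \Phi(x)}, the worst-case assessment) and recipient
#' self-pollen dose \eqn{D_B = \Phi(x - R)} (recipient offset \eqn{R},
#' 0 by default). \eqn{\Phi} is the dispersal-kernel CDF of
#' [pmgf_kernel()]. \eqn{F} is always in \eqn{[0, t_B]}.
#'
#' @param pollen_diameter pollen diameter, micrometres, (0, 500].
#' @param release_height pollen release height, metres, (0, 100].
#' @param outcrossing_rate outcrossing rate of the recipient, percent,
#'   (0, 100].
#' @param crossability donor-recipient crossability, percent, (0, 100].
#' @param wind_speed horizontal wind speed at canopy height, m/s, (0, 50].
#' @param preset optional species preset name (\code{"rice"},
#'   \code{"wheat"}, \code{"maize"}) or a \code{"pmgf_preset"} object;
#'   explicitly supplied parameters override the preset's values.
#' @param donor_depth along-wind donor field depth \eqn{b} in metres, or
#'   \code{Inf} (default) for the worst-case assessment.
#' @param recipient_offset recipient offset \eqn{R} in metres (>= 0).
#' @param constants a [pmgf_constants()] object.
#' @return An object of class \code{"pmgf"}.
#' @examples
#' m <- pmgf(preset = "rice")
#' predict(m, distance = 0.3)           # percent
#' m2 <- pmgf(preset = "maize", wind_speed = 3)
#' predict(m2, distance = 50)
#' @export
pmgf <- function(pollen_diameter = NULL, release_height = NULL,
                 outcrossing_rate = NULL, crossability = NULL,
                 wind_speed = NULL, preset = NULL,
                 donor_depth = Inf, recipient_offset = 0,
                 constants = pmgf_constants()) {
  if (!is.null(preset)) {
    p <- if (inherits(preset, "pmgf_preset")) preset else pmgf_preset(preset)
    if (is.null(pollen_diameter))  pollen_diameter  <- p$pollen_diameter
    if (is.null(release_height))   release_height   <- p$release_height
    if (is.null(outcrossing_rate)) outcrossing_rate <- p$outcrossing_rate
    if (is.null(crossability))     crossability     <- p$crossability
    if (is.null(wind_speed))       wind_speed       <- p$wind_speed
  }
  missing_fields <- c("pollen_diameter", "release_height", "outcrossing_rate",
                      "crossability", "wind_speed")[
    vapply(list(pollen_diameter, release_height, outcrossing_rate,
                crossability, wind_speed), is.null, logical(1))]
  if (length(missing_fields))
    stop("missing parameter(s): ", paste(missing_fields, collapse = ", "),
         call. = FALSE)
  pollen_diameter  <- check_param(pollen_diameter,  "pollen_diameter")
  release_height   <- check_param(release_height,   "release_height")
  outcrossing_rate <- check_param(outcrossing_rate, "outcrossing_rate")
  crossability     <- check_param(crossability,     "crossability")
  wind_speed       <- check_param(wind_speed,       "wind_speed")
  if (!identical(donor_depth, Inf)) donor_depth <- check_positive(donor_depth, "donor_depth")
  recipient_offset <- check_nonneg(recipient_offset, "recipient_offset")

  kernel <- pmgf_kernel(release_height, wind_speed,
                        diameter = pollen_diameter, constants = constants)
  obj <- list(
    params = c(pollen_diameter = pollen_diameter,
               release_height = release_height,
               outcrossing_rate = outcrossing_rate,
               crossability = crossability,
               wind_speed = wind_speed),
    t_B    = outcrossing_rate / 100,
    delta  = crossability / 100,
    donor_depth = donor_depth,
    recipient_offset = recipient_offset,
    kernel = kernel,
    constants = constants
  )
  class(obj) <- "pmgf"
  obj
}

#' Gene-flow frequency at given distances
#'
#' Evaluates the pollen-competition equation of a [pmgf()] model.
#'
#' When \code{x <= recipient_offset} (with infinite donor depth) the
#' recipient dose is zero and the frequency equals the outcrossing rate
#' exactly; this is the documented near-field limit, not an error.
#'
#' @param model a \code{"pmgf"} object.
#' @param x distances from the donor field edge, metres (> 0).
#' @return Gene-flow frequencies as fractions in \eqn{[0, t_B]}.
#' @seealso [predict.pmgf()] for percent output.
#' @export
frequency_at <- function(model, x) {
  stopifnot(inherits(model, "pmgf"))
  if (!is.numeric(x) || !length(x) || any(!is.finite(x)) || any(x <= 0))
    stop("Please input a PROPER value for 'distance': must be positive",
         call. = FALSE)
  P <- kernel_cdf(model$kernel, x)
  DA <- if (identical(model$donor_depth, Inf)) 1 - P
        else kernel_cdf(model$kernel, x + model$donor_depth) - P
  DB <- kernel_cdf(model$kernel, x - model$recipient_offset)
  den <- model$delta * DA + DB
  out <- ifelse(den > 0, model$t_B * model$delta * DA / den, model$t_B)
  pmin(pmax(out, 0), model$t_B)
}

#' Frequency-decline curve
#'
#' Gene-flow frequency on an inclusive distance grid, as displayed by the
#' original interface's "Frequency decline by distance" output.
#'
#' @param model a \code{"pmgf"} object.
#' @param from,to distance range in metres, \code{0 < from <= to}.
#' @param step grid step in metres (> 0).
#' @return A \code{"pmgf_curve"}: data frame with columns \code{distance}
#'   (m) and \code{frequency} (fraction), with the model and step as
#'   attributes.
#' @examples
#' rice <- pmgf(preset = "rice")
#' cv <- frequency_curve(rice, 0.3, 80, step = 0.5)
#' head(as.data.frame(cv))
#' @export
frequency_curve <- function(model, from, to, step = NULL) {
  stopifnot(inherits(model, "pmgf"))
  from <- check_positive(from, "distance range start")
  to   <- check_positive(to, "distance range end")
  if (from > to)
    stop("Please input a PROPER value for 'distance range': start exceeds end",
         call. = FALSE)
  if (is.null(step)) step <- max((to - from) / 200, 1e-6)
  step <- check_positive(step, "step")
  xs <- seq(from, to, by = step)
  if (!length(xs)) stop("empty distance grid", call. = FALSE)
  curve <- data.frame(distance = xs, frequency = frequency_at(model, xs))
  attr(curve, "step") <- step
  attr(curve, "model") <- model
  class(curve) <- c("pmgf_curve", "data.frame")
  curve
}

#' Isolation distance for a threshold frequency
#'
#' Smallest distance (on a regular grid of the given resolution) at which
#' the gene-flow frequency drops to or below a threshold — the "distance for
#' threshold" output used to set spatial isolation between donor and
#' recipient fields (e.g. the 0.9\% low-level presence threshold for
#' GE/non-GE coexistence, or seed-certification purity standards).
#'
#' @param model a \code{"pmgf"} object.
#' @param threshold threshold frequency as a fraction in (0, 1).
#' @param x_min,x_max search range in metres.
#' @param resolution grid resolution in metres (default 0.1, matching the
#'   0.1-m readout of the original interface).
#' @return A \code{"pmgf_isolation"} list: \code{distance} (m),
#'   \code{threshold}, \code{achieved_frequency} (fraction at the reported
#'   distance).
#' @examples
#' m <- pmgf(preset = "maize", wind_speed = 3)
#' isolation_distance(m, threshold = 0.009)
#' @export
isolation_distance <- function(model, threshold, x_min = 0.1, x_max = 10000,
                               resolution = 0.1) {
  stopifnot(inherits(model, "pmgf"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0 || threshold > 1)
    stop("Please input a PROPER value for 'threshold': must lie in (0, 1]",
         call. = FALSE)
  x_min <- check_positive(x_min, "x_min")
  x_max <- check_positive(x_max, "x_max")
  resolution <- check_positive(resolution, "resolution")
  if (x_min > x_max) stop("x_min exceeds x_max", call. = FALSE)

  grid <- seq(x_min, x_max, by = resolution)
  hit <- NA_integer_
  chunk <- 4096L
  for (start in seq(1L, length(grid), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(grid))
    fr <- frequency_at(model, grid[idx])
    j <- which(fr <= threshold)
    if (length(j)) { hit <- idx[j[1L]]; break }
  }
  if (is.na(hit))
    stop(sprintf(
      "threshold %.4g not reached within %.4g m (frequency there: %.4g)",
      threshold, x_max, frequency_at(model, x_max)), call. = FALSE)
  res <- list(distance = grid[hit], threshold = threshold,
              achieved_frequency = frequency_at(model, grid[hit]))
  class(res) <- "pmgf_isolation"
  res
}

# ---- methods ---------------------------------------------------------------

#' @export
print.pmgf <- function(x, ...) {
  cat("Pollen-mediated gene flow model\n")
  cat(sprintf("  pollen diameter   %g um\n", x$params["pollen_diameter"]))
  cat(sprintf("  release height    %g m\n", x$params["release_height"]))
  cat(sprintf("  outcrossing rate  %g %%\n", x$params["outcrossing_rate"]))
  cat(sprintf("  crossability      %g %%\n", x$params["crossability"]))
  cat(sprintf("  wind speed        %g m/s\n", x$params["wind_speed"]))
  cat(sprintf("  donor depth       %s\n",
              if (identical(x$donor_depth, Inf)) "infinite (worst case)"
              else paste0(x$donor_depth, " m")))
  if (x$recipient_offset != 0)
    cat(sprintf("  recipient offset  %g m\n", x$recipient_offset))
  invisible(x)
}

#' @export
summary.pmgf <- function(object, distances = c(1, 5, 10, 50), ...) {
  print(object)
  print(object$kernel)
  ok <- distances > 0
  fr <- frequency_at(object, distances[ok])
  cat("Gene-flow frequency:\n")
  for (i in seq_along(fr))
    cat(sprintf("  %8.1f m  %s %%\n", distances[ok][i], format_pct(fr[i])))
  invisible(object)
}

#' @export
coef.pmgf <- function(object, ...) object$params

#' Predict gene-flow frequency
#'
#' @param object a \code{"pmgf"} model.
#' @param distance distances in metres.
#' @param units \code{"percent"} (default, as shown by the interface) or
#'   \code{"fraction"}.
#' @param ... unused.
#' @return Numeric vector of frequencies.
#' @export
predict.pmgf <- function(object, distance, units = c("percent", "fraction"),
                         ...) {
  units <- match.arg(units)
  fr <- frequency_at(object, distance)
  if (units == "percent") fr * 100 else fr
}

#' @export
print.pmgf_curve <- function(x, n = 6L, ...) {
  cat(sprintf("PMGF frequency-decline curve: %d points, %g-%g m (step %g m)\n",
              nrow(x), min(x$distance), max(x$distance), attr(x, "step")))
  show <- utils::head(data.frame(distance_m = x$distance,
                                 frequency_percent = x$frequency * 100), n)
  print(show, row.names = FALSE)
  if (nrow(x) > n) cat("  ...\n")
  invisible(x)
}

#' Plot a frequency-decline curve
#'
#' Static plot of gene-flow frequency (percent) against distance, the
#' analogue of the original interface's plotting field.
#'
#' @param x a \code{"pmgf_curve"}.
#' @param log_y logical; use a logarithmic frequency axis.
#' @param gridlines logical; add reference gridlines.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.pmgf_curve <- function(x, log_y = FALSE, gridlines = FALSE, ...) {
  graphics::plot(x$distance, x$frequency * 100, type = "l", col = "red",
                 lwd = 2, log = if (log_y) "y" else "",
                 xlab = "Distance to recipient (m)",
                 ylab = "PMGF frequency (%)", ...)
  if (gridlines) graphics::grid(col = "grey70")
  invisible(x)
}

#' @export
print.pmgf_isolation <- function(x, ...) {
  cat(sprintf("Isolation distance: %.1f m\n", x$distance))
  cat(sprintf("  threshold          %s %%\n", format_pct(x$threshold)))
  cat(sprintf("  achieved frequency %s %%\n", format_pct(x$achieved_frequency)))
  invisible(x)
}

# percent formatting: at least 2 significant figures, at most 4 decimals
format_pct <- function(fraction) {
  vapply(fraction, function(f) {
    pct <- f * 100
    if (!is.finite(pct)) return(NA_character_)
    if (abs(pct) >= 1) formatC(pct, format = "f", digits = 2)
    else formatC(round(signif(pct, 2), 4), format = "fg")
  }, character(1))
}
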