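# Species presets: named bundles of the five model parameters, stored as a
# packaged YAML file so users can add species without touching code.

preset_file <- function() {
  system.file("extdata", "presets.yaml", package = "windpollen",
              mustWork = TRUE)
}

load_presets <- function(file = preset_file()) {
  yaml::read_yaml(file)
}

#' Species presets
#'
#' `pmgf_presets()` lists the available preset names; `pmgf_preset()`
#' retrieves one as a validated `"pmgf_preset"` object. The shipped presets
#' are the published rice, wheat and maize crop-to-crop case-study parameter
#' sets.
#'
#' @param name preset name (case-insensitive).
#' @param file optional path to an alternative preset YAML file with the
#'   same schema.
#' @return `pmgf_preset()`: a list with fields `name`, `pollen_diameter`
#'   (um), `release_height` (m), `outcrossing_rate` (%), `crossability` (%),
#'   `wind_speed` (m/s) and `source`.
#' @examples
#' pmgf_presets()
#' pmgf_preset("rice")
#' @export
pmgf_preset <- function(name, file = preset_file()) {
  all <- load_presets(file)
  key <- tolower(as.character(name)[1])
  if (!key %in% names(all))
    stop("unknown preset '", name, "'; available: ",
         paste(names(all), collapse = ", "), call. = FALSE)
  p <- all[[key]]
  p$name <- key
  for (f in c("pollen_diameter", "release_height", "outcrossing_rate",
              "crossability", "wind_speed")) {
    if (is.null(p[[f]])) stop("preset '", key, "' lacks field '", f, "'",
                              call. = FALSE)
    field <- if (f %in% names(.bounds)) f else "pollen_diameter"
    p[[f]] <- check_param(p[[f]], field)
  }
  if (is.null(p$source)) p$source <- ""
  class(p) <- "pmgf_preset"
  p
}

#' @rdname pmgf_preset
#' @export
pmgf_presets <- function(file = preset_file()) names(load_presets(file))

#' Modify one preset field
#'
#' Returns a copy of a preset with a single parameter replaced (the original
#' is untouched); the new value is validated against the interface bounds.
#' Used e.g. for wind-speed what-if scenarios on a published parameter set.
#'
#' @param preset a `"pmgf_preset"` object.
#' @param field one of `pollen_diameter`, `release_height`,
#'   `outcrossing_rate`, `crossability`, `wind_speed`.
#' @param value the replacement value (interface units).
#' @return A new `"pmgf_preset"`.
#' @examples
#' maize3 <- preset_modify(pmgf_preset("maize"), "wind_speed", 3)
#' @export
preset_modify <- function(preset, field, value) {
  stopifnot(inherits(preset, "pmgf_preset"))
  field <- match.arg(field, c("pollen_diameter", "release_height",
                              "outcrossing_rate", "crossability",
                              "wind_speed"))
  out <- preset
  out[[field]] <- check_param(value, field)
  out
}

#' @export
print.pmgf_preset <- function(x, ...) {
  cat(sprintf("PMGF preset '%s'\n", x$name))
  cat(sprintf("  pollen diameter   %g um\n", x$pollen_diameter))
  cat(sprintf("  release height    %g m\n", x$release_height))
  cat(sprintf("  outcrossing rate  %g %%\n", x$outcrossing_rate))
  cat(sprintf("  crossability      %g %%\n", x$crossability))
  cat(sprintf("  wind speed        %g m/s\n", x$wind_speed))
  if (nzchar(x$source)) cat("  source: ", x$source, "\n", sep = "")
  invisible(x)
}
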