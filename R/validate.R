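# Input validation. The original interface rejects out-of-range entries with
# "Please input a PROPER value"; these helpers do the same, naming the field.

.bounds <- list(
  pollen_diameter  = c(0, 500),   # um, open lower bound
  release_height   = c(0, 100),   # m
  wind_speed       = c(0, 50),    # m/s
  outcrossing_rate = c(0, 100),   # %, (0, 100]
  crossability     = c(0, 100)    # %, (0, 100]
)

# validate one scalar parameter against its interface bounds
check_param <- function(value, field) {
  b <- .bounds[[field]]
  if (is.null(b)) stop("unknown parameter '", field, "'", call. = FALSE)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("Please input a PROPER value for '", field,
         "': got a non-numeric or missing entry", call. = FALSE)
  if (value <= b[1] || value > b[2])
    stop("Please input a PROPER value for '", field, "': ", value,
         " is outside (", b[1], ", ", b[2], "]", call. = FALSE)
  as.numeric(value)
}

check_positive <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value <= 0)
    stop("Please input a PROPER value for '", field,
         "': must be a single positive number", call. = FALSE)
  as.numeric(value)
}

check_nonneg <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value < 0)
    stop("Please input a PROPER value for '", field,
         "': must be a single non-negative number", call. = FALSE)
  as.numeric(value)
}
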