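# Environmental cold-stress indices computed from temperature, relative
# humidity and wind speed.

#' Temperature-humidity index (THI)
#'
#' The NRC-style livestock form
#' `(1.8 T + 32) - (0.55 - 0.0055 RH) (1.8 T - 26)` with `T` in degrees
#' Celsius and `RH` in percent. At `RH = 100` the humidity correction
#' vanishes and THI equals the Fahrenheit temperature.
#'
#' @param temperature Air temperature, deg C.
#' @param humidity Relative humidity, percent in `[0, 100]`.
#' @return THI values (unitless).
#' @examples
#' thi(1.21, 71.3)
#' @export
thi <- function(temperature, humidity) {
  if (any(humidity < 0 | humidity > 100, na.rm = TRUE)) {
    rlang::abort("Relative humidity must be in [0, 100] percent.",
      class = "coldstress_error_domain"
    )
  }
  tf <- 1.8 * temperature + 32
  tf - (0.55 - 0.0055 * humidity) * (1.8 * temperature - 26)
}

#' Wind-chill temperature (WCT)
#'
#' The JAG/TI wind-chill formula adopted by the North American weather
#' services: for wind above 4.8 km/h,
#' `13.12 + 0.6215 T - 11.37 v^0.16 + 0.3965 T v^0.16` with `T` in deg C and
#' `v` in km/h; calm air (`v <= 4.8`) returns the air temperature unchanged.
#' The calm-air convention makes the index discontinuous at 4.8 km/h.
#'
#' @param temperature Air temperature, deg C.
#' @param wind Wind speed, km/h, non-negative.
#' @return Perceived temperature, deg C.
#' @examples
#' wct(1.21, 9.34)
#' @export
wct <- function(temperature, wind) {
  if (any(wind < 0, na.rm = TRUE)) {
    rlang::abort("Wind speed must be non-negative.", class = "coldstress_error_domain")
  }
  v16 <- wind^0.16
  ifelse(
    wind > 4.8,
    13.12 + 0.6215 * temperature - 11.37 * v16 + 0.3965 * temperature * v16,
    temperature
  )
}

#' Bin an index value into ordered categories
#'
#' Half-open binning against strictly increasing cutpoints: values up to and
#' including the first cutpoint fall in category 0, values in
#' `(c_k, c_{k+1}]` in category k, values above the last cutpoint in the top
#' category (right-closed at each cutpoint, so a value equal to a cutpoint
#' takes the lower bin).
#'
#' @param x Numeric values.
#' @param cutpoints Strictly increasing numeric vector.
#' @param labels Optional labels, length `length(cutpoints) + 1`; defaults to
#'   the integer category codes.
#' @return Integer codes (0-based) or `labels[code + 1]` when labels are
#'   given.
#' @export
thi_category <- function(x, cutpoints, labels = NULL) {
  if (length(cutpoints) == 0) {
    rlang::abort("At least one cutpoint is required.", class = "coldstress_error_configuration")
  }
  if (is.unsorted(cutpoints, strictly = TRUE)) {
    rlang::abort("Cutpoints must be strictly increasing.", class = "coldstress_error_configuration")
  }
  code <- rowSums(outer(x, cutpoints, ">"))
  if (is.null(labels)) {
    return(as.integer(code))
  }
  stopifnot(length(labels) == length(cutpoints) + 1L)
  labels[code + 1L]
}

#' Append index columns to a record table
#'
#' @param records Data frame with `temperature_c`, `humidity_pct` and `wind`
#'   columns.
#' @return The table with `thi` and `wct` columns added.
#' @export
add_indices <- function(records) {
  need <- c("temperature_c", "humidity_pct", "wind")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    rlang::abort(
      sprintf("Records are missing column(s): %s.", paste(missing, collapse = ", ")),
      class = "coldstress_error_schema"
    )
  }
  dplyr::mutate(
    tibble::as_tibble(records),
    thi = thi(.data$temperature_c, .data$humidity_pct),
    wct = wct(.data$temperature_c, .data$wind)
  )
}
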