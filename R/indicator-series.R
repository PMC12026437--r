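#' One indicator's measurements over storage time at one temperature
#'
#' The basic observation unit of the package: an ordered time series of one
#' quality indicator held at one constant storage temperature. Times are always
#' stored in days (the canonical internal unit; [read_indicator_series()]
#' converts hours on input) and temperatures in degrees Celsius.
#'
#' @param indicator indicator name; canonicalised via [normalize_indicator()].
#' @param temperature_c storage temperature, degrees Celsius (scalar, finite).
#' @param times_days sampling times in days; strictly increasing, all >= 0.
#' @param values measured indicator values, same length as `times_days`
#'   (length >= 2; fitting requires >= 3).
#' @param unit unit label; defaults to the registry unit for known indicators.
#' @param direction `"increasing"` or `"decreasing"`: the quality-change
#'   direction during storage. Defaults to the registry direction; mandatory
#'   for unknown indicators.
#' @return an `indicator_series` object.
#' @export
#' @examples
#' indicator_series("TVB-N", 4, c(0, 2, 4, 6), c(6.9, 9.5, 12.2, 14.8))
indicator_series <- function(indicator, temperature_c, times_days, values,
                             unit = NULL, direction = NULL) {
  indicator <- normalize_indicator(indicator)
  stopifnot(length(indicator) == 1, length(temperature_c) == 1)
  if (!is.finite(temperature_c)) stop("temperature_c must be finite")
  times_days <- as.numeric(times_days)
  values <- as.numeric(values)
  if (length(times_days) != length(values)) {
    stop("times_days and values must have equal length")
  }
  if (length(times_days) < 2) stop("an indicator series needs at least 2 points")
  if (anyNA(times_days) || anyNA(values) || any(!is.finite(values))) {
    stop("times and values must be finite and non-missing")
  }
  if (any(times_days < 0)) stop("times_days must be >= 0")
  if (any(diff(times_days) <= 0)) stop("times_days must be strictly increasing")
  if (is.null(direction)) direction <- default_direction(indicator)
  if (is.na(direction) || is.null(direction)) {
    stop("unknown indicator '", indicator,
         "': supply direction = \"increasing\" or \"decreasing\"")
  }
  direction <- match.arg(direction, c("increasing", "decreasing"))
  if (is.null(unit)) unit <- default_unit(indicator)
  structure(
    list(indicator = indicator, unit = unit,
         temperature_c = as.numeric(temperature_c),
         times_days = times_days, values = values, direction = direction),
    class = "indicator_series"
  )
}

#' @export
print.indicator_series <- function(x, ...) {
  cat(sprintf("<indicator_series> %s [%s] at %g degC, %s\n",
              x$indicator, if (is.na(x$unit)) "?" else x$unit,
              x$temperature_c, x$direction))
  print(data.frame(time_days = x$times_days, value = x$values), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.indicator_series <- function(x, ...) {
  data.frame(indicator = x$indicator, temperature_c = x$temperature_c,
             time_days = x$times_days, value = x$values,
             unit = if (is.null(x$unit) || is.na(x$unit)) NA_character_ else x$unit,
             direction = x$direction, stringsAsFactors = FALSE)
}
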