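# Shelf life = time for an indicator to travel from its initial value A0 to its
# critical limit A at temperature T:
#   order 0:  SL = (A - A0) / k(T)
#   order 1:  SL = (ln A - ln A0) / k(T)
# with k(T) from the Arrhenius fit. Only orders 0 and 1 admit this closed-form
# inversion; order 2 is fit-only.

#' Build a shelf-life prediction model for one indicator
#'
#' Combines an Arrhenius temperature model of the rate constant with an initial
#' value and a critical limit. By convention `a0` is the measured value at
#' t = 0 of the calibration series, not a regression intercept.
#'
#' @param arrhenius an [arrhenius_fit()].
#' @param a0 initial indicator value (must be > 0 for order 1).
#' @param limit_value critical limit, in indicator units.
#' @param limit_side `"upper"` (spoilage accumulates up to the limit) or
#'   `"lower"` (quality decays down to it).
#' @param indicator,order default to the labels carried by `arrhenius`.
#' @return a `shelf_life_model` object.
#' @export
#' @examples
#' af <- arrhenius_fit(-5527.722, 17.924, indicator = "TVC", order = 1)
#' shelf_life_model(af, a0 = 0.57, limit_value = 6, limit_side = "upper")
shelf_life_model <- function(arrhenius, a0, limit_value,
                             limit_side = c("upper", "lower"),
                             indicator = arrhenius$indicator,
                             order = arrhenius$order) {
  stopifnot(inherits(arrhenius, "arrhenius_fit"), is.finite(a0),
            is.finite(limit_value))
  limit_side <- match.arg(limit_side)
  if (is.na(order) || !order %in% c(0, 1)) {
    stop("shelf-life prediction supports orders 0 and 1 only (got ",
         if (is.na(order)) "NA" else order, ")")
  }
  order <- as.integer(order)
  if (order == 1L && (a0 <= 0 || limit_value <= 0)) {
    stop("order-1 shelf life needs a0 > 0 and limit > 0")
  }
  structure(
    list(indicator = normalize_indicator(indicator), order = order,
         arrhenius = arrhenius, a0 = as.numeric(a0),
         limit = list(value = as.numeric(limit_value), side = limit_side)),
    class = "shelf_life_model"
  )
}

#' Predict an indicator value at time t and temperature T
#'
#' Order 0: `A = a0 + k t`; order 1: `A = a0 exp(k t)`, with
#' `k = rate_at(arrhenius, temperature_c)`.
#'
#' @param model a [shelf_life_model()].
#' @param t storage time(s) in days, >= 0.
#' @param temperature_c storage temperature, degrees Celsius.
#' @return predicted indicator value(s).
#' @export
predict_value <- function(model, t, temperature_c) {
  stopifnot(inherits(model, "shelf_life_model"))
  if (any(t < 0)) stop("storage time must be >= 0")
  k <- rate_at(model$arrhenius, temperature_c)
  if (model$order == 0L) model$a0 + k * t else model$a0 * exp(k * t)
}

#' Time for an indicator to reach its critical limit
#'
#' Inverts the kinetic model at the given temperature. The result satisfies the
#' inverse-consistency contract `predict_value(model, SL, T) == limit` (to
#' floating tolerance) whenever SL is finite.
#'
#' @param model a [shelf_life_model()].
#' @param temperature_c storage temperature, degrees Celsius.
#' @return shelf life in days; `Inf` when k = 0 (the indicator never moves).
#'   An unreachable limit (rate pointing away from it) raises an error carrying
#'   the sign diagnostic.
#' @export
shelf_life_time <- function(model, temperature_c) {
  stopifnot(inherits(model, "shelf_life_model"))
  k <- rate_at(model$arrhenius, temperature_c)
  limit <- model$limit$value
  gap <- if (model$order == 0L) limit - model$a0 else log(limit) - log(model$a0)
  if (k == 0) {
    if (gap == 0) return(0)
    message("rate constant is 0 at ", temperature_c,
            " degC: shelf life is unbounded")
    return(Inf)
  }
  sl <- gap / k
  if (sl < 0) {
    stop(sprintf(
      paste0("infeasible shelf life for %s at %g degC: k = %.4g/day moves the ",
             "indicator away from the %s limit %g (a0 = %g)"),
      model$indicator, temperature_c, k, model$limit$side, limit, model$a0))
  }
  sl
}

#' Shelf life of a product limited by several indicators
#'
#' The product's shelf life is the minimum of the per-indicator shelf lives.
#' Indicators with infinite shelf life (k = 0) or an infeasible limit are
#' excluded, with a note. Exact ties are resolved in favour of the first
#' indicator in canonical registry order; all tied indicators are reported.
#'
#' @param models list of [shelf_life_model()] objects.
#' @param temperature_c storage temperature, degrees Celsius.
#' @return list with `shelf_life_days`, `limiting_indicator`, `tied_with`
#'   (character, possibly empty), `per_indicator` (data frame of all finite
#'   shelf lives) and `notes` (excluded indicators).
#' @export
overall_shelf_life <- function(models, temperature_c) {
  stopifnot(is.list(models), length(models) >= 1,
            all(vapply(models, inherits, TRUE, "shelf_life_model")))
  inds <- vapply(models, `[[`, "", "indicator")
  sl <- rep(NA_real_, length(models))
  notes <- character()
  for (i in seq_along(models)) {
    res <- tryCatch(suppressMessages(shelf_life_time(models[[i]], temperature_c)),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      notes <- c(notes, sprintf("%s excluded: %s", inds[i], res))
    } else if (is.infinite(res)) {
      notes <- c(notes, sprintf("%s excluded: infinite shelf life (k = 0)", inds[i]))
    } else {
      sl[i] <- res
    }
  }
  if (all(is.na(sl))) {
    stop("no indicator yields a finite shelf life at ", temperature_c, " degC: ",
         paste(notes, collapse = "; "))
  }
  ok <- which(!is.na(sl))
  ord <- ok[base::order(canonical_indicator_rank(inds)[ok])]
  best <- min(sl[ok])
  hits <- ord[abs(sl[ord] - best) <= 1e-9 * max(1, abs(best))]
  list(
    shelf_life_days = sl[hits[1]],
    limiting_indicator = inds[hits[1]],
    tied_with = inds[hits[-1]],
    per_indicator = data.frame(indicator = inds[ord], shelf_life_days = sl[ord],
                               stringsAsFactors = FALSE),
    notes = notes
  )
}

#' Relative deviation between measured and predicted values, in percent
#'
#' `100 * |measured - predicted| / |predicted|` — the denominator is the
#' predicted value, the convention under which published validation tables for
#' this kind of model are arithmetically self-consistent.
#'
#' @param measured,predicted numeric vectors (recycled); `predicted` nonzero.
#' @return deviations in percent, >= 0.
#' @export
#' @examples
#' relative_deviation(12.71, 11.79) # 7.80
relative_deviation <- function(measured, predicted) {
  stopifnot(is.numeric(measured), is.numeric(predicted))
  if (any(predicted == 0)) stop("relative deviation undefined for predicted = 0")
  100 * abs(measured - predicted) / abs(predicted)
}

#' Validate a shelf-life model against a measured series
#'
#' Predicts the indicator at every measured time point and tabulates the
#' relative deviations.
#'
#' @param measured an [indicator_series()] of validation measurements.
#' @param model the [shelf_life_model()] under test (same indicator).
#' @param temperature_c the validation storage temperature; defaults to the
#'   series' own temperature.
#' @return a `validation_result`: list with `records` (data frame `time_days`,
#'   `measured`, `predicted`, `relative_deviation_pct`) and `summary`
#'   (`max_deviation_pct`, `mean_deviation_pct`, `rmse` in indicator units).
#' @export
validate_predictions <- function(measured, model,
                                 temperature_c = measured$temperature_c) {
  stopifnot(inherits(measured, "indicator_series"),
            inherits(model, "shelf_life_model"))
  if (length(measured$times_days) == 0) stop("empty validation series")
  predicted <- predict_value(model, measured$times_days, temperature_c)
  if (any(predicted == 0)) {
    stop("predicted value is 0 at t = ",
         measured$times_days[which(predicted == 0)[1]], " days")
  }
  dev <- relative_deviation(measured$values, predicted)
  records <- data.frame(time_days = measured$times_days,
                        measured = measured$values, predicted = predicted,
                        relative_deviation_pct = dev)
  structure(
    list(indicator = model$indicator, temperature_c = as.numeric(temperature_c),
         records = records,
         summary = list(max_deviation_pct = max(dev),
                        mean_deviation_pct = mean(dev),
                        rmse = sqrt(mean((measured$values - predicted)^2)))),
    class = "validation_result"
  )
}

#' @export
as.data.frame.validation_result <- function(x, ...) x$records

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> %s at %g degC\n", x$indicator, x$temperature_c))
  print(x$records, row.names = FALSE)
  cat(sprintf("max deviation %.2f%%, mean %.2f%%, RMSE %.4g\n",
              x$summary$max_deviation_pct, x$summary$mean_deviation_pct,
              x$summary$rmse))
  invisible(x)
}

#' @export
print.shelf_life_model <- function(x, ...) {
  cat(sprintf("<shelf_life_model> %s, order %d, a0 = %g, %s limit %g\n",
              x$indicator, x$order, x$a0, x$limit$side, x$limit$value))
  cat(" ", shelf_life_equation(x), "\n")
  invisible(x)
}

#' Render a shelf-life model as a symbolic equation string
#'
#' @param model a [shelf_life_model()].
#' @return a one-line character rendering, e.g.
#'   `"SL = (A - A0) / (2.72e+13 * exp(-8507.39/T))"`.
#' @export
shelf_life_equation <- function(model) {
  stopifnot(inherits(model, "shelf_life_model"))
  af <- model$arrhenius
  sgn <- if (af$rate_sign < 0) "-" else ""
  num <- if (model$order == 0L) "(A - A0)" else "(ln A - ln A0)"
  sprintf("SL = %s / (%s%.6g * exp(%.6g/T))", num, sgn, af$k0, af$slope)
}
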