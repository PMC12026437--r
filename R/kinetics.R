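# Reaction-order kinetics. The change of a quality index A over storage time t
# is modelled, after transformation, as a straight line in t:
#   order 0:  A          = A0 + k t      (linear accumulation/decay)
#   order 1:  ln A       = ln A0 + k t   (exponential)
#   order 2:  1/A        = 1/A0 - k t    (reciprocal-linear)
# The rate constant k is the slope of the transformed response; under order 2
# the conventional rate law dA/dt = -k A^2 gives slope +k in 1/A, so the fitted
# slope is reported as k directly (signed).

.check_order <- function(order) {
  if (length(order) != 1 || !order %in% c(0, 1, 2)) {
    stop("order must be 0, 1 or 2")
  }
  as.integer(order)
}

#' Transform indicator values to the linear space of a reaction order
#'
#' Order 0 is the identity, order 1 the natural logarithm, order 2 the
#' reciprocal. [kinetic_back_transform()] is the exact inverse.
#'
#' @param values numeric vector of indicator values.
#' @param order reaction order, 0, 1 or 2.
#' @param times optional sampling times (days), used only to name the offending
#'   point in domain-error messages.
#' @return transformed numeric vector.
#' @export
#' @examples
#' kinetic_transform(c(1, exp(1), exp(2)), order = 1)
kinetic_transform <- function(values, order, times = NULL) {
  order <- .check_order(order)
  .where <- function(i) {
    if (!is.null(times)) sprintf("t = %g days", times[i]) else sprintf("position %d", i)
  }
  if (order == 1L && any(values <= 0)) {
    stop("first-order transform undefined for value <= 0 at ",
         .where(which(values <= 0)[1]))
  }
  if (order == 2L && any(values == 0)) {
    stop("second-order transform undefined for value == 0 at ",
         .where(which(values == 0)[1]))
  }
  switch(order + 1L, values, log(values), 1 / values)
}

#' @rdname kinetic_transform
#' @param transformed numeric vector in the transformed space.
#' @export
kinetic_back_transform <- function(transformed, order) {
  order <- .check_order(order)
  switch(order + 1L, transformed, exp(transformed), 1 / transformed)
}

#' Construct a kinetic fit record
#'
#' Normally produced by [fit_kinetic()]; the constructor is exported so that
#' fit statistics from external sources (e.g. published tables) can enter the
#' selection machinery of [indicator_kinetics()] and [select_order()].
#'
#' @param indicator indicator name.
#' @param temperature_c storage temperature, degrees Celsius.
#' @param order reaction order (0, 1 or 2).
#' @param k fitted rate constant (slope in transformed space; signed).
#' @param intercept fitted transformed response at t = 0.
#' @param r_squared coefficient of determination in transformed space.
#' @param rmse root-mean-square error of back-transformed predictions, in
#'   original indicator units.
#' @param n_points number of observations used.
#' @return a `kinetic_fit` object.
#' @export
kinetic_fit <- function(indicator, temperature_c, order, k, intercept,
                        r_squared, rmse, n_points) {
  order <- .check_order(order)
  if (!is.na(r_squared) && r_squared > 1 + 1e-12) stop("r_squared must be <= 1")
  if (!is.na(rmse) && rmse < 0) stop("rmse must be >= 0")
  structure(
    list(indicator = normalize_indicator(indicator),
         temperature_c = as.numeric(temperature_c), order = order,
         k = as.numeric(k), intercept = as.numeric(intercept),
         r_squared = as.numeric(r_squared), rmse = as.numeric(rmse),
         n_points = as.integer(n_points)),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> %s at %g degC, order %d: k = %.6g/day, intercept = %.6g, R2 = %.4f, RMSE = %.4g (n = %d)\n",
    x$indicator, x$temperature_c, x$order, x$k, x$intercept, x$r_squared, x$rmse, x$n_points))
  invisible(x)
}

#' Fit one reaction-order model to an indicator series
#'
#' Ordinary least squares of the transformed values against time (days) with a
#' free intercept. The rate constant `k` is the fitted slope and keeps its
#' sign: decaying indicators give negative `k` under orders 0 and 1. R-squared
#' is computed in transformed space (`1 - SS_res/SS_tot`); RMSE is computed in
#' the original indicator units after back-transforming the fitted values.
#'
#' @param series an [indicator_series()] with at least 3 points.
#' @param order reaction order, 0, 1 or 2.
#' @param force_intercept if `TRUE`, the line is forced through the transformed
#'   first observation (the algebraic form of the textbook rate equations).
#'   Default `FALSE`: a conventional free-intercept regression.
#' @return a [kinetic_fit()] object.
#' @export
#' @examples
#' s <- indicator_series("TVB-N", 25, 0:4, 10 + 2 * (0:4))
#' fit_kinetic(s, order = 0)
fit_kinetic <- function(series, order, force_intercept = FALSE) {
  stopifnot(inherits(series, "indicator_series"))
  order <- .check_order(order)
  t <- series$times_days
  a <- series$values
  if (length(t) < 3) {
    stop("insufficient data: fitting needs >= 3 points, got ", length(t))
  }
  if (stats::var(t) == 0) stop("degenerate design: all sampling times equal")
  y <- kinetic_transform(a, order, times = t)

  if (force_intercept) {
    # line constrained through (t[1], y[1])
    slope <- sum((t - t[1]) * (y - y[1])) / sum((t - t[1])^2)
    intercept <- y[1] - slope * t[1]
  } else {
    coefs <- stats::lm.fit(cbind(`(Intercept)` = 1, t = t), y)$coefficients
    intercept <- unname(coefs[1])
    slope <- unname(coefs[2])
  }
  fitted_y <- intercept + slope * t
  ss_res <- sum((y - fitted_y)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else if (ss_res <= 1e-24) 1 else NaN
  fitted_a <- kinetic_back_transform(fitted_y, order)
  rmse <- sqrt(mean((fitted_a - a)^2))
  kinetic_fit(series$indicator, series$temperature_c, order,
              k = slope, intercept = intercept, r_squared = r2, rmse = rmse,
              n_points = length(t))
}

#' Bundle kinetic fits of one indicator across temperatures and orders
#'
#' Computes, for every order that could be fitted at *all* temperatures, the
#' summed R-squared and summed RMSE across temperatures, and selects the best
#' order (see [select_order()]). Orders missing at any temperature are excluded
#' from selection and listed in `infeasible_orders`.
#'
#' @param fits list of [kinetic_fit()] objects for one indicator.
#' @return an `indicator_kinetics` object with elements `indicator`,
#'   `temperatures_c`, `orders`, `fits` (named `"<temp>C|order<o>"`),
#'   `sum_r_squared`, `sum_rmse` (named numeric, `NA` for infeasible orders),
#'   `feasible_orders`, `infeasible_orders`, `selected_order`.
#' @export
indicator_kinetics <- function(fits) {
  stopifnot(is.list(fits), length(fits) > 0,
            all(vapply(fits, inherits, TRUE, "kinetic_fit")))
  inds <- unique(vapply(fits, `[[`, "", "indicator"))
  if (length(inds) != 1) {
    stop("mixed indicators in one kinetics bundle: ", paste(inds, collapse = ", "))
  }
  temps <- sort(unique(vapply(fits, `[[`, 0, "temperature_c")))
  orders <- sort(unique(vapply(fits, `[[`, 0L, "order")))
  names(fits) <- vapply(fits, function(f) {
    sprintf("%gC|order%d", f$temperature_c, f$order)
  }, "")
  if (anyDuplicated(names(fits))) {
    stop("duplicate (temperature, order) fit in kinetics bundle")
  }
  sum_r2 <- sum_rmse <- stats::setNames(rep(NA_real_, length(orders)),
                                        paste0("order", orders))
  feasible <- logical(length(orders))
  for (i in seq_along(orders)) {
    keys <- sprintf("%gC|order%d", temps, orders[i])
    if (all(keys %in% names(fits))) {
      feasible[i] <- TRUE
      sum_r2[i] <- sum(vapply(fits[keys], `[[`, 0, "r_squared"))
      sum_rmse[i] <- sum(vapply(fits[keys], `[[`, 0, "rmse"))
    }
  }
  if (!any(feasible)) stop("no reaction order is feasible at every temperature")
  obj <- structure(
    list(indicator = inds, temperatures_c = temps, orders = orders,
         fits = fits, sum_r_squared = sum_r2, sum_rmse = sum_rmse,
         feasible_orders = orders[feasible],
         infeasible_orders = orders[!feasible],
         selected_order = NA_integer_),
    class = "indicator_kinetics"
  )
  obj$selected_order <- select_order(obj)
  obj
}

#' Fit all reaction orders to one indicator across temperatures
#'
#' Runs [fit_kinetic()] for every requested order on every temperature's
#' series; orders whose domain constraints fail somewhere (e.g. order 1 with a
#' non-positive value) are dropped from selection with a warning rather than
#' aborting the bundle.
#'
#' @param series_by_temperature list of [indicator_series()] for one indicator
#'   at distinct temperatures.
#' @param orders orders to try (default all of 0, 1, 2).
#' @param force_intercept see [fit_kinetic()].
#' @return an [indicator_kinetics()] object.
#' @export
fit_all_orders <- function(series_by_temperature, orders = c(0, 1, 2),
                           force_intercept = FALSE) {
  stopifnot(is.list(series_by_temperature), length(series_by_temperature) >= 1,
            all(vapply(series_by_temperature, inherits, TRUE, "indicator_series")))
  inds <- unique(vapply(series_by_temperature, `[[`, "", "indicator"))
  if (length(inds) != 1) {
    stop("fit_all_orders expects one indicator; got: ", paste(inds, collapse = ", "))
  }
  temps <- vapply(series_by_temperature, `[[`, 0, "temperature_c")
  if (anyDuplicated(temps)) stop("duplicate temperatures for indicator ", inds)
  fits <- list()
  failures <- character()
  for (s in series_by_temperature) {
    for (o in orders) {
      f <- tryCatch(fit_kinetic(s, o, force_intercept = force_intercept),
                    error = function(e) conditionMessage(e))
      if (inherits(f, "kinetic_fit")) {
        fits[[length(fits) + 1L]] <- f
      } else {
        failures <- c(failures, sprintf("order %d at %g degC: %s", o, s$temperature_c, f))
      }
    }
  }
  if (length(fits) == 0) {
    stop("no reaction order could be fitted for ", inds, ": ",
         paste(failures, collapse = "; "))
  }
  if (length(failures) > 0) {
    warning("some fits were infeasible and excluded from selection: ",
            paste(failures, collapse = "; "))
  }
  indicator_kinetics(fits)
}

#' Select the best reaction order by summed R-squared
#'
#' The selected order maximises the sum of R-squared across temperatures, over
#' the orders feasible at every temperature. Ties are broken by (1) smaller
#' summed RMSE across temperatures, then (2) lower order.
#'
#' @param kinetics an [indicator_kinetics()] object.
#' @return the selected order as an integer (0, 1 or 2).
#' @export
select_order <- function(kinetics) {
  stopifnot(inherits(kinetics, "indicator_kinetics"))
  ok <- kinetics$orders %in% kinetics$feasible_orders
  orders <- kinetics$orders[ok]
  r2 <- kinetics$sum_r_squared[ok]
  rmse <- kinetics$sum_rmse[ok]
  best <- orders[.argmin_with_ties(-r2, rmse, orders)]
  as.integer(best)
}

# index of the minimum of `primary`, ties resolved by `secondary` then `tertiary`
.argmin_with_ties <- function(primary, secondary, tertiary, tol = 1e-12) {
  cand <- which(primary <= min(primary) + tol)
  if (length(cand) > 1) {
    cand <- cand[secondary[cand] <= min(secondary[cand]) + tol]
  }
  if (length(cand) > 1) {
    cand <- cand[which.min(tertiary[cand])]
  }
  cand[1]
}

#' @export
print.indicator_kinetics <- function(x, ...) {
  cat(sprintf("<indicator_kinetics> %s at %s degC\n", x$indicator,
              paste(x$temperatures_c, collapse = "/")))
  tab <- data.frame(order = x$orders,
                    sum_r_squared = unname(x$sum_r_squared),
                    sum_rmse = unname(x$sum_rmse))
  print(tab, row.names = FALSE)
  cat("selected order:", x$selected_order, "\n")
  if (length(x$infeasible_orders) > 0) {
    cat("infeasible orders (excluded):", paste(x$infeasible_orders, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.indicator_kinetics <- function(x, ...) {
  do.call(rbind, lapply(x$fits, function(f) {
    data.frame(indicator = f$indicator, temperature_c = f$temperature_c,
               order = f$order, k = f$k, intercept = f$intercept,
               r_squared = f$r_squared, rmse = f$rmse, n_points = f$n_points,
               stringsAsFactors = FALSE)
  }))
}
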