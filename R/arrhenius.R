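# Arrhenius temperature dependence of the rate constant:
#   ln k = ln K0 - Ea / (R T)     i.e.    k = K0 exp(-Ea / (R T))
# with T in Kelvin and R = 8.3144 J K^-1 mol^-1. Rate constants of decaying
# indicators are negative; their absolute values enter the log regression and
# the sign is stored and restored on prediction.

#' Construct an Arrhenius fit from slope and intercept
#'
#' The regression is `ln|k| = intercept + slope * (1/T)`, so `slope` is the
#' (negative, for ordinary positive activation energies) coefficient of `1/T`
#' in Kelvin. Activation energy and pre-exponential factor follow from the
#' arithmetic identities `Ea = -slope * R / 1000` (kJ/mol) and
#' `K0 = exp(intercept)`.
#'
#' @param slope coefficient of 1/T (Kelvin); pass `-8507.390` for a published
#'   line written as `ln k = 30.935 - 8507.390/T`.
#' @param intercept ln K0.
#' @param indicator,order bookkeeping labels (optional).
#' @param r_squared,rmse goodness of fit of the log-space regression, if known.
#' @param rate_sign `+1` or `-1`: the sign restored to predicted rate constants.
#' @param n_temperatures number of temperatures behind the fit, if known.
#' @return an `arrhenius_fit` object with fields `slope`, `intercept`,
#'   `ea_kj_per_mol`, `k0`, `r_squared`, `rmse`, `rate_sign`, ...
#' @export
#' @examples
#' arrhenius_fit(slope = -8507.390, intercept = 30.935, indicator = "TVB-N", order = 0)
arrhenius_fit <- function(slope, intercept, indicator = NA_character_,
                          order = NA_integer_, r_squared = NA_real_,
                          rmse = NA_real_, rate_sign = 1,
                          n_temperatures = NA_integer_) {
  stopifnot(is.finite(slope), is.finite(intercept), rate_sign %in% c(-1, 1))
  structure(
    list(indicator = normalize_indicator(indicator),
         order = if (is.na(order)) NA_integer_ else .check_order(order),
         slope = as.numeric(slope), intercept = as.numeric(intercept),
         ea_kj_per_mol = -slope * R_GAS / 1000,
         k0 = exp(intercept),
         r_squared = as.numeric(r_squared), rmse = as.numeric(rmse),
         rate_sign = as.numeric(rate_sign),
         n_temperatures = as.integer(n_temperatures)),
    class = "arrhenius_fit"
  )
}

#' Fit the Arrhenius equation to rate constants at several temperatures
#'
#' Ordinary least squares of `ln|k|` against `1/T` (Kelvin). All rate constants
#' must share one sign (a mixed-sign set indicates an inconsistent kinetic
#' direction across temperatures); the common sign is stored as `rate_sign` and
#' restored by [rate_at()].
#'
#' @param rates data frame with columns `temperature_c` and `k` (nonzero,
#'   consistent sign), one row per temperature; at least 3 distinct
#'   temperatures (2 are permitted with a warning — the log-space R-squared is
#'   then degenerate).
#' @param indicator,order bookkeeping labels propagated to the result.
#' @return an [arrhenius_fit()] object.
#' @export
#' @examples
#' k <- 2.72e13 * exp(-8507.390 / celsius_to_kelvin(c(4, 25, 37)))
#' fit_arrhenius(data.frame(temperature_c = c(4, 25, 37), k = k))
fit_arrhenius <- function(rates, indicator = NA_character_, order = NA_integer_) {
  stopifnot(is.data.frame(rates),
            all(c("temperature_c", "k") %in% names(rates)))
  rates <- rates[base::order(rates$temperature_c), , drop = FALSE]
  temps <- rates$temperature_c
  k <- rates$k
  if (anyDuplicated(temps)) stop("duplicate temperatures in Arrhenius input")
  if (length(temps) < 2) stop("Arrhenius regression needs at least 2 temperatures")
  if (any(k == 0)) stop("rate constant k = 0 at ", temps[which(k == 0)[1]],
                        " degC: ln|k| undefined")
  if (length(unique(sign(k))) != 1) {
    stop("mixed-sign rate constants across temperatures: ",
         "kinetic direction is inconsistent; fit orders per direction")
  }
  if (length(temps) == 2) {
    warning("only 2 temperatures: Arrhenius fit is exact by construction; R-squared is degenerate")
  }
  x <- 1 / celsius_to_kelvin(temps)
  y <- log(abs(k))
  coefs <- stats::lm.fit(cbind(1, x), y)$coefficients
  intercept <- unname(coefs[1])
  slope <- unname(coefs[2])
  fitted <- intercept + slope * x
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else if (ss_res <= 1e-24) 1 else NaN
  arrhenius_fit(slope = slope, intercept = intercept, indicator = indicator,
                order = order, r_squared = r2, rmse = sqrt(mean((y - fitted)^2)),
                rate_sign = sign(k[1]), n_temperatures = length(temps))
}

#' Activation energy from the Arrhenius slope
#'
#' `Ea = |slope| * R / 1000` in kJ/mol, with R = 8.3144 J/(K mol). Accepts
#' either the fitted (negative) coefficient of 1/T or the positive magnitude as
#' printed in published tables — both give the same positive Ea.
#'
#' @param slope coefficient of 1/T in Kelvin (either sign).
#' @return activation energy in kJ/mol.
#' @export
#' @examples
#' ea_from_slope(8507.390) # ~70.73 kJ/mol
ea_from_slope <- function(slope) {
  stopifnot(is.numeric(slope), all(is.finite(slope)))
  abs(slope) * R_GAS / 1000
}

#' Pre-exponential factor from the Arrhenius intercept
#'
#' @param intercept ln K0.
#' @return K0 = exp(intercept), in the units of the rate constant.
#' @export
k0_from_intercept <- function(intercept) {
  stopifnot(is.numeric(intercept), all(is.finite(intercept)))
  exp(intercept)
}

#' Evaluate the rate constant at a temperature
#'
#' `k = rate_sign * K0 * exp(-Ea * 1000 / (R * T))` with T in Kelvin.
#'
#' @param fit an [arrhenius_fit()].
#' @param temperature_c temperature(s) in degrees Celsius (> -273.15).
#' @return rate constant(s), signed.
#' @export
rate_at <- function(fit, temperature_c) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  t_k <- celsius_to_kelvin(temperature_c)
  fit$rate_sign * fit$k0 * exp(-fit$ea_kj_per_mol * 1000 / (R_GAS * t_k))
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  lab <- if (is.na(x$indicator)) "" else paste0(" ", x$indicator)
  ord <- if (is.na(x$order)) "" else sprintf(" (order %d)", x$order)
  cat(sprintf("<arrhenius_fit>%s%s: ln|k| = %.4f %+.4f/T\n",
              lab, ord, x$intercept, x$slope))
  cat(sprintf("  Ea = %.3f kJ/mol, K0 = %.4g, rate sign %+d, R2 = %.4f\n",
              x$ea_kj_per_mol, x$k0, x$rate_sign, x$r_squared))
  invisible(x)
}
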