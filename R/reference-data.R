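# Published reference values from a storage study of ready-to-eat crayfish
# (vacuum-packed, spicy, held at 4/25/37 degC). These tables carry only the
# study's *printed summary statistics* — per-(temperature, order) fit quality,
# Arrhenius regression lines, a 10 degC validation table and a single-factor
# sensory screen — not raw trajectories, which were shown only graphically.
# They serve as desk-checks of the package's arithmetic (sum-R-squared order
# selection, Ea/K0 identities, deviation percentages) and as worked-example
# inputs.

#' Published kinetic fit quality for ready-to-eat crayfish
#'
#' R-squared (transformed space) and RMSE (original units) of zero-, first- and
#' second-order fits for five spoilage indicators at 4, 25 and 37 degC.
#'
#' @return data frame with columns `indicator`, `temperature_c`, `order`,
#'   `r_squared`, `rmse`.
#' @export
#' @examples
#' ref <- crayfish_kinetics_reference()
#' sum(ref$r_squared[ref$indicator == "TVB-N" & ref$order == 0]) # 2.906
crayfish_kinetics_reference <- function() {
  g <- expand.grid(temperature_c = c(4, 25, 37), order = 0:2,
                   indicator = c("TVB-N", "TVC", "AV", "springiness", "hardness"),
                   stringsAsFactors = FALSE)
  g <- g[, c("indicator", "temperature_c", "order")]
  # R2 then RMSE, listed per indicator as order 0 (4,25,37), order 1, order 2
  g$r_squared <- c(
    0.956, 0.972, 0.978,  0.910, 0.972, 0.974,  0.873, 0.886, 0.797,  # TVB-N
    0.952, 0.963, 0.963,  0.970, 0.952, 0.966,  0.960, 0.855, 0.810,  # TVC
    0.980, 0.979, 0.986,  0.998, 0.993, 0.949,  0.977, 0.856, 0.872,  # AV
    0.934, 0.876, 0.884,  0.924, 0.856, 0.859,  0.913, 0.821, 0.820,  # springiness
    0.988, 0.982, 0.943,  0.991, 0.983, 0.984,  0.989, 0.952, 0.978   # hardness
  )
  g$rmse <- c(
    0.967, 2.961, 3.848,  1.382, 2.955, 4.208,  1.492, 4.019, 4.025,
    0.108, 0.551, 0.629,  0.084, 0.534, 0.600,  0.105, 1.278, 2.301,
    0.107, 0.170, 0.248,  0.032, 0.100, 0.467,  0.031, 1.160, 1.802,
    0.070, 0.151, 0.178,  0.077, 0.161, 0.195,  0.505, 0.813, 1.017,
    3.630, 10.052, 28.032,  3.578, 9.829, 14.868,  5.463, 20.864, 32.768
  )
  g
}

#' Published Arrhenius regression lines for ready-to-eat crayfish
#'
#' For each indicator at its selected reaction order: the regression
#' `ln|k| = intercept + slope/T` (slope stored as the signed coefficient of
#' 1/T in Kelvin), its goodness of fit, and the activation energy (kJ/mol) and
#' pre-exponential factor K0 as printed. Note: the printed springiness K0
#' (4.10e7) is inconsistent with its own intercept (exp(17.259) = 3.13e7,
#' consistent instead with 17.529 — an apparent digit transposition); the
#' package always derives K0 from the intercept.
#'
#' @return data frame with columns `indicator`, `order`, `slope`, `intercept`,
#'   `r_squared`, `rmse`, `ea_published`, `k0_published`, `rate_sign`.
#' @export
crayfish_arrhenius_reference <- function() {
  data.frame(
    indicator = c("TVB-N", "TVC", "AV", "springiness", "hardness"),
    order = c(0L, 1L, 0L, 0L, 1L),
    slope = -c(8507.390, 5527.722, 5911.062, 5521.926, 7776.532),
    intercept = c(30.935, 17.924, 19.695, 17.259, 24.527),
    r_squared = c(0.949, 0.898, 0.968, 0.939, 0.988),
    rmse = c(0.313, 0.298, 0.172, 0.224, 0.137),
    ea_published = c(70.736, 45.961, 49.149, 45.913, 64.660),
    k0_published = c(2.72e13, 6.09e7, 3.58e8, 4.10e7, 4.49e10),
    rate_sign = c(1, 1, 1, -1, -1),
    stringsAsFactors = FALSE
  )
}

#' Published 10 degC validation table for ready-to-eat crayfish
#'
#' Measured versus model-predicted indicator values after 2-10 days at 10 degC,
#' with the printed relative deviation percentages.
#'
#' @return data frame with columns `indicator`, `time_days`, `measured`,
#'   `predicted`, `deviation_published_pct`.
#' @export
crayfish_validation_reference <- function() {
  data.frame(
    indicator = rep(c("TVB-N", "TVC", "AV", "springiness", "hardness"), each = 5),
    time_days = rep(c(2, 4, 6, 8, 10), times = 5),
    measured = c(12.71, 17.18, 21.09, 27.00, 29.31,
                 0.81, 1.21, 2.04, 2.76, 3.83,
                 1.95, 2.51, 3.05, 3.42, 4.48,
                 3.76, 3.73, 3.16, 3.21, 2.94,
                 324.27, 335.13, 251.84, 268.20, 238.05),
    predicted = c(11.79, 16.57, 21.36, 26.15, 30.94,
                  0.84, 1.26, 1.88, 2.81, 4.19,
                  1.81, 2.42, 3.02, 3.63, 4.24,
                  3.96, 3.68, 3.40, 3.13, 2.85,
                  341.38, 307.49, 276.96, 249.47, 224.70),
    deviation_published_pct = c(7.80, 3.66, 1.27, 3.25, 5.24,
                                4.33, 4.22, 8.80, 1.79, 8.45,
                                7.62, 3.89, 0.87, 5.78, 5.61,
                                4.99, 1.43, 7.14, 2.58, 3.11,
                                5.01, 8.99, 9.07, 7.51, 5.94),
    stringsAsFactors = FALSE
  )
}

#' Published single-factor sensory screen for ready-to-eat crayfish
#'
#' Mean panel scores (10-point scale) for three processing factors varied one
#' at a time: spice addition (%), salt addition (%) and simmering time (min).
#'
#' @return named list of three [factor_table()] objects: `spice_pct`,
#'   `salt_pct`, `simmering_min`.
#' @export
crayfish_sensory_reference <- function() {
  list(
    spice_pct = factor_table("spice_pct", c(0.6, 0.8, 1.0, 1.2, 1.4),
                             c(7.62, 7.83, 8.36, 8.92, 8.46),
                             c(0.08, 0.06, 0.10, 0.09, 0.05)),
    salt_pct = factor_table("salt_pct", c(0.35, 0.50, 0.65, 0.80, 0.95),
                            c(7.91, 8.13, 8.37, 8.96, 8.06),
                            c(0.09, 0.06, 0.06, 0.09, 0.12)),
    simmering_min = factor_table("simmering_min", c(50, 60, 70, 80, 90),
                                 c(7.52, 8.29, 9.25, 8.28, 7.80),
                                 c(0.11, 0.07, 0.10, 0.12, 0.10))
  )
}
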