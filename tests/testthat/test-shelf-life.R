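test_that("predict_value implements the order-0 and order-1 laws", {
  m0 <- shelf_life_model(arrhenius_fit(0, log(2), indicator = "TVB-N", order = 0),
                         a0 = 10, limit_value = 35, limit_side = "upper")
  expect_equal(predict_value(m0, 0, 25), 10)
  expect_equal(predict_value(m0, 0:5, 25), 10 + 2 * (0:5)) # k = 2 flat in T

  # published TVC parameters at 10 degC, t = 2 days
  m1 <- tvc_model()
  expect_equal(predict_value(m1, 0, 10), 0.57)
  p2 <- predict_value(m1, 2, 10)
  expect_equal(p2, 0.57 * exp(exp(17.924 - 5527.722 / 283.15) * 2), tolerance = 1e-12)
  expect_equal(p2, 0.85, tolerance = 0.005)  # matches the printed 0.84 within rounding
  expect_lt(abs(p2 - 0.84), 0.02)

  # decaying zero-order indicator decreases strictly in t
  md <- shelf_life_model(arrhenius_fit(0, log(0.3), rate_sign = -1,
                                       indicator = "springiness", order = 0),
                         a0 = 4.23, limit_value = 3, limit_side = "lower")
  vals <- predict_value(md, 0:5, 25)
  expect_true(all(diff(vals) < 0))
  expect_error(predict_value(m0, -1, 25), ">= 0")
})

test_that("order 2 has no shelf-life model", {
  af <- arrhenius_fit(-5000, 10, order = 2)
  expect_error(shelf_life_model(af, a0 = 1, limit_value = 5, limit_side = "upper"),
               "orders 0 and 1")
})

test_that("shelf_life_time inverts the kinetic model", {
  # unit-rate zero order: a0 = 0, k = 1/day, limit 35 -> 35 days
  m <- shelf_life_model(arrhenius_fit(0, log(1), indicator = "TVB-N", order = 0),
                        a0 = 0, limit_value = 35, limit_side = "upper")
  expect_equal(shelf_life_time(m, 25), 35)

  # first-order TVC at 25 degC: SL = ln(6/0.57)/k, and inverse consistency
  m1 <- tvc_model()
  k25 <- rate_at(m1$arrhenius, 25)
  sl <- shelf_life_time(m1, 25)
  expect_equal(sl, log(6 / 0.57) / k25, tolerance = 1e-12)
  expect_equal(predict_value(m1, sl, 25), 6, tolerance = 1e-9)

  # unreachable limit: k > 0 but the limit is below a0
  bad <- shelf_life_model(arrhenius_fit(0, log(2), indicator = "TVB-N", order = 0),
                          a0 = 10, limit_value = 5, limit_side = "lower")
  expect_error(shelf_life_time(bad, 25), "infeasible")

  # k = 0 signals unbounded shelf life, not a number
  frozen <- shelf_life_model(
    structure(list(indicator = "AV", order = 0L, slope = 0, intercept = -Inf,
                   ea_kj_per_mol = 0, k0 = 0, r_squared = NA_real_,
                   rmse = NA_real_, rate_sign = 1, n_temperatures = NA_integer_),
              class = "arrhenius_fit"),
    a0 = 1, limit_value = 5, limit_side = "upper", indicator = "AV", order = 0)
  expect_message(sl0 <- shelf_life_time(frozen, 25), "unbounded")
  expect_identical(sl0, Inf)
})

test_that("inverse consistency and temperature monotonicity hold on a fuzzed grid", {
  set.seed(7)
  for (i in 1:25) {
    order <- sample(0:1, 1)
    ea <- runif(1, 20, 100)
    a0 <- runif(1, 0.5, 20)
    up <- runif(1) < 0.5
    limit <- if (up) a0 * runif(1, 1.5, 4) else a0 * runif(1, 0.3, 0.9)
    # scale K0 so the rate at 20 degC has a sane magnitude
    k0 <- runif(1, 0.05, 2) / exp(-ea * 1000 / (8.3144 * 293.15))
    af <- arrhenius_fit(-ea * 1000 / 8.3144, log(k0),
                        rate_sign = if (up) 1 else -1,
                        indicator = "TVB-N", order = order)
    m <- shelf_life_model(af, a0 = a0, limit_value = limit,
                          limit_side = if (up) "upper" else "lower")
    temps <- c(4, 10, 25, 37)
    sls <- vapply(temps, function(tc) shelf_life_time(m, tc), 0)
    for (j in seq_along(temps)) {
      expect_equal(predict_value(m, sls[j], temps[j]), limit,
                   tolerance = 1e-9 * abs(limit))
    }
    # Ea > 0: spoilage accelerates with temperature, shelf life strictly falls
    expect_true(all(diff(sls) < 0))
  }
})

test_that("overall shelf life is the minimum over feasible indicators", {
  fast <- shelf_life_model(arrhenius_fit(0, log(1), indicator = "TVC", order = 0),
                           a0 = 0, limit_value = 1.5, limit_side = "upper")
  slow <- shelf_life_model(arrhenius_fit(0, log(1), indicator = "TVB-N", order = 0),
                           a0 = 0, limit_value = 4.36, limit_side = "upper")
  res <- overall_shelf_life(list(slow, fast), 25)
  expect_equal(res$shelf_life_days, 1.5)
  expect_identical(res$limiting_indicator, "TVC")

  # an infinite (k = 0) indicator is excluded with a note
  frozen <- shelf_life_model(
    structure(list(indicator = "AV", order = 0L, slope = 0, intercept = -Inf,
                   ea_kj_per_mol = 0, k0 = 0, r_squared = NA_real_,
                   rmse = NA_real_, rate_sign = 1, n_temperatures = NA_integer_),
              class = "arrhenius_fit"),
    a0 = 1, limit_value = 5, limit_side = "upper", indicator = "AV", order = 0)
  res2 <- overall_shelf_life(list(frozen, slow), 25)
  expect_equal(res2$shelf_life_days, 4.36)
  expect_match(res2$notes, "infinite", all = FALSE)

  # tie: first indicator in canonical registry order wins, both reported
  tvb <- shelf_life_model(arrhenius_fit(0, log(1), indicator = "TVB-N", order = 0),
                          a0 = 0, limit_value = 2, limit_side = "upper")
  av <- shelf_life_model(arrhenius_fit(0, log(1), indicator = "AV", order = 0),
                         a0 = 0, limit_value = 2, limit_side = "upper")
  res3 <- overall_shelf_life(list(av, tvb), 25)
  expect_identical(res3$limiting_indicator, "TVB-N")
  expect_identical(res3$tied_with, "AV")

  expect_error(overall_shelf_life(list(frozen), 25), "no indicator")
})

test_that("relative deviation uses the predicted value as denominator", {
  expect_equal(relative_deviation(12.71, 11.79), 7.80, tolerance = 0.005 / 7.80)
  expect_equal(relative_deviation(324.27, 341.38), 5.01, tolerance = 0.005 / 5.01)
  expect_identical(relative_deviation(3.7, 3.7), 0)
  expect_equal(relative_deviation(c(1, 3), c(2, 2)), c(50, 50))
  expect_error(relative_deviation(1, 0), "predicted = 0")
})

test_that("validate_predictions tabulates deviations with a summary", {
  m <- tvc_model()
  times <- c(2, 4, 6, 8, 10)
  truth <- predict_value(m, times, 10)

  # measured == predicted -> all-zero deviations, zero RMSE
  exact <- indicator_series("TVC", 10, times, truth)
  v <- validate_predictions(exact, m)
  expect_equal(v$records$relative_deviation_pct, rep(0, 5))
  expect_equal(v$summary$rmse, 0)

  # perturbed measurements give the hand-computed deviations
  measured <- indicator_series("TVC", 10, times, truth * c(1.05, 0.95, 1, 1.1, 0.9))
  v2 <- validate_predictions(measured, m)
  expect_equal(v2$records$predicted, truth)
  expect_equal(v2$records$relative_deviation_pct, c(5, 5, 0, 10, 10), tolerance = 1e-9)
  expect_equal(v2$summary$max_deviation_pct, 10, tolerance = 1e-9)
  expect_equal(v2$summary$mean_deviation_pct, 6, tolerance = 1e-9)
})
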