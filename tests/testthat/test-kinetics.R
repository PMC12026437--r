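test_that("kinetic transforms are the documented maps with exact inverses", {
  expect_equal(kinetic_transform(c(1, exp(1), exp(2)), 1), c(0, 1, 2))
  expect_equal(kinetic_transform(c(2, 4), 2), c(0.5, 0.25))
  v <- c(3.2, 0.1, 57)
  expect_identical(kinetic_transform(v, 0), v)
  for (o in 0:2) {
    expect_equal(kinetic_back_transform(kinetic_transform(v, o), o), v)
  }
  expect_error(kinetic_transform(c(1, -2), 1, times = c(0, 3)), "t = 3 days")
  expect_error(kinetic_transform(c(1, 0), 2), "position 2")
  expect_error(kinetic_transform(1:3, 3), "order")
})

test_that("fit_kinetic recovers exact lines and handles degenerate input", {
  # noise-free zero order: A = 10 + 2 t
  f0 <- fit_kinetic(exact_series(0, k = 2, times = 0:4), 0)
  expect_equal(f0$k, 2)
  expect_equal(f0$intercept, 10)
  expect_equal(f0$r_squared, 1)
  expect_equal(f0$rmse, 0, tolerance = 1e-12)
  expect_identical(f0$n_points, 5L)

  # noise-free first-order decay: A = 100 exp(-0.3 t), log-linear in t
  s1 <- indicator_series("hardness", 25, 0:3, 100 * exp(-0.3 * (0:3)))
  f1 <- fit_kinetic(s1, 1)
  expect_equal(f1$k, -0.3, tolerance = 1e-12)
  expect_equal(f1$intercept, log(100), tolerance = 1e-12)

  # constant series: zero slope, zero error
  sc <- indicator_series("AV", 4, 0:2, c(5, 5, 5))
  fc <- fit_kinetic(sc, 0)
  expect_equal(fc$k, 0)
  expect_equal(fc$rmse, 0)

  expect_error(fit_kinetic(indicator_series("AV", 4, 0:1, c(1, 2)), 0),
               "insufficient")
  degenerate <- structure(
    list(indicator = "AV", unit = "mg KOH/g", temperature_c = 4,
         times_days = c(1, 1, 1), values = c(1, 2, 3), direction = "increasing"),
    class = "indicator_series")
  expect_error(fit_kinetic(degenerate, 0), "degenerate")
})

test_that("force_intercept pins the line through the transformed first value", {
  s <- indicator_series("TVB-N", 25, 0:3, c(10, 13, 14, 19))
  f <- fit_kinetic(s, 0, force_intercept = TRUE)
  expect_equal(f$intercept, 10)
  # constrained slope oracle: minimise sum((y - y0 - b t)^2) => b = sum(t (y-y0)) / sum(t^2)
  t <- 0:3; y <- c(10, 13, 14, 19)
  expect_equal(f$k, sum(t * (y - 10)) / sum(t^2))
})

test_that("OLS slope/intercept match the normal-equation oracle", {
  set.seed(101)
  for (n in 3:6) {
    t <- sort(runif(n, 0, 10))
    t[1] <- 0
    for (o in 0:2) {
      a <- exp(runif(n, -1, 2)) # positive, valid for all orders
      s <- indicator_series("AV", 25, t, a)
      f <- fit_kinetic(s, o)
      oracle <- ols_oracle(t, kinetic_transform(a, o))
      expect_equal(f$k, oracle$slope, tolerance = 1e-9)
      expect_equal(f$intercept, oracle$intercept, tolerance = 1e-9)
    }
  }
})

test_that("noise-free data generated by order o is identified as order o", {
  cases <- expand.grid(order = 0:2, k = c(0.25, -0.05), a0 = c(10, 4))
  # keep order-2 reciprocal trajectories away from the pole 1/a0 + k t = 0
  cases$k[cases$order == 2 & cases$k < 0] <- -0.01
  for (i in seq_len(nrow(cases))) {
    o <- cases$order[i]
    s <- exact_series(o, cases$k[i], a0 = cases$a0[i], times = 0:5,
                      direction = if (cases$k[i] < 0) "decreasing" else "increasing")
    f <- fit_kinetic(s, o)
    expect_equal(f$r_squared, 1, tolerance = 1e-9)
    expect_equal(f$rmse, 0, tolerance = 1e-9)
    expect_equal(sign(f$k), sign(cases$k[i]))
    # with all three orders feasible, selection returns the generating order
    kin <- fit_all_orders(
      list(s,
           exact_series(o, cases$k[i] * 1.6, a0 = cases$a0[i], times = 0:5,
                        temperature_c = 37,
                        direction = if (cases$k[i] < 0) "decreasing" else "increasing")))
    expect_identical(kin$selected_order, as.integer(o))
  }
})

test_that("fit_all_orders sums R-squared across temperatures per order", {
  kin <- fit_all_orders(list(exact_series(0, 1.0, temperature_c = 4),
                             exact_series(0, 2.0, temperature_c = 25),
                             exact_series(0, 3.0, temperature_c = 37)))
  # exact data: R2 = 1 at each of the three temperatures for order 0
  expect_equal(unname(kin$sum_r_squared["order0"]), 3)
  expect_identical(kin$selected_order, 0L)
  expect_setequal(kin$feasible_orders, 0:2)

  # single temperature: sums equal that temperature's R2
  one <- fit_all_orders(list(exact_series(1, 0.2)))
  f <- fit_kinetic(exact_series(1, 0.2), 0)
  expect_equal(unname(one$sum_r_squared["order0"]), f$r_squared)

  expect_error(fit_all_orders(list(exact_series(0, 1, indicator = "AV"),
                                   exact_series(0, 1, indicator = "TVC",
                                                temperature_c = 37))),
               "one indicator")
})

test_that("orders infeasible at any temperature are excluded and flagged", {
  # a zero value makes orders 1 and 2 infeasible at 25 degC
  s_bad <- indicator_series("springiness", 25, 0:3, c(3, 2, 1, 0),
                            direction = "decreasing")
  s_ok <- exact_series(0, -0.2, a0 = 3, temperature_c = 4,
                       indicator = "springiness", direction = "decreasing")
  expect_warning(kin <- fit_all_orders(list(s_ok, s_bad)), "infeasible")
  expect_identical(kin$feasible_orders, 0L)
  expect_setequal(kin$infeasible_orders, 1:2)
  expect_identical(kin$selected_order, 0L)
})

test_that("select_order maximises sum R2 with rmse then lower-order tie-breaks", {
  mk <- function(r2s, rmses) {
    fits <- list()
    for (o in 0:2) for (i in 1:3) {
      fits[[length(fits) + 1]] <- kinetic_fit(
        "TVB-N", c(4, 25, 37)[i], o, k = 1, intercept = 0,
        r_squared = r2s[[o + 1]][i], rmse = rmses[[o + 1]][i], n_points = 6)
    }
    indicator_kinetics(fits)
  }
  # published-style sums: (2.906, 2.856, 2.556) -> order 0
  kin <- mk(list(c(0.956, 0.972, 0.978), c(0.910, 0.972, 0.974),
                 c(0.873, 0.886, 0.797)),
            list(rep(1, 3), rep(1, 3), rep(1, 3)))
  expect_equal(unname(kin$sum_r_squared), c(2.906, 2.856, 2.556))
  expect_identical(select_order(kin), 0L)

  # R2 tie between orders 0 and 1: smaller rmse sum wins
  tie <- mk(list(c(0.9, 0.9, 0.9), c(0.9, 0.9, 0.9), c(0.1, 0.1, 0.1)),
            list(c(1, 1, 1), c(0.5, 0.5, 1), c(1, 1, 1)))
  expect_identical(select_order(tie), 1L)

  # everything equal: lowest order wins
  flat <- mk(list(rep(0.9, 3), rep(0.9, 3), rep(0.9, 3)),
             list(rep(1, 3), rep(1, 3), rep(1, 3)))
  expect_identical(select_order(flat), 0L)
})

test_that("sum R2 is invariant to temperature ordering", {
  series <- list(exact_series(1, 0.1, temperature_c = 4),
                 exact_series(1, 0.3, temperature_c = 25),
                 exact_series(1, 0.5, temperature_c = 37))
  kin1 <- fit_all_orders(series)
  kin2 <- fit_all_orders(rev(series))
  expect_equal(kin1$sum_r_squared, kin2$sum_r_squared)
  expect_identical(kin1$selected_order, kin2$selected_order)
})
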