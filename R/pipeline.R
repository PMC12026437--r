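# End-to-end orchestration: read -> fit all orders -> select -> Arrhenius ->
# shelf-life models -> (optional) validation, with a structured decision log.
# The JSON report is canonical and deliberately carries no timestamps, so an
# identical configuration and seed rerun is byte-identical.

#' Run the full shelf-life modelling pipeline
#'
#' For every indicator present in the input with series at two or more
#' temperatures: fit the candidate reaction orders at each temperature, select
#' the best order by summed R-squared, regress the selected order's rate
#' constants on 1/T (Arrhenius), and — when a critical limit is configured and
#' the selected order is 0 or 1 — build a shelf-life model and tabulate
#' predicted shelf lives at the requested temperatures. Indicators observed at
#' a single temperature are fitted but skipped for the Arrhenius stage, with a
#' notice in the log.
#'
#' @param input path to the input CSV (see [read_indicator_series()]).
#' @param config optional configuration list from [read_config()]; its `limits`
#'   default to [default_critical_limits()].
#' @param orders candidate reaction orders (default 0, 1, 2).
#' @param predict_temperatures_c temperatures (degC) at which to tabulate shelf
#'   lives (default `c(4, 10, 25)`).
#' @param validation optional list `list(path =, temperature_c =)` of measured
#'   validation series to score against the fitted models.
#' @param indicators optional subset of indicators to process.
#' @param force_intercept see [fit_kinetic()].
#' @param output optional path: the report is also written there as JSON via
#'   [write_results()].
#' @return a `shelfkin_report` object: list with `schema_version`, `input`,
#'   `fits`, `arrhenius`, `shelf_life`, `validation`, `log`.
#' @export
run_pipeline <- function(input, config = NULL, orders = c(0, 1, 2),
                         predict_temperatures_c = c(4, 10, 25),
                         validation = NULL, indicators = NULL,
                         force_intercept = FALSE, output = NULL) {
  series <- read_indicator_series(input, config)
  limits <- if (!is.null(config$limits)) config$limits else default_critical_limits()
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))

  all_inds <- unique(vapply(series, `[[`, "", "indicator"))
  if (!is.null(indicators)) {
    keep <- normalize_indicator(indicators)
    all_inds <- all_inds[all_inds %in% keep]
    if (length(all_inds) == 0) stop("none of the requested indicators are present in the input")
  }
  say("input: %s (%d series, %d indicator(s))", input, length(series), length(all_inds))

  fits <- list()
  arrhenius <- list()
  models <- list()
  shelf_life_tab <- list()
  for (ind in all_inds) {
    grp <- series[vapply(series, function(s) s$indicator == ind, TRUE)]
    kin <- withCallingHandlers(
      fit_all_orders(grp, orders = orders, force_intercept = force_intercept),
      warning = function(w) {
        say("%s: %s", ind, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    fits[[ind]] <- kin
    say("%s: selected order %d (sum R2 = %s)", ind, kin$selected_order,
        paste(sprintf("%s=%.3f", names(kin$sum_r_squared), kin$sum_r_squared),
              collapse = ", "))
    if (length(kin$temperatures_c) < 2) {
      say("%s: only one temperature; Arrhenius stage skipped", ind)
      next
    }
    keys <- sprintf("%gC|order%d", kin$temperatures_c, kin$selected_order)
    k_hat <- vapply(kin$fits[keys], `[[`, 0, "k")
    af <- withCallingHandlers(
      fit_arrhenius(data.frame(temperature_c = kin$temperatures_c, k = k_hat),
                    indicator = ind, order = kin$selected_order),
      warning = function(w) {
        say("%s: %s", ind, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    arrhenius[[ind]] <- af
    say("%s: Arrhenius Ea = %.3f kJ/mol, K0 = %.4g (R2 = %.3f)",
        ind, af$ea_kj_per_mol, af$k0, af$r_squared)

    lim <- get_limit(limits, ind)
    if (is.null(lim)) {
      say("%s: no critical limit configured; shelf-life stage skipped", ind)
      next
    }
    if (!kin$selected_order %in% c(0, 1)) {
      say("%s: selected order %d has no closed-form shelf life; stage skipped",
          ind, kin$selected_order)
      next
    }
    # a0 convention: measured t = 0 value, averaged over temperatures where present
    t0_vals <- unlist(lapply(grp, function(s) s$values[s$times_days == 0]))
    if (length(t0_vals) == 0) {
      say("%s: no t = 0 observation to anchor a0; shelf-life stage skipped", ind)
      next
    }
    a0 <- mean(t0_vals)
    model <- shelf_life_model(af, a0 = a0, limit_value = lim$value,
                              limit_side = lim$side, indicator = ind)
    models[[ind]] <- model
    say("%s: shelf-life model %s (a0 = %.4g, %s limit %g)",
        ind, shelf_life_equation(model), a0, lim$side, lim$value)
    sl <- vapply(predict_temperatures_c, function(tc) {
      tryCatch(suppressMessages(shelf_life_time(model, tc)),
               error = function(e) NA_real_)
    }, 0)
    shelf_life_tab[[ind]] <- data.frame(indicator = ind,
                                        temperature_c = predict_temperatures_c,
                                        shelf_life_days = sl,
                                        stringsAsFactors = FALSE)
  }

  validation_out <- NULL
  if (!is.null(validation)) {
    stopifnot(is.list(validation), !is.null(validation$path))
    measured <- read_indicator_series(validation$path, config)
    validation_out <- list()
    for (s in measured) {
      temp <- if (!is.null(validation$temperature_c)) validation$temperature_c
              else s$temperature_c
      if (is.null(models[[s$indicator]])) {
        say("validation: no model for %s; skipped", s$indicator)
        next
      }
      v <- validate_predictions(s, models[[s$indicator]], temperature_c = temp)
      validation_out[[sprintf("%s@%gC", s$indicator, temp)]] <- v
      say("validation %s at %g degC: max deviation %.2f%%",
          s$indicator, temp, v$summary$max_deviation_pct)
    }
  }

  report <- structure(
    list(schema_version = "shelfkin-report/1",
         input = input,
         indicators = all_inds,
         fits = fits,
         arrhenius = arrhenius,
         shelf_life = list(
           models = models,
           equations = lapply(models, shelf_life_equation),
           table = if (length(shelf_life_tab) > 0) do.call(rbind, c(shelf_life_tab, list(make.row.names = FALSE))) else NULL),
         validation = validation_out,
         log = log),
    class = "shelfkin_report"
  )
  if (!is.null(output)) write_results(report, output)
  report
}

#' @export
print.shelfkin_report <- function(x, ...) {
  cat("<shelfkin_report>", x$schema_version, "\n")
  cat("indicators:", paste(x$indicators, collapse = ", "), "\n\n")
  for (ind in names(x$fits)) print(x$fits[[ind]])
  cat("\n")
  for (ind in names(x$arrhenius)) print(x$arrhenius[[ind]])
  if (!is.null(x$shelf_life$table)) {
    cat("\nshelf life (days):\n")
    print(x$shelf_life$table, row.names = FALSE)
  }
  if (!is.null(x$validation)) {
    cat("\n")
    for (v in x$validation) print(v)
  }
  invisible(x)
}
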