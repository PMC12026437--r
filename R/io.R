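# CSV / JSON plumbing. Input dialect: comma-separated, header row, UTF-8,
# period decimal separator; columns indicator,temperature_c,time,time_unit,value.

.required_columns <- c("indicator", "temperature_c", "time", "time_unit", "value")

.parse_numeric_column <- function(x, column) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad) > 0 || anyNA(out)) {
    row <- if (length(bad) > 0) bad[1] else which(is.na(out))[1]
    stop(sprintf("could not parse column '%s' as a number in row %d (value \"%s\")",
                 column, row, x[row]))
  }
  out
}

#' Read indicator time series from CSV
#'
#' Reads long-format measurements and groups them into one [indicator_series()]
#' per (indicator, storage temperature) pair. Times given in hours are converted
#' to days (division by 24); rows are sorted by time within each group.
#'
#' @param path CSV file with columns `indicator`, `temperature_c`, `time`,
#'   `time_unit` (`"hours"` or `"days"`), `value`. Extra columns (e.g. a
#'   replicate id) are ignored.
#' @param config optional configuration as returned by [read_config()] (or any
#'   list with `directions` / `units` elements) supplying direction and unit for
#'   indicators absent from the built-in registry.
#' @return named list of `indicator_series`, names `"<indicator>@<temp>C"`,
#'   ordered by indicator then temperature.
#' @export
read_indicator_series <- function(path, config = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  missing_cols <- setdiff(.required_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("input CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0) stop("input CSV has no data rows")

  unit_tok <- tolower(trimws(raw$time_unit))
  bad_unit <- which(!unit_tok %in% c("hours", "days"))
  if (length(bad_unit) > 0) {
    stop(sprintf("time_unit must be 'hours' or 'days'; row %d has \"%s\"",
                 bad_unit[1], raw$time_unit[bad_unit[1]]))
  }
  temperature_c <- .parse_numeric_column(raw$temperature_c, "temperature_c")
  time <- .parse_numeric_column(raw$time, "time")
  value <- .parse_numeric_column(raw$value, "value")
  indicator <- normalize_indicator(trimws(raw$indicator))
  time_days <- ifelse(unit_tok == "hours", hours_to_days(time), time)

  key <- paste(indicator, temperature_c, time_days, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf("duplicate record for indicator '%s' at %g degC, t = %g days (row %d)",
                 indicator[d], temperature_c[d], time_days[d], d))
  }

  df <- data.frame(indicator = indicator, temperature_c = temperature_c,
                   time_days = time_days, value = value, stringsAsFactors = FALSE)
  groups <- split(df, list(df$indicator, df$temperature_c), drop = TRUE)
  series <- lapply(groups, function(g) {
    g <- g[order(g$time_days), , drop = FALSE]
    ind <- g$indicator[1]
    indicator_series(
      indicator = ind,
      temperature_c = g$temperature_c[1],
      times_days = g$time_days,
      values = g$value,
      unit = .config_lookup(config, "units", ind),
      direction = .config_lookup(config, "directions", ind)
    )
  })
  ord <- order(canonical_indicator_rank(vapply(series, `[[`, "", "indicator")),
               vapply(series, `[[`, 0, "temperature_c"))
  series <- series[ord]
  names(series) <- vapply(series, function(s) {
    sprintf("%s@%gC", s$indicator, s$temperature_c)
  }, "")
  series
}

.config_lookup <- function(config, field, indicator) {
  if (is.null(config) || is.null(config[[field]])) return(NULL)
  tbl <- config[[field]]
  names(tbl) <- normalize_indicator(names(tbl))
  val <- tbl[[normalize_indicator(indicator)]]
  if (is.null(val)) NULL else as.character(val)
}

#' Read a configuration JSON
#'
#' Schema: `{"limits": {"TVB-N": {"value": 35, "side": "upper"}, ...},
#' "directions": {...}, "units": {...}}`. All blocks are optional; `limits`
#' is returned as a [critical_limits()] object.
#'
#' @param path JSON file.
#' @return list with elements `limits`, `directions`, `units`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list(limits = NULL, directions = NULL, units = NULL)
  if (!is.null(cfg$limits)) out$limits <- critical_limits(cfg$limits)
  if (!is.null(cfg$directions)) out$directions <- lapply(cfg$directions, as.character)
  if (!is.null(cfg$units)) out$units <- lapply(cfg$units, as.character)
  out
}

# ---- JSON serialization of domain objects -----------------------------------
# Every domain class is encoded as {"_class": ..., "_fields": {...}} so that
# read_results(write_results(x)) reconstructs the same object.

.serializable_classes <- c(
  "indicator_series", "kinetic_fit", "indicator_kinetics", "arrhenius_fit",
  "shelf_life_model", "critical_limits", "validation_result",
  "synthetic_config", "shelfkin_report"
)

.encode_payload <- function(x) {
  if (is.null(x)) return(NULL)
  cls <- intersect(class(x), .serializable_classes)
  if (length(cls) > 0) {
    return(list(`_class` = cls[1], `_fields` = lapply(unclass(x), .encode_payload)))
  }
  if (is.data.frame(x)) {
    return(list(`_class` = "data.frame", `_fields` = lapply(as.list(x), .encode_payload)))
  }
  if (is.list(x)) return(lapply(x, .encode_payload))
  # typed wrapper for atomic vectors that plain JSON cannot represent
  # faithfully: empty vectors, scalar NA (would become null) and named vectors.
  # I() keeps jsonlite from unboxing a length-1 _values array.
  if (is.atomic(x) &&
      (length(x) == 0 || (length(x) == 1 && is.na(x)) || !is.null(names(x)))) {
    return(list(`_class` = "vector", `_type` = typeof(x),
                `_names` = if (!is.null(names(x))) as.character(names(x)),
                `_values` = I(unname(x))))
  }
  x
}

.decode_payload <- function(x) {
  if (is.list(x) && !is.null(x[["_class"]])) {
    if (identical(x[["_class"]], "vector")) {
      cast <- switch(x[["_type"]], double = as.double, integer = as.integer,
                     character = as.character, logical = as.logical, identity)
      vals <- x[["_values"]]
      out <- if (length(vals) == 0) cast(vector(x[["_type"]], 0))
             else cast(unlist(vals, use.names = FALSE))
      if (!is.null(x[["_names"]])) names(out) <- unlist(x[["_names"]])
      return(out)
    }
    fields <- lapply(x[["_fields"]], .decode_payload)
    if (identical(x[["_class"]], "data.frame")) {
      if (length(fields) == 0) return(data.frame())
      return(as.data.frame(fields, stringsAsFactors = FALSE, optional = TRUE))
    }
    return(structure(fields, class = x[["_class"]]))
  }
  if (is.list(x)) return(lapply(x, .decode_payload))
  x
}

#' Write pipeline products to disk
#'
#' JSON (default, lossless round-trip through [read_results()]) or CSV for
#' tabular products such as validation records.
#'
#' @param results a domain object (`kinetic_fit`, `arrhenius_fit`,
#'   `validation_result`, report, ...), a data frame, or a (possibly nested)
#'   list of them.
#' @param path output file; format chosen by extension (`.json` or `.csv`)
#'   unless `format` is given.
#' @param format `"json"` or `"csv"`. CSV requires a data frame (or an object
#'   with an `as.data.frame` method, e.g. a `validation_result`).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  format <- match.arg(format, c("json", "csv"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write results: directory does not exist: ", dir)
  if (format == "csv") {
    df <- as.data.frame(results)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    payload <- list(schema = "shelfkin/1", results = .encode_payload(results))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read back results written by [write_results()]
#'
#' @param path JSON file produced by [write_results()].
#' @return the reconstructed object.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(payload$schema, "shelfkin/1")) {
    stop("unrecognised results schema: ", paste(payload$schema, collapse = " "))
  }
  .decode_payload(payload$results)
}
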