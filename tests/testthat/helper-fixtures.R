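# In-code fixture builders shared across test files.

# minimal valid long-format CSV and its path (session tempdir; cleaned on exit)
write_series_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

series_df <- function(indicator = "TVB-N", temperature_c = 25,
                      time = c(0, 12, 24, 36, 48, 60), time_unit = "hours",
                      value = seq(10, by = 2, length.out = length(time))) {
  data.frame(indicator = indicator, temperature_c = temperature_c,
             time = time, time_unit = time_unit, value = value,
             stringsAsFactors = FALSE)
}

# noise-free series following exactly reaction order `order`
exact_series <- function(order, k, a0 = 10, times = 0:5, temperature_c = 25,
                         indicator = "TVB-N", direction = NULL) {
  values <- switch(as.character(order),
                   "0" = a0 + k * times,
                   "1" = a0 * exp(k * times),
                   "2" = 1 / (1 / a0 + k * times))
  indicator_series(indicator, temperature_c, times, values, direction = direction)
}

# a ready shelf-life model from published TVC Arrhenius parameters
tvc_model <- function(a0 = 0.57, limit = 6) {
  af <- arrhenius_fit(slope = -5527.722, intercept = 17.924,
                      indicator = "TVC", order = 1)
  shelf_life_model(af, a0 = a0, limit_value = limit, limit_side = "upper")
}
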