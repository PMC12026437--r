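# Independent oracles, deliberately coded without lm()/lm.fit()/cor() so the
# package's regression arithmetic is checked against a second route.

# closed-form normal equations for y = a + b x
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  det <- n * sxx - sx * sx
  slope <- (n * sxy - sx * sy) / det
  intercept <- (sxx * sy - sx * sxy) / det
  list(slope = slope, intercept = intercept)
}

# brute-force Pearson r from the definition
pearson_oracle <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# gas constant as used package-wide
R_GAS_TEST <- 8.3144

# signed Arrhenius rate, independent forward formula
arrhenius_rate_oracle <- function(ea_kj_per_mol, k0, temperature_c, rate_sign = 1) {
  rate_sign * k0 * exp(-ea_kj_per_mol * 1000 / (R_GAS_TEST * (temperature_c + 273.15)))
}
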