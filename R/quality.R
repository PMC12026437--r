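# Ancillary quality analyses around the kinetic core: titration arithmetic,
# single-factor sensory optimisation, Pearson screening of indicators, and
# acceptability assessment against critical limits.

#' Acid value from a KOH titration
#'
#' `AV = (V - V0) * c * 56.1 / m` in mg KOH per g of sample, where 56.1 g/mol
#' is the molar mass of potassium hydroxide.
#'
#' @param v_sample titrant volume consumed by the specimen (mL).
#' @param v_blank titrant volume consumed by the blank (mL).
#' @param conc titrant molarity (mol/L), > 0.
#' @param mass sample mass (g), > 0.
#' @return acid value in mg KOH/g (vectorised).
#' @export
#' @examples
#' acid_value(v_sample = 10.0, v_blank = 0.1, conc = 0.1, mass = 10)
acid_value <- function(v_sample, v_blank, conc, mass) {
  if (any(mass <= 0)) stop("sample mass must be > 0")
  if (any(conc <= 0)) stop("titrant concentration must be > 0")
  if (any(v_sample < 0) || any(v_blank < 0)) stop("titrant volumes must be >= 0")
  (v_sample - v_blank) * conc * 56.1 / mass
}

#' A single-factor sensory table
#'
#' One processing factor (e.g. salt percentage or simmering minutes) varied over
#' ordered levels, with the mean panel score at each level.
#'
#' @param factor factor name.
#' @param levels ordered numeric level values.
#' @param mean_scores mean sensory score per level (1-10 scale).
#' @param sds optional standard errors per level.
#' @return a `factor_table` data frame.
#' @export
factor_table <- function(factor, levels, mean_scores, sds = NULL) {
  stopifnot(length(levels) == length(mean_scores),
            is.null(sds) || length(sds) == length(levels))
  if (length(levels) == 0) stop("factor table must have at least one level")
  if (any(mean_scores < 1 | mean_scores > 10)) {
    stop("sensory scores must lie on the 1-10 scale")
  }
  out <- data.frame(factor = factor, level = as.numeric(levels),
                    mean_score = as.numeric(mean_scores),
                    sd = if (is.null(sds)) NA_real_ else as.numeric(sds),
                    stringsAsFactors = FALSE)
  class(out) <- c("factor_table", class(out))
  out
}

#' Pick the optimal level of a processing factor
#'
#' The level with the highest mean sensory score; exact ties go to the smaller
#' level value. Invariant under row permutation.
#'
#' @param table a [factor_table()] (or data frame with `level`, `mean_score`).
#' @return list with `level` and `score`.
#' @export
#' @examples
#' tb <- factor_table("simmering_min", c(50, 60, 70, 80, 90),
#'                    c(7.52, 8.29, 9.25, 8.28, 7.80))
#' select_optimum(tb)
select_optimum <- function(table) {
  stopifnot(is.data.frame(table), all(c("level", "mean_score") %in% names(table)))
  if (nrow(table) == 0) stop("empty factor table")
  best <- which(table$mean_score == max(table$mean_score))
  if (length(best) > 1) best <- best[which.min(table$level[best])]
  list(level = table$level[best], score = table$mean_score[best])
}

#' Pearson correlation matrix with two-sided p-values
#'
#' Pairwise Pearson r over variables sampled at common time points, with
#' p-values from the t distribution on n - 2 degrees of freedom. Variables with
#' zero variance get `NA` correlations (flagged, not fatal).
#'
#' @param aligned a data frame or matrix, one column per indicator, one row per
#'   common time point (>= 3 rows).
#' @param bonferroni if `TRUE`, p-values are Bonferroni-adjusted over the
#'   `choose(p, 2)` off-diagonal tests. Default `FALSE`, matching the usual
#'   starred-threshold presentation.
#' @return list with matrices `r` and `p` (unit diagonal / zero diagonal),
#'   `n`, and `degenerate` (names of zero-variance columns).
#' @export
#' @examples
#' pearson_matrix(data.frame(x = 1:4, y = c(1, 3, 2, 4)))
pearson_matrix <- function(aligned, bonferroni = FALSE) {
  m <- as.matrix(aligned)
  storage.mode(m) <- "double"
  n <- nrow(m)
  p_vars <- ncol(m)
  if (n < 3) stop("Pearson screening needs at least 3 common time points")
  vars <- apply(m, 2, stats::var)
  degenerate <- colnames(m)[vars == 0]
  r <- suppressWarnings(stats::cor(m))
  diag(r) <- ifelse(vars == 0, NA_real_, 1)
  # two-sided p from t = r sqrt((n-2)/(1-r^2))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  pmat <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pmat[abs(r) >= 1] <- 0
  pmat[is.na(r)] <- NA_real_
  diag(pmat) <- ifelse(vars == 0, NA_real_, 0)
  if (bonferroni) {
    ntests <- choose(p_vars, 2)
    off <- row(pmat) != col(pmat)
    pmat[off] <- pmin(1, pmat[off] * ntests)
  }
  list(r = r, p = pmat, n = n, degenerate = degenerate)
}

#' First time an indicator breaches its critical limit
#'
#' Scans the sampled series for the earliest time at which the value crosses
#' the limit on its declared side (strictly above an upper limit, strictly
#' below a lower one; the limit value itself counts as acceptable). A linear
#' interpolation between the bracketing samples is reported as a secondary,
#' finer-than-sampling estimate.
#'
#' @param series an [indicator_series()].
#' @param limits a [critical_limits()] set containing the series' indicator.
#' @return list with `status` (`"acceptable throughout"` or `"breached"`),
#'   `first_breach_time_days` (`NA` if acceptable), `interpolated_time_days`
#'   (labelled estimate, `NA` if acceptable), `limit`.
#' @export
assess_acceptability <- function(series, limits) {
  stopifnot(inherits(series, "indicator_series"))
  lim <- get_limit(limits, series$indicator)
  if (is.null(lim)) {
    stop("no critical limit configured for indicator '", series$indicator, "'")
  }
  breach <- if (lim$side == "upper") series$values > lim$value
            else series$values < lim$value
  if (!any(breach)) {
    return(list(status = "acceptable throughout",
                first_breach_time_days = NA_real_,
                interpolated_time_days = NA_real_, limit = lim))
  }
  i <- which(breach)[1]
  interp <- if (i == 1) {
    series$times_days[1]
  } else {
    t0 <- series$times_days[i - 1]; t1 <- series$times_days[i]
    v0 <- series$values[i - 1]; v1 <- series$values[i]
    t0 + (lim$value - v0) / (v1 - v0) * (t1 - t0)
  }
  list(status = "breached",
       first_breach_time_days = series$times_days[i],
       interpolated_time_days = interp, limit = lim)
}
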