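# Canonical registry of spoilage indicators.
#
# Directions are the quality-change direction during storage: TVB-N, TVC and AV
# accumulate as the product spoils; texture (springiness, hardness) and sensory
# score decline. pH dips early then rises with alkaline volatiles; it is
# registered as increasing but is not used for shelf-life prediction.
.indicator_registry <- data.frame(
  indicator = c("TVB-N", "TVC", "AV", "springiness", "hardness", "pH", "sensory"),
  direction = c("increasing", "increasing", "increasing",
                "decreasing", "decreasing", "increasing", "decreasing"),
  unit = c("mg/100 g", "log CFU/g", "mg KOH/g", "N/m2", "g", "pH", "score"),
  stringsAsFactors = FALSE
)

.normalize_token <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Normalize an indicator name against the canonical registry
#'
#' Matching is case-insensitive and ignores punctuation ("tvb-n", "TVBN" and
#' "TVB-N" are the same token). Unknown indicators are returned unchanged; they
#' are allowed everywhere provided a direction (and unit, where needed) is
#' supplied explicitly.
#'
#' @param indicator character vector of indicator names.
#' @return character vector of canonical names where recognised.
#' @export
#' @examples
#' normalize_indicator(c("tvc", "Hardness", "myoglobin"))
normalize_indicator <- function(indicator) {
  idx <- match(.normalize_token(indicator), .normalize_token(.indicator_registry$indicator))
  out <- as.character(indicator)
  out[!is.na(idx)] <- .indicator_registry$indicator[idx[!is.na(idx)]]
  out
}

indicator_is_known <- function(indicator) {
  .normalize_token(indicator) %in% .normalize_token(.indicator_registry$indicator)
}

default_direction <- function(indicator) {
  idx <- match(.normalize_token(indicator), .normalize_token(.indicator_registry$indicator))
  ifelse(is.na(idx), NA_character_, .indicator_registry$direction[idx])
}

default_unit <- function(indicator) {
  idx <- match(.normalize_token(indicator), .normalize_token(.indicator_registry$indicator))
  ifelse(is.na(idx), NA_character_, .indicator_registry$unit[idx])
}

# Registry order, used as the canonical tie-break order for overall shelf life;
# unknown indicators sort after known ones, alphabetically.
canonical_indicator_rank <- function(indicator) {
  idx <- match(.normalize_token(indicator), .normalize_token(.indicator_registry$indicator))
  rank <- ifelse(is.na(idx), nrow(.indicator_registry) + 1L, idx)
  order(order(rank, as.character(indicator)))
}

#' Default critical limits for ready-to-eat crustacean products
#'
#' The conventional acceptability limits for cooked aquatic products: TVB-N
#' 35 mg/100 g and TVC 6 log CFU/g (upper limits), acid value 5.0 mg KOH/g
#' (upper limit), and a 10-point sensory score of 5 (lower limit). Texture
#' indicators have no regulatory limit and are absent.
#'
#' @return a `critical_limits` object: named list of `list(value, side)` with
#'   `side` one of `"upper"` or `"lower"`.
#' @export
#' @examples
#' default_critical_limits()
default_critical_limits <- function() {
  critical_limits(list(
    "TVB-N"   = list(value = 35,  side = "upper"),
    "TVC"     = list(value = 6,   side = "upper"),
    "AV"      = list(value = 5.0, side = "upper"),
    "sensory" = list(value = 5,   side = "lower")
  ))
}

#' Construct a set of critical limits
#'
#' @param limits named list mapping indicator name to `list(value, side)`;
#'   `side` must be `"upper"` (spoilage accumulates toward the limit) or
#'   `"lower"` (quality decays down to the limit).
#' @return a `critical_limits` object (named list, names canonicalised).
#' @export
critical_limits <- function(limits) {
  stopifnot(is.list(limits), length(names(limits)) == length(limits))
  out <- lapply(limits, function(l) {
    if (!is.list(l) || is.null(l$value) || is.null(l$side)) {
      stop("each limit must be list(value =, side =)")
    }
    if (!is.finite(l$value)) stop("critical limit value must be finite")
    l$side <- match.arg(l$side, c("upper", "lower"))
    list(value = as.numeric(l$value), side = l$side)
  })
  names(out) <- normalize_indicator(names(limits))
  structure(out, class = "critical_limits")
}

get_limit <- function(limits, indicator) {
  if (is.null(limits)) return(NULL)
  limits[[normalize_indicator(indicator)]]
}
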