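# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## The six serum markers, in canonical column order.
MARKERS <- c("abeta_ratio", "ptau181", "ptau217", "ttau", "nfl", "gfap")

## Covariate columns every association model adjusts for.
DISEASES <- c("hypertension", "ihd", "heart_failure", "atrial_fib",
              "cerebrovascular", "ckd", "anaemia", "obesity")

REQUIRED_COLS <- c("id", "age", "sex", "education", DISEASES,
                   "n_chronic_diseases", "mmse", "memory_complaints",
                   "apoe_e4", MARKERS, "followup_years", "event", "dropout")

EVENT_LEVELS <- c("none", "ad_dementia", "other_dementia", "death")

## Percentile convention used everywhere (quartiles, spline knots):
## linear interpolation between order statistics (stats::quantile type 7).
pctl <- function(x, probs) {
  stats::quantile(x, probs = probs, na.rm = TRUE, names = FALSE, type = 7)
}

## Percentage on a non-missing denominator, rounded as printed in
## descriptive tables (one decimal).
pct <- function(count, denominator, digits = 1) {
  stopifnot(denominator > 0, count >= 0, count <= denominator)
  round(100 * count / denominator, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_in <- function(x, choices, what = deparse(substitute(x))) {
  if (!all(x %in% choices)) {
    stop(sprintf("%s must be one of: %s", what, paste(choices, collapse = ", ")),
         call. = FALSE)
  }
  x
}
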