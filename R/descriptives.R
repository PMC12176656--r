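## Baseline-characteristics tables, group comparisons, incidence rates.

#' Baseline characteristics by group
#'
#' One row per variable: mean +/- sd with a Welch t-test for continuous
#' variables, n (\%) with a chi-square test for categorical ones, and
#' median (IQR) with a two-sided Mann-Whitney test for the biomarkers
#' (whose skewed distributions make rank tests the convention).
#' Percentages use non-missing denominators; missing counts are reported.
#'
#' @param table cohort data.frame.
#' @param group_col name of a binary/categorical grouping column (e.g. an
#'   incident-dementia indicator).
#' @param variables columns to summarize; defaults to the standard baseline
#'   set plus the six biomarkers.
#' @return data.frame: one row per variable x group plus a `p` column
#'   (repeated within variable) and the missing count.
#' @export
summarize_by_group <- function(table, group_col,
                               variables = c("age", "sex", "education",
                                             "n_chronic_diseases", DISEASES,
                                             "mmse", "memory_complaints",
                                             "apoe_e4", MARKERS)) {
  g <- table[[group_col]]
  if (is.null(g)) stop("unknown group column: ", group_col, call. = FALSE)
  g <- factor(g)
  if (any(table(g) == 0)) stop("empty group in ", group_col, call. = FALSE)
  rows <- list()
  for (v in variables) {
    x <- table[[v]]
    n_missing <- sum(is.na(x))
    ok <- !is.na(x)
    if (v %in% MARKERS) {
      p <- if (nlevels(g) == 1) {
        NA_real_
      } else if (nlevels(g) == 2) {
        mann_whitney(x[ok & g == levels(g)[1]], x[ok & g == levels(g)[2]])$p.value
      } else {
        stats::kruskal.test(x[ok], g[ok])$p.value
      }
      for (lev in levels(g)) {
        xi <- x[ok & g == lev]
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, group = lev, level = NA_character_,
          n = length(xi), denominator = NA_integer_,
          summary = sprintf("%.3g (%.3g-%.3g)", stats::median(xi),
                            pctl(xi, 0.25), pctl(xi, 0.75)),
          percent = NA_real_, p = p, n_missing = n_missing)
      }
    } else if (is.numeric(x)) {
      p <- if (nlevels(g) == 1) {
        NA_real_
      } else if (nlevels(g) == 2) {
        stats::t.test(x[ok] ~ g[ok])$p.value
      } else {
        stats::oneway.test(x[ok] ~ g[ok])$p.value
      }
      for (lev in levels(g)) {
        xi <- x[ok & g == lev]
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, group = lev, level = NA_character_,
          n = length(xi), denominator = NA_integer_,
          summary = sprintf("%.1f ± %.1f", mean(xi), stats::sd(xi)),
          percent = NA_real_, p = p, n_missing = n_missing)
      }
    } else {
      f <- factor(x[ok])
      p <- if (nlevels(g) == 1) NA_real_ else tryCatch(
        stats::chisq.test(base::table(f, droplevels(g[ok])))$p.value,
        warning = function(w) suppressWarnings(
          stats::chisq.test(base::table(f, droplevels(g[ok])))$p.value))
      for (lev in levels(g)) {
        denom <- sum(ok & g == lev)
        for (cat in levels(f)) {
          cnt <- sum(f[g[ok] == lev] == cat)
          rows[[length(rows) + 1L]] <- data.frame(
            variable = v, group = lev, level = cat,
            n = cnt, denominator = denom,
            summary = sprintf("%d (%.1f)", cnt, pct(cnt, denom)),
            percent = pct(cnt, denom), p = p, n_missing = n_missing)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact enumeration for small tie-free samples, tie-corrected normal
#' approximation otherwise (the [stats::wilcox.test()] conventions).
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `statistic` (U, for `x` vs `y`) and `p.value`.
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided",
    exact = (length(x) <= 20 && length(y) <= 20), correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = min(1, wt$p.value))
}

#' Incidence rate per 100 person-years with exact Poisson CI
#'
#' The 95\% interval treats the event count as Poisson and inverts the
#' chi-square relation: lower = `qchisq(.025, 2k)/2`, upper =
#' `qchisq(.975, 2k+2)/2`, both scaled by person-years.
#'
#' @param events event count (>= 0).
#' @param person_years person-years at risk (> 0).
#' @param conf confidence level (default 0.95).
#' @return object of class `incidence_result`: `events`, `person_years`,
#'   `rate`, `ci_low`, `ci_high` (all rates per 100 person-years).
#' @export
incidence_rate <- function(events, person_years, conf = 0.95) {
  stopifnot(events >= 0, person_years > 0)
  a <- (1 - conf) / 2
  lo <- if (events == 0) 0 else stats::qchisq(a, 2 * events) / 2
  hi <- stats::qchisq(1 - a, 2 * events + 2) / 2
  structure(list(events = events, person_years = person_years,
                 rate = 100 * events / person_years,
                 ci_low = 100 * lo / person_years,
                 ci_high = 100 * hi / person_years),
            class = "incidence_result")
}

#' @export
print.incidence_result <- function(x, ...) {
  cat(sprintf("%d events / %.1f person-years: %.2f (%.2f-%.2f) per 100 py\n",
              x$events, x$person_years, x$rate, x$ci_low, x$ci_high))
  invisible(x)
}

#' Incidence of a dementia outcome in a cohort
#'
#' Person-years are the sum of observed follow-up; events are all-cause
#' dementia (AD + other) or AD dementia only.
#'
#' @param table cohort data.frame.
#' @param outcome `"all_cause"` or `"ad"`.
#' @return an [incidence_rate()] result.
#' @export
cohort_incidence <- function(table, outcome = c("all_cause", "ad")) {
  outcome <- match.arg(outcome)
  ev <- if (outcome == "all_cause") {
    table$event %in% c("ad_dementia", "other_dementia")
  } else {
    table$event == "ad_dementia"
  }
  incidence_rate(sum(ev), sum(table$followup_years))
}
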