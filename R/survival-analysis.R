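## Proportional-hazards association stage: restricted cubic splines,
## adjusted quartile hazard ratios with trend tests, Schoenfeld diagnostics,
## cause-specific censoring for the AD outcome, IPW sensitivity analysis.

#' The standard adjustment covariate set
#'
#' Age; sex; education (indicator-coded, elementary as reference); the eight
#' chronic-disease flags; and APOE e4 carrier status.
#' @return character vector of column names.
#' @export
adjustment_covariates <- function() {
  c("age", "sex", "education", DISEASES, "apoe_e4")
}

#' Restricted cubic spline basis with three knots
#'
#' Knots at the 25th/50th/75th percentiles of the observed distribution
#' (linear interpolation between order statistics). With knots
#' `t1 < t2 < t3` the basis is the linear term plus one restricted cubic
#' term
#' `[(x-t1)+^3 - (x-t2)+^3 (t3-t1)/(t3-t2) + (x-t3)+^3 (t2-t1)/(t3-t2)] / (t3-t1)^2`,
#' which is linear outside the boundary knots with continuous first and
#' second derivatives at the knots.
#'
#' @param x numeric vector (at least 10 distinct values when knots are
#'   estimated).
#' @param percentiles knot placement percentiles (default 25/50/75).
#' @param knots optional: explicit knot values (overrides `percentiles`).
#' @return object of class `rcs_basis`: `knots`, `basis` (n x 2 matrix with
#'   columns `lin`, `cub`), and `fun(newx)` evaluating the basis anywhere.
#' @export
rcs_basis <- function(x, percentiles = c(25, 50, 75), knots = NULL) {
  if (is.null(knots)) {
    if (length(unique(stats::na.omit(x))) < 10) {
      stop("need at least 10 distinct values to place spline knots", call. = FALSE)
    }
    knots <- pctl(x, percentiles / 100)
  }
  if (anyDuplicated(knots) || length(knots) != 3) {
    stop("spline knots must be 3 distinct values", call. = FALSE)
  }
  t1 <- knots[1]; t2 <- knots[2]; t3 <- knots[3]
  fun <- function(newx) {
    pp <- function(u) pmax(u, 0)^3
    cub <- (pp(newx - t1) - pp(newx - t2) * (t3 - t1) / (t3 - t2) +
              pp(newx - t3) * (t2 - t1) / (t3 - t2)) / (t3 - t1)^2
    cbind(lin = newx, cub = cub)
  }
  structure(list(knots = knots, basis = fun(x), fun = fun),
            class = "rcs_basis")
}

## Event indicator under the outcome definition; for the AD outcome,
## other dementias and deaths are censored at their event times, so the
## at-risk person-time is identical to the all-cause analysis.
outcome_status <- function(event, outcome = c("all_cause", "ad")) {
  outcome <- match.arg(outcome)
  if (outcome == "all_cause") {
    as.integer(event %in% c("ad_dementia", "other_dementia"))
  } else {
    as.integer(event == "ad_dementia")
  }
}

#' Fit a Cox proportional-hazards model
#'
#' Partial-likelihood maximization via [survival::coxph()] with Efron tie
#' handling by default. `outcome = "ad"` applies cause-specific censoring:
#' other dementias and deaths without dementia are censored at their times.
#'
#' @param frame analysis data.frame (needs `followup_years` and `event`).
#' @param terms character vector of model terms for the exposure of interest
#'   (column names or expressions valid in a formula).
#' @param outcome `"all_cause"` or `"ad"`.
#' @param covariates adjustment covariates (default
#'   [adjustment_covariates()]; use `character(0)` for an unadjusted fit).
#' @param weights optional per-row case weights (e.g. from
#'   [ipw_dropout_weights()]); rows with missing weight are dropped.
#' @param tie_method `"efron"` (default) or `"breslow"`.
#' @return object of class `hazard_fit`: `coefficients`, `vcov`, `n`,
#'   `events`, `tie_method`, `weights_used`, `schoenfeld_p`, and the
#'   underlying `coxph` fit in `$model`.
#' @export
fit_cox <- function(frame, terms, outcome = c("all_cause", "ad"),
                    covariates = adjustment_covariates(), weights = NULL,
                    tie_method = c("efron", "breslow")) {
  outcome <- match.arg(outcome)
  tie_method <- match.arg(tie_method)
  frame$.status <- outcome_status(frame$event, outcome)
  if (sum(frame$.status) < 1) stop("no events under this outcome", call. = FALSE)
  rhs <- paste(c(terms, covariates), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(followup_years, .status) ~", rhs))
  if (!is.null(weights)) {
    frame$.w <- weights
    frame <- frame[!is.na(frame$.w), , drop = FALSE]
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = frame,
                    weights = if (is.null(weights)) NULL else frame$.w,
                    ties = tie_method, x = TRUE),
    warning = function(w) {
      if (grepl("infinite", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep_warn || any(!is.finite(stats::coef(fit)))) {
    stop("monotone likelihood (complete separation) in Cox fit", call. = FALSE)
  }
  zph <- tryCatch({
    z <- survival::cox.zph(fit, transform = "identity")
    tab <- z$table[rownames(z$table) != "GLOBAL", , drop = FALSE]
    stats::setNames(tab[, "p"], rownames(tab))
  }, error = function(e) {
    stats::setNames(rep(NA_real_, length(terms) + length(covariates)),
                    c(terms, covariates))
  })
  structure(list(coefficients = stats::coef(fit), vcov = stats::vcov(fit),
                 n = fit$n, events = fit$nevent, tie_method = tie_method,
                 weights_used = !is.null(weights), schoenfeld_p = zph,
                 outcome = outcome, model = fit),
            class = "hazard_fit")
}

#' @export
print.hazard_fit <- function(x, ...) {
  cat(sprintf("<hazard_fit> outcome=%s n=%d events=%d ties=%s%s\n",
              x$outcome, x$n, x$events, x$tie_method,
              if (x$weights_used) " (weighted)" else ""))
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(coef = x$coefficients,
                    HR = exp(x$coefficients),
                    ci_low = exp(x$coefficients - 1.96 * se),
                    ci_high = exp(x$coefficients + 1.96 * se))
  print(round(tab, 3))
  invisible(x)
}

#' Proportional-hazards diagnostic from scaled Schoenfeld residuals
#'
#' Per-covariate score test of zero slope when scaled Schoenfeld residuals
#' are regressed against survival time (identity time transform). Undefined
#' (e.g. too few events) diagnostics are reported as `NA`.
#'
#' @param fit a [fit_cox()] result.
#' @return named vector of per-covariate p-values.
#' @export
schoenfeld_check <- function(fit) {
  stopifnot(inherits(fit, "hazard_fit"))
  fit$schoenfeld_p
}

#' Adjusted hazard ratios by biomarker quartile with a trend test
#'
#' One Cox model per biomarker with three quartile indicators (reference per
#' the marker's risk direction: Q1, or Q4 for the amyloid ratio) plus the
#' standard covariates. The trend p-value refits the model with the quartile
#' index as a single ordinal score (1 at the reference, 4 at the
#' highest-risk quartile) and Wald-tests its coefficient. Per-quartile
#' incidence rates accompany the HRs.
#'
#' @param frame analysis frame from [build_analysis_frame()].
#' @param biomarker marker name (a `<marker>_q` column must exist).
#' @param outcome `"all_cause"` or `"ad"`.
#' @inheritParams fit_cox
#' @return data.frame (class `quartile_hr_table`) with one row per quartile
#'   in reference-first order: `quartile`, `n`, `events`, `ir`, `ir_low`,
#'   `ir_high`, `hr`, `ci_low`, `ci_high`, `reference`; the trend p-value is
#'   in column `p_trend` and attribute `"p_trend"`.
#' @export
quartile_hr_table <- function(frame, biomarker, outcome = c("all_cause", "ad"),
                              covariates = adjustment_covariates(),
                              weights = NULL) {
  outcome <- match.arg(outcome)
  qcol <- paste0(biomarker, "_q")
  if (is.null(frame[[qcol]])) stop("no quartile column for ", biomarker, call. = FALSE)
  q <- frame[[qcol]]
  ref <- attr(q, "reference") %||% "Q1"
  if (any(table(q) == 0)) stop("empty quartile for ", biomarker, call. = FALSE)
  order_levels <- if (ref == "Q4") paste0("Q", 4:1) else paste0("Q", 1:4)
  frame$.q <- factor(q, levels = order_levels)  # reference first
  fit <- fit_cox(frame, ".q", outcome, covariates, weights)
  frame$.score <- as.integer(frame$.q)          # 1 = reference .. 4 = top risk
  tfit <- fit_cox(frame, ".score", outcome, covariates, weights)
  b <- tfit$coefficients[".score"]
  p_trend <- 2 * stats::pnorm(-abs(b / sqrt(tfit$vcov[".score", ".score"])))
  status <- outcome_status(frame$event, outcome)
  rows <- lapply(order_levels, function(lev) {
    sel <- frame$.q == lev
    ir <- incidence_rate(sum(status[sel]), sum(frame$followup_years[sel]))
    nm <- paste0(".q", lev)
    if (lev == order_levels[1]) {
      data.frame(quartile = lev, n = sum(sel), events = ir$events,
                 ir = ir$rate, ir_low = ir$ci_low, ir_high = ir$ci_high,
                 hr = 1, ci_low = NA_real_, ci_high = NA_real_,
                 reference = TRUE)
    } else {
      co <- fit$coefficients[nm]
      se <- sqrt(fit$vcov[nm, nm])
      data.frame(quartile = lev, n = sum(sel), events = ir$events,
                 ir = ir$rate, ir_low = ir$ci_low, ir_high = ir$ci_high,
                 hr = exp(co), ci_low = exp(co - 1.96 * se),
                 ci_high = exp(co + 1.96 * se), reference = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_trend <- unname(p_trend)
  structure(out, p_trend = unname(p_trend), biomarker = biomarker,
            outcome = outcome, class = c("quartile_hr_table", "data.frame"))
}

#' Hazard-ratio curve from a spline Cox fit
#'
#' `HR(x) = exp(eta(x) - eta(ref))` where `eta` is the spline part of the
#' linear predictor; pointwise 95\% CI by the delta method on the contrast.
#' The curve is exactly 1 (zero-width interval) at the reference value.
#'
#' @param fit a [fit_cox()] result whose first two terms are the columns of
#'   `basis` (names given in `term_names`).
#' @param basis the [rcs_basis()] used in the fit.
#' @param reference_value marker value where HR = 1 (default: the first
#'   knot, i.e. the 25th percentile).
#' @param x grid of marker values for the curve.
#' @param term_names names of the spline coefficients in the fit.
#' @return data.frame `x`, `hr`, `ci_low`, `ci_high`, `extrapolated` (beyond
#'   the fitted data range).
#' @export
spline_hr_curve <- function(fit, basis, reference_value = basis$knots[1],
                            x = NULL,
                            term_names = c("lin", "cub")) {
  stopifnot(inherits(fit, "hazard_fit"), inherits(basis, "rcs_basis"))
  rng <- range(basis$basis[, "lin"])
  if (is.null(x)) x <- seq(rng[1], rng[2], length.out = 100)
  B <- basis$fun(x)
  Bref <- basis$fun(reference_value)
  C <- sweep(B, 2, Bref)  # contrast vs the reference value
  beta <- fit$coefficients[term_names]
  V <- fit$vcov[term_names, term_names]
  eta <- drop(C %*% beta)
  se <- sqrt(pmax(rowSums((C %*% V) * C), 0))
  data.frame(x = x, hr = exp(eta),
             ci_low = exp(eta - 1.96 * se), ci_high = exp(eta + 1.96 * se),
             extrapolated = x < rng[1] | x > rng[2])
}

#' Spline dose-response Cox fit for one biomarker
#'
#' Convenience wrapper: builds the 3-knot restricted cubic basis on the raw
#' marker, fits the adjusted Cox model with both spline terms, and returns
#' fit, basis and the [spline_hr_curve()].
#'
#' @inheritParams quartile_hr_table
#' @param reference_value where HR = 1 on the curve (default: first knot,
#'   the marker's 25th percentile).
#' @return list with `fit`, `basis`, `curve`.
#' @export
fit_spline_cox <- function(frame, biomarker, outcome = c("all_cause", "ad"),
                           covariates = adjustment_covariates(),
                           weights = NULL, reference_value = NULL) {
  outcome <- match.arg(outcome)
  basis <- rcs_basis(frame[[biomarker]])
  frame$lin <- basis$basis[, "lin"]
  frame$cub <- basis$basis[, "cub"]
  fit <- fit_cox(frame, c("lin", "cub"), outcome, covariates, weights)
  curve <- spline_hr_curve(fit, basis,
                           reference_value %||% basis$knots[1])
  list(fit = fit, basis = basis, curve = curve)
}

#' Stabilized inverse-probability-of-dropout weights
#'
#' Logistic model for retention (not dropping out) on age, sex, education,
#' chronic-disease count and the six baseline biomarker levels. Retained
#' participants receive the stabilized weight
#' `P(retained) / P(retained | covariates)`; dropped participants get `NA`
#' (they contribute no follow-up). Fitted probabilities are truncated at
#' configurable percentiles to bound the weights.
#'
#' @param frame cohort data.frame with a logical `dropout` column.
#' @param truncate_pct lower/upper truncation percentiles for the fitted
#'   retention probabilities (default 1st/99th).
#' @return numeric weight per row (`NA` for dropouts), with attributes
#'   `"model"` (the glm) and `"n_truncated"`.
#' @export
ipw_dropout_weights <- function(frame, truncate_pct = c(0.01, 0.99)) {
  if (is.null(frame$dropout)) stop("dropout flag column required", call. = FALSE)
  frame$.retained <- as.integer(!frame$dropout)
  if (all(frame$.retained == 1)) {
    w <- rep(1, nrow(frame))
    return(structure(w, model = NULL, n_truncated = 0L))
  }
  rhs <- paste(c("age", "sex", "education", "n_chronic_diseases", MARKERS),
               collapse = " + ")
  gfit <- stats::glm(stats::as.formula(paste(".retained ~", rhs)),
                     data = frame, family = stats::binomial())
  p <- stats::predict(gfit, newdata = frame, type = "response")
  lims <- pctl(p, truncate_pct)
  n_trunc <- sum(p < lims[1] | p > lims[2], na.rm = TRUE)
  p <- pmin(pmax(p, lims[1]), lims[2])
  w <- mean(frame$.retained) / p
  w[frame$.retained == 0] <- NA_real_
  structure(w, model = gfit, n_truncated = n_trunc)
}
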