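## 10-year horizon labelling, confusion metrics with bootstrap CIs, rank AUC
## with DeLong intervals, biomarker-combination predictors.

#' Binary outcome labels at a fixed prediction horizon
#'
#' Converts censored time-to-event follow-up into a binary classification
#' target: positive = qualifying event at or before the horizon; negative =
#' event-free with follow-up reaching the horizon. Participants whose
#' follow-up ends before the horizon without a qualifying event (death,
#' other dementia under the AD outcome, withdrawal, or administrative
#' censoring) are excluded by default, with reasons recorded — their
#' horizon status is unobserved. `censored_as_negative = TRUE` switches to
#' the alternative convention of counting them as negatives.
#'
#' @param frame cohort data.frame.
#' @param horizon years (> 0), default 10.
#' @param outcome `"all_cause"` or `"ad"`.
#' @param censored_as_negative count unobserved non-cases as negative?
#' @return data.frame `id`, `label` (1/0/NA), `excluded`, `reason`.
#' @export
horizon_labels <- function(frame, horizon = 10, outcome = c("all_cause", "ad"),
                           censored_as_negative = FALSE) {
  outcome <- match.arg(outcome)
  if (horizon <= 0) stop("horizon must be positive", call. = FALSE)
  qualifying <- if (outcome == "all_cause") {
    frame$event %in% c("ad_dementia", "other_dementia")
  } else {
    frame$event == "ad_dementia"
  }
  t <- frame$followup_years
  pos <- qualifying & t <= horizon
  neg <- !pos & t >= horizon
  excluded <- !pos & !neg
  reason <- rep(NA_character_, nrow(frame))
  reason[excluded & frame$event == "death"] <- "death before horizon"
  reason[excluded & frame$event == "other_dementia"] <- "other dementia before horizon"
  reason[excluded & frame$event == "none"] <- "censored before horizon"
  label <- ifelse(pos, 1L, ifelse(neg, 0L, NA_integer_))
  if (censored_as_negative) {
    label[excluded] <- 0L
    excluded <- excluded & FALSE
  }
  data.frame(id = frame$id, label = label, excluded = excluded,
             reason = reason, stringsAsFactors = FALSE)
}

#' Confusion-matrix performance with bootstrap percentile CIs
#'
#' Sensitivity, specificity, PPV, NPV and accuracy (all in percent) with
#' 95\% percentile-bootstrap intervals over participants. Metrics with a
#' zero denominator are reported as `NA`, not 0.
#'
#' @param labels binary truth (0/1); both classes must be present.
#' @param predictions logical/binary test results.
#' @param ci_reps bootstrap replicates (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame with rows accuracy, sensitivity, specificity, ppv,
#'   npv: `value`, `ci_low`, `ci_high` (percent); attribute `"counts"`
#'   holds TP/FP/FN/TN.
#' @export
confusion_metrics <- function(labels, predictions, ci_reps = 2000, seed = 1L) {
  labels <- as.integer(labels)
  predictions <- as.integer(as.logical(predictions))
  ok <- !is.na(labels) & !is.na(predictions)
  labels <- labels[ok]; predictions <- predictions[ok]
  if (length(unique(labels)) < 2) stop("both classes required", call. = FALSE)
  point <- confusion_point(labels, predictions)
  boot <- with_seed(seed, {
    n <- length(labels)
    vapply(seq_len(ci_reps), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      confusion_point(labels[i], predictions[i])
    }, numeric(5))
  })
  ci <- apply(boot, 1, function(v) pctl(v, c(0.025, 0.975)))
  out <- data.frame(metric = names(point),
                    value = 100 * unname(point),
                    ci_low = 100 * ci[1, ], ci_high = 100 * ci[2, ],
                    row.names = NULL)
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == 0 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  tn <- sum(labels == 0 & predictions == 0)
  structure(out, counts = c(tp = tp, fp = fp, fn = fn, tn = tn))
}

confusion_point <- function(labels, predictions) {
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == 0 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  tn <- sum(labels == 0 & predictions == 0)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  c(accuracy = div(tp + tn, tp + fp + fn + tn),
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    ppv = div(tp, tp + fp),
    npv = div(tn, tn + fn))
}

#' Rank (Mann-Whitney) AUC with a DeLong or bootstrap interval
#'
#' `AUC = P(score_pos > score_neg) + 0.5 P(equal)` over all positive-negative
#' pairs. The default 95\% CI uses the DeLong placement variance; a
#' participant bootstrap is available. For markers whose *low* values carry
#' risk, negate the scores first.
#'
#' @param scores numeric predictor values (higher = more at risk).
#' @param labels binary truth (0/1).
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param ci_reps bootstrap replicates when `ci_method = "bootstrap"`.
#' @param seed bootstrap seed.
#' @return list `auc`, `ci_low`, `ci_high`, `se`, `ci_method`
#'   (AUC on the 0-1 scale).
#' @export
auc_rank <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                     ci_reps = 2000, seed = 1L) {
  ci_method <- match.arg(ci_method)
  labels <- as.integer(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0) stop("both classes required", call. = FALSE)
  ys <- sort(y)
  ## placement of each positive among negatives: P(Y < x) + .5 P(Y = x)
  v10 <- (findInterval(x, ys, left.open = TRUE) +
            findInterval(x, ys)) / (2 * n)
  xs <- sort(x)
  v01 <- 1 - (findInterval(y, xs, left.open = TRUE) +
                findInterval(y, xs)) / (2 * m)
  auc <- mean(v10)
  if (ci_method == "delong") {
    se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
    if (!is.finite(se)) se <- 0
    ci <- pmin(1, pmax(0, auc + c(-1, 1) * 1.96 * se))
  } else {
    boot <- with_seed(seed, {
      N <- length(scores)
      vapply(seq_len(ci_reps), function(b) {
        repeat {
          i <- sample.int(N, N, replace = TRUE)
          if (length(unique(labels[i])) == 2) break
        }
        auc_point(scores[i], labels[i])
      }, numeric(1))
    })
    se <- stats::sd(boot)
    ci <- pctl(boot, c(0.025, 0.975))
  }
  list(auc = auc, ci_low = ci[1], ci_high = ci[2], se = se,
       ci_method = ci_method)
}

auc_point <- function(scores, labels) {
  x <- scores[labels == 1]; y <- sort(scores[labels == 0])
  mean((findInterval(x, y, left.open = TRUE) + findInterval(x, y)) / (2 * length(y)))
}

#' Combine per-marker elevation flags into a predictor
#'
#' @param flags data.frame/matrix of logical elevation flags (columns =
#'   markers, e.g. p-tau217, NfL, GFAP from [apply_cutoff()]).
#' @param rule `"count"` (ordinal number of elevated markers),
#'   `"at_least_k"`, `"exactly_k"`, or `"pair_and"` (both named markers
#'   elevated).
#' @param k threshold for the `*_k` rules.
#' @param pair two column names for `"pair_and"`.
#' @return numeric scores (`count`) or logical predictions (other rules).
#' @export
combine_elevated <- function(flags, rule = c("count", "at_least_k",
                                             "exactly_k", "pair_and"),
                             k = 1, pair = c("ptau217", "nfl")) {
  rule <- match.arg(rule)
  flags <- as.data.frame(flags)
  counts <- rowSums(flags)
  switch(rule,
    count = counts,
    at_least_k = counts >= k,
    exactly_k = counts == k,
    pair_and = {
      if (!all(pair %in% names(flags))) {
        stop("pair markers not among flag columns", call. = FALSE)
      }
      flags[[pair[1]]] & flags[[pair[2]]]
    })
}
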