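## Table-3-style evaluation: horizon AUC + at-cut-off confusion metrics for
## single markers and elevation combinations, on train and test splits.

#' Evaluate single-marker and combination predictors at a horizon
#'
#' For every biomarker with a cut-off: the continuous rank AUC (scores
#' negated for the amyloid ratio, whose low values carry risk) and the full
#' confusion-metric panel at the frozen cut-off. For the p-tau217 / NfL /
#' GFAP elevation flags: the ordinal count predictor (AUC), the
#' one/two/three-elevated rules and the three pairwise AND rules. Reports
#' are produced separately for the training and test split (cut-offs must
#' have been derived on the training split only).
#'
#' @param frame analysis cohort.
#' @param cutoffs named numeric vector of per-marker cut-offs (any subset of
#'   the six markers).
#' @param horizon prediction horizon in years (default 10).
#' @param outcome `"all_cause"` or `"ad"`.
#' @param split optional list with `train`/`test` id vectors
#'   ([split_train_test()]); omitted = single dataset `"all"`.
#' @param subgroup optional [analysis_filters()] name applied first (e.g.
#'   `"memory_complaints"`).
#' @param combo_markers markers whose elevation flags are combined.
#' @param censored_as_negative passed to [horizon_labels()].
#' @param ci_reps,seed bootstrap settings for the confusion-metric CIs.
#' @param specs biomarker directions ([biomarker_specs()]).
#' @return data.frame of class `prediction_report`, one row per dataset x
#'   predictor: AUC and confusion metrics (percent) with CIs, counts of
#'   classified/excluded participants, horizon, cut-off used.
#' @export
evaluate_pipeline <- function(frame, cutoffs, horizon = 10,
                              outcome = c("all_cause", "ad"), split = NULL,
                              subgroup = NULL,
                              combo_markers = c("ptau217", "nfl", "gfap"),
                              censored_as_negative = FALSE,
                              ci_reps = 2000, seed = 1L,
                              specs = biomarker_specs()) {
  outcome <- match.arg(outcome)
  if (!is.null(subgroup)) frame <- analysis_filters(frame, subgroup)
  datasets <- if (is.null(split)) {
    list(all = frame)
  } else {
    list(train = frame[frame$id %in% split$train, , drop = FALSE],
         test = frame[frame$id %in% split$test, , drop = FALSE])
  }
  rows <- list()
  for (ds_name in names(datasets)) {
    ds <- datasets[[ds_name]]
    hl <- horizon_labels(ds, horizon, outcome, censored_as_negative)
    keep <- !is.na(hl$label)
    if (!any(keep) || length(unique(hl$label[keep])) < 2) {
      stop("classifiable set in '", ds_name,
           "' does not contain both classes", call. = FALSE)
    }
    lab <- hl$label[keep]
    sub <- ds[keep, , drop = FALSE]
    n_excl <- sum(hl$excluded)
    add_row <- function(predictor, kind, auc, cm, cutoff = NA_real_) {
      g <- function(metric, col) {
        v <- cm[cm$metric == metric, col]
        if (length(v)) v else NA_real_
      }
      rows[[length(rows) + 1L]] <<- data.frame(
        dataset = ds_name, predictor = predictor, kind = kind,
        horizon = horizon, outcome = outcome, cutoff = cutoff,
        n_classified = length(lab), n_positive = sum(lab), n_excluded = n_excl,
        auc = 100 * auc$auc, auc_low = 100 * auc$ci_low,
        auc_high = 100 * auc$ci_high,
        accuracy = g("accuracy", "value"),
        accuracy_low = g("accuracy", "ci_low"),
        accuracy_high = g("accuracy", "ci_high"),
        sensitivity = g("sensitivity", "value"),
        sensitivity_low = g("sensitivity", "ci_low"),
        sensitivity_high = g("sensitivity", "ci_high"),
        specificity = g("specificity", "value"),
        specificity_low = g("specificity", "ci_low"),
        specificity_high = g("specificity", "ci_high"),
        ppv = g("ppv", "value"), ppv_low = g("ppv", "ci_low"),
        ppv_high = g("ppv", "ci_high"),
        npv = g("npv", "value"), npv_low = g("npv", "ci_low"),
        npv_high = g("npv", "ci_high"))
    }
    flags <- list()
    for (m in intersect(specs$name, names(cutoffs))) {
      dir <- specs$direction[specs$name == m]
      score <- if (dir == "low_is_risk") -sub[[m]] else sub[[m]]
      auc <- auc_rank(score, lab)
      pred <- apply_cutoff(sub[[m]], cutoffs[[m]], dir)
      cm <- confusion_metrics(lab, pred, ci_reps = ci_reps, seed = seed)
      add_row(m, "single", auc, cm, cutoff = cutoffs[[m]])
      flags[[m]] <- pred
    }
    if (all(combo_markers %in% names(flags))) {
      fl <- as.data.frame(flags)[combo_markers]
      counts <- combine_elevated(fl, "count")
      add_row("elevated_count", "combination", auc_rank(counts, lab),
              confusion_metrics(lab, counts >= 1, ci_reps = ci_reps,
                                seed = seed))
      for (k in seq_along(combo_markers)) {
        pred <- combine_elevated(fl, "at_least_k", k = k)
        add_row(paste0("at_least_", k, "_elevated"), "combination",
                auc_rank(as.integer(pred), lab),
                confusion_metrics(lab, pred, ci_reps = ci_reps, seed = seed))
      }
      pairs <- utils::combn(combo_markers, 2, simplify = FALSE)
      for (pr in pairs) {
        pred <- combine_elevated(fl, "pair_and", pair = pr)
        add_row(paste(pr, collapse = "_and_"), "combination",
                auc_rank(as.integer(pred), lab),
                confusion_metrics(lab, pred, ci_reps = ci_reps, seed = seed))
      }
    }
  }
  structure(do.call(rbind, rows),
            class = c("prediction_report", "data.frame"))
}

#' @export
print.prediction_report <- function(x, digits = 1, ...) {
  cols <- c("dataset", "predictor", "auc", "accuracy", "sensitivity",
            "specificity", "ppv", "npv")
  df <- as.data.frame(x)[cols]
  df[-(1:2)] <- lapply(df[-(1:2)], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
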