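## Bootstrap Youden-index cut-point estimation with internal 80/20 validation.

#' Deterministic 80/20 train/test split
#'
#' Disjoint, exhaustive partition; the training set holds
#' `floor(ratio * n)` ids (documented rounding rule).
#'
#' @param frame data.frame with an `id` column (n >= 10).
#' @param ratio training fraction (default 0.8).
#' @param seed RNG seed.
#' @return list with `train` and `test` id vectors.
#' @export
split_train_test <- function(frame, ratio = 0.8, seed = 1L) {
  n <- nrow(frame)
  if (n < 10) stop("need at least 10 participants to split", call. = FALSE)
  n_train <- floor(ratio * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = frame$id[sort(idx)], test = frame$id[sort(setdiff(seq_len(n), idx))])
}

#' Youden's index
#'
#' `J = sensitivity + specificity - 1`.
#' @param sensitivity,specificity values in `[0, 1]`.
#' @return J.
#' @export
youden <- function(sensitivity, specificity) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1))
  sensitivity + specificity - 1
}

#' Single best Youden cut point over all observed candidate values
#'
#' Candidates are the unique observed marker values. A participant tests
#' positive when the value is `>=` the candidate (`<=` for `low_is_risk`
#' markers). Returns the candidate maximizing J; ties in J return the mean
#' of the tied candidates.
#'
#' @param marker numeric marker values.
#' @param labels binary outcome (0/1 or logical).
#' @param direction `"high_is_risk"` (default) or `"low_is_risk"`.
#' @return the cut point; attribute `"J"` holds the attained Youden index.
#' @export
best_cutpoint <- function(marker, labels, direction = "high_is_risk") {
  assert_in(direction, c("high_is_risk", "low_is_risk"), "direction")
  labels <- as.integer(labels)
  ok <- !is.na(marker) & !is.na(labels)
  marker <- marker[ok]; labels <- labels[ok]
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes required", call. = FALSE)
  ## sort ascending; cumulative class counts give sens/spec at each candidate
  o <- order(marker)
  x <- marker[o]; y <- labels[o]
  cand <- !duplicated(x, fromLast = TRUE)  # last index of each unique value
  ux <- x[cand]
  ## counts of values strictly below each unique candidate
  ## positive if value >= c: TP = pos with value >= c = n_pos - pos_below(c)
  pos_lt <- c(0, utils::head(cumsum(y)[cand], -1))
  neg_lt <- c(0, utils::head(cumsum(1 - y)[cand], -1))
  if (direction == "high_is_risk") {
    sens <- (n_pos - pos_lt) / n_pos        # value >= c is positive
    spec <- neg_lt / n_neg
  } else {
    sens <- cumsum(y)[cand] / n_pos         # value <= c is positive
    spec <- (n_neg - cumsum(1 - y)[cand]) / n_neg
  }
  J <- youden(sens, spec)
  best <- which(J >= max(J) - 1e-12)
  structure(mean(ux[best]), J = max(J))
}

#' Bootstrap-aggregated Youden cut point
#'
#' Draws `B` resamples with replacement of (marker, label) pairs, finds the
#' J-maximizing cut point in each ([best_cutpoint()]), and aggregates by the
#' arithmetic mean. Resamples containing a single outcome class are redrawn
#' (counted in `n_redrawn`).
#'
#' @inheritParams best_cutpoint
#' @param B number of bootstrap resamples (5,000 in the reference
#'   procedure; smaller values for quick runs).
#' @param seed RNG seed; results are reproducible exactly at a fixed seed.
#' @param max_retries redraw budget for single-class resamples.
#' @param name optional biomarker name carried into the result.
#' @return object of class `cutpoint_result`: `biomarker` (optional name),
#'   `direction`, `mean_cutpoint`, `cutpoints` (length B), `B`, `seed`,
#'   `n_redrawn`.
#' @export
bootstrap_cutpoint <- function(marker, labels, direction = "high_is_risk",
                               B = 5000, seed = 1L, max_retries = 100L,
                               name = NULL) {
  labels <- as.integer(labels)
  ok <- !is.na(marker) & !is.na(labels)
  marker <- marker[ok]; labels <- labels[ok]
  if (length(unique(marker)) < 2) {
    stop("degenerate marker: fewer than 2 distinct values", call. = FALSE)
  }
  if (length(unique(labels)) < 2) stop("both classes required", call. = FALSE)
  n <- length(marker)
  n_redrawn <- 0L
  cuts <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      for (try in seq_len(max_retries)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2) {
          return(as.numeric(best_cutpoint(marker[idx], labels[idx], direction)))
        }
        n_redrawn <<- n_redrawn + 1L
      }
      stop("could not draw a two-class bootstrap resample", call. = FALSE)
    }, numeric(1))
  })
  structure(list(biomarker = name, direction = direction,
                 mean_cutpoint = mean(cuts), cutpoints = cuts,
                 B = B, seed = seed, n_redrawn = n_redrawn),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("<cutpoint_result>%s %s: mean cut-off %.4g over B=%d (seed %d)\n",
              if (is.null(x$biomarker)) "" else paste0(" ", x$biomarker),
              x$direction, x$mean_cutpoint, x$B, x$seed))
  invisible(x)
}

#' Dichotomize a marker at a cut-off
#'
#' Elevated/positive means `>=` the cut-off; for `low_is_risk` markers
#' (the amyloid-beta 42/40 ratio) positive means `<=` the cut-off. A value
#' exactly at the cut-off is positive.
#'
#' @inheritParams best_cutpoint
#' @param cutpoint the threshold.
#' @return logical vector of positive flags.
#' @export
apply_cutoff <- function(marker, cutpoint, direction = "high_is_risk") {
  assert_in(direction, c("high_is_risk", "low_is_risk"), "direction")
  if (direction == "high_is_risk") marker >= cutpoint else marker <= cutpoint
}
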