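# Shared fixtures: tiny hand-built cohorts, cached calibrated configs, and
# independent brute-force oracles used across test files.

## A minimal, fully-typed cohort with hand-chosen follow-up, built in code.
toy_cohort <- function(followup = c(4, 12, 3, 8, 16, 2),
                       event = c("ad_dementia", "none", "death",
                                 "other_dementia", "none", "none"),
                       dropout = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)) {
  n <- length(followup)
  data.frame(
    id = seq_len(n),
    age = seq(62, 62 + 5 * (n - 1), by = 5),
    sex = factor(rep(c("female", "male"), length.out = n),
                 levels = c("female", "male")),
    education = factor(rep(c("elementary", "high school", "university"),
                           length.out = n),
                       levels = c("elementary", "high school", "university")),
    hypertension = rep(c(TRUE, FALSE), length.out = n),
    ihd = FALSE, heart_failure = FALSE, atrial_fib = FALSE,
    cerebrovascular = FALSE, ckd = rep(c(FALSE, TRUE), length.out = n),
    anaemia = FALSE, obesity = FALSE,
    n_chronic_diseases = rep(2:4, length.out = n),
    mmse = rep(c(29, 26, 30), length.out = n),
    memory_complaints = rep(c(TRUE, FALSE), length.out = n),
    apoe_e4 = rep(c(TRUE, FALSE, NA), length.out = n),
    abeta_ratio = seq(0.05, 0.08, length.out = n),
    ptau181 = seq(0.8, 2.4, length.out = n),
    ptau217 = seq(0.07, 0.25, length.out = n),
    ttau = seq(0.4, 1.2, length.out = n),
    nfl = seq(9, 45, length.out = n),
    gfap = seq(70, 260, length.out = n),
    followup_years = followup,
    event = factor(event, levels = c("none", "ad_dementia",
                                     "other_dementia", "death")),
    dropout = dropout
  )
}

## Calibrating the default configuration costs ~1 s; do it once per session.
calibrated_config <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_baseline_hazard(sim_config())
    cache
  }
})

simulated_frame <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- simulate_cohort(calibrated_config(), seed = 91L)
      cache <<- build_analysis_frame(co[!co$dropout, ])
    }
    cache
  }
})

## A config with all hazards switched off (no dementia, no death, no dropout):
## every participant reaches administrative censoring.
null_hazard_config <- function(...) {
  cfg <- sim_config(...)
  cfg$hazard_params$scale <- 0
  cfg$death_params$rate <- 1e-12
  cfg$dropout_params$intercept <- -50
  cfg
}

## Independent oracle: exhaustive Youden search over all observed candidate
## cut points, double loop, both orientations handled explicitly.
oracle_best_cutpoint <- function(marker, labels, direction) {
  cands <- unique(marker)
  best_j <- -Inf
  best_c <- c()
  for (cc in cands) {
    pred <- if (direction == "high_is_risk") marker >= cc else marker <= cc
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_c <- cc
    } else if (abs(j - best_j) <= 1e-12) {
      best_c <- c(best_c, cc)
    }
  }
  mean(best_c)
}

## Independent oracle: AUC as the mean over all positive x negative pairs.
oracle_auc_allpairs <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  tot <- 0
  for (xi in x) tot <- tot + sum(xi > y) + 0.5 * sum(xi == y)
  tot / (length(x) * length(y))
}

## Independent oracle: Cox partial likelihood (no ties) maximized by a
## 1-D numeric search, for a single covariate and <= 6 subjects.
oracle_cox_beta <- function(time, status, x) {
  neg_logpl <- function(beta) {
    ll <- 0
    for (i in which(status == 1)) {
      risk <- time >= time[i]
      ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
    }
    -ll
  }
  stats::optimize(neg_logpl, c(-15, 15), tol = 1e-10)$minimum
}

## Independent oracle: type-7 percentile by direct interpolation of order
## statistics (written without stats::quantile).
oracle_pctl <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}
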