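# Horizon labelling, confusion metrics, rank AUC, combination predictors.

test_that("horizon labels follow the stated decision rule", {
  co <- toy_cohort(
    followup = c(4, 12, 3, 8, 16, 9),
    event = c("ad_dementia", "none", "death", "other_dementia", "none", "none"),
    dropout = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  hl_ad <- horizon_labels(co, 10, "ad")
  expect_equal(hl_ad$label[1], 1L)                 # AD at 4y -> positive
  expect_equal(hl_ad$label[2], 0L)                 # censored alive at 12y
  expect_true(is.na(hl_ad$label[3]))               # death at 3y -> excluded
  expect_match(hl_ad$reason[3], "death")
  expect_true(is.na(hl_ad$label[4]))               # other dementia under AD outcome
  expect_match(hl_ad$reason[4], "other dementia")
  expect_true(is.na(hl_ad$label[6]))               # dropout at 9y
  expect_match(hl_ad$reason[6], "censored")
  hl_all <- horizon_labels(co, 10, "all_cause")
  expect_equal(hl_all$label[4], 1L)                # other dementia counts
  ## alternative convention: unobserved non-cases become negatives
  hl_neg <- horizon_labels(co, 10, "ad", censored_as_negative = TRUE)
  expect_equal(hl_neg$label[3], 0L)
  expect_false(any(hl_neg$excluded))
  expect_error(horizon_labels(co, 0), "positive")
})

test_that("confusion metrics reproduce hand arithmetic with ordered CIs", {
  labels <- c(rep(1, 9), rep(0, 11))
  preds <- c(rep(1, 8), 0, rep(1, 2), rep(0, 9))  # TP=8 FP=2 FN=1 TN=9
  cm <- confusion_metrics(labels, preds, ci_reps = 500, seed = 2)
  get <- function(m) cm$value[cm$metric == m]
  expect_equal(get("sensitivity"), 100 * 8 / 9, tolerance = 1e-10)
  expect_equal(get("specificity"), 100 * 9 / 11, tolerance = 1e-10)
  expect_equal(get("ppv"), 80)
  expect_equal(get("npv"), 90)
  expect_equal(get("accuracy"), 85)
  expect_true(all(cm$ci_low <= cm$value & cm$value <= cm$ci_high))
  ## perfect predictions
  cmp <- confusion_metrics(labels, labels, ci_reps = 100, seed = 1)
  expect_true(all(cmp$value == 100))
  ## all-negative predictions: PPV undefined -> NA, not 0
  cmn <- confusion_metrics(labels, rep(0, 20), ci_reps = 100, seed = 1)
  expect_true(is.na(cmn$value[cmn$metric == "ppv"]))
  expect_error(confusion_metrics(rep(1, 5), rep(1, 5)), "both classes")
})

test_that("bootstrap CI for sensitivity has near-nominal coverage", {
  set.seed(940)
  true_sens <- 0.8
  hits <- replicate(120, {
    lab <- rbinom(400, 1, 0.3)
    pred <- ifelse(lab == 1, rbinom(400, 1, true_sens), rbinom(400, 1, 0.2))
    cm <- confusion_metrics(lab, pred, ci_reps = 300,
                            seed = sample.int(1e6, 1))
    s <- cm[cm$metric == "sensitivity", ]
    s$ci_low <= 100 * true_sens && 100 * true_sens <= s$ci_high
  })
  expect_gt(mean(hits), 0.88)
})

test_that("rank AUC matches the all-pairs oracle exactly", {
  r <- auc_rank(c(1, 1, 2), c(0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(auc_rank(c(1, 2, 3, 10), c(0, 0, 1, 1))$auc, 1)
  expect_equal(auc_rank(-c(1, 2, 3, 10), c(0, 0, 1, 1))$auc, 0)
  set.seed(402)
  for (i in 1:30) {
    n <- sample(10:200, 1)
    scores <- round(rnorm(n), 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(auc_rank(scores, labels)$auc,
                 oracle_auc_allpairs(scores, labels), tolerance = 1e-12)
  }
})

test_that("permuted labels give a null AUC of one half", {
  set.seed(403)
  scores <- rnorm(120)
  labels <- rbinom(120, 1, 0.5)
  aucs <- replicate(1000, auc_rank(scores, sample(labels))$auc)
  expect_equal(mean(aucs), 0.5, tolerance = 0.01)
})

test_that("DeLong interval agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(404)
  scores <- rnorm(300)
  labels <- rbinom(300, 1, plogis(scores))
  ours <- auc_rank(scores, labels, ci_method = "delong")
  ref <- pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE,
                                direction = "<"), method = "delong")
  expect_equal(ours$auc, as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                        quiet = TRUE,
                                                        direction = "<"))))
  expect_equal(ours$ci_low, ref[1], tolerance = 1e-4)
  expect_equal(ours$ci_high, ref[3], tolerance = 1e-4)
})

test_that("combination rules behave as declared", {
  fl <- data.frame(ptau217 = c(TRUE, FALSE, TRUE),
                   nfl = c(TRUE, FALSE, FALSE),
                   gfap = c(FALSE, FALSE, TRUE))
  expect_equal(combine_elevated(fl, "count"), c(2, 0, 2))
  expect_equal(combine_elevated(fl, "at_least_k", k = 1), c(TRUE, FALSE, TRUE))
  expect_equal(combine_elevated(fl, "exactly_k", k = 2), c(TRUE, FALSE, TRUE))
  expect_equal(combine_elevated(fl, "pair_and", pair = c("ptau217", "nfl")),
               c(TRUE, FALSE, FALSE))
  expect_error(combine_elevated(fl, "pair_and", pair = c("ptau217", "ttau")),
               "not among")
})

test_that("ordinal count predictor dominates its binary constituents", {
  ## markers conditionally independent given the outcome
  set.seed(505)
  wins <- replicate(100, {
    n <- 500
    lab <- rbinom(n, 1, 0.3)
    fl <- as.data.frame(replicate(3, rbinom(n, 1, ifelse(lab == 1, 0.7, 0.3))))
    names(fl) <- c("a", "b", "c")
    auc_count <- auc_rank(combine_elevated(fl, "count"), lab)$auc
    auc_single <- max(vapply(fl, function(f) auc_rank(f, lab)$auc, 0))
    auc_count >= auc_single - 1e-9
  })
  expect_gt(mean(wins), 0.95)
})

test_that("evaluation reports are internally consistent and deterministic", {
  fr <- simulated_frame()
  split <- split_train_test(fr, seed = 21)
  cuts <- c(ptau217 = 0.134, nfl = 20.171, gfap = 142.5, abeta_ratio = 0.057)
  rep1 <- evaluate_pipeline(fr, cuts, outcome = "all_cause", split = split,
                            ci_reps = 100, seed = 8)
  rep2 <- evaluate_pipeline(fr, cuts, outcome = "all_cause", split = split,
                            ci_reps = 100, seed = 8)
  expect_identical(rep1, rep2)
  expect_setequal(unique(rep1$dataset), c("train", "test"))
  expect_true(all(rep1$auc >= 0 & rep1$auc <= 100))
  ## exact identity: accuracy = sens*prev + spec*(1-prev)
  single <- rep1[rep1$kind == "single", ]
  prev <- single$n_positive / single$n_classified
  expect_equal(single$accuracy,
               single$sensitivity * prev + single$specificity * (1 - prev),
               tolerance = 1e-8)
  ## Bayes identity for the predictive values
  ppv_bayes <- 100 * (single$sensitivity / 100 * prev) /
    (single$sensitivity / 100 * prev + (1 - single$specificity / 100) * (1 - prev))
  expect_equal(single$ppv, ppv_bayes, tolerance = 1e-8)
})

test_that("an uninformative marker has NPV near 1 - prevalence", {
  set.seed(606)
  n <- 4000
  lab <- rbinom(n, 1, 0.2)
  pred <- rbinom(n, 1, 0.5)
  cm <- confusion_metrics(lab, pred, ci_reps = 100, seed = 3)
  expect_equal(cm$value[cm$metric == "npv"], 80, tolerance = 3)
  expect_equal(cm$value[cm$metric == "ppv"], 20, tolerance = 3)
})

test_that("a designed binormal AUC of 0.8 is recovered on the test split", {
  ## binormal design: separation delta = sqrt(2)*qnorm(AUC)
  set.seed(707)
  n <- 2148
  lab <- rbinom(n, 1, 0.25)
  delta <- sqrt(2) * qnorm(0.8)
  score <- rnorm(n, mean = delta * lab)
  test_idx <- sample.int(n, round(0.2 * n))
  r <- auc_rank(score[test_idx], lab[test_idx])
  expect_true(r$ci_low <= 0.8 && 0.8 <= r$ci_high)
})
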