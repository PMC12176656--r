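# Spline basis, Cox fits vs brute-force oracles, quartile tables,
# diagnostics, IPW weights.

test_that("restricted cubic basis is linear outside the boundary knots", {
  set.seed(10)
  x <- rlnorm(300)
  b <- rcs_basis(x)
  expect_equal(b$knots, unname(quantile(x, c(0.25, 0.5, 0.75))))
  ## below the first knot the cubic column vanishes
  lo <- seq(0, b$knots[1], length.out = 20)
  expect_true(all(b$fun(lo)[, "cub"] == 0))
  ## beyond the last knot: numeric second difference ~ 0
  hi <- max(x) + 1:20
  f <- function(z) b$fun(z)[, "cub"]
  h <- 1e-3
  second <- (f(hi + h) - 2 * f(hi) + f(hi - h)) / h^2
  expect_lt(max(abs(second)), 1e-5)
  ## first and second derivatives continuous at an interior knot
  t2 <- b$knots[2]
  d2 <- function(z) (f(z + h) - 2 * f(z) + f(z - h)) / h^2
  expect_equal(d2(t2 - 2 * h), d2(t2 + 2 * h), tolerance = 0.05)
  expect_error(rcs_basis(rep(1:3, 10)), "distinct")
})

test_that("spline fit on a purely linear hazard finds no nonlinearity", {
  set.seed(2207)
  n <- 3000
  x <- rlnorm(n, sdlog = 0.5)
  t <- rexp(n, rate = 0.05 * exp(0.5 * scale(x)[, 1]))
  df <- data.frame(id = seq_len(n), followup_years = pmin(t, 16),
                   event = factor(ifelse(t <= 16, "ad_dementia", "none"),
                                  levels = levels(toy_cohort()$event)),
                   x = x)
  basis <- rcs_basis(df$x)
  df$lin <- basis$basis[, "lin"]
  df$cub <- basis$basis[, "cub"]
  fit <- fit_cox(df, c("lin", "cub"), covariates = character(0))
  se_cub <- sqrt(fit$vcov["cub", "cub"])
  expect_lt(abs(fit$coefficients[["cub"]]), 3 * se_cub)
  expect_gt(fit$coefficients[["lin"]], 0)
})

test_that("fit_cox equals a brute-force partial-likelihood search on toys", {
  ## the classic 3-subject instance
  df <- data.frame(id = 1:3, followup_years = c(1, 2, 3),
                   event = factor(c("ad_dementia", "ad_dementia", "none"),
                                  levels = levels(toy_cohort()$event)),
                   x = c(1, 0, 1))
  fit <- fit_cox(df, "x", covariates = character(0))
  expect_equal(unname(fit$coefficients["x"]),
               oracle_cox_beta(df$followup_years, c(1, 1, 0), df$x),
               tolerance = 1e-6)
  ## random <= 6-subject instances without ties
  set.seed(1405)
  for (i in 1:40) {
    n <- sample(3:6, 1)
    t <- sort(runif(n, 1, 10))  # distinct times
    status <- rbinom(n, 1, 0.7)
    x <- round(rnorm(n), 2)
    if (sum(status) == 0 || length(unique(x[status == 1])) == 0) next
    df <- data.frame(id = seq_len(n), followup_years = t,
                     event = factor(ifelse(status == 1, "ad_dementia", "none"),
                                    levels = levels(toy_cohort()$event)),
                     x = x)
    beta_oracle <- oracle_cox_beta(t, status, x)
    if (abs(beta_oracle) > 10) next  # effectively separated instance
    fit <- fit_cox(df, "x", covariates = character(0))
    expect_equal(unname(fit$coefficients["x"]), beta_oracle, tolerance = 1e-6)
  }
})

test_that("negating a binary covariate negates its coefficient", {
  fr <- simulated_frame()
  fr$flag <- as.integer(fr$sex == "female")
  f1 <- fit_cox(fr, "flag", covariates = c("age"))
  fr$flag <- 1 - fr$flag
  f2 <- fit_cox(fr, "flag", covariates = c("age"))
  expect_equal(unname(f1$coefficients["flag"]),
               -unname(f2$coefficients["flag"]), tolerance = 1e-8)
})

test_that("a known log-hazard ratio is recovered within 3 SE", {
  set.seed(881)
  n <- 5000
  x <- rnorm(n)
  t <- rexp(n, rate = 0.05 * exp(0.5 * x))
  df <- data.frame(id = seq_len(n), followup_years = pmin(t, 12),
                   event = factor(ifelse(t <= 12, "ad_dementia", "none"),
                                  levels = levels(toy_cohort()$event)),
                   x = x)
  fit <- fit_cox(df, "x", covariates = character(0))
  se <- sqrt(fit$vcov["x", "x"])
  expect_lt(abs(fit$coefficients[["x"]] - 0.5), 3 * se)
})

test_that("AD cause-specific analysis keeps the all-cause person-time", {
  fr <- simulated_frame()
  all_fit <- fit_cox(fr, "ptau217_z", outcome = "all_cause")
  ad_fit <- fit_cox(fr, "ptau217_z", outcome = "ad")
  ## same rows at risk, only the event labels differ
  expect_identical(all_fit$n, ad_fit$n)
  expect_lt(ad_fit$events, all_fit$events)
  expect_identical(sum(fr$followup_years), sum(fr$followup_years))
})

test_that("quartile table: reference HR 1, trend detects the simulated effect", {
  fr <- simulated_frame()
  tab <- quartile_hr_table(fr, "ptau217", "all_cause")
  expect_equal(tab$hr[tab$reference], 1)
  expect_true(all(is.na(tab$ci_low[tab$reference])))
  expect_identical(tab$quartile[1], "Q1")
  ## a strong simulated dose-response: trend p < 0.001
  expect_lt(attr(tab, "p_trend"), 0.001)
  ## IR columns recompute from events and person-time
  q1 <- fr[fr$ptau217_q == "Q1", ]
  expect_equal(tab$ir[1],
               100 * sum(q1$event %in% c("ad_dementia", "other_dementia")) /
                 sum(q1$followup_years))
  ## the amyloid ratio's reference is its highest quartile
  tab_ab <- quartile_hr_table(fr, "abeta_ratio", "all_cause")
  expect_identical(tab_ab$quartile[1], "Q4")
  expect_equal(tab_ab$hr[1], 1)
})

test_that("quartile HRs are invariant to monotone marker transforms", {
  fr <- simulated_frame()
  t1 <- quartile_hr_table(fr, "nfl", "all_cause")
  fr2 <- fr
  fr2$nfl <- log(fr2$nfl)
  q <- quartile_assign(fr2$nfl, "high_is_risk")
  fr2$nfl_q <- q
  t2 <- quartile_hr_table(fr2, "nfl", "all_cause")
  expect_equal(t1$hr, t2$hr, tolerance = 1e-8)
  expect_equal(attr(t1, "p_trend"), attr(t2, "p_trend"), tolerance = 1e-8)
})

test_that("null-biomarker quartile CIs cover 1 at roughly nominal rate", {
  set.seed(3303)
  covered <- 0L
  reps <- 60
  for (r in seq_len(reps)) {
    n <- 500
    t <- rexp(n, 0.08)
    df <- data.frame(id = seq_len(n), followup_years = pmin(t, 12),
                     event = factor(ifelse(t <= 12, "ad_dementia", "none"),
                                    levels = levels(toy_cohort()$event)),
                     marker = rlnorm(n))
    df$marker_q <- quartile_assign(df$marker, "high_is_risk")
    tab <- quartile_hr_table(df, "marker", covariates = character(0))
    covered <- covered +
      all(tab$ci_low[-1] <= 1 & tab$ci_high[-1] >= 1)
  }
  ## joint coverage of 3 intervals; binomial slack around ~0.93^1
  expect_gt(covered / reps, 0.75)
})

test_that("spline HR curve is 1 at the reference with a zero-width interval", {
  fr <- simulated_frame()
  sp <- fit_spline_cox(fr, "nfl", "all_cause")
  ref <- sp$basis$knots[1]
  at_ref <- spline_hr_curve(sp$fit, sp$basis, ref, x = ref)
  expect_equal(at_ref$hr, 1)
  expect_equal(at_ref$ci_low, 1)
  expect_equal(at_ref$ci_high, 1)
  ## zero coefficients -> flat curve at 1
  sp0 <- sp$fit
  sp0$coefficients[c("lin", "cub")] <- 0
  flat <- spline_hr_curve(sp0, sp$basis, ref)
  expect_true(all(flat$hr == 1))
  ## extrapolation flagged
  out <- spline_hr_curve(sp$fit, sp$basis, ref, x = max(fr$nfl) + 10)
  expect_true(out$extrapolated)
})

test_that("spline curve recovers a known smooth dose-response within its CIs", {
  ## generate from a log-hazard lying in the fitted spline family, so the
  ## pointwise intervals should cover the truth at near-nominal rate
  set.seed(515)
  n <- 4000
  x <- rnorm(n, 2.7, 0.5)  # log-concentration scale
  gen_basis <- rcs_basis(x)
  eta <- drop(gen_basis$basis %*% c(0.3, 0.5))  # flat-ish then rising
  t <- rexp(n, rate = 0.03 * exp(eta - mean(eta)))
  df <- data.frame(id = seq_len(n), followup_years = pmin(t, 16),
                   event = factor(ifelse(t <= 16, "ad_dementia", "none"),
                                  levels = levels(toy_cohort()$event)),
                   marker = x)
  sp <- fit_spline_cox(df, "marker", covariates = character(0))
  ref <- sp$basis$knots[1]
  grid <- as.numeric(quantile(x, seq(0.05, 0.95, by = 0.05)))
  curve <- spline_hr_curve(sp$fit, sp$basis, ref, x = grid)
  truth <- exp(drop((gen_basis$fun(grid) - rep(gen_basis$fun(ref),
                                               each = length(grid))) %*%
                      c(0.3, 0.5)))
  inside <- curve$ci_low <= truth & truth <= curve$ci_high
  expect_gte(mean(inside), 0.9)
})

test_that("Schoenfeld diagnostic is calibrated and has power", {
  ## under proportional hazards the p-values are roughly uniform
  set.seed(700)
  ps <- replicate(60, {
    n <- 300
    x <- rnorm(n)
    t <- rexp(n, 0.1 * exp(0.4 * x))
    df <- data.frame(id = seq_len(n), followup_years = pmin(t, 10),
                     event = factor(ifelse(t <= 10, "ad_dementia", "none"),
                                    levels = levels(toy_cohort()$event)),
                     x = x)
    schoenfeld_check(fit_cox(df, "x", covariates = character(0)))[["x"]]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  ## a strongly time-varying effect is detected
  set.seed(701)
  hits <- replicate(20, {
    n <- 600
    x <- rbinom(n, 1, 0.5)
    ## effect reverses over time: early harm, late protection
    t0 <- rexp(n, 0.25 * exp(1.5 * x))
    t1 <- 2 + rexp(n, 0.25 * exp(-1.5 * x))
    t <- ifelse(t0 < 2, t0, t1)
    df <- data.frame(id = seq_len(n), followup_years = pmin(t, 12),
                     event = factor(ifelse(t <= 12, "ad_dementia", "none"),
                                    levels = levels(toy_cohort()$event)),
                     x = x)
    schoenfeld_check(fit_cox(df, "x", covariates = character(0)))[["x"]] < 0.05
  })
  expect_gt(mean(hits), 0.8)
  ## single-event data: diagnostic undefined, reported as missing
  df1 <- toy_cohort(followup = c(1, 2, 3, 4, 5, 6),
                    event = c("ad_dementia", rep("none", 5)),
                    dropout = rep(FALSE, 6))
  fit1 <- suppressWarnings(fit_cox(df1, "nfl", covariates = character(0)))
  expect_true(is.na(schoenfeld_check(fit1)[["nfl"]]))
})

test_that("IPW weights are 1 without dropout and stable under random dropout", {
  co <- toy_cohort()
  co$dropout <- FALSE
  w <- ipw_dropout_weights(co)
  expect_true(all(w == 1))
  ## dropout independent of covariates: stabilized weights concentrate at 1
  co2 <- simulate_cohort(calibrated_config(), n = 10000, seed = 55)
  set.seed(56)
  co2$dropout <- runif(nrow(co2)) < 0.1
  w2 <- ipw_dropout_weights(co2)
  expect_lt(sd(w2[!co2$dropout]), 0.05)
  expect_equal(mean(w2[!co2$dropout]), 1, tolerance = 0.02)
  expect_true(all(is.na(w2[co2$dropout])))
})
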