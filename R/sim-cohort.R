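## Synthetic-cohort generator: Gaussian-copula biomarkers, covariate margins,
## Weibull proportional-hazards dementia with competing death, administrative
## censoring and covariate-dependent dropout.

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Convert a Spearman target to the latent Pearson correlation
#'
#' For a Gaussian copula, monotone marginal transforms preserve Spearman's
#' rho, and the latent (Pearson) correlation that yields a given Spearman
#' rho_s is `2*sin(pi*rho_s/6)`.
#'
#' @param rho_s Spearman correlation(s) in (-1, 1); a matrix is converted
#'   entry-wise with its diagonal kept at 1.
#' @return latent Pearson correlation(s), same shape as the input.
#' @export
spearman_to_latent_pearson <- function(rho_s) {
  off <- if (is.matrix(rho_s)) rho_s[row(rho_s) != col(rho_s)] else rho_s
  if (any(off <= -1 | off >= 1)) {
    stop("Spearman correlations must lie in (-1, 1)", call. = FALSE)
  }
  out <- 2 * sin(pi * rho_s / 6)
  if (is.matrix(rho_s)) diag(out) <- 1
  out
}

## Clip eigenvalues to repair a non-positive-definite correlation matrix.
nearest_pd_correlation <- function(S, eps = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) > eps) return(list(mat = S, repaired = FALSE))
  vals <- pmax(e$values, eps)
  R <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- 1 / sqrt(diag(R))
  list(mat = R * tcrossprod(d), repaired = TRUE)
}

#' Draw correlated biomarker concentrations from a Gaussian copula
#'
#' Latent multivariate-normal scores with correlation
#' `spearman_to_latent_pearson(spearman_matrix)` are pushed through each
#' marker's marginal quantile function (log-normal; logit-normal for the
#' amyloid-beta 42/40 ratio). Monotone marginals leave ranks untouched, so
#' sample Spearman correlations converge to the configured targets.
#' Values below the detection limit are returned raw; left-censoring them
#' is an explicit later step ([impute_below_lod()]).
#'
#' @param config a [sim_config()].
#' @param n number of participants (default `config$n_participants`).
#' @param seed RNG seed (default `config$seed`).
#' @return data.frame of the six marker columns; the latent standard-normal
#'   scores are attached as attribute `"latent_z"` (used by the hazard model).
#' @export
generate_biomarkers <- function(config, n = config$n_participants,
                                seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  P <- spearman_to_latent_pearson(config$spearman_matrix)
  rep_pd <- nearest_pd_correlation(P)
  if (rep_pd$repaired) {
    message("latent correlation matrix was not positive definite; ",
            "nearest-PD repair applied")
  }
  L <- chol(rep_pd$mat)
  z <- with_seed(seed, matrix(stats::rnorm(n * 6), n, 6) %*% L)
  colnames(z) <- MARKERS
  out <- data.frame(matrix(NA_real_, n, 6, dimnames = list(NULL, MARKERS)))
  for (m in MARKERS) {
    p <- config$marginal_params[[m]]
    out[[m]] <- switch(p$dist,
      lnorm = exp(p$meanlog + p$sdlog * z[, m]),
      logitnorm = stats::plogis(p$meanlog + p$sdlog * z[, m]),
      stop("unknown marginal distribution: ", p$dist)
    )
  }
  attr(out, "latent_z") <- z
  out
}

#' Draw baseline covariates from the configured margins
#'
#' Age is truncated normal; sex, disease flags, APOE and memory complaints are
#' independent Bernoulli draws; education is categorical; the chronic-disease
#' count is the sum of the eight flags plus a Poisson count of further
#' conditions. Joint structure between covariates beyond these margins is not
#' modelled.
#'
#' @inheritParams generate_biomarkers
#' @return data.frame of covariate columns.
#' @export
generate_covariates <- function(config, n = config$n_participants,
                                seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  cv <- config$covariate_params
  with_seed(seed, {
    lo <- stats::pnorm(cv$age_range[1], cv$age_mean, cv$age_sd)
    hi <- stats::pnorm(cv$age_range[2], cv$age_mean, cv$age_sd)
    age <- stats::qnorm(stats::runif(n, lo, hi), cv$age_mean, cv$age_sd)
    sex <- factor(ifelse(stats::runif(n) < cv$female_frac, "female", "male"),
                  levels = c("female", "male"))
    education <- factor(
      sample(names(cv$education_probs), n, replace = TRUE,
             prob = cv$education_probs),
      levels = names(cv$education_probs))
    flags <- vapply(DISEASES,
                    function(d) stats::runif(n) < cv$disease_prev[[d]],
                    logical(n))
    n_chronic <- rowSums(flags) + stats::rpois(n, cv$extra_disease_lambda)
    mmse <- pmin(30L, pmax(0L, as.integer(round(
      stats::rnorm(n, cv$mmse_mean, cv$mmse_sd)))))
    memory <- stats::runif(n) < cv$memory_complaints_frac
    memory[stats::runif(n) < cv$memory_missing_frac] <- NA
    apoe <- stats::runif(n) < cv$apoe_frac
    apoe[stats::runif(n) < cv$apoe_missing_frac] <- NA
    out <- data.frame(age = age, sex = sex, education = education)
    out[DISEASES] <- as.data.frame(flags)
    out$n_chronic_diseases <- n_chronic
    out$mmse <- mmse
    out$memory_complaints <- memory
    out$apoe_e4 <- apoe
    out
  })
}

## Dementia log-hazard linear predictor (relative to the baseline Weibull).
## Biomarker effects act on the latent copula score z: flat on the low-risk
## side of the configured knot percentile, linear in z beyond it (inverted
## for the amyloid ratio, whose low values carry risk).
dementia_lp <- function(covariates, latent_z, config) {
  b <- config$hazard_params$log_hr
  cv <- config$covariate_params
  lp <- b[["age"]] * (covariates$age - cv$age_mean) +
    b[["female"]] * (covariates$sex == "female") +
    b[["edu_high_school"]] * (covariates$education == "high school") +
    b[["edu_university"]] * (covariates$education == "university")
  for (d in DISEASES) lp <- lp + b[[d]] * covariates[[d]]
  apoe <- covariates$apoe_e4
  apoe[is.na(apoe)] <- FALSE  # carriers with unknown genotype get baseline risk
  lp <- lp + b[["apoe_e4"]] * apoe
  for (m in MARKERS) {
    eff <- config$hazard_params$biomarker_effects[[m]]
    knot <- stats::qnorm(eff$knot_pct)
    lp <- lp + if (m == "abeta_ratio") {
      eff$slope * pmax(knot - latent_z[, m], 0)
    } else {
      eff$slope * pmax(latent_z[, m] - knot, 0)
    }
  }
  unname(lp)
}

death_lp <- function(covariates, config) {
  b <- config$death_params$log_hr
  cv <- config$covariate_params
  unname(b[["age"]] * (covariates$age - cv$age_mean) +
           b[["n_chronic"]] * (covariates$n_chronic_diseases - 3.84) +
           b[["female"]] * (covariates$sex == "female"))
}

dropout_lp <- function(covariates, latent_z, config) {
  dp <- config$dropout_params
  cv <- config$covariate_params
  lp <- dp$intercept +
    dp$coef[["age"]] * (covariates$age - cv$age_mean) +
    dp$coef[["edu_high_school"]] * (covariates$education == "high school") +
    dp$coef[["edu_university"]] * (covariates$education == "university") +
    dp$coef[["n_chronic"]] * (covariates$n_chronic_diseases - 3.84)
  for (m in MARKERS) lp <- lp + dp$coef[[m]] * latent_z[, m]
  unname(lp)
}

#' Calibrate the baseline Weibull scale to a target incidence rate
#'
#' Finds the baseline Weibull rate such that the expected all-cause dementia
#' events per 100 person-years — over the configured covariate/biomarker
#' distribution and in the presence of competing death, dropout and
#' administrative censoring — matches `hazard_params$target_ir`. The
#' expectation is evaluated by Monte-Carlo integration on a fixed internal
#' seed, and the scale is found by root-finding (relative tolerance 1e-4 on
#' the rate), so calibration is deterministic for a given configuration.
#'
#' @param config a [sim_config()].
#' @param mc_n Monte-Carlo integration sample size (default 100,000).
#' @return the configuration with `hazard_params$scale` filled in; the
#'   attained Monte-Carlo rate is attached as attribute `"calibration"`.
#' @export
calibrate_baseline_hazard <- function(config, mc_n = 1e5) {
  stopifnot(inherits(config, "sim_config"))
  mc_seed <- 424243L  # fixed: calibration is part of the model, not the draw
  cov <- generate_covariates(config, n = mc_n, seed = mc_seed)
  bio <- generate_biomarkers(config, n = mc_n, seed = mc_seed + 1L)
  z <- attr(bio, "latent_z")
  lp <- dementia_lp(cov, z, config)
  shape <- config$hazard_params$shape
  parts <- with_seed(mc_seed + 2L, {
    list(e_dem = stats::rexp(mc_n),
         e_death = stats::rexp(mc_n),
         u_drop = stats::runif(mc_n),
         t_drop = stats::runif(mc_n, 0, config$admin_censor_years))
  })
  dlp <- death_lp(cov, config)
  t_death <- (parts$e_death /
                (config$death_params$rate * exp(dlp)))^(1 / config$death_params$shape)
  drops <- parts$u_drop < stats::plogis(dropout_lp(cov, z, config))
  cens <- pmin(t_death, config$admin_censor_years,
               ifelse(drops, parts$t_drop, Inf))
  ir_at <- function(log_scale) {
    t_dem <- (parts$e_dem / (exp(log_scale) * exp(lp)))^(1 / shape)
    events <- sum(t_dem <= cens)
    py <- sum(pmin(t_dem, cens))
    100 * events / py
  }
  target <- config$hazard_params$target_ir
  root <- stats::uniroot(function(ls) ir_at(ls) - target,
                         lower = log(1e-8), upper = log(1),
                         tol = 1e-6, extendInt = "upX")
  config$hazard_params$scale <- exp(root$root)
  attr(config, "calibration") <- list(mc_n = mc_n, attained_ir = ir_at(root$root),
                                      target_ir = target)
  if (abs(attr(config, "calibration")$attained_ir - target) > 0.01 * target) {
    stop("baseline-hazard calibration did not reach the target rate", call. = FALSE)
  }
  config
}

#' Simulate follow-up: event times, types and dropout
#'
#' Dementia onset is drawn by inverse-transform sampling from the Weibull
#' proportional-hazards model (`H(t) = scale * t^shape * exp(lp)`); death is an
#' independent competing Weibull; withdrawal is a Bernoulli flag with a
#' uniform withdrawal time. Observed follow-up is the minimum of dementia,
#' death, withdrawal and administrative censoring; dementia events are split
#' into AD and other dementia by an independent Bernoulli with the configured
#' AD fraction.
#'
#' @param covariates data.frame from [generate_covariates()].
#' @param biomarkers data.frame from [generate_biomarkers()] (with its
#'   `"latent_z"` attribute).
#' @param config a calibrated [sim_config()].
#' @param seed RNG seed.
#' @return data.frame with `followup_years`, `event` (factor: none,
#'   ad_dementia, other_dementia, death) and `dropout` (logical: follow-up
#'   ended by withdrawal).
#' @export
simulate_followup <- function(covariates, biomarkers, config,
                              seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (is.na(config$hazard_params$scale)) {
    stop("hazard_params$scale is not set; run calibrate_baseline_hazard() first",
         call. = FALSE)
  }
  n <- nrow(covariates)
  z <- attr(biomarkers, "latent_z")
  if (is.null(z)) stop("biomarkers must carry the 'latent_z' attribute", call. = FALSE)
  hp <- config$hazard_params
  lp <- dementia_lp(covariates, z, config)
  draws <- with_seed(seed + 1L, {
    list(e_dem = stats::rexp(n), e_death = stats::rexp(n),
         u_drop = stats::runif(n),
         t_drop = stats::runif(n, 0, config$admin_censor_years),
         u_ad = stats::runif(n))
  })
  t_dem <- (draws$e_dem / (hp$scale * exp(lp)))^(1 / hp$shape)
  t_death <- (draws$e_death /
                (config$death_params$rate * exp(death_lp(covariates, config))))^
    (1 / config$death_params$shape)
  withdrew <- draws$u_drop < stats::plogis(dropout_lp(covariates, z, config))
  t_drop <- ifelse(withdrew, draws$t_drop, Inf)
  t_obs <- pmin(t_dem, t_death, t_drop, config$admin_censor_years)
  event <- rep("none", n)
  event[t_obs == t_death] <- "death"
  is_dem <- t_obs == t_dem
  event[is_dem] <- ifelse(draws$u_ad[is_dem] < hp$ad_fraction,
                          "ad_dementia", "other_dementia")
  data.frame(followup_years = t_obs,
             event = factor(event, levels = EVENT_LEVELS),
             dropout = t_obs == t_drop)
}

#' Generate a complete synthetic cohort
#'
#' Covariates, copula-correlated biomarkers and follow-up in one seeded call.
#' If the baseline hazard is uncalibrated it is calibrated first.
#'
#' @inheritParams generate_biomarkers
#' @return a `cohort` data.frame (one row per participant) with the calibrated
#'   configuration attached as attribute `"sim_config"`.
#' @export
simulate_cohort <- function(config, n = config$n_participants,
                            seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (is.na(config$hazard_params$scale)) {
    config <- calibrate_baseline_hazard(config)
  }
  covariates <- generate_covariates(config, n = n, seed = seed)
  biomarkers <- generate_biomarkers(config, n = n, seed = seed + 1L)
  fu <- simulate_followup(covariates, biomarkers, config, seed = seed + 2L)
  out <- cbind(data.frame(id = seq_len(n)), covariates,
               as.data.frame(biomarkers), fu)
  class(out) <- c("cohort", "data.frame")
  attr(out, "sim_config") <- config
  out
}
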