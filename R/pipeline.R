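## End-to-end orchestration: simulate/read -> preprocess -> describe ->
## survival -> cut-points -> predict, as a seeded, logged, reproducible run.

#' Configuration for a full pipeline run
#'
#' @param input a [sim_config()] (cohort is simulated) or a path to a cohort
#'   CSV.
#' @param output_dir directory for artifacts (created if absent).
#' @param seeds named list: `simulation`, `split`, `bootstrap`, `ci` —
#'   independent seeds per randomness source so stages can be re-run in
#'   isolation.
#' @param horizon prediction horizon in years.
#' @param boot_reps bootstrap resamples for cut-point estimation (5,000 in
#'   the reference procedure; reduce for quick demos).
#' @param ci_reps bootstrap replicates for confusion-metric CIs.
#' @param split_ratio training fraction.
#' @param subgroup optional [analysis_filters()] name applied to the
#'   prediction stage.
#' @param outcomes outcomes to analyse.
#' @param ipw add a stabilized-IPW sensitivity fit to the quartile stage?
#' @return validated `run_config` list.
#' @export
run_config <- function(input = sim_config(), output_dir = "admarkers-run",
                       seeds = list(simulation = 1L, split = 2L,
                                    bootstrap = 3L, ci = 4L),
                       horizon = 10, boot_reps = 5000, ci_reps = 2000,
                       split_ratio = 0.8, subgroup = NULL,
                       outcomes = c("all_cause", "ad"), ipw = FALSE) {
  stopifnot(boot_reps >= 1, ci_reps >= 1, split_ratio > 0, split_ratio < 1)
  stopifnot(all(c("simulation", "split", "bootstrap", "ci") %in% names(seeds)))
  assert_in(outcomes, c("all_cause", "ad"), "outcomes")
  structure(list(input = input, output_dir = output_dir, seeds = seeds,
                 horizon = horizon, boot_reps = boot_reps, ci_reps = ci_reps,
                 split_ratio = split_ratio, subgroup = subgroup,
                 outcomes = outcomes, ipw = ipw),
            class = "run_config")
}

md5_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Stages: cohort acquisition (simulated or read), preprocessing,
#' descriptive table, quartile hazard-ratio tables, spline dose-response
#' curves, bootstrap cut-point estimation on the training split, and
#' horizon prediction reports on both splits. Every artifact is a plain
#' CSV/JSON file; the run log carries stage diagnostics (no wall-clock
#' content, so repeat runs are byte-identical); the manifest records seeds,
#' a configuration hash and artifact checksums.
#'
#' @param config a [run_config()].
#' @return (invisibly) the manifest as a list; artifacts are written under
#'   `config$output_dir`: `cohort.csv` (if simulated), `table1.csv`,
#'   `table2.csv`, `spline_curves.csv`, `cutoffs.json`, `table3.csv`,
#'   `combinations.csv`, `run.log`, `manifest.json`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  artifacts <- character(0)

  ## --- cohort ---
  cohort <- stage("cohort", {
    if (inherits(config$input, "sim_config")) {
      cfg <- config$input
      cfg$seed <- as.integer(config$seeds$simulation)
      cfg <- calibrate_baseline_hazard(cfg)
      say("simulate: n=%d seed=%d calibrated scale=%.6g",
          cfg$n_participants, cfg$seed, cfg$hazard_params$scale)
      co <- simulate_cohort(cfg)
      write_cohort(co, file.path(out, "cohort.csv"))
      artifacts <- c(artifacts, "cohort.csv")
      read_cohort(file.path(out, "cohort.csv"))  # canonical typed form
    } else {
      if (!file.exists(config$input)) {
        stop("input file not found: ", config$input)
      }
      say("read: %s", config$input)
      read_cohort(config$input)
    }
  })
  if ("cohort.csv" %in% list.files(out)) artifacts <- union(artifacts, "cohort.csv")

  ## --- preprocess ---
  frame <- stage("preprocess", {
    analytic <- cohort[!cohort$dropout, , drop = FALSE]
    f <- build_analysis_frame(analytic)
    say("preprocess: analytical n=%d (of %d); imputed below LOD: %s",
        nrow(f), nrow(cohort),
        paste(names(attr(f, "imputation_counts")),
              attr(f, "imputation_counts"), sep = "=", collapse = " "))
    f
  })

  ## --- descriptives ---
  stage("describe", {
    frame$incident_dementia <- ifelse(
      frame$event %in% c("ad_dementia", "other_dementia"),
      "incident dementia", "no dementia")
    t1 <- summarize_by_group(frame, "incident_dementia")
    utils::write.csv(t1, file.path(out, "table1.csv"), row.names = FALSE)
    artifacts <- c(artifacts, "table1.csv")
    ir <- cohort_incidence(frame, "all_cause")
    ad <- cohort_incidence(frame, "ad")
    say("describe: all-cause IR %.2f (%.2f-%.2f), AD IR %.2f (%.2f-%.2f) /100py",
        ir$rate, ir$ci_low, ir$ci_high, ad$rate, ad$ci_low, ad$ci_high)
  })

  ## --- survival: quartile HRs and splines ---
  stage("survival", {
    weights <- if (config$ipw) {
      w <- ipw_dropout_weights(cohort)
      as.numeric(w)[match(frame$id, cohort$id)]
    } else NULL
    t2 <- list(); curves <- list()
    for (oc in config$outcomes) {
      for (m in MARKERS) {
        tab <- quartile_hr_table(frame, m, oc, weights = weights)
        tab <- cbind(biomarker = m, outcome = oc, as.data.frame(tab))
        t2[[paste(oc, m)]] <- tab
        sp <- fit_spline_cox(frame, m, oc, weights = weights)
        curves[[paste(oc, m)]] <- cbind(biomarker = m, outcome = oc, sp$curve)
      }
    }
    utils::write.csv(do.call(rbind, t2), file.path(out, "table2.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, curves),
                     file.path(out, "spline_curves.csv"), row.names = FALSE)
    artifacts <- c(artifacts, "table2.csv", "spline_curves.csv")
    say("survival: %d quartile tables, %d spline curves%s",
        length(t2), length(curves), if (config$ipw) " (IPW-weighted)" else "")
  })

  ## --- cut-points on the training split ---
  split <- split_train_test(frame, config$split_ratio,
                            seed = as.integer(config$seeds$split))
  cutres <- stage("cutpoints", {
    say("split: train=%d test=%d (ratio %.2f, seed %d)",
        length(split$train), length(split$test), config$split_ratio,
        as.integer(config$seeds$split))
    train <- frame[frame$id %in% split$train, , drop = FALSE]
    specs <- biomarker_specs()
    res <- list()
    for (oc in config$outcomes) {
      hl <- horizon_labels(train, config$horizon, oc)
      keep <- !is.na(hl$label)
      for (i in seq_len(nrow(specs))) {
        m <- specs$name[i]
        bc <- bootstrap_cutpoint(train[[m]][keep], hl$label[keep],
                                 specs$direction[i], B = config$boot_reps,
                                 seed = as.integer(config$seeds$bootstrap),
                                 name = m)
        res[[oc]][[m]] <- list(
          direction = bc$direction, cutoff = bc$mean_cutpoint,
          B = bc$B, seed = bc$seed, n_redrawn = bc$n_redrawn,
          bootstrap_quartiles = as.list(stats::setNames(
            pctl(bc$cutpoints, c(0.25, 0.5, 0.75)), c("q25", "q50", "q75"))))
        say("cutpoint[%s/%s]: %.4g (B=%d)", oc, m, bc$mean_cutpoint, bc$B)
      }
    }
    jsonlite::write_json(res, file.path(out, "cutoffs.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts <- c(artifacts, "cutoffs.json")
    res
  })

  ## --- prediction reports ---
  stage("predict", {
    t3 <- list()
    for (oc in config$outcomes) {
      cuts <- vapply(cutres[[oc]], function(x) x$cutoff, numeric(1))
      rep <- evaluate_pipeline(frame, cuts, horizon = config$horizon,
                               outcome = oc, split = split,
                               subgroup = config$subgroup,
                               ci_reps = config$ci_reps,
                               seed = as.integer(config$seeds$ci))
      t3[[oc]] <- as.data.frame(rep)
    }
    t3 <- do.call(rbind, t3)
    utils::write.csv(t3[t3$kind == "single", ],
                     file.path(out, "table3.csv"), row.names = FALSE)
    utils::write.csv(t3[t3$kind == "combination", ],
                     file.path(out, "combinations.csv"), row.names = FALSE)
    artifacts <- c(artifacts, "table3.csv", "combinations.csv")
    say("predict: %d report rows (horizon %gy)", nrow(t3), config$horizon)
  })

  writeLines(log_lines, file.path(out, "run.log"))
  cfg_for_hash <- config
  cfg_for_hash$output_dir <- NULL  # the run is the same wherever it lands
  manifest <- list(
    package_version = as.character(utils::packageVersion("admarkers")),
    config_hash = md5_of(cfg_for_hash),
    seeds = config$seeds,
    horizon = config$horizon, boot_reps = config$boot_reps,
    ci_reps = config$ci_reps, split_ratio = config$split_ratio,
    artifacts = as.list(tools::md5sum(
      file.path(out, sort(unique(c(artifacts, "run.log"))))))
  )
  names(manifest$artifacts) <- basename(names(manifest$artifacts))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
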