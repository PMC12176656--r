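## Cohort I/O, validation, and preprocessing conventions: detection-limit
## imputation, whole-sample z-scores, quartile categories, analysis filters.

#' Biomarker specifications
#'
#' Name, risk direction and assay detection limit for each of the six serum
#' markers. The amyloid-beta 42/40 ratio is the only marker whose *low*
#' values carry risk; its highest quartile is therefore the reference
#' category and its cut-offs flag values at or *below* threshold.
#'
#' @param lod named detection limits (defaults from [default_lod()]).
#' @return data.frame with columns `name`, `direction`, `lod`.
#' @export
biomarker_specs <- function(lod = default_lod()) {
  data.frame(
    name = MARKERS,
    direction = ifelse(MARKERS == "abeta_ratio", "low_is_risk", "high_is_risk"),
    lod = unname(lod[MARKERS])
  )
}

#' Read and write cohort tables
#'
#' CSV with a header row, UTF-8, "." decimal, empty cells for missing values.
#' `read_cohort()` checks the schema (all required columns present, biomarkers
#' numeric and non-negative, follow-up non-negative, one record per id) and
#' types the categorical columns; extra columns are preserved.
#'
#' @param path CSV file path.
#' @param table a cohort data.frame.
#' @return `read_cohort()` returns a `cohort` data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing_cols <- setdiff(REQUIRED_COLS, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (m in MARKERS) {
    if (!is.numeric(raw[[m]])) stop("non-numeric biomarker column: ", m, call. = FALSE)
    if (any(raw[[m]] < 0, na.rm = TRUE)) stop("negative values in ", m, call. = FALSE)
  }
  if (any(raw$followup_years < 0)) stop("negative follow-up time", call. = FALSE)
  if (anyDuplicated(raw$id)) stop("duplicate participant ids", call. = FALSE)
  raw$sex <- factor(raw$sex, levels = c("female", "male"))
  raw$education <- factor(raw$education,
                          levels = c("elementary", "high school", "university"))
  raw$event <- factor(raw$event, levels = EVENT_LEVELS)
  if (anyNA(raw$event)) stop("unknown event label", call. = FALSE)
  for (fl in c(DISEASES, "memory_complaints", "apoe_e4", "dropout")) {
    raw[[fl]] <- as.logical(raw[[fl]])
  }
  class(raw) <- c("cohort", "data.frame")
  raw
}

#' @rdname read_cohort
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Impute values below the assay detection limit to zero
#'
#' Left-censored measurements (below the limit of detection) are replaced by
#' a single value of 0, a not-missing-at-random convention for immunoassay
#' panels; the number of imputed values is recorded.
#'
#' @param values numeric vector of raw concentrations.
#' @param lod detection limit (same units), >= 0.
#' @return numeric vector with values `< lod` set to 0; the imputation count
#'   is attached as attribute `"n_imputed"`.
#' @export
impute_below_lod <- function(values, lod) {
  stopifnot(is.numeric(lod), length(lod) == 1, lod >= 0)
  below <- !is.na(values) & values < lod
  values[below] <- 0
  structure(values, n_imputed = sum(below))
}

#' Standardize values against a reference sample
#'
#' z-scores computed with the mean and standard deviation of the *reference*
#' sample — by convention the whole baseline sample with available
#' biomarkers, so that subgroup analyses stay on a common scale.
#'
#' @param values numeric vector to standardize.
#' @param reference_values numeric vector defining the scale
#'   (default: `values`).
#' @return `(values - mean(ref)) / sd(ref)`.
#' @export
standardize <- function(values, reference_values = values) {
  m <- mean(reference_values, na.rm = TRUE)
  s <- stats::sd(reference_values, na.rm = TRUE)
  if (!is.finite(s) || s <= 0) {
    stop("reference sample has zero variance; cannot standardize", call. = FALSE)
  }
  (values - m) / s
}

#' Assign sample quartile categories with a direction-aware reference
#'
#' Cuts at the 25th/50th/75th sample percentiles (linear interpolation
#' between order statistics); values exactly at a boundary go to the lower
#' quartile. For `high_is_risk` markers the lowest quartile (Q1) is the
#' reference; for `low_is_risk` (the amyloid ratio) the highest (Q4).
#'
#' @param values numeric vector (>= 8 non-missing values).
#' @param direction `"high_is_risk"` or `"low_is_risk"`.
#' @return factor with levels Q1-Q4; attributes `"reference"` (the reference
#'   level) and `"cuts"` (the three percentile cut points).
#' @export
quartile_assign <- function(values, direction = "high_is_risk") {
  assert_in(direction, c("high_is_risk", "low_is_risk"), "direction")
  ok <- !is.na(values)
  if (sum(ok) < 8) stop("need at least 8 non-missing values", call. = FALSE)
  cuts <- pctl(values, c(0.25, 0.5, 0.75))
  if (anyDuplicated(cuts)) {
    stop("degenerate quartiles: tied percentile cut points", call. = FALSE)
  }
  q <- cut(values, breaks = c(-Inf, cuts, Inf),
           labels = paste0("Q", 1:4), right = TRUE)
  structure(q,
            reference = if (direction == "high_is_risk") "Q1" else "Q4",
            cuts = cuts)
}

#' Analysis filters and subgroup selectors
#'
#' The cohort filters used by the sensitivity and subgroup analyses:
#' \describe{
#'   \item{`mmse_ge_27`}{drop participants with baseline MMSE below 27.}
#'   \item{`truncate_6y`}{restrict follow-up to the first `years` (default 6):
#'     follow-up is capped and later events relabelled as censoring.}
#'   \item{`age_lt_78` / `age_ge_78`}{age strata.}
#'   \item{`female` / `male`}{sex strata.}
#'   \item{`apoe_carrier` / `apoe_noncarrier`}{APOE e4 strata (missing
#'     genotype excluded).}
#'   \item{`memory_complaints`}{participants reporting memory complaints.}
#'   \item{`complete_biomarkers`}{drop participants missing any of the six
#'     markers (the analytical-sample rule).}
#' }
#'
#' @param table cohort data.frame.
#' @param filter filter name (see above).
#' @param years truncation horizon for `truncate_6y`.
#' @return filtered (and for truncation, relabelled) cohort.
#' @export
analysis_filters <- function(table, filter, years = 6) {
  switch(filter,
    mmse_ge_27 = table[!is.na(table$mmse) & table$mmse >= 27, , drop = FALSE],
    truncate_6y = {
      over <- table$followup_years > years
      table$event[over] <- "none"
      table$dropout[over] <- FALSE
      table$followup_years[over] <- years
      table
    },
    age_lt_78 = table[table$age < 78, , drop = FALSE],
    age_ge_78 = table[table$age >= 78, , drop = FALSE],
    female = table[table$sex == "female", , drop = FALSE],
    male = table[table$sex == "male", , drop = FALSE],
    apoe_carrier = table[!is.na(table$apoe_e4) & table$apoe_e4, , drop = FALSE],
    apoe_noncarrier = table[!is.na(table$apoe_e4) & !table$apoe_e4, , drop = FALSE],
    memory_complaints = table[!is.na(table$memory_complaints) &
                                table$memory_complaints, , drop = FALSE],
    complete_biomarkers = table[stats::complete.cases(table[MARKERS]), ,
                                drop = FALSE],
    stop("unknown filter: ", filter, call. = FALSE)
  )
}

#' Build the analysis frame: z-scores and quartile categories
#'
#' Applies the preprocessing conventions to a cohort: detection-limit
#' imputation to 0, exclusion of participants missing any biomarker,
#' whole-sample z-score standardization, and direction-aware quartile
#' categories. All derived columns are recomputable from the raw columns;
#' rerunning is idempotent.
#'
#' @param table cohort data.frame (raw concentrations).
#' @param specs biomarker specification table ([biomarker_specs()]).
#' @return the analytical cohort with added columns `<marker>_z` and
#'   `<marker>_q`, plus attributes `"imputation_counts"`, `"quartile_cuts"`
#'   and `"specs"`.
#' @export
build_analysis_frame <- function(table, specs = biomarker_specs()) {
  imputed <- integer(0)
  for (i in seq_len(nrow(specs))) {
    m <- specs$name[i]
    v <- impute_below_lod(table[[m]], specs$lod[i])
    imputed[m] <- attr(v, "n_imputed")
    table[[m]] <- as.numeric(v)
  }
  table <- analysis_filters(table, "complete_biomarkers")
  cuts <- list()
  for (i in seq_len(nrow(specs))) {
    m <- specs$name[i]
    table[[paste0(m, "_z")]] <- standardize(table[[m]])
    q <- quartile_assign(table[[m]], specs$direction[i])
    cuts[[m]] <- attr(q, "cuts")
    table[[paste0(m, "_q")]] <- q
  }
  structure(table, imputation_counts = imputed, quartile_cuts = cuts,
            specs = specs)
}
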