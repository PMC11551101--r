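#' @section Data model:
#' A trial dataset is a plain `data.frame` with one row per participant,
#' carrying arm, demographics, longitudinal quality-of-life scores (mental
#' and physical component summaries at weeks 0/12/24), EQ-5D utilities at
#' months 0/3/6, a windowed cost ledger (five components in each of a
#' 12-week pre-trial window and two 13-week within-trial windows), a
#' week-24 completion flag and adherence counters. Metadata (currency year,
#' analysis horizon in years) and per-cell imputation provenance travel as
#' attributes under the S3 class `trial_dataset`.
#'
#' @name beamcea-package
#' @aliases beamcea
#' @keywords internal
"_PACKAGE"

# ---- schema -----------------------------------------------------------------

COST_COMPONENTS <- c("primary_care", "medications", "hospital", "social_care",
                     "intervention")
COST_WINDOWS <- c("pretrial_12wk", "trial_0_3mo", "trial_3_6mo")
TRIAL_WINDOWS <- c("trial_0_3mo", "trial_3_6mo")

cost_col <- function(component, window) paste0("cost_", component, "_", window)

cost_columns <- function() {
  as.vector(vapply(COST_WINDOWS,
                   function(w) cost_col(COST_COMPONENTS, w),
                   character(length(COST_COMPONENTS))))
}

outcome_columns <- function() {
  c("mcs_w0", "mcs_w12", "mcs_w24",
    "pcs_w0", "pcs_w12", "pcs_w24",
    "eq5d_m0", "eq5d_m3", "eq5d_m6")
}

# cells that can be missing / imputed and therefore carry provenance
value_columns <- function() c(outcome_columns(), cost_columns())

trial_schema_columns <- function() {
  c("participant_id", "arm", "age", "sex",
    outcome_columns(), cost_columns(),
    "completed_week24", "sessions_structured", "sessions_education",
    "minutes_structured")
}

ARM_LEVELS <- c("intervention", "control")
SEX_LEVELS <- c("male", "female", "unspecified")

# visit time grid (years) of the utility schedule: months 0, 3, 6
UTILITY_TIMES_YEARS <- c(0, 0.25, 0.5)

# window lengths in weeks: 12-week pre-trial, two 13-week trial windows
DEFAULT_WINDOW_WEEKS <- c(pretrial_12wk = 12, trial_0_3mo = 13, trial_3_6mo = 13)

# ---- constructor / validation ----------------------------------------------

#' Construct a validated trial dataset
#'
#' Wraps a participant-level data frame in the `trial_dataset` class after
#' validation. Missing measurements are `NA`; costs, when present, must be
#' nonnegative; the pre-trial window carries no intervention cost.
#'
#' @param records data.frame with the documented column schema
#'   (see [read_trial_csv()]).
#' @param currency_year label for the price year of all monetary values,
#'   e.g. `"2021/2022"`; a pass-through label, never interpreted.
#' @param horizon_years analysis horizon in years (default 0.5 = six months).
#' @param allocation_seed optional integer recording the seed used to
#'   generate the dataset (for provenance only).
#' @return A `trial_dataset`: the records with metadata attributes and an
#'   all-`FALSE` imputation-provenance matrix.
#' @export
trial_dataset <- function(records, currency_year = "2021/2022",
                          horizon_years = 0.5, allocation_seed = NULL) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(trial_schema_columns(), names(records))
  abort_if(length(missing_cols) > 0, "missing required column(s): %s",
           paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records)[, trial_schema_columns()]
  records$participant_id <- as.character(records$participant_id)
  records$arm <- as.character(records$arm)
  records$sex <- as.character(records$sex)
  records$completed_week24 <- as.logical(records$completed_week24)
  for (col in c("age", value_columns(),
                "sessions_structured", "sessions_education",
                "minutes_structured")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  x <- structure(records,
                 currency_year = currency_year,
                 horizon_years = horizon_years,
                 allocation_seed = allocation_seed,
                 imputed = new_provenance(nrow(records)),
                 class = c("trial_dataset", "data.frame"))
  validate_trial_dataset(x)
  x
}

new_provenance <- function(n) {
  matrix(FALSE, nrow = n, ncol = length(value_columns()),
         dimnames = list(NULL, value_columns()))
}

#' Validate a trial dataset
#'
#' Checks the invariants of the data model: unique participant ids, known
#' arm and sex labels, both arms present, positive ages, nonnegative costs,
#' zero intervention cost in the pre-trial window, adherence counters within
#' their maxima, and a positive horizon. Errors name the offending row
#' (by participant id) and column.
#'
#' @param x a `trial_dataset`.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_trial_dataset <- function(x) {
  stopifnot(inherits(x, "trial_dataset"))
  abort_if(attr(x, "horizon_years") <= 0, "horizon_years must be > 0")
  dup <- x$participant_id[duplicated(x$participant_id)]
  abort_if(length(dup) > 0, "duplicate participant_id: %s",
           paste(unique(dup), collapse = ", "))
  bad_arm <- !x$arm %in% ARM_LEVELS
  abort_if(any(bad_arm), "unknown arm label '%s' for participant %s",
           x$arm[bad_arm][1], x$participant_id[bad_arm][1])
  abort_if(!all(ARM_LEVELS %in% x$arm),
           "both arms must be represented; found only '%s'", unique(x$arm)[1])
  bad_sex <- !x$sex %in% SEX_LEVELS
  abort_if(any(bad_sex), "unknown sex label '%s' for participant %s",
           x$sex[bad_sex][1], x$participant_id[bad_sex][1])
  bad_age <- !is.na(x$age) & x$age <= 0
  abort_if(any(bad_age), "nonpositive age for participant %s",
           x$participant_id[bad_age][1])
  for (col in cost_columns()) {
    bad <- !is.na(x[[col]]) & x[[col]] < 0
    abort_if(any(bad), "negative cost in column %s for participant %s",
             col, x$participant_id[bad][1])
  }
  pre_int <- x[[cost_col("intervention", "pretrial_12wk")]]
  bad <- !is.na(pre_int) & pre_int != 0
  abort_if(any(bad),
           "pre-trial intervention cost must be 0 (participant %s)",
           x$participant_id[bad][1])
  bad <- !is.na(x$eq5d_m0) & x$eq5d_m0 > 1 |
    !is.na(x$eq5d_m3) & x$eq5d_m3 > 1 |
    !is.na(x$eq5d_m6) & x$eq5d_m6 > 1
  abort_if(any(bad), "EQ-5D utility above 1 for participant %s",
           x$participant_id[bad][1])
  bad <- !is.na(x$sessions_structured) &
    (x$sessions_structured < 0 | x$sessions_structured > 24)
  abort_if(any(bad), "sessions_structured outside 0..24 for participant %s",
           x$participant_id[bad][1])
  bad <- !is.na(x$sessions_education) &
    (x$sessions_education < 0 | x$sessions_education > 12)
  abort_if(any(bad), "sessions_education outside 0..12 for participant %s",
           x$participant_id[bad][1])
  bad <- !is.na(x$minutes_structured) & x$minutes_structured < 0
  abort_if(any(bad), "negative minutes_structured for participant %s",
           x$participant_id[bad][1])
  invisible(x)
}

#' @export
print.trial_dataset <- function(x, ...) {
  n <- table(factor(x$arm, ARM_LEVELS))
  cat(sprintf("<trial_dataset> %d participants (%d intervention, %d control)\n",
              nrow(x), n[["intervention"]], n[["control"]]))
  cat(sprintf("  currency year %s, horizon %.2g years; %d imputed cell(s)\n",
              attr(x, "currency_year"), attr(x, "horizon_years"),
              sum(attr(x, "imputed"))))
  invisible(x)
}

# carry class + metadata onto a modified copy of the records
rebuild_dataset <- function(records, template, imputed = NULL) {
  structure(as.data.frame(records),
            currency_year = attr(template, "currency_year"),
            horizon_years = attr(template, "horizon_years"),
            allocation_seed = attr(template, "allocation_seed"),
            imputed = if (is.null(imputed)) attr(template, "imputed") else imputed,
            class = c("trial_dataset", "data.frame"))
}

# ---- CSV i/o ----------------------------------------------------------------

#' Read a trial dataset from CSV
#'
#' Reads the participant-level CSV schema: one row per participant, columns
#' `participant_id, arm, age, sex, mcs_w0..w24, pcs_w0..w24, eq5d_m0..m6`,
#' `cost_<component>_<window>` for the five cost components
#' (primary_care, medications, hospital, social_care, intervention) crossed
#' with the three windows (pretrial_12wk, trial_0_3mo, trial_3_6mo), then
#' `completed_week24, sessions_structured, sessions_education,
#' minutes_structured`. Empty cells (and the sentinel `NA`) become explicit
#' missing values, never zeros.
#'
#' @param path CSV file path.
#' @param schema_version schema label; only `"1"` is defined.
#' @param currency_year,horizon_years metadata attached to the result.
#' @return A validated [trial_dataset()].
#' @export
read_trial_csv <- function(path, schema_version = "1",
                           currency_year = "2021/2022", horizon_years = 0.5) {
  abort_if(!identical(schema_version, "1"),
           "unknown schema_version '%s'", schema_version)
  abort_if(!file.exists(path), "file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  missing_cols <- setdiff(trial_schema_columns(), names(raw))
  abort_if(length(missing_cols) > 0,
           "malformed header: missing column(s) %s",
           paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(raw), trial_schema_columns())
  abort_if(length(extra) > 0,
           "malformed header: unknown column(s) %s",
           paste(extra, collapse = ", "))
  trial_dataset(raw, currency_year = currency_year,
                horizon_years = horizon_years)
}

#' Write a trial dataset to CSV
#'
#' Inverse of [read_trial_csv()]: missing values are written as empty cells
#' (never `"0"` or the string `"NA"`), so read-after-write reproduces the
#' dataset value-for-value and missing-for-missing. Imputation provenance is
#' deliberately not serialized; a freshly read file is all-observed.
#'
#' @param dataset a `trial_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(dataset, path) {
  validate_trial_dataset(dataset)
  out <- as.data.frame(dataset)
  out$completed_week24 <- ifelse(is.na(out$completed_week24), "",
                                 ifelse(out$completed_week24, "TRUE", "FALSE"))
  ok <- tryCatch({
    utils::write.table(out, path, sep = ",", na = "", row.names = FALSE,
                       col.names = TRUE, qmethod = "double")
    TRUE
  }, error = function(e) e)
  abort_if(!isTRUE(ok), "cannot write '%s': %s", path, conditionMessage(ok))
  invisible(path)
}
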