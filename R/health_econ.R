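# Construction of the economic endpoints: per-participant QALYs as the
# area under the EQ-5D utility curve over the horizon, completion of the
# windowed cost ledger by last value carried forward, aggregation of costs
# (care components + intervention delivery fee, optionally inflated to the
# base price year), and a table- or affine-driven 5L-to-3L utility mapping.
# Money is summed in integer pence so totals are exact.

#' Quality-adjusted life years by trapezoidal area under the curve
#'
#' Integrates utility over time with the trapezoid rule. Constant utility
#' `u` over a horizon `T` gives exactly `u * T` QALYs; the result is linear
#' in the utilities and unchanged by inserting a collinear midpoint.
#'
#' @param times observation times in years, strictly increasing, starting
#'   at 0 and ending at `horizon`.
#' @param utilities utility at each time (may be negative, at most 1).
#' @param horizon analysis horizon in years.
#' @return QALYs accrued over the horizon (numeric scalar).
#' @export
#' @examples
#' qaly_auc(c(0, 0.25, 0.5), c(0.6, 0.8, 1.0), horizon = 0.5) # 0.4
qaly_auc <- function(times, utilities, horizon = max(times)) {
  abort_if(length(times) < 2, "need at least two time points")
  abort_if(length(times) != length(utilities),
           "times and utilities differ in length")
  abort_if(anyNA(times) || anyNA(utilities), "missing time or utility value")
  abort_if(times[1] != 0, "utility schedule must start at time 0")
  abort_if(any(diff(times) <= 0), "times must be strictly increasing")
  abort_if(abs(times[length(times)] - horizon) > 1e-12,
           "last observation time (%g) must equal the horizon (%g)",
           times[length(times)], horizon)
  abort_if(any(utilities > 1 + 1e-12), "utility above 1")
  sum(diff(times) * (utilities[-length(utilities)] + utilities[-1]) / 2)
}

#' Per-participant QALYs for a trial dataset
#'
#' Applies [qaly_auc()] to each participant's month-0/3/6 utilities over
#' the dataset horizon. Participants with any missing utility are omitted
#' (impute upstream, e.g. with [locf_impute()] on the `"eq5d"` outcome, if
#' an intention-to-treat QALY is wanted).
#'
#' @param dataset a [trial_dataset()].
#' @return data.frame with `participant_id`, `arm`, `qaly` and
#'   `any_imputed` (whether any utility used was flagged as imputed).
#' @export
compute_qalys <- function(dataset) {
  validate_trial_dataset(dataset)
  ucols <- c("eq5d_m0", "eq5d_m3", "eq5d_m6")
  horizon <- attr(dataset, "horizon_years")
  times <- UTILITY_TIMES_YEARS * (horizon / 0.5)
  u <- as.matrix(as.data.frame(dataset)[ucols])
  keep <- stats::complete.cases(u)
  imp <- attr(dataset, "imputed")[, ucols, drop = FALSE]
  data.frame(
    participant_id = dataset$participant_id[keep],
    arm = dataset$arm[keep],
    qaly = apply(u[keep, , drop = FALSE], 1, function(row)
      qaly_auc(times, row, horizon)),
    any_imputed = apply(imp[keep, , drop = FALSE], 1, any),
    stringsAsFactors = FALSE)
}

#' Complete the cost ledger by last value carried forward
#'
#' Each missing within-trial cost component is replaced by the most recent
#' earlier window's value for that component, scaled by the ratio of window
#' lengths (so a GBP x pre-trial 12-week value becomes x * 13/12 in a
#' 13-week trial window). Filled cells are flagged in the provenance
#' matrix; the operation is idempotent and never alters observed cells.
#'
#' @param dataset a [trial_dataset()].
#' @param window_weeks named lengths (weeks) of the three windows; default
#'   12/13/13.
#' @param zero_fill_pretrial if `TRUE`, missing pre-trial components are
#'   set to 0 (flagged) before carrying; otherwise a missing pre-trial cell
#'   is an error, since nothing can be carried from it.
#' @return The dataset with a complete cost ledger and provenance flags.
#' @export
lvcf_costs <- function(dataset, window_weeks = DEFAULT_WINDOW_WEEKS,
                       zero_fill_pretrial = FALSE) {
  validate_trial_dataset(dataset)
  stopifnot(all(COST_WINDOWS %in% names(window_weeks)))
  out <- as.data.frame(dataset)
  imp <- attr(dataset, "imputed")
  for (comp in COST_COMPONENTS) {
    pre <- cost_col(comp, "pretrial_12wk")
    if (anyNA(out[[pre]])) {
      abort_if(!zero_fill_pretrial,
               "missing pre-trial %s cost for participant %s (set zero_fill_pretrial = TRUE to zero-fill)",
               comp, out$participant_id[is.na(out[[pre]])][1])
      miss <- is.na(out[[pre]])
      out[[pre]][miss] <- 0
      imp[miss, pre] <- TRUE
    }
    for (j in 2:length(COST_WINDOWS)) {
      w <- COST_WINDOWS[j]
      prev <- COST_WINDOWS[j - 1]
      col <- cost_col(comp, w)
      miss <- is.na(out[[col]])
      if (!any(miss)) next
      scale <- window_weeks[[w]] / window_weeks[[prev]]
      out[[col]][miss] <-
        round_half_up(out[[cost_col(comp, prev)]][miss] * scale, 2)
      imp[miss, col] <- TRUE
    }
  }
  rebuild_dataset(out, dataset, imputed = imp)
}

#' Aggregate per-participant costs over the analysis horizon
#'
#' Sums the four care components (primary care, medications, hospital,
#' social care) over the two within-trial windows, adds the intervention
#' delivery fee for intervention-arm participants, and applies an optional
#' multiplicative inflation index. The intervention component is
#' recomputed from the stated policy (not read from the ledger): under
#' `"full"` attribution the whole per-year fee is charged to the horizon
#' (the emulated base case charges GBP 15/person to the 6-month analysis);
#' under `"prorata"` it is scaled by `horizon_years`. All arithmetic is in
#' integer pence, so `trial_cost` equals the component sum exactly.
#'
#' @param dataset a [trial_dataset()] with a complete (e.g. LVCF'd) ledger.
#' @param intervention_cost_per_year delivery fee, GBP per participant-year.
#' @param attribution `"full"` or `"prorata"` (see above).
#' @param inflation_index optional named numeric of multiplicative factors
#'   by currency-year label; must contain the dataset's currency year.
#' @return data.frame with `participant_id`, `arm`, `baseline_cost`,
#'   `trial_cost`, one column per component total, and `any_imputed`.
#' @export
aggregate_costs <- function(dataset, intervention_cost_per_year = 15,
                            attribution = c("full", "prorata"),
                            inflation_index = NULL) {
  validate_trial_dataset(dataset)
  attribution <- match.arg(attribution)
  care <- setdiff(COST_COMPONENTS, "intervention")
  trial_cols <- as.vector(outer(care, TRIAL_WINDOWS, cost_col))
  miss <- !stats::complete.cases(
    as.data.frame(dataset)[c(cost_col(care, "pretrial_12wk"), trial_cols)])
  abort_if(any(miss),
           "incomplete cost ledger for participant %s; run lvcf_costs() first",
           dataset$participant_id[miss][1])
  factor <- 1
  if (!is.null(inflation_index)) {
    yr <- attr(dataset, "currency_year")
    abort_if(!yr %in% names(inflation_index),
             "inflation index has no factor for source year '%s'", yr)
    factor <- inflation_index[[yr]]
  }
  n <- nrow(dataset)
  comp_pence <- matrix(0, n, length(care) + 1,
                       dimnames = list(NULL, c(care, "intervention")))
  for (comp in care) {
    tot <- rowSums(vapply(TRIAL_WINDOWS, function(w)
      to_pence(dataset[[cost_col(comp, w)]] * factor), numeric(n)))
    comp_pence[, comp] <- tot
  }
  fee <- intervention_cost_per_year *
    if (attribution == "full") 1 else attr(dataset, "horizon_years")
  comp_pence[, "intervention"] <-
    ifelse(dataset$arm == "intervention", to_pence(fee * factor), 0)
  base_pence <- rowSums(vapply(care, function(comp)
    to_pence(dataset[[cost_col(comp, "pretrial_12wk")]] * factor),
    numeric(n)))
  imp <- attr(dataset, "imputed")[, cost_columns(), drop = FALSE]
  out <- data.frame(participant_id = dataset$participant_id,
                    arm = dataset$arm,
                    baseline_cost = from_pence(base_pence),
                    trial_cost = from_pence(rowSums(comp_pence)),
                    stringsAsFactors = FALSE)
  for (comp in colnames(comp_pence))
    out[[paste0("cost_", comp)]] <- from_pence(comp_pence[, comp])
  out$any_imputed <- apply(imp, 1, any)
  out
}

#' Define a utility mapping (5L to 3L crosswalk)
#'
#' Either an affine map `u' = intercept + slope * u` or a lookup table of
#' input utilities to output utilities. No value set is bundled: the
#' crosswalk is always user-supplied.
#'
#' @param table optional data.frame with columns `from`, `to`.
#' @param slope,intercept affine coefficients (ignored when `table` given).
#' @param digits inputs are matched to the table after rounding to this
#'   many decimal places.
#' @return An object of class `utility_mapping`.
#' @export
utility_mapping <- function(table = NULL, slope = 1, intercept = 0,
                            digits = 3) {
  if (!is.null(table)) {
    stopifnot(is.data.frame(table), all(c("from", "to") %in% names(table)))
    abort_if(any(table$to > 1), "mapped utilities must be <= 1")
    table$from <- round(table$from, digits)
    abort_if(anyDuplicated(table$from) > 0, "duplicate 'from' values in table")
  }
  structure(list(table = table, slope = slope, intercept = intercept,
                 digits = digits),
            class = "utility_mapping")
}

#' Apply a utility mapping to all EQ-5D columns
#'
#' Replaces every observed utility via the mapping; the original values are
#' retained under the `"utilities_premap"` attribute for provenance.
#' Table-driven mappings must cover every observed value; unmapped inputs
#' raise an error listing the offending values.
#'
#' @param dataset a [trial_dataset()].
#' @param mapping a [utility_mapping()].
#' @return The dataset with mapped utilities.
#' @export
map_utilities <- function(dataset, mapping) {
  validate_trial_dataset(dataset)
  stopifnot(inherits(mapping, "utility_mapping"))
  ucols <- c("eq5d_m0", "eq5d_m3", "eq5d_m6")
  out <- as.data.frame(dataset)
  orig <- out[ucols]
  for (col in ucols) {
    v <- out[[col]]
    obs <- !is.na(v)
    if (is.null(mapping$table)) {
      out[[col]][obs] <- mapping$intercept + mapping$slope * v[obs]
    } else {
      key <- round(v[obs], mapping$digits)
      idx <- match(key, mapping$table$from)
      abort_if(anyNA(idx), "unmapped utility value(s): %s",
               paste(unique(key[is.na(idx)]), collapse = ", "))
      out[[col]][obs] <- mapping$table$to[idx]
    }
  }
  abort_if(any(out[ucols] > 1 + 1e-12, na.rm = TRUE),
           "mapping produced utilities above 1")
  res <- rebuild_dataset(out, dataset)
  attr(res, "utilities_premap") <- orig
  res
}
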