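# Intention-to-treat and per-protocol analysis of the longitudinal
# quality-of-life outcomes: single imputation by last observation carried
# forward (the trial's primary, most conservative approach), baseline- and
# age-adjusted ANCOVA at follow-up, and a proper multiple-imputation
# sensitivity analysis pooled by Rubin's rules.

# visit columns for an outcome label, ordered by time
outcome_visit_cols <- function(outcome) {
  switch(outcome,
         mcs = c("mcs_w0", "mcs_w12", "mcs_w24"),
         pcs = c("pcs_w0", "pcs_w12", "pcs_w24"),
         eq5d = c("eq5d_m0", "eq5d_m3", "eq5d_m6"),
         stop(sprintf("unknown outcome '%s'", outcome), call. = FALSE))
}

resolve_visit <- function(outcome, followup_visit) {
  cols <- outcome_visit_cols(outcome)
  hit <- grep(paste0("_", followup_visit, "$"), cols, value = TRUE)
  abort_if(length(hit) != 1L, "unknown visit '%s' for outcome '%s'",
           followup_visit, outcome)
  hit
}

#' Last observation carried forward
#'
#' Replaces each missing follow-up value of `outcome` with the most recent
#' earlier observed value for that participant (week 12 falls back to
#' baseline; week 24 falls back to week 12 if observed, else baseline).
#' Observed cells are never altered and the operation is idempotent.
#' Imputed cells are flagged in the dataset's provenance matrix so that
#' downstream per-protocol filtering can distinguish observed from carried
#' values. Records without a baseline value cannot be carried forward and
#' are dropped with a warning.
#'
#' @param dataset a [trial_dataset()].
#' @param outcome one of `"mcs"`, `"pcs"`, `"eq5d"`.
#' @return The dataset with the outcome completed and provenance flags set.
#' @export
locf_impute <- function(dataset, outcome = "mcs") {
  validate_trial_dataset(dataset)
  cols <- outcome_visit_cols(outcome)
  out <- as.data.frame(dataset)
  imp <- attr(dataset, "imputed")
  no_base <- is.na(out[[cols[1]]])
  if (any(no_base)) {
    warning(sprintf(
      "%d record(s) without baseline %s excluded from LOCF: %s",
      sum(no_base), outcome,
      paste(out$participant_id[no_base], collapse = ", ")))
    out <- out[!no_base, , drop = FALSE]
    imp <- imp[!no_base, , drop = FALSE]
  }
  for (j in 2:length(cols)) {
    miss <- is.na(out[[cols[j]]])
    if (!any(miss)) next
    carried <- out[[cols[j - 1]]][miss] # earlier visits already completed
    out[[cols[j]]][miss] <- carried
    imp[miss, cols[j]] <- TRUE
  }
  rebuild_dataset(out, dataset, imputed = imp)
}

#' Baseline- and age-adjusted ANCOVA
#'
#' Ordinary least squares of the follow-up value on an arm indicator,
#' the baseline value of the same outcome, and age:
#' `y_followup ~ arm + y_baseline + age`. The reported effect is the arm
#' coefficient (intervention minus control) with its t-based 95% CI and
#' two-sided p-value. Residual normality (Shapiro-Wilk) and baseline
#' balance of the covariates across arms are checked and reported as
#' warnings only, never failures.
#'
#' @param dataset a completed [trial_dataset()] (no missing follow-up after
#'   imputation, or a complete-case subset).
#' @param outcome one of `"mcs"`, `"pcs"`, `"eq5d"`.
#' @param followup_visit visit suffix, e.g. `"w24"` (default), `"w12"`,
#'   `"m6"`.
#' @param population analysis-population label stored on the estimate.
#' @return An object of class `ancova_estimate`: effect, se, ci_low,
#'   ci_high, p_value, n_used, df, population, covariates.
#' @export
ancova_fit <- function(dataset, outcome = "mcs", followup_visit = "w24",
                       population = "ITT_LOCF") {
  validate_trial_dataset(dataset)
  ycol <- resolve_visit(outcome, followup_visit)
  bcol <- outcome_visit_cols(outcome)[1]
  d <- data.frame(y = dataset[[ycol]],
                  baseline = dataset[[bcol]],
                  age = dataset$age,
                  arm = factor(dataset$arm, levels = c("control",
                                                       "intervention")))
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]
  per_arm <- table(d$arm)
  abort_if(any(per_arm < 3) || length(per_arm) < 2,
           "ANCOVA needs >= 3 records per arm (have %s)",
           paste(per_arm, collapse = "/"))
  fit <- stats::lm(y ~ arm + baseline + age, data = d)
  co <- summary(fit)$coefficients
  # degenerate covariates (e.g. constant age) are dropped by least squares;
  # only an inestimable arm contrast is fatal
  abort_if(is.na(stats::coef(fit)["armintervention"]),
           "singular ANCOVA design: arm effect inestimable")
  est <- co["armintervention", "Estimate"]
  se <- co["armintervention", "Std. Error"]
  df <- fit$df.residual
  crit <- stats::qt(0.975, df)

  res <- stats::residuals(fit)
  if (length(res) >= 4 && length(res) <= 5000) {
    sw <- stats::shapiro.test(res)
    if (sw$p.value < 0.001)
      warning(sprintf("ANCOVA residuals look non-normal (Shapiro-Wilk p = %.2g)",
                      sw$p.value))
  }
  for (cov in c("baseline", "age")) {
    if (stats::sd(d[[cov]]) == 0) next # constant covariate: trivially balanced
    bal <- stats::t.test(d[[cov]] ~ d$arm)
    if (bal$p.value < 0.001)
      warning(sprintf("covariate '%s' imbalanced across arms (p = %.2g)",
                      cov, bal$p.value))
  }

  structure(list(effect = unname(est), se = unname(se),
                 ci_low = unname(est - crit * se),
                 ci_high = unname(est + crit * se),
                 p_value = unname(co["armintervention", "Pr(>|t|)"]),
                 n_used = nrow(d), df = df,
                 population = population,
                 outcome = outcome, followup_visit = followup_visit,
                 covariates = c("baseline", "age")),
            class = "ancova_estimate")
}

#' @export
print.ancova_estimate <- function(x, ...) {
  cat(sprintf(
    "ANCOVA [%s] %s at %s: effect %.2f (95%% CI %.2f to %.2f), p = %.3g, n = %d\n",
    x$population, x$outcome, x$followup_visit,
    x$effect, x$ci_low, x$ci_high, x$p_value, x$n_used))
  invisible(x)
}

# one proper linear-regression imputation of `ycol` from the design in
# `predictors`: posterior draws of (sigma^2, beta) under the standard
# noninformative prior, then predictive draws for the missing rows
draw_imputation <- function(d, ycol, predictors) {
  obs <- !is.na(d[[ycol]])
  f <- stats::reformulate(predictors, response = ycol)
  fit <- stats::lm(f, data = d[obs, , drop = FALSE])
  abort_if(anyNA(stats::coef(fit)), "imputation model is singular")
  X_obs <- stats::model.matrix(fit)
  df <- nrow(X_obs) - ncol(X_obs)
  abort_if(df < 1, "too few observed cases to impute %s", ycol)
  rss <- sum(stats::residuals(fit)^2)
  sigma2 <- rss / stats::rchisq(1, df)
  xtx_inv <- summary(fit)$cov.unscaled
  beta <- stats::coef(fit) +
    drop(chol(sigma2 * xtx_inv) %*% stats::rnorm(ncol(X_obs)))
  tt <- stats::delete.response(stats::terms(fit))
  mf <- stats::model.frame(tt, data = d[!obs, , drop = FALSE],
                           xlev = fit$xlevels)
  X_mis <- stats::model.matrix(tt, mf)
  drop(X_mis %*% beta) + stats::rnorm(sum(!obs), 0, sqrt(sigma2))
}

#' Multiple imputation by chained linear regressions
#'
#' Produces `m` completed copies of the dataset. Missing intermediate
#' visits are imputed first from (arm, age, baseline); the final visit is
#' then imputed from (arm, age, baseline, intermediate). Imputations are
#' proper: regression coefficients and the residual variance are drawn
#' from their posterior under the standard noninformative prior before
#' each predictive draw, so between-imputation variance is not understated.
#' Observed cells are identical across the `m` copies. Records without a
#' baseline value are dropped with a warning, as in [locf_impute()].
#'
#' @param dataset a [trial_dataset()].
#' @param outcome one of `"mcs"`, `"pcs"`, `"eq5d"`.
#' @param m number of imputations (>= 2; the emulated analysis used 5).
#' @param seed integer seed; the i-th imputation uses a stream derived
#'   from `(seed, i)`, so results are reproducible and independent of `m`.
#' @return A list of `m` completed [trial_dataset()]s with provenance flags.
#' @export
mi_impute <- function(dataset, outcome = "mcs", m = 5L, seed = 1L) {
  validate_trial_dataset(dataset)
  abort_if(!is_count(m, min = 2), "m must be an integer >= 2")
  cols <- outcome_visit_cols(outcome)
  out <- as.data.frame(dataset)
  imp0 <- attr(dataset, "imputed")
  no_base <- is.na(out[[cols[1]]])
  if (any(no_base)) {
    warning(sprintf("%d record(s) without baseline %s excluded from imputation",
                    sum(no_base), outcome))
    out <- out[!no_base, , drop = FALSE]
    imp0 <- imp0[!no_base, , drop = FALSE]
  }
  for (a in ARM_LEVELS) {
    abort_if(all(is.na(out[[cols[3]]][out$arm == a])),
             "all follow-up values missing in the %s arm: model unidentifiable", a)
  }
  lapply(seq_len(m), function(i) {
    set.seed(derive_seed(seed, 100L + i))
    d <- out
    imp <- imp0
    if (anyNA(d[[cols[2]]])) {
      miss <- is.na(d[[cols[2]]])
      d[[cols[2]]][miss] <- draw_imputation(
        d, cols[2], c("arm", "age", cols[1]))
      imp[miss, cols[2]] <- TRUE
    }
    if (anyNA(d[[cols[3]]])) {
      miss <- is.na(d[[cols[3]]])
      d[[cols[3]]][miss] <- draw_imputation(
        d, cols[3], c("arm", "age", cols[1], cols[2]))
      imp[miss, cols[3]] <- TRUE
    }
    rebuild_dataset(d, dataset, imputed = imp)
  })
}

#' Pool ANCOVA estimates across imputations by Rubin's rules
#'
#' Point estimate = mean of the per-imputation effects; within-imputation
#' variance W = mean of squared standard errors; between-imputation
#' variance B = sample variance of the effects; total variance
#' T = W + (1 + 1/m) B, exactly. Interval and p-value use the
#' Barnard-Rubin small-sample degrees of freedom; with a single estimate
#' (or zero between-imputation variance) pooling degenerates to the input.
#'
#' @param estimates list of [ancova_fit()] results from the same model
#'   specification applied to each completed dataset.
#' @return An object of class `pooled_estimate` with fields effect,
#'   within_var, between_var, total_var, m, ci_low, ci_high, p_value, df.
#' @export
rubin_pool <- function(estimates) {
  abort_if(length(estimates) < 1, "need at least one estimate to pool")
  stopifnot(all(vapply(estimates, inherits, TRUE, "ancova_estimate")))
  spec <- unique(vapply(estimates, function(e)
    paste(e$outcome, e$followup_visit, paste(e$covariates, collapse = "+")),
    character(1)))
  abort_if(length(spec) > 1, "estimates come from different model specifications")
  m <- length(estimates)
  eff <- vapply(estimates, `[[`, numeric(1), "effect")
  w <- mean(vapply(estimates, `[[`, numeric(1), "se")^2)
  b <- if (m > 1) stats::var(eff) else 0
  total <- w + (1 + 1 / m) * b
  pooled <- mean(eff)
  df_com <- min(vapply(estimates, `[[`, numeric(1), "df"))
  if (b > 0 && m > 1) {
    lambda <- (1 + 1 / m) * b / total
    df_old <- (m - 1) / lambda^2
    df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
    df <- 1 / (1 / df_old + 1 / df_obs)
  } else {
    df <- df_com
  }
  crit <- stats::qt(0.975, df)
  se <- sqrt(total)
  structure(list(effect = pooled, within_var = w, between_var = b,
                 total_var = total, m = m,
                 ci_low = pooled - crit * se, ci_high = pooled + crit * se,
                 p_value = 2 * stats::pt(-abs(pooled / se), df), df = df),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "Pooled over %d imputations: effect %.2f (95%% CI %.2f to %.2f), p = %.3g\n",
    x$m, x$effect, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Per-protocol subset
#'
#' Retains exactly the records whose baseline and final-visit values of
#' `outcome` were observed, i.e. present and not flagged as imputed in the
#' dataset's provenance matrix. Safe to apply after [locf_impute()]:
#' carried-forward cells do not count as observed.
#'
#' @param dataset a [trial_dataset()].
#' @param outcome one of `"mcs"`, `"pcs"`, `"eq5d"`.
#' @return The filtered [trial_dataset()].
#' @export
per_protocol_filter <- function(dataset, outcome = "mcs") {
  validate_trial_dataset(dataset)
  cols <- outcome_visit_cols(outcome)
  imp <- attr(dataset, "imputed")
  keep <- !is.na(dataset[[cols[1]]]) & !is.na(dataset[[cols[3]]]) &
    !imp[, cols[1]] & !imp[, cols[3]]
  rebuild_dataset(as.data.frame(dataset)[keep, , drop = FALSE], dataset,
                  imputed = imp[keep, , drop = FALSE])
}
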