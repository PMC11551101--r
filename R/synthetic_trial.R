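# Synthetic two-arm trial generator.
#
# The generator emulates the statistical structure of a six-month digital
# physical-activity trial in chronic kidney disease: ~340 participants
# allocated 1:1 (173/167), a mental component summary (MCS) outcome that is
# approximately Normal with SD ~10.5 and baseline--follow-up correlation 0.7,
# EQ-5D utilities around 0.65--0.73 (SD 0.25, clipped at 1), right-skewed
# Gamma costs with a ~GBP 1850 pre-trial-window mean, and heavy differential
# dropout (~39% intervention vs ~15% control, mostly in the first week).

#' Simulation configuration for a synthetic two-arm trial
#'
#' Defaults state the structure of the emulated trial; they are a fixed
#' world, not tuning knobs. Means and effects are on the scale of the
#' measure (MCS in arbitrary units, utilities unitless, costs GBP).
#'
#' @param n_intervention,n_control arm sizes (defaults 173/167).
#' @param mcs_baseline_mean,mcs_baseline_sd baseline MCS distribution,
#'   identical in both arms by construction (46.3 is the pooled baseline of
#'   the emulated cohort; SD 10.5).
#' @param baseline_followup_correlation correlation between week-0 and
#'   week-24 MCS (and between month-0 and month-6 utility).
#' @param true_effect_mcs additive intervention-minus-control effect on
#'   week-24 MCS, in AU.
#' @param pcs_baseline_mean,pcs_baseline_sd,true_effect_pcs same structure
#'   for the physical component summary.
#' @param utility_baseline_mean_by_arm named numeric: baseline EQ-5D mean
#'   per arm (the emulated cohort was imbalanced: 0.65 vs 0.73).
#' @param utility_sd utility SD (0.25); draws above 1 are clipped to 1.
#' @param true_effect_utility additive intervention effect on utility,
#'   present in full from month 3 onward.
#' @param cost_mean_pretrial mean total cost over the 12-week pre-trial
#'   window, GBP.
#' @param cost_gamma_shape Gamma shape of each cost component (costs are
#'   right-skewed; shape 1.5 gives coefficient of variation ~0.8).
#' @param cost_family `"gamma"` (model-consistent default) or `"lognormal"`
#'   (same mean/variance, for misspecification experiments).
#' @param cost_arm_multiplier within-trial control-to-intervention mean cost
#'   ratio (>1 means the intervention arm uses less care; the default 1.025
#'   implies a saving of roughly GBP 100 over six months before the
#'   intervention fee).
#' @param dropout_rate_by_arm named numeric proportion per arm.
#' @param dropout_first_week_fraction fraction of dropouts who leave within
#'   the first week and so contribute no post-baseline data (the remainder
#'   lose only week-24 / month-6 / second-window data).
#' @param dropout_mechanism `"MCAR"` (default) or `"MAR"`, in which case
#'   dropout probability depends on baseline MCS through
#'   `mar_logit_slope` (per AU below the baseline mean).
#' @param mar_logit_slope log-odds of dropout per AU of baseline MCS below
#'   the mean (only used for `"MAR"`).
#' @param intervention_cost_per_year delivery cost of the intervention,
#'   GBP per participant per year (GBP 15).
#' @param seed integer seed; all generation is deterministic given it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_intervention = 173L,
                              n_control = 167L,
                              mcs_baseline_mean = 46.3,
                              mcs_baseline_sd = 10.5,
                              baseline_followup_correlation = 0.7,
                              true_effect_mcs = 5.9,
                              pcs_baseline_mean = 40.6,
                              pcs_baseline_sd = 11.4,
                              true_effect_pcs = 1.5,
                              utility_baseline_mean_by_arm =
                                c(intervention = 0.65, control = 0.73),
                              utility_sd = 0.25,
                              true_effect_utility = 0.10,
                              cost_mean_pretrial = 1850,
                              cost_gamma_shape = 1.5,
                              cost_family = c("gamma", "lognormal"),
                              cost_arm_multiplier = 1.025,
                              dropout_rate_by_arm =
                                c(intervention = 0.39, control = 0.15),
                              dropout_first_week_fraction = 0.75,
                              dropout_mechanism = c("MCAR", "MAR"),
                              mar_logit_slope = 0.05,
                              intervention_cost_per_year = 15,
                              seed = 20210506L) {
  cfg <- list(
    n_intervention = as.integer(n_intervention),
    n_control = as.integer(n_control),
    mcs_baseline_mean = mcs_baseline_mean,
    mcs_baseline_sd = mcs_baseline_sd,
    baseline_followup_correlation = baseline_followup_correlation,
    true_effect_mcs = true_effect_mcs,
    pcs_baseline_mean = pcs_baseline_mean,
    pcs_baseline_sd = pcs_baseline_sd,
    true_effect_pcs = true_effect_pcs,
    utility_baseline_mean_by_arm = utility_baseline_mean_by_arm,
    utility_sd = utility_sd,
    true_effect_utility = true_effect_utility,
    cost_mean_pretrial = cost_mean_pretrial,
    cost_gamma_shape = cost_gamma_shape,
    cost_family = match.arg(cost_family),
    cost_arm_multiplier = cost_arm_multiplier,
    dropout_rate_by_arm = dropout_rate_by_arm,
    dropout_first_week_fraction = dropout_first_week_fraction,
    dropout_mechanism = match.arg(dropout_mechanism),
    mar_logit_slope = mar_logit_slope,
    intervention_cost_per_year = intervention_cost_per_year,
    seed = seed)
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  abort_if(cfg$n_intervention < 2 || cfg$n_control < 2, "arm sizes must be >= 2")
  rho <- cfg$baseline_followup_correlation
  abort_if(!is.finite(rho) || abs(rho) >= 1, "correlation must lie in (-1, 1)")
  abort_if(cfg$mcs_baseline_sd <= 0 || cfg$pcs_baseline_sd <= 0 ||
             cfg$utility_sd <= 0, "SDs must be > 0")
  abort_if(cfg$cost_mean_pretrial <= 0, "cost_mean_pretrial must be > 0")
  abort_if(cfg$cost_gamma_shape <= 0, "cost_gamma_shape must be > 0")
  abort_if(cfg$cost_arm_multiplier <= 0, "cost_arm_multiplier must be > 0")
  abort_if(!all(ARM_LEVELS %in% names(cfg$utility_baseline_mean_by_arm)),
           "utility_baseline_mean_by_arm must name both arms")
  abort_if(!all(ARM_LEVELS %in% names(cfg$dropout_rate_by_arm)),
           "dropout_rate_by_arm must name both arms")
  abort_if(!all(vapply(cfg$dropout_rate_by_arm, is_prob, TRUE)),
           "dropout rates must lie in [0, 1]")
  abort_if(!is_prob(cfg$dropout_first_week_fraction),
           "dropout_first_week_fraction must lie in [0, 1]")
  abort_if(cfg$intervention_cost_per_year < 0,
           "intervention_cost_per_year must be >= 0")
  invisible(cfg)
}

#' Read a simulation configuration from JSON
#'
#' JSON keys mirror the arguments of [simulation_config()]; absent keys take
#' the defaults.
#'
#' @param path JSON file path.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  abort_if(!file.exists(path), "file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  abort_if(length(unknown) > 0, "unknown configuration key(s): %s",
           paste(unknown, collapse = ", "))
  do.call(simulation_config, raw)
}

# (baseline, follow-up) bivariate Gaussian with common sd and correlation rho;
# midpoint = average of the two endpoints plus just enough independent noise
# to restore the marginal SD, so corr(baseline, midpoint) = (1 + rho) / 2.
sample_longitudinal <- function(n, mean, sd, rho, effect) {
  w0 <- stats::rnorm(n, mean, sd)
  w24 <- mean + rho * (w0 - mean) +
    stats::rnorm(n, 0, sd * sqrt(1 - rho^2)) + effect
  w12 <- (w0 + w24) / 2 + stats::rnorm(n, 0, sd * sqrt((1 - rho) / 2))
  cbind(w0 = w0, w12 = w12, w24 = w24)
}

# mean of min(X, 1) for X ~ Normal(mu, sd): closed form used as the oracle
# for utility moments under clipping
clipped_normal_mean <- function(mu, sd) {
  a <- (1 - mu) / sd
  mu * stats::pnorm(a) - sd * stats::dnorm(a) + (1 - stats::pnorm(a))
}

# right-skewed positive draws with given mean; Gamma by default, lognormal
# (moment-matched) for misspecification experiments
sample_cost <- function(n, mean, shape, family) {
  if (family == "gamma") {
    stats::rgamma(n, shape = shape, rate = shape / mean)
  } else {
    sigma2 <- log(1 + 1 / shape) # matches Gamma CV^2 = 1/shape
    stats::rlnorm(n, log(mean) - sigma2 / 2, sqrt(sigma2))
  }
}

# fraction of each within-trial cost component mean, by component;
# hospital care dominates resource use in this population
COST_COMPONENT_SHARES <- c(primary_care = 0.15, medications = 0.20,
                           hospital = 0.55, social_care = 0.10)

#' Generate a complete synthetic trial (no missingness)
#'
#' Draws a fully observed dataset from the configured world: baseline
#' distributions identical across arms (utilities excepted, whose baseline
#' means are configurable per arm to emulate the observed imbalance),
#' week-24 outcomes correlated with baseline with an additive arm effect,
#' Gamma cost components per window, the intervention delivery fee in the
#' intervention arm's within-trial ledger, and adherence counters.
#' Missingness is injected separately by [apply_dropout()].
#'
#' @param config a [simulation_config()].
#' @return A [trial_dataset()] with `n_intervention + n_control` rows.
#' @export
generate_trial <- function(config) {
  validate_simulation_config(config)
  set.seed(derive_seed(config$seed, 1L))
  n_i <- config$n_intervention
  n_c <- config$n_control
  n <- n_i + n_c
  arm <- rep(ARM_LEVELS, c(n_i, n_c))
  is_int <- arm == "intervention"
  rho <- config$baseline_followup_correlation

  mcs <- sample_longitudinal(n, config$mcs_baseline_mean,
                             config$mcs_baseline_sd, rho,
                             ifelse(is_int, config$true_effect_mcs, 0))
  pcs <- sample_longitudinal(n, config$pcs_baseline_mean,
                             config$pcs_baseline_sd, rho,
                             ifelse(is_int, config$true_effect_pcs, 0))

  u_mean <- config$utility_baseline_mean_by_arm[arm]
  u_eff <- ifelse(is_int, config$true_effect_utility, 0)
  u0 <- stats::rnorm(n, u_mean, config$utility_sd)
  u6 <- u_mean + rho * (u0 - u_mean) +
    stats::rnorm(n, 0, config$utility_sd * sqrt(1 - rho^2)) + u_eff
  # effect sustained in full from month 3: the midpoint average carries
  # half the effect through u6, the other half is added explicitly
  u3 <- (u0 + u6) / 2 + u_eff / 2 +
    stats::rnorm(n, 0, config$utility_sd * sqrt((1 - rho) / 2))
  u0 <- pmin(u0, 1); u3 <- pmin(u3, 1); u6 <- pmin(u6, 1)

  # measurement precision of the instruments (scores 0.1 AU, utilities
  # 0.001, costs a penny) -- also makes CSV round-trips exact
  mcs <- round_half_up(mcs, 1)
  pcs <- round_half_up(pcs, 1)
  records <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    arm = arm, age = round_half_up(stats::rnorm(n, 53.8, 13.5), 1),
    sex = sample(c("male", "female"), n, replace = TRUE,
                 prob = c(0.54, 0.46)),
    mcs_w0 = mcs[, "w0"], mcs_w12 = mcs[, "w12"], mcs_w24 = mcs[, "w24"],
    pcs_w0 = pcs[, "w0"], pcs_w12 = pcs[, "w12"], pcs_w24 = pcs[, "w24"],
    eq5d_m0 = round_half_up(u0, 3), eq5d_m3 = round_half_up(u3, 3),
    eq5d_m6 = round_half_up(u6, 3),
    stringsAsFactors = FALSE)
  records$age <- pmax(records$age, 18)

  # cost ledger: component means share the window mean; within-trial window
  # means scale with window length; the control arm spends `multiplier`
  # times the intervention arm's mean in the trial windows
  for (w in COST_WINDOWS) {
    wk <- DEFAULT_WINDOW_WEEKS[[w]]
    base_mean <- config$cost_mean_pretrial * wk / 12
    arm_scale <- if (w == "pretrial_12wk") rep(1, n)
                 else ifelse(is_int, 1, config$cost_arm_multiplier)
    for (comp in names(COST_COMPONENT_SHARES)) {
      m <- base_mean * COST_COMPONENT_SHARES[[comp]] * arm_scale
      records[[cost_col(comp, w)]] <-
        round_half_up(sample_cost(n, m, config$cost_gamma_shape,
                                  config$cost_family), 2)
    }
    records[[cost_col("intervention", w)]] <-
      if (w == "pretrial_12wk") 0
      else ifelse(is_int, config$intervention_cost_per_year / 2, 0)
  }

  # adherence: structured sessions out of 24 (median ~15), education out of
  # 12 (median ~6), ~35 platform-minutes per structured session
  sess_s <- ifelse(is_int, round_half_up(24 * stats::rbeta(n, 1.6, 1.0)), 0)
  sess_e <- ifelse(is_int, round_half_up(12 * stats::rbeta(n, 1.0, 1.0)), 0)
  records$sessions_structured <- pmin(pmax(sess_s, 0), 24)
  records$sessions_education <- pmin(pmax(sess_e, 0), 12)
  records$minutes_structured <-
    round_half_up(records$sessions_structured *
                    stats::runif(n, 28, 42))
  records$completed_week24 <- TRUE

  trial_dataset(records, allocation_seed = config$seed)
}

#' Inject dropout into a fully observed synthetic trial
#'
#' Marks the configured per-arm fraction of participants as non-completers
#' (deterministic half-up rounding of `n * rate`, so the default 0.39/0.15
#' rates on 173/167 yield roughly 105 and 142 completers). The configured
#' fraction of dropouts leave within the first week and lose all
#' post-baseline outcomes, utilities and within-trial costs; the remainder
#' lose only the week-24 / month-6 visit and the second trial window.
#' Baseline data are never removed, so missingness is monotone within a
#' participant. Under the `"MAR"` mechanism, participants with lower
#' baseline MCS are preferentially selected.
#'
#' @param dataset a fully observed [trial_dataset()].
#' @param config the [simulation_config()] used to generate it.
#' @return The dataset with missingness and updated `completed_week24`.
#' @export
apply_dropout <- function(dataset, config) {
  validate_simulation_config(config)
  validate_trial_dataset(dataset)
  abort_if(anyNA(dataset[value_columns()]),
           "apply_dropout expects a dataset without missingness")
  set.seed(derive_seed(config$seed, 2L))
  out <- as.data.frame(dataset)
  late_cols <- c("mcs_w24", "pcs_w24", "eq5d_m6",
                 cost_col(COST_COMPONENTS, "trial_3_6mo"))
  early_cols <- c(late_cols, "mcs_w12", "pcs_w12", "eq5d_m3",
                  cost_col(COST_COMPONENTS, "trial_0_3mo"))
  for (a in ARM_LEVELS) {
    idx <- which(out$arm == a)
    n_drop <- round_half_up(length(idx) * config$dropout_rate_by_arm[[a]])
    if (n_drop == 0) next
    w <- if (config$dropout_mechanism == "MAR") {
      stats::plogis(-config$mar_logit_slope *
                      (out$mcs_w0[idx] - mean(out$mcs_w0[idx])))
    } else rep(1, length(idx))
    dropouts <- sample(idx, n_drop, prob = w)
    n_first <- round_half_up(n_drop * config$dropout_first_week_fraction)
    first_week <- dropouts[seq_len(n_first)]
    later <- setdiff(dropouts, first_week)
    out[first_week, early_cols] <- NA_real_
    out[later, late_cols] <- NA_real_
    out$completed_week24[dropouts] <- FALSE
  }
  rebuild_dataset(out, dataset)
}
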