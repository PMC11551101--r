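# Fixtures are built in code; nothing on disk.

# minimal valid records table, n alternating arms, fully observed
toy_records <- function(n = 6) {
  stopifnot(n >= 2)
  arm <- rep(c("intervention", "control"), length.out = n)
  rec <- data.frame(
    participant_id = sprintf("T%02d", seq_len(n)),
    arm = arm,
    age = 40 + ((seq_len(n) * 7) %% 23), # not collinear with the scores
    sex = rep(c("male", "female"), length.out = n),
    mcs_w0 = 44 + seq_len(n), mcs_w12 = 45 + seq_len(n),
    mcs_w24 = 46 + seq_len(n),
    pcs_w0 = 40 + seq_len(n), pcs_w12 = 40.5 + seq_len(n),
    pcs_w24 = 41 + seq_len(n),
    eq5d_m0 = 0.6, eq5d_m3 = 0.65, eq5d_m6 = 0.7,
    stringsAsFactors = FALSE)
  for (w in c("pretrial_12wk", "trial_0_3mo", "trial_3_6mo")) {
    rec[[paste0("cost_primary_care_", w)]] <- 30
    rec[[paste0("cost_medications_", w)]] <- 45.5
    rec[[paste0("cost_hospital_", w)]] <- 200
    rec[[paste0("cost_social_care_", w)]] <- 0
    rec[[paste0("cost_intervention_", w)]] <-
      ifelse(w == "pretrial_12wk" | arm == "control", 0, 7.5)
  }
  rec$completed_week24 <- TRUE
  rec$sessions_structured <- ifelse(arm == "intervention", 15, 0)
  rec$sessions_education <- ifelse(arm == "intervention", 6, 0)
  rec$minutes_structured <- ifelse(arm == "intervention", 529, 0)
  rec
}

toy_dataset <- function(n = 6) trial_dataset(toy_records(n))

# small, fast simulation world for structural tests
small_config <- function(...) {
  simulation_config(n_intervention = 60L, n_control = 60L, seed = 11L, ...)
}

quick_cea_config <- function(burn_in = 500L, kept = 1000L, chains = 2L,
                             seed = 5L, ...) {
  cea_model_config(burn_in = burn_in, kept = kept, chains = chains,
                   seed = seed, ...)
}

# synthetic participant-level data straight from the bivariate Gamma model
# (zero covariate effects), for fitting and oracle comparisons
make_gamma_cea_data <- function(n_per_arm, mean_cost = c(2000, 1900),
                                mean_eff = c(0.70, 0.67),
                                shape_cost = 2, shape_eff = 50, seed = 1) {
  set.seed(seed)
  arm <- rep(c("control", "intervention"), each = n_per_arm)
  k <- rep(1:2, each = n_per_arm)
  list(arm = arm,
       costs = rgamma(2 * n_per_arm, shape_cost,
                      rate = shape_cost / mean_cost[k]),
       qalys = 1 - rgamma(2 * n_per_arm, shape_eff,
                          rate = shape_eff / mean_eff[k]),
       baseline_cost = rgamma(2 * n_per_arm, 2, rate = 2 / 1850),
       baseline_utility = pmin(rnorm(2 * n_per_arm, 0.70, 0.25), 1))
}

# fabricate a posterior object from given draws (for summary-layer oracles)
fake_posterior <- function(delta_cost, delta_qaly,
                           config = cea_model_config(burn_in = 1L, kept = 1L)) {
  structure(list(draws = data.frame(delta_cost = delta_cost,
                                    delta_qaly = delta_qaly),
                 config = config, converged = TRUE,
                 n = length(delta_cost)),
            class = "cea_posterior")
}
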