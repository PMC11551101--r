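test_that("QALY area under the curve: closed forms and properties", {
  # constant utility u over horizon T gives exactly u * T
  expect_equal(qaly_auc(c(0, 0.25, 0.5), c(1, 1, 1), 0.5), 0.5)
  expect_equal(qaly_auc(c(0, 0.25, 0.5), c(0.7, 0.7, 0.7), 0.5), 0.35)
  # forced trapezoid arithmetic
  expect_equal(qaly_auc(c(0, 0.25, 0.5), c(0.6, 0.8, 1.0), 0.5), 0.400)
  # linearity in utilities
  u1 <- c(0.5, 0.6, 0.7); u2 <- c(0.2, -0.1, 0.1); t <- c(0, 0.25, 0.5)
  expect_equal(qaly_auc(t, u1 + 2 * u2, 0.5),
               qaly_auc(t, u1, 0.5) + 2 * qaly_auc(t, u2, 0.5))
  # invariant to inserting a collinear midpoint
  expect_equal(qaly_auc(c(0, 0.5), c(0.6, 1.0), 0.5),
               qaly_auc(c(0, 0.25, 0.5), c(0.6, 0.8, 1.0), 0.5))
  # error cases
  expect_error(qaly_auc(c(0.1, 0.5), c(1, 1), 0.5), "time 0")
  expect_error(qaly_auc(c(0, 0.5, 0.25), c(1, 1, 1), 0.5), "increasing")
  expect_error(qaly_auc(c(0, 0.25), c(1, 1), 0.5), "horizon")
  expect_error(qaly_auc(c(0, 0.5), c(1, 1.2), 0.5), "above 1")
})

test_that("mean QALY difference matches the generator's closed form", {
  cfg <- simulation_config(n_intervention = 5000L, n_control = 5000L,
                           seed = 17L)
  d <- generate_trial(cfg)
  q <- compute_qalys(d)
  # oracle: trapezoid of expected clipped-normal utilities per arm; each
  # visit's pre-clip marginal is Normal(mean + effect_t, sd)
  clip_mean <- function(mu, s) {
    a <- (1 - mu) / s
    mu * pnorm(a) - s * dnorm(a) + (1 - pnorm(a))
  }
  expected_qaly <- function(mu0, eff, s) {
    u <- c(clip_mean(mu0, s), clip_mean(mu0 + eff, s), clip_mean(mu0 + eff, s))
    0.25 * (u[1] + u[2]) / 2 + 0.25 * (u[2] + u[3]) / 2
  }
  oracle_diff <- expected_qaly(0.65, 0.10, 0.25) - expected_qaly(0.73, 0, 0.25)
  qi <- q$qaly[q$arm == "intervention"]; qc <- q$qaly[q$arm == "control"]
  emp_diff <- mean(qi) - mean(qc)
  se <- sqrt(var(qi) / length(qi) + var(qc) / length(qc))
  expect_lt(abs(emp_diff - oracle_diff), 3 * se)
})

test_that("LVCF fills missing components from the previous window, scaled", {
  d <- toy_dataset(3)
  d$cost_hospital_trial_3_6mo[1] <- NA      # carried from 0-3mo at scale 1
  d$cost_medications_trial_0_3mo[2] <- NA   # carried from pre-trial x 13/12
  out <- lvcf_costs(d)
  expect_equal(out$cost_hospital_trial_3_6mo[1], 200)
  expect_equal(out$cost_medications_trial_0_3mo[2],
               round(45.5 * 13 / 12, 2))
  imp <- attr(out, "imputed")
  expect_true(imp[1, "cost_hospital_trial_3_6mo"])
  expect_true(imp[2, "cost_medications_trial_0_3mo"])
  # complete ledger unchanged; idempotent
  expect_identical(as.data.frame(lvcf_costs(out)), as.data.frame(out))
  expect_equal(out$cost_hospital_trial_0_3mo, d$cost_hospital_trial_0_3mo)
})

test_that("LVCF chains across both windows when everything is missing", {
  d <- toy_dataset(2)
  for (comp in c("primary_care", "medications", "hospital", "social_care")) {
    d[[paste0("cost_", comp, "_trial_0_3mo")]] <- NA
    d[[paste0("cost_", comp, "_trial_3_6mo")]] <- NA
  }
  out <- lvcf_costs(d)
  # hand oracle: pre-trial 200 -> 200 * 13/12 = 216.67 in both windows
  expect_equal(out$cost_hospital_trial_0_3mo, rep(216.67, 2))
  expect_equal(out$cost_hospital_trial_3_6mo, rep(216.67, 2))
  expect_equal(out$cost_social_care_trial_3_6mo, rep(0, 2))
})

test_that("LVCF refuses a missing pre-trial window unless told to zero-fill", {
  d <- toy_dataset(2)
  d$cost_hospital_pretrial_12wk[1] <- NA
  expect_error(lvcf_costs(d), "pre-trial hospital")
  out <- lvcf_costs(d, zero_fill_pretrial = TRUE)
  expect_equal(out$cost_hospital_pretrial_12wk[1], 0)
})

test_that("cost aggregation: fee attribution and penny-exact sums", {
  d <- toy_dataset(2) # row 1 intervention, row 2 control
  for (col in grep("^cost_", names(as.data.frame(d)), value = TRUE))
    d[[col]] <- 0
  agg <- aggregate_costs(d, intervention_cost_per_year = 15,
                         attribution = "full")
  expect_equal(agg$trial_cost[agg$arm == "control"], 0)
  expect_equal(agg$trial_cost[agg$arm == "intervention"], 15)
  agg <- aggregate_costs(d, 15, attribution = "prorata")
  expect_equal(agg$trial_cost[agg$arm == "intervention"], 7.5)

  # toy ledger: (30 + 45.50 + 200 + 0) x 2 windows = 551.00 + fee
  d2 <- toy_dataset(2)
  agg <- aggregate_costs(d2, 15, attribution = "full")
  expect_equal(agg$trial_cost[agg$arm == "control"], 551.00)
  expect_equal(agg$trial_cost[agg$arm == "intervention"], 551.00 + 15)
  expect_equal(agg$baseline_cost, rep(275.50, 2))

  # component sum equals the total to the penny on messy synthetic data
  cfg <- simulation_config(n_intervention = 50L, n_control = 50L, seed = 19L)
  dd <- generate_trial(cfg)
  agg <- aggregate_costs(dd, 15, "full")
  comp <- rowSums(agg[grep("^cost_", names(agg))])
  expect_identical(round(comp * 100), round(agg$trial_cost * 100))
})

test_that("inflation is multiplicative and unknown years are rejected", {
  d <- toy_dataset(2)
  plain <- aggregate_costs(d, 0, "full")
  idx <- c("2021/2022" = 1)
  expect_equal(aggregate_costs(d, 0, "full", inflation_index = idx),
               plain) # identity index + zero fee = plain summation
  idx2 <- c("2021/2022" = 1.10)
  infl <- aggregate_costs(d, 0, "full", inflation_index = idx2)
  expect_equal(infl$trial_cost, round(1.10 * plain$trial_cost, 2),
               tolerance = 0.011) # per-component penny rounding
  expect_error(aggregate_costs(d, 0, "full",
                               inflation_index = c("1999" = 1)),
               "2021/2022")
})

test_that("utility mapping: identity, affine, and strict table coverage", {
  d <- toy_dataset(3)
  ident <- map_utilities(d, utility_mapping())
  expect_equal(as.data.frame(ident), as.data.frame(d), ignore_attr = TRUE)
  aff <- map_utilities(d, utility_mapping(slope = 0.9))
  expect_equal(aff$eq5d_m0, 0.9 * d$eq5d_m0)
  expect_equal(attr(aff, "utilities_premap")$eq5d_m0, d$eq5d_m0)
  tab <- utility_mapping(table = data.frame(from = c(0.6, 0.65),
                                            to = c(0.55, 0.60)))
  expect_error(map_utilities(d, tab), "0.7")
  tab2 <- utility_mapping(table = data.frame(from = c(0.6, 0.65, 0.7),
                                             to = c(0.55, 0.60, 0.66)))
  mapped <- map_utilities(d, tab2)
  expect_equal(mapped$eq5d_m6, rep(0.66, 3))
})
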