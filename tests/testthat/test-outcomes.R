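test_that("LOCF carries the most recent observed value forward", {
  d <- toy_dataset(4)
  d$mcs_w0[1] <- 50; d$mcs_w12[1] <- 55; d$mcs_w24[1] <- NA
  d$mcs_w0[2] <- 44.6; d$mcs_w12[2] <- NA; d$mcs_w24[2] <- NA
  out <- locf_impute(d, "mcs")
  expect_equal(out$mcs_w24[1], 55)         # week 12, not baseline
  expect_equal(out$mcs_w12[2], 44.6)
  expect_equal(out$mcs_w24[2], 44.6)
  expect_equal(out$mcs_w24[3:4], d$mcs_w24[3:4])  # observed untouched
  imp <- attr(out, "imputed")
  expect_true(imp[1, "mcs_w24"] && imp[2, "mcs_w12"] && imp[2, "mcs_w24"])
  expect_false(any(imp[3:4, ]))
  # idempotent
  expect_identical(as.data.frame(locf_impute(out, "mcs")),
                   as.data.frame(out))
})

test_that("LOCF drops records with no baseline, with a warning", {
  d <- toy_dataset(4)
  d$mcs_w0[2] <- NA
  expect_warning(out <- locf_impute(d, "mcs"), "T02")
  expect_equal(nrow(out), 3)
})

test_that("ANCOVA is exact on degenerate no-change data", {
  d <- toy_dataset(10)
  d$mcs_w24 <- d$mcs_w0
  d$age <- 50
  # lm warns about the (intentionally) perfect fit
  est <- suppressWarnings(ancova_fit(d, "mcs"))
  expect_equal(est$effect, 0, tolerance = 1e-12)
})

test_that("ANCOVA equals the normal-equations oracle", {
  # 6-record toy: solve X'X b = X'y by generic linear solve
  d <- toy_dataset(6)
  set.seed(1)
  d$mcs_w24 <- d$mcs_w0 + rnorm(6, 2)
  est <- ancova_fit(d, "mcs")
  X <- cbind(1, d$arm == "intervention", d$mcs_w0, d$age)
  b <- solve(t(X) %*% X, t(X) %*% d$mcs_w24)
  expect_equal(est$effect, b[2, 1], tolerance = 1e-10)
  # property: holds on random datasets of varying size
  for (s in 1:5) {
    cfg <- simulation_config(n_intervention = 30L + 5L * s,
                             n_control = 40L, seed = 100L + s)
    dd <- generate_trial(cfg)
    est <- ancova_fit(dd, "mcs")
    X <- cbind(1, dd$arm == "intervention", dd$mcs_w0, dd$age)
    b <- solve(t(X) %*% X, t(X) %*% dd$mcs_w24)
    expect_equal(est$effect, b[2, 1], tolerance = 1e-8)
    expect_true(est$ci_low <= est$effect && est$effect <= est$ci_high)
  }
})

test_that("ANCOVA type-I error is calibrated under the null", {
  reps <- 1000
  alpha <- 0.05
  rej <- 0
  set.seed(42)
  for (r in seq_len(reps)) {
    n <- 30
    arm <- rep(c("intervention", "control"), each = n)
    b <- rnorm(2 * n, 46, 10)
    y <- 46 + 0.7 * (b - 46) + rnorm(2 * n, 0, 10 * sqrt(1 - 0.49))
    fit <- lm(y ~ arm + b + rep(50:59, 6))
    p <- summary(fit)$coefficients["armintervention", "Pr(>|t|)"]
    rej <- rej + (p < alpha)
  }
  half <- qnorm(0.995) * sqrt(alpha * (1 - alpha) / reps)
  expect_lt(abs(rej / reps - alpha), half + 1e-12)
})

test_that("ANCOVA recovers the configured effect on a large trial", {
  cfg <- simulation_config(n_intervention = 2000L, n_control = 2000L,
                           seed = 21L)
  d <- generate_trial(cfg)
  est <- ancova_fit(d, "mcs")
  expect_lt(abs(est$effect - 5.9), 3 * est$se)
})

test_that("ANCOVA errors on degenerate designs", {
  d <- toy_dataset(4)
  expect_error(ancova_fit(d[d$arm == "control", ], "mcs"))
  expect_error(ancova_fit(toy_dataset(4), "bogus"), "unknown outcome")
})

test_that("multiple imputation leaves observed cells invariant", {
  cfg <- simulation_config(seed = 31L)
  d <- apply_dropout(generate_trial(cfg), cfg)
  sets <- mi_impute(d, "mcs", m = 5, seed = 7)
  expect_length(sets, 5)
  obs <- !is.na(d$mcs_w24)
  for (s in sets) {
    expect_false(anyNA(s$mcs_w24))
    expect_equal(s$mcs_w24[obs], d$mcs_w24[obs])
    expect_true(all(attr(s, "imputed")[!obs, "mcs_w24"]))
  }
  # differs across imputations only in originally-missing cells
  expect_false(identical(sets[[1]]$mcs_w24[!obs], sets[[2]]$mcs_w24[!obs]))
  # deterministic given seed
  sets2 <- mi_impute(d, "mcs", m = 5, seed = 7)
  expect_identical(as.data.frame(sets[[3]]), as.data.frame(sets2[[3]]))
})

test_that("multiple imputation with nothing to impute returns copies", {
  d <- toy_dataset(8)
  sets <- mi_impute(d, "mcs", m = 3, seed = 1)
  for (s in sets) expect_identical(as.data.frame(s), as.data.frame(d))
})

test_that("multiple imputation fails when an arm has no follow-up", {
  d <- toy_dataset(8)
  d$mcs_w24[d$arm == "intervention"] <- NA
  expect_error(mi_impute(d, "mcs", m = 2, seed = 1), "unidentifiable")
})

test_that("pooled MI recovers the effect under MAR dropout", {
  cfg <- simulation_config(n_intervention = 2000L, n_control = 2000L,
                           dropout_mechanism = "MAR", mar_logit_slope = 0.1,
                           seed = 23L)
  d <- apply_dropout(generate_trial(cfg), cfg)
  sets <- mi_impute(d, "mcs", m = 20, seed = 3)
  pooled <- rubin_pool(lapply(sets, ancova_fit, outcome = "mcs",
                              population = "ITT_MI"))
  expect_lt(abs(pooled$effect - 5.9), 3 * sqrt(pooled$total_var))
})

test_that("Rubin pooling follows the combining rules exactly", {
  mk <- function(effect, se) structure(
    list(effect = effect, se = se, ci_low = effect - 2 * se,
         ci_high = effect + 2 * se, p_value = 0.05, n_used = 100L,
         df = 96, population = "ITT_MI", outcome = "mcs",
         followup_visit = "w24", covariates = c("baseline", "age")),
    class = "ancova_estimate")

  # zero between-imputation variance
  p <- rubin_pool(replicate(5, mk(5.8, 0.5), simplify = FALSE))
  expect_equal(p$effect, 5.8)
  expect_equal(p$between_var, 0)
  expect_equal(sqrt(p$total_var), 0.5)

  # hand-computed case: effects {5,6,7}, variances {1,1,1}
  p <- rubin_pool(list(mk(5, 1), mk(6, 1), mk(7, 1)))
  expect_equal(p$effect, 6)
  expect_equal(p$within_var, 1)
  expect_equal(p$between_var, 1)
  expect_equal(p$total_var, 1 + (1 + 1 / 3) * 1)

  # m = 1 degeneracy
  p <- rubin_pool(list(mk(4.2, 0.7)))
  expect_equal(p$effect, 4.2)
  expect_equal(p$between_var, 0)
  expect_equal(p$total_var, 0.49)

  # invariant T = W + (1 + 1/m) B on random inputs
  set.seed(2)
  for (r in 1:10) {
    m <- sample(2:8, 1)
    ests <- lapply(seq_len(m), function(i) mk(rnorm(1, 5), runif(1, .3, 1)))
    p <- rubin_pool(ests)
    expect_equal(p$total_var,
                 p$within_var + (1 + 1 / p$m) * p$between_var)
    expect_true(p$ci_low <= p$effect && p$effect <= p$ci_high)
  }

  expect_error(rubin_pool(list()), "at least one")
  expect_error(rubin_pool(list(mk(5, 1),
                               modifyList(mk(5, 1), list(outcome = "pcs")))),
               "different model")
})

test_that("per-protocol keeps only observed baseline + week-24 records", {
  d <- toy_dataset(15)
  d$mcs_w24[1:5] <- NA
  expect_equal(nrow(per_protocol_filter(d, "mcs")), 10)
  # after LOCF, imputed week-24 cells still do not count as observed
  locf <- locf_impute(d, "mcs")
  expect_equal(nrow(per_protocol_filter(locf, "mcs")), 10)
  # per-arm retention on the default synthetic world
  cfg <- simulation_config(seed = 41L)
  dd <- apply_dropout(generate_trial(cfg), cfg)
  pp <- per_protocol_filter(dd, "mcs")
  expect_lt(abs(sum(pp$arm == "intervention") / 173 - 0.61), 0.02)
  expect_lt(abs(sum(pp$arm == "control") / 167 - 0.85), 0.02)
})

test_that("LOCF is conservative when the control arm declines", {
  # world in which controls decline between week 12 and week 24; losing
  # week-24 data and carrying week 12 forward then understates the
  # between-group effect relative to the complete-data analysis
  set.seed(77)
  n <- 400
  arm <- rep(c("intervention", "control"), each = n)
  w0 <- rnorm(2 * n, 46, 10)
  w12 <- w0 + rnorm(2 * n, 0, 5)
  w24 <- w12 + ifelse(arm == "control", -4, 0) + rnorm(2 * n, 0, 5)
  rec <- toy_records(2 * n)
  rec$arm <- arm
  rec$mcs_w0 <- w0; rec$mcs_w12 <- w12; rec$mcs_w24 <- w24
  full <- trial_dataset(rec)
  est_full <- ancova_fit(full, "mcs")
  rec$mcs_w24[sample(2 * n, n)] <- NA  # MCAR week-24 loss
  est_locf <- ancova_fit(locf_impute(trial_dataset(rec), "mcs"), "mcs")
  expect_lt(est_locf$effect, est_full$effect)
  expect_gt(est_locf$effect, 0)
})
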