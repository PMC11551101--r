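test_that("sufficient-statistic Gamma log-likelihood matches dgamma", {
  set.seed(3)
  for (r in 1:5) {
    x <- rgamma(200, 2, rate = 1 / 900)
    mu <- runif(200, 1000, 3000)
    s <- runif(1, 0.5, 60)
    oracle <- sum(dgamma(x, shape = s, rate = s / mu, log = TRUE))
    expect_equal(beamcea:::gamma_ll_suff(s, length(x), sum(log(x)),
                                         sum(log(mu)), sum(x / mu)),
                 oracle, tolerance = 1e-10)
  }
})

test_that("ICER arithmetic and dominance labelling", {
  expect_equal(icer(-93.03, 0.027)$value, 93.03 / 0.027)
  expect_true(icer(-93.03, 0.027)$dominant)
  expect_equal(icer(273.60, 0.026)$value, 273.60 / 0.026)
  expect_false(icer(273.60, 0.026)$dominant)
  expect_equal(icer(0, 0.01)$value, 0)
  expect_error(icer(100, 0), "zero")
})

test_that("CEAC definition, monotonicity and limits", {
  # degenerate dominant draws: probability 1 at every threshold
  p <- fake_posterior(delta_cost = rep(-50, 500), delta_qaly = rep(0.01, 500))
  cc <- ceac(p, c(0, 10000, 20000, 30000))
  expect_equal(cc$probability_cost_effective, rep(1, 4))
  # lambda = 0: fraction of cost-saving draws
  set.seed(8)
  dc <- rnorm(5000, 20, 100); dq <- abs(rnorm(5000, 0.02, 0.01))
  p <- fake_posterior(dc, dq)
  expect_equal(ceac(p, c(0, 20000, 30000))$probability_cost_effective[1],
               mean(dc < 0))
  # nondecreasing in lambda when all delta_qaly >= 0, limit P(dq > 0)
  grid <- seq(0, 1e6, length.out = 40)
  probs <- ceac(p, grid)$probability_cost_effective
  expect_true(all(diff(probs) >= 0))
  expect_equal(probs[40], mean(dq > 0), tolerance = 0.01)
})

test_that("CEAC and net benefit agree with the closed-form Gaussian oracle", {
  set.seed(12)
  n <- 2e5
  dq <- rnorm(n, 0.027, 0.0069)
  dc <- rnorm(n, -93, 248)
  p <- fake_posterior(dc, dq)
  lambda <- 20000
  oracle <- pnorm((lambda * 0.027 + 93) /
                    sqrt((lambda * 0.0069)^2 + 248^2))
  got <- ceac(p, c(lambda, 30000))$probability_cost_effective[1]
  expect_lt(abs(got - oracle), 3 * sqrt(oracle * (1 - oracle) / n) + 0.002)
  nb <- net_benefit(p, lambda)
  expect_equal(nb$mean, lambda * 0.027 + 93, tolerance = 0.02)
  expect_equal(nb$sd, sqrt((lambda * 0.0069)^2 + 248^2), tolerance = 0.02)
  # lambda = 0: mean net benefit is the mean cost saving
  expect_equal(net_benefit(p, 0)$mean, mean(-dc))
  # zero-effect draws: net benefit is minus the incremental cost
  p0 <- fake_posterior(dc, rep(0, n))
  expect_equal(net_benefit(p0, 50000)$mean, mean(-dc))
})

test_that("cost-effectiveness plane geometry", {
  # constant draws degenerate to a point in one quadrant
  p <- fake_posterior(rep(-100, 200), rep(0.02, 200))
  pl <- ce_plane(p)
  expect_equal(unname(pl$center), c(0.02, -100))
  expect_equal(max(abs(pl$ellipse[, "delta_qaly"] - 0.02)), 0)
  expect_equal(unname(pl$quadrants["se"]), 1)
  # isotropic Gaussian cloud: near-equal axes, ~95% inside
  set.seed(5)
  dq <- rnorm(20000); dc <- rnorm(20000)
  p <- fake_posterior(dc, dq)
  pl <- ce_plane(p)
  ev <- eigen(pl$covariance)$values
  expect_equal(ev[1] / ev[2], 1, tolerance = 0.05)
  ctr <- sweep(cbind(dq, dc), 2, pl$center)
  md <- rowSums((ctr %*% solve(pl$covariance)) * ctr)
  expect_equal(mean(md <= qchisq(0.95, 2)), 0.95, tolerance = 0.01)
  expect_error(ce_plane(fake_posterior(1:10, 1:10)), "100 draws")
})

test_that("the fit is reproducible and validates its inputs", {
  dat <- make_gamma_cea_data(60, seed = 2)
  cfg <- quick_cea_config(burn_in = 100L, kept = 150L, chains = 1L)
  f1 <- suppressWarnings(fit_cea(dat$costs, dat$qalys, dat$arm,
                                 dat$baseline_cost, dat$baseline_utility, cfg))
  f2 <- suppressWarnings(fit_cea(dat$costs, dat$qalys, dat$arm,
                                 dat$baseline_cost, dat$baseline_utility, cfg))
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws), 150)

  expect_error(fit_cea(dat$costs, rep(1.2, length(dat$qalys)), dat$arm,
                       dat$baseline_cost, dat$baseline_utility, cfg),
               "horizon")
  expect_error(fit_cea(dat$costs, dat$qalys, rep("intervention",
                                                 length(dat$arm)),
                       dat$baseline_cost, dat$baseline_utility, cfg),
               "both arms")
  expect_error(fit_cea(-dat$costs, dat$qalys, dat$arm,
                       dat$baseline_cost, dat$baseline_utility, cfg),
               "negative")
  zc <- dat$costs; zc[1] <- 0
  expect_message(suppressWarnings(
    fit_cea(zc, dat$qalys, dat$arm, dat$baseline_cost,
            dat$baseline_utility, cfg)), "0.01")
})

test_that("posterior means approach sample-mean differences in the normal limit", {
  # large Gamma shapes, zero covariate effects: the model's arm means should
  # agree with the frequentist arm means within Monte-Carlo error
  for (s in 1:3) {
    dat <- make_gamma_cea_data(400, mean_cost = c(2000, 1950),
                               mean_eff = c(0.70, 0.68),
                               shape_cost = 500, shape_eff = 500,
                               seed = 30 + s)
    post <- fit_cea(dat$costs, dat$qalys, dat$arm, dat$baseline_cost,
                    dat$baseline_utility,
                    quick_cea_config(burn_in = 400L, kept = 800L, seed = s))
    iv <- dat$arm == "intervention"
    freq_dc <- mean(dat$costs[iv]) - mean(dat$costs[!iv])
    freq_dq <- mean(dat$qalys[iv]) - mean(dat$qalys[!iv])
    expect_lt(abs(mean(post$draws$delta_cost) - freq_dc),
              3 * sd(post$draws$delta_cost))
    expect_lt(abs(mean(post$draws$delta_qaly) - freq_dq),
              3 * sd(post$draws$delta_qaly))
  }
})

test_that("Bayesian CEAC agrees with a nonparametric bootstrap oracle", {
  dat <- make_gamma_cea_data(500, seed = 44)
  post <- fit_cea(dat$costs, dat$qalys, dat$arm, dat$baseline_cost,
                  dat$baseline_utility,
                  quick_cea_config(burn_in = 600L, kept = 1200L, seed = 9L))
  grid <- c(0, 5000, 10000, 20000, 30000, 50000)
  bayes <- ceac(post, grid)$probability_cost_effective
  # oracle: resample participants within arm, recompute mean increments
  set.seed(99)
  iv <- which(dat$arm == "intervention"); cv <- which(dat$arm == "control")
  boot <- replicate(2000, {
    i <- sample(iv, replace = TRUE); c <- sample(cv, replace = TRUE)
    c(mean(dat$costs[i]) - mean(dat$costs[c]),
      mean(dat$qalys[i]) - mean(dat$qalys[c]))
  })
  boot_ceac <- vapply(grid, function(l) mean(l * boot[2, ] - boot[1, ] > 0), 0)
  expect_lt(max(abs(bayes - boot_ceac)), 0.05)
})

test_that("summaries are internally consistent", {
  dat <- make_gamma_cea_data(150, seed = 7)
  post <- suppressWarnings(
    fit_cea(dat$costs, dat$qalys, dat$arm, dat$baseline_cost,
            dat$baseline_utility,
            quick_cea_config(burn_in = 300L, kept = 400L)))
  summ <- cea_summary(post)
  # ICER consistency with the posterior-mean increments, exactly
  expect_identical(summ$icer$value,
                   icer(mean(post$draws$delta_cost),
                        mean(post$draws$delta_qaly))$value)
  expect_equal(summ$mean_cost_saving, -mean(post$draws$delta_cost))
  expect_equal(unname(summ$p_ce_at["20000"]),
               ceac(post, c(20000, 30000))$probability_cost_effective[1])
  expect_true(all(summ$p_ce_at >= 0 & summ$p_ce_at <= 1))
})

test_that("model configuration is validated", {
  expect_error(cea_model_config(wtp_grid = c(0, 30000)), "20000")
  expect_error(cea_model_config(wtp_grid = c(30000, 20000)), "ascending")
  expect_error(cea_model_config(burn_in = 0), "positive")
})
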