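# Bayesian bivariate cost-effectiveness model.
#
# Costs c_i and transformed effects e_i = 1 - QALY_i are both given Gamma
# likelihoods parameterized by (shape, mean). For participant i in arm k,
#
#   c_i ~ Gamma(s_c, mean mu_i),  mu_i = mu_k + g1 (c0_i - C) + g2 (u0_i - U)
#   e_i ~ Gamma(s_e, mean nu_i),  nu_i = nu_k + d1 (c0_i - C) + d2 (u0_i - U)
#                                        + beta (c_i - mu_i)
#
# where c0/u0 are baseline cost and baseline utility and (C, U) are the
# centering values at which arm means are reported (GBP 1850, 0.70 by
# default). The marginals are linked through the conditional mean of the
# effect given the cost residual (effect-conditional-on-cost), so the
# dependence coefficient beta captures within-person cost-effect
# correlation. Incremental cost is mu_intervention - mu_control; because
# larger e means fewer QALYs, incremental QALYs are nu_control -
# nu_intervention. Priors are vague: Normal(0, sd 1e5) on mean-scale
# coefficients (with rejection whenever any participant-level mean would
# be nonpositive) and Exponential(0.001) on both shapes. Sampling is
# Metropolis-within-Gibbs with per-parameter Gaussian random walks whose
# scales adapt during burn-in only and are frozen afterwards, preserving
# detailed balance for the kept draws.

#' Configuration of the cost-effectiveness model and sampler
#'
#' @param burn_in iterations discarded per chain (default 20000).
#' @param kept iterations kept per chain (default 20000).
#' @param chains number of independent chains (default 2).
#' @param seed integer; chain c uses a stream derived from `(seed, c)`.
#' @param centering_baseline_cost,centering_baseline_utility values at
#'   which the arm-level means are reported (defaults GBP 1850 and 0.70,
#'   the average baseline cost and EQ-5D of the emulated cohort).
#' @param wtp_grid willingness-to-pay grid, GBP/QALY, ascending and
#'   nonnegative; must include 20000 and 30000.
#' @param coef_prior_sd prior SD of the Normal(0, .) priors on mean-scale
#'   coefficients.
#' @param shape_prior_rate rate of the Exponential prior on Gamma shapes.
#' @param rhat_threshold split-chain convergence threshold (default 1.05);
#'   above it the fit is flagged, never silently returned.
#' @return A list of class `cea_model_config`.
#' @export
cea_model_config <- function(burn_in = 20000L, kept = 20000L, chains = 2L,
                             seed = 1L,
                             centering_baseline_cost = 1850,
                             centering_baseline_utility = 0.70,
                             wtp_grid = c(0, 5000, 10000, 15000, 20000,
                                          25000, 30000, 40000, 50000),
                             coef_prior_sd = 1e5,
                             shape_prior_rate = 0.001,
                             rhat_threshold = 1.05) {
  abort_if(!is_count(burn_in, 1) || !is_count(kept, 1),
           "burn_in and kept must be positive integers")
  abort_if(!is_count(chains, 1), "chains must be a positive integer")
  abort_if(any(wtp_grid < 0) || is.unsorted(wtp_grid, strictly = TRUE),
           "wtp_grid must be nonnegative and ascending")
  abort_if(!all(c(20000, 30000) %in% wtp_grid),
           "wtp_grid must include 20000 and 30000")
  structure(list(burn_in = as.integer(burn_in), kept = as.integer(kept),
                 chains = as.integer(chains), seed = seed,
                 centering_baseline_cost = centering_baseline_cost,
                 centering_baseline_utility = centering_baseline_utility,
                 wtp_grid = wtp_grid,
                 coef_prior_sd = coef_prior_sd,
                 shape_prior_rate = shape_prior_rate,
                 rhat_threshold = rhat_threshold),
            class = "cea_model_config")
}

# sum log Gamma density in (shape, mean) parameterization; -Inf if any
# mean is nonpositive (outside the support of the model)
gamma_loglik <- function(x, shape, mean) {
  if (any(mean <= 0)) return(-Inf)
  sum(stats::dgamma(x, shape = shape, rate = shape / mean, log = TRUE))
}

# split-chain potential scale reduction factor (each chain halved)
split_rhat <- function(draws) { # iterations x chains
  n2 <- floor(nrow(draws) / 2)
  halves <- cbind(draws[seq_len(n2), , drop = FALSE],
                  draws[n2 + seq_len(n2), , drop = FALSE])
  m <- ncol(halves); n <- nrow(halves)
  mu <- colMeans(halves)
  b <- n * stats::var(mu)
  w <- mean(apply(halves, 2, stats::var))
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

# effective sample size from pooled-chain autocorrelations (Geyer initial
# positive sequence, simplified: truncate at first nonpositive)
ess_basic <- function(draws) {
  v <- as.vector(draws)
  n <- length(v)
  if (stats::var(v) == 0) return(n)
  ac <- stats::acf(v, lag.max = min(200, n - 1), plot = FALSE)$acf[-1]
  cut <- which(ac <= 0)[1]
  if (!is.na(cut)) ac <- ac[seq_len(cut - 1)]
  n / (1 + 2 * sum(ac))
}

# Gamma log-likelihood in (shape, mean) form from sufficient statistics:
#   sum log f(x) = n s log s - s sum(log mu) - n lgamma(s)
#                  + (s - 1) sum(log x) - s sum(x / mu)
# sum(log x) is fixed per fit, so each Metropolis update only needs the two
# mu-dependent reductions; this matches dgamma() exactly (tested) but is an
# order of magnitude faster inside the chain.
gamma_ll_suff <- function(s, n, sumlogx, sum_log_mu, sum_x_over_mu) {
  n * s * log(s) - s * sum_log_mu - n * lgamma(s) +
    (s - 1) * sumlogx - s * sum_x_over_mu
}

# one Metropolis-within-Gibbs chain; returns kept draws + acceptance rates
run_cea_chain <- function(cost, eff, arm_idx, xc, xu, cfg, chain_id) {
  set.seed(derive_seed(cfg$seed, 1000L + chain_id))
  n <- length(cost)
  sdp <- cfg$coef_prior_sd
  lprior_coef <- function(v) stats::dnorm(v, 0, sdp, log = TRUE)
  lprior_shape <- function(s) stats::dexp(s, cfg$shape_prior_rate, log = TRUE) +
    log(s) # Jacobian of the log-scale random walk
  sumlog_c <- sum(log(cost))
  sumlog_e <- sum(log(eff))

  # method-of-moments initialization
  mu_k <- vapply(1:2, function(k) mean(cost[arm_idx == k]), 0)
  nu_k <- vapply(1:2, function(k) mean(eff[arm_idx == k]), 0)
  s_c <- max(mean(cost)^2 / stats::var(cost), 0.1)
  s_e <- max(mean(eff)^2 / stats::var(eff), 0.1)
  g <- c(0, 0); d <- c(0, 0); beta <- 0

  mu <- mu_k[arm_idx] + g[1] * xc + g[2] * xu
  nu <- nu_k[arm_idx] + d[1] * xc + d[2] * xu + beta * (cost - mu)
  abort_if(any(mu <= 0) || any(nu <= 0),
           "initial participant-level means nonpositive; data inconsistent with the Gamma model")
  slm_c <- sum(log(mu)); sxm_c <- sum(cost / mu)
  slm_e <- sum(log(nu)); sxm_e <- sum(eff / nu)
  ll_c <- gamma_ll_suff(s_c, n, sumlog_c, slm_c, sxm_c)
  ll_e <- gamma_ll_suff(s_e, n, sumlog_e, slm_e, sxm_e)

  # parameter table: name, initial proposal scale
  scales <- c(mu1 = mu_k[1] / 20, mu2 = mu_k[2] / 20,
              g1 = 0.05, g2 = mu_k[1] / 10,
              lsc = 0.2,
              nu1 = nu_k[1] / 20, nu2 = nu_k[2] / 20,
              d1 = 1e-5, d2 = 0.2, beta = 1e-5,
              lse = 0.2)
  acc <- scales * 0
  tries <- acc
  total_iter <- cfg$burn_in + cfg$kept
  keep <- matrix(NA_real_, cfg$kept, 11,
                 dimnames = list(NULL, names(scales)))

  for (it in seq_len(total_iter)) {
    adapting <- it <= cfg$burn_in
    for (p in names(scales)) {
      step <- stats::rnorm(1, 0, scales[[p]])
      tries[[p]] <- tries[[p]] + 1
      if (p %in% c("mu1", "mu2", "g1", "g2")) {
        mu_k2 <- mu_k; g2_ <- g
        if (p == "mu1") mu_k2[1] <- mu_k[1] + step
        if (p == "mu2") mu_k2[2] <- mu_k[2] + step
        if (p == "g1") g2_[1] <- g[1] + step
        if (p == "g2") g2_[2] <- g[2] + step
        mu_new <- mu_k2[arm_idx] + g2_[1] * xc + g2_[2] * xu
        nu_new <- nu - beta * (mu_new - mu) # cost residual shifts
        if (all(mu_new > 0) && all(nu_new > 0)) {
          slm_c2 <- sum(log(mu_new)); sxm_c2 <- sum(cost / mu_new)
          slm_e2 <- sum(log(nu_new)); sxm_e2 <- sum(eff / nu_new)
          ll_c_new <- gamma_ll_suff(s_c, n, sumlog_c, slm_c2, sxm_c2)
          ll_e_new <- gamma_ll_suff(s_e, n, sumlog_e, slm_e2, sxm_e2)
          old_par <- switch(p, mu1 = mu_k[1], mu2 = mu_k[2],
                            g1 = g[1], g2 = g[2])
          lr <- ll_c_new + ll_e_new - ll_c - ll_e +
            lprior_coef(old_par + step) - lprior_coef(old_par)
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            mu_k <- mu_k2; g <- g2_; mu <- mu_new; nu <- nu_new
            slm_c <- slm_c2; sxm_c <- sxm_c2
            slm_e <- slm_e2; sxm_e <- sxm_e2
            ll_c <- ll_c_new; ll_e <- ll_e_new
            acc[[p]] <- acc[[p]] + 1
          }
        }
      } else if (p == "lsc") {
        s_new <- exp(log(s_c) + step)
        ll_c_new <- gamma_ll_suff(s_new, n, sumlog_c, slm_c, sxm_c)
        lr <- ll_c_new - ll_c + lprior_shape(s_new) - lprior_shape(s_c)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          s_c <- s_new; ll_c <- ll_c_new; acc[[p]] <- acc[[p]] + 1
        }
      } else if (p == "lse") {
        s_new <- exp(log(s_e) + step)
        ll_e_new <- gamma_ll_suff(s_new, n, sumlog_e, slm_e, sxm_e)
        lr <- ll_e_new - ll_e + lprior_shape(s_new) - lprior_shape(s_e)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          s_e <- s_new; ll_e <- ll_e_new; acc[[p]] <- acc[[p]] + 1
        }
      } else { # effect-side mean parameters
        nu_k2 <- nu_k; d2_ <- d; beta2 <- beta
        if (p == "nu1") nu_k2[1] <- nu_k[1] + step
        if (p == "nu2") nu_k2[2] <- nu_k[2] + step
        if (p == "d1") d2_[1] <- d[1] + step
        if (p == "d2") d2_[2] <- d[2] + step
        if (p == "beta") beta2 <- beta + step
        nu_new <- nu_k2[arm_idx] + d2_[1] * xc + d2_[2] * xu +
          beta2 * (cost - mu)
        if (all(nu_new > 0)) {
          slm_e2 <- sum(log(nu_new)); sxm_e2 <- sum(eff / nu_new)
          ll_e_new <- gamma_ll_suff(s_e, n, sumlog_e, slm_e2, sxm_e2)
          old_par <- switch(p, nu1 = nu_k[1], nu2 = nu_k[2],
                            d1 = d[1], d2 = d[2], beta = beta)
          lr <- ll_e_new - ll_e +
            lprior_coef(old_par + step) - lprior_coef(old_par)
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            nu_k <- nu_k2; d <- d2_; beta <- beta2; nu <- nu_new
            slm_e <- slm_e2; sxm_e <- sxm_e2
            ll_e <- ll_e_new; acc[[p]] <- acc[[p]] + 1
          }
        }
      }
    }
    if (adapting && it %% 50 == 0) {
      rate <- acc / pmax(tries, 1)
      scales <- scales * exp(0.6 * (rate - 0.44))
      acc[] <- 0; tries[] <- 0
    }
    if (!adapting) {
      keep[it - cfg$burn_in, ] <- c(mu_k, g, s_c, nu_k, d, beta, s_e)
    }
  }
  list(draws = keep, accept = acc / pmax(tries, 1))
}

#' Fit the bivariate Gamma cost-effectiveness model
#'
#' @param costs per-participant total within-trial cost, GBP (> 0; exact
#'   zeros are offset by one penny, with a message).
#' @param qalys per-participant QALYs over the horizon (< 1, so that the
#'   transformed effect 1 - QALY is positive).
#' @param arm character vector of `"intervention"` / `"control"`.
#' @param baseline_cost,baseline_utility per-participant pre-trial window
#'   cost and baseline EQ-5D utility (complete; LVCF upstream).
#' @param config a [cea_model_config()].
#' @return An object of class `cea_posterior`: a data.frame of kept draws
#'   across chains (arm-level cost and effect means at the centering
#'   values, shapes, covariate and dependence coefficients, and the
#'   per-draw `delta_cost` = intervention - control and `delta_qaly` =
#'   gain in QALYs), plus split-chain convergence statistics, effective
#'   sample sizes and a `converged` flag.
#' @export
fit_cea <- function(costs, qalys, arm, baseline_cost, baseline_utility,
                    config = cea_model_config()) {
  stopifnot(inherits(config, "cea_model_config"))
  n <- length(costs)
  abort_if(length(qalys) != n || length(arm) != n ||
             length(baseline_cost) != n || length(baseline_utility) != n,
           "inputs must have one entry per participant")
  abort_if(anyNA(costs) || anyNA(qalys) || anyNA(baseline_cost) ||
             anyNA(baseline_utility),
           "missing values: complete costs/QALYs/covariates upstream")
  abort_if(!all(arm %in% ARM_LEVELS), "unknown arm label")
  abort_if(!all(ARM_LEVELS %in% arm), "both arms must be present")
  abort_if(any(costs < 0), "negative cost")
  n_zero <- sum(costs == 0)
  if (n_zero > 0) {
    message(sprintf("%d zero cost(s) offset by GBP 0.01", n_zero))
    costs[costs == 0] <- 0.01
  }
  eff <- 1 - qalys
  abort_if(any(eff <= 0),
           "QALYs >= 1 leave no room for the Gamma-transformed effect; check the horizon")
  arm_idx <- ifelse(arm == "intervention", 1L, 2L)
  xc <- baseline_cost - config$centering_baseline_cost
  xu <- baseline_utility - config$centering_baseline_utility

  chains <- lapply(seq_len(config$chains), function(ch)
    run_cea_chain(costs, eff, arm_idx, xc, xu, config, ch))
  draws <- do.call(rbind, lapply(seq_along(chains), function(ch) {
    k <- as.data.frame(chains[[ch]]$draws)
    k$chain <- ch
    k
  }))
  draws$delta_cost <- draws$mu1 - draws$mu2
  draws$delta_qaly <- draws$nu2 - draws$nu1

  diag <- do.call(rbind, lapply(c("delta_cost", "delta_qaly", "lsc", "lse"),
    function(q) {
      m <- matrix(draws[[q]], ncol = config$chains)
      data.frame(quantity = q, rhat = split_rhat(m), ess = ess_basic(m))
    }))
  converged <- all(diag$rhat < config$rhat_threshold)
  if (!converged)
    warning(sprintf(
      "chains may not have converged (max split R-hat %.3f >= %.2f); result flagged",
      max(diag$rhat), config$rhat_threshold))

  structure(list(draws = draws, diagnostics = diag, converged = converged,
                 config = config, n = n, n_zero_offset = n_zero,
                 accept = lapply(chains, `[[`, "accept")),
            class = "cea_posterior")
}

#' @export
print.cea_posterior <- function(x, ...) {
  cat(sprintf(
    "<cea_posterior> %d draws (%d chains), n = %d participants, converged: %s\n",
    nrow(x$draws), x$config$chains, x$n, x$converged))
  cat(sprintf("  E[delta cost] = %.2f GBP, E[delta QALY] = %.4f\n",
              mean(x$draws$delta_cost), mean(x$draws$delta_qaly)))
  invisible(x)
}

#' Incremental cost-effectiveness ratio
#'
#' Reported as the magnitude of the incremental cost per QALY gained,
#' `|delta_cost| / delta_qaly`, following the convention of quoting a
#' positive cost-per-QALY figure alongside a mean saving; when the
#' intervention both saves money and gains QALYs it is additionally
#' labelled dominant.
#'
#' @param delta_cost incremental cost, GBP (intervention - control).
#' @param delta_qaly incremental QALYs (gain; must be nonzero).
#' @return List with `value` (GBP/QALY) and `dominant` (logical).
#' @export
#' @examples
#' icer(-93.03, 0.027)$value # 3445.56
icer <- function(delta_cost, delta_qaly) {
  abort_if(delta_qaly == 0, "undefined ratio: delta_qaly is zero")
  list(value = abs(delta_cost) / delta_qaly,
       dominant = delta_cost < 0 && delta_qaly > 0)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the posterior probability that
#' the intervention is cost-effective: the fraction of draws whose net
#' monetary benefit `wtp * delta_qaly - delta_cost` is positive.
#'
#' @param posterior a [fit_cea()] result.
#' @param wtp_grid thresholds, GBP/QALY (default from the fit config).
#' @return data.frame (class `ceac_curve`) with `wtp` and
#'   `probability_cost_effective`.
#' @export
ceac <- function(posterior, wtp_grid = posterior$config$wtp_grid) {
  stopifnot(inherits(posterior, "cea_posterior"))
  dq <- posterior$draws$delta_qaly
  dc <- posterior$draws$delta_cost
  structure(data.frame(
    wtp = wtp_grid,
    probability_cost_effective = vapply(
      wtp_grid, function(l) mean(l * dq - dc > 0), 0)),
    class = c("ceac_curve", "data.frame"))
}

#' Net monetary benefit at a threshold
#'
#' @param posterior a [fit_cea()] result.
#' @param wtp willingness-to-pay, GBP/QALY.
#' @return List with `mean`, `sd`, `ci_low`, `ci_high` (95% credible
#'   interval) of the per-draw net benefit `wtp * delta_qaly - delta_cost`.
#' @export
net_benefit <- function(posterior, wtp) {
  stopifnot(inherits(posterior, "cea_posterior"))
  nb <- wtp * posterior$draws$delta_qaly - posterior$draws$delta_cost
  q <- stats::quantile(nb, c(0.025, 0.975), names = FALSE)
  list(mean = mean(nb), sd = stats::sd(nb), ci_low = q[1], ci_high = q[2])
}

#' Cost-effectiveness plane summary
#'
#' Draw cloud on the (incremental QALY, incremental cost) plane: mean,
#' covariance, a 95% Gaussian ellipse, and quadrant proportions (the
#' southeast quadrant -- QALYs gained at lower cost -- is dominance).
#'
#' @param posterior a [fit_cea()] result with at least 100 draws.
#' @param level ellipse coverage level (default 0.95).
#' @return List with `center`, `covariance`, `level`, `ellipse` (polygon
#'   coordinates) and `quadrants` (proportions named ne/nw/se/sw).
#' @export
ce_plane <- function(posterior, level = 0.95) {
  stopifnot(inherits(posterior, "cea_posterior"))
  dq <- posterior$draws$delta_qaly
  dc <- posterior$draws$delta_cost
  abort_if(length(dq) < 100, "need at least 100 draws")
  center <- c(delta_qaly = mean(dq), delta_cost = mean(dc))
  covm <- stats::cov(cbind(delta_qaly = dq, delta_cost = dc))
  r <- sqrt(stats::qchisq(level, df = 2))
  theta <- seq(0, 2 * pi, length.out = 181)
  circle <- rbind(cos(theta), sin(theta)) * r
  eg <- eigen(covm, symmetric = TRUE)
  half <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  ell <- t(half %*% circle + center)
  colnames(ell) <- c("delta_qaly", "delta_cost")
  quadrants <- c(ne = mean(dq > 0 & dc >= 0), nw = mean(dq <= 0 & dc >= 0),
                 se = mean(dq > 0 & dc < 0), sw = mean(dq <= 0 & dc < 0))
  list(center = center, covariance = covm, level = level,
       ellipse = ell, quadrants = quadrants)
}

#' Summarize a cost-effectiveness posterior
#'
#' Mirrors the usual base-case reporting table: mean cost saving
#' (= minus the mean incremental cost) with 95% credible interval, mean
#' incremental QALYs with CrI, the ICER at the posterior means, the
#' probability of cost-effectiveness at each threshold, and the plane
#' ellipse.
#'
#' @param posterior a [fit_cea()] result.
#' @param wtp_grid thresholds for the acceptability probabilities.
#' @return An object of class `cea_summary`.
#' @export
cea_summary <- function(posterior, wtp_grid = posterior$config$wtp_grid) {
  stopifnot(inherits(posterior, "cea_posterior"))
  dc <- posterior$draws$delta_cost
  dq <- posterior$draws$delta_qaly
  qc <- stats::quantile(-dc, c(0.025, 0.975), names = FALSE)
  qq <- stats::quantile(dq, c(0.025, 0.975), names = FALSE)
  cc <- ceac(posterior, wtp_grid)
  structure(list(
    mean_cost_saving = mean(-dc), cost_saving_ci = qc,
    mean_delta_qaly = mean(dq), delta_qaly_ci = qq,
    icer = icer(mean(dc), mean(dq)),
    p_ce_at = stats::setNames(cc$probability_cost_effective, cc$wtp),
    plane = ce_plane(posterior),
    converged = posterior$converged, n = posterior$n),
    class = "cea_summary")
}

#' @export
print.cea_summary <- function(x, ...) {
  cat(sprintf("Mean cost saving: GBP %.2f (95%% CrI %.2f to %.2f)\n",
              x$mean_cost_saving, x$cost_saving_ci[1], x$cost_saving_ci[2]))
  cat(sprintf("Mean incremental QALYs: %.4f (95%% CrI %.4f to %.4f)\n",
              x$mean_delta_qaly, x$delta_qaly_ci[1], x$delta_qaly_ci[2]))
  cat(sprintf("ICER: GBP %.2f per QALY%s\n", x$icer$value,
              if (x$icer$dominant) " (dominant)" else ""))
  for (w in names(x$p_ce_at))
    cat(sprintf("P(cost-effective) @ GBP %s/QALY: %.2f\n", w, x$p_ce_at[[w]]))
  invisible(x)
}
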