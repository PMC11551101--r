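---
title: "Methods: within-trial cost-utility analysis with beamcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-trial cost-utility analysis with beamcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`beamcea` implements the evaluation machinery of a two-arm randomized
controlled trial with a six-month horizon, of the kind used to assess a
digital physical-activity intervention in chronic kidney disease: clinical
outcome analysis on the mental/physical component summary (MCS/PCS)
scales, construction of QALYs and costs, a Bayesian bivariate model of
incremental costs and effects, and the sample-size machinery behind the
design. Because no participant-level data are publicly deposited for such
trials, the package ships a synthetic-trial generator whose defaults state
the published structure of the target cohort; every analysis stage is
exercised and tested against that stated world.

## The synthetic world

`simulation_config()` fixes a world; its defaults are not tuning knobs.

* **Allocation**: 173 intervention / 167 control, 1:1 randomization.
* **MCS**: baseline Normal(46.3, 10.5) in both arms (46.3 is the pooled
  baseline of the emulated cohort, SD 10.5 its typical spread); week-24
  correlated 0.7 with baseline, plus an additive intervention effect of
  5.9 AU. Week 12 is the average of the two endpoints plus exactly enough
  independent noise to restore the marginal SD, which implies
  cor(week 0, week 12) = (1 + 0.7)/2 = 0.85 — a choice, since only the
  baseline–follow-up correlation is stated.
* **Utilities**: baseline means 0.65 (intervention) and 0.73 (control) —
  the cohort was imbalanced at baseline — SD 0.25, clipped at 1. The
  intervention effect (+0.10) is present in full from month 3 onward.
  Clipping shifts means down by a few hundredths; tests compare against
  the closed-form truncated-normal expectation rather than the nominal
  mean.
* **Costs**: per-window component costs are Gamma with shape 1.5
  (coefficient of variation ≈ 0.8, right-skewed as health-care costs
  are), component shares 15/20/55/10% (primary care, medications,
  hospital, social care) summing to a pre-trial 12-week mean of £1850.
  Within-trial 13-week windows scale by 13/12. The control arm's
  within-trial mean is 1.025 times the intervention arm's: with a
  six-month care total of roughly £4000 this implies a saving of about
  £100 before the £15 delivery fee, the order of magnitude of the
  emulated trial. A lognormal option with matched mean and CV exists for
  misspecification experiments.
* **Dropout**: 39% intervention, 15% control (deterministic half-up
  rounding, so 173/167 yield 106 and 142 completers); 75% of dropouts
  leave in the first week and lose all post-baseline data, the rest lose
  only the final visit and second cost window. The published account of
  first-week withdrawal is internally inconsistent (a "77%" that computes
  to 69%), so the fraction is a parameter; 0.75 is the default. Dropout
  is MCAR by default — completers and non-completers were reported
  similar — with a MAR option (probability increasing as baseline MCS
  falls) for sensitivity work.
* **Adherence**: structured sessions ≈ 24·Beta(1.6, 1), education
  ≈ 12·Beta(1, 1), ≈ 28–42 platform-minutes per session; chosen to give
  medians near 15/24, 6/12 and ≈ 500 minutes.

What the generator does **not** emulate: site effects, visit-date jitter,
item-level questionnaire structure, adverse events, within-person
cost–utility correlation beyond what the independent component draws
induce, and any non-monotone missingness. A green test therefore
establishes that the machinery is correct under the stated world, not
that the published trial estimates are reproducible — they depend on
undeposited data.

## Outcome analysis

The primary analysis is ANCOVA of the week-24 score on an arm indicator,
the baseline score, and age (linear; the published analysis does not say
whether age was categorized, and linear is the parsimonious reading):

$$y_{24,i} = \beta_0 + \beta_1 \,\mathrm{arm}_i + \beta_2\, y_{0,i} +
\beta_3\, \mathrm{age}_i + \varepsilon_i .$$

`ancova_fit()` reports $\hat\beta_1$ with its $t$-based 95% CI and
two-sided $p$ (significance at 0.05). Residual normality and covariate
balance are diagnostics emitted as warnings, never failures; constant
covariates are dropped by least squares rather than treated as errors.
No multiplicity adjustment is applied across subscales, matching the
emulated analysis.

Missing data: the primary population is intention-to-treat with **LOCF**
— each missing follow-up takes the most recent earlier observation
(week 24 falls back to week 12 if observed, else baseline; "last
observation" is read as most recent, not baseline-only). Imputed cells
carry provenance flags, so `per_protocol_filter()` can later select
exactly the records with *observed* baseline and week-24 values. LOCF is
idempotent, never alters observed cells, and in a world where controls
decline after week 12 it biases the effect toward zero — the sense in
which it is conservative; this direction is asserted by a test on a
constructed scenario.

The **multiple-imputation** sensitivity path draws proper imputations
from chained linear regressions (week 12 from arm + age + baseline, then
week 24 from those plus week 12 — the predictor set is a documented
choice, as the published description names only "linear regression
imputations"). Coefficients and residual variance are drawn from their
posterior under the standard noninformative prior before each predictive
draw; deterministic prediction would understate between-imputation
variance. Pooling uses Rubin's rules with the Barnard–Rubin small-sample
degrees of freedom — the standard completion, since no pooling math is
published. Zero between-imputation variance is kept at exactly zero.

## QALYs and costs

QALYs are the trapezoid area under the EQ-5D utility curve at months
0/3/6 over the 0.5-year horizon (three points, since utilities were
collected at baseline, 3 and 6 months); constant utility $u$ gives
exactly $0.5u$. Any 5L→3L crosswalk is a user-supplied table or affine
map — no value set is bundled.

Costs live in a windowed ledger (pre-trial 12 weeks, two 13-week trial
windows; lengths configurable). Missing within-trial components are
completed by last value carried forward, scaled by the window-length
ratio. Aggregation is in integer pence, so component sums equal totals
exactly. The intervention delivery fee is recomputed from policy rather
than read from the ledger: the stated fee is £15 per participant-year
but the base-case table charges £15 per person to a six-month analysis,
so `"full"` attribution (the default) charges the whole £15 to the
horizon and `"prorata"` charges £7.50. The inflation index is a
user-supplied mapping from price-year label to factor — no live CPI
lookup, for reproducibility.

## The bivariate cost-effectiveness model

Costs $c_i$ and transformed effects $e_i = 1 - \mathrm{QALY}_i$ are both
Gamma (effects must be "folded" because QALY distributions are
left-skewed with an upper bound):

$$c_i \sim \Gamma(s_c,\ \mu_{k(i)} + \gamma_1(c_{0i}-\bar C) +
\gamma_2(u_{0i}-\bar U)),$$
$$e_i \sim \Gamma(s_e,\ \nu_{k(i)} + \delta_1(c_{0i}-\bar C) +
\delta_2(u_{0i}-\bar U) + \beta(c_i - \mu_i)),$$

in a (shape, mean) parameterization, with baseline-cost and
baseline-utility adjustment and the two marginals linked through the
conditional mean of effect given the cost residual. Whether the original
bivariate construction conditioned effect on cost or cost on effect is
not published; effect-conditional-on-cost is adopted and documented.
Arm means are reported at centering values $\bar C = £1850$,
$\bar U = 0.70$ (configurable); because both arms share the covariate
coefficients, the increments $\Delta C = \mu_{\mathrm{int}} -
\mu_{\mathrm{con}}$ and $\Delta Q = \nu_{\mathrm{con}} -
\nu_{\mathrm{int}}$ are invariant to the centering point.

Priors are intended to be noninformative and are fully configurable:
Normal(0, sd $10^5$) on all mean-scale coefficients, with rejection of
any proposal that would make a participant-level mean nonpositive, and
Exponential(0.001) on both shapes. The sampler is Metropolis-within-Gibbs
with per-parameter Gaussian random walks; proposal scales adapt toward a
0.44 acceptance rate during burn-in only and are frozen afterwards, so
the kept draws satisfy detailed balance. Defaults are 20,000 burn-in and
20,000 kept iterations on 2 chains; split-chain $\hat R < 1.05$ on the
reported quantities is required, otherwise the result is flagged (never
silently returned). The Gamma log-likelihood is evaluated from sufficient
statistics ($\sum \log x$ precomputed) and tested for exact agreement
with `dgamma()`. Zero costs are offset by one penny (the smallest
currency unit) with a message. The fit is deterministic given (data,
config, seed).

Summaries: ICER is reported as $|\Delta C| / \Delta Q$ with a dominance
label when the intervention both saves money and gains QALYs, matching
the convention of quoting a positive cost-per-QALY beside a mean saving;
the CEAC at threshold $\lambda$ is the fraction of draws with
$\lambda\,\Delta Q - \Delta C > 0$; the plane ellipse is the 95% Gaussian
ellipse of the draw cloud. Tests check the CEAC against a closed-form
Gaussian oracle and against a nonparametric bootstrap of participant
means, and check posterior increments against frequentist mean
differences in the large-shape (normal-limit) regime.

## Design machinery

With outcome SD $\sigma$ and repeated-measure correlation $\rho$, the
change score has SD $\sigma\sqrt{2(1-\rho)}$; `sample_size_change_score()`
finds the smallest per-group $n$ whose exact noncentral-$t$ two-sample
power reaches the target. The change-score formulation is adopted
because it uniquely reconciles the stated inputs (SD 10, $\rho$ 0.7,
$\Delta$ 3, 80% power, 5% alpha) with 106 per group; the normal
approximation gives 105, an ANCOVA-style formulation
($\sigma\sqrt{1-\rho^2}$) about 90 and is available as a labelled
alternative mode. `inflate_for_dropout()` is a plain ceiling; note the
published total of 340 also reflects power for secondary outcomes and is
therefore not an output of this calculation. `simulate_power()` verifies
the design by simulating baseline/follow-up pairs and testing change
scores with a pooled-variance $t$-test.

## Numerical and engineering choices

* Report percentages round half away from zero (`round_half_up()`), so
  15/24 → 63% and 105/173 → 61%; base R's round-half-even would differ.
* Money is carried as integer pence; GBP floats appear only in reports.
* Measurements are generated at instrument precision (0.1 AU, 0.001
  utility, £0.01), which also makes CSV round-trips exact; missing cells
  are written as empty strings, never `"0"` or `"NA"`.
* Independent random streams are derived from the master seed per stage
  (generation, dropout, each imputation, each chain), so changing one
  stage's consumption cannot silently shift another's.
* Test-suite MCMC runs are scaled down from the production 20k + 20k
  (e.g. 1k + 2k for recovery, 0.4k + 0.8k per null-calibration
  replicate); the tested properties are coverage and recovery within
  posterior spread, which chain length affects only through Monte-Carlo
  error.

## Known limitations

* The published headline estimates (MCS +5.9, ΔQALY 0.027, 93%/98%
  cost-effectiveness probabilities) are not reproducible without the
  trial data; the package demonstrates the machinery on the stated world
  instead, and its acceptance checks are parameter recovery, calibration
  and arithmetic identities.
* The MCS-per-unit ICER published alongside the headline figures
  (£14.44) cannot be reconstructed from the printed saving and effect
  (93.03 / 5.9 ≈ 15.77); the package computes the ratio from its own
  inputs and ties no acceptance value to the printed figure.
* The sampler is single-threaded interpreted R; at the production
  iteration counts a fit takes a few minutes at trial scale. This is
  deliberate: no compiled code, fewer install-time failure modes.
* No lifetime extrapolation, subgroup CEA, value-of-information, or
  group-sequential features.

## A worked run

```{r example}
library(beamcea)
cfg <- simulation_config()            # the stated world
trial <- apply_dropout(generate_trial(cfg), cfg)

ancova_fit(locf_impute(trial, "mcs"), "mcs")   # ITT-LOCF primary analysis

econ <- lvcf_costs(locf_impute(trial, "eq5d"))
q <- compute_qalys(econ)
costs <- aggregate_costs(econ, intervention_cost_per_year = 15)

post <- fit_cea(costs$trial_cost, q$qaly, q$arm, costs$baseline_cost,
                econ$eq5d_m0, cea_model_config(seed = 1))
cea_summary(post)

sample_size_change_score(design_spec())        # 106
```
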