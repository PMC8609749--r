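---
title: "Matching with replacement and oversampling in small samples: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching with replacement and oversampling in small samples: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmover)
```

## The problem

Observational comparisons of surgical therapies are typically small (one
hundred to a few hundred patients) and strongly confounded: treatment
assignment depends on baseline characteristics. Propensity score matching
(PSM) addresses the confounding, but classical 1:1 nearest-neighbour
matching without replacement can discard a large share of an already small
cohort. Two levers promise relief: *oversampling* (matching K > 1 controls
to each treated unit) and *replacement* (letting a control serve several
treated units). Both change the statistical behaviour of the estimator of
the average treatment effect on the treated (ATT), here measured as an
absolute risk difference,

$$\tau = E[Y(1) - Y(0) \mid T = 1],$$

and of its variance estimators. `psmover` implements a complete Monte
Carlo laboratory for studying these trade-offs, plus an applied-analysis
entry point for real cohorts.

## Data-generating process

Each simulated cohort has six baseline covariates drawn from a latent
multivariate normal with zero means and unit variances. The design fixes
the latent correlations as a Toeplitz structure with lag-$k$ correlation
$0.6 - 0.1k$, so the off-diagonal entries span exactly 0.1 to 0.5 —
neighbouring covariates are strongly dependent, distant ones weakly. Only
the range of correlations is fixed by the study design; the Toeplitz form
is this package's concrete, positive-definite and reproducible choice for
filling it in. Covariates 1–3 are dichotomized at the normal quantiles
giving marginal probabilities 0.25, 0.30 and 0.20 (a latent value exactly
at the cutoff codes 0 — a probability-zero event, fixed for determinism);
covariates 4–6 stay continuous.

Treatment is assigned by a logistic model,
$\mathrm{logit}\, p_T = \beta_0 + \tilde\beta^\top x$, with two published
slope regimes: *weak* assignment
$\tilde\beta = (\log 1.25, \log 1.5, \log 1.25, \log 1.5, \log 1.25, \log 1.5)$
and *strong* assignment
$\tilde\beta = (\log 1.5, \log 1.75, \log 1.5, \log 1.75, \log 1.5, \log 1.75)$.

The primary outcome family is logistic:
$\mathrm{logit}\, p_Y = \gamma_0 + \tilde\gamma^\top x + \gamma_T T$ with
$\tilde\gamma = (\log 1.25, \log 1.25, \log 1.5, \log 1.5, \log 1.75,
\log 1.75)$, mixing weak and strong confounders. Because the logit link
makes a constant $\gamma_T$ produce *heterogeneous* individual risk
differences, a secondary linear-probability family with an exactly
additive effect ($p_1 = p_0 + \gamma_T$, truncated to $[0,1]$) is also
provided to study the homogeneous-effect case.

### Calibration

Three scalar parameters are free and are calibrated on a dedicated draw of
$10^6$ covariate vectors (seed documented in the calibration record):

* $\beta_0$ so the marginal treated proportion is 0.3, 0.5 or 0.7;
* $\gamma_T$ so the ATT — the mean of $p_1 - p_0$ among the treated — is
  0.15 on the risk-difference scale, exploiting the collapsibility of the
  risk difference;
* $\gamma_0$ so the marginal prevalence of the *observed* outcome
  (treatment effect included) is 0.20. Whether prevalence should be
  measured before or after adding the treatment effect is genuinely
  ambiguous; this package defines it as the marginal prevalence of the
  observed outcome, which is the quantity an analyst can verify in data.

Each target is monotone in its parameter, so a bisection search (the
efficient refinement of a grid search) solves each one-dimensional
problem; $\gamma_T$ and $\gamma_0$ interact and are iterated to joint
convergence ($\gamma_T$ inner, $\gamma_0$ outer, at most 20 sweeps —
prevalence depends only weakly on $\gamma_T$, so convergence takes a few
sweeps). All targets are evaluated as conditional expectations over
treatment assignment given the calibration draw (subjects weighted by
$p_T$), which removes the Bernoulli noise of drawing $T$; the only Monte
Carlo error left is the covariate draw, about $5 \times 10^{-4}$ at
$n_{\mathrm{cal}} = 10^6$. The tolerance on all three probability targets
is $5 \times 10^{-3}$. The *achieved* large-sample ATT, not the nominal
0.15, is stored as `att_true` and used as the truth for bias and coverage.

For the linear-probability family the covariate coefficients are set to
$(0.005, 0.005, 0.01, 0.01, 0.015, 0.015)$ on the risk-difference scale —
the same weak-to-strong confounding ladder as the logistic family, scaled
so that truncation of $p_0$ or $p_1$ at the $[0,1]$ boundary affects fewer
than 1% of subjects in every scenario (the worst case, treated proportion
0.7, truncates about 0.25%). Larger coefficients would make the nominally
additive effect substantially non-additive through truncation, which would
defeat the purpose of the homogeneous-effect family; the truncation
fraction is recorded at calibration and exceeding 1% is an error, not a
warning.

## Matching

The propensity score is always estimated by logistic regression of
treatment on the six covariates, main effects only. Matching is greedy
nearest-neighbour on the **logit** propensity scale within a caliper of
0.2 sample standard deviations of the logit score, for all ten strategies:
\{with, without replacement\} × K ∈ 1..5. Design choices the literature
leaves open, fixed here:

* **Processing order.** Treated units are processed in a random
  permutation drawn from a per-replication seed. No order is canonical;
  randomizing avoids systematic order artifacts while staying reproducible.
* **Distance scale.** Distances are absolute differences of the logit
  score — the same scale as the caliper, keeping the two rules consistent.
* **Incomplete sets.** A treated unit that cannot obtain all K in-caliper
  (available) controls is discarded entirely rather than kept with a
  partial set. This makes the proportion of matched treated (PMT) an
  interpretable per-strategy diagnostic and keeps every set the same size.
* **Ties.** Equal distances resolve toward the lower control index —
  deterministic and testable; with continuous scores ties have probability
  zero anyway.
* **Weights.** Within a set of K controls each control carries weight 1/K
  and the treated unit weight 1 (the ratio-matching convention: a
  control's total weight is the number of sets it serves divided by K). An
  alternative reading — down-weighting controls by their reuse frequency
  across sets — exists but is not implemented.

## Estimation

The ATT estimate is the mean over matched sets of (treated outcome −
mean control outcome). Two variance estimators are computed:

* **Standard (matched-sample).** The paired-difference variance: sample
  SD of the per-set differences over $\sqrt{n_{\mathrm{sets}}}$. For 1:1
  binary data this is exactly the classical matched-pairs
  difference-in-proportions form (the tests verify the algebra against the
  discordance table).
* **Abadie–Imbens (AI).** Computed only when matching used replacement
  (without replacement it coincides with the matched-sample view):
  $$\hat V = \frac{1}{n_s^2}\Big[\sum_i (d_i - \hat\tau)^2 +
  \sum_j (K_j^2 - K'_j)\,\hat\sigma^2_j\Big],$$
  where $K_j$ is control $j$'s total weight across sets, $K'_j$ the sum of
  squared within-set weights, and $\hat\sigma^2_j$ a conditional outcome
  variance estimated from the single nearest control-group neighbour on
  the logit scale ($J = 1$, the minimal estimator; $(y_j - y_{\ell(j)})^2/2$).
  The correction term is nonnegative and vanishes exactly when no control
  is reused.

Confidence intervals are normal-theory at 95%; no t correction is applied
(a deliberate knob — replication counts are large and set counts moderate).

## Balance diagnostics

Standardized mean differences divide the weighted treated-minus-control
mean by a *fixed* reference SD computed on the unmatched cohort (pooled
two-group form, $p(1-p)$ variances for binary covariates), so pre- and
post-matching SMDs share a denominator. The ASMD is the mean of absolute
SMDs — signed averaging would let imbalances cancel. The overlap
coefficient (OVL) integrates the pointwise minimum of the two groups'
weighted Gaussian kernel density estimates of the propensity score
(probability scale; Silverman bandwidths per group; 512-point common grid
padded by three bandwidths; trapezoidal integration). Whether the original
diagnostics used the probability or logit scale and which estimator is
unstated in the literature this design follows; these settings are this
package's documented, fixed choice. PMT and the proportion of resampled
controls (PRC — the fraction of distinct matched controls used in more
than one set) complete the diagnostics.

## The simulation engine

The full study is a 24-scenario grid per outcome family — \{weak, strong\}
× \{0.3, 0.5, 0.7\} × \{100, 250, 500, 1000\} — each crossed with the 10
strategies, with 10,000 replications per scenario in the reference design.
Per replication one cohort is generated, one propensity fit is shared by
all strategies, and one record per strategy is written. Performance
measures per cell: relative bias $|\overline{\hat\tau} - \tau| / \tau
\times 100$, RMSE $\sqrt{V(\hat\tau) + \mathrm{bias}^2}$ (variance with
denominator $R$ — the population form; fixed for determinism and
negligible against $R-1$ at study scale), and nominal coverage of both CI
methods.

Failure handling is explicit because the reference design is silent on
it: a replication whose propensity fit does not converge (including
perfect separation) or that yields fewer than two matched sets is recorded
as invalid with a reason, excluded from the aggregates, and counted.

Seeds derive hierarchically (study seed → scenario → replication →
purpose), so any single replication is reproducible in isolation and
results are independent of the number of parallel workers.

### Problem sizes used by the packaged checks

The packaged test-suite and the acceptance script run the study at desk
scale, the package's own choice of sizes for a reproducible check that
completes in minutes: calibration draws of $10^6$; the headline-bias check
at sample sizes 500 and 1000 (both strengths, all treated proportions)
with 500 replications per cell and the five with-replacement strategies;
the directional small-sample checks at $n = 100$, treated proportion 0.5,
with 1000 replications of all ten strategies; the secondary-family
coverage check at $n = 500$ with 500 replications. At these sizes the
Monte Carlo standard error of a relative-bias entry is roughly 1.5–2
percentage points and of a coverage entry about 1 point, which the test
tolerances respect.

## What the generator does and does not emulate

The synthetic cohorts reproduce the *statistical structure* the study
design states: correlated mixed-type covariates, logistic assignment of
known strength, a calibrated marginal prevalence and a calibrated
risk-difference ATT, with or without effect heterogeneity. They do not
emulate real clinical data in other respects: no missing values, no
measurement error, no unmeasured confounding, no covariate–treatment
interactions in the outcome model, no time-to-event structure. Passing
tests therefore demonstrates correctness of the estimators and the
machinery under the stated DGP, not robustness to those violations. The
applied-analysis command (`applied_analysis()`) runs the identical
strategy grid on user data but inherits the same modelling assumptions
(binary treatment and outcome, main-effects propensity model,
complete-case analysis).

## Incomplete matching and the discard rule

The discard-if-incomplete rule has a quantitative consequence worth
understanding before interpreting the bias tables. Under the logistic
outcome family the individual risk difference $p_1 - p_0$ grows with the
linear predictor over most of its range at a 0.20 prevalence, and the
linear predictors of the outcome and treatment models are positively
correlated; the treated units hardest to match — those in the right tail
of the propensity distribution, where controls are scarce — are therefore
also the units with the *largest* individual effects. Discarding them
shifts the estimand of the matched sample downward relative to the ATT
over all treated. The shift is negligible when controls are plentiful
(treated proportion 0.3 or 0.5, or K small) but becomes the dominant bias
component when 70% of the cohort is treated and K is large: there the
proportion of matched treated drops to roughly 0.7 even with replacement,
and the relative bias of the matched-sample estimate can reach the 15–25%
range at n = 500–1000 — an order of magnitude above the residual
confounding left inside the caliper (which decomposition puts below 0.001
on the risk-difference scale). Keeping partial sets (matching however many
in-caliper controls are available, reweighting by the realized set size)
removes most of this component, but it changes what PMT measures and makes
set sizes heterogeneous; this package implements the strict rule — every
retained set has exactly K controls — and reports PMT so that the
estimand shift is visible rather than silent.

## Known limitations

* The AI variance uses a single nearest neighbour for the conditional
  variances; with very few controls the estimate is coarse (and set to 0
  with a flag when no second control exists).
* Optimal, full, Mahalanobis and exact matching are out of scope, as are
  bootstrap variances and estimators accounting for propensity-estimation
  uncertainty.
* The linear-probability family's coefficients are a package choice (see
  Calibration); published per-scenario intercept tables for that family
  were not available to compare against, so only their calibration targets
  — not the coefficient values — are checkable.

## A minimal run

```{r, eval = FALSE}
cfg <- calibrate_scenario(scenario_config("weak", 0.5, 250))
study <- run_study(cfg, strategy_grid(), n_reps = 200, seed = 1)
study$summary[, c("strategy", "relative_bias", "rmse",
                  "nc_standard", "nc_ai", "mean_asmd", "mean_pmt")]
```
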