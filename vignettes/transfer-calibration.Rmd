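---
title: "Calibrated prior effects and stacked penalized regression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated prior effects and stacked penalized regression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priorstack)
```

## The problem

In many high-dimensional biomedical prediction tasks — methylation-based
classification, proteomic risk models, SNP-based polygenic scores — an
external study has already estimated effects for the same (or matched)
features: penalized regression coefficients, or signed log10 p-values from a
genome-wide association study. Sharing the *data* across studies is often
impossible; sharing per-feature summary numbers is routine. `priorstack`
treats each such external vector as a source of *prior effects*
$z_{\cdot k}$, assumed (by default) positively correlated with the target
study's true coefficients, and transfers the information in two steps:
per-source calibration to the target data, then stacked combination with a
co-data-free penalized baseline.

The target model is an ordinary GLM,
$E[y_i] = h^{-1}(\beta_0 + \sum_j \beta_j x_{ij})$, with the identity link
for gaussian responses and the logit link for binomial responses coded in
{0, 1}. Everything the pipeline produces collapses back into a single
intercept $\beta_0^\star$ and coefficient vector $\beta^\star$, so the fitted
ensemble predicts — and is interpreted — exactly like one penalized GLM.

## Calibration

Prior effects carry usable information in their *signs* and their *order*,
but not in their scale or shape: a source study may measure a related but
different outcome, so weak effects there may matter more or less here. Both
calibration methods therefore estimate a monotone re-mapping of
$z_{\cdot k}$ on the target data, and both are invariant under multiplication
of $z_{\cdot k}$ by a positive scalar (rescaling each source to $[-1, 1]$ is
a convenience, not a requirement — `rescale_priors()` divides by the maximum
absolute value and never recenters).

**Exponential calibration** fits the two-parameter power law
$\gamma_{jk} = \theta_k\,\mathrm{sign}(z_{jk})\,|z_{jk}|^{\tau_k}$ with
$\theta_k \ge 0$. For each candidate exponent $\tau$ the single synthetic
covariate $v_i = \sum_j \mathrm{sign}(z_{jk})|z_{jk}|^\tau x_{ij}$ is
regressed on the target (intercept free, non-negative slope), and the
deviance-minimizing $\tau$ is kept. We use the grid
$\tau \in \{0, 0.25, \ldots, 3\}$: exponents 0.5, 1 and 2 are the regimes a
power-law relation between prior and true effects typically occupies, and
the grid brackets them with margin on both sides; ties select the smallest
$\tau$. The convention $0^0 = 0$ pins $z_{jk} = 0$ features at
$\gamma_{jk} = 0$ for every $\tau$. With three free parameters
($\alpha_k, \theta_k, \tau_k$) the method is robust but rigid: it behaves
symmetrically for negative and positive prior effects.

**Isotonic calibration** estimates $\gamma_{\cdot k}$ under sign constraints
($\gamma_{jk}$ shares the sign of $z_{jk}$, zero where $z_{jk} = 0$) and
order constraints ($z_{jk} \ge z_{lk} \Rightarrow \gamma_{jk} \ge
\gamma_{lk}$). Optimization uses a cumulative-sum reformulation: order the
features by increasing prior effect, take cumulative sums of the ordered
feature columns from the left over the $q$ negative positions and from the
right over the rest, and fit the combined columns under plain sign
constraints (non-positive on the first $q$, non-negative after). The linear
predictors of the two parametrizations are identical, and the
order-constrained effects are recovered as suffix/prefix sums of the
sign-constrained ones (`build_cumulative_design()`, `recover_gamma()`).
Features with *equal* prior effects are merged into one tie group before
building the design: the bidirectional order constraints force equal
calibrated effects anyway, and merging (columns summed, one coefficient per
group) makes that exact rather than numerical.

The sign-constrained fit itself is maximum likelihood stabilized by a fixed
tiny ridge ($10^{-8}$ on the internally standardized scale), computed as the
end of a warm-started constrained ridge path. The stabilizer matters:
unpenalized constrained ML is ill-posed when the cumulative design has more
columns than samples, which is the normal situation ($p \gg n$), and
binomial fits can separate. The choice of $10^{-8}$ is far below any
statistically meaningful shrinkage; tests verify agreement with exact
non-negative least squares and with a projected-gradient optimizer on the
original parametrization to $10^{-4}$ or better. Binomial fits whose linear
predictors exceed ±30 are flagged `separated` but returned (they are bounded
by the stabilizer).

When a source may be *negatively* related to the target
(`allow_negative = TRUE`), exponential calibration simply drops the
$\theta_k \ge 0$ constraint, and isotonic calibration fits both orientations
and keeps the lower-deviance one, flagged `inverted`. The default assumes
positive correlation, which is the convention when sources are, e.g., GWAS
effects for the same disease.

**Source filtering.** After full-data calibration, each source is screened
with a paired one-sided Wilcoxon signed-rank test comparing per-sample
residual magnitudes of the calibrated model against the intercept-only model
(absolute raw residuals for gaussian, absolute deviance residuals for
binomial; zero differences dropped; exact distribution up to n = 25, normal
approximation with continuity correction beyond). A source is retained when
p ≤ 0.05. Two implementation notes: the residual type and the exact/normal
switch are conventions we fixed, and the procedure is *conservative* under
the null — in roughly a third of null draws the constrained calibration
degenerates to the intercept-only fit, which can never be retained, and the
paired comparison is itself mildly conservative for a weakly overfitted
model. Measured over thousands of null replicates the false-retention rate
is near 2%, comfortably below the nominal 5%. Filtering happens before
stacking; excluded sources keep an all-zero column and a meta-weight of
exactly 0, so the report stays aligned with the input sources.

## The co-data-free baseline and cross-validation

Independently of any co-data, the target is fitted by ridge or lasso
regression along a decreasing sequence of 100 regularization values
(glmnet's sequence construction). One 10-fold split — stratified by class
for binomial responses — is drawn per model fit and shared by *every*
cross-validated component: the co-data-free path, the per-fold
recalibrations, and the meta-learner. Reusing one fold plan avoids
information-leakage asymmetries between components; whether the original
procedure redraws folds per component is unknowable from the outside, and
sharing is the conservative choice.

Per-fold refits provide held-out linear predictors for every lambda; the
cross-validated loss (squared error or logistic deviance) selects
$\lambda_{min}$, and the one-standard-error rule selects
$\lambda_{1se} \ge \lambda_{min}$ (standard error = SD of fold means /
$\sqrt{K}$). Both fits are always passed to the meta-learner, even when the
two indices coincide: informative co-data can make the optimal co-data-free
shrinkage *stronger* than $\lambda_{min}$, and offering the pair lets the
meta-learner decide. The redundancy is harmless — its lasso simply splits or
drops a duplicated column.

## Stacking

The meta-learner is trained on cross-validated linear predictors, never on
in-sample fits: row $i$ of every column is computed from fits that excluded
sample $i$'s fold. Co-data columns contain only the feature-dependent part
$x_i^\top \hat\gamma^{-\kappa(i)}_{\cdot k}$ (the calibration intercept is
deliberately zeroed out — it would only recenter a column and distort the
combination algebra); the two co-data-free columns keep their intercepts.

**Standard stacking** regresses the target on the $m + 2$ stacked columns
under lasso with a free intercept and non-negative slopes, lambda chosen by
cross-validation on the shared folds with the $\lambda_{min}$ rule (the
original description fixes lasso but not the selection rule; $\lambda_{min}$
is the default a practitioner would use). The meta-features are *not*
standardized: they already live on the common linear-predictor scale, and
standardizing would silently reweight the combination. The fitted weights
$\hat\omega$ then combine the *full-data* component fits:
$\beta_j^\star = \sum_k \hat\omega_k \hat\gamma_{jk} +
\hat\omega_{m+1}\hat\beta_{min,j} + \hat\omega_{m+2}\hat\beta_{1se,j}$, and
likewise for the intercept with $\hat\omega_0$. Cross-validated fits are
used only to *learn* the weights; predictions use components refitted on all
n samples.

**Simultaneous stacking** regresses the target jointly on the m co-data
columns (unpenalized, non-negative) and the p raw features (user's ridge or
lasso penalty), so the combined coefficients
$\beta_j^\star = \sum_k \hat\omega_k \hat\gamma_{jk} + \hat\beta_j$ shrink
toward the weighted calibrated priors as lambda grows, with the
$\hat\beta_j$ acting as per-feature deviations. This suits sources that are
reliable for some features and unreliable or missing for others, and with a
lasso penalty the deviations are sparse even though the combination is
dense. Because the meta-weights are unpenalized the mode refuses more than
n/2 sources; the co-data-free $\lambda_{min}/\lambda_{1se}$ columns are not
part of the joint regression (the raw features already play that role).
Penalizing the meta-weights themselves, which would be needed for many
sources, is out of scope.

Both modes satisfy an exact algebraic identity — predicting through
$(\beta_0^\star, \beta^\star)$ equals stacking the component linear
predictors — which the test suite asserts to $10^{-10}$ on every fitted
model, and which is what makes the combined coefficients interpretable
as ordinary GLM coefficients.

## Simulation designs

`simulate_external()` reproduces a widely used transfer-learning benchmark:
AR(0.5)-correlated gaussian features (generated by the distributionally
equivalent recursion $x_j = \rho x_{j-1} + \sqrt{1-\rho^2}\,e_j$ rather than
an explicit Cholesky factor); target coefficients 0.5 on the first s
features and 0 elsewhere; transferable sources perturbed by $\pm h/p$ with
fair Bernoulli signs; non-transferable sources with the causal block
relocated and $\pm 2h/p$ perturbations; gaussian targets $y = X\beta +
\varepsilon$ (sources get a 0.5 intercept) or Bernoulli draws from the
corresponding logistic probabilities. Defaults: $n_{target} = 100$,
$n_{source} = 150$, $p = 1000$, K = 5 sources, 10 000 test samples.

`simulate_internal()` varies what that design holds fixed: effect sizes are
continuous, feature correlation is $\rho_x^{|i-j|}$ with configurable
$\rho_x$, and coefficient vectors are correlated across datasets — draws
$B_1, B_2$ from a 4-dataset gaussian copula in which the first source is
uncorrelated with everything and the target and remaining two sources share
$\rho_\beta$, thinned as $B = B_1 \cdot 1[B_2 > \Phi^{-1}(1-\pi)]$ with
$\pi = 0.2$ (dense) or 0.05 (sparse). The two transferable sources are then
distorted non-linearly (square, and square root, of the absolute values
with signs kept; between the two natural readings of the second transform,
the square-root reading reproduces the benchmark's coefficient-correlation
diagnostic max$(\hat\rho_\beta) \approx 0.89$ at $\rho_\beta = 0.99$ while
the identity reading gives 0.91, so we adopt the former). The latent signal $X\beta$ is standardized per dataset and mixed as
$\sqrt{w}\,z^* + \sqrt{1-w}\,\varepsilon$, so $w = 0.8$ fixes a 4:1
signal-to-noise ratio exactly; binomial responses round the logistic
probability to a class (p ≥ 0.5 → 1). Target train and test samples are
generated jointly (one standardization) and split, so both come from the
same finite-sample calibration of the latent scale.

Prior effects are derived from each simulated source by cross-validated
penalized regression — ridge in dense settings, elastic net with
$\alpha = 0.95$ in sparse settings, where pure lasso would make the prior
vector erratic — taking the $\lambda_{min}$ coefficients
(`derive_priors()`).

Performance is summarized by `percent_of_null()`: test MSE (gaussian) or
mean logistic deviance (binomial) divided by the same metric for predicting
the training mean or prevalence, ×100. `run_study()` runs replicate
scenarios with one random sub-stream per replicate for data and another for
fitting, so the simulated datasets are invariant to which methods are run;
`summarize_study()` adds means, SDs, and paired one-sided Wilcoxon p-values
against the co-data-free baseline.

What the generators deliberately do not emulate: real linkage
disequilibrium or block correlation beyond AR(1), partially overlapping
feature spaces, allele-matching and other harmonization issues, covariate
shift between source and target populations, and non-GLM outcome types. A
passing benchmark here shows the machinery transfers information under the
stated generative assumptions; it does not certify performance on data that
violate them.

## Numerical choices and edge cases

* Penalized fitting, lambda sequences, penalty factors, and box constraints
  are delegated to glmnet; stated lambdas therefore follow its conventions
  (for gaussian responses, the ridge term at stated $\lambda$ acts on the
  raw objective as $\lambda / \mathrm{sd}_n(y)$; the lasso term is
  unscaled). Cross-validated selection is unaffected.
* An all-zero penalty-factor vector means nothing is penalized; the path is
  then constant in lambda and equal to the unpenalized fit (handled
  explicitly, since the solver refuses the degenerate input).
* Degenerate prior columns (all zero) calibrate to $\gamma = 0$, are never
  retained, and contribute zero columns and zero weights.
* A calibration failure inside one cross-validation fold zeroes that fold's
  entries for that source and warns, rather than aborting the fit.
* Solver dust crossing an orthant boundary (at the $10^{-12}$ level) is
  clamped so sign constraints hold exactly in returned objects.
* Model files are JSON with 17 significant digits, which round-trips IEEE
  doubles bit-exactly; `read_model_json()` refuses unknown format versions.
* Binomial responses must contain both classes in every fold context, so
  each class needs at least K samples.

## Problem sizes used in the test suite

The acceptance-style checks reproduce four benchmark table cells (external
dense gaussian with one transferable source; external sparse gaussian and
dense binomial with five; internal dense gaussian at
$\rho_x = 0.95, \rho_\beta = 0.99$) at their published scale — 10 replicates
of $n_{target} = 100$ with 10 000 test samples, $p = 1000$ (external) or 500
(internal) — judged within two printed standard deviations, one-sided where
a smaller prediction error is the better outcome. Property suites
(calibration scale invariance, reformulation identities, oracle agreement,
stacking identities, filter level, serialization) run on small instances
where exact or near-exact assertions are meaningful. The six-scenario
calibration battery uses 20 replicates of $n = 200, p = 500$, matching the
published figure's setup.

## Known limitations

Isotonic calibration fits up to p parameters under shape constraints only;
on very weak signals it can overfit in-sample, which the cross-validated
stacking absorbs but the in-sample filter does not — the filter is therefore
more liberal for isotonic than for exponential calibration. The Poisson
family, categorical co-data, prior *weights* without signs, and differential
penalization of many meta-weights are out of scope. Sources are assumed to
share the target's feature space after identifier matching; unmatched
features receive a prior of zero, which is interpreted as "no information",
not as evidence of a null effect.
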