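---
title: "Nested trajectory models: methods, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested trajectory models: methods, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestlme)
```

## The problem and the model

Longitudinal animal experiments with a nested design — several human donors
per treatment group, several mice per donor, each mouse measured repeatedly
over days — produce three layers of correlation: repeated measures within a
mouse, shared donor material across mice, and serial correlation between
neighbouring days. A two-way ANOVA on such data treats all observations as
independent and can be badly miscalibrated in either direction. `nestlme`
fits the linear mixed effects models appropriate for this design and
quantifies the consequences of getting the covariance structure wrong.

The fixed-effects mean is always the full two-group linear trajectory

$$Y_{ij} = \beta_0 + \beta_1\,\mathrm{group}_i + \beta_2\,t_{ij} +
\beta_3\,(\mathrm{group}_i \times t_{ij}) + \varepsilon_{ij},$$

with group coded 0/1 (reference level = first factor level, lexicographic
unless the factor is supplied with explicit levels). $\beta_3$ is the
effect of interest: the difference in growth rate between groups. Random
effects act at up to two strictly nested levels, cluster (donor) and
subject (mouse); each level contributes a random intercept and/or a random
time slope with an unstructured (correlated) covariance matrix $G_\ell$.
Residuals are either independent, $\mathrm{Var}(\varepsilon) = \sigma^2 I$,
or stationary AR(1) over the within-subject *observation order*,
$\mathrm{Cov}(\varepsilon_j, \varepsilon_k) = \sigma^2\phi^{|j-k|}$.

Assumptions worth stating plainly: Gaussian random effects and residuals;
linear time trends (no saturation or non-linearity); strict nesting (a
mouse belongs to exactly one donor, a donor to exactly one group);
cross-level independence (donor-level and mouse-level effects are mutually
independent — only the intercept–slope correlation *within* a level is
estimated); homoscedastic residual variance.

## Likelihood evaluation

The engine evaluates the exact marginal likelihood by assembling, per
outermost block (donor when donor-level terms are present, mouse
otherwise),

$$V_b = Z_c G_c Z_c^\top +
\mathrm{blockdiag}_s\!\left(Z_s G_s Z_s^\top + \sigma^2 C(\phi)\right),$$

factoring it by Cholesky, and profiling the fixed effects by generalized
least squares. For ML,
$-\ell = \tfrac12\left[N\log 2\pi + \log|V| + r^\top V^{-1} r\right]$ with
$r = y - X\hat\beta_{GLS}$; REML adds $\tfrac12\log|X^\top V^{-1}X|$ and
replaces $N$ by $N-p$ in the constant (the same convention `lme4` reports,
against which the engine is cross-checked in the test suite; `nlme::lme`
differs by a constant $\tfrac12\log|X^\top X|$, so REML values are compared
to `lme4` and ML values to both). Blocks that share a covariance pattern —
identical measurement days and subject layout, the common case in balanced
simulations — reuse a single factorization, which is what makes the
Monte-Carlo studies below affordable: one small Cholesky per objective
evaluation regardless of the number of subjects.

Optimization is over an unconstrained parameterization: log-Cholesky
factors for each $G$ (logged diagonal, free off-diagonal), $\log\sigma$,
and $\mathrm{atanh}\,\phi$. Every point in the search space therefore maps
to a valid covariance. The default optimizer is `nlminb` (quasi-Newton)
with `optim`'s Nelder–Mead, BFGS, L-BFGS-B and CG available for stability
comparisons (`refit_all_optimizers()`); the objective tolerance is `1e-8`,
the start is a method-of-moments split of the OLS residual variance across
levels, and additional warm starts can be supplied (the comparison ladder
warm-starts every model from the embedded solution of the models nested
inside it, which guarantees the fitted ML log-likelihoods respect nesting
monotonicity up to optimizer precision). A numerically singular covariance
returns a large finite penalty so optimizers recover gracefully. A fit is
declared *singular* when any estimated variance falls below
$10^{-8}\hat\sigma^2$, a within-level correlation exceeds $1-10^{-6}$ in
magnitude, or $|\hat\phi| > 1-10^{-6}$; singular fits signal an
over-specified random-effects structure. $\sigma^2$ is estimated jointly
with the other parameters rather than profiled out, keeping the AR(1) and
independent families on one code path.

Two indexing choices deserve a note. AR(1) lags count *observation order*
within subject, not elapsed days, so on the uneven day grid (0, 1, 3, ...,
32) day 1 and day 3 are one lag apart; this matches the discrete
autoregressive recursion over successive time points and the behaviour of
`corAR1` grouped by subject. Time is used in days without centering or
scaling; rescaling is a convergence remedy, not a default.

## Hypothesis tests

* **Wald z-test** (`wald_test`): $z = \hat\beta/\mathrm{se}(\hat\beta)$
  against a standard normal. The plain z reference (not a
  Satterthwaite-type t) is deliberate: the simulation study is precisely
  about the finite-sample behaviour of this approximation, which is what
  the rejection-rate tables reflect.
* **Likelihood-ratio test** (`lrt`): $2\Delta\ell$ from ML refits against
  $\chi^2_{\Delta k}$ with the naive parameter-count degrees of freedom.
  When the tested parameters are variances the null sits on the boundary of
  the parameter space and this reference is conservative; the result is
  flagged and the bootstrap below is the recommended companion. Nesting is
  verified structurally and REML fits are refused.
* **Parametric bootstrap** (`parametric_bootstrap_test`): simulate `B`
  datasets from the fitted null (fixed effects, variance components,
  residual family), refit both models per replicate, and report
  $p = (1 + \#\{LRT^* \ge LRT_{obs}\})/(B_{ok}+1)$ — the add-one convention
  avoids zero p-values. Failed refits are excluded from numerator and
  denominator, reported, and the result is flagged unreliable above 20%
  failures. `B = 1000` by default; the original analyses' replicate count
  is not documented anywhere, so this is a package convention.

A distributional subtlety: under a boundary null the LRT statistic has an
atom at zero (roughly half the replicates estimate the tested variance at
exactly the boundary), so the bootstrap p-value has matching mass near 1.
Its distribution is uniform *below* the atom — $P(p \le \alpha) = \alpha$
for $\alpha$ up to about 0.5 — which is the property that makes the test
valid; the suite checks exactly this lower-tail calibration rather than a
global uniformity statistic, which the atom would fail by construction.

## The model ladder

`make_model_spec()` builds the eight named structures (see the README
table). Nesting edges are fixed a priori: the chain I ⊃ II ⊃ III ⊃ IV ⊃ V
for the independent-error models and VI, VII ⊃ VIII ⊃ V for the AR(1)
branch; arbitrary non-nested pairs are refused. `comparison_table()`
reports coefficients and standard errors from REML fits but takes all LRT
p-values from ML refits — REML likelihoods of models with a common mean are
comparable, but the ML refit convention keeps the tests on the standard
footing. Models VI–VIII are full citizens of the library even though
simpler interactive front-ends often defer autocorrelation support.

## Synthetic data: what it emulates and what it does not

`simulate_dataset()` draws, for each subject independently, a response
vector from $N(X\beta,\; Z g Z^\top + \sigma^2 I)$ over the subject's
measurement days — the exact construction of the simulation study, with one
shared covariance per scenario and three scenarios mirroring Models III,
IV and V (`intercept_slope`, `intercept_only`, `none`). The interaction
coefficient is multiplied by an *effect fraction* in $[0,1]$ (0, 0.10,
0.25, 0.50, 1.0 in the canonical grid) while the other fixed effects stay
put, so fraction 0 is the type I error condition and the rest trace a
power curve.

The generating truth for the original re-analysis was never published, so
the package ships a documented default set, versioned `blanton_like_v1`
(`default_sim_params()`): $\beta = (0.3, -0.5, 0.55, -0.25)$ in percent
weight change (units %/day for the slopes), mouse intercept variance 4,
slope variance 0.02 with zero intercept–slope covariance, residual variance
4. These were chosen once as plausible magnitudes for percent weight-change
trajectories over 32 days (healthy trajectory about +18% by day 32,
undernourished about 8 points lower, between-mouse SD of 2% at baseline);
every calibration claim checked by the suite (type I error at effect
fraction 0) is insensitive to the particular values, and the
`intercept_slope` scenario's zero intercept–slope covariance is
configurable. Two standard designs are provided: the balanced simulation
grid (4+4 donors × 5 mice × 12 days = 480 cells) and the independent
design (n donors, one mouse each, half per group) used at n = 40, 100,
1000.

`make_demo_dataset()` instead emulates the *re-analysed* dataset: 3 healthy
+ 5 undernourished donors, 5 mice each, the 12 days from 0 to 32, and 43
records removed completely at random to land on 437 observations. Because
the outcome is percent change from baseline, every trajectory is anchored
at exactly 0 on day 0; the generator therefore uses slope-only random
effects at both levels (donor slope SD 0.12, mouse slope SD 0.10 %/day,
residual SD 1.5%) and zero noise at baseline. Which 43 cells were missing
in the original data is unknown; uniform MCAR is a package convention, not
a claim about the original missingness mechanism. What the generator does
*not* emulate: informative missingness, non-linear growth, heteroscedastic
noise, AR(1)-correlated scenario data (the simulation study scenarios are
all independent-error), or donor-level effects in the three canonical
scenarios (mice are generated independent there by design). Passing tests
therefore certify the estimator and test machinery under the stated
Gaussian linear conditions — not robustness to features real data may add.

## Monte-Carlo harness

`rejection_rate()` simulates, fits by REML, applies the interaction Wald
test at $\alpha$ (0.05 by default), and reports the rejection proportion
over converged fits with an exact Clopper–Pearson interval; non-converged
replicates are excluded from the denominator and counted, and a cell with
more than 10% failures is flagged. Replicate datasets are a deterministic
function of (root seed, scenario, design) alone — never of the fitted model
or the effect fraction's noise stream — so models within a table row are
compared on identical data (common random numbers) and the fraction-0
column of a power curve equals the type I error cell. Each replicate and
bootstrap draw gets its own derived stream, so results are independent of
execution order and reproducible from one integer.

## Problem sizes and numerical choices in the shipped suite

The test suite runs the studies at reduced but still informative scales,
chosen as the smallest sizes at which the exact binomial bands are decisive:
nominal-calibration checks at 2,000 replicates (matched random-intercept
model, 40 independent subjects) and 10,000 replicates (matched linear
model); directional misspecification checks at 1,000 replicates;
CI coverage at 1,000 replicates; parameter recovery at 60 replicates of 200
subjects; ladder monotonicity over 20 simulated datasets; bootstrap
calibration over 200 outer replications with B = 99. Oracle agreement
(blocked-Cholesky engine vs a dense brute-force evaluation of the full
$N \times N$ Gaussian density) is required to $10^{-8}$ relative on 50
random small instances. Monotonicity assertions use a relative tolerance of
$10^{-6}$ on the log-likelihood, matching optimizer precision.

## Known limitations

Two random-effect levels at most; no crossed designs; Gaussian outcomes
only; no Satterthwaite/Kenward–Roger small-sample corrections (the plain z
reference is the object of study); no chi-bar-square boundary mixtures (the
bootstrap covers that need); no multiple-testing adjustment across the
ladder. Whether the original AR(1) analyses lagged by observation order or
by elapsed days on the uneven grid is not documented; the package uses
observation order and states it.
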