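---
title: "Monte Carlo power analysis for mediation and moderated mediation: models and methods"
author: "modmedpower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo power analysis for mediation and moderated mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modmedpower)
```

## The problem

Experiments that posit mediation ask whether a manipulated factor $X$
affects an outcome $Y$ through an intermediate variable $M$: the indirect
effect is the product $ab$ of the $X \to M$ slope ($a$) and the
$M \to Y$ slope controlling for $X$ ($b$), and the total effect is
$c' + ab$.  Moderated mediation adds a second manipulated factor $W$ that
changes the indirect effect; when $W$ moderates the $a$ path, the
conditional indirect effects are $\mathrm{ind}_{w0} = a_{w0} b$ and
$\mathrm{ind}_{w1} = (a_{w0} + a_{\mathrm{mod}}) b$, and their difference
$a_{\mathrm{mod}} b$ — the index of moderated mediation — is the target of
inference.

Because products of coefficients have markedly non-normal sampling
distributions at realistic sample sizes, no closed-form power formula is
trustworthy, and analytic tools built for single regression coefficients
do not apply.  This package estimates power by brute force: specify the
population path model over the *fixed* experimental design, simulate many
samples, fit the analysis model to each, test the effects of interest,
and report the rejection rate.

## The model

All models are recursive path models with fixed exogenous covariates.  Per
group $g$, with covariate row $x_i$ (dummy codes and their products),

$$y_i = \alpha_g + B_g\, y_i + K_g\, x_i + \zeta_i,
  \qquad \zeta_i \sim N(0, \Psi_g),$$

where $K$ holds covariate-to-endogenous slopes, $B$ (strictly
lower-triangular after permutation) holds endogenous-to-endogenous slopes,
$\Psi$ is the diagonal residual covariance, and $\alpha$ the intercepts.
Each cell of each matrix is either fixed or carries a free-parameter
label; one label bound to several cells — within or across groups — is a
single equality-constrained parameter.  Moderation by a dichotomous
factor can be written either as an interaction column in a single group
or as between-group differences in a multigroup model; both are supported
and, with matching constraints, are exact reparameterizations of one
another (the package tests this parameter-for-parameter).

### Standardized population parameters

Population slopes are interpreted as standardized effects by solving, in
topological order, for residual variances that make every model-implied
total variance equal 1:
$\psi_j = 1 - \operatorname{Var}(\text{explained}_j)$, where the
explained variance uses the joint covariance of the covariates and the
previously solved endogenous variables.  Covariate moments use the
unbiased ($n-1$) divisor: with the 2×2, 25-per-cell design this yields
$\psi_M = 0.8718434$ and $\psi_Y = 0.8061616$ for the moderated-mediation
population model, and $\psi_M = 0.9368687$, $\psi_Y = 0.8096970$ for the
simple-mediation model.  The solver is verified against the reduced-form
implied covariance $\Pi \Sigma_x \Pi' + (I-B)^{-1}\Psi(I-B)^{-T}$,
$\Pi = (I-B)^{-1}K$: feeding the solved $\psi$ back in reproduces unit
total variances to $10^{-10}$.  Note the consequence: the standardizing
$\psi$ depend (mildly) on $N$ through the divisor, so sample-size sweeps
re-solve them at every grid point.

### Estimation

Fitting maximizes the Gaussian log-likelihood of the endogenous variables
conditional on the fixed covariates.  The likelihood factors into one
regression per (group, equation) cell; coefficients enter linearly, so
the implementation alternates two exact updates — a stacked weighted
least-squares step for all coefficient labels given the variances, and
pooled residual-mean-square updates (ML divisor $n$) for shared variance
labels given the coefficients — iterating to a relative log-likelihood
change below $10^{-12}$ (cap 500 iterations).  Unconstrained models
converge to the per-equation OLS solution, which the test suite checks to
$10^{-8}$ against `lm()`.  The parameter covariance is the inverse
*observed* information, assembled analytically (coefficient blocks
$Z'Z/\psi$, variance blocks $\mathrm{RSS}/\psi^3 - n/(2\psi^2)$, and the
coefficient–variance cross terms $Z'r/\psi^2$, which vanish only when an
equation is unconstrained); the expected information is available as a
cross-check option.  Degenerate data (collinear regressors, zero residual
variance) set convergence/boundary flags rather than raising errors, so a
batch of thousands of replications never dies mid-run.

### Tests of indirect effects

Two tests of $H_0{:}\ \theta = 0$ are computed for every user-defined
parameter (expressions over labels restricted to `+`, `-`, `*` and
parentheses, which keeps gradients trivial and products well-defined):

* **Delta-method Wald test** — $SE = \sqrt{g' V g}$ with $g$ the central
  finite-difference gradient (step $10^{-6}\max(1,|\theta|)$) at the
  estimates; for $ab$ with independent $\hat a, \hat b$ this is exactly
  the Sobel formula.
* **Monte Carlo confidence interval (MCCI)** — a parametric bootstrap:
  draw 20,000 parameter vectors from
  $N(\hat\theta_{\mathrm{sub}}, \hat V_{\mathrm{sub}})$ restricted to the
  labels the expressions use, evaluate each expression per draw, and take
  empirical percentile bounds.  Only the coefficient estimates themselves
  are assumed normal, so the interval respects the skewness of a product.
  20,000 draws keep the 2.5% percentile stable to about $\pm 0.002$;
  fewer than 100 draws are refused.

### The engine

A study = population model + analysis model (they may differ, e.g. a
heteroskedastic truth analyzed under constraints) + fixed design + Monte
Carlo settings.  One master seed spawns L'Ecuyer-CMRG substreams, two per
replication — one for data generation, one for the MCCI draws — so
results are bit-reproducible for any worker count and power noise can be
decomposed into data noise versus interval noise.  Nonconverged
replications are dropped from every numerator and denominator and
reported via `n_converged`; below 95% convergence the summary warns
prominently.  Per parameter the summary reports the estimate average,
average bias (flagged at $|{\cdot}| \ge 0.10$), coverage of the
delta-method intervals, and power per method.  Defined parameters inherit
population values evaluated at the population model, so their bias and
coverage come for free; a constrained label bound to cells whose
population values disagree (e.g. a homoskedasticity constraint over a
heteroskedastic truth) gets `NA` bias and coverage but still gets power.

## The four preset studies

The presets encode the package's worked examples, with the standardized
smallest effects of interest $a = .5$, $b = .4$, $c' = .2$,
$a_{\mathrm{mod}} = .3$, $\alpha = .05$:

1. `preset_simple_mediation()` — one group, $N = 100$ (50 per arm).
2. `preset_simple_mediation_multigroup()` — $X$ as grouping variable;
   intercept offsets $\mp a/2$, $\mp c'/2$; $b$ and residual variances
   constrained equal (liftable via `constrain = FALSE`); residual
   variances taken from the single-group standardization so parameters
   stay in pooled-SD units.
3. `preset_modmed()` — 2×2 with interaction, 25 per cell; moderator
   simple effects $+0.1$ on $M$ and $-0.1$ on $Y$ (nonzero nuisance
   paths of the population model); interaction effect on $Y$ fixed to 0.
4. `preset_modmed_multigroup()` — $W$ as grouping variable, 50 per
   group, within-group slopes $a_{w0} = .5$ and $a_{w1} = .8$, shared
   $b$, treatment residual variances ×1.5 (heteroskedasticity).

## Design choices worth recording

* **Covariance divisor.** Unbiased $n-1$ throughout.  It is the only
  convention under which the package's standardizations agree across the
  single-group and multigroup routes to the same population model, and it
  matches what `cov()`/`cov.wt()` produce by default.
* **Mean structure of the analysis models.**  The single-group
  simple-mediation study is analyzed *with* free intercepts: with a dummy
  predictor, omitting the intercept forces the control-group mean to
  zero and roughly halves $\operatorname{Var}(\hat a)$, which changes
  power for $ab$ from ~.57 to ~.87 — fitting intercepts is what an
  analyst would do and what makes the model an exact reparameterization
  of the multigroup formulation.  The single-group moderated-mediation
  study is analyzed without intercepts (its population has zero means and
  the no-mean-structure fit is the convention for that design).  The
  multigroup moderated-mediation *analysis* estimates free per-group
  intercepts even though the population means are zero, because that is
  how multigroup SEM fitters parameterize group models; the
  `intercepts = FALSE` switch removes them.  These choices are exposed,
  not hard-coded.
* **The $X \to Y$ path across moderator groups** in the multigroup
  moderated-mediation analysis is free per group (`c.w0`, `c.w1`) by
  default; `constrain_c = TRUE` shares it.  Power for the index is
  insensitive to this choice (the index involves only $a$ and $b$
  labels).
* **Recursive models only; diagonal $\Psi$.**  Covers every design the
  package targets while keeping identification trivial; freeing residual
  covariances or allowing feedback loops would require machinery
  (instrumental identification, non-recursive stability checks) with no
  payoff here.
* **Fixed-versus-population disagreement is an error.**  A cell fixed at
  one value with a different population value is almost surely a typo;
  silent override would corrupt a study invisibly.
* **Nonconvergence policy.**  Dropped with a visible count, never
  imputed; all-replications-failed is a hard error.

## What the generator does and does not emulate

Samples are multivariate normal conditional on the design: fixed dummy
covariates (never resampled — the variance-reduction property of
experimental designs), normal homoskedastic-within-group residuals via
the diagonal Cholesky, and exact recursive structure.  Real data deviate
in ways the generator deliberately ignores: non-normal or skewed
mediators and outcomes, measurement error (no latent variables),
missingness, discretized scales, and unbalanced attrition.  Power
estimates here are therefore best read as upper bounds for sloppier data;
passing the package's tests says the engine is calibrated for its model,
not that the model is true of any particular experiment.

## Numerical and test scale choices

Power estimates carry binomial Monte Carlo error
$\sqrt{p(1-p)/\mathrm{nRep}}$, about $\pm 1.3$ points at
$\mathrm{nRep} = 1500$ near $p = .6$.  The package's own test suite runs
the four preset studies at nRep between 1,200 and 2,000 — enough that
simulation noise (±1–3 points) is small against the ±6 to ±10 point
bands used to compare with published operating points, while keeping the
default suite around three minutes.  Calibration checks (type-I error of
the product tests under $a = 0$, coverage of free slopes) use
nRep = 2,000; coverage tests allow, besides 3 Monte Carlo SEs, a
1.5-point finite-sample term because the Wald intervals use asymptotic
$z$ critical values with ML (divisor-$n$) variances at $N = 100$.  One
published operating point deserves a caveat: for the total effect in the
single-group simple-mediation study this package measures MCCI power of
about 54% (confirmed by an independent `lm()`-plus-MVN-draws oracle),
which sits at the boundary of the ±10-point band around the published
64% — a value itself carrying ±10 points of binomial noise at the 100
replications used to produce it.

## Limitations

No latent variables, non-normal residuals, missing data, ordinal
endogenous variables, nonparametric bootstrap, or fit indices.  Factors
are two-level; effect-size elicitation is out of scope.  Multigroup
studies require group codes as sequential integers 1..G with the group
column last — the layout the generator emits.
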