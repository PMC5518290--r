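---
title: "Missing binary outcomes in cluster randomised trials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missing binary outcomes in cluster randomised trials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtmiss)
```

## The problem

In a two-arm cluster randomised trial (CRT), randomisation happens at the
level of clusters (schools, clinics, villages) while outcomes are measured
on individuals. Outcomes of individuals in the same cluster are correlated,
summarised by the intraclass correlation coefficient (ICC). When a binary
outcome is partially missing and the probability of missingness depends on
a fully observed baseline covariate — *covariate-dependent missingness*
(CDM), a special case of missing-at-random — the two standard repair
strategies are complete-records analysis (CRA, drop the unobserved
individuals) and multiple imputation. Whether CRA is valid turns out to
depend on the estimand (risk difference, risk ratio, odds ratio), on the
link function of the true outcome model, and on whether the two arms share
the same covariate effect and the same missingness mechanism. `crtmiss`
implements the estimators, the imputation engine and a simulation harness
to study exactly these questions.

## Generative model

`dgm_config()` describes a balanced trial with `k` clusters per arm and `m`
individuals per cluster. The baseline covariate is clustered,

$$X_{ijl} = \alpha_{ij} + u_{ijl}, \qquad
  \alpha_{ij} \sim N(\mu_x, \sigma^2_\alpha),\;
  u_{ijl} \sim N(0, \sigma^2_u),$$

so $\mathrm{Var}(X) = \sigma^2_\alpha + \sigma^2_u$ and the covariate ICC
is $\rho_x = \sigma^2_\alpha / (\sigma^2_\alpha + \sigma^2_u)$. The outcome
follows a random-intercept binary model

$$g(\pi_{ijl}) = \beta_0 + \beta_1 i + \beta_{2(i)} X_{ijl} + \delta_{ij},
  \qquad \delta_{ij} \sim N(0, \sigma^2_b),\quad
  Y_{ijl} \sim \mathrm{Bernoulli}(\pi_{ijl}),$$

with $g$ either the logit (default) or the log link, arm indicator
$i \in \{0, 1\}$, and a covariate effect $\beta_{2(i)}$ that may differ by
arm. Missingness is imposed per individual with probability
$\mathrm{expit}(\psi_i + \phi_i X_{ijl})$ (`missingness_config()`), so it
depends on the covariate but, given the covariate, not on the outcome.

`scenario_preset()` returns the four study scenarios S1–S4. All share
$\mu_x = 0$, $\sigma^2_u = 3.37$, $\sigma^2_\alpha = 0.18$ (so
$\sigma^2_x = 3.55$, $\rho_x \approx 0.05$), $\sigma^2_b = 0.20$,
$\beta_0 = 0$, $\beta_1 = 1.36$, $\phi_i = 1$, and cluster size $m = 50$;
they differ in whether $\beta_{2(0)} = \beta_{2(1)}$ (1 vs 0.588/1) and
whether $\psi_0 = \psi_1$ ($-1.34$ in both arms, i.e. about 30% missing,
versus $\psi_1 = 0.65$, about 60% missing in the intervention arm). These
intercepts can be re-derived with `calibrate_psi()`, which root-finds
$\psi$ against the quadrature-integrated missing proportion; the presets
hard-code the published constants rather than re-calibrating, so printed
scenarios are exactly reproducible.

Two numerical oracles accompany the generator. Marginal success
probabilities $\pi_i$ integrate the inverse link over the normal laws of
$X$ and $\delta$ with a 64-node tensor Gauss–Hermite rule (absolute
accuracy far below $10^{-6}$ here); `estimate_outcome_icc()` estimates the
per-arm outcome ICC $\rho_i = \mathrm{Var}(\pi_{ij}) / \pi_i(1 - \pi_i)$
from the *true* cluster success probabilities of a very large simulated
dataset, the standard route since the binary-outcome ICC has no closed
form. Under S1 these give $\pi_0 = 0.50$, $\pi_1 \approx 0.70$,
$\rho_0 \approx 0.037$, $\rho_1 \approx 0.032$.

Under the log link the linear predictor must stay negative for $\pi < 1$.
The generator truncates both $X$ and $\delta$ at $\pm 4$ SD and rejects
configurations whose maximum achievable linear predictor is non-negative.
(Truncating only the covariate would leave $\pi \ge 1$ reachable through
the cluster effect.) Log-link configurations are therefore slightly
truncated-normal rather than normal; the truncation mass is
$\approx 6\times 10^{-5}$ and irrelevant at the Monte-Carlo resolutions
used here.

## Estimators

**Cluster-level analyses** are two-stage. Stage one reduces each cluster to
its observed success proportion $p_{ij}$ (unadjusted) or to a residual from
a covariate-only individual-level logistic regression
$\mathrm{logit}(\pi) = \lambda_1 + \lambda_2 X$ fitted to the pooled arms,
ignoring arm and clustering (adjusted): the *difference residual*
$(N_{ij} - \hat N_{ij})/m$ or the *ratio residual* $N_{ij}/\hat N_{ij}$,
where $\hat N_{ij}$ sums fitted probabilities over exactly the records
contributing to the observed count $N_{ij}$. Stage two is a two-sample
$t$ comparison of the per-arm means of those summaries with
$2k - 2$ degrees of freedom; the log risk ratio uses the delta-method
variance $s^2_0 / (k \bar{v}_0^2) + s^2_1 / (k \bar{v}_1^2)$. With full
data the adjusted RD satisfies the exact decomposition
$\widehat{RD}_{adj} = \widehat{RD}_{unadj} + \frac{1}{mk}\sum_j (\hat
N_{0j} - \hat N_{1j})$, which the test suite checks to $10^{-12}$. Under
complete records the difference residual divides by the cluster's observed
count instead of $m$, and clusters left without observed outcomes drop
out, with all degrees of freedom and variance formulas using the realised
per-arm cluster counts (the equal-count formulas are the balanced special
case).

**Individual-level analyses** estimate odds ratios. `fit_relr()` is
random-effects logistic regression — the conditional (cluster-specific)
log OR — fitted by adaptive Gauss–Hermite maximum likelihood
(`lme4::glmer`, 15 nodes by default); `fit_gee()` estimates the
population-averaged log OR by generalised estimating equations with an
exchangeable working correlation. The GEE solver is implemented in the
package (Liang–Zeger moment estimators for the scale and common
correlation, closed-form exchangeable inverse, fully vectorised over
clusters) and is verified in the tests against ordinary logistic
regression in degenerate cases, against a clustered-robust covariance from
the `sandwich` package under the independence structure, and against a
frozen reference fit from an independent GEE implementation. Because the
sandwich variance is biased downward with few clusters, it is multiplied
by $k/(k-1)$ and confidence intervals use $t_{2k-2}$ quantiles rather than
normal ones. The wording "correcting the SE by $k/(k-1)$" is ambiguous in
parts of the literature; the package applies the factor to the *variance*
(SE scaled by $\sqrt{k/(k-1)}$), the convention of the underlying
correction, and exposes `correction = "se"` for the alternative reading.
If the exchangeable fit fails to converge the model is automatically
refitted with an independence working correlation before giving up.

When the covariate effect differs between arms (S3/S4), analysis models
include an arm-by-covariate interaction. The covariate is empirically
centred at the mean over *all* individuals — including those with missing
outcomes, since the covariate is always observed — so the arm coefficient
is the effect at the covariate mean. No variance correction is attempted
for the estimated centring constant; the simulation coverage results are
the check that ignoring it is harmless at these designs.

Marginal and conditional log ORs differ (non-collapsibility): the
population-averaged effect implied by a random-intercept logit model has
no closed form, so `empirical_marginal_logor()` estimates it as the mean
of full-data GEE estimates over simulated replications, and the harness
uses the study's own mean full-data GEE estimate as the coverage target
for GEE whenever full-data fits are part of the run.

## Multilevel multiple imputation

`impute()` fits a Bayesian random-intercept *probit* model to the observed
outcomes by a data-augmentation Gibbs sampler written in the package:

1. latent normals $Z_{ijl}$ are drawn truncated to $(0, \infty)$ or
   $(-\infty, 0)$ according to the observed $Y$, and untruncated at
   missing positions;
2. coefficients are drawn from their multivariate-normal full conditional
   under a flat prior;
3. cluster effects from their normal full conditionals;
4. the random-intercept variance $\tau^2$ from its inverse-gamma full
   conditional, prior $\mathrm{IG}(0.001, 0.001)$ — weakly informative,
   chosen because reference implementations of this sampler do not
   publish their hyperparameters;
5. at retained iterations, missing outcomes are drawn Bernoulli with
   probability $\Phi(\text{linear predictor} + \text{cluster effect})$.

Defaults are $Q = 15$ imputations, 100 burn-in iterations and thinning 25,
the settings of the replicated study design. The probit link is used for
the imputation model even though the analyses are logistic: with success
probabilities away from the extremes the two links produce nearly
identical imputed distributions, and the resulting mild uncongeniality is
accepted by design. Imputation uses both arms jointly with arm as a fixed
covariate (matching the analysis models), with the arm-by-covariate
interaction added for S3/S4-type designs. Observed outcomes are never
altered; this is asserted in the tests.

Per-imputation estimates $\hat\theta_q$ with variances $\hat V_q$ are
pooled by Rubin's rules (`rubin_pool()`): $\bar\theta = Q^{-1}\sum
\hat\theta_q$, $T = W + (1 + 1/Q)B$. The usual MI degrees of freedom
$\upsilon = (Q-1)(1 + QW/((Q+1)B))^2$ assume infinite complete-data df,
which is wrong in CRTs where the complete-data df are $\nu_{com} = 2k - 2$
and often single-digit. The Barnard–Rubin adjustment

$$\nu_{adj} = \left(\upsilon^{-1} + \hat\nu_{obs}^{-1}\right)^{-1},
 \qquad
 \hat\nu_{obs} = \frac{\nu_{com}+1}{\nu_{com}+3}\,\nu_{com}
 \left(1 + \frac{Q+1}{Q}\frac{B}{W}\right)^{-1}
 \le \nu_{com},$$

is always applied. When $B = 0$ (all imputations agree), $\upsilon =
\infty$ and $\nu_{adj} = \hat\nu_{obs}$; $W = 0$ with $B > 0$ is rejected
as degenerate. Ratio-scale effects (RR, OR) are pooled on the log scale,
the standard choice for approximately normal completed-data estimators.
If an estimator fails on any single imputed dataset the whole MMI analysis
of that replicate fails (and the harness records it): silently pooling a
subset would bias the between-imputation variance.

## Validity conditions for complete-records analyses

Writing $\pi_{ijl} = \pi_i + g_i(X, \delta)$, the unadjusted
complete-records cluster-level RD is unbiased iff
$E[g_1 | R = 1] = E[g_0 | R = 1]$; writing
$\pi_{ijl} = \pi_i\, h_i(X, \delta)$, the RR analogue is consistent iff
$E[h_1 | R = 1] / E[h_0 | R = 1] = 1$. `check_condition()` estimates these
conditional expectations by Monte Carlo over $(X, \delta, R)$ with $\pi_i$
from quadrature, reporting the difference/ratio with its Monte-Carlo SE
and a 3-SE verdict. The characteristic results, all reproduced in the test
suite: with a logit-link model and a true effect ($\beta_1 \ne 0$) the RD
condition fails *even with identical missingness mechanisms and covariate
effects in both arms*, while it holds at the null; with a log-link model
and matched arms the RR condition holds exactly. An independent
brute-force check integrates the same expectations on a discretised
$(X, \delta)$ grid and agrees with the Monte-Carlo oracle.

## Simulation harness

`run_study()` reproduces the study design: per replication one full
dataset, one missingness imposition, then every requested method under
full data, CRA and MMI — so all handlings see the same data. Seeding is
hierarchical: each (stage, k, replication) combination derives its own
sub-seed from the root seed with a small integer fold, so any replication
can be reproduced in isolation and results are independent of execution
order (and of any parallel scheduling built on top). Aggregation yields
the average estimate, its Monte-Carlo error $SD/\sqrt{n_{reps}}$, the
average estimated SE, coverage of the nominal 95% intervals against the
generative truth (RD/log RR from quadrature, conditional log OR
$= \beta_1$, marginal log OR from the full-data GEE mean), and failure
counts; cells with more than 10% failed replications are flagged.
`autoplot()` displays estimates or coverage against $k$ by method and
handling.

## Problem sizes and numerical choices

The replication studies run in the package's tests use the S1 design at
$k = 50$, $m = 50$: the cluster-level studies (cheap) run the full 1000
replications, while the RELR/GEE and $k = 50$ imputation studies run 300
replications with tolerance bands widened accordingly by the combined
Monte-Carlo errors; the published per-cell Monte-Carlo bound
($SD/\sqrt{1000} < 0.016$) is checked directly from the replicated
standard deviations. The $k = 5$ imputation coverage study runs 1000
replications. With the weakly informative variance prior used here the
$k = 5$ overcoverage is real but milder (about 96–97%) than reported for
engines with more informative cluster-variance priors, so resolving it
above the nominal 95% needs the full replication count. For those runs RELR uses 7 adaptive quadrature nodes
— at cluster size 50 the 7- and 15-node fits agree to about $10^{-6}$ on
both estimate and SE — and `glmer` is run without its finite-difference
Hessian pass (`calc.derivs = FALSE`), which changes SEs by ~0.3% at these
sizes. The outcome-ICC oracle uses 1500–2000 clusters of 500 individuals.
GEE convergence is declared at a coefficient step below $10^{-8}$; the
stage-1 logistic at an IRLS tolerance of $10^{-10}$ with separation
reported as an error rather than returning runaway coefficients.

## What the generator does and does not emulate

The synthetic mechanism covers balanced designs, a single continuous
individual-level covariate, equal cluster sizes before missingness, and
outcome-independent (given the covariate) missingness. Real trials deviate
in ways deliberately out of scope: unequal cluster counts or sizes,
multiple or cluster-level covariates, missing covariates, and
missing-not-at-random outcomes. Passing tests therefore demonstrate
correctness of the estimators and the imputation machinery under CDM with
a correctly specified covariate model — not robustness to misspecified
missingness assumptions, for which sensitivity analyses would be needed.

## Known limitations

* The imputation model is probit while analyses are logistic; with very
  small or very large success probabilities the two links diverge and the
  pooling may inherit bias.
* RELR with MMI is known to be slightly upward biased for very small $k$;
  MMI with the adjusted df overcovers at $k = 5$ (reproduced in the
  tests), so small-$k$ MMI intervals are conservative.
* RD/RR obtained by marginalising RELR or GEE fits are not implemented;
  cluster-level analyses are the supported route to those estimands.
* One covariate per record: the schema reserves room for extensions, but
  all estimators take a single $X$.
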