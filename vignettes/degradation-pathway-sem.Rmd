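---
title: "Inferring protein degradation pathways with structural equation models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring protein degradation pathways with structural equation models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsem)
```

## The model

`pathsem` treats a hypothesised protein degradation pathway as a system of
simultaneous linear equations among observed protein abundances and latent
variables, and asks whether the sample covariance matrix of the abundances
is consistent with that system.

Every observed variable $y$ loads on a node variable $\eta$ (all-y LISREL
parameterization): observed-only proteins get a pass-through node (loading
fixed at 1, measurement error fixed at 0), while proteins absorbed into a
latent variable become its indicators (first loading fixed at 1 for scale,
the rest free, free error variances). The structural equations are
$\eta = B\eta + \zeta$ with $\zeta \sim N(0, \Psi)$, giving the implied
covariance

$$\Sigma(\theta) \;=\; \Lambda (I-B)^{-1} \Psi (I-B)^{-\top} \Lambda^\top + \Theta_\epsilon .$$

One parameterization serves every stage — prior skeleton, ML fitting,
search, simulation and Gibbs sampling — which is why it was chosen over a
leaner path-analysis form.

Assumptions worth stating plainly: abundances are treated as continuous and
jointly Gaussian on (something like) a log scale; samples are exchangeable
(see "What the generator does not emulate"); relationships are linear; and
the pathway hypothesis fixes which coefficients exist — the data only prune,
never add.

## Maximum-likelihood estimation

`sem_fit()` minimises
$F(\theta) = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma^{-1}(\theta)) - \log|S| - p$
with BFGS using the analytic gradient
$\partial F = \mathrm{tr}[(\Sigma^{-1} - \Sigma^{-1}S\Sigma^{-1})\,\partial\Sigma]$.
Numerical choices:

* **Starting values**: 0.5 for free loadings and paths; sample variances for
  variance slots (split between disturbance and measurement error for
  indicators); 0 for free covariances.
* **Positive definiteness**: parameter values where $\Sigma(\theta)$ is not
  positive definite get a large penalised objective value so line searches
  back off; variances themselves are unconstrained, and negative estimates
  (Heywood cases) are reported as warnings, never silently truncated.
* **Convergence**: relative tolerance $10^{-12}$ plus one polishing restart
  by default; the model-search loop uses $10^{-10}$ without the restart
  because it only needs Wald p-values. The convergence flag and evaluation
  count are part of the fit object.
* **Standard errors**: inverse of the numerically differentiated Hessian of
  $\tfrac{N-1}{2}F$ at $\hat\theta$. When that Hessian is singular — which
  genuinely happens for unidentified ridges such as a self-feedback loop
  $\eta_i = b\,\eta_i + \dots$, where only $b/(1-b)$-type combinations are
  identified — a Moore–Penrose pseudo-inverse is used and flagged.
* **Identification**: models with more free parameters than $p(p+1)/2$ are
  rejected before optimization; fit indices require $df \ge 1$.

Fit indices follow the standard definitions: $\chi^2 = (N-1)F(\hat\theta)$;
$\mathrm{RMSEA} = \sqrt{\max(\chi^2 - df, 0)/(df\,(N-1))}$ with the 90%
confidence interval obtained by inverting the noncentral-$\chi^2$
distribution in its noncentrality (lower bound from
$P(\chi^2_{df,\lambda} \le T) = 0.95$, upper from $0.05$, truncated at 0)
and the close-fit p-value $P(\chi^2_{df,\lambda_0} \ge T)$ at
$\lambda_0 = 0.05^2\,df\,(N-1)$; SRMR is the root mean square of the
correlation-scaled residuals over the lower triangle including the
diagonal. The working thresholds used in reporting are RMSEA < 0.1 with
p-close > 0.05, and SRMR alongside path-level significance.

## The refinement loop

`sem_search()` mirrors the two-phase refinement this kind of analysis uses:

1. **Collinearity collapse, once, first.** Groups are connected components
   of the graph with an edge wherever $|r| > 0.9$ (the threshold is a
   `search_config()` parameter, dimensionless). Protein pairs this
   correlated carry one signal between them; each group becomes a latent
   variable, and all structural paths touching members re-attach to the
   latent with duplicates merged.
2. **Backward pruning, one path at a time.** After each fit the structural
   path with the largest Wald p-value $\ge \alpha$ (default 0.05) is
   removed and the model refit. Single-step removal guards against
   joint-significance artefacts: removing one path changes every other
   p-value. A `batch_prune` flag removes all non-significant paths at once
   for users who prefer that reading; it is not the default. A parameter
   whose standard error collapses to zero sits on an unidentified ridge,
   so its significance cannot be established and it is pruned first.

The loop is deterministic given the data, terminates in at most $q$ steps
(each prune removes exactly one parameter and raises $df$ by one), and the
returned trace replays every decision with the fit indices after each step.

Design choice made here deliberately: no forward selection and no
modification indices. A pathway edge the prior never hypothesised cannot
enter the model; it shows up instead as residual misfit — which is the
honest behaviour for a tool whose prior graph is a scientific hypothesis.

## Bayesian re-estimation

`sem_bayes()` re-estimates the selected model by data-augmentation Gibbs
sampling, alternating three closed-form conditional draws: latent factor
scores (multivariate normal, vectorized across samples), coefficients
equation-by-equation (conjugate normal), and variances (conjugate
inverse-gamma). Tunable parameters, with defaults and rationale:

* `prior_coef_sd = 10` (abundance SD units): normal(0, $10^2$) on loadings
  and paths is effectively flat on standardized-coefficient scales while
  keeping conditionals conjugate.
* `prior_var_shape = prior_var_rate = 0.001`: the conventional diffuse
  inverse-gamma on variances.
* `n_chains = 4`, `n_iter = 20000`, `burn_in = n_iter/2`: four chains of
  20,000 sweeps with the first half discarded; burn-in defaults to half the
  chain because only total iteration counts are conventionally reported.
* `overdispersed_starts = TRUE`: chain $k$ starts at the ML solution
  perturbed by $\sim$2-standard-error offsets (variances jittered
  multiplicatively, kept positive), so the Gelman–Rubin contrast between
  chains is meaningful rather than cosmetic.

Two structural restrictions are enforced with explicit errors rather than
worked around: the structural matrix must be recursive (a self-feedback
loop has no closed-form conditional and is anyway unidentifiable from
cross-sectional data — prune it first), and disturbance covariances must be
diagonal (free exogenous covariances are an ML-stage feature; the conjugate
sweep assumes independent disturbances).

`gelman_rubin()` reports, per parameter with $m$ chains of length $n$:
$W$ = mean within-chain variance, $B = n \cdot$ variance of chain means,
$\hat V = \frac{n-1}{n} W + \frac{B}{n}$, $\mathrm{psrf} = \sqrt{\hat V/W}$
— the basic form, without the sampling-variability degrees-of-freedom
correction — and the Brooks–Gelman multivariate statistic
$\sqrt{(n-1)/n + \frac{m+1}{m}\lambda_1}$ with $\lambda_1$ the largest
eigenvalue of $W^{-1}B/n$ on the pooled covariance matrices. The univariate
form matches the hand-computable two-chain example
($[1,2,3,4]$ vs $[2,3,4,5] \to 1.0247$); the multivariate statistic agrees
with coda's implementation to about $10^{-4}$ on null chains.

## What the synthetic generator emulates — and what it does not

`sem_simulate()` draws $\zeta \sim N(0,\Psi)$, solves
$\eta = (I-B)^{-1}\zeta$, and emits $y = \Lambda\eta + \epsilon$. The
Rubisco fixtures (`rubisco_fixture()`) encode the two stages of the
analysis with documented constants:

* the **prior** stage: intact Large Subunit feeding dp39/dp12/dp37, dp39
  feeding dp7/dp15/dp17, the Small Subunit pair feeding dp44, RSS
  up-regulating RLS2 — with the RSS174/RSS175 pair and the dp15/dp17
  residual pair correlated at 0.926 so both multicollinear groups are
  planted above the 0.9 cutoff. The literature self-feedback loop is part
  of the prior *graph* but excluded from the generating model, because a
  self-loop is not identifiable from cross-sectional covariances and a
  generating model must be refittable.
* the **final** stage: latents `RSS` (RSS174/RSS175) and `dplat`
  (dp15/dp17), paths RSS → dp39/dp12/dp37, RLS2 → dp44, dp39 → dp7,
  dp39 → dplat. True standardized path coefficients lie in [0.5, 0.8]
  (0.60–0.75), node variances are 1 by construction, and indicator error
  variances of 0.08 give within-pair correlations of $1/1.08 = 0.926$.
  These values are implementation choices on the scale typical of
  log-abundance data, not estimates from any dataset.

The default study scale is $n = 48$ samples, matching the size of the
proteome study this workflow is designed around, so small-sample behaviour
(mediocre RMSEA, wide intervals) is exercised realistically.

What the generator does **not** emulate: 2DE spot-detection noise, missing
spots, heavy-tailed or skewed abundance distributions, and — most
importantly — the time-series structure of a senescence experiment. Samples
are exchangeable by default (an optional block covariate is the extension
point); a dynamic, time-resolved variant is out of scope. Passing tests on
this generator therefore show that the estimators and diagnostics are
correct for the model class, not that real proteome data satisfy the model.

## Problem sizes used in the validation suite

The test suite validates at the scales the claims are stated at: oracle
equivalences (OLS closed form, saturated fits, hand-computed psrf) at
$n$ in the hundreds; parameter recovery at $n = 5000$ (±0.05) and Wald
coverage at $n = 48$ over 200 replicates (95% ± 5 points); structure
recovery over 50 seeded searches at $n = 5000$; Monte-Carlo cross-checks of
the implied covariance at $2\times 10^5$ draws; and the convergence
headline at the full 4 × 20,000-iteration, $n = 48$ configuration. Pruning
calibration uses 500 null simulations (type-I error 0.05 ± 0.03).

## Known limitations

* ML only — no GLS/WLS/robust estimators, no mean structures, no
  multi-group models, no missing-data machinery beyond listwise deletion.
* The search never adds paths; a wrong prior shows up as residual misfit,
  not as a corrected graph.
* Nonrecursive structures are representable (and simulable when $I-B$ is
  invertible) but not identifiable from cross-sectional covariances and not
  accepted by the Gibbs sampler.
* Bayesian model comparison (DIC/WAIC/Bayes factors) is out of scope; the
  Bayesian stage answers "does the selected model converge and what are its
  posteriors", not "which model is best".
* Peptide-set evidence is compared ignoring the reference subunit (that is
  what lets one fragment match two near-identical subunits); interval
  evidence requires a shared named reference. Mixed-kind comparisons are an
  explicit error, and the prior-graph scan simply treats such pairs as
  non-comparable.
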