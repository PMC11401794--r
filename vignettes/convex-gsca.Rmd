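---
title: "Convex GSCA: model, algorithm and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convex GSCA: model, algorithm and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convexgsca)
```

## The model

Generalized structured component analysis (GSCA) relates $J$ observed
indicators $\mathbf z$ and $P$ components $\boldsymbol\gamma$ through three
sub-models:

$$
\boldsymbol\gamma \equiv \mathbf W'\mathbf z, \qquad
\mathbf z = \mathbf c_0 + \mathbf C'\boldsymbol\gamma + \boldsymbol\xi, \qquad
\boldsymbol\gamma = \mathbf b_0 + \mathbf B'\boldsymbol\gamma + \boldsymbol\zeta .
$$

The weighted relation model defines each component as a weighted sum of its
own block of indicators; the measurement model regresses each indicator on
its component (loadings, always estimated here — a reflective
specification); the structural model regresses components on components
(paths). Errors are residuals, not causal entities: nothing is assumed
about their correlation structure within a block.

A component is either

* **convex** — its weights satisfy $\mathbf 1'\mathbf w_p = 1$ (optionally
  also $\mathbf w_p \ge 0$) and its indicators stay on their original
  scale. Its scores then lie inside the range of its indicators' scores,
  its mean inside the range of the indicator means, and its SD in
  $[0, \max_j \mathrm{sd}(z_j)]$; a score of $x$ is interpretable as "the
  level of someone who answers $x$ on every item". Weights read as
  contribution rates when non-negative, and they are unique given linearly
  independent indicator columns (hence the estimator refuses a singular
  convex-block covariance).
* **standardized** — its indicators are standardized and the weights
  satisfy $\mathbf w_p' \boldsymbol\Sigma_p \mathbf w_p = 1$, as in classic
  GSCA. This is the right choice when a block mixes measurement scales
  (package rule: scale type is *declared*, never inferred from data).

If everything is standardized the model reduces exactly to classic GSCA;
the package exposes that comparator as `method = "standardized"`, together
with the traditional after-the-fact rescaling
$\widehat{\mathbf W}_{uni} = \widehat\Delta_z^{-1}\widehat{\mathbf W}_{std}$
(`rescale_weights_unstandardized()`), mainly to show what it does wrong:
it divides by indicator SDs, so low-variance indicators get inflated
unstandardized weights and the component SD stays pinned at 1.

## The objective and its penalty

Unstandardized blocks can live on wildly different scales, so the plain sum
of error variances would be dominated by the largest block. The estimator
minimizes

$$
f(\mathbf W, \mathbf A, \mathbf a_0)
 = \operatorname{tr}\!\big(\mathbf O\, E(\mathbf e\mathbf e')\,\mathbf O\big),
 \qquad \mathbf e = [\boldsymbol\xi; \boldsymbol\zeta],
$$

where $\mathbf O$ is diagonal and the entry of each *dependent* variable
(every indicator, and every component with an incoming path) is the
**reciprocal of the average SD of its indicator block**; non-dependent
variables get 0, standardized blocks get 1. With block SDs $[1,2,3]$ and
$[100,200,300]$, both blocks then contribute $(1+4+9)/2^2 = 3.5$ to the
null-model objective — that is the point of the penalty, and the worked
example is frozen in the test suite. The penalty divides, not multiplies:
the formal definition of the entries could be read either way, but only the
reciprocal reproduces the equal-contribution illustration.

Two consequences matter in practice:

* **Moment sufficiency.** Expanding the quadratic form shows $f$ depends on
  the data only through the indicator means and covariances. The package
  therefore fits equally from raw tables and from printed moment sets
  (`gsca_moments_set()`), and the two agree to $10^{-10}$ (tested). The
  exported `gsca_objective()` is the per-observation scale: the raw-data
  sum of squares divided by $N-1$, with unbiased ($N-1$) covariances
  throughout — pinned by the requirement that standardizing
  $\{49,50,51\}$ gives exactly $\{-1,0,1\}$.
* **Partial scale invariance.** A common affine change $a\,\mathbf z_p + b$
  of one block ($a>0$) leaves the minimized objective and all weight
  estimates unchanged; convex component means/SDs transform by the same
  map, loadings, paths and intercepts consistently. This holds exactly in
  the implementation (property-tested to $10^{-8}$) and is why a 1–10
  versus 0–100 scoring convention does not change the analysis.

## The alternating least squares algorithm

Starting from equal weights ($1/J_p$ for convex blocks; equal weights
rescaled to unit component variance for standardized ones — a deterministic
default that makes golden tests exact; random multistarts are available via
`init = "random"`), each cycle:

1. **Coefficients.** For fixed $\mathbf W$, every dependent variable's free
   loadings/paths solve their own weighted least-squares equation exactly;
   because $\mathbf O$ is diagonal, the penalty scales each equation's
   residual but not its minimizer. Intercepts are the mean equations
   $\mathbf a_0 = (\mathbf V - \mathbf W\mathbf A)'\boldsymbol\mu$.
2. **Weights**, one component at a time in declaration order. Collecting
   the terms in $\mathbf w_p$ gives the quadratic
   $c_1\,\mathbf w_p'\mathbf S_p\mathbf w_p + 2\,\boldsymbol\ell'\mathbf w_p
   + \text{const}$ with $c_1 > 0$. For a convex component this is an
   equality-constrained least-squares problem with the single constraint
   $\mathbf 1'\mathbf w_p = 1$, solved exactly by its KKT system; with
   non-negativity on, an active-set scheme over the simplex (validated
   against dense grid searches in the tests). For a standardized component
   the constraint matrix $\mathbf S_p$ *equals* the quadratic's matrix up
   to the scalar $c_1$, so the quadratic term is constant on the constraint
   ellipsoid and the classic "unconstrained solve, then renormalize to unit
   variance" recipe is the *exact* constrained minimizer — which is why the
   objective is monotone non-increasing across every update, standardized
   blocks included (tested on 100 random models at relative $10^{-12}$).

Cycles stop when the objective change drops below `tol` ($10^{-5}$ by
default, the customary GSCA tolerance; `max_iter = 1000`, non-convergence
is flagged, not raised). Single-indicator convex blocks have weight
identically 1 (the only feasible point). Standardized components carry a
sign convention (weights sum to a positive number), applied only at
convergence because a mid-cycle flip would not be objective-neutral.
Singular normal equations fall back to a tiny ridge with a warning; a
fully collinear *standardized* block is thereby still fittable (the
symmetric two-test toy relies on it), whereas a singular *convex* block is
rejected up front since its weights would not be identified.

## Fit and cross-validation indexes

With $\hat{\mathbf O}$ from the sample SDs, `gsca_fit_indices()` reports

* **FIT^UD**: $1 - $ (weighted residual SS) / (weighted centered total SS)
  over all dependent variables, evaluated from moments; 1 for a saturated
  model, 0 for the mean-only model. When everything is standardized,
  $\mathrm{FIT}^{UD} = \tfrac{T}{T_Y}\mathrm{FIT}$ with $T = P+J$ and $T_Y$
  the number of dependent variables — an identity the suite checks at
  $10^{-10}$, alongside classic FIT/AFIT (AFIT uses the
  $d_0 = NT,\; d_1 = NT - n_{par}$ degrees-of-freedom adjustment) which are
  reported only for all-standardized models.
* **FIT_M^UD / FIT_S^UD**: the same ratio restricted to dependent
  indicators (measurement) and dependent components (structural); their
  weighted numerators and denominators add up exactly to the overall
  index's.
* **R²** per dependent structural equation (unweighted).
* **GFI / SRMR** from a model-implied indicator covariance — see the
  conventions section below.
* **OPE^UD** (`gsca_ope()`): bootstrap out-of-bag cross-validation. Each
  replicate refits on a bootstrap sample (warm-started from the full-sample
  solution) and scores the weighted prediction SS on the left-out rows
  against mean-prediction SS, with the penalty and the standardization of
  standardized blocks taken from the *training* sample. 0 means perfect
  prediction; values above 1 are worse than predicting means. The
  all-standardized relation
  $\mathrm{OPE}^{UD} = \tfrac{T}{T_Y}\mathrm{OPE} - \tfrac{T-T_Y}{T_Y}$ is
  exact per replicate when every variable is dependent (the suite checks a
  two-component feedback system against an independently coded classic
  index at $10^{-10}$); with exogenous components it is a population
  identity that finite out-of-bag samples satisfy only approximately,
  because per-column denominators fluctuate — the suite checks it at a 2%
  band on a chain model and documents why.

## Conventions the indexes depend on

Choices that published tables rarely spell out are isolated and documented
here; each is a one-point change in the code.

* **Implied covariance for GFI/SRMR** (`gsca_gfi_srmr()`): the components
  jointly mediate *all* cross-block association. With
  $\Lambda = \mathbf S\mathbf W(\mathbf W'\mathbf S\mathbf W)^{-1}$ (the
  multivariate regression of indicators on all components) and
  $\hat\Phi$ the component covariance propagated recursively through the
  structural equations (exogenous components keep sample covariances;
  structural residuals uncorrelated across equations; component variances
  at their sample values), the implied matrix is
  $\Lambda\hat\Phi\Lambda'$ off-block, while within-block covariances stay
  at their sample values — within-block error covariances are free in
  GSCA, and error covariances across blocks are zero. Residuals are taken
  on the correlation metric (sample SDs), so the diagonal residual is
  zero; GFI $= 1 - SS(\mathbf R - \hat{\mathbf R})/SS(\mathbf R)$ and SRMR
  is the RMS over the $J(J+1)/2$ unique elements. Published GSCA analyses
  are not fully explicit about this construction; alternatives we examined
  (loadings-only cross-block covariances with free within-block errors, or
  diagonal error covariances everywhere) change GFI/SRMR for the worked
  customer-satisfaction example by about $.01$ and $.04$ respectively,
  which is the order of latitude one should attach to these two indexes
  when comparing against published values. The implied covariance needs a
  recursive (acyclic) structural graph; cyclic models get `NA` with the
  other indexes unaffected.
* **Bootstrap** (`gsca_bootstrap()`): percentile CIs (the GSCA-literature
  default), replicates warm-started from the full-sample fit, standardized
  weight columns sign-aligned to it by maximal inner product (convex
  columns need no alignment — sum-to-one fixes the sign), non-converged
  replicates dropped and counted with a warning above 5%. With a fixed
  seed results are bit-reproducible.
* **Surrogate data**: SEs/CIs and OPE need raw rows. For moment-only
  inputs, `draw_sample(moments, N)` generates multivariate-normal
  surrogate data matching the moments — clearly an approximation: real
  survey items are discrete and skewed, so surrogate-based SEs tend to run
  somewhat below those computed on the real rows (for the
  customer-satisfaction example, about .011 versus the published .015 for
  the focal weight).

## The simulation engine

`gsca_population()` emulates the usual recovery design: four convex
components, four indicators each, block means stepping down from
$[6,5,4,3]$ by half a point per block, three variance conditions
($[1,1,1,1]$, $[1,2,3,4]$, $[1,4,9,16]$ as SDs$^2$), three within-block
correlation patterns (`correlation_condition(1:3)`, weak to strong), and
component correlations $\in \{0, .2, .4\}$. Design choices that were
genuinely open:

* **Population weights are derived, not prescribed.** In a
  measurement-only model the fitted weights of a block depend only on that
  block's covariance, so the package takes the per-block exact-moment
  convex minimizer as the population value. That makes the construction
  self-consistent twice over: the min-norm cross-block covariance
  reproduces the prescribed component correlations through
  $\mathbf W_{pop}$ exactly (to $10^{-8}$), and feeding the population
  moments to the estimator returns $\mathbf W_{pop}, \mathbf C_{pop}$, the
  intercepts and the component means/variances to $10^{-6}$ — the
  sharpest identifiability check available, and it makes the population
  values the estimand that bias/RMSE are measured against. Prescribing
  weights manually is allowed but then the recovery target is the
  pseudo-true (population-fit) value, not the prescription.
* **Cross-block covariance** is the minimum-norm matrix satisfying the
  component-correlation constraint; positive semi-definiteness of the
  assembled matrix is verified, with an explicit error otherwise.
* **Non-normal marginals** use the third-order polynomial (power-method)
  transform with pairwise intermediate-correlation adjustment, so the
  population covariance survives the marginal change. The conventional
  skewed condition pairs skewness 1.25 with "kurtosis 3.75"; with the
  normal reference at raw kurtosis 3 that pair is *outside* the
  third-order transform's feasible region (the boundary at skewness 1.25
  is excess kurtosis $\approx 1.34$), so the package reads it as excess
  kurtosis and targets raw 6.75 — at $N=10^6$ the generated marginals hit
  skewness $1.25 \pm .02$ and preserve the covariance to $\pm .02$
  (tested). Infeasible pairs raise an error rather than silently shifting
  the target.
* **What passing recovery tests show — and what they do not.** The engine
  samples continuous, exactly-moment-matched populations in which the
  model holds by construction. Real survey indicators are bounded and
  discrete, blocks can be misspecified, and missing data are out of scope;
  recovery results here speak to the estimator's statistical behavior
  (consistency toward the pseudo-true values, error decreasing in $N$),
  not to robustness against those features. The shipped study sizes — 200
  replicates at $N \in \{100, 400, 1500\}$ for the acceptance property,
  30 replicates for unit tests — were chosen so the Monte-Carlo error is
  an order of magnitude below the thresholds being asserted (weight-family
  absolute bias below .01 at $N = 1500$).

## Numerical notes and limitations

* Tolerances: objective change $10^{-5}$ (absolute) for fitting;
  constraint satisfaction at $10^{-10}$/$10^{-8}$; ridge fallback
  $10^{-8}\max(\mathrm{diag})$ only on singular normal equations.
* Ties/degeneracies: exchangeable indicators give equal weights; a weight
  column that the objective ignores (an unused, exogenous component with no
  outgoing coefficients) is left at its current value rather than solved
  from a zero system.
* Cyclic structural graphs are estimable (each equation is still a
  regression) but warned about, and GFI/SRMR are undefined for them.
* Score *ranges* (min/max) require raw rows; moment-only fits report them
  as `NA` — a published range cannot be recovered from moments.
* Not covered by design: higher-order or multilevel components,
  categorical-indicator quantification, component interactions,
  factor-based variants, missing data, and analytic (non-bootstrap)
  standard errors.
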