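# convexgsca

Convex generalized structured component analysis (GSCA) for R: build and
test path-analytic models among *components* — weighted composites of
observed indicators — where a component can be a **convex combination** of
its unstandardized indicators, so that its scores, mean and standard
deviation stay on the indicators' original measurement scale.

Classic GSCA standardizes every indicator and component. That makes a
composite's score purely relative: it tells you where a person stands in
the sample, not whether a patient's depression is "moderate" or a
customer's satisfaction is 7 on a 1–10 scale. It also erases differences in
indicator variability — two tests scored {49, 50, 51} and {0, 50, 100} both
become {−1, 0, 1} — and the usual after-the-fact rescaling of standardized
weights (dividing each weight by its indicator's SD) inflates the influence
of low-variance indicators (weights .5 and .01 for those two tests).

`convexgsca` instead estimates, for each same-scale block, weights that sum
to one (optionally also non-negative): the component

γ<sub>p</sub> = **w**<sub>p</sub>′**z**<sub>p</sub>,  **1**′**w**<sub>p</sub> = 1

then satisfies, for every person, `min(block) ≤ score ≤ max(block)`, its
mean lies in the range of the indicator means, its SD in `[0, max block
SD]`, and a score of 3 reads as "equivalent to answering 3 on every item".
Blocks on mixed scales stay standardized (unit-variance constraint), so
both kinds of components coexist in one model.

## What it computes

* **Estimation** by alternating least squares of the objective
  `tr(O E(ee′) O)` — the sum of error variances of all dependent variables,
  each divided by the average SD of its indicator block (the diagonal
  penalty `O` stops large-scale blocks from dominating). Every update is an
  exact constrained least-squares solve, so the objective never increases.
  The whole fit runs on means and covariances, so printed moment tables are
  first-class inputs.
* **Fit indexes**: FIT<sup>UD</sup> and its measurement/structural local
  versions (share of weighted total variance of dependent variables
  explained), per-equation R², and GFI / SRMR from the model-implied
  indicator covariance; classic FIT/AFIT for all-standardized models.
* **Inference**: bootstrap SEs and 95% percentile CIs (warm-started,
  sign-aligned replicates), and the out-of-bag prediction error
  OPE<sup>UD</sup> for comparing models by predictive generalizability
  (0 = perfect, 1 = no better than predicting means).
* **Simulation**: population models with prescribed block means/SDs,
  within-block correlation patterns, component correlations, and normal or
  skewed/kurtotic marginals (third-order polynomial transform with
  intermediate-correlation adjustment), plus a Monte-Carlo engine for
  absolute-bias / RMSE parameter-recovery studies.

## Worked example: the customer-satisfaction index

The package ships the published moment set (means and covariances of 14
survey items, N = 774) and the six-component ACSI model — customer
expectations (CE), perceived quality (PQ), perceived value (PV), customer
satisfaction (CS), complaints (CC) and loyalty (CL, standardized because
its two items are on different scales):

```r
library(convexgsca)

fit <- gsca_fit(acsi_moments(), acsi_model())
fit
#> <gsca_fit> convex GSCA: 6 components, 14 indicators, N = 774
#>   converged in 5 cycles; objective = 5.30375
#>   FIT^UD = 0.712  FIT_M^UD = 0.800  FIT_S^UD = 0.433  GFI = 0.999  SRMR = 0.017

tidy(fit, "weights") |> dplyr::filter(grepl("^CS", term))
#> # A tibble: 3 × 3
#>   type   term   estimate
#>   <chr>  <chr>     <dbl>
#> 1 weight CS:z9     0.424
#> 2 weight CS:z10    0.253
#> 3 weight CS:z11    0.323

gsca_component_summary(fit)[4, ]
#> # A tibble: 1 × 5
#>   component  mean    sd   min   max
#>   <chr>     <dbl> <dbl> <dbl> <dbl>
#> 1 CS         7.13  2.35    NA    NA
```

Read: overall satisfaction (z9) contributes 42% of a unit increase in the
CS composite; the average customer sits at 7.13 on the original 1–10 scale
with an SD of 2.35 scale points — numbers a standardized analysis cannot
give. The model explains 71% of the weighted total variance of all
dependent variables (80% for the measurement part, 43% for the structural
part), and the PQ → CS path of 0.72 means a one-point rise on every
perceived-quality item predicts a 0.72-point rise in satisfaction.
`gsca_bootstrap()` adds SEs/CIs, `gsca_ope()` / `gsca_compare()` rank
competing specifications by out-of-bag prediction error, and raw-data fits
(`gsca_fit(data, model)`) add per-person scores via `gsca_scores()`.

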