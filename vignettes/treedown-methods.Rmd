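---
title: "Downscaling ALS forest inventories to tree lists: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Downscaling ALS forest inventories to tree lists: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treedown)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, the numerical
choices made where the design was genuinely open, and what the synthetic
test bed does and does not demonstrate.

## The problem

Area-based ALS inventories predict *stand-level* variables — total basal
area BA (m²·ha⁻¹), quadratic mean diameter Dg (cm), broadleaf basal-area
proportion BA_b — on a 25 m raster, but many applications (forest dynamics
models, habitat analyses, management simulators) need *individual trees*.
`treedown` bridges the two: it borrows the tree list of the most similar
field plot for each cell and transforms it so the cell attains its
predicted BA and BA_b exactly, then assigns model heights. The underlying
assumption is that the (BA, Dg, BA_b) triple is a sufficient synthetic
summary of stand structure and composition for choosing a donor plot; the
within-plot diameter distribution and species mix come entirely from the
donor.

## Stand-variable models

For BA and Dg we search, per stratum, for the ordinary linear regression
with the highest adjusted R² using at most `max_vars = 6` ALS metrics
(`fit_linear_best_subset()`). Two response transformations are supported:

* **log–log**: back-transformed predictions are multiplied by
  `exp(v/2)` — without it the lognormal back-transform is biased low by
  the factor `exp(v/2)`, where `v` is the residual variance on the log
  scale.
* **Box-Cox** on the response: `lambda` is chosen by maximising the
  profile log-likelihood on `[-2, 2]` (`boxcox_lambda()`); predictions
  apply the inverse transform with the second-order correction
  `(1 + v/2·(1−λ)/(λŶ+1)²)`. `lambda = 0` is handled as the log limit
  (the inverse formula is undefined there); predictions whose
  `λŶ + 1 ≤ 0` are clamped to the domain boundary with a warning.

BA_b lives in [0, 1], so it gets a logit-link binomial GLM with the plot
basal areas as binomial totals and both-direction stepwise AIC selection
starting from the full metric set (`fit_bab_glm()`). Its predictions are in
(0, 1) by construction. On complete separation the fit falls back to a
ridge-penalised binomial fit.

Design choices in this module that the underlying approach leaves open:

* **Search strategy.** Exhaustive subset search up to 12 candidate metrics
  (at 12 candidates and 6 variables that is ~2,500 least-squares fits),
  greedy forward selection beyond; the strategy used is recorded in the
  model object. Ties break by enumeration order — smaller subsets first,
  then column order — so selection is deterministic.
* **Residual variance.** `v` uses denominator `n − p − 1`, matching the
  unbiased estimator of the regression it corrects.
* **Transform choice.** With `transform = "auto"`, the form (none / log /
  Box-Cox) with the lowest leave-one-out RMSE wins; ties go to the simpler
  form. The default is `"none"`: on the synthetic test bed the generating
  relations are linear or log-linear and the LOOCV selection triples the
  fitting cost.
* **Stratification.** One model per stratum; strata under `min_plots = 30`
  calibration plots are merged into a pooled fallback stratum, and a model
  fitted on *all* plots handles unknown strata at prediction time. Thirty
  plots is a common floor for stable 6-variable stand-level regressions.
* **Prediction floors.** Mapped BA is floored at 0 and Dg at the minimum
  inventoried diameter (default 7.5 cm): the downscaling step divides by
  Dg and matches on it, so nonsensical nonpositive predictions must not
  propagate.

## The downscaling algorithm

Cells and plots are projected into the three-dimensional space of
min-max-scaled (BA, Dg, BA_b). Scaling is *joint* — one range per variable
across both sets — so a systematic offset between field and ALS ranges
does not distort distances. Each cell takes the nearest plot by Euclidean
distance (`match_plot()`); equidistant plots resolve to the smallest
`plot_id`. An optional forest-type constraint restricts candidates to
plots of the cell's type, falling back to the full pool (with a warning)
when none exists.

The matched plot's tree list is then transformed in four exact steps
(`generate_cell()`):

1. `α = Dg_ALS / Dg_F` rescales all diameters, so the donor's Dg reaches
   the cell's exactly while preserving every inter-species Dg ratio.
2. Each tree receives the target basal area
   `ba_tree = BA_ALS · Prop_BC · Prop_Sp · Prop_tree`
   (class share from the cell, species-within-class and tree-within-species
   shares from the plot). Summed over the plot these targets equal
   `BA_ALS` exactly whenever both classes are present.
3. The continuous per-cell weight is
   `ω/16 = 40000/(16π) · ba_tree/(α·dbh_F)²`; 16 is the area ratio between
   1 ha and a 25 × 25 m cell, so one tree fully enumerated on a 400 m²
   plot always carries weight 1.5625. Because that decimal part is a
   deterministic artefact of plot geometry, nearest-integer rounding would
   bias stem counts; instead a Bernoulli draw on the decimal part makes
   the integer weight unbiased (1.5625 → 2 with probability 0.5625).
4. Diameters are adjusted once more,
   `dbh_final = √(40000/π · ba_tree/(16 ω_int))`, so each retained record
   attains its target exactly; when rounding did not change the weight
   this reduces to `α·dbh_F`.

Open points resolved here, and how:

* **Trees rounded to weight 0** are dropped; their basal area is reported
  per cell in the diagnostics (`lost_ba`), not redistributed. The cell's
  generated BA therefore equals the prediction minus exactly that reported
  loss — an auditable shortfall rather than a hidden one.
* **Class mismatch** (the cell assigns basal area to a class the donor
  plot lacks): the missing class's share is reallocated to the available
  class with a warning, keeping total BA attainable. The alternative —
  re-matching to the nearest plot containing both classes — changes the
  matching semantics and was rejected as the default.
* **Randomness** is confined to the Bernoulli draws. Each cell uses a
  private substream seeded by a hash of the global seed and its
  `cellID25`, so output is reproducible and independent of processing
  order (and trivially parallelisable).
* **Cell Dg for height prediction** is recomputed from the generated tree
  list rather than read from the ALS map: after weight redistribution and
  rounding the list's Dg is the one consistent with the trees receiving
  heights.

## The diameter–height model

Heights follow the asymptotic species-specific form

h = 1.3 + (1 + α_site) · α_sp · (1 − e^(−α₁·Dg^α₂)) · (1 − e^(−β_sp·dbh/Dg))^γ

with `dbh/Dg` carrying the tree's social status and Dg the stand's
development stage. The curve passes through breast height (1.3 m) as
dbh → 0 and saturates at `1.3 + α_sp(1 − e^(−α₁Dg^α₂))`; `β_sp` governs how
fast a species approaches its asymptote. `α_site` is a plot-level random
effect entering multiplicatively; residuals are heteroscedastic, modelled
as a power of the fitted values.

Fitting (`fit_height_model()`) uses `nlme::nlme` with `varPower` and
maximum likelihood, exactly the estimator a forest biometrician would
reach for. Convergence of this model is start-sensitive, so a preliminary
fixed-effects `nls` fit (algorithm `"port"`, bounded; asymptote guess =
1.1 × max species height, `β = 1.5`, `γ = 1.4`, `α₁ = 0.02`, `α₂ = 1.1`)
supplies the starting values. Species with fewer than `min_obs = 100`
height observations are pooled into an `OtherSp.` category before fitting.

Passing `fixed = list(beta_sp = ..., gamma = ...)` freezes the
within-stand shape and estimates only the asymptotes and Dg response —
the borrowing scheme needed when a site's height sample covers only
dominant trees (as in the shipped Snežnik parameter set, whose `β_sp` and
`γ` come from the Bauges fit; `published_height_params("sneznik")` records
this in its `borrowed` field).

Two practical caveats, visible in the package's own simulations:

* The asymptote `α_sp` is only weakly identified when Dg does not
  approach saturation: it trades off against `α₁, α₂` with the fitted
  curve nearly unchanged. Single-dataset recovery errors of 5–15% are
  normal — of the same order as the standard errors the shipped parameter
  tables themselves report. Parameter-recovery checks therefore use a
  stratified Dg design spanning 10–55 cm.
* Heights assigned to generated trees use the population level
  (`site_effect = 0`) and no residual noise by default, yielding a
  deterministic, reproducible dataset; `add_noise = TRUE` adds varPower
  residuals for applications that need realistic height scatter.

## Validation

`loocv_workflow()` holds each plot out of *everything* — model fitting and
the matching pool — predicts its (BA, Dg, BA_b) from its co-located
metrics, generates its tree list, assigns heights, and compares observed
with generated stand variables and stem-weighted quantiles (dbh Q95,
height Q50/Q95; weighted quantiles use the left-continuous inverse of the
weighted ECDF, with per-hectare weights on the observed side and integer
cell weights on the generated side). It also reports the pure model LOOCV
RMSEs for comparison: the downscaling step adds error only through
rounding losses and matching mismatch, so the two should be close — and on
the synthetic default landscape the workflow/model RMSE ratios come out
near 1.1 for all three variables.

Dominant heights offer an additional field-data-free check:
`hdom_t()` (mean of the six tallest generated trees, counting
multiplicities) against `hdom_als()` (mean of the six highest CHM local
maxima, maxima below 5 m discarded, plateau ties excluded for
determinism). The comparison report repeats the caveat that metrics
entering the stand-variable models may correlate with the ALS dominant
height, so agreement here is necessary rather than sufficient.

## The synthetic test bed

`synthetic_config()` and its simulators produce a self-consistent world:
smooth true (BA, Dg, BA_b) fields (moving-average-filtered Gaussian noise,
logistic-squashed proportion), plots whose tree lists match their cell's
true triple *exactly* (three closed-form rescalings: class weights →
broadleaf share, global diameter scale → Dg, global weight scale → BA),
ALS metrics as stratum-specific monotone functions of the true variables
plus Gaussian noise, and cone-rendered CHMs whose local maxima equal the
tree heights.

Default conditions (chosen once, as the study conditions the package
targets): a 20 × 20 cell landscape, two acquisition strata, 300 plots of
~18 trees — plot networks behind operational area-based inventories number
in the hundreds, and matching-pool density in the (BA, Dg, BA_b) space is
what controls downscaling losses — and metric noise `sd = 0.3` calibrated
so the plot-level model LOOCV RMSEs land in the operational accuracy
regime (BA ≈ 5–7 m²·ha⁻¹, Dg ≈ 3–4 cm, BA_b ≈ 10–15 points). Diameters
follow a two-parameter Weibull (shape 2), the standard stand-modelling
choice.

What passing tests on this bed do **not** show about real data: metrics
here are low-dimensional, monotone and Gaussian-noised, plots are
error-free summaries of their cells (no co-registration error, no nested
sub-sampling noise, no measurement error), strata differ only in
coefficients, and species composition has no spatial or environmental
structure. Real acquisitions add all of these, which is why published
applications of this workflow validate against independent inventories.

## Problem sizes and runtimes

The shipped test-and-acceptance configurations were sized for a single
core: the whole-workflow LOOCV runs 300 folds with full per-fold refits
(~2 minutes), the Bernoulli Monte Carlo uses 10⁵ draws, the exact-BA sweep
1,000 random cells, and parameter recovery one 50-plot × 20-tree fit.
Larger landscapes scale linearly in cells for mapping and generation and
quadratically in plots for LOOCV.

## Known limitations

* Tree positions within cells, crown dimensions and temporal dynamics are
  out of scope; the output schema is `cellID25, sp, n, dbh, h` plus a cell-ID
  raster (ESRI ASCII grid, 25 m).
* Basal area lost with zero-weight trees is reported, not compensated;
  landscape BA is therefore biased low by the (small) summed losses.
* Strata are plain labels; polygon GIS handling and real point-cloud
  processing (LAS/LAZ, ground classification, co-registration) are not
  included — per-cell metrics are expected as tabular input, or simulated.
* The matching step reproduces donor-plot composition; it cannot invent
  species mixtures absent from the plot network.
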