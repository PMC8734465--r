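---
title: "Marked point-pattern and stand-structure analysis with standmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marked point-pattern and stand-structure analysis with standmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standmarks)
```

## What the package models

`standmarks` analyses fully mapped forest censuses of the ForestGEO type:
every woody stem at least 1 cm in diameter at breast height (dbh, measured
at 1.3 m) inside a rectangular plot is tagged, identified to species,
measured to 0.1 cm, and mapped to plot coordinates. Standing dead stems
enter the census at 5 cm. The reference geometry throughout is a
500 x 700 m (35 ha) plot gridded into 20 x 20 m quadrats, but every
function takes an arbitrary rectangular `plot_window()`.

Three questions drive the toolkit:

1. **Composition and structure.** Which species dominate, at what density,
   basal area (`pi (dbh/200)^2` in m^2) and allometric biomass, and what do
   their diameter distributions look like? Density counts *individuals*
   (multi-stemmed plants collapse to one), while basal area and biomass sum
   over every qualifying *stem* — the census convention that
   `species_summary()` implements.
2. **Spatial pattern.** Are trees of a species clustered? Are nearby
   conspecifics smaller than expected (intraspecific competition)? Are the
   sizes of two species spatially coupled (e.g. a foundation species
   suppressing or tracking its neighbours)? Three statistics answer these:
   the pair-correlation function g(r), the univariate mark-correlation
   function kmm(r), and Schlather's Moran's-I bivariate mark correlation
   I(r), each read against Monte Carlo null envelopes.
3. **Habitat and history.** How much of the spatial variation in abundance
   and size is attributable to mapped covariates — historical land-use
   classes, soils, and local neighbourhood structure? A
   conditional-inference-style regression-tree ensemble with permutation
   variable importance ranks the predictors.

## The spatial statistics

All three estimators share one kernel scheme: pair contributions at
distance `d` are spread over lags with an Epanechnikov kernel
`k_h(u) = 0.75 (1 - (u/h)^2)/h` on `|u| < h`, with bandwidth `h = 5` m by
default.

**Pair-correlation function.**

    ghat(r) = sum_{i != j} k_h(r - d_ij) w_ij / (lambda^2 |W| 2 pi r)

with intensity `lambda = n/|W|` and translation edge weights
`w_ij = |W| / ((W_x - |dx|)(W_y - |dy|))`, which are exact for rectangular
windows. Under complete spatial randomness (CSR) g(r) = 1; g > 1 is
clustering, g < 1 overdispersion. Two properties of this estimator are
worth knowing. First, using `lambda^2` rather than the unbiased
`n(n-1)/|W|^2` product biases ghat by `(n-1)/n` — 0.05% at n = 2000,
irrelevant at census scale but visible if you push n below ~50. Second, at
lags `r < h` the kernel window crosses zero distance, where no pairs can
exist, so ghat is boundary-biased low there (and the `1/(2 pi r)` factor
varies strongly across the window). Interpret lags below the bandwidth
qualitatively only; the package's own calibration checks run at `r >= h`.

**Mark correlation.**

    kmm(r) = [ sum k_h(r - d_ij) m_i m_j / sum k_h(r - d_ij) ] / mu^2

the kernel-weighted mean product of dbh marks among r-separated pairs,
normalised by the squared mean mark. Edge weights cancel in this ratio and
are not applied. kmm < 1 at a lag means trees that close together are
smaller than random relabelling would predict — the signature of
competition. The statistic is invariant to rescaling all marks by a
positive constant.

**Schlather's Moran's-I bivariate mark correlation.** For cross pairs (i
in the focal species, j in the other),

    I(r) = sum k_h(r - d_ij)(m1_i - mu1)(m2_j - mu2) / (s1 s2 sum k_h)

with marginal means and standard deviations of each species' marks (sample
sd, n-1 denominator; the choice is immaterial because I is invariant to
positive affine transforms of either mark set and flips sign under
negative slope). Values lie in [-1, 1] up to estimation noise — the kernel
ratio is not algebraically bounded, so values a few percent outside can
occur at sparse lags.

Lags with no pairs inside the kernel support return 0 with a warning
rather than NaN, so envelope machinery downstream never sees missing
values; `n_pairs` in the returned curve makes such lags easy to mask.

## Null models and envelopes

`envelope_test()` pairs each statistic with the null model that matches its
question:

* `g` with **CSR**: point positions are re-drawn uniformly, conditioned on
  the observed count (a binomial process — the null randomises "the tree
  map" holding n fixed).
* `kmm` with **random labelling**: positions fixed, all marks permuted.
* `I` with **non-focal relabelling**: positions and focal marks fixed, the
  other species' marks permuted.

With `nsim` simulations and envelope rank `k`, the pointwise envelopes are
the k-th smallest/largest simulated values per lag, a two-sided test of
exact level `2k/(nsim+1)` — 0.05 for the defaults nsim = 199, k = 5, which
is why captions conventionally call these 95% envelopes. The envelopes are
**pointwise**: with 50 lags, about 2-3 lags will poke out by chance under
the null, and the multiple-testing liberality of reading envelopes lag by
lag is well documented. A global rank-envelope option is future work;
until then, treat isolated single-lag excursions with caution.

Replicate RNG uses L'Ecuyer-CMRG substreams spawned from one master seed,
one stream per replicate, so enlarging `nsim` appends replicates without
changing earlier ones, and a fixed seed makes the whole
`EnvelopeResult` — and every pipeline artefact — byte-reproducible.
Mark-shuffling nulls reuse the observed pair geometry across replicates
(only mark sums are recomputed), which is what makes 199-replicate
envelopes cheap.

## Habitat covariates and variable importance

`focal_abundance_surface()` rasterises stem counts at 20-m resolution and
smooths with a 3x3 moving mean, truncated at plot edges (corner cells
average over their 4 existing neighbours). Sampling that surface at each
tree yields the local-abundance response. `neighborhood_features()` adds
the five neighbourhood predictors (count, mean and CV of dbh, mean and CV
of distance, all within 10 m; CVs are sample sd / mean and are flagged
`NA` below 2 neighbours). Trees within 10 m of a plot edge carry a
`border` flag — their neighbourhoods are censored — and are retained by
default with `drop_border` as the switch.

`fit_citree()` grows a regression tree in the conditional-inference style:
at each node every predictor is association-tested against the response
(correlation-type z statistic for continuous predictors; one-way
`(n-1) R^2` chi-squared statistic for categorical ones), p-values are
Bonferroni-corrected across predictors, and the node splits on the most
significant predictor only if the corrected p-value passes `alpha = 0.05`.
Separating *whether/where to split* (the test) from *how to split* (the
best RSS-reducing cutpoint or level subset) is what removes the selection
bias towards many-valued predictors that naive exhaustive search has; our
tests confirm root-only trees on pure noise in ~95% of runs. This is a
deliberately lean re-derivation of the published conditional-inference
framework — normal/chi-squared approximations instead of the full
permutation-distribution machinery — and we document it as an
approximation, not a clone. Categorical predictors split by exhaustive
level-subset search up to 8 levels, beyond that by ordering levels on
their mean response; ties in the selection statistic go to the
lowest-index column; missing predictor values follow the larger child.

`ensemble_importance()` fits `n_iter` trees (default 500), each on a
0.632 subsample without replacement, and scores each predictor by
**out-of-bag permutation importance**: the increase in held-out MSE when
that predictor's column is permuted, averaged over iterations — the
marginal loss of prediction accuracy, in squared response units. We chose
out-of-bag permutation (not conditional permutation) because it matches
that "marginal loss" reading; correlated predictors therefore share
credit, a known property to keep in mind when two neighbourhood features
move together.

## The synthetic stand generator

`generate_synthetic_census()` builds censuses with the statistical
structure the analysis assumes, with the generating truth retained so
recovery is testable:

* **Clustering** by a Thomas process — Poisson parents of intensity `rho`,
  Poisson(`mu_off`) offspring displaced by an isotropic Gaussian
  (`sigma_disp`). Parents are drawn on the window buffered by
  `4 sigma_disp`, so offspring intensity has no edge deficit. The Thomas
  pcf has the closed form `g(r) = 1 + exp(-r^2/(4 sigma^2))/(4 pi rho
  sigma^2)`, giving an analytic surface against which the estimator is
  validated.
* **Habitat filtering** by a Voronoi land-use mosaic: each species keeps a
  stem falling on class c with its affinity probability, emulating the
  blocky historical field/stand maps that structure real plots.
* **Marks**: lognormal dbh (right-skewed, reverse-J after binning — the
  regenerating-population shape), optionally with a crowding penalty
  `exp(beta0 - beta * n_10m + noise)` that drives kmm below 1 at short
  lags, or a linear spatial gradient that drives Schlather's I towards
  +/-1. Marks below the 1-cm census threshold are dropped, exactly as the
  field protocol drops them, so generated censuses always validate.

The reference configuration (`default_synthetic_truth()`) emulates a 35-ha
temperate stand: 50 species with log-spaced abundances totalling on the
order of 1e5 stems, a 12-patch 4-class mosaic, crowding marks for the 8
commonest species. What the generator does **not** emulate: swamp
hydrology and topographic gradients, dead stems, spatially correlated
measurement error, species interactions beyond shared habitat, and any
real species' allometry. Tests passing on synthetic data therefore
demonstrate estimator and pipeline correctness under known structure — not
ecological fidelity to any particular forest.

## Numerical and design choices

* **Quadrat and raster cell assignment** is half-open, `[a, a+cell)`, with
  the plot's outer maximal edges closed, so cells partition the window and
  boundary stems are never double-counted. How boundary stems were
  assigned during the original digitisation is unknowable from the data;
  this convention is the package's own and is applied identically in
  `assign_quadrats()` and `sample_raster_at_points()`.
* **One point per individual** (largest stem carries the dbh mark) is the
  default for spatial statistics, with `per = "stem"` available; the
  choice matters only for multi-stemmed shrubs.
* **Allometry is data, not code**: a CSV of two-parameter equations
  (`a dbh^b`, or its log-linear twin) with a `*` fallback row. Biomass is
  summed per stem, consistent with the basal-area rule for multi-stemmed
  plants.
* **Diameter bins** default to 5-cm classes from 1 cm, left-closed with
  the top edge folded in; `reverse_J` is operationalised as non-increasing
  binned counts — a reproducible version of a qualitative label.
* **Envelope rank** k = 5 of nsim = 199 gives exact 5% pointwise level;
  min/max bands (k = 1) are available via `rank = 1`.
* **Degenerate inputs** are contracts, not crashes: fewer than 2 points,
  absent or zero-variance marks, empty shuffle scopes, and non-increasing
  bin edges all raise informative errors; empty species yield empty
  histograms; isolated trees yield flagged-NA neighbourhood features.
* **Threads**: the CLI accepts `--threads` for interface stability but
  executes serially; results are thus trivially independent of thread
  count.

## Problem sizes used in the shipped checks

The package's validation suite runs at desk scale, chosen so the full
suite completes in minutes while every check retains statistical power:
CSR calibration of g uses 50 replicates of n = 2000 in the 500 x 700 m
window (mean over 10-50 m lags, tolerance 0.02); the Thomas closed-form
check uses 30 replicates at lags 5-50 m against 3 Monte Carlo standard
errors; brute-force O(n^2) oracle equivalence runs at n = 500 (tolerance
1e-10); envelope calibration uses 120 independent runs of nsim = 199 on
n = 120 patterns; importance recovery uses a ~2000-tree synthetic census
with 120 tree iterations. The full-plot configuration (1e5 stems, 500
iterations) runs through the same code paths via `run_pipeline()` when
you have the time budget for it.

## A worked end-to-end run

```{r pipeline, eval = FALSE}
cfg <- tempfile(fileext = ".yml")
yaml::write_yaml(list(
  seed = 42,
  window = list(width = 300, height = 300),
  paths = list(synthetic = TRUE, n_species = 6, scale = 0.05),
  lags = list(r_max = 50, h = 5),
  null = list(nsim = 199, rank = 5),
  species = list(top_n = 3)), cfg)
out <- file.path(tempdir(), "demo_run")
run_pipeline(cfg, out)
make_report(out)   # report.md + envelope and importance panels
```

## Known limitations

* Homogeneous nulls only: no inhomogeneous-intensity g(r), no
  heterogeneous-Poisson or pattern-reconstruction nulls.
* Pointwise envelopes, as discussed above.
* The tree ensemble approximates the conditional-inference framework with
  asymptotic tests; p-values at very small nodes lean on normal/
  chi-squared approximations.
* Translation edge correction assumes a rectangular window; irregular
  plot boundaries are out of scope.
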