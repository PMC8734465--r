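# standmarks

Marked point-pattern and stand-structure analysis for fully mapped forest
censuses.

ForestGEO-style plots map every woody stem ≥ 1 cm dbh in a large rectangle
(the reference geometry here is the 500 × 700 m, 35-ha Harvard Forest
plot). Because every tree is a point with a location and a size mark,
three families of questions become statistically tractable, and this
package implements the full workflow for ecologists asking them:

1. **Stand structure** — species density (individuals, with multi-stemmed
   plants collapsed), basal area `π(dbh/200)²` and allometric biomass
   `a·dbh^b` (summed over stems), diameter distributions and their
   reverse-J / unimodal classification.
2. **Spatial pattern** — kernel estimators of the pair-correlation
   function *g*(*r*) (clustering vs overdispersion, translation edge
   correction), the mark-correlation function *kmm*(*r*) (are nearby
   conspecifics smaller than expected? `< 1` signals competition), and
   Schlather's Moran's-I bivariate mark correlation *I*(*r*) (size
   coupling between species, in [−1, 1]) — each tested against 199 Monte
   Carlo null simulations (CSR for *g*; random mark relabelling for *kmm*
   and *I*) with pointwise rank envelopes (k = 5 of 199 → exact 5% level).
3. **Habitat and history** — 3×3 focal-window abundance surfaces on a
   20-m grid, 10-m neighbourhood predictors, and a
   conditional-inference-style regression-tree ensemble with out-of-bag
   permutation variable importance that ranks land-use, soil and
   neighbourhood predictors of abundance and size without the selection
   bias of mixed categorical/continuous predictors.

A synthetic stand generator (Thomas cluster processes thinned by a Voronoi
land-use mosaic, lognormal/crowding/gradient dbh marks, retained ground
truth) makes every stage testable without field data: the Thomas process'
closed-form pcf `g(r) = 1 + exp(−r²/4σ²)/(4πρσ²)` is the analytic
benchmark for the estimator.

## Worked example

Published whole-plot totals for the 35-ha reference census ship with the
package; per-hectare figures and dominance shares derive from them:

```r
library(standmarks)
tab <- stand_totals_per_ha(published_stand_totals(), area_ha = 35)
tab[order(-tab$basal_area_m2),
    c("scientific_name", "basal_area_m2_per_ha", "biomass_Mg_per_ha",
      "basal_area_share_pct")][1:4, ]
#>  scientific_name basal_area_m2_per_ha biomass_Mg_per_ha basal_area_share_pct
#> Tsuga canadensis                14.03              61.1                 33.3
#>    Quercus rubra                 9.57              75.1                 22.7
#>      Acer rubrum                 7.24              33.8                 17.2
#>    Pinus strobus                 4.45              20.7                 10.5
```

The hemlock–oak–maple–pine quartet carries 84% of plot basal area; hemlock
alone contributes 14.0 m²/ha.

A clustered pattern against its CSR envelope:

```r
set.seed(42)
w   <- plot_window(500, 700)
pat <- simulate_thomas(thomas_params(rho = 1e-4, mu_off = 50, sigma_disp = 10), w)
pat
#> marked pattern: 1870 points in 500 x 700 m window

env <- envelope_test(pat, "g", lag_spec(r = 5:50),
                     null_spec("csr", nsim = 199, rank = 5, seed = 42))
env
#> envelope test: g(r) vs csr, nsim = 199, rank = 5 (pointwise level 0.050)
#>   lags above/within/below envelope: 45/1/0
head(as.data.frame(env), 3)
#>   r observed  lower upper  call
#> 1 5    7.778 0.9377 1.048 above
#> 2 6    7.579 0.9445 1.045 above
#> 3 7    7.359 0.9472 1.047 above
```

The observed curve sits far above the envelope at short lags — the
generated clustering (theory: g(20) = 3.93 for these parameters) is
detected at essentially every lag, exactly the behaviour real overstory
species show against CSR. `plot(env)` draws the standard
observed-vs-envelope panel; `envelope_test(..., "kmm", ...)` and
`schlather_I()` follow the same pattern for mark statistics.

End-to-end runs are driven by a YAML config:

```r
run_pipeline("config.yml", "run1")   # census → summaries → envelopes → importance
make_report("run1")                  # report.md + plots, manifest-checksummed
```

See the vignette (`vignettes/stand-pattern-analysis.Rmd`) for the models,
their assumptions, and every default's rationale.

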