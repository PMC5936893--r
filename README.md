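# psgls

Joint phylogenetic–spatial generalized least squares for comparative
analysis of cross-cultural (or cross-species) data.

## The problem

Observations on related societies are not independent: countries whose
languages descend from a common ancestor inherit correlated traits
vertically, and neighbouring countries exchange them horizontally. A
regression that ignores either channel overstates its certainty and can
attribute shared history to whatever covariate happens to track it. `psgls`
fits a GLS model whose error covariance prices both channels explicitly

    y = X β + ε,   ε ~ N(0, σ² V(λ, ϕ))
    V(λ, ϕ) = γ I + λ′ Σ* + ϕ W,   λ′ = (1−ϕ)λ,   γ = (1−ϕ)(1−λ)

where Σ\* is the unit-diagonal Brownian-motion covariance implied by a dated
tree (shared root-to-ancestor path lengths), W is a spatial similarity
matrix built from pairwise haversine great-circle distances, and the
weights λ, ϕ ∈ [0, 1] measure how much of the modelled covariance is
attributable to ancestry and to proximity (γ + λ′ + ϕ = 1). The weights are
estimated by profiled maximum likelihood over an exhaustive grid (step
0.02, 51 × 51 points) and tested with likelihood-ratio tests among the four
nested models (both weights / ancestry only / proximity only / neither).
Fits can be repeated across a posterior sample of trees and summarized by
across-tree means, 95% highest-density intervals and mean p-values.

The package also ships indicator-panel preprocessing (year filtering,
within-year standardization, averaging, country ANOVA, bivariate OLS
screens) and a synthetic-data generator (Yule trees, perturbed
posterior-style tree sets, coordinates, traits with known λ, ϕ, β) so that
every stage is testable by simulation, including full parameter-recovery
experiments.

## Worked example

Simulate a trait evolved almost entirely along a 44-tip tree (λ = 0.9,
ϕ = 0), then re-estimate the weights across a 25-tree perturbed sample:

```r
library(psgls)
sim <- simulate_dataset(n_tips = 44, lambda = 0.9, phi = 0,
                        n_trees = 25, seed = 1)
ens <- fit_over_trees(sim$trees, sim$y, X = NULL, coords = sim$coords,
                      taxa = sim$tree$tip.label)
ens
#> Ensemble over 25 trees (mode: both )
#>     parameter   mean hpd_lo hpd_hi    mean_p stars
#>  lambda_prime 0.9992 1.0000 1.0000 7.643e-10   ***
#>           phi 0.0000 0.0000 0.0000 1.000e+00
#>         gamma 0.0008 0.0000 0.0000        NA
#>   (Intercept) 0.1123 0.0692 0.1486 7.928e-01
```

The ancestry share `lambda_prime` is estimated near 1 with a highly
significant likelihood-ratio test (mean p across trees ≈ 8e−10), while the
spatial share `phi` stays at 0 with p = 1: the estimator attributes the
phylogenetically simulated trait to ancestry, not to the independent
geography. A single-tree fit exposes the full likelihood surface and the
coefficient table:

```r
profile_grid_fit(sim$y, NULL, sim$sigma_star, sim$w)
#> Phylogenetic-spatial GLS grid fit (mode: both, step 0.02)
#> weights: lambda = 0.98, phi = 0  (lambda' = 0.98, gamma = 0.02)
#> logLik at ML point: -43.31432
#> LRT p-values: lambda = 1.69e-10, phi = 1.00e+00, joint = 1.38e-09
#> GLS fit (ML): n = 44  logLik = -43.31432  sigma2 = 1.1509
#>             estimate     se      p
#> (Intercept)    0.117 0.4718 0.8052
```

For real data, build the pieces from a tree file and a country table:

```r
trees  <- read_trees("trees.nex", format = "nexus")
tbl    <- read_country_table("countries.csv")     # taxon, lat, lon, ...
scores <- average_country_scores(
            standardize_by_year(filter_years(indicator_panel(tbl, "hdi"))))
ens    <- fit_over_trees(trees, scores[tbl$taxon], X = religion_design(tbl),
                         coords = tbl)
```

See the vignette (`vignettes/phylospatial-gls.Rmd`) for the model's
assumptions, the spatial-similarity transform, boundary behaviour of the
LRTs, and what the simulation-based tests do and do not establish.

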