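---
title: "Joint phylogenetic and spatial GLS: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint phylogenetic and spatial GLS: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psgls)
```

## The problem

Cross-cultural (and cross-species) observations are not independent.
Countries whose languages descend from a common ancestor inherit correlated
institutions, norms and technologies; countries that are geographically
close exchange them horizontally. A regression of, say, a development
indicator on a policy variable that ignores either channel of
non-independence produces overconfident coefficients and can mistake shared
history for a causal effect. `psgls` implements a generalized least squares
model that prices both channels at once and lets the data decide how much of
the residual covariance each one carries.

## The model

For $n$ taxa (countries, societies, species) with response $y$ and design
matrix $X$,

$$ y = X\beta + \varepsilon, \qquad
   \varepsilon \sim \mathcal{N}\!\left(0,\; \sigma^2 V(\lambda, \phi)\right), $$

$$ V(\lambda,\phi) \;=\; \gamma I \;+\; \lambda' \Sigma^{*} \;+\; \phi W,
   \qquad \lambda' = (1-\phi)\lambda,\quad \gamma = (1-\phi)(1-\lambda). $$

* $\Sigma^{*}$ is the Brownian-motion trait covariance implied by a dated
  tree — entry $(i,j)$ is the shared root-to-ancestor path length of tips
  $i$ and $j$ — rescaled to unit diagonal (`phylo_covariance()` then
  `normalize_covariance()`).
* $W$ is a spatial similarity matrix with unit diagonal built from pairwise
  great-circle distances (`distance_matrix()`, `spatial_similarity()`).
* $\lambda \in [0,1]$ weights ancestry, $\phi \in [0,1]$ weights proximity.
  After reparameterization the three shares $\gamma + \lambda' + \phi = 1$
  partition the *modelled* covariance into independent, phylogenetic and
  spatial proportions. They are proportions of covariance, not of explained
  variance.

### Why a unit-diagonal convention

With all tips contemporaneous (an ultrametric tree) the raw diagonal of
$\Sigma$ is a constant $h$, and the classical writing of the model,
$(1-\phi)[(1-\lambda)h + \lambda\Sigma] + \phi W$, differs from ours only by
the global factor $h$, which the profiled scale $\sigma^2$ absorbs. We
normalize $\Sigma$ to unit diagonal anyway, for two reasons: it makes the
three components commensurable even when a supplied tree is slightly
non-ultrametric, and it makes $\lambda$, $\phi$ directly interpretable as
covariance proportions. This is a convention of this package; with
ultrametric input it is exactly equivalent to carrying $h$.

### The spatial similarity transform

A distance matrix itself cannot act as a covariance (zero diagonal, values
growing with separation), so a decreasing unit-diagonal transform is
required. The default is linear decay, $w_{ij} = 1 - d_{ij}/d_{\max}$, with
$d_{\max}$ always taken from the supplied matrix; an exponential kernel
$\exp(-d_{ij}/\rho)$ is available via `spatial_similarity(transform =
"exponential")` (default range $\rho = d_{\max}/3$). The linear form keeps
the farthest pair exactly at similarity 0 and needs no tuning parameter,
which is why it is the default; the results of any analysis should be read
as conditional on this choice. The linear transform is not guaranteed
positive semidefinite — see *Numerical choices* below for how the fitter
handles that.

Distances use the haversine formula on a sphere of radius 6371 km;
coordinates are decimal degrees. This is a physical-distance proxy: it does
not attempt climatic similarity or travel cost.

## Estimation

$\beta$ and $\sigma^2$ have closed-form maximum-likelihood solutions given
$V$; $\sigma^2$ is profiled analytically (ML, denominator $n$), so the only
free covariance parameters are $(\lambda, \phi)$. These are estimated by an
exhaustive grid search with increment 0.02 — 51 points per active axis,
2601 joint evaluations — rather than a hill climber, because the likelihood
surface in $(\lambda, \phi)$ can be ridged when ancestry and proximity are
themselves correlated, and the exhaustive grid is immune to local optima at
this dimension. Exact ties on the surface resolve to the smallest $\lambda$,
then the smallest $\phi$: parsimony toward the independent-errors null.

Significance of each weight comes from likelihood-ratio tests among the
four nested models (both weights, ancestry only, proximity only, neither):
the test of $\lambda$ compares the joint fit against proximity-only (1 df),
the test of $\phi$ against ancestry-only (1 df), and the joint test against
independent errors (2 df). The plain $\chi^2$ reference is the default even
though the null pins a weight to the boundary of its range, which makes the
test conservative; simulation below quantifies by how much. A
boundary-adjusted mixture reference ($\tfrac12\chi^2_0 + \tfrac12\chi^2_d$)
is available (`null = "mixture"`) but off by default, so that reported
p-values err on the safe side.

Coefficient standard errors use the unbiased residual variance
$\mathrm{RSS}_V/(n-k)$ and a $t$ reference with $n-k$ degrees of freedom;
at $\lambda = \phi = 0$ the fit therefore reproduces ordinary least squares
inference exactly, which is one of the package's acceptance properties. The
$t$ reference (rather than normal) is deliberate at the design scale of
$n = 44$ observations.

### Tree ensembles

Phylogenies are estimated objects. `fit_over_trees()` repeats the grid fit
across a (posterior) sample of trees — the spatial matrix is computed once,
since coordinates do not depend on the tree — and reports, per parameter,
the across-tree mean, the empirical 95% highest-density interval, and the
across-tree mean p-value with significance stars at 0.05/0.01/0.001. The
HPD is the shortest contiguous window of the sorted per-tree estimates, with
no kernel smoothing: weight estimates live on a 0.02 grid, and smoothing a
grid-discrete sample would manufacture precision. Summaries are
order-independent, so per-tree fits may be executed in any order.

## The synthetic-data generator

Every stage above is exercised against data with known truth, generated by
the package itself:

* `simulate_tree()` — pure-birth (Yule) trees rescaled to unit depth, the
  desk-scale stand-in for a dated language phylogeny; 44 tips is the default
  scale throughout because that is the sample size the model is designed
  around.
* `simulate_tree_set()` — emulates a posterior sample by multiplying every
  edge by a lognormal factor (sdlog 0.1 by default) and re-stretching
  terminal branches so trees stay ultrametric: branch-length uncertainty on
  a fixed topology.
* `simulate_coordinates()` — uniform points in a Eurasian-scale box
  (latitude 5–65, longitude −10–95), matching the geographic footprint the
  model targets.
* `simulate_trait()` — multivariate-normal draws with mean $X\beta$ and
  covariance $\sigma^2 V(\lambda,\phi)$, via the Cholesky factor of the
  same $V$ the fitter uses.
* `identifiability_experiment()` — the recovery loop: for each generating
  $(\lambda, \phi)$ it simulates replicate traits on one tree + coordinate
  set and re-estimates, reporting estimate means/SDs and LRT rejection
  rates.

What the generator does *not* emulate: topological uncertainty across the
tree sample, non-Gaussian traits, measurement error in coordinates, and any
dependence of the spatial process on landmass shape. Passing recovery tests
therefore show the estimator is consistent *under its own assumptions*, not
that those assumptions hold for any particular empirical dataset.

Under the default conditions ($n = 44$, $\sigma^2 = 1$, intercept-only
design) the package's acceptance suite verifies: a trait generated with
$(\lambda, \phi) = (0.9, 0)$ is recovered with mean $\hat\lambda \in [0.8,
1]$ and mean $\hat\phi \le 0.2$ over 200 replicates, and symmetrically a
$(0, 0.9)$ trait with mean $\hat\phi \ge 0.7$, mean $\hat\lambda \le 0.2$;
an i.i.d. trait rejects the ancestry LRT at the 5% level in at most 8% of
500 replicates (the boundary conservatism noted above in fact keeps the
empirical rate near 1%); and a binary covariate with effect −0.7 at
$\sigma^2 = 0.25$ is recovered within ±0.1 on average over 100 replicates.
These replicate counts (200/500/100) are the package's chosen simulation
sizes: large enough that the Monte-Carlo error of each summary is several
times smaller than the acceptance band it must land in.

## Indicator preprocessing

For country-by-year development panels the package fixes this order:

1. `filter_years()` — drop years missing for more than one country
   (`max_missing = 1`);
2. `standardize_by_year()` — z-score across countries within each retained
   year ($n-1$ denominator), removing secular trends;
3. `average_country_scores()` — per-country mean over available years.

The order matters (averaging before standardizing weights years unequally
when data are missing), and a test asserts that permuting it changes the
result. `country_anova()` quantifies whether collapsing years is defensible:
a one-way ANOVA of values by country, with $\eta^2 =
SS_{between}/SS_{total}$. It runs on raw values by default —
`standardized = TRUE` switches to within-year z-scores — because the
variance-decomposition question ("is a country's level stable across
years?") is about the raw panel; the package exposes both since either
reading of the pipeline is defensible. `bivariate_ols()` provides the
standard single-predictor screens with $t$-based intervals. In regression
designs the "other" religion category is the complement and is excluded
(`religion_design()`) to avoid the dummy-variable trap; judgement calls
about individual countries' coding belong in the input table, not in code.

## Numerical choices

* **Non-PSD spatial matrices.** The linear similarity transform can have
  small negative eigenvalues. During a grid search, any point where the
  combined $V$ fails its Cholesky factorization gets log-likelihood
  $-\infty$ and drops out of the argmax; only if every point fails is it an
  error. When a single $V$ is requested directly
  (`combine_covariance()`), a smallest eigenvalue in $(-10^{-8}, 0]$ is
  treated as numerical noise and repaired by adding
  $|\text{min eig}| + 10^{-10}$ to the diagonal; anything below $-10^{-8}$
  is a hard error, because silently repairing a substantially indefinite
  $W$ would change the model.
* **Degenerate inputs.** Zero-length terminal branches are allowed; a zero
  root-to-tip depth is an error (the normalization would divide by zero).
  Years with zero cross-country spread cannot be standardized. Responses or
  covariates with missing entries are dropped listwise, with the covariance
  matrices subset consistently and a message recording the row count.
* **Performance.** For fixed $(\Sigma^*, W, X)$ the grid's Cholesky factors
  and whitened designs are computed once and reused across replicate
  responses, so recovery experiments cost one triangular solve per grid
  point per replicate. This is an implementation detail: every grid point
  is still an exact profiled-ML evaluation.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
sim <- simulate_dataset(n_tips = 44, lambda = 0.9, phi = 0,
                        n_trees = 25, seed = 1)
ens <- fit_over_trees(sim$trees, sim$y, X = NULL, coords = sim$coords,
                      taxa = sim$tree$tip.label)
ens$summary
```

The `lambda_prime` row should dominate (`mean` near 0.9 with a small HPD)
and `phi` should sit at or near zero — the estimator attributing a trait
evolved along the tree to ancestry, not to the (independent) geography.

## Known limitations

* The grid never interpolates: estimates are multiples of the step (0.02 by
  default), and the HPD of an ensemble inherits that granularity.
* The spatial transform is a modelling choice the data cannot fully
  adjudicate; analyses that hinge on the precise value of $\phi$ should be
  repeated under the exponential kernel.
* Likelihood-ratio p-values use a conservative reference at the parameter
  boundary; borderline significance near $p = 0.05$ should be read
  accordingly.
* No support for non-Gaussian responses, within-taxon replicates, or
  reticulate (network) ancestry.
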