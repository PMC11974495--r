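---
title: "Models and methods: metacommunity assembly of beach meiofauna"
author: "metasandy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: metacommunity assembly of beach meiofauna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Sandy-beach meiofauna — microscopic sediment invertebrates in the ~40 µm to
1 mm range — live across one of the sharpest environmental gradients on
Earth, the few tens of metres between dune foot and low-tide line.
Metabarcoding makes it feasible to census hundreds of these taxa at once,
and metacommunity theory asks which processes assemble the observed
communities: *species sorting* along environmental gradients, *spatial
processes* (dispersal limitation or spatially structured environments), or
*biotic associations* (co-occurrence structure left after environment and
space are accounted for, which may reflect interactions or unmeasured
covariates).

`metasandy` implements the complete analysis chain for this question on
presence/absence community matrices derived from OTU read-count tables:

1. **Preprocessing** (`preprocess_community()`): per-sample relative-abundance
   filtering, depth filtering, replicate merging, taxonomy thresholds,
   occupancy filtering.
2. **Covariate selection** (`correlation_prune()`, `vif_stepwise()`).
3. **Generalised dissimilarity modelling** (`fit_gdm()`): community turnover
   against environmental differences and geographic distance.
4. **Joint species distribution modelling** (`fit_jsdm()`): a Monte-Carlo
   multivariate probit with a spatial trend surface and a low-rank latent
   species covariance.
5. **Internal-structure variation partitioning** (`partition_assembly()`):
   per-site and per-OTU allocation of explained variation to environment,
   space and biotic association, with median quantile regressions of the
   component shares against site distinctiveness
   (`internal_structure_analysis()`).

A seeded generator (`simulate_metacommunity()`) emulates the full study
design so that every stage is testable without field data.

# Preprocessing

The filters mirror standard metabarcoding practice for tag-jump and
contamination control, with strict inequalities throughout:

* Entries `< 0.03%` of a sample's reads are zeroed *per sample*
  (`min_rel = 0.0003`). Tag jumping deposits a small fraction of one
  sample's reads into another, so the artefact is a per-sample phenomenon;
  removing whole OTUs table-wide is available via
  `scope = "table"` for users who read the rule the other way.
* Samples with `< 3000` total reads are dropped.
* The three transect replicates per tidal level are merged by **summing**
  counts (`merge_mode = "sum"`). Since the downstream matrix is binarised,
  summing is equivalent to the union of presences; the `union` mode makes
  that explicit.
* Taxonomy thresholds are strict: identity `> 97%` species, `> 95%` genus,
  `> 90%` family, `> 85%` order; at or below 85% an OTU is unassigned and
  excluded, as are OTUs flagged non-meiofauna.
* OTUs present in fewer than 10 composite samples are dropped — joint
  occurrence models are sensitive to false-negative-riddled rare OTUs.

# Covariate selection

Pairwise Pearson correlation pruning (`|r| > 0.7`, greedy: from the worst
pair drop the member with the larger mean absolute correlation) is followed
by stepwise VIF exclusion. A VIF threshold below 1 is impossible
(`VIF = 1/(1-R²) ≥ 1`), so the package defaults to `vif_max = 2`, the value
the retained covariate sets in this literature actually satisfy; the
threshold is configurable.

Geographic distances are haversine great-circle distances on a sphere of
radius 6371 km. *Distinctiveness* — used as a regression predictor in the
internal-structure analysis — is a site's mean distance to all other sites
(Euclidean on the standardised covariates, or the km matrix for the spatial
version), z-scored with the population standard deviation so the scores
satisfy `sum(z²) = n`. Distance to the centroid is available as an
alternative (`method = "centroid"`). The package computes distinctiveness
on the retained, standardised covariates.

# Generalised dissimilarity modelling

Pairwise Jaccard dissimilarity `d` is modelled as
`d̂ = 1 − exp(−η)` with

```
η = α + Σ_p Σ_k β_pk |I_pk(x_pi) − I_pk(x_pj)|,   α, β ≥ 0
```

where `I_pk` are monotone I-splines (default `K = 3` per predictor, knots at
the 0/50/100-percentiles of the observed values, order-2, i.e.
piecewise-quadratic; `K = 1` degenerates to the linear ramp). Geographic
distance enters through its own I-spline basis evaluated on the pairwise km
distance itself. The binomial-type deviance
`Σ 2[d ln(d/d̂) + (1−d) ln((1−d)/(1−d̂))]` (with `0·ln 0 ≡ 0`) is minimised
by L-BFGS-B under non-negativity bounds, with predictions clipped to
`[1e−9, 1−1e−9]` inside logarithms only; site pairs are weighted uniformly.
The intercept-only model supplies the null deviance, and
`% deviance explained = 100(1 − D/D₀)`; when the null deviance is itself
(numerically) zero — all observed dissimilarities equal — the percentage is
defined as 0. Predictor importance is the sum of I-spline coefficients, so
a flat (zero-importance) predictor has a flat partial-response curve.

The I-splines are evaluated through the classic identity with B-splines one
order higher (tail sums of `splines::splineDesign()` bases); the test suite
checks interior values against direct quadrature of recursively-defined
M-spline densities.

# The joint species distribution model

Occurrence is multivariate probit: site `i` holds species `j` iff

```
a_j + (X B')_ij + (S G')_ij + (L h_i)_j + ε_ij > 0,
h_i ~ N(0, I_r),  ε_ij ~ N(0, 1)
```

with `X` the standardised covariates, `S` the second-order trend surface of
the scaled coordinates (columns `x, y, x², y², xy`), and `L` the `S × r`
factor loading matrix implying the species covariance `Σ = L L' + I`,
reported as the correlation matrix `R`. The site integral over `h_i` has no
closed form; it is estimated by Monte Carlo:

```
log P(y_i) ≈ log (1/M) Σ_m Π_j Φ((2y_ij − 1)(μ_ij + (L h_m)_j))
```

computed with log-sum-exp stabilisation. Draws are **antithetic**
(`h` paired with `−h`) and **moment-matched** (columns rescaled to exact
unit sample variance) — both classical variance-reduction devices that
roughly quintuple the effective sample size for these smooth integrands.

**Optimisation.** Adam on the analytic gradient, 500 iterations by default,
with a plateau scheduler that multiplies the learning rate by 0.9 after 10
non-improving iterations. The Monte-Carlo draws are **resampled every
iteration**. This is a deliberate choice: with a single fixed draw the
latent loadings overfit that draw's atoms — each site aligns its latent
variable with the nearest fixed `h_m`, and we measured the loading norms
inflating roughly two-fold with the fixed-effect coefficients dragged along
(slope ≈ 3.9 against truth). Resampling makes the objective an unbiased
stochastic estimate whose noise Adam averages out; the whole procedure
remains deterministic given the `jsdm_spec()` seed. Initialisation
warm-starts the
intercepts and fixed effects from independent per-species probit GLMs
(computed on a maximal linearly independent feature subset, coefficients
clipped to ±4 against separation) and small random loadings.

`M = 100` draws during fitting and `M = 10000` for the final reported
log-likelihood are the defaults; the final evaluation is chunked so memory
stays bounded. The default latent rank is `⌈S/2⌉`.

**Identifiability.** `L` is identified only up to orthogonal rotation —
`Σ`, `R` and the likelihood are rotation-invariant, which the tests assert
— so loadings themselves are never interpreted, only `R`. On a perfectly
straight coastline the trend surface is rank-deficient (`y` is affine in
`x`); fitting is unaffected, and the Wald machinery detects aliased columns
and reports their standard errors as missing. Note the study design also
confounds smoothly varying environment with space: a second-order
polynomial in position can absorb a long-range environmental gradient, and
the Shapley partition (below) then genuinely splits that credit. Parameter
recovery is therefore validated under short-range environmental
autocorrelation (`gp_range_km = 15`), where the components are
identifiable.

**Inference.** Standard errors come from the empirical (outer-product,
"BHHH") information of the per-site scores, block-diagonal per species over
that species' intercept, environmental and spatial coefficients, with `L`
held fixed (a profile approximation that ignores latent-factor
uncertainty). Star codes are `*` 0.05, `**` 0.01, `***` 0.001, with no
multiple-testing correction. On pure-noise communities the resulting Wald
tests hold their nominal size; the acceptance band for the measured
rejection rate is set a priori at [0.02, 0.09] around the nominal 0.05,
covering binomial noise over the simulated tests plus the usual mild
small-sample anticonservatism of Wald tests.

**Pseudo-R².** McFadden, `1 − logL/logL₀`, against the exact closed-form
intercept-only probit (`a_j = Φ⁻¹(prevalence)`); Nagelkerke (computed per
binary observation) is also reported since turnover studies do not always
name their variant.

**Associations.** The biotic-association matrix keeps off-diagonal entries
of `R` outside the 2.5th–97.5th percentile band of all off-diagonal values
(the 5% most extreme positive and negative associations), masks the rest,
and orders rows by higher-taxon group.

# Internal structure: variation partitioning

Eight models — every subset of {environment E, space S, biotic covariance
C}, an excluded component's parameters removed entirely (no C means rank
0) — are fitted under the same specification and seed. Per-site McFadden
R² against the exact null gives each subset a per-site value, and the
three components' contributions are allocated by **Shapley averaging** over
the 3! orderings. This allocation is exact by construction: contributions
sum to the full-model per-site R² (efficiency), are symmetric in the
labels, and reduce to solo gains when components are additive — all
asserted to 1e−9 on every run. Shares are absolute contributions
normalised to sum 1; a site with all-zero contributions is flagged and
excluded from the regressions. Per-species values use the per-species
marginal Monte-Carlo likelihood under the same draws, since the joint
likelihood does not factor over species.

The per-site/per-OTU resolution is the point: rather than one global
variance decomposition, the analysis asks *where* and *for whom* each
assembly process dominates, then regresses the per-site component shares on
environmental distinctiveness, spatial distinctiveness, OTU richness and
each covariate using **median (τ = 0.5) quantile regression** — shares are
bounded and non-normal, so the conditional median is the right summary.
The pinball loss is minimised by ε-annealed iteratively reweighted least
squares followed by an interpolation polish (an optimal median fit passes
through p data points); the suite verifies coefficients against exhaustive
grid search. P-values come from a seeded case-resampling bootstrap (1000
resamples by default) as twice the smaller tail proportion of the bootstrap
slope distribution around zero. The default polynomial degree is 2, since
share-versus-gradient responses in this literature are visibly curved;
degree 1 is used where only a monotone trend is asked about.

# The synthetic generator

`sim_config()` defaults emulate the targeted study design: 24 beaches along
a 650 km coastline (straight segment between (3.5°E, 51.5°N) and (8.5°E,
55°N) — monotone coordinates are what matters), 3 transects × 8 tidal
levels per beach (576 physical samples, 192 composites), with
`missing_fraction` available to mimic field losses (the emulated study
retained 550 of 576). Beach-level covariates are a Gaussian process along
the coast with exponential covariance (range 100 km by default — real
shorelines are autocorrelated, and this deliberately reproduces the
space/environment confounding discussed above; the range is a knob).
Distance from low tide runs equidistantly 100..0 within every transect.
Occurrence follows exactly the probit model the fitting side assumes — the
generative twin — with component strengths set by `env_scale`,
`spatial_scale`, `biotic_scale` (each the SD of that component's total
contribution to the linear predictor).

Read counts add the noise the preprocessing filters are designed to remove,
and only that noise, so the filters provably undo it: present OTUs get
log-normal relative abundances floored at 0.0012 (every genuine occurrence
stays above the 0.03% filter after depth scaling), absent OTUs get
Bernoulli contamination strictly below 0.03% of the realised sample total,
sample depths are log-normal truncated at ≥ 3334 reads (so a single read is
always below 0.03%) except for a configurable fraction forced under 3000
reads, which the depth filter removes. The round-trip identity — simulate,
filter, recover the planted matrix exactly on retained OTUs and samples —
is the generator's key integration test.

What the generator does **not** emulate: sequence-level artefacts (PCR
bias, chimeras), abundance information (the models are presence/absence by
design, because read abundance is not a reliable organism-abundance proxy),
non-probit link misspecification, and real coastline geometry. Passing
tests therefore demonstrate correctness of the estimators under the model's
own assumptions, not robustness to their violation.

# Problem sizes and budgets

The validation suite uses deliberately scaled simulations: parameter
recovery at 200 sites × 30 species × rank 5 (unit per-entry environmental
effects, no spatial component, short-range environmental autocorrelation);
type-I error over 20 seeds of 100-site × 8-species pure-noise communities;
three assembly regimes (environment-, space- and covariance-dominant) at
192 sites with 24–32 species, asserting that the matching component has the
largest median share and that the planted directional trends (E share
rising with environmental distinctiveness under sorting, S share rising
with spatial distinctiveness under dispersal limitation) are recovered as
positive, significant median-regression slopes. The acceptance script runs
the full pipeline at the study geometry with 80 species, rank 8, M = 50 and
300 iterations. These sizes are the package's reference configurations;
they keep a complete run on a single CPU in the minutes range while leaving
all statistical conclusions stable across seeds.

# Known limitations

* Standard errors ignore uncertainty in `L`; intervals for fixed effects
  are mildly optimistic when the latent structure is strong.
* The Monte-Carlo likelihood is a consistent but noisy estimate; reported
  log-likelihoods carry O(M^{-1/2}) error (with `M = 10⁴` and variance
  reduction this is far below any decision threshold used here).
* McFadden and Nagelkerke pseudo-R² can differ substantially; comparisons
  across studies must match variants.
* The Shapley partition inherits the identifiability limits of its
  components: where space can mimic environment, credit is genuinely split,
  and no allocation scheme can undo that.
* Quantile-regression bootstrap p-values are approximate at small n; with
  fewer than ~30 sites, treat significance flags as indicative.
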