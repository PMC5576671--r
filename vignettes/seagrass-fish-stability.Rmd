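---
title: "Methods: seasonal stability of seagrass fish communities under protection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal stability of seagrass fish communities under protection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seastab)
```

## The question and the design

Marine protected areas (MPAs) are expected to buffer communities against
disturbance. In East African seagrass meadows the dominant disturbance cycle
is the monsoon: short rains (SR), long rains (LR) and a dry season (D)
reshape both fishing activity and seagrass habitat within a single year.
`seastab` implements a complete analysis chain for asking whether protection
dampens that within-year variability in seagrass-associated fish
communities.

The survey design the package models is a repeated underwater visual census:
four sites (two MPA, two open-access), each surveyed by replicate 25 × 4 m
belt transects (10/7/10/10 per site) in each of the three seasons —
(10+10+10+7) × 3 = 111 transect records, 51 in MPAs and 60 in open-access
sites. Every fish is identified, counted, and its length recorded to the
nearest 5 cm; seagrass cover is estimated to the nearest 10% in six 0.25 m²
quadrats per transect, averaged before analysis. Densities are reported per
100 m², so with the default transect area density equals the raw count.

Fish are staged into juveniles, subadults and adults by species-specific
length cut-points with half-open intervals ([0, c1) juvenile, [c1, c2)
subadult, [c2, ∞) adult), so boundary lengths deterministically join the
upper class. Published stage tables are rarely available for whole
assemblages, so the default cut-points are c1 = Lmax/3 and c2 = 2·Lmax/3
from the species' maximum length — a standard fraction-of-maximum staging —
and can be overridden per species via `cut1_cm`/`cut2_cm` columns in the
species table.

## The synthetic community generator

Raw transect data for surveys of this kind are rarely deposited, so the
package carries a first-class generator (`generator_config()`,
`generate_survey()`) whose defaults *are* the study conditions every
simulation-based test runs under. Counts for species *k* on a transect of
site *s* (management *M*) in season *t* are negative binomial with

log μ = α_k + u_s + γ_kt + β_k · z(V̄) + φ_M · f_t

* α_k — species baseline log density, N(log 0.5, 1.1²): a long-tailed
  assemblage of ~40 species totalling ≈ 40–50 fish per 100 m² transect,
  the magnitude typical of seagrass (not reef) fish surveys.
* u_s — site effect, N(0, 0.2²).
* γ_kt — species-specific seasonal response, N(0, 0.15²) centred per
  species: moderate idiosyncratic seasonality (growth, recruitment,
  migration) shared by both management levels.
* β_k · z(V̄) — seagrass affinity times the transect's observed mean cover,
  standardized by the design-wide true-cover moments; β_k ~ N(0.3, 0.15):
  cover is, on average, a positive driver of fish density.
* φ_M · f_t — a synchronous multiplier common to *all* species with seasonal
  shape f = (+1, 0, −1) over (SR, LR, D), amplitude φ_MPA = 0 and
  φ_open = 0.4. This is the unselective, monsoon-following fishing signal:
  it moves every species together and only outside MPAs.

Quadrat covers are beta-distributed around a site mean (65/60% in MPA
sites, 55/50% in open sites) displaced by a management-scaled seasonal
amplitude (shape (−1, +1, 0); a_MPA = 0.03, a_open = 0.12 of cover), then
rounded to 10% steps — the field recording resolution. The open-access
amplitude being four times the MPA amplitude emulates the more seasonally
variable cover of fished meadows. φ and the amplitudes are calibration
knobs, not estimates: the field literature documents the direction of both
mechanisms but not their size, and the defaults were chosen once to make the
generator exhibit the documented management contrast at a realistic
signal-to-noise level.

Two documented configurations matter downstream:

* the **default contrast** (φ_open > 0, a_open > a_MPA) drives every
  stability and synchrony comparison;
* the **mediation configuration** (`season_sd = 0, phi_open = 0`, default
  β) removes all direct seasonal forcing on fish, so the only seasonal path
  is season → cover → fish; it is the ground truth for the structural
  equation model recovery checks.

`ground_truth()` returns the closed-form expected density per species ×
site × season, evaluated at the expected cover. The curvature term from
quadrat cover noise (E exp(βz) > exp(βE z)) is deliberately neglected; at
the default noise level it biases expectations by under 1%, well inside the
Monte-Carlo tolerance the recovery test uses.

What the generator does *not* emulate — and hence what passing tests cannot
show about real data: spatial structure within meadows, movement between
sites, recruitment pulses, observer error in counts or lengths, and
between-year variation. It generates exactly the dependence structure the
analyses assume (site random effects, cover mediation, synchronous
forcing), which is what makes it a fair ground truth for the machinery and
nothing more.

## Univariate models

Per-transect responses (total/juvenile/subadult/adult density, species
richness, Shannon H′ in nats) are square-root transformed (densities only)
and z-standardized over all 111 transects jointly — not per group — so
coefficients are comparable across responses. Standardization uses the
sample standard deviation, as R's `scale()` would.

`fit_lmm()` fits season × management with a site random intercept. "Site
nested within management" collapses to a plain site intercept because site
labels are unique across management levels. Estimation is REML for
estimates, ML for the likelihood-ratio validation against the random-only
null. Per-term F tests are marginal (Type III) with Satterthwaite
denominator df by default; a `ddf = "residual"` option (n − p) is provided
and tagged, since reported tables in this literature often use the residual
convention. Marginal and conditional R² follow the standard mixed-model
variance decomposition (`nakagawa_r2()`), Tukey all-pair season contrasts
use estimated marginal means with single-step adjustment (within each
management level when the interaction is present), and `vif()` screens
candidate covariates — seagrass cover is collinear with season by
construction, which is exactly why its influence is handled by the
structural equation model rather than as a covariate.

A caveat the package surfaces rather than hides: with only four sites, the
χ² reference of the likelihood-ratio test is anticonservative for the
between-site management term (the effective sample size for that term is
the number of sites, not the number of transects). The calibration tests
therefore verify the LRT machinery in its asymptotic regime (60 sites),
and inference on management from four sites should lean on the permutation
comparisons below.

## Community structure

Bray-Curtis dissimilarities are computed on site-level summed abundances
(one value per species × site × season). Two all-zero samples are defined
to be at distance 0 — the convention that keeps rare age-class tables free
of NaN.

`permanova()` partitions the Gower-centred inner-product matrix by
sequential (Type I) sums of squares in the order season, management,
interaction (configurable), and tests each pseudo-F against label
permutations constrained to shuffle only within sites (`strata = "site"`),
respecting the repeated seasonal measurement of the same sites. The
p-value is (1 + #{F* ≥ F}) / (1 + n_perm), never zero; the permutation
matrix is returned so the strata constraint is assertable draw by draw.
`simper()` decomposes the between-group dissimilarity into per-species
contributions averaged over all between-group sample pairs; contributions
sum exactly to the mean between-group Bray-Curtis.

`nmds()` is a non-metric MDS by Guttman-transform majorization with
isotonic regression (Kruskal stress-1), k = 2, 20 restarts (metric-MDS
start first, then random), tolerance 1e-7, at most 300 iterations per
restart. An update that fails to decrease stress terminates the restart,
so the recorded stress trace is non-increasing by construction. The
returned configuration is centred, principal-axis rotated, and rescaled so
configuration distances are on the scale of the input dissimilarities —
stress is invariant to all three, but it makes trajectory metrics
comparable across ordinations. Dimensionality and restart counts are
package choices (this literature rarely reports them); simulation-heavy
tests reduce restarts to 5, which on 12-point configurations reaches the
same stress.

## Trajectory stability

For each site, its three seasonal ordination points (in chronological
order SR → LR → D) yield four variability metrics — the inverse of
stability: polygon **area** (the convex hull, identical to the triangle
for three seasons and well-defined for more), **range** (maximum pairwise
distance), **mean distance to centroid**, and **mean distance between
consecutive points** (no wrap-around: SR→LR and LR→D averaged).

Comparing these between management levels faces a degenerate design: one
value per site, four sites. The stated mixed model (management fixed, site
random) cannot separate site variance from residual variance there;
`compare_stability()` reports it as attempted-and-degenerate and bases
inference on two tagged fallbacks: a Welch two-sample comparison across
site values and — the default inferential surface — an exact permutation
test enumerating all 6 assignments of four sites to two managements. With
two sites per level the smallest attainable two-sided p is 1/3, which is
the honest resolution of this design.

## Piecewise structural equation models

The causal question — does season act on fish directly, or through
seagrass cover? — is a DAG: season → cover, cover → fish, with the direct
season → fish edge either claimed or omitted. Each endogenous node is fit
as a mixed model with a site random intercept on the same transformed
responses as the univariate models (`standardized_responses()`); the
transform matters, because the generative process is log-linear and
untransformed densities leave curvature in the residuals that masquerades
as a direct seasonal effect.

Season, a three-level factor, is a composite variable: it enters every
regression as its dummy columns, is tested jointly by a Type III F, and
its per-dummy coefficients are reported but flagged sign-uninterpretable.
The d-separation basis set contains one claim per non-adjacent pair;
exogenous variables are allowed to covary freely and generate no claim;
claim orientation is canonical (descendant, else the endogenous node, else
alphabetical), so the set is invariant to edge listing order. Claim
p-values combine into Fisher's C = −2Σln p ~ χ² with 2k df; a model is
accepted when p(C) > 0.05, meaning no missing paths. Omitting the direct
edge puts exactly that edge's claim in the basis set, so acceptance of the
mediation-only model is the test that the seasonal signal in fish is fully
cover-mediated. Management enters by splitting: separate MPA and
open-access fits, the split used when season and management interact.
Standardized path coefficients are raw coefficients times sd(x)/sd(y).

## Species-pair synchrony

If unselective fishing drives open-access variability, species densities
there should rise and fall together. For every unordered pair of species
seen in both management levels, `pairwise_slopes()` regresses the
alphabetically later species' site-level mean density on the earlier one
(site random intercept, with a tagged OLS fallback when the 6-point fit is
singular — common and expected at this size). "Slopes of correlation" is
ambiguous in this literature; regression slopes are the default and a
Pearson-correlation alternative sits behind `statistic = "correlation"`.
Pairs with a zero-variance predictor are excluded and logged.
`compare_mean_slopes()` then runs a paired t-test on per-pair differences
(open − MPA); zero-variance differences are reported as degenerate rather
than forced through the t formula.

## Numerical choices and degenerate inputs

* Permutation p-values use the (1+)/(1+) estimator everywhere; exact
  enumeration is used where the space is small (6 site assignments).
* All RNG consumers take explicit seeds; the generator derives a
  deterministic sub-stream per transect from the root seed, so a survey is
  reproducible record by record, and the pipeline fans one root seed out
  per stage and logs it in the manifest.
* Zero-variance responses, all-zero abundance vectors, empty quadrat
  lists, p-values of exactly 0 in Fisher's C (floored with a warning at
  machine precision), cyclic path models, and missing site × season
  ordination points are all explicit errors or flagged fallbacks rather
  than silent NaN.
* Test problem sizes are package choices for a desk-scale suite: the
  default 40-species generator for design-level checks, an 8-species
  variant for replicate-heavy simulations, 200 replicates for the contrast
  recovery checks and 500 for null calibration.

## Known limitations

* Four sites is the design's hard ceiling: between-site inference (the MPA
  effect) rests on an exact permutation test with a minimum two-sided p of
  1/3, and the LRT is anticonservative for that term.
* The generator's φ and cover amplitudes are calibration knobs; analyses
  of real surveys should treat the simulated effect sizes as illustrative
  only.
* No underwater-visual-census bias correction, no length→biomass
  conversion, no rarefaction or Hill numbers, no constrained ordination
  (the PERMANOVA carries the inference that such plots visualize), and no
  bootstrap over transects within sites.
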