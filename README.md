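# seastab

Do marine protected areas (MPAs) buffer seagrass fish communities against
monsoon-driven seasonal variability? `seastab` is an R package implementing
the full analysis chain for that question, aimed at community ecologists
working with repeated underwater-visual-census surveys:

* a data model for belt-transect fish counts (with length-based age
  classes) and quadrat seagrass cover, plus validation and CSV I/O;
* a negative-binomial community simulator with seasonal forcing,
  seagrass-cover mediation and a management-dependent synchronous
  perturbation, used as ground truth throughout the test suite;
* univariate linear mixed models (season × management, site random
  intercept) with likelihood-ratio validation, marginal/conditional R²,
  Tukey all-pair contrasts and VIF screening;
* multivariate community structure: Bray-Curtis dissimilarities, PERMANOVA
  with permutations constrained within sites (strata), SIMPER species
  contributions, and non-metric MDS (Kruskal stress-1, isotonic
  regression, majorization);
* four ordination-trajectory temporal-variability metrics per site — area,
  range, mean distance to centroid, mean distance between consecutive
  points — and their management comparison (Welch + exact permutation over
  site relabelings);
* piecewise structural equation models (season → seagrass cover → fish)
  fitted as local mixed models, tested globally by the d-separation basis
  set and Fisher's C = −2Σln p ~ χ²(2k);
* species-pair synchrony: per-pair density slopes within each management
  level and a paired t-test on their differences.

The model at the package's core, for the simulator and the analyses alike,
is a fish community whose per-species density follows

> log μ = α_k + u_site + γ_k,season + β_k · z(cover) + φ_mgmt · f(season)

where φ_MPA = 0 < φ_open encodes unselective, monsoon-following fishing
pressure outside protected areas and β_k the species' seagrass affinity.
See `vignette("seagrass-fish-stability")` for the methods account.

## Worked example

```r
library(seastab)

survey <- generate_survey(generator_config(), seed = 1)
survey
#> Seagrass fish survey: 4720 fish observations, 40 taxa, 111 transect records

site_sum <- aggregate_density(survey, "site", "sum")
permanova(bray_curtis(site_sum), site_sum$samples, strata = "site",
          n_perm = 999, seed = 1)
#> PERMANOVA (999 permutations, strata-constrained):
#>               term df      ss      r2     f     p
#>             season  2 0.18937 0.34190 3.040 0.030
#>         management  1 0.05059 0.09133 1.624 0.059
#>  season:management  2 0.12706 0.22939 2.040 0.170
#>           Residual  6 0.18687 0.33738    NA    NA
#>              Total 11 0.55388 1.00000    NA    NA

ord <- nmds(bray_curtis(site_sum), seed = 1)
metrics <- stability_by_site(ord, site_sum$samples)
metrics
#>   site management    area range dist_centroid dist_consecutive
#> 1 MPA1        MPA 0.03047 0.306         0.156            0.253
#> 2 MPA2        MPA 0.00161 0.380         0.131            0.294
#> 3  OA1       open 0.00619 0.479         0.168            0.347
#> 4  OA2       open 0.03936 0.612         0.235            0.463
```

Season moves community structure (permutation p = 0.030 within sites) and
every trajectory metric is larger at the open-access sites — the simulated
fished sites are less temporally stable. `compare_stability(metrics)` makes
that comparison formally (the exact permutation over 4 sites bottoms out at
p = 1/3, the resolution of a 2 + 2 site design), `fit_psem()` separates
direct from cover-mediated seasonal effects, and `pairwise_slopes()` /
`compare_mean_slopes()` test whether species fluctuate in synchrony outside
MPAs. `run_full_analysis(analysis_config(...))` chains every stage per age
class into a reproducible report bundle, also available from the shell via
`inst/scripts/seastab simulate|validate|analyze`.

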