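# nichematch

Do species use habitat differently inside and outside protected areas?
`nichematch` implements a complete, testable pipeline for that question,
aimed at macroecologists working with large structured survey programmes
(line transects, track counts) and land-cover covariates:

1. **Matched design** — each protected survey unit is paired with its most
   similar unprotected unit (propensity score or Mahalanobis distance,
   one-to-one nearest neighbour without replacement, caliper 0.25 SD of the
   propensity scores) inside exact vegetation-zone × period strata, with
   standardized-mean-difference balance reports.
2. **Niche estimation** — a species' realised niche per period and
   protection class is a Gaussian kernel *n*-dimensional hypervolume over
   seven land-cover proportion axes; volumes come from importance sampling
   of the kernel mixture's 95%-mass level set. Units with < 5 occurrences
   or < 5 varying axes are excluded.
3. **Decomposition** — with shared volume *a* and unique volumes *b*, *c*,
   total niche differentiation `(b+c)/(a+b+c)` splits exactly into a
   habitat-**shift** (replacement) component `2·min(b,c)/(a+b+c)` and a
   volume-**expansion** (net difference) component `|b−c|/(a+b+c)`;
   0 = complete overlap, 1 = complete separation.
4. **Hypothesis classification** — with a 0.20 threshold on each component:
   HP0 no change, HP1 expansion only, HP2 shift only, HP3 both; plus a
   threshold-sensitivity grid.
5. **Trait models** — beta mixed-effects regressions (logit link, random
   intercepts for species and period, via glmmTMB) of shift and expansion
   on red-list status, Gini habitat/diet specialization, trophic level and
   log body mass, with the standard transforms, scaling and a |r| > 0.7
   collinearity screen.
6. **Phylogenetic diagnostic** — maximum-likelihood Pagel's λ (with a
   boundary-corrected LRT) on per-species mean model residuals.

A first-class synthetic-data module generates sites, occurrences, traits
and phylogenies with known ground truth (controllable confounding, niche
shift, niche expansion, trait effects and phylogenetic signal), so the
whole pipeline is exercised end-to-end without any external data.

## Worked example

Forty-eight synthetic comparisons (12 species × 4 periods, three species
per hypothesis class, strong effects) through the full pipeline:

```r
library(nichematch)

sites  <- generate_sites(3600, confounding_strength = 1, seed = 11)
specs  <- hp_scenario_specs(n_per_class = 3, seed = 12)
occ    <- generate_occurrences(sites, specs, seed = 13)
traits <- generate_traits(specs, seed = 14)
tree   <- generate_tree(traits$species_id, lambda_true = 0, seed = 15)

res <- run_pipeline(sites, occ, pipeline_config(taxon = "mammals", seed = 16),
                    traits = traits, tree = tree$tree)
res
#> Niche-comparison pipeline run
#>   matched pairs: 1159 (88.1% of protected sites)
#>   species x period comparisons: 48
#>   species labels: HP0=3 HP1=3 HP2=3 HP3=3
```

All twelve species are classified into their generative hypothesis class.
The matching stage removed the built-in protection–habitat confounding:

```r
dplyr::filter(res$balance, abs(smd_before) > 0.3)
#> # A tibble: 4 × 4
#>   covariate            smd_before smd_after zero_sd
#>   <chr>                     <dbl>     <dbl> <lgl>
#> 1 habitat_artificial       -0.427   -0.0342 FALSE
#> 2 habitat_agricultural     -0.606   -0.0338 FALSE
#> 3 habitat_coniferous        0.359    0.0493 FALSE
#> 4 habitat_shrub_herb        0.373    0.0389 FALSE
```

Covariates that differed by up to 0.6 pooled SD before matching differ by
less than 0.05 after. Per-species niche components (mean over periods; the
HP0 species sit below the 0.20 threshold on both components, the HP1
species show expansion without shift):

```r
head(res$species_summary)
#> # A tibble: 6 × 8
#>   species_id total  shift expansion signed_volume_change n_periods label
#> 1 sp_HP0_01  0.252 0.117     0.136           -0.00112            4 HP0
#> 2 sp_HP0_02  0.228 0.146     0.0819          -0.000834           4 HP0
#> 3 sp_HP0_03  0.241 0.167     0.0736          -0.00000136         4 HP0
#> 4 sp_HP1_01  0.319 0.0615    0.258            0.00520            4 HP1
#> 5 sp_HP1_02  0.311 0.100     0.211            0.00541            4 HP1
#> 6 sp_HP1_03  0.386 0.0147    0.371            0.00620            4 HP1
```

Trait models and the residual phylogenetic check (these traits were
generated with no trait–niche coupling and no phylogenetic signal, so λ̂ is
0 with p = 1):

```r
tidy(res$models$shift)       # coefficient table, Wald 95% CIs
glance(res$lambda$shift)
#> # A tibble: 1 × 7
#>   lambda_hat loglik loglik0 lrt_stat p_value lambda_max uninformative
#> 1          0   43.1    43.1        0       1       1.02 FALSE
```

Plots: `plot_hypothesis_counts(res$species_summary, traits)`,
`plot_balance(res$balance)`, `plot_threshold_sensitivity(res$sensitivity)`,
`autoplot(res$models$shift)`. `write_report(res, dir, traits)` writes all
tables as CSV plus a JSON summary.

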