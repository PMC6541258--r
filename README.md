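# lurefx

Attractants — edible bait and scent lure placed at camera-trap stations —
raise detection rates of elusive species, but they are not a constant
stimulus: bait is eaten, meat dries out, scent dissipates. `lurefx` is for
camera-trap ecologists who bait their stations and need to know what that
does to their data. It answers two questions per species:

1. **Does detection probability change with attractant freshness and
   survey effort?** Single-season occupancy models with constant occupancy
   ψ and daily detection p modelled on the logit scale as a function of
   observation-level covariates — days since the attractant was refreshed,
   cumulative station activity, and total deployment length — compared by
   AICc:

   logit(p_ij) = β₀ + β_attract · age_ij + …,  AICc = −2ℓ + 2K + 2K(K+1)/(n−K−1)

2. **Do animals visit stations more or less often just after baiting?**
   The proportion of a species' independent site visits falling 1, 2, …, 7
   days after refresh is compared against 1000 random capture histories of
   the same size, built by drawing stations from the species' capture
   locations, dates from those stations' active days, and times from the
   species' diel activity density (a von Mises circular kernel density).
   Rank p-values below 0.025 flag decreased visitation, above 0.975
   increased.

The package also ships a synthetic-survey generator with known ground
truth (occupancy, baseline detection, attractant effect, diel rhythm,
servicing cadence), so the whole pipeline is testable end to end without
any field data.

## Worked example

```r
library(lurefx)

sv <- generate_survey(scenario_config(), seed = 2013)
sv
#> <lure_survey> 45 stations, 3293 trap-days, 787 captures of 4 species

table1_summary(sv$captures, sv$deployments)
#> # A tibble: 4 × 6
#>   species  n_independent capture_rate naive_detection naive_occupancy trap_days
#> 1 civet              110         3.34          0.0334           0.489      3293
#> 2 duiker             223         6.77          0.0677           0.6        3293
#> 3 genet              117         3.55          0.0355           0.533      3293
#> 4 mongoose           337        10.2           0.102            0.778      3293
```

Capture rates are per 100 trap-days; naive occupancy is the fraction of
stations with at least one independent detection, uncorrected for
imperfect detection. Model the effect of attractant age on the genet-like
species (its generating truth is ψ = 0.5, p₀ = 0.12, β_attract = −0.20
per day):

```r
ind <- filter_independent(sv$captures) |> add_refresh_age(sv$refresh_log)
dm  <- build_detection_matrix(ind[ind$species == "genet", ], sv$deployments, "genet")
covs <- list(
  attractant_age     = build_covariate_matrix("attractant_age", sv$deployments, sv$refresh_log),
  total_effort       = build_covariate_matrix("total_effort", sv$deployments),
  incremental_effort = build_covariate_matrix("incremental_effort", sv$deployments)
)
ms <- run_model_set(dm, covs)
ms
#>   model                                       K loglik  AICc  dAICc  weight
#> 1 psi(.) p(attractant_age)                    3  -437.  880.  0      0.452
#> 2 psi(.) p(attractant_age + total_effort)     4  -436.  880.  0.180  0.413
#> 3 psi(.) p(attractant_age + incremental_eff…  4  -437.  883.  2.41   0.135
#> 4 psi(.) p(.)                                 2  -459.  923. 43.1    ...
tidy(ms$fit[[1]])
#>   term             estimate std.error statistic  p.value
#> 1 psi_(Intercept)     0.147    0.301      0.489 6.25e- 1
#> 2 p_(Intercept)      -1.86     0.140    -13.2   4.52e-40
#> 3 p_attractant_age   -0.254    0.0431    -5.89  3.76e- 9
```

The attractant model wins the AICc ranking and recovers the injected
decay: detection drops by e^−0.254 ≈ 22% per day of attractant age
(truth −0.20). `predict_detection()` / `plot_detection_curve()` give the
fitted curve with delta-method 95% bands, and the short-term visitation
test reads:

```r
pt <- permutation_test(ind[ind$species == "genet", ], sv$deployments,
                       sv$refresh_log, seed = 99)
tidy(pt)
#>     day observed null_mean null_lo null_hi p.value classification
#> 1     1   0.171     0.129   0.0684   0.197  0.903  none
#> ...
#> 7     7   0.0256    0.0801  0.0342   0.128  0.0130 decreased
```

Each row compares the observed share of visits in that 24-h bin since
refresh against the randomized null (violin plots via `autoplot(pt)`).
`run_attractant_analysis()` + `assemble_run()` execute every stage for
every species and write the result tables with a digest manifest; a thin
command-line wrapper lives at `inst/cli/lurefx.R`.

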