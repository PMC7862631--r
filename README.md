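# coexipm

Coupled, climate-driven integral projection models (IPMs) for two
interacting semiarid shrub populations.

`coexipm` is for population ecologists who want to ask how climate
variability and plant–plant interactions jointly shape the persistence and
coexistence of two co-dominant species — here two gypsum-soil shrubs,
coded `HS` (short-lived, binary flowering, Helianthemum-like) and `LS`
(long-lived, ordinal flowering, Lepidium-like). The package implements the
whole chain from individual-level census data to stochastic coexistence
scenarios:

1. **Synthetic censuses** (`simulate_population()`, `make_fixture()`): a
   generative twin of the analysis — plot random intercepts,
   logit-Bernoulli survival with quadratic size, Gaussian growth on the
   annual size difference, binary/ordinal flowering, Poisson plot-level
   seedling counts allocated to adults — so every downstream stage is
   testable without field data.
2. **Vital-rate GLMMs** (`fit_vital_rate()`, `select_model()`): survival,
   growth, probability of reproduction and fecundity per species, with
   plant size, block, intra-/interspecific cover indices and three climate
   covariates; AIC selection with a ΔAIC < 2 parsimony rule and REML
   readjustment of the selected model.
3. **Species-level IPMs** (`build_kernel()`, `dominant_lambda()`): the
   kernel n(y, t+1) = ∫ [s(x) g(y|x) + f(y, x)] n(x, t) dx over crown area
   [T, U], discretised by the midpoint rule into a 200 × 200 matrix; λ is
   its dominant eigenvalue.
4. **The coupled dynamic IPM** (`step_coupled()`, `run_projection()`):
   both species projected together, every year's covers recomputed from
   the size-structured abundances and fed back into both kernels.
5. **Stochastic scenarios** (`run_scenario()`, `run_scenario_battery()`):
   climate years resampled from a pool with enriched favourable or
   unfavourable year frequencies, recruitment pulses (2/5/10× fecundity in
   favourable years), initial-density experiments, and an interaction
   on/off toggle; summarised as medians and quartiles of the stochastic
   growth rate log λ_s = (1/T) log(N_T/N_0) over 100 replicates of 14
   transitions.

The packaged default coefficients are the published fixed-effect estimates
for the two study populations (`published_coefficients()`); size terms and
intercepts, which were not published, are package defaults calibrated at
documented reference conditions (see the methods vignette,
`vignettes/coupled-ipm-methods.Rmd`).

## Worked example

```r
library(coexipm)

sets <- default_model_sets()          # published coefficients + defaults
pool <- default_climate_pool()        # synthetic 16-year climate pool

# deterministic growth rate at reference conditions (covers 0.30, block A)
ref <- list(winter_min_temp = 2, spring_rain = 150, summer_wb = -10)
lam_hs <- dominant_lambda(build_kernel(sets$HS, ref, 0.3, 0.3, "A"))
lam_ls <- dominant_lambda(build_kernel(sets$LS, ref, 0.3, 0.3, "A"))
round(c(HS = as.numeric(lam_hs), LS = as.numeric(lam_ls)), 3)
#>    HS    LS
#> 1.022 1.083

# which pool years are climatically favourable / unfavourable?
des <- designate_years(pool, sets)
des$favourable; des$unfavourable
#>   HS   LS
#> 2005 2004
#> [1] 2001

# a stochastic scenario: HS-favourable years enriched to 1/3, twofold
# recruitment pulses in those years, 5 replicates of 14 transitions
spec <- scenario_spec("demo", "favourable_HS", recruit_multiplier = 2,
                      n_replicates = 5, seed = 11)
run_scenario(spec, sets, pool, des)$summary[, c("species", "q25", "median", "q75")]
#>  species       q25    median       q75
#>       HS 1.8201096 2.2015353 3.0044617
#>       LS 0.2949477 0.4173979 0.4221286
```

Both species are near stationarity (λ ≈ 1) under average climate; under
HS-favourable enrichment with recruitment pulses the HS stochastic growth
rate rises to a median of ≈ 2.2 on the log scale (its favourable year is
a strong recruitment-pulse year), while LS grows far more slowly. Medians and quartiles are over
replicate simulations; extinct or failed replicates are counted
separately, never dropped silently.

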