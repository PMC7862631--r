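---
title: "Methods: coupled climate-driven IPMs for two interacting shrubs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled climate-driven IPMs for two interacting shrubs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexipm)
```

## The demographic model

`coexipm` models two co-dominant gypsum shrubs — coded `HS` (short-lived,
binary flowering) and `LS` (long-lived, ordinal flowering) — whose vital
rates respond to annual climate and to the covers of both species, and
whose population dynamics feed back on those covers. The pipeline has
three stages.

**Stage 1 — vital-rate regressions.** Four rates per species are modelled
as GLMMs with a plot random intercept: survival (binomial-logit, with a
quadratic size term), growth (Gaussian on the *annual size difference* in
cm², with previous size as a covariate), probability of reproduction
(binomial-logit; summer water balance is structurally excluded because
both species flower before June), and fecundity (Poisson-log on the
per-adult seedling allocations). Fixed covariates are plant size, block,
the intra- and interspecific interaction indices (summed covers within the
plot, the focal plant excluded from the conspecific sum), winter minimum
temperature (°C), spring rainfall (mm) and summer water balance
(P − 2T, mm). Candidate models are all additive covariate subsets (size
always included); selection uses AIC with a parsimony rule (within
ΔAIC < 2, fewest parameters wins), block and the interspecific index are
forced back in when they appear in the near-tied set, and the final
Gaussian model is readjusted with REML (REML is undefined for the
binomial/Poisson families, which are returned as ML fits).

**Stage 2 — species-level IPMs.** The selected models define the kernel
$n(y, t+1) = \int_T^U [s(x)\,g(y \mid x) + f(y, x)]\, n(x, t)\,dx$
over crown projected area $[T, U]$, discretised by the midpoint rule into
a 200 × 200 matrix. The dominant eigenvalue $\lambda$ is the deterministic
annual growth rate; $\lambda = 1$ is stationarity.

**Stage 3 — the coupled dynamic IPM.** The two matrices are coupled
through cover: each year, every species' abundance vector is converted to
cover (abundance per size class × class-midpoint area / ground area), and
both covers enter both species' kernels for the next transition. Scenario
simulations resample climate years from a 16-year pool, optionally
enriching the frequency of favourable (λ-maximising) or unfavourable
years, multiply the fecundity kernel by a recruitment-pulse factor
(2/5/10×) in favourable years, and summarise the stochastic growth rate
$\log \lambda_s = \tfrac1T \log(N_T/N_0)$ over 100 replicates of 14
transitions.

## Parameterisation choices

The packaged default coefficients (`published_coefficients()`) are the
published fixed-effect estimates for the two study populations, stored as
printed; covariates are deliberately *unstandardised*, so each coefficient
applies per natural unit (e.g. 0.073 per mm of spring rainfall on the
survival logit). Three groups of parameters were not published and are
package choices, made once and documented here:

* **Size terms and intercepts.** Size enters every linear predictor on the
  log-area scale (areas span four orders of magnitude); the default size
  coefficients (`default_size_terms()`) make survival and reproduction
  increase with size (survival saturating via the quadratic term) and
  growth increments increase with log size. Intercepts are *calibrated*:
  each is solved so that the rate hits a target value at reference
  conditions (block A, covers 0.30, mid-range climate) —
  survival 0.85/0.90 (HS/LS) and flowering 0.5 for a typical 150 cm²
  adult, ~1.5/1.2 seedlings per flowering adult, and a +2 cm² expected
  increment for a 2 cm² recruit (anchoring growth at recruit size keeps
  expected early growth positive, which a log-linear size term cannot
  guarantee at both ends). These targets put both species near
  stationarity (λ ≈ 1.02 and 1.08) at the reference point, matching a
  community that persists at roughly stable cover.
* **Climate ranges.** The synthetic climate generator draws each covariate
  uniformly and independently within `default_climate_ranges()` (winter
  minima 0–4 °C, spring rainfall 120–180 mm, summer water balance −30 to
  10 mm). The spans were set jointly with the published per-unit
  magnitudes: they produce drought-mortality episodes and 100–1000-fold
  fecundity pulses between years — the pulse dynamics typical of these
  shrublands — without deterministically extinguishing a 9-census
  synthetic community. Wider spans make single dry springs remove entire
  cohorts (a −6 logit survival shift), which contradicts a study design
  that followed thousands of plants for nine years. Serial independence is
  deliberate: the scenario machinery resamples whole observed years, so
  only coverage of the ranges matters.
* **Recruit sizes and establishment.** Recruit sizes are log-normal
  (meanlog log 2 cm², sdlog 0.5), truncated to the mesh; a counted
  seedling enters the next census as a plant with probability 0.2
  (field first-summer survival was 12–22%). Expected plot-level emergence
  saturates at 137.5 seedlings m⁻² (the maximum observed emergence
  density), representing microsite limitation; without a saturation level
  the unstandardised fecundity coefficients would produce physically
  impossible seedling carpets in pulse years.

## The synthetic-data generator

`simulate_population()` is the generative twin of the fitted models: plot
random intercepts per vital rate (`sigma_plot`, default 0.3), Bernoulli
survival and flowering through the stated logits, Gaussian growth on the
size-difference scale floored at the mesh lower bound (0.2 cm², keeping
sizes positive), a latent-logistic ordinal flowering for LS with
cut-points (0, 1.5, 3) — the first cut-point is 0 so that the binary
"flowered at all" margin coincides with the reproduction GLMM — and
plot-level Poisson seedling counts whose mean is the summed expected
fecundity of the plot's flowering adults. Interaction indices are
recomputed from simulated covers every year, so the biotic covariates
carry realistic spatial and temporal structure.

What the generator does *not* emulate: seed-bank dynamics (germination is
tied to current adults; the study system has a persistent seed bank),
spatially explicit dispersal (allocation is plot-level), size-dependent
growth variance, and serially correlated climate. Passing tests therefore
demonstrate that the estimation and projection machinery is correct under
the model's own assumptions — not that the model captures every feature of
the field system.

## Numerical choices

* **Discretisation.** Midpoint rule over the source size; in the
  destination direction each cell receives the exact Gaussian (or
  log-normal, for recruits) probability mass of the cell. This keeps the
  kernel accurate when the growth SD (5 cm²) is comparable to the cell
  width (6 cm² at the default 200-cell mesh on [0.2, 1200] cm²); a pure
  midpoint evaluation of a density narrower than the cells can lose or
  invent several percent of mass.
* **Eviction.** Growth mass falling outside the mesh is returned by
  renormalising each column to its on-mesh mass, so column sums of the
  survival-growth component equal the predicted survival probabilities
  exactly and no artificial boundary mortality occurs. Columns whose raw
  on-mesh mass drops below 0.995 are recorded in the kernel object and
  reported under `options(coexipm.verbose = TRUE)`. The recruit density
  must retain ≥ 0.99 of its mass on the mesh, otherwise the kernel build
  errors (the mesh is too narrow for the recruit distribution).
* **Eigenvalues.** Power iteration with a 1e−12 relative tolerance;
  matrices on which the iteration cannot converge (tied eigenvalue moduli)
  fall back to a direct eigendecomposition.
* **GLMM fitting.** Covariates are standardised internally for the
  optimiser and estimates are transformed back, so reported coefficients
  are unstandardised. Fixed-effect standard errors are taken from the
  joint observed information over the variance component *and* the fixed
  effects, which propagates the uncertainty in the plot variance into the
  intervals; conditioning on the estimated variance (the plain Wald
  covariance, kept as a fallback) is anticonservative for between-plot
  contrasts such as the block effect. Fecundity responses are the
  non-integer proportional seedling allocations; they are fitted by the
  continuous-Poisson likelihood (the Poisson score equations evaluated at
  the allocated values, with the `lgamma` saturated term in the AIC), so
  seedling counts are conserved exactly instead of being rounded.
* **Scenario sampling.** Under an enriched rule the designated year is
  drawn with exactly its nominal probability (1/3 or 1/4) and the
  remaining mass is uniform over the *other* pool years; the combined
  rules draw favourable first, then unfavourable on the remaining mass.
  The recruitment multiplier applies in the years where the designated
  favourable year was drawn. Replicates are seeded counter-style
  (`seed + replicate`), so results are independent of execution order, and
  quartiles use linear interpolation (`quantile` type 7).
* **Cover.** Covers are clipped at 1 (overlapping crowns can push the raw
  sum above the ground area); clips are logged. With the interaction flag
  off, the interspecific covariate is frozen at its initial-year value —
  the feedback is cancelled, not the covariate.

## Design decisions on open points

* Growth is defined as a size *difference* but modelled against previous
  size; `predict_rate()` therefore returns `size + η` for growth, which
  satisfies both statements simultaneously.
* The favourable/unfavourable years of the synthetic pool are designated
  at run time by ranking each species' λ across the pool
  (`designate_years()`), mirroring how the observed extreme years were
  identified from the species-level models.
* "1 of every 3/4 years" is implemented as a per-year probability, not a
  deterministic cycle (configurable through `p_favourable`).
* Extinct replicates return `log λ_s = −∞` and are reported separately;
  scenario medians are over surviving replicates with the extinct count
  alongside.

## Problem sizes used by the test-suite and acceptance script

Simulation-based checks run at sizes chosen to give stable Monte-Carlo
behaviour while staying quick on a single core: parameter recovery uses
the full study design (2 × 50 plots, 9 censuses, ≈ 3–4 × 10³ plant-years)
with 50 replicate fits; trend orderings use 20 replicates of 14
transitions; sampler calibration uses 10⁵ draws; deterministic-limit
checks use 160 constant-climate transitions with a 120-transition
transient discarded.

## Known limitations

The fecundity allocation cannot distinguish seed-bank germination from
current reproduction, so fecundity is an emergence-attribution model, not
a seed-production model. The interaction indices are plot-level sums, not
distance-weighted neighbourhoods. Only two species are modelled; the
community context beyond them is absorbed into intercepts and the block
effect. The coupled model is annual, with no within-year sub-steps, and
covers enter kernels as measured at the start of each transition.
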