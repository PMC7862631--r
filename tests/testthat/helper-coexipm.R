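# shared fixtures built in code

# a minimal constant-rate model set: survival probability `s`, no growth
# (expected next size = size), flowering probability `p`, fecundity `f` per
# flowering adult, with near-delta growth spread unless overridden
toy_set <- function(species = "HS", s = 0.7, p = 0, f = 0,
                    sigma_growth = 1e-3,
                    recruit_meanlog = log(2), recruit_sdlog = 0.5) {
  mk <- function(rate, icpt) {
    vital_rate_model(species, rate, coef = c("(Intercept)" = icpt),
                     sigma_resid = if (rate == "growth") sigma_growth)
  }
  vital_rate_set(
    species,
    survival = mk("survival", qlogis(min(max(s, 1e-12), 1 - 1e-12))),
    growth = mk("growth", 0),
    reproduction = mk("reproduction",
                      qlogis(min(max(p, 1e-12), 1 - 1e-12))),
    fecundity = mk("fecundity", if (f > 0) log(f) else -50),
    recruit_meanlog = recruit_meanlog, recruit_sdlog = recruit_sdlog)
}

ref_climate <- function() {
  list(winter_min_temp = 2, spring_rain = 150, summer_wb = -10)
}

# density-independent variant of the default model sets: biotic-interaction
# terms removed so lambda does not depend on covers
density_independent_sets <- function() {
  strip <- function(set) {
    models <- lapply(vital_rate_names(), function(rate) {
      m <- set[[rate]]
      keep <- setdiff(names(m$coef), c("intra", "inter"))
      vital_rate_model(m$species, rate, coef = m$coef[keep],
                       sigma_plot = m$sigma_plot,
                       sigma_resid = if (rate == "growth") m$sigma_resid,
                       size_scale = m$size_scale)
    })
    names(models) <- vital_rate_names()
    vital_rate_set(set$species, models$survival, models$growth,
                   models$reproduction, models$fecundity,
                   recruit_meanlog = set$recruit_meanlog,
                   recruit_sdlog = set$recruit_sdlog)
  }
  lapply(default_model_sets(), strip)
}

# small simulated dataset cached across tests within one run
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(n_plots_per_block = 8L, n_years = 6L, seed = 42L)
      cache <<- simulate_population(cfg)
    }
    cache
  }
})
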