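#' Configuration for the synthetic census generator
#'
#' Describes a simulated monitoring design mirroring the field study: two
#' 20 x 20 m blocks, 0.5 x 0.5 m permanent plots, annual April censuses of
#' every focal-species plant, and plot-level seedling counts. The generative
#' model is the exact structure the downstream GLMMs assume: per plot and
#' vital rate a Gaussian random intercept; logit-Bernoulli survival with
#' quadratic (log-)size; Gaussian growth on the size-difference scale with a
#' positivity floor; logit-Bernoulli flowering (HS) or a latent-logistic
#' ordinal flowering with three cut-points (LS, first cut-point 0 so the
#' binary flowering margin matches the reproduction model); plot-level
#' seedling counts Poisson with mean equal to the summed expected
#' fecundities of the plot's flowering adults. The Poisson mean saturates at
#' `max_seedlings_m2` (microsite limitation; the observed maximum emergence
#' density). Intra-/interspecific indices are recomputed from simulated
#' covers every year.
#'
#' @param model_sets Named list of [vital_rate_set()]s for `HS` and `LS`
#'   (generating coefficients; defaults to [default_model_sets()]).
#' @param n_plots_per_block Plots per block (field design: 50).
#' @param blocks Block labels (field design: `"A"`, `"B"`).
#' @param n_years Number of annual censuses (field design: 9, giving 8
#'   transitions).
#' @param init_density Named initial densities, individuals per m^2
#'   (observed 2004 values: HS 16, LS 2.4).
#' @param plot_area_cm2 Plot area (0.5 x 0.5 m = 2500 cm^2).
#' @param adult_size_meanlog,adult_size_sdlog Log-normal initial adult size
#'   distribution (log cm^2).
#' @param establishment Probability that a counted seedling enters the next
#'   census as a plant.
#' @param max_seedlings_m2 Saturation level of expected seedling emergence
#'   (per m^2).
#' @param size_floor Lower bound for simulated sizes (cm^2); growth is
#'   floored here so sizes stay positive.
#' @param ls_cutpoints Three increasing cut-points of the latent-logistic
#'   ordinal flowering model for LS; the first must be 0.
#' @param climate_ranges Ranges for [generate_climate_series()].
#' @param seed Master seed.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(model_sets = default_model_sets(),
                             n_plots_per_block = 50L,
                             blocks = c("A", "B"),
                             n_years = 9L,
                             init_density = c(HS = 16, LS = 2.4),
                             plot_area_cm2 = 2500,
                             adult_size_meanlog = log(150),
                             adult_size_sdlog = 0.7,
                             establishment = 0.2,
                             max_seedlings_m2 = 137.5,
                             size_floor = 0.2,
                             ls_cutpoints = c(0, 1.5, 3),
                             climate_ranges = default_climate_ranges(),
                             seed = 1L) {
  stopifnot(all(species_codes() %in% names(model_sets)))
  for (sp in species_codes()) {
    if (!inherits(model_sets[[sp]], "vital_rate_set")) {
      stop("`model_sets` must contain vital_rate_set objects", call. = FALSE)
    }
    for (rate in vital_rate_names()) {
      m <- model_sets[[sp]][[rate]]
      if (any(!is.finite(m$coef))) stop("non-finite coefficient", call. = FALSE)
      if (m$sigma_plot < 0) stop("negative variance parameter", call. = FALSE)
    }
  }
  check_number(n_plots_per_block, "n_plots_per_block", lower = 1)
  check_number(n_years, "n_years", lower = 2)
  if (any(init_density < 0)) stop("densities must be >= 0", call. = FALSE)
  check_number(plot_area_cm2, "plot_area_cm2", lower = 1e-6)
  check_number(establishment, "establishment", lower = 0, upper = 1)
  check_number(size_floor, "size_floor", lower = 1e-9)
  if (length(ls_cutpoints) != 3L || is.unsorted(ls_cutpoints, strictly = TRUE) ||
      ls_cutpoints[1] != 0) {
    stop("`ls_cutpoints` must be three increasing values starting at 0",
         call. = FALSE)
  }
  structure(
    list(model_sets = model_sets, n_plots_per_block = as.integer(n_plots_per_block),
         blocks = blocks, n_years = as.integer(n_years),
         init_density = init_density, plot_area_cm2 = plot_area_cm2,
         adult_size_meanlog = adult_size_meanlog,
         adult_size_sdlog = adult_size_sdlog,
         establishment = establishment, max_seedlings_m2 = max_seedlings_m2,
         size_floor = size_floor, ls_cutpoints = ls_cutpoints,
         climate_ranges = climate_ranges, seed = as.integer(seed)),
    class = "generator_config")
}

# internal: draw flowering for one species given linear predictors
draw_flowering <- function(eta, species, cutpoints) {
  n <- length(eta)
  if (species == "HS") {
    as.character(rbinom(n, 1, plogis(eta)))
  } else {
    # latent-logistic ordinal: P(Y > level k) = plogis(eta - c_k)
    u <- runif(n)
    exceed <- outer(eta, cutpoints, function(e, ck) plogis(e - ck))
    idx <- rowSums(u < exceed) + 1L   # 1 = none .. 4 = high
    flowering_levels()[idx]
  }
}

#' Simulate a demographic census under known coefficients
#'
#' Runs the generative model of [generator_config()] forward over
#' `n_years` annual censuses and returns individual plant-year transition
#' records, plot-level seedling counts, and the climate series that drove
#' them. Fully reproducible: identical configurations (including seed) give
#' identical output.
#'
#' @param config A [generator_config()].
#' @return List with elements `records` (one row per observed plant-year
#'   transition: `plant_id`, `species`, `block`, `plot_id`, `year`,
#'   `size_cm2`, `alive_next`, `size_next_cm2`, `flowering`), `seedlings`
#'   (`plot_id`, `block`, `year`, `species`, `seedlings`; the year is the
#'   emergence census, one after the parental transition year), and
#'   `climate` (one row per transition year).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n_trans <- config$n_years - 1L
  climate <- generate_climate_series(n_trans, config$climate_ranges,
                                     seed = config$seed + 1L,
                                     start_year = 2004L)
  set.seed(config$seed)
  plots <- expand.grid(block = config$blocks,
                       plot_in_block = seq_len(config$n_plots_per_block),
                       stringsAsFactors = FALSE)
  plots$plot_id <- sprintf("%s%02d", plots$block, plots$plot_in_block)
  plot_area_m2 <- config$plot_area_cm2 / 1e4

  # plot random intercepts: one per plot x species x rate
  re <- list()
  for (sp in species_codes()) {
    re[[sp]] <- sapply(vital_rate_names(), function(rate) {
      rnorm(nrow(plots), 0, config$model_sets[[sp]][[rate]]$sigma_plot)
    })
    rownames(re[[sp]]) <- plots$plot_id
  }

  # initial population: Poisson number of adults per plot at the observed
  # 2004 densities, log-normal sizes
  pop <- list()
  next_id <- 1L
  for (p in seq_len(nrow(plots))) {
    for (sp in species_codes()) {
      k <- rpois(1, config$init_density[[sp]] * plot_area_m2)
      if (k == 0) next
      sizes <- pmax(rlnorm(k, config$adult_size_meanlog,
                           config$adult_size_sdlog), config$size_floor)
      pop[[length(pop) + 1L]] <- data.frame(
        plant_id = seq.int(next_id, length.out = k),
        species = sp, block = plots$block[p], plot_id = plots$plot_id[p],
        size = sizes, stringsAsFactors = FALSE)
      next_id <- next_id + k
    }
  }
  pop <- if (length(pop)) do.call(rbind, pop) else
    stop("initial population is empty; raise `init_density`", call. = FALSE)

  records <- vector("list", n_trans)
  seedrec <- vector("list", n_trans)
  for (t in seq_len(n_trans)) {
    yr <- climate$year[t]
    cli <- climate[t, ]
    # plot-level covers and per-plant interaction indices
    pop$cover <- pop$size / config$plot_area_cm2
    idx <- do.call(rbind, lapply(split(pop, pop$plot_id), function(pp) {
      cbind(pp[, c("plant_id", "species", "block", "plot_id", "size")],
            plot_interaction_indices(pp)[, c("intra", "inter")])
    }))
    idx <- idx[order(idx$plant_id), , drop = FALSE]
    rownames(idx) <- NULL
    nd <- data.frame(size = idx$size, block = idx$block,
                     intra = idx$intra, inter = idx$inter,
                     winter_min_temp = cli$winter_min_temp,
                     spring_rain = cli$spring_rain,
                     summer_wb = cli$summer_wb)
    plot_row <- match(idx$plot_id, plots$plot_id)

    out <- idx[, c("plant_id", "species", "block", "plot_id")]
    out$year <- yr
    out$size_cm2 <- idx$size
    out$alive_next <- NA_integer_
    out$size_next_cm2 <- NA_real_
    out$flowering <- NA_character_
    fec_mu <- numeric(nrow(idx))
    for (sp in species_codes()) {
      m <- config$model_sets[[sp]]
      j <- which(idx$species == sp)
      if (!length(j)) next
      ndj <- nd[j, , drop = FALSE]
      rj <- plot_row[j]
      eta_s <- predict_rate(m$survival, ndj, type = "link") +
        re[[sp]][rj, "survival"]
      out$alive_next[j] <- rbinom(length(j), 1, plogis(eta_s))
      eta_g <- predict_rate(m$growth, ndj, type = "link") +
        re[[sp]][rj, "growth"]
      delta <- rnorm(length(j), eta_g, m$growth$sigma_resid)
      out$size_next_cm2[j] <- pmax(idx$size[j] + delta, config$size_floor)
      eta_f <- predict_rate(m$reproduction, ndj, type = "link") +
        re[[sp]][rj, "reproduction"]
      out$flowering[j] <- draw_flowering(eta_f, sp, config$ls_cutpoints)
      eta_c <- predict_rate(m$fecundity, ndj, type = "link") +
        re[[sp]][rj, "fecundity"]
      flowered <- if (sp == "HS") out$flowering[j] == "1" else
        out$flowering[j] != "none"
      fec_mu[j] <- exp(eta_c) * as.numeric(flowered)
    }
    out$size_next_cm2[out$alive_next == 0] <- NA_real_

    # plot-level seedling emergence (recorded at the next census year)
    cap <- config$max_seedlings_m2 * plot_area_m2
    sl <- expand.grid(plot_id = plots$plot_id, species = species_codes(),
                      stringsAsFactors = FALSE)
    sl$block <- plots$block[match(sl$plot_id, plots$plot_id)]
    sl$year <- yr + 1L
    mu <- vapply(seq_len(nrow(sl)), function(i) {
      sum(fec_mu[idx$plot_id == sl$plot_id[i] & idx$species == sl$species[i]])
    }, numeric(1))
    sl$seedlings <- rpois(nrow(sl), pmin(mu, cap))
    seedrec[[t]] <- sl[, c("plot_id", "block", "year", "species", "seedlings")]
    records[[t]] <- out

    # advance population: survivors plus established recruits
    surv_pop <- data.frame(plant_id = out$plant_id, species = out$species,
                           block = out$block, plot_id = out$plot_id,
                           size = out$size_next_cm2,
                           stringsAsFactors = FALSE)[out$alive_next == 1, ]
    recruits <- list()
    estab <- rbinom(nrow(sl), sl$seedlings, config$establishment)
    for (i in which(estab > 0)) {
      k <- estab[i]
      recruits[[length(recruits) + 1L]] <- data.frame(
        plant_id = seq.int(next_id, length.out = k),
        species = sl$species[i], block = sl$block[i], plot_id = sl$plot_id[i],
        size = pmax(rlnorm(k, config$model_sets[[sl$species[i]]]$recruit_meanlog,
                           config$model_sets[[sl$species[i]]]$recruit_sdlog),
                    config$size_floor),
        stringsAsFactors = FALSE)
      next_id <- next_id + k
    }
    pop <- rbind(surv_pop, if (length(recruits)) do.call(rbind, recruits))
    rownames(pop) <- NULL
    if (nrow(pop) == 0L) break
  }
  list(records = do.call(rbind, records),
       seedlings = do.call(rbind, seedrec),
       climate = climate)
}

#' Write a synthetic fixture to disk
#'
#' Generates a census with [simulate_population()] and writes the three CSV
#' interchange files (`census.csv`, `climate.csv`, `seedlings.csv`). The
#' `"paper"` scale reproduces the study design (2 blocks x 50 plots, 9
#' censuses, initial densities 16 and 2.4 individuals per m^2); `"tiny"` is
#' a fast miniature for tests and examples.
#'
#' @param dir Output directory (created if needed).
#' @param scale `"tiny"` or `"paper"`.
#' @param seed Master seed; regeneration with the same seed is
#'   byte-identical.
#' @param config Optional [generator_config()] overriding the scale presets.
#' @return Named character vector of the three file paths, invisibly.
#' @export
make_fixture <- function(dir, scale = c("tiny", "paper"), seed = 1L,
                         config = NULL) {
  scale <- match.arg(scale)
  if (is.null(config)) {
    config <- if (scale == "tiny") {
      generator_config(n_plots_per_block = 3L, n_years = 4L, seed = seed)
    } else {
      generator_config(seed = seed)
    }
  }
  sim <- simulate_population(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(census = file.path(dir, "census.csv"),
             climate = file.path(dir, "climate.csv"),
             seedlings = file.path(dir, "seedlings.csv"))
  write_census(sim$records, paths[["census"]])
  write_climate(sim$climate, paths[["climate"]])
  write_seedlings(sim$seedlings, paths[["seedlings"]])
  invisible(paths)
}
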