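#' Size-structured population state
#'
#' Abundance vector over the mesh classes, in individuals per m^2 per size
#' class; the total density is `sum(n)`.
#'
#' @param species `"HS"` or `"LS"`.
#' @param n Non-negative abundance vector of length `grid$n`.
#' @param grid The [build_grid()] mesh the abundances live on.
#' @param year Year index (0 = initial state).
#' @return Object of class `population_state`.
#' @export
population_state <- function(species, n, grid, year = 0L) {
  species <- match.arg(species, species_codes())
  stopifnot(inherits(grid, "ipm_grid"))
  if (length(n) != grid$n) stop("`n` must match the mesh size", call. = FALSE)
  if (any(!is.finite(n)) || any(n < 0)) {
    stop("abundances must be finite and non-negative", call. = FALSE)
  }
  structure(list(species = species, n = as.numeric(n), grid = grid,
                 year = as.integer(year)),
            class = "population_state")
}

#' Initial state at a given density
#'
#' Distributes `density` individuals per m^2 over the mesh according to a
#' log-normal adult size distribution (the observed first-census size
#' structure analogue).
#'
#' @param species Species code.
#' @param density Individuals per m^2 (>= 0).
#' @param grid Mesh.
#' @param meanlog,sdlog Log-normal size distribution parameters (log cm^2).
#' @return A [population_state()].
#' @export
initial_state <- function(species, density, grid,
                          meanlog = log(150), sdlog = 0.7) {
  check_number(density, "density", lower = 0)
  w <- dlnorm(grid$mid, meanlog, sdlog)
  sw <- sum(w)
  if (sw <= 0) stop("size distribution has no mass on the mesh", call. = FALSE)
  population_state(species, density * w / sw, grid)
}

#' Initial state from a census file
#'
#' Converts the first census year of a records table into a mesh-binned
#' abundance vector in individuals per m^2: observed sizes are binned into
#' the mesh cells and divided by the total sampled area.
#'
#' @param records Census records ([read_census()] format).
#' @param species Species code to extract.
#' @param grid Mesh.
#' @param plot_area_cm2 Area of one plot.
#' @param n_plots Total number of sampled plots (defaults to the number of
#'   distinct `plot_id` values in `records`; pass the design value when
#'   some plots hold no plants).
#' @param year Census year to use (default: the first).
#' @return A [population_state()].
#' @export
initial_state_from_census <- function(records, species, grid,
                                      plot_area_cm2 = 2500, n_plots = NULL,
                                      year = NULL) {
  species <- match.arg(species, species_codes())
  if (is.null(year)) year <- min(records$year)
  if (is.null(n_plots)) n_plots <- length(unique(records$plot_id))
  sizes <- records$size_cm2[records$species == species &
                              records$year == year]
  sizes <- pmin(pmax(sizes, grid$lower), grid$upper - 1e-9 * grid$h)
  cell <- pmin(grid$n, pmax(1L, ceiling((sizes - grid$lower) / grid$h)))
  counts <- tabulate(cell, nbins = grid$n)
  area_m2 <- n_plots * plot_area_cm2 / 1e4
  population_state(species, counts / area_m2, grid)
}

#' Export projection trajectories as tidy CSV
#'
#' @param summary The `summary` data frame of [run_projection()] (or any
#'   tidy trajectory table).
#' @param path Output CSV path.
#' @param seed,config_hash Optional provenance comment.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(summary, path, seed = NULL, config_hash = NULL) {
  write_with_header(summary, path, seed, config_hash)
}

#' Cover fraction of a population state
#'
#' Multiplies the abundance of each size class by its class-midpoint crown
#' area and divides by the reference ground area, clipping at 1 (a clip is
#' logged under `options(coexipm.verbose)` and recorded in the
#' `"clipped"` attribute).
#'
#' @param state A [population_state()].
#' @param reference_area Ground area corresponding to the abundance units
#'   (cm^2; default 1 m^2 = 10^4 cm^2 for per-m^2 abundances).
#' @return Cover fraction in `[0, 1]` with attribute `clipped`.
#' @export
cover_from_state <- function(state, reference_area = 1e4) {
  stopifnot(inherits(state, "population_state"))
  check_number(reference_area, "reference_area", lower = 1e-12)
  raw <- sum(state$n * state$grid$mid) / reference_area
  clipped <- raw > 1
  if (clipped) {
    coexipm_log(sprintf("%s cover %.3f clipped to 1", state$species, raw))
  }
  structure(min(1, raw), clipped = clipped)
}

#' Coupled two-species state
#'
#' Bundles the two species' population states with the derived covers, the
#' block, and the interaction flag. When the flag is off, each species'
#' interspecific covariate is frozen at `baseline_inter` (by default the
#' covers at construction time) instead of tracking the other species'
#' dynamics: the feedback is cancelled, not the covariate.
#'
#' @param states Named list of [population_state()]s for `HS` and `LS`.
#' @param block `"A"` or `"B"`.
#' @param interaction_on Dynamic interspecific feedback flag.
#' @param baseline_inter Named baseline interspecific covariate per focal
#'   species used when the flag is off; defaults to the other species'
#'   cover at construction.
#' @param reference_area Ground area for cover computation (cm^2).
#' @return Object of class `coupled_state`.
#' @export
coupled_state <- function(states, block = "A", interaction_on = TRUE,
                          baseline_inter = NULL, reference_area = 1e4) {
  stopifnot(all(species_codes() %in% names(states)))
  block <- match.arg(block, c("A", "B"))
  covers <- vapply(species_codes(), function(sp) {
    as.numeric(cover_from_state(states[[sp]], reference_area))
  }, numeric(1))
  if (is.null(baseline_inter)) {
    baseline_inter <- c(HS = unname(covers["LS"]), LS = unname(covers["HS"]))
  }
  stopifnot(all(species_codes() %in% names(baseline_inter)))
  structure(list(states = states[species_codes()], covers = covers,
                 block = block, interaction_on = isTRUE(interaction_on),
                 baseline_inter = baseline_inter,
                 reference_area = reference_area,
                 year = states[[1]]$year),
            class = "coupled_state")
}

#' Advance the coupled system one annual transition
#'
#' For each species a kernel is built under the year's climate with `intra`
#' equal to its own current cover and `inter` equal to the other species'
#' current cover (or the frozen baseline when the interaction flag is
#' off); the fecundity component is scaled by `recruit_multiplier`; the
#' next state is the kernel-vector product; covers are then recomputed
#' from the new states for the following iteration.
#'
#' @param cs A [coupled_state()].
#' @param sets Named list of [vital_rate_set()]s for both species.
#' @param climate One climate year.
#' @param recruit_multiplier Fecundity scaling for this transition (applies
#'   to both species; >= 0).
#' @return The [coupled_state()] at `t + 1`.
#' @export
step_coupled <- function(cs, sets, climate, recruit_multiplier = 1) {
  stopifnot(inherits(cs, "coupled_state"))
  check_number(recruit_multiplier, "recruit_multiplier", lower = 0)
  new_states <- list()
  for (sp in species_codes()) {
    other <- setdiff(species_codes(), sp)
    inter <- if (cs$interaction_on) cs$covers[[other]] else
      cs$baseline_inter[[sp]]
    K <- build_kernel(sets[[sp]], climate,
                      intra = cs$covers[[sp]], inter = inter,
                      block = cs$block, grid = cs$states[[sp]]$grid,
                      recruit_multiplier = recruit_multiplier)
    n_new <- as.vector(K$K %*% cs$states[[sp]]$n)
    if (any(!is.finite(n_new))) {
      stop(sprintf("non-finite abundance for species %s at iteration %d",
                   sp, cs$year + 1L), call. = FALSE)
    }
    new_states[[sp]] <- population_state(sp, n_new, cs$states[[sp]]$grid,
                                         year = cs$year + 1L)
  }
  coupled_state(new_states, block = cs$block,
                interaction_on = cs$interaction_on,
                baseline_inter = cs$baseline_inter,
                reference_area = cs$reference_area)
}

#' Project the coupled system over a climate sequence
#'
#' Iterates [step_coupled()] over `nrow(climate_seq)` annual transitions
#' (the study design simulates 14 transitions, i.e. 15 years), recording
#' per-year total densities and covers.
#'
#' @param cs Initial [coupled_state()].
#' @param sets Named list of [vital_rate_set()]s.
#' @param climate_seq Data frame, one row per transition.
#' @param recruit_multipliers Per-transition fecundity multipliers
#'   (recycled scalar allowed).
#' @return List: `states` (length transitions + 1, including the initial
#'   state), `summary` (tidy data frame `year`, `species`,
#'   `total_density`, `cover`).
#' @export
run_projection <- function(cs, sets, climate_seq, recruit_multipliers = 1) {
  n_trans <- nrow(climate_seq)
  if (length(recruit_multipliers) == 1L) {
    recruit_multipliers <- rep(recruit_multipliers, n_trans)
  }
  stopifnot(length(recruit_multipliers) == n_trans)
  states <- vector("list", n_trans + 1L)
  states[[1L]] <- cs
  for (t in seq_len(n_trans)) {
    cs <- step_coupled(cs, sets, climate_seq[t, ],
                       recruit_multiplier = recruit_multipliers[t])
    states[[t + 1L]] <- cs
  }
  summary <- do.call(rbind, lapply(states, function(s) {
    data.frame(year = s$year, species = species_codes(),
               total_density = vapply(species_codes(), function(sp)
                 sum(s$states[[sp]]$n), numeric(1)),
               cover = unname(s$covers[species_codes()]),
               row.names = NULL)
  }))
  list(states = states, summary = summary)
}

#' Single-species projection
#'
#' Projects one species alone with dynamic intraspecific cover and a fixed
#' interspecific covariate, through exactly the same kernel path as
#' [step_coupled()]; with the interaction flag off and zero interspecific
#' coefficients, a coupled projection decomposes into two of these,
#' floating-point identically.
#'
#' @param state Initial [population_state()].
#' @param set The species' [vital_rate_set()].
#' @param climate_seq Data frame of transitions.
#' @param inter Fixed interspecific covariate.
#' @param block Block label.
#' @param recruit_multipliers Per-transition fecundity multipliers.
#' @param reference_area Cover reference area (cm^2).
#' @return List: `states`, `summary` (year, total_density, cover).
#' @export
project_single <- function(state, set, climate_seq, inter = 0,
                           block = "A", recruit_multipliers = 1,
                           reference_area = 1e4) {
  n_trans <- nrow(climate_seq)
  if (length(recruit_multipliers) == 1L) {
    recruit_multipliers <- rep(recruit_multipliers, n_trans)
  }
  states <- vector("list", n_trans + 1L)
  states[[1L]] <- state
  for (t in seq_len(n_trans)) {
    cover <- as.numeric(cover_from_state(state, reference_area))
    K <- build_kernel(set, climate_seq[t, ], intra = cover, inter = inter,
                      block = block, grid = state$grid,
                      recruit_multiplier = recruit_multipliers[t])
    n_new <- as.vector(K$K %*% state$n)
    if (any(!is.finite(n_new))) {
      stop(sprintf("non-finite abundance for species %s at iteration %d",
                   state$species, state$year + 1L), call. = FALSE)
    }
    state <- population_state(state$species, n_new, state$grid,
                              year = state$year + 1L)
    states[[t + 1L]] <- state
  }
  summary <- do.call(rbind, lapply(states, function(s) {
    data.frame(year = s$year, total_density = sum(s$n),
               cover = as.numeric(cover_from_state(s, reference_area)))
  }))
  list(states = states, summary = summary)
}
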