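#' Designate favourable and unfavourable climate years
#'
#' Ranks the years of a climate pool by each species' deterministic lambda
#' (at fixed covers, as in the species-level response curves) and returns
#' the lambda-maximising year per species (its favourable year) and the
#' year minimising the mean of the two species' log lambdas (the shared
#' unfavourable year).
#'
#' @param pool Climate pool data frame (e.g. [default_climate_pool()]).
#' @param sets Named list of [vital_rate_set()]s.
#' @param intra,inter,block,grid Passed to [lambda_vs_climate()].
#' @return List: `favourable` (named year vector per species),
#'   `unfavourable` (year), `lambda_table` (year x species lambdas).
#' @export
designate_years <- function(pool, sets, intra = 0.30, inter = 0.30,
                            block = "A", grid = default_grid()) {
  tabs <- lapply(species_codes(), function(sp) {
    lambda_vs_climate(sets[[sp]], pool, intra = intra, inter = inter,
                      block = block, grid = grid)$lambda
  })
  names(tabs) <- species_codes()
  lt <- data.frame(year = pool$year, HS = tabs$HS, LS = tabs$LS)
  fav <- vapply(species_codes(), function(sp) lt$year[which.max(lt[[sp]])],
                numeric(1))
  unfav <- lt$year[which.min(log(lt$HS) + log(lt$LS))]
  list(favourable = fav, unfavourable = unfav, lambda_table = lt)
}

scenario_rules <- function() {
  c("random", "favourable_HS", "favourable_LS", "unfavourable",
    "combined_HS", "combined_LS")
}

#' Specify one climate-ecology scenario
#'
#' A fully seeded description of one stochastic simulation experiment:
#' which climate rule enriches the year sampling, the recruitment
#' multiplier applied in favourable years, initial densities, the
#' interspecific-interaction flag, block, and the replication design
#' (defaults: 100 replicates of 14 annual transitions, matching the
#' 15-year observed-climate window).
#'
#' Climate rules: `random` samples uniformly from the pool;
#' `favourable_HS`/`favourable_LS` draw the focal species' favourable year
#' with probability 1/3 / 1/4 (otherwise uniformly among the remaining
#' years); `unfavourable` draws the unfavourable year with probability
#' 1/3; `combined_HS`/`combined_LS` first apply the favourable rule, then
#' the unfavourable rule on the remaining probability mass.
#'
#' @param name Scenario label.
#' @param climate_rule One of `r paste(scenario_rules(), collapse = ", ")`.
#' @param recruit_multiplier Fecundity multiplier in favourable years
#'   (1, 2, 5 or 10 in the study design; any non-negative value accepted).
#' @param init_density Named initial densities (individuals per m^2).
#' @param interaction_on Dynamic interspecific feedback flag.
#' @param block `"A"` or `"B"`.
#' @param n_replicates Replicated simulations per scenario.
#' @param n_transitions Annual transitions per replicate.
#' @param p_favourable Favourable-year probability (default 1/3 for HS
#'   rules, 1/4 for LS rules).
#' @param p_unfavourable Unfavourable-year probability for the
#'   unfavourable/combined rules.
#' @param seed Scenario master seed; replicate `r` uses `seed + r`
#'   (counter-based, so replicates are independent of execution order).
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(name = climate_rule,
                          climate_rule = "random",
                          recruit_multiplier = 1,
                          init_density = c(HS = 16, LS = 2.4),
                          interaction_on = TRUE,
                          block = "A",
                          n_replicates = 100L,
                          n_transitions = 14L,
                          p_favourable = NULL,
                          p_unfavourable = 1 / 3,
                          seed = 1L) {
  climate_rule <- match.arg(climate_rule, scenario_rules())
  if (!recruit_multiplier %in% c(1, 2, 5, 10)) {
    check_number(recruit_multiplier, "recruit_multiplier", lower = 0)
  }
  stopifnot(all(species_codes() %in% names(init_density)))
  if (any(init_density < 0)) stop("densities must be >= 0", call. = FALSE)
  block <- match.arg(block, c("A", "B"))
  check_number(n_replicates, "n_replicates", lower = 1)
  check_number(n_transitions, "n_transitions", lower = 1)
  if (is.null(p_favourable)) {
    p_favourable <- if (grepl("_LS$", climate_rule)) 1 / 4 else 1 / 3
  }
  check_number(p_favourable, "p_favourable", lower = 0, upper = 1)
  check_number(p_unfavourable, "p_unfavourable", lower = 0, upper = 1)
  structure(list(name = name, climate_rule = climate_rule,
                 recruit_multiplier = recruit_multiplier,
                 init_density = init_density,
                 interaction_on = isTRUE(interaction_on), block = block,
                 n_replicates = as.integer(n_replicates),
                 n_transitions = as.integer(n_transitions),
                 p_favourable = p_favourable,
                 p_unfavourable = p_unfavourable,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Sample a climate sequence under a scenario rule
#'
#' Draws `n_transitions` years from the pool. Under a favourable rule each
#' draw is the designated favourable year with probability `p_fav`,
#' otherwise uniform over the remaining pool years, so the favourable
#' year's nominal frequency is exactly `p_fav`; the unfavourable rule is
#' analogous; the combined rules draw favourable first, then unfavourable
#' on the remaining mass, then uniform over the rest. The favourable-year
#' mask (which triggers recruitment pulses) marks the draws equal to the
#' designated favourable year.
#'
#' @param rule One of `r paste(scenario_rules(), collapse = ", ")`.
#' @param pool Climate pool data frame with a `year` column.
#' @param n_transitions Sequence length.
#' @param seed Integer seed.
#' @param fav_year,unfav_year Designated years (required by the non-random
#'   rules; see [designate_years()]).
#' @param p_fav,p_unfav Rule probabilities (defaults as in
#'   [scenario_spec()]).
#' @return List: `years` (drawn year labels), `climate` (the drawn rows),
#'   `favourable_mask` (logical).
#' @export
sample_climate_sequence <- function(rule, pool, n_transitions, seed,
                                    fav_year = NULL, unfav_year = NULL,
                                    p_fav = NULL, p_unfav = 1 / 3) {
  rule <- match.arg(rule, scenario_rules())
  if (!nrow(pool)) stop("climate pool is empty", call. = FALSE)
  check_number(n_transitions, "n_transitions", lower = 1)
  if (is.null(p_fav)) p_fav <- if (grepl("_LS$", rule)) 1 / 4 else 1 / 3
  years <- pool$year
  needs_fav <- grepl("^(favourable|combined)", rule)
  needs_unfav <- rule %in% c("unfavourable", "combined_HS", "combined_LS")
  if (needs_fav && (is.null(fav_year) || !fav_year %in% years)) {
    stop("rule ", rule, " needs a `fav_year` from the pool", call. = FALSE)
  }
  if (needs_unfav && (is.null(unfav_year) || !unfav_year %in% years)) {
    stop("rule ", rule, " needs an `unfav_year` from the pool", call. = FALSE)
  }
  set.seed(as.integer(seed))
  rest <- setdiff(years, c(if (needs_fav) fav_year,
                           if (needs_unfav) unfav_year))
  draw <- integer(n_transitions)
  # three uniforms are consumed per year under every rule, so sequences
  # drawn under different rules from the same seed share their random
  # numbers: rule comparisons at a fixed seed are paired (common random
  # numbers)
  for (t in seq_len(n_transitions)) {
    u <- runif(1)   # favourable / unfavourable branch decision
    w <- runif(1)   # secondary unfavourable decision (combined rules)
    v <- runif(1)   # uniform-branch year
    if (needs_fav && u < p_fav) {
      draw[t] <- fav_year
    } else if (needs_unfav &&
               ((rule == "unfavourable" && u < p_unfav) ||
                (rule != "unfavourable" && w < p_unfav))) {
      draw[t] <- unfav_year
    } else {
      draw[t] <- rest[min(length(rest), 1L + floor(v * length(rest)))]
    }
  }
  mask <- if (!is.null(fav_year)) draw == fav_year else
    rep(FALSE, n_transitions)
  list(years = draw, climate = pool[match(draw, years), , drop = FALSE],
       favourable_mask = mask)
}

#' Stochastic population growth rate
#'
#' The long-run mean annual log change of total density,
#' `log lambda_s = (1/T) sum log(N_t / N_(t-1)) = (1/T) log(N_T / N_0)`. In
#' the deterministic, density-independent limit this reduces to the log of
#' the kernel's dominant eigenvalue. Extinction (`N_t = 0`) returns `-Inf`
#' flagged with attribute `extinct = TRUE`.
#'
#' @param totals Numeric vector of total densities `N_0 .. N_T` (a
#'   trajectory), `N_0 > 0`; alternatively the result of
#'   [run_projection()] together with `species`.
#' @param species When `totals` is a projection result: which species'
#'   totals to use.
#' @param discard Number of initial transitions to drop (transient
#'   removal) before computing the rate.
#' @return Scalar log growth rate (possibly `-Inf`, attribute `extinct`).
#' @export
stochastic_growth_rate <- function(totals, species = NULL, discard = 0L) {
  if (is.list(totals) && !is.null(totals$summary)) {
    stopifnot(!is.null(species))
    s <- totals$summary
    totals <- s$total_density[s$species == species][order(s$year[s$species == species])]
  }
  if (!is.numeric(totals) || length(totals) < 2L) {
    stop("need a trajectory of at least two totals", call. = FALSE)
  }
  if (discard > 0) totals <- totals[-seq_len(discard)]
  if (totals[1] <= 0) stop("initial total density must be positive", call. = FALSE)
  if (any(totals == 0)) {
    return(structure(-Inf, extinct = TRUE))
  }
  Tn <- length(totals) - 1L
  structure(log(totals[length(totals)] / totals[1]) / Tn, extinct = FALSE)
}

#' Run one scenario
#'
#' Executes `n_replicates` independent projections of the coupled
#' two-species IPM under the scenario's climate rule, each replicate with
#' its own counter-based seed (`spec$seed + replicate`), applying the
#' recruitment multiplier only in favourable-mask years, and summarises
#' the stochastic growth rates per species by median and quartiles
#' (`quantile` type 7, linear interpolation). Extinct and failed
#' replicates are recorded, never silently dropped; summaries are over the
#' surviving replicates with the extinct/failed counts reported.
#'
#' @param spec A [scenario_spec()].
#' @param sets Named list of [vital_rate_set()]s.
#' @param pool Climate pool.
#' @param designations Favourable/unfavourable years from
#'   [designate_years()] (computed from `pool` and `sets` when omitted).
#' @param grid Integration mesh.
#' @return Object of class `scenario_result`: `spec`, `replicates` (tidy
#'   per-replicate log growth rates), `summary` (per species median,
#'   quartiles, extinct and failed counts).
#' @export
run_scenario <- function(spec, sets, pool = default_climate_pool(),
                         designations = NULL, grid = default_grid()) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(designations)) designations <- designate_years(pool, sets,
                                                             grid = grid)
  fav_sp <- sub("^(favourable|combined)_", "", spec$climate_rule)
  fav_year <- if (fav_sp %in% species_codes())
    designations$favourable[[fav_sp]] else NULL
  unfav_year <- designations$unfavourable
  reps <- vector("list", spec$n_replicates)
  for (r in seq_len(spec$n_replicates)) {
    res <- tryCatch({
      seq_r <- sample_climate_sequence(
        spec$climate_rule, pool, spec$n_transitions,
        seed = spec$seed + r, fav_year = fav_year, unfav_year = unfav_year,
        p_fav = spec$p_favourable, p_unfav = spec$p_unfavourable)
      mult <- ifelse(seq_r$favourable_mask, spec$recruit_multiplier, 1)
      cs <- coupled_state(
        list(HS = initial_state("HS", spec$init_density[["HS"]], grid),
             LS = initial_state("LS", spec$init_density[["LS"]], grid)),
        block = spec$block, interaction_on = spec$interaction_on)
      proj <- run_projection(cs, sets, seq_r$climate,
                             recruit_multipliers = mult)
      lam <- lapply(species_codes(), function(sp)
        stochastic_growth_rate(proj, species = sp))
      data.frame(replicate = r, species = species_codes(),
                 log_lambda_s = vapply(lam, as.numeric, numeric(1)),
                 extinct = vapply(lam, function(x)
                   isTRUE(attr(x, "extinct")), logical(1)),
                 failed = FALSE, error = NA_character_)
    }, error = function(e) {
      data.frame(replicate = r, species = species_codes(),
                 log_lambda_s = NA_real_, extinct = NA, failed = TRUE,
                 error = conditionMessage(e))
    })
    reps[[r]] <- res
  }
  reps <- do.call(rbind, reps)
  summ <- do.call(rbind, lapply(species_codes(), function(sp) {
    x <- reps[reps$species == sp, ]
    ok <- !x$failed & !x$extinct
    q <- if (any(ok)) quantile(x$log_lambda_s[ok], c(0.25, 0.5, 0.75),
                               type = 7, names = FALSE) else rep(NA_real_, 3)
    data.frame(scenario = spec$name, species = sp, block = spec$block,
               interaction_on = spec$interaction_on,
               climate_rule = spec$climate_rule,
               recruit_multiplier = spec$recruit_multiplier,
               q25 = q[1], median = q[2], q75 = q[3],
               n = sum(ok), n_extinct = sum(x$extinct %in% TRUE),
               n_failed = sum(x$failed))
  }))
  structure(list(spec = spec, replicates = reps, summary = summ),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s (%d replicates x %d transitions)\n",
              x$spec$name, x$spec$n_replicates, x$spec$n_transitions))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Run a battery of scenarios
#'
#' Runs every spec in turn, collecting the per-species summaries into one
#' tidy table; a scenario that errors is recorded (`error` column) and the
#' battery continues.
#'
#' @param specs Non-empty list of [scenario_spec()]s.
#' @param sets Named list of [vital_rate_set()]s.
#' @param pool Climate pool.
#' @param designations Precomputed [designate_years()] result (computed
#'   once when omitted).
#' @param grid Integration mesh.
#' @return Data frame of summaries; attribute `"results"` keeps the full
#'   `scenario_result` objects.
#' @export
run_scenario_battery <- function(specs, sets, pool = default_climate_pool(),
                                 designations = NULL, grid = default_grid()) {
  if (!length(specs)) stop("empty scenario list", call. = FALSE)
  if (is.null(designations)) designations <- designate_years(pool, sets,
                                                             grid = grid)
  results <- lapply(specs, function(spec) {
    tryCatch(run_scenario(spec, sets, pool, designations, grid),
             error = function(e) e)
  })
  rows <- lapply(seq_along(specs), function(i) {
    r <- results[[i]]
    if (inherits(r, "error")) {
      data.frame(scenario = specs[[i]]$name, species = NA_character_,
                 block = specs[[i]]$block,
                 interaction_on = specs[[i]]$interaction_on,
                 climate_rule = specs[[i]]$climate_rule,
                 recruit_multiplier = specs[[i]]$recruit_multiplier,
                 q25 = NA_real_, median = NA_real_, q75 = NA_real_,
                 n = 0L, n_extinct = NA_integer_, n_failed = NA_integer_,
                 error = conditionMessage(r))
    } else {
      cbind(r$summary, error = NA_character_)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}

#' The default scenario battery
#'
#' The 24 climate-by-recruitment simulations (six climate rules crossed
#' with recruitment multipliers 1, 2, 5 and 10) plus the initial-density
#' experiments (the four 2/20 individuals-per-m^2 combinations under
#' tenfold recruitment and three contrasting climate rules), for one block
#' and one interaction-flag setting. Use [expand_scenarios()] to replicate
#' a battery across blocks and interaction settings.
#'
#' @param n_replicates,n_transitions Replication design per scenario.
#' @param block,interaction_on Scenario context.
#' @param seed Base seed; scenario `i` uses `seed + 1000 i`.
#' @return List of [scenario_spec()]s.
#' @export
default_battery <- function(n_replicates = 100L, n_transitions = 14L,
                            block = "A", interaction_on = TRUE, seed = 1L) {
  specs <- list()
  i <- 0L
  for (rule in scenario_rules()) {
    for (m in c(1, 2, 5, 10)) {
      i <- i + 1L
      specs[[i]] <- scenario_spec(
        name = sprintf("sim%02d_%s_x%g", i, rule, m),
        climate_rule = rule, recruit_multiplier = m,
        block = block, interaction_on = interaction_on,
        n_replicates = n_replicates, n_transitions = n_transitions,
        seed = seed + 1000L * i)
    }
  }
  for (rule in c("random", "favourable_HS", "favourable_LS")) {
    for (dh in c(2, 20)) for (dl in c(2, 20)) {
      i <- i + 1L
      specs[[i]] <- scenario_spec(
        name = sprintf("dens_%s_HS%d_LS%d", rule, dh, dl),
        climate_rule = rule, recruit_multiplier = 10,
        init_density = c(HS = dh, LS = dl),
        block = block, interaction_on = interaction_on,
        n_replicates = n_replicates, n_transitions = n_transitions,
        seed = seed + 1000L * i)
    }
  }
  specs
}

#' Replicate scenario specs across blocks and interaction settings
#'
#' @param specs List of [scenario_spec()]s.
#' @param blocks Block labels to cover.
#' @param interaction_on Logical settings to cover.
#' @return Expanded list of specs with suffixed names.
#' @export
expand_scenarios <- function(specs, blocks = c("A", "B"),
                             interaction_on = c(TRUE, FALSE)) {
  out <- list()
  for (spec in specs) for (b in blocks) for (flag in interaction_on) {
    s <- spec
    s$block <- b
    s$interaction_on <- flag
    s$name <- sprintf("%s_%s_%s", spec$name, b, if (flag) "int" else "noint")
    out[[length(out) + 1L]] <- s
  }
  out
}

#' Spearman rank correlation between two lambda series
#'
#' Synchrony measure between the two species' annual growth-rate series;
#' ties are mid-ranked. Constant series have undefined rank correlation
#' and return `NA` with a warning.
#'
#' @param series_a,series_b Equal-length numeric series (length >= 3).
#' @return Spearman rho in `[-1, 1]`, or `NA` for constant input.
#' @export
compare_lambda_series <- function(series_a, series_b) {
  if (length(series_a) != length(series_b) || length(series_a) < 3L) {
    stop("series must have equal length >= 3", call. = FALSE)
  }
  if (sd(series_a) == 0 || sd(series_b) == 0) {
    warning("rank correlation undefined for a constant series")
    return(NA_real_)
  }
  cor(series_a, series_b, method = "spearman")
}
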