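#' Summer water balance
#'
#' Drought covariate used by the vital-rate models: accumulated June to
#' September rainfall minus twice the mean June to September temperature,
#' `P - 2 T`, in mm.
#'
#' @param rain_mm Accumulated June--September rainfall (mm), non-negative.
#' @param mean_temp_c Mean June--September temperature (degrees C).
#' @return Water balance in mm (may be negative).
#' @examples
#' summer_water_balance(100, 25) # 50
#' @export
summer_water_balance <- function(rain_mm, mean_temp_c) {
  if (!is.numeric(rain_mm) || !is.numeric(mean_temp_c)) {
    stop("`rain_mm` and `mean_temp_c` must be numeric", call. = FALSE)
  }
  if (any(is.na(rain_mm)) || any(rain_mm < 0)) {
    stop("`rain_mm` must be non-negative", call. = FALSE)
  }
  rain_mm - 2 * mean_temp_c
}

#' Default annual climate covariate ranges
#'
#' Uniform sampling ranges for the three annual climate covariates: mean of
#' daily minimum temperatures December--February (degrees C), accumulated
#' February--May rainfall (mm), and June--September water balance (mm,
#' P - 2T). The spans are set so that, at the per-unit magnitudes of the
#' packaged vital-rate coefficients, interannual variation produces strong
#' but survivable fluctuations: adult survival swings between drought
#' mortality episodes and near-certain survival without deterministically
#' extinguishing a 9-census synthetic community, while fecundity swings by
#' two to three orders of magnitude (the pulse recruitment typical of
#' semiarid gypsum shrublands).
#'
#' @return Named list of length-2 numeric ranges: `winter_min_temp`,
#'   `spring_rain`, `summer_wb`.
#' @export
default_climate_ranges <- function() {
  list(
    winter_min_temp = c(0, 4),
    spring_rain     = c(120, 180),
    summer_wb       = c(-30, 10)
  )
}

climate_covariates <- function() c("winter_min_temp", "spring_rain", "summer_wb")

#' Generate an annual climate series
#'
#' Draws each covariate independently and uniformly within its range, one
#' value per year. Intended to emulate an observed interannual climate table;
#' the scenario machinery resamples whole years from such a pool, so only
#' coverage of the ranges matters, not serial structure.
#'
#' @param n_years Number of years (>= 1).
#' @param ranges Named list of `c(min, max)` ranges as
#'   [default_climate_ranges()].
#' @param seed Integer seed; identical seeds give identical series.
#' @param start_year First calendar year label.
#' @return A data frame with columns `year`, `winter_min_temp`,
#'   `spring_rain`, `summer_wb`.
#' @export
generate_climate_series <- function(n_years, ranges = default_climate_ranges(),
                                    seed = 1L, start_year = 2000L) {
  check_number(n_years, "n_years", lower = 1)
  vars <- climate_covariates()
  if (!all(vars %in% names(ranges))) {
    stop("`ranges` must name ", paste(vars, collapse = ", "), call. = FALSE)
  }
  for (v in vars) {
    r <- ranges[[v]]
    if (length(r) != 2L || any(!is.finite(r)) || r[2] <= r[1]) {
      stop("empty or inverted range for `", v, "`", call. = FALSE)
    }
    if (v == "spring_rain" && r[1] < 0) {
      stop("spring rainfall range must be non-negative", call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  out <- data.frame(year = seq.int(start_year, length.out = n_years))
  for (v in vars) {
    out[[v]] <- runif(n_years, ranges[[v]][1], ranges[[v]][2])
  }
  out
}

#' Default synthetic climate pool (2000--2015 analogue)
#'
#' A fixed 16-year synthetic climate table playing the role of the observed
#' 2000--2015 record that drives the scenario simulations. It is generated
#' (deterministically) from [generate_climate_series()]; it is a synthetic
#' stand-in, not observed data.
#'
#' @param seed Seed for the pool (fixed default so the pool is stable).
#' @return Data frame of 16 climate years, 2000--2015.
#' @export
default_climate_pool <- function(seed = 2000L) {
  generate_climate_series(16L, default_climate_ranges(), seed = seed,
                          start_year = 2000L)
}

# internal: validate a single climate row / named list
check_climate <- function(climate) {
  vars <- climate_covariates()
  if (is.data.frame(climate)) {
    if (nrow(climate) != 1L) stop("`climate` must be a single year", call. = FALSE)
    climate <- as.list(climate)
  }
  if (!all(vars %in% names(climate))) {
    missing <- setdiff(vars, names(climate))
    stop("climate is missing: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  lapply(climate[vars], function(x) check_number(x, "climate covariate"))
  climate[vars]
}
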