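#' @name census_io
#' @title Read and write demographic interchange files
#'
#' @description
#' Plain CSV interchange formats (comma-separated, UTF-8, `.` decimal,
#' header required; columns may appear in any order). Readers validate and
#' reject malformed rows with their file line numbers rather than coercing.
#' Lines starting with `#` are treated as comments (writers may prepend a
#' provenance comment recording the master seed and configuration hash).
#'
#' * census: `plant_id, species, block, plot_id, year, size_cm2,
#'   alive_next, size_next_cm2, flowering`
#' * climate: `year, winter_min_temp, spring_rain, summer_wb`
#' * seedlings: `plot_id, block, year, species, seedlings`
NULL

census_columns <- function() {
  c("plant_id", "species", "block", "plot_id", "year", "size_cm2",
    "alive_next", "size_next_cm2", "flowering")
}

read_table_checked <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(columns, names(d))
  if (length(missing)) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d[, columns, drop = FALSE]
}

# collect per-row validation failures and raise one error naming data lines
reject_rows <- function(bad, why, path) {
  if (!any(bad)) return(invisible(NULL))
  lines <- which(bad) + 1L  # +1 for the header line
  stop(sprintf("%s: %s at line(s) %s", basename(path), why,
               paste(head(lines, 10L), collapse = ", ")), call. = FALSE)
}

#' @rdname census_io
#' @param path File path.
#' @return `read_census()`: validated data frame of plant-year records.
#' @export
read_census <- function(path) {
  d <- read_table_checked(path, census_columns())
  reject_rows(!d$species %in% species_codes(), "unknown species code", path)
  reject_rows(!is.finite(d$size_cm2) | d$size_cm2 <= 0,
              "non-positive size_cm2", path)
  reject_rows(!d$alive_next %in% c(0L, 1L), "alive_next must be 0/1", path)
  reject_rows(d$alive_next == 1L &
                (!is.finite(d$size_next_cm2) | d$size_next_cm2 <= 0),
              "survivors need positive size_next_cm2", path)
  reject_rows(d$alive_next == 0L & !is.na(d$size_next_cm2),
              "size_next_cm2 must be absent for dead plants", path)
  hs_bad <- d$species == "HS" & !d$flowering %in% c("0", "1")
  ls_bad <- d$species == "LS" & !d$flowering %in% flowering_levels()
  reject_rows(hs_bad | ls_bad, "invalid flowering code", path)
  d$flowering <- as.character(d$flowering)
  d
}

write_with_header <- function(d, path, seed = NULL, config_hash = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(seed)) {
    writeLines(sprintf("# coexipm seed=%s config=%s", format(seed),
                       if (is.null(config_hash)) "-" else config_hash), con)
  }
  write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname census_io
#' @param records Data frame of census records (see `read_census`).
#' @param seed,config_hash Optional provenance written as a leading comment.
#' @export
write_census <- function(records, path, seed = NULL, config_hash = NULL) {
  write_with_header(records[, census_columns()], path, seed, config_hash)
}

#' @rdname census_io
#' @export
read_climate <- function(path) {
  d <- read_table_checked(path, c("year", climate_covariates()))
  reject_rows(!is.finite(d$spring_rain) | d$spring_rain < 0,
              "spring_rain must be non-negative", path)
  for (v in c("winter_min_temp", "summer_wb")) {
    reject_rows(!is.finite(d[[v]]), paste(v, "must be finite"), path)
  }
  d
}

#' @rdname census_io
#' @param climate Data frame of climate years.
#' @export
write_climate <- function(climate, path, seed = NULL, config_hash = NULL) {
  write_with_header(climate[, c("year", climate_covariates())], path,
                    seed, config_hash)
}

#' @rdname census_io
#' @export
read_seedlings <- function(path) {
  d <- read_table_checked(path, c("plot_id", "block", "year", "species",
                                  "seedlings"))
  reject_rows(!d$species %in% species_codes(), "unknown species code", path)
  reject_rows(!is.finite(d$seedlings) | d$seedlings < 0 |
                d$seedlings != round(d$seedlings),
              "seedlings must be a non-negative count", path)
  d
}

#' @rdname census_io
#' @param seedlings Data frame of plot-level seedling counts.
#' @export
write_seedlings <- function(seedlings, path, seed = NULL, config_hash = NULL) {
  write_with_header(seedlings[, c("plot_id", "block", "year", "species",
                                  "seedlings")], path, seed, config_hash)
}

#' Hash a configuration object
#'
#' Small polynomial rolling hash over the deparsed object, used to stamp
#' output artifacts so reruns with identical configuration are
#' recognisable.
#'
#' @param x Any R object.
#' @return 8-hex-digit character scalar.
#' @export
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read a run configuration file
#'
#' Hierarchical YAML configuration driving [run_pipeline()]: input file
#' paths, mesh settings, candidate-set definition, scenario battery, master
#' seed, output directory. Missing entries take package defaults;
#' referenced input files must exist.
#'
#' @param path YAML file path.
#' @return Named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    seed = 1L,
    output_dir = ".",
    mesh = list(lower = 0.2, upper = 1200, n = 200),
    candidates = NULL,     # NULL = full additive candidate set
    scenarios = NULL,      # NULL = default battery
    replicates = 100L,
    transitions = 14L
  )
  cfg <- modifyList(defaults, cfg)
  for (f in c("census", "climate", "seedlings")) {
    if (!is.null(cfg$files[[f]]) && !file.exists(cfg$files[[f]])) {
      stop("configured file does not exist: ", cfg$files[[f]], call. = FALSE)
    }
  }
  class(cfg) <- "run_config"
  cfg
}
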