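#' Intra- and interspecific interaction indices for a focal plant
#'
#' The intraspecific index is the summed cover of all conspecifics in the
#' plot excluding the focal plant itself; the interspecific index is the
#' summed cover of all individuals of the other focal species in the plot.
#' Covers are fractions of plot area; both indices are dimensionless and
#' non-negative (sums of fractions may exceed 1 when crowns overlap). Only
#' the two focal species are considered.
#'
#' @param focal Integer/character id of the focal plant; must match one row
#'   of `plot_plants`.
#' @param plot_plants Data frame with columns `plant_id`, `species`
#'   (`"HS"`/`"LS"`) and `cover` (fraction of plot area, >= 0) describing
#'   every focal-species plant in the plot.
#' @return Named numeric vector `c(intra = , inter = )`.
#' @examples
#' plants <- data.frame(plant_id = 1:4, species = c("HS", "HS", "HS", "LS"),
#'                      cover = c(0.10, 0.20, 0.30, 0.15))
#' interaction_indices(1, plants) # intra 0.50, inter 0.15
#' @export
interaction_indices <- function(focal, plot_plants) {
  need <- c("plant_id", "species", "cover")
  if (!all(need %in% names(plot_plants))) {
    stop("`plot_plants` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  i <- which(plot_plants$plant_id == focal)
  if (length(i) != 1L) {
    stop("focal plant not found (exactly once) in `plot_plants`", call. = FALSE)
  }
  if (any(plot_plants$cover < 0)) stop("covers must be >= 0", call. = FALSE)
  sp <- plot_plants$species[i]
  other <- setdiff(species_codes(), sp)
  same <- plot_plants$species == sp
  c(intra = sum(plot_plants$cover[same]) - plot_plants$cover[i],
    inter = sum(plot_plants$cover[plot_plants$species == other]))
}

#' Interaction indices for every plant in a plot
#'
#' Vectorised form of [interaction_indices()]: one `(intra, inter)` pair per
#' row of `plot_plants`, each excluding that row's own cover from its
#' conspecific sum.
#'
#' @inheritParams interaction_indices
#' @return Data frame with columns `plant_id`, `intra`, `inter` aligned with
#'   the rows of `plot_plants`.
#' @export
plot_interaction_indices <- function(plot_plants) {
  if (any(plot_plants$cover < 0)) stop("covers must be >= 0", call. = FALSE)
  tot <- vapply(species_codes(), function(s) {
    sum(plot_plants$cover[plot_plants$species == s])
  }, numeric(1))
  own <- tot[plot_plants$species]
  other <- tot[setdiff_species(plot_plants$species)]
  data.frame(plant_id = plot_plants$plant_id,
             intra = unname(own - plot_plants$cover),
             inter = unname(other))
}

# internal: vectorised "the other focal species"
setdiff_species <- function(sp) {
  codes <- species_codes()
  ifelse(sp == codes[1], codes[2], codes[1])
}
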