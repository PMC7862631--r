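#' Flowering-degree allocation weights
#'
#' Relative weights used to split plot-level seedling counts among flowering
#' adults of the ordinal-flowering species: 60%, 30% and 10% for high,
#' medium and low flowering degree, and 0 for non-flowering plants.
#'
#' @return Named numeric vector over `none`, `low`, `medium`, `high`.
#' @export
flowering_weights <- function() {
  c(none = 0, low = 0.1, medium = 0.3, high = 0.6)
}

#' Flowering degree levels
#' @return Ordered character vector of the four ordinal flowering levels.
#' @export
flowering_levels <- function() c("none", "low", "medium", "high")

#' Allocate plot seedlings to adults as per-plant fecundities
#'
#' Observed plot-level seedling counts are assigned to the plot's adults in
#' proportion to plant size (species `"HS"`), or to plant size times the
#' flowering-degree weight (species `"LS"`, weights 0.6/0.3/0.1 for
#' high/medium/low and 0 for none). Allocated fecundities sum exactly to the
#' seedling count (the largest-weight share absorbs any floating-point
#' residual).
#'
#' @param plot_seedlings Non-negative seedling count for the plot-year.
#' @param sizes Adult sizes (crown projected area, cm^2), positive.
#' @param species `"HS"` or `"LS"`.
#' @param flowering For `"HS"`: logical/0-1 flowering status. For `"LS"`:
#'   character or factor with levels in [flowering_levels()].
#' @return Numeric vector of per-adult fecundities, summing to
#'   `plot_seedlings`. When `plot_seedlings > 0` but all weights are 0 the
#'   plot-year is unassignable: all values are `NA` and the result carries
#'   attribute `unassignable = TRUE` (such rows are excluded from fitting).
#' @examples
#' fecundity_per_plant(10, c(100, 300), "HS", c(1, 1)) # 2.5, 7.5
#' @export
fecundity_per_plant <- function(plot_seedlings, sizes, species, flowering) {
  check_number(plot_seedlings, "plot_seedlings", lower = 0)
  species <- match.arg(species, species_codes())
  n <- length(sizes)
  if (length(flowering) != n) {
    stop("`sizes` and `flowering` lengths differ", call. = FALSE)
  }
  if (n == 0L) {
    if (plot_seedlings > 0) {
      out <- numeric(0)
      attr(out, "unassignable") <- TRUE
      return(out)
    }
    return(numeric(0))
  }
  if (any(sizes <= 0)) stop("sizes must be positive", call. = FALSE)
  if (species == "HS") {
    fl <- as.numeric(flowering)
    if (any(is.na(fl)) || !all(fl %in% c(0, 1))) {
      stop("HS flowering must be binary", call. = FALSE)
    }
    w <- sizes * fl
  } else {
    lev <- as.character(flowering)
    if (!all(lev %in% flowering_levels())) {
      stop("LS flowering degrees must be one of ",
           paste(flowering_levels(), collapse = "/"), call. = FALSE)
    }
    w <- sizes * flowering_weights()[lev]
  }
  if (plot_seedlings == 0) return(numeric(n))
  sw <- sum(w)
  if (sw == 0) {
    out <- rep(NA_real_, n)
    attr(out, "unassignable") <- TRUE
    return(out)
  }
  fec <- plot_seedlings * w / sw
  # enforce exact conservation of the seedling count: push the residual of
  # the floating-point sum onto the largest share until sum(fec) == total
  k <- which.max(w)
  for (i in 1:5) {
    resid <- plot_seedlings - sum(fec)
    if (resid == 0) break
    fec[k] <- fec[k] + resid
  }
  unname(fec)
}
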