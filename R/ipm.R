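#' Midpoint-rule integration mesh
#'
#' Discretises the size domain `[lower, upper]` (crown area, cm^2) into
#' `n_mesh` equal cells; kernels are evaluated at the cell midpoints
#' `z_i = lower + (i - 1/2) h` with cell width `h = (upper - lower)/n_mesh`.
#'
#' @param lower,upper Integration limits of the kernel (sizes), `upper >
#'   lower`.
#' @param n_mesh Number of midpoints (>= 2); the IPM matrix is
#'   `n_mesh x n_mesh`, 200 by default throughout the package.
#' @return Object of class `ipm_grid`: `lower`, `upper`, `n`, `h`, `mid`.
#' @examples
#' build_grid(0, 1, 2)$mid # 0.25, 0.75
#' @export
build_grid <- function(lower, upper, n_mesh = 200L) {
  check_number(lower, "lower")
  check_number(upper, "upper")
  if (upper <= lower) stop("`upper` must exceed `lower`", call. = FALSE)
  check_number(n_mesh, "n_mesh", lower = 2)
  n_mesh <- as.integer(n_mesh)
  h <- (upper - lower) / n_mesh
  structure(list(lower = lower, upper = upper, n = n_mesh, h = h,
                 mid = lower + (seq_len(n_mesh) - 0.5) * h),
            class = "ipm_grid")
}

#' Default size mesh
#'
#' Covers recruit sizes through the largest crowns the default growth model
#' can plausibly produce. With census data at hand, prefer bounds of half
#' the minimum to 1.2 times the maximum observed size
#' ([grid_from_sizes()]).
#'
#' @param n_mesh Number of midpoints.
#' @return An [build_grid()] object on `[0.2, 1200]` cm^2.
#' @export
default_grid <- function(n_mesh = 200L) build_grid(0.2, 1200, n_mesh)

#' Mesh bounds from observed sizes
#'
#' @param sizes Observed sizes (cm^2).
#' @param n_mesh Number of midpoints.
#' @return An [build_grid()] object on `[0.5 min(sizes), 1.2 max(sizes)]`.
#' @export
grid_from_sizes <- function(sizes, n_mesh = 200L) {
  sizes <- sizes[is.finite(sizes)]
  if (!length(sizes) || any(sizes <= 0)) {
    stop("`sizes` must be positive", call. = FALSE)
  }
  build_grid(0.5 * min(sizes), 1.2 * max(sizes), n_mesh)
}

#' Build a discretised IPM kernel
#'
#' Assembles the midpoint-rule discretisation of the kernel
#' `K(y, x) = s(x) g(y | x) + f(y, x)` from a species' four vital-rate
#' models under a fixed covariate context (one climate year, intra- and
#' interspecific covers, block):
#'
#' * survival-growth component `P[j, i] = s(z_i) g(z_j | z_i) h`, with `g` a
#'   Gaussian density of next size centred on the growth model's expected
#'   next size (floored at the mesh lower bound) with the model's residual
#'   SD. The integration over the source size `x` uses the midpoint rule;
#'   in the destination direction each cell receives the exact Gaussian
#'   probability mass of that cell (CDF differences divided by `h`), which
#'   stays accurate when the growth SD is comparable to the cell width.
#'   Probability mass falling off the mesh (eviction) is corrected by
#'   renormalising each column to its on-mesh mass, so column sums of `P`
#'   equal the predicted survival probabilities exactly; columns whose raw
#'   on-mesh mass falls below `eviction_threshold` are recorded in the
#'   kernel's `eviction` field and logged when `options(coexipm.verbose)`
#'   is set.
#' * fecundity component `F[j, i] = p_repro(z_i) fec(z_i) c(z_j) h`, with
#'   `c` the log-normal recruit-size density truncated and renormalised on
#'   the mesh (an error if its on-mesh mass is below 0.99: mesh too
#'   narrow). No separate establishment probability is applied: fecundity
#'   is calibrated on emerged seedlings, so first-summer mortality is part
#'   of the first survival transition. `F` is scaled by
#'   `recruit_multiplier` (recruitment-pulse scenarios).
#'
#' The build is pure: identical inputs give bit-identical matrices.
#'
#' @param set A [vital_rate_set()] with all four rates.
#' @param climate One climate year (named list or single-row data frame
#'   with `winter_min_temp`, `spring_rain`, `summer_wb`).
#' @param intra,inter Cover covariates in `[0, Inf)` (fractions).
#' @param block `"A"` or `"B"`.
#' @param grid An [build_grid()] mesh.
#' @param recruit_multiplier Non-negative scaling of the fecundity
#'   component only.
#' @param eviction_threshold Raw on-mesh growth mass below which a column is
#'   flagged as heavily evicted.
#' @return Object of class `ipm_kernel`: matrices `K`, `P`, `F`, the
#'   `grid`, the covariate `context`, per-column `eviction`, and the
#'   survival vector `s`.
#' @export
build_kernel <- function(set, climate, intra, inter, block = "A",
                         grid = default_grid(), recruit_multiplier = 1,
                         eviction_threshold = 0.995) {
  stopifnot(inherits(set, "vital_rate_set"), inherits(grid, "ipm_grid"))
  climate <- check_climate(climate)
  check_number(intra, "intra", lower = 0)
  check_number(inter, "inter", lower = 0)
  check_number(recruit_multiplier, "recruit_multiplier", lower = 0)
  block <- match.arg(block, c("A", "B"))
  z <- grid$mid
  h <- grid$h
  nd <- data.frame(size = z, block = block, intra = intra, inter = inter,
                   winter_min_temp = climate$winter_min_temp,
                   spring_rain = climate$spring_rain,
                   summer_wb = climate$summer_wb)
  s  <- predict_rate(set$survival, nd)
  pr <- predict_rate(set$reproduction, nd)
  fe <- predict_rate(set$fecundity, nd)
  mu <- pmax(predict_rate(set$growth, nd), grid$lower)
  sg <- set$growth$sigma_resid

  edges <- grid$lower + (0:grid$n) * h
  G <- vapply(seq_along(z), function(i) {
    p <- pnorm(edges, mu[i], sg)
    (p[-1L] - p[-length(p)]) / h
  }, numeric(grid$n))
  mass <- h * colSums(G)
  if (any(mass <= 0)) {
    stop("growth density has no mass on the mesh; widen the grid",
         call. = FALSE)
  }
  flagged <- which(mass < eviction_threshold)
  if (length(flagged)) {
    coexipm_log(sprintf(
      "%s: eviction renormalisation on %d/%d column(s) (min mass %.4f)",
      set$species, length(flagged), grid$n, min(mass)))
  }
  P <- sweep(G, 2, s * h / mass, `*`)

  pc <- plnorm(edges, set$recruit_meanlog, set$recruit_sdlog)
  cdens <- (pc[-1L] - pc[-length(pc)]) / h
  cmass <- h * sum(cdens)
  if (cmass < 0.99) {
    stop(sprintf("recruit density mass on mesh is %.3f (< 0.99): mesh too narrow",
                 cmass), call. = FALSE)
  }
  cnorm <- cdens / cmass
  Fm <- (recruit_multiplier * h) * tcrossprod(cnorm, pr * fe)

  structure(list(K = P + Fm, P = P, F = Fm, grid = grid,
                 context = list(climate = climate, intra = intra,
                                inter = inter, block = block,
                                recruit_multiplier = recruit_multiplier),
                 eviction = 1 - mass, s = s),
            class = "ipm_kernel")
}

#' @export
print.ipm_kernel <- function(x, ...) {
  cat(sprintf("<ipm_kernel> %d x %d on [%.3g, %.3g]; block %s, intra %.2f, inter %.2f\n",
              x$grid$n, x$grid$n, x$grid$lower, x$grid$upper,
              x$context$block, x$context$intra, x$context$inter))
  invisible(x)
}

kernel_matrix <- function(x) {
  if (inherits(x, "ipm_kernel")) x$K
  else if (is.matrix(x)) x
  else stop("expected an ipm_kernel or a matrix", call. = FALSE)
}

#' Dominant eigenvalue (deterministic population growth rate)
#'
#' Computes the dominant eigenvalue lambda of a non-negative kernel matrix
#' by power iteration, falling back to a direct eigendecomposition when the
#' iteration does not converge (e.g. for rotation-like matrices with tied
#' leading eigenvalue moduli). The associated stable size distribution
#' (right eigenvector, summing to 1) is attached as attribute
#' `"stable_dist"`.
#'
#' @param kernel An `ipm_kernel` or a non-negative square matrix.
#' @param tol Convergence tolerance on successive lambda estimates.
#' @param max_iter Maximum power iterations.
#' @return Numeric lambda (>= 0) with attribute `stable_dist`.
#' @export
dominant_lambda <- function(kernel, tol = 1e-12, max_iter = 2000L) {
  K <- kernel_matrix(kernel)
  if (any(K < 0)) stop("kernel matrix must be non-negative", call. = FALSE)
  n <- nrow(K)
  w <- rep(1 / n, n)
  lam <- NA_real_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    v <- K %*% w
    lam_new <- sum(v)
    if (lam_new == 0) {  # nilpotent / zero kernel
      lam <- 0
      w <- rep(1 / n, n)
      converged <- TRUE
      break
    }
    w_new <- as.vector(v) / lam_new
    if (!is.na(lam) && abs(lam_new - lam) <= tol * max(1, abs(lam_new))) {
      lam <- lam_new
      w <- w_new
      converged <- TRUE
      break
    }
    lam <- lam_new
    w <- w_new
  }
  if (!converged) {
    e <- eigen(K)
    i <- which.max(abs(e$values))
    lam <- abs(e$values[i])
    wv <- abs(Re(e$vectors[, i]))
    w <- wv / sum(wv)
  }
  structure(lam, stable_dist = w)
}

#' Deterministic growth rate across a climate series
#'
#' One lambda per climate year at fixed covers and block: the machinery
#' behind lambda-versus-climate response curves.
#'
#' @param set A [vital_rate_set()].
#' @param climate_table Data frame of climate years.
#' @param intra,inter Fixed cover covariates (default 0.30, the
#'   community-median shrub cover).
#' @param block Block label.
#' @param grid Integration mesh.
#' @return Data frame `year`, `lambda`.
#' @export
lambda_vs_climate <- function(set, climate_table, intra = 0.30, inter = 0.30,
                              block = "A", grid = default_grid()) {
  if (!nrow(climate_table)) stop("`climate_table` is empty", call. = FALSE)
  lam <- vapply(seq_len(nrow(climate_table)), function(i) {
    as.numeric(dominant_lambda(build_kernel(
      set, climate_table[i, ], intra = intra, inter = inter,
      block = block, grid = grid)))
  }, numeric(1))
  data.frame(year = climate_table$year, lambda = lam)
}

#' Growth-rate surface over intra- and interspecific cover
#'
#' Evaluates lambda at every combination of the supplied cover levels under
#' one fixed climate, and flags the cells where the surface crosses the
#' stationarity contour lambda = 1 (a cell is flagged when any of its
#' axis-neighbours lies on the other side of 1).
#'
#' @param set A [vital_rate_set()].
#' @param climate One climate year.
#' @param intra_levels,inter_levels Cover levels in `[0, 1]`.
#' @param block Block label.
#' @param grid Integration mesh.
#' @return Tidy data frame `intra`, `inter`, `lambda`, `on_contour`;
#'   attribute `"lambda_matrix"` holds the intra x inter matrix.
#' @export
lambda_cover_surface <- function(set, climate,
                                 intra_levels = seq(0, 1, by = 0.1),
                                 inter_levels = seq(0, 1, by = 0.1),
                                 block = "A", grid = default_grid()) {
  if (any(intra_levels < 0 | intra_levels > 1) ||
      any(inter_levels < 0 | inter_levels > 1)) {
    stop("cover levels must lie in [0, 1]", call. = FALSE)
  }
  L <- matrix(NA_real_, length(intra_levels), length(inter_levels))
  for (i in seq_along(intra_levels)) {
    for (j in seq_along(inter_levels)) {
      L[i, j] <- as.numeric(dominant_lambda(build_kernel(
        set, climate, intra = intra_levels[i], inter = inter_levels[j],
        block = block, grid = grid)))
    }
  }
  above <- L >= 1
  contour <- matrix(FALSE, nrow(L), ncol(L))
  if (nrow(L) > 1) {
    d <- above[-1, , drop = FALSE] != above[-nrow(L), , drop = FALSE]
    contour[-1, ] <- contour[-1, ] | d
    contour[-nrow(L), ] <- contour[-nrow(L), ] | d
  }
  if (ncol(L) > 1) {
    d <- above[, -1, drop = FALSE] != above[, -ncol(L), drop = FALSE]
    contour[, -1] <- contour[, -1] | d
    contour[, -ncol(L)] <- contour[, -ncol(L)] | d
  }
  out <- expand.grid(intra = intra_levels, inter = inter_levels)
  out$lambda <- as.vector(L)
  out$on_contour <- as.vector(contour)
  attr(out, "lambda_matrix") <- L
  out
}

#' Export a kernel as CSV plus JSON sidecar
#'
#' Writes the kernel matrix as a plain CSV of numbers and a JSON sidecar
#' recording the mesh and the covariate context under which it was built.
#'
#' @param kernel An `ipm_kernel`.
#' @param path CSV output path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "ipm_kernel"))
  utils::write.table(kernel$K, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  side <- list(grid = kernel$grid[c("lower", "upper", "n", "h")],
               context = kernel$context)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
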