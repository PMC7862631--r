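#' Construct a vital-rate regression model
#'
#' A fitted (or externally specified) regression model for one vital rate of
#' one species: the link family is implied by the rate (survival and
#' reproduction: binomial-logit; growth: Gaussian-identity; fecundity:
#' Poisson-log). Plant size enters the linear predictor as `log(area)` by
#' default (`size_scale = "log"`), or as raw area (`size_scale = "raw"`);
#' survival additionally carries a quadratic size term. Reproduction models
#' never contain the summer water balance (flowering precedes summer).
#'
#' Growth is modelled as the size difference between consecutive years
#' (response in cm^2) with previous size as a covariate, so the predicted
#' response of the growth model is the expected next size
#' `size + eta` (see [predict_rate()]).
#'
#' @param species `"HS"` or `"LS"`.
#' @param rate One of [vital_rate_names()].
#' @param coef Named numeric vector of coefficients. Recognised names:
#'   `(Intercept)`, `size`, `size2` (survival only), `block_b`, `intra`,
#'   `inter`, `winter_temp`, `spring_rain`, `summer_wb`. Terms absent from
#'   the vector are dropped from the model.
#' @param se Optional named standard errors (matching `coef` names).
#' @param sigma_plot Plot random-intercept standard deviation (>= 0).
#' @param sigma_resid Residual standard deviation (growth models only, > 0).
#' @param size_scale `"log"` or `"raw"`: transform applied to size before it
#'   enters the linear predictor.
#' @param aic AIC of the fit (NA until fitted).
#' @param n_par Number of estimated parameters (fixed effects + variance
#'   components); computed from `coef` when missing.
#' @param converged Logical convergence flag; non-converged models carry
#'   `aic = Inf` and are never selected.
#' @param vcov Optional variance-covariance matrix of the coefficients.
#' @return An object of class `vital_rate_model`.
#' @export
vital_rate_model <- function(species, rate, coef, se = NULL,
                             sigma_plot = 0, sigma_resid = NULL,
                             size_scale = c("log", "raw"),
                             aic = NA_real_, n_par = NULL,
                             converged = TRUE, vcov = NULL) {
  species <- match.arg(species, species_codes())
  rate <- match.arg(rate, vital_rate_names())
  size_scale <- match.arg(size_scale)
  if (!is.numeric(coef) || is.null(names(coef)) || any(names(coef) == "")) {
    stop("`coef` must be a named numeric vector", call. = FALSE)
  }
  allowed <- c("(Intercept)", "size", "size2", model_terms_all())
  bad <- setdiff(names(coef), allowed)
  if (length(bad)) stop("unknown coefficient(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(!is.finite(coef))) stop("non-finite coefficient", call. = FALSE)
  if ("size2" %in% names(coef) && rate != "survival") {
    stop("quadratic size term is used for survival only", call. = FALSE)
  }
  if (rate == "reproduction" && "summer_wb" %in% names(coef)) {
    stop("reproduction models never contain summer_wb", call. = FALSE)
  }
  check_number(sigma_plot, "sigma_plot", lower = 0)
  if (rate == "growth") {
    if (is.null(sigma_resid)) sigma_resid <- NA_real_
    if (!is.na(sigma_resid)) check_number(sigma_resid, "sigma_resid", lower = 0)
  } else if (!is.null(sigma_resid)) {
    stop("`sigma_resid` applies to growth models only", call. = FALSE)
  }
  if (is.null(n_par)) {
    n_par <- length(coef) + (sigma_plot > 0) + (rate == "growth")
  }
  structure(
    list(species = species, rate = rate,
         family = rate_family(rate), link = rate_link(rate),
         coef = coef, se = se, vcov = vcov,
         sigma_plot = sigma_plot, sigma_resid = sigma_resid,
         size_scale = size_scale, aic = aic, n_par = n_par,
         converged = converged),
    class = "vital_rate_model")
}

model_terms_all <- function() {
  c("block_b", "intra", "inter", climate_covariates())
}

rate_family <- function(rate) {
  switch(rate, survival = "binomial", reproduction = "binomial",
         growth = "gaussian", fecundity = "poisson")
}

rate_link <- function(rate) {
  switch(rate, survival = "logit", reproduction = "logit",
         growth = "identity", fecundity = "log")
}

#' @export
print.vital_rate_model <- function(x, ...) {
  cat(sprintf("<vital_rate_model> %s %s (%s-%s)%s\n", x$species, x$rate,
              x$family, x$link,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  est <- data.frame(estimate = x$coef)
  if (!is.null(x$se)) est$se <- x$se[rownames(est)]
  print(round(est, 4))
  cat(sprintf("sigma_plot = %.4g", x$sigma_plot))
  if (x$rate == "growth") cat(sprintf(", sigma_resid = %.4g", x$sigma_resid))
  if (is.finite(x$aic)) cat(sprintf(", AIC = %.2f (k = %d)", x$aic, x$n_par))
  cat("\n")
  invisible(x)
}

# internal: size transform on the modelling scale of the linear predictor
size_covariate <- function(size, size_scale) {
  if (any(size <= 0)) stop("size must be positive", call. = FALSE)
  if (size_scale == "log") log(size) else size
}

# internal: linear predictor for a vital_rate_model over a covariate table
linear_predictor <- function(model, newdata) {
  cf <- model$coef
  n <- if (is.data.frame(newdata)) nrow(newdata) else
    max(lengths(newdata[lengths(newdata) > 0]), 1L)
  eta <- rep(0, n)
  need <- function(col, term) {
    if (is.null(newdata[[col]])) {
      stop(sprintf("covariate `%s` needed by term `%s` is missing", col, term),
           call. = FALSE)
    }
    newdata[[col]]
  }
  for (term in names(cf)) {
    x <- switch(term,
      "(Intercept)" = 1,
      size  = size_covariate(need("size", "size"), model$size_scale),
      size2 = size_covariate(need("size", "size2"), model$size_scale)^2,
      block_b = as.numeric(need("block", "block_b") == "B"),
      need(term, term))
    if (any(!is.finite(x))) {
      stop(sprintf("non-finite covariate for term `%s`", term), call. = FALSE)
    }
    eta <- eta + cf[[term]] * x
  }
  eta
}

#' Predict a vital rate from a fitted model
#'
#' Applies the model's linear predictor to a table of covariates and passes
#' it through the inverse link: survival and reproduction return
#' probabilities, fecundity returns expected per-adult seedling counts, and
#' growth returns the expected *next size* `size + eta` (the growth response
#' is the annual size difference in cm^2).
#'
#' @param model A [vital_rate_model()].
#' @param newdata Data frame (or named list) supplying every covariate the
#'   model uses: `size` (cm^2), `block` (`"A"`/`"B"`), `intra`, `inter`,
#'   `winter_min_temp`... climate columns are `winter_min_temp`,
#'   `spring_rain`, `summer_wb`. A missing covariate raises an error naming
#'   the term.
#' @param type `"response"` (default) or `"link"` (the raw linear predictor;
#'   for growth this is the expected size difference).
#' @return Numeric vector of predictions.
#' @export
predict_rate <- function(model, newdata, type = c("response", "link")) {
  stopifnot(inherits(model, "vital_rate_model"))
  type <- match.arg(type)
  eta <- linear_predictor(model, newdata)
  if (type == "link") return(eta)
  switch(model$family,
    binomial = plogis(eta),
    poisson  = exp(eta),
    gaussian = {
      if (is.null(newdata[["size"]])) {
        stop("covariate `size` needed by term `size` is missing", call. = FALSE)
      }
      newdata[["size"]] + eta
    })
}
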