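#' Assemble the transition-level modelling table
#'
#' Joins census records, climate and seedling counts into one row per
#' observed plant-year transition with everything the vital-rate GLMMs
#' need: responses (`surv`, `growth` = size difference in cm^2, `flowered`,
#' `fec` = allocated per-adult fecundity), the size covariate, plot-level
#' intra-/interspecific interaction indices (cover fractions of plot area,
#' own cover excluded from `intra`), and the three climate covariates of
#' the transition year.
#'
#' Seedlings counted in census year `t + 1` are allocated among the plot's
#' flowering adults of year `t` ([fecundity_per_plant()]); plot-years with
#' seedlings but no positive allocation weight are unassignable and
#' reported via the `"unassigned"` attribute (their `fec` stays `NA`).
#'
#' @param records Census records as returned by [read_census()] or
#'   [simulate_population()].
#' @param climate Climate table (`year` + covariates).
#' @param seedlings Plot-level seedling counts.
#' @param plot_area_cm2 Plot reference area for cover fractions.
#' @return Data frame, one row per plant-year; attribute `"unassigned"`
#'   lists unassignable plot-years.
#' @export
prepare_vital_rate_data <- function(records, climate, seedlings = NULL,
                                    plot_area_cm2 = 2500) {
  d <- records
  names(d)[names(d) == "size_cm2"] <- "size"
  d$cover <- d$size / plot_area_cm2
  idx <- do.call(rbind, lapply(split(d, list(d$plot_id, d$year), drop = TRUE),
    function(pp) {
      cbind(pp[, c("plant_id", "year")],
            plot_interaction_indices(
              pp[, c("plant_id", "species", "cover")])[, c("intra", "inter")])
    }))
  d <- merge(d, idx, by = c("plant_id", "year"), sort = FALSE)
  d <- merge(d, climate[, c("year", climate_covariates())], by = "year",
             sort = FALSE)
  d$surv <- d$alive_next
  d$growth <- d$size_next_cm2 - d$size
  d$flowered <- ifelse(d$species == "HS", as.integer(d$flowering == "1"),
                       as.integer(d$flowering != "none"))
  d$fec <- NA_real_
  unassigned <- list()
  if (!is.null(seedlings)) {
    key <- interaction(d$plot_id, d$year, d$species, drop = TRUE)
    for (g in split(seq_len(nrow(d)), key)) {
      row <- d[g[1], ]
      s <- seedlings$seedlings[seedlings$plot_id == row$plot_id &
                                 seedlings$year == row$year + 1L &
                                 seedlings$species == row$species]
      if (length(s) != 1L) next
      fl <- if (row$species == "HS") d$flowered[g] else d$flowering[g]
      fec <- fecundity_per_plant(s, d$size[g], row$species, fl)
      if (isTRUE(attr(fec, "unassignable"))) {
        unassigned[[length(unassigned) + 1L]] <-
          data.frame(plot_id = row$plot_id, year = row$year,
                     species = row$species, seedlings = s)
        next
      }
      d$fec[g] <- fec
    }
  }
  d <- d[order(d$year, d$plot_id, d$plant_id), ]
  rownames(d) <- NULL
  unassigned <- if (length(unassigned)) do.call(rbind, unassigned) else NULL
  if (!is.null(unassigned)) {
    coexipm_log(nrow(unassigned), " unassignable plot-year(s) excluded from ",
                "fecundity fitting")
  }
  attr(d, "unassigned") <- unassigned
  d
}

# continuous-Poisson saturated-likelihood constant: -2*logLik = deviance + csat
continuous_poisson_csat <- function(y) {
  ylogy <- ifelse(y > 0, y * log(y), 0)
  2 * sum(lgamma(y + 1) - ylogy + y)
}

# internal: response vector, fitting rows and design columns for one rate
rate_response <- function(data, rate) {
  switch(rate,
    survival = list(y = data$surv, keep = !is.na(data$surv)),
    growth = list(y = data$growth,
                  keep = !is.na(data$growth) & data$surv == 1),
    reproduction = list(y = data$flowered, keep = !is.na(data$flowered)),
    fecundity = list(y = data$fec, keep = !is.na(data$fec) & data$flowered == 1))
}

#' Fit one vital-rate GLMM
#'
#' Fits the requested vital rate for one species as a generalised linear
#' mixed model with a plot random intercept (Laplace-approximated maximum
#' likelihood via \pkg{lme4}), over the covariate subset `terms` plus the
#' mandatory size term(s) (survival also gets the quadratic size term).
#' Covariates are standardised internally for numerical stability and the
#' coefficients and their covariance are transformed back, so reported
#' estimates are on the natural, unstandardised scale.
#'
#' Families: survival/reproduction binomial-logit, growth
#' Gaussian-identity on the annual size difference (candidates compared by
#' ML; see [select_model()] for the REML readjustment), fecundity
#' Poisson-log fitted as a continuous-Poisson likelihood on the allocated
#' (non-integer) fecundities, with AIC computed from the Laplace deviance
#' plus the continuous-Poisson saturated term.
#'
#' A fixed-effects-only fallback (`use_plot_re = FALSE`, or automatic when
#' the mixed fit fails) uses `glm()`/`lm()`. Non-converged fits are flagged
#' (`converged = FALSE`) and carry infinite AIC so they can never be
#' selected.
#'
#' @param data Modelling table from [prepare_vital_rate_data()].
#' @param rate One of [vital_rate_names()].
#' @param species `"HS"` or `"LS"`.
#' @param terms Character subset of `block_b`, `intra`, `inter`,
#'   `winter_min_temp`, `spring_rain`, `summer_wb` (no `summer_wb` for
#'   reproduction).
#' @param size_scale `"log"` (default) or `"raw"` size covariate.
#' @param use_plot_re Include the plot random intercept?
#' @param include_size Keep the mandatory size term(s)? Every candidate in
#'   model selection contains them; `FALSE` exists for degenerate
#'   intercept-only diagnostics.
#' @param nAGQ Number of adaptive Gauss-Hermite quadrature points for the
#'   integral over the plot random intercept in the binomial/Poisson
#'   families (1 = Laplace). The default 10 gives a more accurate
#'   likelihood -- and noticeably better-calibrated variance components and
#'   standard errors for between-plot contrasts -- at modest extra cost.
#' @param reml Refit by restricted maximum likelihood instead of ML: the
#'   Gaussian family through \pkg{lme4}, the binomial/Poisson families
#'   through \pkg{glmmTMB} (which profiles the fixed effects out of the
#'   Laplace likelihood). Used for the final readjustment of a selected
#'   model; candidate comparison always uses ML AIC, which
#'   [select_model()] carries over. REML corrects the downward
#'   finite-sample bias of the ML plot-variance estimate, which otherwise
#'   makes intervals for between-plot contrasts (such as the block
#'   effect) anticonservative. Ignored for fixed-effects-only fits.
#' @return A [vital_rate_model()] with coefficients, standard errors,
#'   variance components, AIC and parameter count filled in.
#' @export
fit_vital_rate <- function(data, rate, species, terms = model_terms_all(),
                           size_scale = c("log", "raw"),
                           use_plot_re = TRUE, reml = FALSE,
                           include_size = TRUE, nAGQ = 10L) {
  rate <- match.arg(rate, vital_rate_names())
  species <- match.arg(species, species_codes())
  size_scale <- match.arg(size_scale)
  terms <- unique(terms)
  bad <- setdiff(terms, model_terms_all())
  if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (rate == "reproduction" && "summer_wb" %in% terms) {
    stop("reproduction models never contain summer_wb", call. = FALSE)
  }
  d <- data[data$species == species, , drop = FALSE]
  resp <- rate_response(d, rate)
  d <- d[resp$keep, , drop = FALSE]
  y <- resp$y[resp$keep]
  if (nrow(d) < 5L) stop("too few observations to fit ", rate, call. = FALSE)
  if (use_plot_re && length(unique(d$plot_id)) < 2L) {
    stop("need >= 2 plots for a plot random intercept", call. = FALSE)
  }

  X <- data.frame(row.names = seq_len(nrow(d)))
  if (include_size) {
    X$sizev <- size_covariate(d$size, size_scale)
    if (rate == "survival") X$sizev2 <- X$sizev^2
  }
  if ("block_b" %in% terms) X$block_b <- as.numeric(d$block == "B")
  for (v in intersect(terms, c("intra", "inter", climate_covariates()))) {
    X[[v]] <- d[[v]]
  }
  # standardise for the optimiser; constant columns are left unscaled
  ctr <- vapply(X, mean, numeric(1))
  scl <- vapply(X, sd, numeric(1))
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- if (ncol(X)) as.data.frame(scale(X, ctr, scl)) else
    data.frame(row.names = seq_len(nrow(d)))
  Xs$.y <- y
  Xs$.plot <- factor(d$plot_id)

  rhs <- if (ncol(X)) paste(names(X), collapse = " + ") else "1"
  family <- rate_family(rate)
  fit <- NULL
  converged <- TRUE
  sigma_plot <- 0
  sigma_resid <- NULL
  used_re <- use_plot_re

  fit_mixed <- function() {
    f <- as.formula(paste(".y ~", rhs, "+ (1 | .plot)"))
    if (family == "gaussian") {
      lme4::lmer(f, data = Xs, REML = reml,
                 control = lme4::lmerControl(calc.derivs = FALSE))
    } else if (reml) {
      glmmTMB::glmmTMB(f, data = Xs, family = poisson_or(family),
                       REML = TRUE)
    } else {
      lme4::glmer(f, data = Xs, family = poisson_or(family), nAGQ = nAGQ,
                  control = lme4::glmerControl(calc.derivs = FALSE))
    }
  }
  fit_fixed <- function() {
    f <- as.formula(paste(".y ~", rhs))
    if (family == "gaussian") lm(f, data = Xs)
    else glm(f, data = Xs, family = poisson_or(family))
  }

  if (use_plot_re) {
    fit <- tryCatch(suppressMessages(suppressWarnings(fit_mixed())),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      coexipm_log(rate, " ", species, ": mixed fit failed (",
                  conditionMessage(fit), "); falling back to fixed effects")
      used_re <- FALSE
      fit <- NULL
    } else if (inherits(fit, "merMod") &&
               !is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0) {
      converged <- FALSE
    }
  }
  if (is.null(fit)) {
    fit <- tryCatch(suppressWarnings(fit_fixed()), error = function(e) e)
    if (inherits(fit, "error")) {
      stop("vital-rate fit failed: ", conditionMessage(fit), call. = FALSE)
    }
  }

  if (used_re && inherits(fit, "glmmTMB")) {
    beta_s <- glmmTMB::fixef(fit)$cond
    V_s <- as.matrix(vcov(fit)$cond)
    sigma_plot <- attr(glmmTMB::VarCorr(fit)$cond$.plot, "stddev")[[1]]
    if (!isTRUE(fit$sdr$pdHess) || fit$fit$convergence != 0) {
      converged <- FALSE
    }
    dev <- -2 * as.numeric(logLik(fit))
  } else if (used_re) {
    beta_s <- lme4::fixef(fit)
    V_s <- as.matrix(vcov(fit))
    vc <- lme4::VarCorr(fit)
    sigma_plot <- attr(vc$.plot, "stddev")[[1]]
    if (family == "gaussian") sigma_resid <- attr(vc, "sc")
    dev <- if (family == "gaussian" && reml) lme4::REMLcrit(fit) else
      deviance(fit)
  } else {
    beta_s <- coef(fit)
    V_s <- as.matrix(vcov(fit))
    if (family == "gaussian") {
      sigma_resid <- sqrt(sum(fit$residuals^2) / length(y))  # ML estimate
      dev <- -2 * as.numeric(logLik(fit))
    } else {
      dev <- fit$deviance
    }
  }

  # back-transform standardised coefficients to the natural scale
  nm <- names(beta_s)[-1]
  A <- diag(length(beta_s))
  diag(A)[-1] <- 1 / scl[nm]
  A[1, -1] <- -ctr[nm] / scl[nm]
  beta <- drop(A %*% beta_s)
  V <- A %*% V_s %*% t(A)
  names(beta) <- c("(Intercept)", nm)
  dimnames(V) <- list(names(beta), names(beta))

  # rename design columns back to model term names
  rename <- c(sizev = "size", sizev2 = "size2")
  names(beta)[-1] <- ifelse(names(beta)[-1] %in% names(rename),
                            rename[names(beta)[-1]], names(beta)[-1])
  dimnames(V) <- list(names(beta), names(beta))

  k <- length(beta) + used_re + (family == "gaussian")
  aic <- if (!converged) Inf else switch(family,
    binomial = if (used_re) AIC(fit) else fit$aic,
    gaussian = dev + 2 * k,
    poisson  = dev + continuous_poisson_csat(y) + 2 * k)
  if (family == "gaussian" && used_re && !reml) {
    aic <- if (converged) AIC(fit) else Inf
  }

  model <- vital_rate_model(
    species, rate, coef = beta, se = sqrt(diag(V)),
    sigma_plot = unname(sigma_plot),
    sigma_resid = if (family == "gaussian") unname(sigma_resid),
    size_scale = size_scale, aic = aic, n_par = k,
    converged = converged, vcov = V)
  attr(model, "terms") <- sort(terms)
  attr(model, "n_obs") <- length(y)
  attr(model, "used_plot_re") <- used_re
  model
}

# quasipoisson-free continuous Poisson: lme4/glm fit the score equations of
# the Poisson family; only likelihood extraction needs the continuous form
poisson_or <- function(family) {
  if (family == "binomial") binomial() else poisson()
}

#' Candidate covariate subsets for model selection
#'
#' All additive combinations (no interactions) of block, the two biotic
#' interaction indices and the three climate covariates; every candidate
#' implicitly contains the size term(s). Reproduction candidates exclude
#' summer water balance.
#'
#' @param rate One of [vital_rate_names()].
#' @param covariates Pool of optional covariates to combine.
#' @return List of character vectors (including the empty, size-only
#'   candidate).
#' @export
candidate_terms <- function(rate, covariates = model_terms_all()) {
  rate <- match.arg(rate, vital_rate_names())
  if (rate == "reproduction") covariates <- setdiff(covariates, "summer_wb")
  n <- length(covariates)
  idx <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  lapply(seq_len(nrow(idx)), function(i) covariates[unlist(idx[i, ])])
}

#' Fit every candidate covariate subset
#'
#' @inheritParams fit_vital_rate
#' @param candidates List of term subsets, as [candidate_terms()].
#' @param ... Passed to [fit_vital_rate()].
#' @return List of fitted [vital_rate_model()]s; failed candidates are
#'   flagged non-converged with infinite AIC.
#' @export
fit_candidates <- function(data, rate, species,
                           candidates = candidate_terms(rate), ...) {
  lapply(candidates, function(terms) {
    tryCatch(fit_vital_rate(data, rate, species, terms = terms, ...),
             error = function(e) {
               m <- vital_rate_model(species, rate,
                                     coef = c("(Intercept)" = 0),
                                     aic = Inf, converged = FALSE)
               attr(m, "terms") <- sort(terms)
               attr(m, "error") <- conditionMessage(e)
               m
             })
  })
}

#' Select the most plausible vital-rate model
#'
#' AIC selection with a parsimony rule: among converged candidates within
#' ΔAIC < 2 of the minimum, the model with fewest parameters wins (ties
#' broken by lower AIC, then by term set, so the result is invariant to
#' candidate ordering). If block or the interspecific index appears in any
#' candidate of the ΔAIC < 2 set, the winner is refit with them forcibly
#' included (block was part of the design; the interspecific interaction is
#' a main focus). The selected model is then readjusted with restricted
#' maximum likelihood (lme4 for the Gaussian family, glmmTMB for the
#' binomial/Poisson families); its AIC is kept from the ML fit, since REML
#' criteria are not comparable across fixed-effect structures.
#'
#' @param fits List of candidate [vital_rate_model()]s from
#'   [fit_candidates()].
#' @param data Modelling table; required when a refit (forced inclusion or
#'   REML readjustment) is needed.
#' @param ... Passed to [fit_vital_rate()] on refits.
#' @return The selected [vital_rate_model()]; attribute `"selection"` is a
#'   data frame of all candidates (terms, AIC, ΔAIC, k).
#' @export
select_model <- function(fits, data = NULL, ...) {
  if (!length(fits)) stop("no candidate fits", call. = FALSE)
  aics <- vapply(fits, function(m) m$aic, numeric(1))
  ks <- vapply(fits, function(m) m$n_par, numeric(1))
  terms <- lapply(fits, function(m) attr(m, "terms"))
  term_str <- vapply(terms, function(t)
    if (length(t)) paste(sort(t), collapse = "+") else "(size only)",
    character(1))
  ok <- is.finite(aics)
  if (!any(ok)) stop("no converged candidate model", call. = FALSE)
  delta <- aics - min(aics[ok])
  close <- which(ok & delta < 2)
  # most parsimonious within the close set; ties -> lower AIC -> term string
  ord <- close[order(ks[close], aics[close], term_str[close])]
  best <- ord[1L]
  chosen <- fits[[best]]

  forced <- intersect(c("block_b", "inter"),
                      unique(unlist(terms[close])))
  need <- setdiff(forced, attr(chosen, "terms"))
  rate <- chosen$rate
  if (is.null(data)) {
    if (length(need)) {
      stop("refit with forced terms (", paste(need, collapse = ", "),
           ") requires `data`", call. = FALSE)
    }
  } else {
    final_terms <- union(attr(chosen, "terms"), forced)
    aic_ml <- if (length(need)) {
      fit_vital_rate(data, rate, chosen$species,
                     terms = final_terms, ...)$aic
    } else {
      chosen$aic
    }
    reml_fit <- fit_vital_rate(data, rate, chosen$species,
                               terms = final_terms, reml = TRUE, ...)
    reml_fit$aic <- aic_ml
    chosen <- reml_fit
  }
  attr(chosen, "selection") <- data.frame(
    terms = term_str, aic = aics, delta = delta, k = ks,
    converged = ok)[order(aics), ]
  chosen
}
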