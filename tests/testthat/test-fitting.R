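test_that("predict_rate applies the stated links", {
  m <- vital_rate_model("HS", "reproduction", coef = c("(Intercept)" = 0))
  expect_equal(predict_rate(m, data.frame(size = 10)), 0.5)

  mp <- vital_rate_model("HS", "fecundity", coef = c("(Intercept)" = log(2)))
  expect_equal(predict_rate(mp, data.frame(size = 10)), 2)

  mg <- vital_rate_model("HS", "growth",
                         coef = c("(Intercept)" = 3, size = 2),
                         sigma_resid = 1)
  # growth returns expected next size = size + eta, size covariate on log scale
  expect_equal(predict_rate(mg, data.frame(size = 10)), 10 + 3 + 2 * log(10))
  expect_error(predict_rate(mg, data.frame(intra = 1)), "size")
})

test_that("predictions equal a hand-computed inverse-logit dot product", {
  pub <- published_coefficients()$HS$survival
  cf <- c("(Intercept)" = -11, size = 0.8, size2 = -0.05,
          vapply(pub, `[[`, numeric(1), "estimate"))
  m <- vital_rate_model("HS", "survival", coef = cf)
  nd <- data.frame(size = 80, block = "B", intra = 0.22, inter = 0.41,
                   winter_min_temp = 1.3, spring_rain = 141, summer_wb = -17)
  eta <- -11 + 0.8 * log(80) - 0.05 * log(80)^2 + cf[["block_b"]] * 1 +
    cf[["intra"]] * 0.22 + cf[["inter"]] * 0.41 +
    cf[["winter_min_temp"]] * 1.3 + cf[["spring_rain"]] * 141 +
    cf[["summer_wb"]] * (-17)
  expect_equal(predict_rate(m, nd), 1 / (1 + exp(-eta)), tolerance = 1e-12)
  expect_error(predict_rate(m, nd[, -2]), "block_b")
})

test_that("model constructor enforces the family structure", {
  expect_error(vital_rate_model("HS", "reproduction",
                                coef = c("(Intercept)" = 0, summer_wb = 1)),
               "summer_wb")
  expect_error(vital_rate_model("HS", "growth",
                                coef = c("(Intercept)" = 0, size2 = 1)),
               "survival only")
  expect_error(vital_rate_model("HS", "survival",
                                coef = c("(Intercept)" = Inf)), "finite")
  expect_error(fit_vital_rate(data.frame(), "reproduction", "HS",
                              terms = "summer_wb"), "summer_wb")
})

test_that("a saturated intercept-only binomial fit recovers the mean", {
  d <- data.frame(species = "HS", plot_id = rep(c("p1", "p2"), 500),
                  block = "A", size = exp(rnorm(1000, 3, 1)),
                  surv = c(0L, rep(1L, 999)))
  fit <- fit_vital_rate(d, "survival", "HS", terms = character(),
                        use_plot_re = FALSE, include_size = FALSE)
  expect_equal(plogis(fit$coef[["(Intercept)"]]), 0.999, tolerance = 1e-6)
})

test_that("noise-free Gaussian growth is recovered exactly", {
  set.seed(1)
  d <- data.frame(species = "LS", plot_id = rep(sprintf("p%d", 1:5), 40),
                  block = "A", size = runif(200, 1, 400))
  d$surv <- 1L
  d$growth <- -0.5 * d$size + 3
  fit <- suppressWarnings(
    fit_vital_rate(d, "growth", "LS", terms = character(),
                   size_scale = "raw", use_plot_re = FALSE))
  expect_equal(fit$coef[["size"]], -0.5, tolerance = 1e-8)
  expect_equal(fit$coef[["(Intercept)"]], 3, tolerance = 1e-6)
  expect_lt(fit$sigma_resid, 1e-6)
})

test_that("generating coefficients are recovered within 2 SE on one draw", {
  sim <- tiny_sim()
  tab <- prepare_vital_rate_data(sim$records, sim$climate, sim$seedlings)
  truth <- default_model_set("HS")$survival$coef
  fit <- fit_vital_rate(tab, "survival", "HS")
  # focus on the well-identified demographic coefficients at this scale
  for (term in c("spring_rain", "block_b")) {
    expect_lt(abs(fit$coef[[term]] - truth[[term]]), 2 * fit$se[[term]])
  }
  expect_true(is.finite(fit$aic))
})

test_that("continuous-Poisson fecundity fits have finite comparable AIC", {
  sim <- tiny_sim()
  tab <- prepare_vital_rate_data(sim$records, sim$climate, sim$seedlings)
  f0 <- fit_vital_rate(tab, "fecundity", "HS", terms = character())
  f1 <- fit_vital_rate(tab, "fecundity", "HS", terms = "spring_rain")
  expect_true(is.finite(f0$aic) && is.finite(f1$aic))
  expect_false(isTRUE(all.equal(f0$aic, f1$aic)))
  # allocated responses are non-integer, yet predictions stay positive
  expect_true(all(predict_rate(f1, tab[tab$species == "HS", ]) >= 0))
})

test_that("AIC selection follows the parsimony-within-2 rule", {
  mk <- function(aic, k, terms) {
    m <- vital_rate_model("HS", "survival", coef = c("(Intercept)" = 0),
                          aic = aic, n_par = k)
    attr(m, "terms") <- terms
    m
  }
  fits <- list(mk(100.0, 5, c("intra", "winter_min_temp", "spring_rain")),
               mk(101.5, 3, "intra"),
               mk(104.0, 4, c("intra", "spring_rain")))
  sel <- select_model(fits)
  expect_equal(sel$aic, 101.5)

  # single candidate selects itself
  expect_equal(select_model(fits[2])$aic, 101.5)

  # parsimony tie broken by lower AIC (no design-forced terms involved)
  tie <- list(mk(100.0, 3, "intra"), mk(101.9, 3, "spring_rain"))
  expect_equal(select_model(tie)$aic, 100.0)

  # invariant to candidate ordering
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(select_model(fits[perm])$aic, 101.5)
  }

  # non-converged candidates can never win
  fits2 <- c(fits, list(mk(Inf, 1, character())))
  fits2[[4]]$converged <- FALSE
  expect_equal(select_model(fits2)$aic, 101.5)
  expect_error(select_model(list(fits2[[4]])), "no converged")
})

test_that("block and interspecific terms are forced into the winner", {
  sim <- tiny_sim()
  tab <- prepare_vital_rate_data(sim$records, sim$climate, sim$seedlings)
  cands <- list(character(), "block_b", "inter", "spring_rain")
  fits <- fit_candidates(tab, "survival", "HS", candidates = cands,
                         use_plot_re = FALSE)
  sel <- select_model(fits, data = tab, use_plot_re = FALSE)
  expect_s3_class(sel, "vital_rate_model")
  expect_true(is.finite(sel$aic))
  close_sets <- attr(sel, "selection")
  close_terms <- unlist(strsplit(close_sets$terms[close_sets$delta < 2], "\\+"))
  for (forced in intersect(c("block_b", "inter"), close_terms)) {
    expect_true(forced %in% names(sel$coef))
  }
})

test_that("the selected growth model is readjusted with REML", {
  sim <- tiny_sim()
  tab <- prepare_vital_rate_data(sim$records, sim$climate, sim$seedlings)
  fits <- fit_candidates(tab, "growth", "HS",
                         candidates = list(character(), "spring_rain"))
  sel <- select_model(fits, data = tab)
  ml <- fit_vital_rate(tab, "growth", "HS",
                       terms = attr(sel, "terms"), reml = FALSE)
  reml <- fit_vital_rate(tab, "growth", "HS",
                         terms = attr(sel, "terms"), reml = TRUE)
  expect_equal(sel$sigma_resid, reml$sigma_resid)
  expect_equal(sel$aic, ml$aic)  # AIC carried over from the ML fit
})
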