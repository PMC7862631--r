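test_that("the midpoint mesh partitions the domain", {
  g <- build_grid(0, 1, 2)
  expect_equal(g$mid, c(0.25, 0.75))
  expect_equal(g$h, 0.5)

  g2 <- build_grid(0, 10, 200)
  expect_length(g2$mid, 200)
  expect_equal(g2$h, 0.05)
  expect_equal(sum(rep(g2$h, g2$n)), g2$upper - g2$lower)
  expect_equal(g2$mid, g2$lower + (seq_len(200) - 0.5) * g2$h)

  expect_error(build_grid(5, 1), "exceed")
  expect_equal(default_grid()$n, 200)
})

test_that("a pure-survival kernel has lambda equal to the survival rate", {
  set <- toy_set(s = 0.7)
  g <- build_grid(0.2, 100, 50)
  K <- build_kernel(set, ref_climate(), 0, 0, "A", g)
  expect_equal(max(abs(K$F)), 0)
  expect_equal(colSums(K$P), rep(0.7, 50))  # eviction renormalisation exact
  expect_equal(as.numeric(dominant_lambda(K)), 0.7, tolerance = 1e-10)
})

test_that("a fecundity-only kernel matches the analytic rank-one eigenvalue", {
  set <- toy_set(s = 1e-12, p = 0.4, f = 3)
  g <- build_grid(0.2, 400, 150)
  K <- build_kernel(set, ref_climate(), 0, 0, "A", g)
  Fm <- K$F
  # F = h * c outer r: lambda = h * sum(r_i c_i)
  r <- predict_rate(set$reproduction, data.frame(size = g$mid)) *
    predict_rate(set$fecundity, data.frame(size = g$mid))
  cvec <- Fm[, 1] / (g$h * r[1])
  lam_analytic <- g$h * sum(r * cvec)
  expect_equal(as.numeric(dominant_lambda(Fm)), lam_analytic,
               tolerance = 1e-12)
})

test_that("dominant_lambda handles canonical matrices", {
  expect_equal(as.numeric(dominant_lambda(diag(5))), 1)
  # periodic 2x2: power iteration cannot converge, eigen fallback applies
  M <- matrix(c(0, 0.5, 2, 0), 2, 2)
  expect_equal(as.numeric(dominant_lambda(M)), 1, tolerance = 1e-12)
  # linearity in overall scale
  set.seed(2)
  A <- matrix(runif(64), 8, 8)
  expect_equal(as.numeric(dominant_lambda(3.5 * A)),
               3.5 * as.numeric(dominant_lambda(A)), tolerance = 1e-9)
  expect_error(dominant_lambda(-diag(2)), "non-negative")
  # the stable size distribution is available and normalised
  w <- attr(dominant_lambda(A), "stable_dist")
  expect_equal(sum(w), 1)
  expect_equal(as.vector(A %*% w) / as.numeric(dominant_lambda(A)), w,
               tolerance = 1e-8)
})

test_that("kernel construction is pure and continuous in climate", {
  set <- default_model_set("HS")
  g <- default_grid(80)
  K1 <- build_kernel(set, ref_climate(), 0.3, 0.3, "A", g)
  K2 <- build_kernel(set, ref_climate(), 0.3, 0.3, "A", g)
  expect_identical(K1$K, K2$K)

  lam <- as.numeric(dominant_lambda(K1))
  cli <- ref_climate()
  cli$spring_rain <- cli$spring_rain + 1e-8
  lam2 <- as.numeric(dominant_lambda(build_kernel(set, cli, 0.3, 0.3, "A", g)))
  expect_lt(abs(lam2 - lam), 1e-6)
})

test_that("halving the mesh changes lambda only marginally on a smooth kernel", {
  # every density scale (growth SD, recruit SD) far exceeds the cell width
  set <- toy_set(s = 0.6, p = 0.5, f = 1.5, sigma_growth = 40,
                 recruit_meanlog = log(80), recruit_sdlog = 0.6)
  lam200 <- as.numeric(dominant_lambda(
    build_kernel(set, ref_climate(), 0.3, 0.3, "A", build_grid(0.2, 800, 200))))
  lam100 <- as.numeric(dominant_lambda(
    build_kernel(set, ref_climate(), 0.3, 0.3, "A", build_grid(0.2, 800, 100))))
  expect_lt(abs(lam200 - lam100), 1e-3)
})

test_that("a too-narrow mesh for the recruit density errors", {
  set <- toy_set(f = 2, p = 0.5, recruit_meanlog = log(2), recruit_sdlog = 0.3)
  expect_error(build_kernel(set, ref_climate(), 0, 0, "A",
                            build_grid(50, 400, 100)),
               "mesh too narrow")
})

test_that("lambda-vs-climate series equals element-wise kernel calls", {
  set <- default_model_set("LS")
  g <- default_grid(60)
  pool <- default_climate_pool()[1:4, ]
  series <- lambda_vs_climate(set, pool, grid = g)
  expect_equal(nrow(series), 4)
  for (i in 1:4) {
    expect_identical(series$lambda[i], as.numeric(dominant_lambda(
      build_kernel(set, pool[i, ], 0.3, 0.3, "A", g))))
  }
  # constant climate gives a constant series
  const <- pool[rep(1, 3), ]
  expect_equal(length(unique(lambda_vs_climate(set, const, grid = g)$lambda)), 1)
  expect_error(lambda_vs_climate(set, pool[0, ]), "empty")
})

test_that("lambda increases with summer water balance when its survival and
          fecundity coefficients are positive", {
  base <- toy_set(s = 0.6, p = 0.5, f = 1.5, sigma_growth = 5)
  pos <- function(m, extra) {
    vital_rate_model(m$species, m$rate, coef = c(m$coef, extra),
                     sigma_resid = m$sigma_resid)
  }
  set <- vital_rate_set("HS",
    survival = pos(base$survival, c(summer_wb = 0.05)),
    growth = base$growth,
    reproduction = base$reproduction,
    fecundity = pos(base$fecundity, c(summer_wb = 0.02)))
  g <- build_grid(0.2, 300, 80)
  wb <- seq(-40, 20, by = 15)
  cli <- data.frame(year = seq_along(wb), winter_min_temp = 2,
                    spring_rain = 150, summer_wb = wb)
  lam <- lambda_vs_climate(set, cli, grid = g)$lambda
  expect_true(all(diff(lam) > 0))
})

test_that("cover surfaces are consistent with single lambda calls", {
  set <- default_model_set("HS")
  g <- default_grid(50)
  lv <- c(0, 0.5, 1)
  surf <- lambda_cover_surface(set, ref_climate(), lv, lv, grid = g)
  expect_equal(nrow(surf), 9)
  for (i in seq_len(9)) {
    expect_identical(surf$lambda[i], as.numeric(dominant_lambda(
      build_kernel(set, ref_climate(), surf$intra[i], surf$inter[i],
                   "A", g))))
  }
  # no interaction terms: flat surface
  flat <- lambda_cover_surface(toy_set(s = 0.5, p = 0.5, f = 2),
                               ref_climate(), lv, lv,
                               grid = build_grid(0.2, 300, 60))
  expect_equal(length(unique(round(flat$lambda, 12))), 1)
  expect_error(lambda_cover_surface(set, ref_climate(), c(-0.1, 0.5), lv),
               "\\[0, 1\\]")
})

test_that("negative intra effects on fecundity propagate to the surface", {
  base <- toy_set(s = 0.6, p = 0.5, f = 2, sigma_growth = 5)
  fec <- vital_rate_model("HS", "fecundity",
                          coef = c("(Intercept)" = log(2), intra = -2))
  set <- vital_rate_set("HS", base$survival, base$growth,
                        base$reproduction, fec)
  g <- build_grid(0.2, 300, 60)
  lv <- seq(0, 1, by = 0.25)
  surf <- lambda_cover_surface(set, ref_climate(), lv, 0, grid = g)
  lam <- surf$lambda[order(surf$intra)]
  expect_true(all(diff(lam) < 0))
  # finite-difference sign agrees with the coefficient sign
  expect_lt(lam[2] - lam[1], 0)
})
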