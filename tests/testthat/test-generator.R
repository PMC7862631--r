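test_that("simulation is reproducible and validated", {
  cfg <- generator_config(n_plots_per_block = 4L, n_years = 4L, seed = 3L)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a, b)
  c <- simulate_population(generator_config(n_plots_per_block = 4L,
                                            n_years = 4L, seed = 4L))
  expect_false(identical(a$records, c$records))

  # records respect the structural invariants
  expect_true(all(a$records$size_cm2 > 0))
  dead <- a$records$alive_next == 0
  expect_true(all(is.na(a$records$size_next_cm2[dead])))
  expect_true(all(a$records$size_next_cm2[!dead] > 0))
  ls <- a$records$species == "LS"
  expect_true(all(a$records$flowering[ls] %in% flowering_levels()))
  expect_true(all(a$records$flowering[!ls] %in% c("0", "1")))
  expect_true(all(a$seedlings$seedlings >= 0))

  bad <- default_model_sets()
  bad$HS$survival$sigma_plot <- -1
  expect_error(generator_config(model_sets = bad), "variance")
})

test_that("null coefficients give the logistic baselines", {
  flat <- function(species, s_icpt) {
    mk <- function(rate, icpt = 0) {
      vital_rate_model(species, rate, coef = c("(Intercept)" = icpt),
                       sigma_plot = 0,
                       sigma_resid = if (rate == "growth") 1)
    }
    vital_rate_set(species, mk("survival", s_icpt), mk("growth"),
                   mk("reproduction"), mk("fecundity", -50))
  }
  # all-zero survival predictor: inverse-logit(0) = 1/2
  cfg <- generator_config(
    model_sets = list(HS = flat("HS", 0), LS = flat("LS", 0)),
    n_plots_per_block = 40L, n_years = 3L,
    init_density = c(HS = 40, LS = 40), seed = 5L)
  sim <- simulate_population(cfg)
  expect_gt(nrow(sim$records), 1000)
  expect_lt(abs(mean(sim$records$alive_next) - 0.5), 0.03)

  # survival intercept +10: essentially everyone survives
  cfg2 <- generator_config(
    model_sets = list(HS = flat("HS", 10), LS = flat("LS", 10)),
    n_plots_per_block = 20L, n_years = 3L,
    init_density = c(HS = 40, LS = 40), seed = 6L)
  sim2 <- simulate_population(cfg2)
  expect_gt(mean(sim2$records$alive_next), 0.999)
})

test_that("fixtures regenerate byte-identically and load back", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- make_fixture(d1, "tiny", seed = 9L)
  p2 <- make_fixture(d2, "tiny", seed = 9L)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  census <- read_census(p1[["census"]])
  expect_lte(nrow(census), 200)
  climate <- read_climate(p1[["climate"]])
  seedl <- read_seedlings(p1[["seedlings"]])
  expect_true(all(census$year %in% climate$year))
  expect_true(all(seedl$plot_id %in% census$plot_id))
})

test_that("paper-scale fixture matches the study design and densities", {
  d <- withr::local_tempdir()
  paths <- make_fixture(d, "paper", seed = 2L)
  census <- read_census(paths[["census"]])
  first <- census[census$year == min(census$year), ]
  expect_setequal(unique(census$block), c("A", "B"))
  expect_equal(length(unique(census$year)), 8)  # 9 censuses, 8 transitions
  # initial per-plot counts are Poisson(density * 0.25 m^2): check the
  # realised block-level densities stay within generous Poisson bounds
  n_plots <- 100
  for (sp in species_codes()) {
    dens <- sum(first$species == sp) / (n_plots * 0.25)
    target <- c(HS = 16, LS = 2.4)[[sp]]
    expect_lt(abs(dens - target), 4 * sqrt(target / (n_plots * 0.25)))
  }
})
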