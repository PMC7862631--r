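test_that("climate sequences are deterministic pool members", {
  pool <- default_climate_pool()
  s1 <- sample_climate_sequence("random", pool, 30, seed = 4)
  s2 <- sample_climate_sequence("random", pool, 30, seed = 4)
  expect_identical(s1, s2)
  expect_true(all(s1$years %in% pool$year))
  expect_false(any(s1$favourable_mask))
  expect_error(sample_climate_sequence("favourable_HS", pool, 5, seed = 1),
               "fav_year")
  expect_error(sample_climate_sequence("nonsense", pool, 5, seed = 1))
})

test_that("enriched rules hit their nominal frequencies", {
  pool <- default_climate_pool()
  n <- 20000
  fhs <- sample_climate_sequence("favourable_HS", pool, n, seed = 10,
                                 fav_year = 2012)
  p_hat <- mean(fhs$years == 2012)
  expect_lt(abs(p_hat - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / n))
  expect_identical(fhs$favourable_mask, fhs$years == 2012)

  fls <- sample_climate_sequence("favourable_LS", pool, n, seed = 11,
                                 fav_year = 2006)
  expect_lt(abs(mean(fls$years == 2006) - 1 / 4),
            3 * sqrt((1 / 4) * (3 / 4) / n))

  unf <- sample_climate_sequence("unfavourable", pool, n, seed = 12,
                                 unfav_year = 2001)
  expect_lt(abs(mean(unf$years == 2001) - 1 / 3),
            3 * sqrt((1 / 3) * (2 / 3) / n))

  comb <- sample_climate_sequence("combined_HS", pool, n, seed = 13,
                                  fav_year = 2012, unfav_year = 2001)
  expect_lt(abs(mean(comb$years == 2012) - 1 / 3),
            3 * sqrt((1 / 3) * (2 / 3) / n))
  # unfavourable on the remaining mass: (1 - 1/3) * 1/3 = 2/9
  expect_lt(abs(mean(comb$years == 2001) - 2 / 9),
            3 * sqrt((2 / 9) * (7 / 9) / n))
})

test_that("stochastic growth rate has its closed forms", {
  expect_equal(as.numeric(stochastic_growth_rate(2^(0:10))), log(2))
  expect_equal(as.numeric(stochastic_growth_rate(rep(3.7, 15))), 0)
  ext <- stochastic_growth_rate(c(4, 2, 0, 0))
  expect_identical(as.numeric(ext), -Inf)
  expect_true(attr(ext, "extinct"))
  expect_error(stochastic_growth_rate(c(0, 1, 2)), "positive")
  # transient removal drops leading transitions
  expect_equal(as.numeric(stochastic_growth_rate(c(100, 1, 2, 4), discard = 1)),
               log(2))
})

test_that("scenario runs are reproducible and order-independent", {
  sets <- default_model_sets()
  pool <- default_climate_pool()
  des <- designate_years(pool, sets, grid = default_grid(40))
  spec <- scenario_spec("rep", "favourable_HS", recruit_multiplier = 2,
                        n_replicates = 4, n_transitions = 6, seed = 21)
  g <- default_grid(40)
  a <- run_scenario(spec, sets, pool, des, grid = g)
  b <- run_scenario(spec, sets, pool, des, grid = g)
  expect_identical(a$replicates, b$replicates)
  # counter-based seeding: a wider run reproduces the first replicates
  spec2 <- modifyList(spec, list(n_replicates = 2L))
  class(spec2) <- "scenario_spec"
  c2 <- run_scenario(spec2, sets, pool, des, grid = g)
  expect_identical(c2$replicates,
                   a$replicates[a$replicates$replicate <= 2, ])
  # summaries recompute exactly from the stored replicates
  hs <- a$replicates[a$replicates$species == "HS" & !a$replicates$failed, ]
  expect_identical(a$summary$median[a$summary$species == "HS"],
                   unname(quantile(hs$log_lambda_s, 0.5, type = 7)))
})

test_that("scenario batteries combine single runs and survive errors", {
  sets <- default_model_sets()
  pool <- default_climate_pool()
  g <- default_grid(40)
  des <- designate_years(pool, sets, grid = g)
  specs <- list(
    scenario_spec("s1", "random", n_replicates = 2, n_transitions = 5,
                  seed = 31),
    scenario_spec("s2", "unfavourable", n_replicates = 2, n_transitions = 5,
                  seed = 32))
  bat <- run_scenario_battery(specs, sets, pool, des, grid = g)
  one <- run_scenario(specs[[1]], sets, pool, des, grid = g)
  expect_equal(bat[bat$scenario == "s1", names(one$summary)], one$summary,
               ignore_attr = TRUE)
  expect_error(run_scenario_battery(list(), sets), "empty")

  expanded <- expand_scenarios(specs, blocks = c("A", "B"),
                               interaction_on = c(TRUE, FALSE))
  expect_length(expanded, 8)
  expect_setequal(vapply(expanded, function(s) s$block, character(1)),
                  c("A", "B"))
})

test_that("structural defaults match the study design", {
  spec <- scenario_spec()
  expect_equal(spec$n_replicates, 100L)
  expect_equal(spec$n_transitions, 14L)
  expect_equal(spec$init_density, c(HS = 16, LS = 2.4))
  expect_equal(scenario_spec(climate_rule = "favourable_LS")$p_favourable,
               1 / 4)
  expect_equal(scenario_spec(climate_rule = "favourable_HS")$p_favourable,
               1 / 3)
  expect_error(scenario_spec(init_density = c(HS = -1, LS = 2)), ">= 0")
  batt <- default_battery(n_replicates = 1, n_transitions = 1)
  expect_length(batt, 24 + 12)
  expect_equal(sum(vapply(batt[1:24], function(s)
    s$recruit_multiplier, numeric(1)) == 10), 6)
})

test_that("rank correlation matches hand-computed Spearman values", {
  expect_equal(compare_lambda_series(1:5, 1:5 * 2), 1)
  expect_equal(compare_lambda_series(1:5, rev(1:5)), -1)
  expect_equal(compare_lambda_series(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_warning(r <- compare_lambda_series(rep(1, 4), 1:4), "undefined")
  expect_true(is.na(r))
  expect_error(compare_lambda_series(1:3, 1:4), "equal length")
})
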