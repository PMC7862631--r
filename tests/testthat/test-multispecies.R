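test_that("cover arithmetic is exact, clips at 1 and handles empty states", {
  g <- build_grid(0, 1000, 2)  # midpoints 250, 750
  st <- population_state("HS", c(2, 0), g)
  expect_equal(as.numeric(cover_from_state(st, 2500)), 0.2)
  expect_false(attr(cover_from_state(st, 2500), "clipped"))

  empty <- population_state("HS", c(0, 0), g)
  expect_equal(as.numeric(cover_from_state(empty, 2500)), 0)

  heavy <- population_state("HS", c(20, 0), g)  # 2x the reference area
  cv <- cover_from_state(heavy, 2500)
  expect_equal(as.numeric(cv), 1)
  expect_true(attr(cv, "clipped"))

  expect_error(population_state("HS", c(-1, 0), g), "non-negative")
})

test_that("adding individuals never decreases cover", {
  g <- default_grid(40)
  set.seed(8)
  n <- runif(40)
  base <- as.numeric(cover_from_state(population_state("LS", n, g)))
  for (k in c(1, 20, 40)) {
    n2 <- n
    n2[k] <- n2[k] + 0.5
    expect_gte(as.numeric(cover_from_state(population_state("LS", n2, g))),
               base)
  }
})

test_that("census files seed initial states at the observed density", {
  sim <- tiny_sim()
  g <- default_grid(50)
  n_plots <- length(unique(sim$records$plot_id))
  st <- initial_state_from_census(sim$records, "HS", g)
  first <- sim$records[sim$records$year == min(sim$records$year) &
                         sim$records$species == "HS", ]
  expect_equal(sum(st$n), nrow(first) / (n_plots * 0.25))
  # total crown area is conserved up to binning resolution
  expect_equal(sum(st$n * g$mid) * (n_plots * 0.25),
               sum(first$size_cm2), tolerance = 0.2)
  d <- withr::local_tempdir()
  proj <- project_single(st, density_independent_sets()$HS,
                         default_climate_pool()[1:2, ])
  p <- write_trajectory(proj$summary, file.path(d, "traj.csv"), seed = 1)
  expect_equal(read.csv(p, comment.char = "#"), proj$summary,
               ignore_attr = TRUE)
})

test_that("one coupled step matches a hand-built kernel-vector product", {
  g <- build_grid(0, 1000, 2)
  sets <- list(HS = toy_set("HS", s = 0.6, p = 0.5, f = 2, sigma_growth = 200,
                            recruit_meanlog = log(100), recruit_sdlog = 0.8),
               LS = toy_set("LS", s = 0.4, p = 0.5, f = 1, sigma_growth = 200,
                            recruit_meanlog = log(100), recruit_sdlog = 0.8))
  cs <- coupled_state(list(HS = population_state("HS", c(1, 0.5), g),
                           LS = population_state("LS", c(0.2, 0.1), g)))
  nxt <- step_coupled(cs, sets, ref_climate())
  for (sp in species_codes()) {
    K <- build_kernel(sets[[sp]], ref_climate(),
                      intra = cs$covers[[sp]],
                      inter = cs$covers[[setdiff(species_codes(), sp)]],
                      block = "A", grid = g)
    expect_identical(nxt$states[[sp]]$n,
                     as.vector(K$K %*% cs$states[[sp]]$n))
    expect_true(all(nxt$states[[sp]]$n >= 0))
  }
})

test_that("extinction dynamics behave: zero kernel and zero state", {
  g <- build_grid(0.2, 400, 30)
  dead <- list(HS = toy_set("HS", s = 1e-12, f = 0),
               LS = toy_set("LS", s = 1e-12, f = 0))
  cs <- coupled_state(list(HS = initial_state("HS", 5, g),
                           LS = initial_state("LS", 5, g)))
  nxt <- step_coupled(cs, dead, ref_climate(), recruit_multiplier = 0)
  expect_lt(sum(nxt$states$HS$n), 1e-10)

  zero <- coupled_state(list(HS = population_state("HS", rep(0, 30), g),
                             LS = population_state("LS", rep(0, 30), g)))
  traj <- run_projection(zero, density_independent_sets(),
                         default_climate_pool()[1:3, ])
  expect_true(all(traj$summary$total_density == 0))
})

test_that("a 14-transition projection yields 15 states with summaries", {
  g <- default_grid(30)
  sets <- density_independent_sets()
  cs <- coupled_state(list(HS = initial_state("HS", 16, g),
                           LS = initial_state("LS", 2.4, g)))
  cli <- default_climate_pool()[rep(1, 14), ]
  proj <- run_projection(cs, sets, cli)
  expect_length(proj$states, 15)
  expect_equal(nrow(proj$summary), 30)
  expect_equal(sort(unique(proj$summary$year)), 0:14)
  expect_true(all(proj$summary$total_density >= 0))
  expect_true(all(proj$summary$cover >= 0 & proj$summary$cover <= 1))
})

test_that("decoupled projections equal independent single-species runs", {
  g <- default_grid(40)
  sets <- density_independent_sets()  # no intra/inter terms at all
  cli <- default_climate_pool()[1:6, ]
  cs <- coupled_state(list(HS = initial_state("HS", 16, g),
                           LS = initial_state("LS", 2.4, g)),
                      interaction_on = FALSE)
  coupled <- run_projection(cs, sets, cli)
  for (sp in species_codes()) {
    single <- project_single(initial_state(sp, c(HS = 16, LS = 2.4)[[sp]], g),
                             sets[[sp]], cli,
                             inter = cs$baseline_inter[[sp]])
    for (t in 1:7) {
      expect_identical(coupled$states[[t]]$states[[sp]]$n,
                       single$states[[t]]$n)
    }
  }
})

test_that("constant-climate density-independent growth follows log lambda", {
  g <- default_grid(60)
  sets <- density_independent_sets()
  cli1 <- default_climate_pool()[1, ]
  K <- build_kernel(sets$HS, cli1, 0.3, 0.3, "A", g)
  lam <- as.numeric(dominant_lambda(K))
  single <- project_single(initial_state("HS", 16, g), sets$HS,
                           cli1[rep(1, 200), ], inter = 0.3)
  tot <- single$summary$total_density
  slopes <- diff(log(tot))
  # after the transient the log-density increments equal log lambda
  expect_equal(slopes[200], log(lam), tolerance = 1e-8)
})

test_that("negative intraspecific fecundity effects create density dependence", {
  g <- build_grid(0.2, 400, 40)
  base <- toy_set("HS", s = 0.5, p = 0.8, f = 3, sigma_growth = 5)
  fec <- vital_rate_model("HS", "fecundity",
                          coef = c("(Intercept)" = log(3), intra = -4))
  dd <- vital_rate_set("HS", base$survival, base$growth, base$reproduction,
                       fec)
  cli <- default_climate_pool()[rep(1, 3), ]
  lo <- project_single(initial_state("HS", 2, g), dd, cli, inter = 0)
  hi <- project_single(initial_state("HS", 20, g), dd, cli, inter = 0)
  rate_lo <- log(lo$summary$total_density[4] / lo$summary$total_density[1]) / 3
  rate_hi <- log(hi$summary$total_density[4] / hi$summary$total_density[1]) / 3
  expect_lt(rate_hi, rate_lo)
})
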