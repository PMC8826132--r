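test_that("parameter validation rejects impossible settings", {
  expect_error(sim_params(sigma_within = -1), "sigmas")
  expect_error(sim_params(n_species = c(carnivore = 2)), "dietary categories")
  expect_error(sim_params(season_amplitude = 2, season_period_mm = 0),
               "period")
  expect_error(sim_params(samples_per_tooth = 0), ">= 1")
  expect_error(scenario_params("omnivore"), "valid scenarios")
})

test_that("zero variance collapses every species to its diet mean", {
  p <- sim_params(sigma_species = 0, sigma_individual = 0, sigma_within = 0,
                  season_amplitude = 0, seed = 2)
  sim <- simulate_isoserial(p)
  for (d in names(p$n_species)) {
    v <- sim$samples$d13c[sim$samples$diet == d]
    expect_true(all(v == p$mu_diet[[d]]))
  }
  ni <- species_niche(sim$samples, min_individuals = 1, quiet = TRUE)
  expect_true(all(is.na(ni$iii)))
  expect_true(all(!ni$iii_defined))
})

test_that("the same seed reproduces the dataset byte for byte", {
  a <- simulate_isoserial(sim_params(seed = 99, balanced = FALSE))
  b <- simulate_isoserial(sim_params(seed = 99, balanced = FALSE))
  expect_identical(a$samples, b$samples)
  expect_identical(a$species_effects, b$species_effects)
  c_ <- simulate_isoserial(sim_params(seed = 100, balanced = FALSE))
  expect_false(identical(a$samples, c_$samples))
  # the caller's RNG stream is untouched
  set.seed(7); x1 <- runif(3)
  set.seed(7); invisible(simulate_isoserial(sim_params(seed = 1)))
  x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("ground truth and samples are mutually consistent", {
  p <- sim_params(seed = 13)
  sim <- simulate_isoserial(p)
  m_sp <- match(sim$samples$taxon, sim$species_effects$taxon)
  m_in <- match(sim$samples$individual_id,
                sim$individual_effects$individual_id)
  resid <- sim$samples$d13c -
    (sim$species_effects$mu_diet[m_sp] +
       sim$species_effects$species_effect[m_sp] +
       sim$individual_effects$individual_effect[m_in])
  expect_lt(abs(mean(resid)), 4 * p$sigma_within / sqrt(nrow(sim$samples)))
  expect_equal(stats::sd(resid), p$sigma_within, tolerance = 0.15)
})

test_that("within-individual residual variance converges to sigma_within^2", {
  p <- sim_params(n_species = c(grazer = 1), individuals_per_species = 1,
                  samples_per_tooth = 1e5, sigma_species = 0,
                  sigma_individual = 0, sigma_within = 0.7, seed = 21)
  sim <- simulate_isoserial(p)
  expect_equal(stats::var(sim$samples$d13c), 0.49, tolerance = 0.02)
})

test_that("without seasonality, range distributions are species-agnostic", {
  # individual range depends only on sigma_within and n; two species'
  # range samples should look like draws from one distribution
  pass <- 0L
  for (seed in 1:10) {
    p <- sim_params(n_species = c(grazer = 2), individuals_per_species = 40,
                    samples_per_tooth = 6, season_amplitude = 0, seed = seed)
    sim <- simulate_isoserial(p)
    s <- individual_summaries(sim$samples)
    taxa <- unique(s$taxon)
    ks <- suppressWarnings(stats::ks.test(s$range[s$taxon == taxa[1]],
                                          s$range[s$taxon == taxa[2]]))
    if (ks$p.value > 0.05) pass <- pass + 1L
  }
  expect_gte(pass, 8L)
})

test_that("seasonality adds a sinusoid of the configured amplitude", {
  p <- sim_params(n_species = c(mixed_feeder = 1), individuals_per_species = 1,
                  samples_per_tooth = 240, sigma_species = 0,
                  sigma_individual = 0, sigma_within = 0,
                  season_amplitude = 2, season_period_mm = 30,
                  position_spacing_mm = 0.25, seed = 3)
  sim <- simulate_isoserial(p)
  v <- sim$samples$d13c
  expect_equal(max(v) - min(v), 4, tolerance = 0.01)   # peak-to-trough 2A
  expect_equal(mean(v), p$mu_diet[["mixed_feeder"]], tolerance = 0.05)
})

test_that("scenario presets pass validation and discriminate III regimes", {
  spec <- simulate_isoserial(scenario_params("specialist", seed = 1))
  gen <- simulate_isoserial(scenario_params("generalist", seed = 1))
  expect_true(validate_isoserial(spec$samples)$ok)
  expect_true(validate_isoserial(gen$samples)$ok)
  ni_s <- species_niche(filter_min_samples(spec$samples, 3), quiet = TRUE)
  ni_g <- species_niche(filter_min_samples(gen$samples, 3), quiet = TRUE)
  expect_lt(mean(ni_s$iii), 0.3)
  expect_gt(mean(ni_g$iii), 0.7)
})
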