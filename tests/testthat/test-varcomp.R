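test_that("balanced nested ANOVA matches the closed form and the oracle", {
  # a = 2 species, b = 2 individuals, n = 2 samples, hand-chosen values
  y <- c(1, 2, 4, 6, 10, 12, 20, 23)
  sp <- rep(c("A a", "B b"), each = 4)
  ind <- rep(c("a1", "a2", "b1", "b2"), each = 2)
  d <- data.frame(d13c = y, taxon = sp, individual_id = ind)
  fit <- nested_varcomp(d, "mom", min_tooth_samples = 1)

  orc <- oracle_nested_anova(y, sp, ind)
  expect_equal(unname(fit$anova$SS), unname(orc$SS), tolerance = 1e-12)
  expect_equal(unname(fit$anova$df), unname(orc$df))
  # balanced design: coefficients collapse to (n, n, b*n) exactly
  expect_identical(unname(fit$coefficients), c(2, 2, 4))
  # balanced closed form: MS differences divided by n and b*n
  ms <- fit$anova$MS
  expect_equal(fit$components_raw[["within"]], ms[3])
  expect_equal(fit$components_raw[["individual"]], (ms[2] - ms[3]) / 2)
  expect_equal(fit$components_raw[["species"]], (ms[1] - ms[2]) / 4)
  # SS decomposition: total = species + individual + within
  expect_equal(sum(fit$anova$SS), sum((y - mean(y))^2), tolerance = 1e-10)
  expect_equal(sum(fit$anova$df), length(y) - 1)
})

test_that("unbalanced coefficients and components match a brute-force oracle", {
  set.seed(77)
  n_ij <- c(2, 3, 5, 2, 3)          # individuals across 2 species
  sp <- rep(c("A a", "A a", "A a", "B b", "B b"), times = n_ij)
  ind <- rep(c("a1", "a2", "a3", "b1", "b2"), times = n_ij)
  y <- rnorm(sum(n_ij), mean = c(-8, -4)[as.integer(factor(sp))])
  d <- data.frame(d13c = y, taxon = sp, individual_id = ind)
  fit <- nested_varcomp(d, "mom", min_tooth_samples = 1)
  orc <- oracle_nested_anova(y, sp, ind)
  expect_equal(unname(fit$coefficients), unname(orc$coef), tolerance = 1e-12)
  expect_equal(unname(fit$components_raw), unname(orc$components),
               tolerance = 1e-10)
  expect_equal(unname(fit$anova$SS), unname(orc$SS), tolerance = 1e-10)
})

test_that("grouped sums of squares equal naive double loops on larger data", {
  set.seed(123)
  sim <- simulate_isoserial(sim_params(
    n_species = c(grazer = 8, browser = 8), individuals_per_species = 5,
    samples_per_tooth = 6, balanced = FALSE, seed = 123))
  x <- sim$samples
  expect_gt(nrow(x), 300)
  fit <- nested_varcomp(x, "mom", min_tooth_samples = 1)
  orc <- oracle_nested_anova(x$d13c, x$taxon, x$individual_id)
  expect_lt(max(abs(fit$anova$SS - orc$SS)) / max(orc$SS), 1e-9)
  expect_equal(unname(fit$components_raw), unname(orc$components),
               tolerance = 1e-10)
})

test_that("degenerate inputs are rejected or flagged, never mangled", {
  flat <- data.frame(d13c = rep(-8, 8),
                     taxon = rep(c("A a", "B b"), each = 4),
                     individual_id = rep(c("a1", "a2", "b1", "b2"), each = 2))
  fit <- nested_varcomp(flat, "mom", min_tooth_samples = 1)
  expect_equal(unname(fit$components), c(0, 0, 0))
  expect_true(fit$flags[["undefined"]])
  expect_true(all(is.na(fit$proportions)))

  one_sp <- data.frame(d13c = rnorm(6), taxon = "A a",
                       individual_id = rep(c("i1", "i2"), each = 3))
  expect_error(nested_varcomp(one_sp, "mom", min_tooth_samples = 1),
               "at least 2 species")
  expect_error(nested_varcomp(
    data.frame(d13c = rnorm(4), taxon = rep(c("A a", "B b"), each = 2),
               individual_id = letters[1:4]), "mom", min_tooth_samples = 1),
    "2 individuals|2 serial samples")
})

test_that("row order never affects the fit", {
  set.seed(5)
  sim <- simulate_isoserial(sim_params(seed = 5))
  x <- sim$samples
  fit1 <- nested_varcomp(x, "mom", min_tooth_samples = 1)
  xs <- x[sample(nrow(x)), ]
  fit2 <- nested_varcomp(xs, "mom", min_tooth_samples = 1)
  expect_equal(fit1$components, fit2$components, tolerance = 1e-12)
  expect_equal(fit1$proportions, fit2$proportions, tolerance = 1e-12)
})

test_that("negative moment estimates are truncated and flagged", {
  # within-individual noise dwarfs group structure -> negative estimates
  set.seed(31)
  d <- data.frame(d13c = rnorm(40, 0, 5),
                  taxon = rep(c("A a", "B b"), each = 20),
                  individual_id = rep(sprintf("i%d", 1:8), each = 5))
  fit <- nested_varcomp(d, "mom", min_tooth_samples = 1)
  expect_true(all(fit$components >= 0))
  if (any(fit$components_raw < 0)) expect_true(fit$flags[["truncated"]])
  expect_equal(sum(fit$proportions), 1)
})

test_that("REML handles internally constant individuals", {
  d <- data.frame(d13c = rep(c(1, 2, 5, 7), each = 4),
                  taxon = rep(c("A a", "A a", "B b", "B b"), each = 4),
                  individual_id = rep(c("i1", "i2", "i3", "i4"), each = 4))
  fit <- nested_varcomp(d, "reml", min_tooth_samples = 1)
  expect_lte(fit$components[["within"]], 1e-6)
  expect_gt(fit$components[["individual"]], 0)
})

test_that("REML agrees with method of moments on balanced synthetic data", {
  sim <- simulate_isoserial(sim_params(
    n_species = c(grazer = 30), individuals_per_species = 5,
    samples_per_tooth = 6, sigma_species = 2, sigma_individual = sqrt(2),
    sigma_within = 1, seed = 8))
  mom <- nested_varcomp(sim$samples, "mom", min_tooth_samples = 1)
  reml <- nested_varcomp(sim$samples, "reml", min_tooth_samples = 1)
  expect_equal(unname(reml$components), unname(mom$components),
               tolerance = 0.1)
})

test_that("both estimators recover generating proportions on a large design", {
  p <- sim_params(n_species = c(grazer = 300), individuals_per_species = 6,
                  samples_per_tooth = 6, sigma_species = sqrt(5.5),
                  sigma_individual = 2, sigma_within = sqrt(0.5), seed = 11)
  sim <- simulate_isoserial(p)
  truth <- c(5.5, 4, 0.5) / 10
  mom <- nested_varcomp(sim$samples, "mom", min_tooth_samples = 1)
  reml <- nested_varcomp(sim$samples, "reml", min_tooth_samples = 1)
  expect_lt(max(abs(mom$proportions - truth)), 0.05)
  expect_lt(max(abs(reml$proportions - truth)), 0.05)
})

test_that("the per-tooth sample threshold drops short teeth before fitting", {
  x <- rbind(
    make_samples(list(a = rnorm(6), b = rnorm(6)), taxon = "A a"),
    make_samples(list(c = rnorm(6), d = rnorm(3)), taxon = "B b")
  )
  fit <- nested_varcomp(x, "mom", min_tooth_samples = 5)
  expect_equal(fit$design$N, 18)  # d's 3-sample tooth excluded
  expect_equal(fit$design$B, 3)
})

test_that("variance proportions normalize components", {
  expect_equal(variance_proportions(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(variance_proportions(c(0, 0, 3)), c(0, 0, 1))
  expect_warning(p <- variance_proportions(c(0, 0, 0)), "undefined")
  expect_true(all(is.na(p)))
  expect_error(variance_proportions(c(-1, 1, 1)), "non-negative")
})
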