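test_that("individual summaries compute order statistics and moments", {
  x <- make_samples(list(a = c(-9.1, -8.0, -7.2), b = c(-8, -8, -8),
                         c = c(-11.4)))
  s <- individual_summaries(x)
  sa <- s[s$individual_id == "a", ]
  expect_equal(sa$min, -9.1)
  expect_equal(sa$max, -7.2)
  expect_equal(sa$range, 1.9)
  expect_equal(sa$mean, -8.1)
  # hand computation: deviations (-1, 0.1, 0.9), SS = 1.82, var = 0.91
  expect_equal(sa$sd, sqrt(0.91))
  sb <- s[s$individual_id == "b", ]
  expect_equal(c(sb$range, sb$sd, sb$mean), c(0, 0, -8))
  sc <- s[s$individual_id == "c", ]
  expect_equal(sc$range, 0)
  expect_true(is.na(sc$sd))
  expect_false(sc$sd_defined)
  expect_error(individual_summaries(x[0, ]), "no finite")
})

test_that("III is the ratio of average individual range to species range", {
  # two individuals with range 1.1 at opposite ends of a 13.4 permil niche
  x <- make_samples(list(lo = c(0, 1.1, 0.5), hi = c(12.3, 13.4, 12.9)),
                    taxon = "Cormohipparion testus", diet = "mixed_feeder")
  ni <- species_niche(x, min_individuals = 2, quiet = TRUE)
  expect_equal(ni$species_total_range, 13.4)
  expect_equal(ni$avg_individual_range, 1.1)
  expect_equal(ni$iii, 1.1 / 13.4, tolerance = 1e-12)
  expect_equal(round(ni$iii, 3), 0.082)

  # single-individual species spans its own range exactly
  one <- make_samples(list(solo = c(-9, -7.5, -8)))
  ni1 <- species_niche(one, min_individuals = 1, quiet = TRUE)
  expect_equal(ni1$iii, 1)

  # every individual constant but species range positive
  cst <- make_samples(list(p = c(-8, -8, -8), q = c(-4, -4, -4)))
  ni0 <- species_niche(cst, min_individuals = 2, quiet = TRUE)
  expect_equal(ni0$iii, 0)

  # zero species range: III undefined, flagged
  flat <- make_samples(list(p = c(-8, -8, -8), q = c(-8, -8, -8)))
  nif <- species_niche(flat, min_individuals = 2, quiet = TRUE)
  expect_true(is.na(nif$iii))
  expect_false(nif$iii_defined)
})

test_that("III is invariant under affine transforms; ranges scale", {
  for (seed in 1:5) {
    x <- random_samples(seed)
    x <- filter_min_samples(x, 2)
    ni <- species_niche(x, min_individuals = 1, species_level_only = FALSE,
                        quiet = TRUE)
    ok <- ni$iii_defined
    y <- x; y$d13c <- 3.7 * x$d13c + 11
    niy <- species_niche(y, min_individuals = 1, species_level_only = FALSE,
                         quiet = TRUE)
    expect_equal(niy$iii[ok], ni$iii[ok], tolerance = 1e-12)
    expect_equal(niy$species_total_range, 3.7 * ni$species_total_range,
                 tolerance = 1e-12)
    expect_true(all(ni$avg_individual_range <=
                      ni$species_total_range + 1e-12))
  }
})

test_that("genus-level records are excluded from III unless lumped", {
  x <- rbind(
    make_samples(list(a = c(-1, -2, -3), b = c(-2, -3, -4)),
                 taxon = "Equus ferus"),
    make_samples(list(c = c(-5, -6, -7), d = c(-6, -7, -8)),
                 taxon = "Equus sp.")
  )
  expect_message(ni <- species_niche(x, min_individuals = 2),
                 "genus-level")
  expect_equal(ni$taxon, "Equus ferus")
  expect_equal(ni$n_individuals, 2)
  lump <- data.frame(from = "Equus sp.", to = "Equus ferus")
  ni2 <- species_niche(x, min_individuals = 2, lump_table = lump,
                       quiet = TRUE)
  expect_equal(ni2$n_individuals, 4)
})

test_that("per-diet III averages are unweighted over species", {
  niche <- data.frame(taxon = c("A a", "B b"), diet = "grazer",
                      n_individuals = 3, species_total_range = 5,
                      avg_individual_range = c(1, 2), iii = c(0.2, 0.4),
                      iii_defined = TRUE, stringsAsFactors = FALSE)
  expect_warning(got <- mean_iii_by_diet(niche), "no species in diet")
  expect_equal(got$mean_iii, 0.3)
  expect_equal(got$n_species, 2L)
  expect_equal(got$sd_iii, stats::sd(c(0.2, 0.4)))
})

test_that("range bins are right-closed with zero ranges in the first bin", {
  b <- bin_individual_ranges(c(0.5, 1.5, 2.5, 3.5))
  expect_equal(b$n, rep(1L, 4))
  expect_equal(b$cum_prop[3], 0.75)  # P(range <= 3)
  expect_equal(prop_range_at_most(c(0.5, 1.5, 2.5, 3.5), 3), 0.75)

  b1 <- bin_individual_ranges(rep(0.5, 7))
  expect_equal(b1$prop, 1)
  expect_equal(b1$bin_hi, 1)

  # boundary values land in the bin they close; zeros join the first bin
  b2 <- bin_individual_ranges(c(0, 1, 2, 2.0000001))
  expect_equal(b2$n, c(2L, 1L, 1L))

  # per-group proportions each sum to 1; cumulative proportions monotone
  set.seed(9)
  r <- rexp(60); g <- sample(c("browser", "grazer"), 60, replace = TRUE)
  bg <- bin_individual_ranges(r, g)
  for (gg in unique(bg$group)) {
    sub <- bg[bg$group == gg, ]
    expect_equal(sum(sub$prop), 1)
    expect_true(all(diff(sub$cum_prop) >= -1e-12))
  }
  expect_error(bin_individual_ranges(numeric(0)), "no ranges")
  expect_error(bin_individual_ranges(c(1, -0.1)), "non-negative")
})

test_that("group range tables summarize ranges and attach rank tests", {
  x <- rbind(
    make_samples(list(g1 = c(-1, -3), g2 = c(-2, -4.5), g3 = c(0, -2.8)),
                 diet = "grazer"),
    make_samples(list(b1 = c(-12, -12.5), b2 = c(-11, -11.8),
                      b3 = c(-13, -13.4)), diet = "browser")
  )
  s <- individual_summaries(x)
  rt <- range_group_table(s, by = "diet")
  expect_s3_class(rt, "range_table")
  expect_equal(sum(rt$group_stats$n), 6)
  expect_equal(rt$group_stats$mean[rt$group_stats$group == "browser"],
               mean(c(0.5, 0.8, 0.4)))
  expect_equal(nrow(rt$pairwise), 1)
  expect_equal(rt$kw$df, 1)

  # degenerate equal-range groups still summarize when tests are off
  eq <- data.frame(range = rep(1, 6),
                   diet = rep(c("browser", "grazer"), each = 3))
  rt0 <- range_group_table(eq, by = "diet", tests = FALSE)
  expect_equal(rt0$group_stats$mean, c(1, 1))
  expect_equal(rt0$group_stats$sd, c(0, 0))
  expect_error(range_group_table(eq[eq$diet == "grazer", ], by = "diet"),
               "2 non-empty groups")
})

test_that("body-size grouping derives categories and drops unknown masses", {
  s <- data.frame(range = c(1, 2, 1.5, 2.5, 3, 1),
                  body_mass_kg = c(50, 60, 200, 210, 400, NA))
  rt <- range_group_table(s, by = "body_size", tests = FALSE)
  expect_setequal(rt$group_stats$group, c("small", "medium", "large"))
  expect_equal(sum(rt$group_stats$n), 5)
})
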