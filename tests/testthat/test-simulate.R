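test_that("the same seed reproduces an identical dataset", {
  cfg <- sim_config(n_groups = 2, n_fixes_per_group = 80, n_calls = 12,
                    border_bias = 0.3, seed = 5)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$fixes, d2$fixes)
  expect_identical(d1$calls, d2$calls)
  expect_identical(d1$individuals, d2$individuals)
  expect_identical(d1$pedigree, d2$pedigree)
  expect_identical(d1$weights, d2$weights)
})

test_that("landscapes respect spacing, size bounds and plant related dominants", {
  cfg <- sim_config(n_groups = 2, territory_spacing = 800, seed = 2,
                    related_fraction = 1)
  land <- simulate_landscape(cfg)
  expect_equal(unname(dist(land$centres)[1]), 800)   # zero jitter
  sizes <- table(land$individuals$group_id)
  expect_true(all(sizes >= 2 & sizes <= 15))
  # with full related fraction, G02's dominant female is kin of G01
  A <- relatedness_matrix(land$pedigree)
  df2 <- land$individuals$id[land$individuals$group_id == "G02" &
                             land$individuals$rank == "dominant" &
                             land$individuals$sex == "female"]
  expect_equal(relatedness(A, df2, "G01_DF"), 0.5)
  # explicit sizes override
  cfg2 <- sim_config(n_groups = 4, group_sizes = c(3, 8), seed = 2)
  land2 <- simulate_landscape(cfg2)
  expect_equal(as.integer(table(land2$individuals$group_id)),
               c(3L, 8L, 3L, 8L))
  expect_error(sim_config(n_groups = 1), "n_groups")
})

test_that("movement is a mean-reverting walk with the right stationary variance", {
  still <- simulate_movement(c(10, 20), 50, theta = 0.5, sigma = 0, seed = 1)
  expect_true(all(still$x == 10 & still$y == 20))

  # theta = 1: fixes after the first are i.i.d. normal about the centre
  iid <- simulate_movement(c(0, 0), 5000, theta = 1, sigma = 40, seed = 2)
  expect_equal(sd(iid$x[-1]), 40, tolerance = 0.05 * 40)
  expect_equal(mean(iid$x), 0, tolerance = 3 * 40 / sqrt(5000))

  th <- 0.2; sg <- 30
  long <- simulate_movement(c(0, 0), 20000, theta = th, sigma = sg, seed = 3)
  expect_equal(var(long$x), sg^2 / (th * (2 - th)),
               tolerance = 0.05 * sg^2 / (th * (2 - th)))
  # timestamps every 15 minutes
  expect_equal(unique(diff(as.numeric(long$timestamp))), 900)
})

test_that("call placement honours border bias and partner weighting", {
  fixes <- simulate_movement(c(0, 0), 100, 0.2, 50, seed = 4)
  profiles <- rbind(
    data.frame(focal_caller = "C", neighbour_group = "N1", related = FALSE,
               n_adults = 6, n_potential_partners = 5,
               n_same_sex_unrelated_adults = 0, n_unknown_sex_adults = 0),
    data.frame(focal_caller = "C", neighbour_group = "N2", related = FALSE,
               n_adults = 3, n_potential_partners = 1,
               n_same_sex_unrelated_adults = 0, n_unknown_sex_adults = 0))
  incs <- list(N1 = square_poly(100, 500, 0), N2 = square_poly(100, -600, 0))

  # border_bias = 0: calls are a subsample of fix locations
  c0 <- simulate_calls("C", "G", fixes, incs, profiles, 30, 0, 0, seed = 5)
  expect_true(all(paste(c0$x, c0$y) %in% paste(fixes$x, fixes$y)))

  # border_bias = 1, one unrelated neighbour: all inside that polygon
  c1 <- simulate_calls("C", "G", fixes, incs[1], profiles[1, ], 30, 1, 0,
                       seed = 6)
  expect_true(all(points_in_poly(c1$x, c1$y, incs$N1)))

  # strong partner exponent: nearly all border calls at the 5-partner border
  c2 <- simulate_calls("C", "G", fixes, incs, profiles, 200, 1, 6, seed = 7)
  at1 <- mean(points_in_poly(c2$x, c2$y, incs$N1))
  expect_gte(at1, 0.95)   # (6/2)^6 : 1 odds

  # no unrelated borders: falls back to movement placement and records it
  rel <- profiles; rel$related <- TRUE
  c3 <- simulate_calls("C", "G", fixes, incs, rel, 20, 1, 0, seed = 8)
  expect_equal(attr(c3, "fallback_calls"), 20)
  expect_true(all(paste(c3$x, c3$y) %in% paste(fixes$x, fixes$y)))
})

test_that("weight simulation plants the calling effect exactly when noiseless", {
  w <- simulate_weights(c("A", "B", "C"), calling_effect = -2,
                        baseline_gain = 2, noise_sd = 0, seed = 9)
  pairs <- weight_cost_pairs(w)
  expect_equal(nrow(pairs), 3)
  expect_true(all(pairs$change_calling - pairs$change_noncalling == -2))
  expect_true(all(pairs$gap_days >= 2 & pairs$gap_days <= 11))
})

test_that("simulated datasets pass validation and support call resampling", {
  cfg <- sim_config(n_groups = 2, n_fixes_per_group = 80, n_calls = 12,
                    seed = 10)
  ds <- simulate_dataset(cfg)
  expect_s3_class(ds, "call_dataset")
  expect_silent(validate_dataset(ds))
  ds2 <- resimulate_calls(ds, 999)
  expect_identical(ds2$fixes, ds$fixes)
  expect_false(identical(ds2$calls$x, ds$calls$x))
  expect_identical(names(ds2$calls), names(ds$calls))
})
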