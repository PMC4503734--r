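make_calls <- function(x, y, caller = "C1", group = "G") {
  data.frame(caller_id = caller, group_id = group,
             timestamp = as.POSIXct("2010-10-01 08:00:00", tz = "UTC") +
               seq_along(x) * 3600,
             x = x, y = y,
             session_id = "2010-10-01", stringsAsFactors = FALSE)
}

test_that("calling locations deduplicate by 1 m rounded coordinates", {
  five <- make_calls(rep(10, 5), rep(20, 5))
  d <- dedupe_locations(five)
  expect_equal(nrow(d), 1)
  expect_equal(d$n_calls, 5)

  three <- make_calls(c(0, 50, 100), c(0, 0, 0))
  expect_equal(nrow(dedupe_locations(three)), 3)

  near <- make_calls(c(100.0, 100.4), c(200.0, 200.3))
  d2 <- dedupe_locations(near)
  expect_equal(nrow(d2), 1)
  expect_equal(d2$n_calls, 2)
  expect_equal(sum(dedupe_locations(near)$n_calls), 2)  # total preserved
})

test_that("caller eligibility uses an inclusive minimum of located calls", {
  calls <- rbind(make_calls(rnorm(9), rnorm(9), caller = "low"),
                 make_calls(rnorm(10), rnorm(10), caller = "ten"),
                 make_calls(rnorm(38), rnorm(38), caller = "many"))
  expect_setequal(filter_eligible_callers(calls), c("ten", "many"))
  expect_length(filter_eligible_callers(calls[0, ]), 0)
})

test_that("expected band counts are the unnormalised half/quarter/fifth split", {
  e <- expected_band_counts(40)
  expect_equal(unname(e), c(20, 10, 8))
  expect_equal(names(e), c("core50", "band50_75", "band75_95"))
  expect_equal(unname(expected_band_counts(0)), c(0, 0, 0))
  expect_equal(sum(expected_band_counts(100)), 95)   # not renormalised
  expect_error(expected_band_counts(-1), ">= 0")
})

test_that("band counts over the four bands sum to the caller's total calls", {
  terr <- concentric_territory()
  set.seed(31)
  calls <- make_calls(runif(40, -400, 400), runif(40, -400, 400))
  bc <- band_counts(calls, terr)
  expect_equal(sum(bc$counts), 40)
  expect_equal(sum(bc$location_counts), nrow(dedupe_locations(calls)))
  expect_equal(sum(bc$expected), 0.95 * 40)
})

test_that("border statistics follow the area-proportional expectation formula", {
  # focal: 1 km square (100 ha), abutting neighbour -> 10 ha strip
  focal <- structure(list(isopleths = list("0.95" = square_poly(1000)),
                          group_id = "F"), class = "locoh")
  nb <- structure(list(isopleths = list("0.95" = square_poly(1000, 1000, 0)),
                       group_id = "N"), class = "locoh")
  # 30 calls, 10 of them inside the strip (x >= 900)
  calls <- make_calls(c(runif(20, 0, 800), runif(10, 901, 999)),
                      runif(30, 1, 999))
  bs <- border_stat(calls, focal, nb)
  expect_equal(bs$inclusion_area_ha, 10, tolerance = 0.01)
  expect_equal(bs$observed_calls, 10)
  expect_equal(bs$expected_calls, 30 / 100 * bs$inclusion_area_ha)
  expect_equal(bs$calls_per_ha, 10 / bs$inclusion_area_ha)

  # saturating case: inclusion polygon covering the whole focal territory
  bs2 <- callscape:::border_stat_from_poly(calls, 100, square_poly(1000),
                                           "N2")
  expect_equal(bs2$expected_calls, 30, tolerance = 1e-6)
  # linearity in total calls
  bs3 <- border_stat(rbind(calls, calls), focal, nb)
  expect_equal(bs3$expected_calls, 2 * bs$expected_calls)
})

test_that("uniform calls give observed counts near expectation (binomial oracle)", {
  focal <- structure(list(isopleths = list("0.95" = square_poly(1000)),
                          group_id = "F"), class = "locoh")
  nb <- structure(list(isopleths = list("0.95" = square_poly(1000, 1000, 0)),
                       group_id = "N"), class = "locoh")
  set.seed(41)
  bad <- 0
  for (i in 1:20) {
    calls <- make_calls(runif(200, 0, 1000), runif(200, 0, 1000))
    bs <- border_stat(calls, focal, nb)
    p <- bs$inclusion_area_ha / 100
    sdev <- sqrt(200 * p * (1 - p))
    if (abs(bs$observed_calls - bs$expected_calls) > 3 * sdev) bad <- bad + 1
  }
  expect_lte(bad, 1)   # >= 99% within 3 binomial SD over many replicates
})

test_that("paired tables select neighbours by the right metrics with tie-breaks", {
  profiles <- rbind(
    data.frame(focal_caller = "C1", neighbour_group = "N1", related = TRUE,
               n_adults = 5, n_potential_partners = 4,
               n_same_sex_unrelated_adults = 1, n_unknown_sex_adults = 0),
    data.frame(focal_caller = "C1", neighbour_group = "N2", related = FALSE,
               n_adults = 3, n_potential_partners = 1,
               n_same_sex_unrelated_adults = 2, n_unknown_sex_adults = 0),
    data.frame(focal_caller = "C2", neighbour_group = "N1", related = FALSE,
               n_adults = 4, n_potential_partners = 2,
               n_same_sex_unrelated_adults = 2, n_unknown_sex_adults = 0))
  border_stats <- rbind(
    data.frame(focal_caller = "C1", neighbour = "N1", inclusion_area_ha = 2,
               observed_calls = 4, observed_locations = 3,
               expected_calls = 2, expected_locations = 1.5,
               calls_per_ha = 2, locations_per_ha = 1.5),
    data.frame(focal_caller = "C1", neighbour = "N2", inclusion_area_ha = 1,
               observed_calls = 6, observed_locations = 5,
               expected_calls = 1, expected_locations = 0.8,
               calls_per_ha = 6, locations_per_ha = 5),
    data.frame(focal_caller = "C2", neighbour = "N1", inclusion_area_ha = 1,
               observed_calls = 2, observed_locations = 2,
               expected_calls = 1, expected_locations = 1,
               calls_per_ha = 2, locations_per_ha = 2))
  tabs <- paired_border_tables(profiles, border_stats)
  # C2 has a single neighbour: excluded everywhere
  for (nm in names(tabs))
    expect_true("C2" %in% attr(tabs[[nm]], "excluded"))
  # partner counts (4, 1): max = N1, min = N2
  expect_equal(tabs$max_vs_min_partners$high_group, "N1")
  expect_equal(tabs$max_vs_min_partners$low_group, "N2")
  expect_equal(tabs$max_vs_min_partners$calls_per_ha_high, 2)
  expect_equal(tabs$max_vs_min_partners$calls_per_ha_low, 6)
  # related vs unrelated: unrelated (N2) is "high", related (N1) "low"
  expect_equal(tabs$related_vs_unrelated$calls_per_ha_high, 6)
  expect_equal(tabs$related_vs_unrelated$calls_per_ha_low, 2)

  # tie in the metric -> lexicographically smallest group, tie logged
  profiles$n_adults <- 5
  tabs2 <- paired_border_tables(profiles, border_stats)
  expect_equal(tabs2$largest_vs_smallest$high_group, "N1")
  expect_equal(tabs2$largest_vs_smallest$low_group, "N2")
  expect_true(any(grepl("n_adults", attr(tabs2, "ties"))))
})

test_that("related-vs-unrelated pooling sums counts and areas within class", {
  profiles <- rbind(
    data.frame(focal_caller = "C1", neighbour_group = "R1", related = TRUE,
               n_adults = 3, n_potential_partners = 0,
               n_same_sex_unrelated_adults = 0, n_unknown_sex_adults = 0),
    data.frame(focal_caller = "C1", neighbour_group = "R2", related = TRUE,
               n_adults = 3, n_potential_partners = 0,
               n_same_sex_unrelated_adults = 0, n_unknown_sex_adults = 0),
    data.frame(focal_caller = "C1", neighbour_group = "U1", related = FALSE,
               n_adults = 3, n_potential_partners = 2,
               n_same_sex_unrelated_adults = 0, n_unknown_sex_adults = 0))
  border_stats <- rbind(
    data.frame(focal_caller = "C1", neighbour = "R1", inclusion_area_ha = 1,
               observed_calls = 1, observed_locations = 1,
               expected_calls = 1, expected_locations = 1,
               calls_per_ha = 1, locations_per_ha = 1),
    data.frame(focal_caller = "C1", neighbour = "R2", inclusion_area_ha = 3,
               observed_calls = 3, observed_locations = 2,
               expected_calls = 3, expected_locations = 2,
               calls_per_ha = 1, locations_per_ha = 2 / 3),
    data.frame(focal_caller = "C1", neighbour = "U1", inclusion_area_ha = 2,
               observed_calls = 10, observed_locations = 6,
               expected_calls = 2, expected_locations = 1.5,
               calls_per_ha = 5, locations_per_ha = 3))
  tabs <- paired_border_tables(profiles, border_stats)
  t1 <- tabs$related_vs_unrelated
  expect_equal(t1$calls_per_ha_low, (1 + 3) / (1 + 3))   # pooled related
  expect_equal(t1$calls_per_ha_high, 10 / 2)
})

test_that("weight pairing respects bout threshold, window and tie rules", {
  base <- as.Date("2010-10-01")
  w <- data.frame(
    individual_id = c("A", "A", "B", "B", "C", "C", "C"),
    date = c(base, base + 11, base, base + 15, base + 5, base, base + 9),
    mass_start = 80, mass_end = c(82, 81, 82, 81, 83, 81, 81),
    n_calling_bouts = c(6L, 0L, 7L, 0L, 8L, 0L, 0L))
  pairs <- weight_cost_pairs(w)
  expect_setequal(pairs$individual_id, c("A", "C"))  # B outside 14-day window
  expect_equal(pairs$gap_days[pairs$individual_id == "A"], 11)
  # C: two controls at gaps 5 and 4 -> nearest (base) chosen
  expect_equal(pairs$noncalling_date[pairs$individual_id == "C"], base + 9)
  expect_equal(pairs$gap_days[pairs$individual_id == "C"], 4)
  # identical mass change on both days -> paired difference 0
  w0 <- data.frame(individual_id = "D", date = base + c(0, 3),
                   mass_start = c(80, 82), mass_end = c(83, 85),
                   n_calling_bouts = c(9L, 0L))
  p0 <- weight_cost_pairs(w0)
  expect_equal(p0$change_calling - p0$change_noncalling, 0)
  # below the bout threshold never pairs
  w1 <- data.frame(individual_id = "E", date = base + c(0, 3),
                   mass_start = 80, mass_end = 82,
                   n_calling_bouts = c(5L, 0L))
  expect_equal(nrow(weight_cost_pairs(w1)), 0)
})
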