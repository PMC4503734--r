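test_that("adaptive neighbour selection follows the cumulative-distance budget", {
  pts <- cbind(c(0, 1, 2, 3), c(0, 0, 0, 0))
  expect_setequal(select_neighbours_adaptive(pts, 1, 0), 1)
  # distances from point 1: 1, 2, 3; cumsum 1, 3, 6 -> budget 3 keeps two
  expect_setequal(select_neighbours_adaptive(pts, 1, 3), c(1, 2, 3))
  expect_setequal(select_neighbours_adaptive(pts, 1, 6), 1:4)
  expect_setequal(select_neighbours_adaptive(pts, 1, 100), 1:4)
  expect_error(select_neighbours_adaptive(pts, 9, 1), "root")
})

test_that("neighbour selection matches the exhaustive oracle on random instances", {
  set.seed(42)
  for (i in 1:50) {
    pts <- cbind(runif(30, 0, 1000), runif(30, 0, 1000))
    root <- sample(30, 1)
    a <- runif(1, 0, 3000)
    expect_identical(sort(select_neighbours_adaptive(pts, root, a)),
                     sort(neighbour_oracle(pts, root, a)))
  }
})

test_that("local hulls are convex hulls of their member sets", {
  tri <- cbind(c(0, 100, 0), c(0, 0, 100))
  hulls <- build_local_hulls(tri, 1e6)
  expect_length(hulls, 3)
  for (h in hulls) expect_equal(h$area_m2, 100 * 100 / 2)
  sq <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  hulls <- build_local_hulls(sq, 1e6)
  for (h in hulls) expect_equal(h$area_m2, 10000)
  # degenerate: collinear members give zero area
  seg <- cbind(c(0, 1, 2), c(0, 0, 0))
  hulls <- build_local_hulls(seg, 1e6)
  expect_true(all(vapply(hulls, `[[`, numeric(1), "area_m2") == 0))
})

test_that("choose_a returns the maximum pairwise distance", {
  expect_equal(choose_a(cbind(c(0, 250), c(0, 0))), 250)
  sq <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  expect_equal(choose_a(sq), 100 * sqrt(2))
  set.seed(5)
  pts <- cbind(runif(50, 0, 500), runif(50, 0, 500))
  brute <- max(apply(pts, 1, function(p)
    max(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2))))
  expect_equal(choose_a(pts), brute)
  expect_error(choose_a(cbind(c(1, 1), c(2, 2))), "identical")
})

test_that("isopleths cover, nest and are minimal on simulated fixes", {
  set.seed(7)
  fx <- data.frame(x = rnorm(100, sd = 200), y = rnorm(100, sd = 200))
  fit <- locoh(fx, a = 0.3 * choose_a(as.matrix(fx)))
  n <- fit$n
  for (j in seq_along(fit$levels)) {
    lev <- fit$levels[j]
    iso <- fit$isopleths[[as.character(lev)]]
    covered <- sum(points_in_poly(fx$x, fx$y, iso))
    expect_gte(covered, ceiling(lev * n))
  }
  # nesting: area of inner minus outer is ~0
  d1 <- callscape:::poly_difference(fit$isopleths[["0.5"]],
                                    fit$isopleths[["0.75"]])
  d2 <- callscape:::poly_difference(fit$isopleths[["0.75"]],
                                    fit$isopleths[["0.95"]])
  expect_lt(area_hectares(d1), 1e-6)
  expect_lt(area_hectares(d2), 1e-6)
  # minimality: the recorded prefix is the first to reach the threshold,
  # so one hull fewer must fall short
  hulls <- build_local_hulls(as.matrix(fx), fit$a)
  ord <- callscape:::order_hulls(hulls)
  for (j in seq_along(fit$levels)) {
    k <- fit$n_hulls_used[j]
    thr <- ceiling(fit$levels[j] * n)
    if (k > 1) {
      cov <- rep(FALSE, n)
      for (i in seq_len(k - 1)) {
        hit <- callscape:::hull_covers(hulls[[ord[i]]], as.matrix(fx))
        cov <- cov | hit
      }
      expect_lt(sum(cov), thr)
    }
  }
})

test_that("the level-1 isopleth at saturating a is the global convex hull", {
  set.seed(11)
  fx <- data.frame(x = runif(40, 0, 500), y = runif(40, 0, 500))
  pts <- as.matrix(fx)
  a <- sum(dist(pts))  # larger than any cumulative distance
  fit <- locoh(fx, a = a, levels = 1)
  hull <- callscape:::convex_hull_poly(pts[, 1], pts[, 2])
  expect_equal(area_hectares(fit$isopleths[["1"]]), area_hectares(hull),
               tolerance = 1e-6)
  sym <- c(callscape:::poly_difference(hull, fit$isopleths[["1"]]),
           callscape:::poly_difference(fit$isopleths[["1"]], hull))
  expect_lt(area_hectares(sym), 1e-6)
})

test_that("the level-1 isopleth area is non-decreasing in a", {
  set.seed(13)
  fx <- data.frame(x = rnorm(60, sd = 100), y = rnorm(60, sd = 100))
  amax <- choose_a(as.matrix(fx))
  areas <- vapply(c(0.1, 0.25, 0.5, 1) * amax, function(a)
    locoh(fx, a = a, levels = 1)$areas_ha[[1]], numeric(1))
  expect_true(all(diff(areas) >= -1e-9))
})

test_that("isopleth areas are scale equivariant", {
  set.seed(17)
  fx <- data.frame(x = rnorm(50, sd = 100), y = rnorm(50, sd = 100))
  s <- 3
  fit1 <- locoh(fx)
  fit2 <- locoh(fx * s)
  expect_equal(as.numeric(fit2$areas_ha), as.numeric(fit1$areas_ha) * s^2,
               tolerance = 1e-6)
})

test_that("duplicate fixes count toward coverage and degenerate input errors", {
  fx <- data.frame(x = rep(c(0, 100, 100, 0, 50), each = 4),
                   y = rep(c(0, 0, 100, 100, 50), each = 4))
  fit <- locoh(fx, a = 50)
  expect_gte(fit$coverage[["0.5"]], ceiling(0.5 * nrow(fx)))
  expect_error(locoh(data.frame(x = rep(1, 5), y = rep(2, 5))), "identical")
})

test_that("band classification picks the innermost containing isopleth", {
  terr <- concentric_territory()
  expect_equal(as.character(classify_band(c(0, 0), terr)), "core50")
  expect_equal(as.character(classify_band(c(70, 0), terr)), "band50_75")
  expect_equal(as.character(classify_band(c(120, 0), terr)), "band75_95")
  expect_equal(as.character(classify_band(c(400, 0), terr)), "outside95")
  # boundaries are inclusive toward the inner band
  expect_equal(as.character(classify_band(c(50, 0), terr)), "core50")
  b <- predict(terr, data.frame(x = c(0, 70, 120, 400), y = 0))
  expect_equal(as.character(b),
               c("core50", "band50_75", "band75_95", "outside95"))
})

test_that("print, summary and plot methods run", {
  set.seed(19)
  fit <- locoh(data.frame(x = rnorm(40, sd = 50), y = rnorm(40, sd = 50)),
               group_id = "G1")
  expect_output(print(fit), "a-LoCoH")
  s <- summary(fit)
  expect_s3_class(s, "summary.locoh")
  expect_output(print(s), "fixes")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
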