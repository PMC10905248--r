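test_that("normalization divides by the masked sum and rejects empty maps", {
  g <- tiny_grid(10, 10)
  uni <- suitability_map(g, matrix(0.42, 10, 10), "cloglog")
  p <- normalize_surface(uni)
  expect_true(all(abs(p$p - 0.01) < 1e-15))
  # a map already summing to one is unchanged
  m2 <- suitability_map(g, matrix(0.01, 10, 10), "raw")
  expect_equal(normalize_surface(m2)$p, m2$values, tolerance = 1e-15)
  g2 <- raster_grid(1, 2, cellsize = 1)
  m3 <- suitability_map(g2, matrix(c(2, 6), 1, 2), "raw")
  expect_equal(as.vector(normalize_surface(m3)$p), c(0.25, 0.75))
  expect_error(normalize_surface(suitability_map(g, matrix(0, 10, 10), "raw")),
               "zero or missing")
})

test_that("Schoener's D matches its definitional cases", {
  g <- raster_grid(1, 2, cellsize = 1)
  mk <- function(v) normalize_surface(suitability_map(g, matrix(v, 1, 2), "raw"))
  expect_equal(schoener_d(mk(c(0.7, 0.3)), mk(c(0.7, 0.3))), 1)
  expect_equal(schoener_d(mk(c(1, 1e-300)), mk(c(1e-300, 1))), 0,
               tolerance = 1e-12)
  expect_equal(schoener_d(mk(c(0.7, 0.3)), mk(c(0.5, 0.5))), 0.8)
})

test_that("Warren's I matches its definitional cases", {
  g <- raster_grid(1, 2, cellsize = 1)
  mk <- function(v) normalize_surface(suitability_map(g, matrix(v, 1, 2), "raw"))
  expect_equal(warren_i(mk(c(0.7, 0.3)), mk(c(0.7, 0.3))), 1)
  expect_equal(warren_i(mk(c(1, 1e-300)), mk(c(1e-300, 1))), 0,
               tolerance = 1e-6)
  expect_equal(warren_i(mk(c(0.7, 0.3)), mk(c(0.5, 0.5))),
               1 - 0.5 * ((sqrt(0.7) - sqrt(0.5))^2 + (sqrt(0.3) - sqrt(0.5))^2),
               tolerance = 1e-12)
  expect_equal(warren_i(mk(c(0.7, 0.3)), mk(c(0.5, 0.5))), 0.97891,
               tolerance = 1e-5)
})

test_that("overlap metrics demand a shared grid and mask", {
  g <- raster_grid(1, 2, cellsize = 1)
  p1 <- normalize_surface(suitability_map(g, matrix(c(1, 1), 1, 2), "raw"))
  g2 <- raster_grid(1, 2, xmin = 5, cellsize = 1)
  p2 <- normalize_surface(suitability_map(g2, matrix(c(1, 1), 1, 2), "raw"))
  expect_error(schoener_d(p1, p2), "different grids")
  v <- matrix(c(1, NA), 1, 2)
  p3 <- normalize_surface(suitability_map(g, v, "raw"))
  expect_error(warren_i(p1, p3), "mask")
})

test_that("I >= D on random surface pairs and both are scale-invariant", {
  set.seed(51)
  for (i in 1:60) {
    pair <- random_prob_surface_pair(sample(2:12, 1), sample(2:12, 1))
    d <- schoener_d(pair$px, pair$py)
    i_ <- warren_i(pair$px, pair$py)
    expect_gte(i_, d - 1e-12)
    expect_true(d >= 0 && d <= 1 && i_ >= 0 && i_ <= 1 + 1e-12)
  }
  # multiplying an input map by a positive constant changes nothing
  g <- tiny_grid(5, 5)
  v <- matrix(rexp(25), 5, 5)
  m1 <- suitability_map(g, v, "raw")
  m2 <- suitability_map(g, 37.5 * v, "raw")
  ref <- normalize_surface(suitability_map(g, matrix(runif(25), 5, 5), "raw"))
  expect_equal(schoener_d(normalize_surface(m1), ref),
               schoener_d(normalize_surface(m2), ref), tolerance = 1e-12)
})

test_that("habitat change percentages follow the H-sum formulas", {
  expect_equal(habitat_change(110, 100), 10)
  expect_equal(habitat_change(55, 55), 0)
  expect_equal(habitat_change(99.2, 20), 396)
  expect_error(habitat_change(5, 0), "positive")
  expect_equal(combined_change(6, 6, 5, 5), 20)
  expect_equal(combined_change(3, 4, 3, 4), 0)
  # equal references, +10% and -10% cancel
  expect_equal(combined_change(110, 90, 100, 100), 0)
  expect_error(combined_change(1, 1, 0, 0), "positive")
})

vuln_fixture <- function() {
  g <- tiny_grid(10, 10, cellsize = 0.1, xmin = 0, ymin = 0)
  set.seed(52)
  mk <- function() suitability_map(g, matrix(runif(100, 0.2, 0.8), 10, 10),
                                   "cloglog")
  current <- list(A = mk(), B = mk())
  ranges <- list(A = box_range(0, 0, 0.7, 1, species = "A"),
                 B = box_range(0.3, 0, 1, 1, species = "B"))
  list(g = g, current = current, ranges = ranges)
}

test_that("identity scenarios give a uniformly zero report", {
  fx <- vuln_fixture()
  rep_ <- vulnerability_report(fx$current,
                               list(same = fx$current), fx$ranges)
  expect_true(all(abs(rep_$table) < 1e-9))
  expect_identical(rownames(rep_$table), c("A", "B", "Overlap area"))
})

test_that("scaling future maps by 1.10 yields +10 percent everywhere", {
  fx <- vuln_fixture()
  scaled <- lapply(fx$current, function(m)
    suitability_map(m$grid, m$values * 1.10, m$scale))
  rep_ <- vulnerability_report(fx$current, list(up = scaled), fx$ranges)
  expect_equal(unname(rep_$table[, "up"]), rep(10, 3), tolerance = 1e-9)
  # past direction: current is the new state relative to the scenario
  rep_p <- vulnerability_report(fx$current, list(past = scaled), fx$ranges,
                                scenario_kind = c(past = "past"))
  expect_equal(unname(rep_p$table[, "past"]), rep(100 * (1 / 1.1 - 1), 3),
               tolerance = 1e-9)
})

test_that("percent changes are recomputable from the audited H values", {
  fx <- vuln_fixture()
  scaled <- lapply(fx$current, function(m)
    suitability_map(m$grid, m$values * 0.9, m$scale))
  rep_ <- vulnerability_report(fx$current, list(dn = scaled), fx$ranges)
  h <- rep_$h_values
  rowA <- h[h$species == "A" & h$area == "range", ]
  expect_equal(rep_$table["A", "dn"],
               100 * (rowA$H_scenario - rowA$H_current) / rowA$H_current,
               tolerance = 1e-12)
  rowO <- h[h$area == "overlap", ]
  expect_equal(rep_$table["Overlap area", "dn"],
               100 * (rowO$H_scenario - rowO$H_current) / rowO$H_current,
               tolerance = 1e-12)
})

test_that("doubling every map leaves all percent changes unchanged", {
  fx <- vuln_fixture()
  scen <- lapply(fx$current, function(m)
    suitability_map(m$grid, m$values * 1.07, m$scale))
  r1 <- vulnerability_report(fx$current, list(s = scen), fx$ranges)
  dbl <- function(l) lapply(l, function(m)
    suitability_map(m$grid, m$values * 2, m$scale))
  r2 <- vulnerability_report(dbl(fx$current), list(s = dbl(scen)), fx$ranges)
  expect_equal(r1$table, r2$table, tolerance = 1e-9)
})

test_that("scale mismatches across maps are rejected", {
  fx <- vuln_fixture()
  bad <- fx$current
  bad$B <- suitability_map(fx$g, bad$B$values / sum(bad$B$values), "raw")
  expect_error(vulnerability_report(bad, list(), fx$ranges), "scale mismatch")
})
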