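test_that("masking to a full-extent polygon with zero buffer changes nothing", {
  g <- tiny_grid(10, 10, cellsize = 0.1, xmin = 0, ymin = 0)
  st <- raster_stack(g, list(a = matrix(rnorm(100), 10, 10)))
  full <- box_range(-1, -1, 2, 2)
  expect_identical(buffer_and_mask(st, full)$layers$a, st$layers$a)
})

test_that("half-extent polygon keeps exactly the cells whose centers fall inside", {
  g <- tiny_grid(10, 10, cellsize = 0.1, xmin = 0, ymin = 0)
  st <- raster_stack(g, list(a = matrix(1, 10, 10)))
  left <- box_range(0, 0, 0.5, 1)   # left half: 5 columns x 10 rows
  masked <- buffer_and_mask(st, left)
  expect_equal(sum(!is.na(masked$layers$a)), 50)
  # valid-cell values are untouched
  expect_true(all(masked$layers$a[!is.na(masked$layers$a)] == 1))
})

test_that("a buffer far smaller than the cell size gives the same mask as no buffer", {
  g <- tiny_grid(10, 10, cellsize = 0.01, xmin = 0, ymin = 45) # ~1.1 km cells
  st <- raster_stack(g, list(a = matrix(1, 10, 10)))
  poly <- box_range(0.012, 45.012, 0.078, 45.078)
  m0 <- is.na(buffer_and_mask(st, poly)$layers$a)
  poly36 <- box_range(0.012, 45.012, 0.078, 45.078, buffer_m = 36)
  m36 <- is.na(buffer_and_mask(st, poly36)$layers$a)
  expect_identical(m0, m36)
})

test_that("a metric buffer of about one cell grows the mask outward", {
  g <- tiny_grid(10, 10, cellsize = 0.01, xmin = 0, ymin = 45)
  st <- raster_stack(g, list(a = matrix(1, 10, 10)))
  poly <- box_range(0.035, 45.035, 0.065, 45.065)
  n0 <- sum(!is.na(buffer_and_mask(st, poly)$layers$a))
  polyb <- box_range(0.035, 45.035, 0.065, 45.065, buffer_m = 1200)
  nb <- sum(!is.na(buffer_and_mask(st, polyb)$layers$a))
  expect_gt(nb, n0)
})

test_that("disjoint polygon raises a data error", {
  g <- tiny_grid(5, 5, cellsize = 0.1, xmin = 0, ymin = 0)
  st <- raster_stack(g, list(a = matrix(1, 5, 5)))
  expect_error(buffer_and_mask(st, box_range(10, 10, 11, 11)),
               "does not intersect")
})

test_that("TRI is zero on flat terrain and sqrt(8) at a unit spike", {
  expect_true(all(compute_tri(matrix(5, 7, 7)) == 0))
  z <- matrix(0, 3, 3); z[2, 2] <- 1
  expect_equal(compute_tri(z)[2, 2], sqrt(8), tolerance = 1e-12)
})

test_that("TRI matches a brute-force neighbor sum on a linear slope", {
  # slope of 1 unit per cell along x
  z <- matrix(rep(1:6, each = 5), 5, 6)
  tri <- compute_tri(z)
  brute <- matrix(NA_real_, 5, 6)
  for (r in 1:5) for (c in 1:6) {
    s <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= 5 && cc >= 1 && cc <= 6)
        s <- s + (z[rr, cc] - z[r, c])^2
    }
    brute[r, c] <- sqrt(s)
  }
  expect_equal(tri, brute, tolerance = 1e-12)
  # interior cells of a unit slope: 3 neighbors at +1, 3 at -1, 2 at 0
  expect_equal(tri[3, 3], sqrt(6), tolerance = 1e-12)
})

test_that("TRI is invariant to elevation translation and propagates nodata", {
  z <- matrix(rnorm(36), 6, 6)
  expect_equal(compute_tri(z), compute_tri(z + 100), tolerance = 1e-9)
  z[3, 3] <- NA
  expect_true(is.na(compute_tri(z)[3, 3]))
  expect_false(anyNA(compute_tri(z)[-3, ]))
})

test_that("correlation filter drops the lower-priority member of a perfect pair", {
  g <- tiny_grid(20, 20)
  a <- matrix(rnorm(400), 20, 20)
  st <- raster_stack(g, list(A = a, B = a, C = matrix(rnorm(400), 20, 20)))
  out <- select_uncorrelated(st, threshold = 0.8, priority = c("A", "B", "C"))
  expect_identical(names(out$layers), c("A", "C"))
  expect_identical(attr(out, "dropped"), "B")
})

test_that("three mutually correlated layers leave only the top-priority survivor", {
  set.seed(3)
  base <- rnorm(400)
  mk <- function() matrix(0.97 * base + sqrt(1 - 0.97^2) * rnorm(400), 20, 20)
  st <- raster_stack(tiny_grid(20, 20), list(p = mk(), q = mk(), r = mk()))
  out <- select_uncorrelated(st, threshold = 0.8, priority = c("q", "p", "r"))
  expect_identical(names(out$layers), "q")
})

test_that("independent layers are all kept and the output satisfies the bound", {
  set.seed(4)
  st <- raster_stack(tiny_grid(25, 25),
                     stats::setNames(lapply(1:4, function(i)
                       matrix(rnorm(625), 25, 25)), paste0("L", 1:4)))
  out <- select_uncorrelated(st, threshold = 0.8)
  expect_identical(names(out$layers), paste0("L", 1:4))
  cm <- abs(stats::cor(sapply(out$layers, as.vector)))
  diag(cm) <- 0
  expect_lt(max(cm), 0.8)
})

test_that("zero-variance layers are excluded with a warning", {
  st <- raster_stack(tiny_grid(20, 20),
                     list(flat = matrix(7, 20, 20),
                          a = matrix(rnorm(400), 20, 20),
                          b = matrix(rnorm(400), 20, 20)))
  expect_warning(out <- select_uncorrelated(st), "zero-variance")
  expect_identical(names(out$layers), c("a", "b"))
})

test_that("identity resample is bit-identical and constants stay constant", {
  g <- tiny_grid(8, 8)
  st <- raster_stack(g, list(a = matrix(rnorm(64), 8, 8)))
  expect_identical(resample_to_grid(st, g)$layers$a, st$layers$a)
  coarse <- tiny_grid(4, 4, cellsize = 0.1, xmin = -100, ymin = 40)
  fine <- tiny_grid(8, 8, cellsize = 0.05, xmin = -100, ymin = 40)
  cst <- raster_stack(coarse, list(a = matrix(3.5, 4, 4)))
  out <- resample_to_grid(cst, fine)
  expect_true(all(abs(out$layers$a - 3.5) < 1e-12))
})

test_that("bilinear upsampling of a 2x2 step produces a monotone gradient", {
  coarse <- raster_grid(2, 2, xmin = 0, ymin = 0, cellsize = 1)
  st <- raster_stack(coarse, list(a = matrix(c(0, 0, 1, 1), 2, 2)))
  fine <- raster_grid(4, 4, xmin = 0, ymin = 0, cellsize = 0.5)
  out <- resample_to_grid(st, fine)$layers$a
  cm <- colMeans(out)
  expect_true(all(diff(cm) >= 0))
  expect_gt(cm[4], cm[1])
})

test_that("disjoint extents are a data error; nearest handles categories", {
  a <- raster_stack(raster_grid(4, 4, 0, 0, 1), list(k = matrix(1:16, 4, 4)))
  far <- raster_grid(4, 4, 100, 100, 1)
  expect_error(resample_to_grid(a, far), "disjoint")
  fine <- raster_grid(8, 8, 0, 0, 0.5)
  nn <- resample_to_grid(a, fine, method = "nearest")$layers$k
  expect_true(all(nn %in% 1:16))
})
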