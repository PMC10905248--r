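# shared fixtures, built in code at test time

tiny_grid <- function(nrow = 10, ncol = 10, cellsize = 0.05,
                      xmin = -100, ymin = 40) {
  raster_grid(nrow, ncol, xmin = xmin, ymin = ymin, cellsize = cellsize)
}

uniform_bias <- function(grid) {
  structure(list(grid = grid, weights = matrix(1, grid$nrow, grid$ncol)),
            class = "bias_surface")
}

# single-layer stack from a matrix
one_layer_stack <- function(m, grid = NULL, name = "x") {
  if (is.null(grid)) grid <- tiny_grid(nrow(m), ncol(m))
  raster_stack(grid, stats::setNames(list(m), name))
}

# rectangle range covering a lon/lat box
box_range <- function(x0, y0, x1, y1, species = "sp", buffer_m = 0) {
  range_area(species, rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)),
             buffer_m = buffer_m)
}

# the raw occurrence cleaning fixture: 10 rows of which 2 lack latitude
# (rows 3, 5), 1 is a subspecies (row 8), and 2 duplicate kept rows
# (rows 6, 7 copy rows 1, 2) -> survivors are rows 1, 2, 4, 9, 10
dirty_occurrences <- function() {
  data.frame(
    species = "sp",
    decimalLongitude = c(1, 2, 3, 4, 5, 1, 2, 6, 7, 8),
    decimalLatitude  = c(1, 2, NA, 4, NA, 1, 2, 6, 7, 8),
    taxonRank = c("species", "species", "species", "species", "species",
                  "species", "species", "subspecies", "species", "species"),
    stringsAsFactors = FALSE)
}

# small environment + presence/background draw with a known log-linear truth
signal_dataset <- function(seed = 11, n_presence = 400, n_background = 3000,
                           coefficients = c(env01 = 2),
                           quad_coefficients = c(env01 = -1)) {
  g <- raster_grid(30, 30, cellsize = 0.05)
  st <- make_env_stack(g, 4, 0, seed = seed)
  tr <- truth_spec(names(st$layers), coefficients, quad_coefficients,
                   seed = seed + 1)
  ts <- make_truth_and_sample(st, tr, n_presence, dirty_frac = 0)
  bg <- sample_background(uniform_bias(g), n_background, seed = seed + 2)
  list(grid = g, stack = st, truth = ts$truth,
       presence_env = extract_values(st, ts$occurrences$decimalLongitude,
                                     ts$occurrences$decimalLatitude),
       background_env = extract_values(st, bg$decimalLongitude,
                                       bg$decimalLatitude))
}

# brute-force overlap oracles (explicit loops, independent of the package)
brute_schoener_d <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) s <- s + abs(p[i] - q[i])
  1 - s / 2
}
brute_warren_i <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) s <- s + (sqrt(p[i]) - sqrt(q[i]))^2
  1 - s / 2
}

# exhaustive pair-counting AUC oracle
brute_auc <- function(pres, bg) {
  wins <- 0
  for (a in pres) for (b in bg)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(pres) * length(bg))
}

random_prob_surface_pair <- function(nr, nc) {
  g <- raster_grid(max(nr, 1), max(nc, 1), cellsize = 0.1)
  mk <- function() {
    v <- matrix(stats::rexp(nr * nc), nr, nc)
    suitability_map(g, v, scale = "raw")
  }
  mask <- matrix(TRUE, nr, nc)
  list(px = normalize_surface(mk(), mask), py = normalize_surface(mk(), mask))
}
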