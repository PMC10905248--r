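#' Ground-truth niche specification for the synthetic generator
#'
#' The generator's "true" habitat suitability is a log-linear (Gibbs) density
#' over the grid: s(x) proportional to exp(sum_j lambda_j z_j(x) +
#' sum_j gamma_j z_j(x)^2) with z_j the standardized environmental layers.
#' This mirrors the family the estimator fits, so parameter-recovery checks
#' are well-posed.
#'
#' @param layer_names names of the layers the truth may reference.
#' @param coefficients named numeric vector of linear weights on the
#'   standardized layers.
#' @param quad_coefficients optional named numeric vector of weights on the
#'   squared standardized layers (a negative value creates an optimum).
#' @param bias_strength nonnegative strength of the synthetic sampling-effort
#'   gradient (0 = unbiased sampling).
#' @param seed integer seed used when sampling occurrences from this truth.
#' @return an object of class `truth_spec`.
#' @export
truth_spec <- function(layer_names, coefficients,
                       quad_coefficients = numeric(0),
                       bias_strength = 0, seed = 1) {
  stopifnot(is.character(layer_names), bias_strength >= 0)
  coefficients <- unlist(coefficients)
  quad_coefficients <- unlist(quad_coefficients)
  bad <- setdiff(c(names(coefficients), names(quad_coefficients)), layer_names)
  if (length(bad))
    stop("truth references unknown layer(s): ", paste(bad, collapse = ", "))
  structure(list(layer_names = layer_names, coefficients = coefficients,
                 quad_coefficients = quad_coefficients,
                 bias_strength = bias_strength, seed = as.integer(seed)),
            class = "truth_spec")
}

#' Scenario perturbation of a layer stack
#'
#' A cell-wise affine change x -> x * factor + shift per listed layer;
#' layers absent from the map are held constant, the way static terrain
#' layers (elevation, ruggedness, percent sand) are held constant across
#' climate periods.
#'
#' @param layer_deltas named list; each element `list(shift =, factor =)`
#'   (either may be omitted; defaults 0 and 1). Factors must be positive.
#' @param label scenario label, e.g. `"RCP8.5-like"`.
#' @return an object of class `scenario_delta`.
#' @export
scenario_delta <- function(layer_deltas, label = "scenario") {
  stopifnot(is.list(layer_deltas))
  layer_deltas <- lapply(layer_deltas, function(d) {
    d <- list(shift = d$shift %||% 0, factor = d$factor %||% 1)
    if (d$factor <= 0) stop("scenario factors must be positive")
    d
  })
  structure(list(layer_deltas = layer_deltas, label = label),
            class = "scenario_delta")
}

#' Generate a synthetic environmental layer stack
#'
#' Layers are smoothed Gaussian random fields (white noise convolved with a
#' Gaussian kernel, then standardized), emulating spatially autocorrelated
#' climate predictors, plus one deterministic latitudinal-gradient layer
#' (named `"lat_gradient"`) standing in for a static terrain covariate. When
#' `pairwise_corr > 0`, layers are built in consecutive pairs by mixing,
#' B = rho*A + sqrt(1 - rho^2)*noise, giving a closed-form target
#' correlation for the correlation-pruning stage to find.
#'
#' @param grid a `raster_grid` with at least 20 x 20 cells.
#' @param n_layers number of random layers (>= 2); the gradient layer is
#'   added on top, so the stack has `n_layers + 1` layers.
#' @param pairwise_corr target Pearson correlation within designated pairs,
#'   in `[0, 1)`.
#' @param seed integer seed; generation is bit-reproducible.
#' @param kernel_cells Gaussian smoothing bandwidth in cells (default 2).
#' @return a `raster_stack` with layers `env01..envNN` and `lat_gradient`.
#' @export
make_env_stack <- function(grid, n_layers, pairwise_corr = 0, seed = 1,
                           kernel_cells = 2) {
  stopifnot(inherits(grid, "raster_grid"), n_layers >= 2)
  if (grid$nrow < 20 || grid$ncol < 20)
    stop("grid must have at least 20 x 20 cells")
  if (pairwise_corr < 0 || pairwise_corr >= 1)
    stop("pairwise_corr must be in [0, 1)")
  std <- function(m) (m - mean(m)) / stats::sd(as.vector(m))
  field <- function() {
    std(smooth_matrix(matrix(stats::rnorm(grid$nrow * grid$ncol),
                             grid$nrow, grid$ncol),
                      kernel_cells, renormalize = TRUE))
  }
  layers <- with_seed(seed, {
    out <- vector("list", n_layers)
    i <- 1
    while (i <= n_layers) {
      a <- field()
      out[[i]] <- a
      if (pairwise_corr > 0 && i + 1 <= n_layers) {
        noise <- field()
        out[[i + 1]] <- std(pairwise_corr * a +
                              sqrt(1 - pairwise_corr^2) * noise)
        i <- i + 2
      } else {
        i <- i + 1
      }
    }
    out
  })
  names(layers) <- sprintf("env%02d", seq_len(n_layers))
  cc <- cell_centers(grid)
  layers$lat_gradient <- std(cc$y)
  raster_stack(grid, layers)
}

# standardized layer values over valid cells (NA kept as NA)
standardize_layer <- function(l) {
  v <- as.vector(l)
  (l - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
}

# true suitability surface from a truth_spec: raw scale, sums to 1
truth_surface <- function(stack, truth) {
  mask <- stack_mask(stack)
  if (!any(mask)) stop("stack has no valid cells")
  eta <- matrix(0, stack$grid$nrow, stack$grid$ncol)
  for (nm in names(truth$coefficients)) {
    z <- standardize_layer(stack$layers[[nm]])
    eta <- eta + truth$coefficients[[nm]] * z
  }
  for (nm in names(truth$quad_coefficients)) {
    z <- standardize_layer(stack$layers[[nm]])
    eta <- eta + truth$quad_coefficients[[nm]] * z^2
  }
  eta[!mask] <- NA_real_
  s <- exp(eta - max(eta, na.rm = TRUE))
  s <- s / sum(s, na.rm = TRUE)
  suitability_map(stack$grid, s, scale = "raw")
}

#' Generate a true suitability surface and a biased occurrence sample
#'
#' Builds the ground-truth suitability from `truth` (see [truth_spec()]),
#' then draws `n_presence` presence points with per-cell probability
#' proportional to suitability times sampling effort (`bias`, 1 everywhere
#' when absent), placing each point uniformly within its cell. A fraction of
#' "dirty" rows — missing coordinates, exact duplicates, subspecies-tagged
#' records — is appended so the cleaning stage has real work to do.
#'
#' @param stack environmental `raster_stack` (valid cells define the
#'   sampling footprint).
#' @param truth a `truth_spec`.
#' @param n_presence number of presence points (>= 1).
#' @param bias optional `bias_surface` on the same grid.
#' @param species species label for the records.
#' @param dirty_frac fraction of extra dirty rows appended (default 0.05).
#' @return list with `truth` (a raw-scale `suitability_map` summing to 1)
#'   and `occurrences` (data.frame with `species`, `decimalLongitude`,
#'   `decimalLatitude`, `taxonRank`, `flag = "raw"`).
#' @export
make_truth_and_sample <- function(stack, truth, n_presence, bias = NULL,
                                  species = "species_A", dirty_frac = 0.05) {
  stopifnot(inherits(truth, "truth_spec"), n_presence >= 1)
  s_map <- truth_surface(stack, truth)
  g <- stack$grid
  p <- as.vector(s_map$values)
  if (!is.null(bias)) {
    if (!grids_equal(g, bias$grid)) stop("bias surface grid mismatch")
    p <- p * as.vector(bias$weights)
  }
  p[is.na(p)] <- 0
  if (sum(p) <= 0) stop("no cell has positive sampling probability")
  occ <- with_seed(truth$seed, {
    cells <- sample.int(length(p), n_presence, replace = TRUE, prob = p)
    row <- ((cells - 1) %% g$nrow) + 1
    col <- ((cells - 1) %/% g$nrow) + 1
    lon <- g$xmin + (col - 1 + stats::runif(n_presence)) * g$cellsize
    lat <- grid_ymax(g) - (row - 1 + stats::runif(n_presence)) * g$cellsize
    df <- data.frame(species = species, decimalLongitude = lon,
                     decimalLatitude = lat, taxonRank = "species",
                     flag = "raw", stringsAsFactors = FALSE)
    n_dirty <- round(dirty_frac * n_presence)
    if (n_dirty > 0) {
      kinds <- rep(c("missing", "duplicate", "subspecies"),
                   length.out = n_dirty)
      src <- sample.int(n_presence, n_dirty, replace = TRUE)
      dirty <- df[src, , drop = FALSE]
      dirty$decimalLatitude[kinds == "missing"] <- NA_real_
      dirty$taxonRank[kinds == "subspecies"] <- "subspecies"
      # subspecies rows get jittered coords so only the rank filter catches
      # them; duplicates stay exact copies
      jit <- kinds == "subspecies"
      dirty$decimalLongitude[jit] <- dirty$decimalLongitude[jit] +
        stats::runif(sum(jit), -0.5, 0.5) * g$cellsize
      df <- rbind(df, dirty)
    }
    rownames(df) <- NULL
    df
  })
  list(truth = s_map, occurrences = occ)
}

#' Synthetic sampling-effort surface
#'
#' Effort increases exponentially along a smoothed random gradient, a cheap
#' stand-in for the roadside/population-center bias of real biodiversity
#' databases. Strength 0 gives uniform effort.
#'
#' @param grid a `raster_grid`.
#' @param strength exponential gradient strength (>= 0).
#' @param seed integer seed.
#' @return a `bias_surface`.
#' @export
make_effort_surface <- function(grid, strength = 1, seed = 1) {
  stopifnot(strength >= 0)
  f <- with_seed(seed, {
    m <- smooth_matrix(matrix(stats::rnorm(grid$nrow * grid$ncol),
                              grid$nrow, grid$ncol), 3, renormalize = TRUE)
    (m - mean(m)) / stats::sd(as.vector(m))
  })
  structure(list(grid = grid, weights = exp(strength * f)),
            class = "bias_surface")
}

#' Apply a scenario perturbation to a stack
#'
#' Listed layers are transformed cell-wise (`x * factor + shift`); unlisted
#' layers are returned bit-identical, and nodata cells stay nodata.
#'
#' @param stack a `raster_stack`.
#' @param delta a `scenario_delta`.
#' @return the perturbed `raster_stack`.
#' @export
make_scenario <- function(stack, delta) {
  stopifnot(inherits(stack, "raster_stack"), inherits(delta, "scenario_delta"))
  bad <- setdiff(names(delta$layer_deltas), names(stack$layers))
  if (length(bad))
    stop("scenario references unknown layer(s): ", paste(bad, collapse = ", "))
  for (nm in names(delta$layer_deltas)) {
    d <- delta$layer_deltas[[nm]]
    stack$layers[[nm]] <- stack$layers[[nm]] * d$factor + d$shift
  }
  stack
}

#' Rectangular synthetic range polygon
#'
#' A species range as an axis-aligned rectangle covering the stated fraction
#' of the grid extent; two overlapping rectangles emulate a sympatric pair.
#'
#' @param grid a `raster_grid`.
#' @param xfrac,yfrac length-2 fractions of the x / y extent (0 = min edge,
#'   1 = max edge).
#' @param species species label.
#' @param buffer_m dispersal buffer in meters.
#' @return a `range_area`.
#' @export
make_range_polygon <- function(grid, xfrac = c(0, 1), yfrac = c(0, 1),
                               species = "species", buffer_m = 0) {
  x0 <- grid$xmin + xfrac[1] * (grid_xmax(grid) - grid$xmin)
  x1 <- grid$xmin + xfrac[2] * (grid_xmax(grid) - grid$xmin)
  y0 <- grid$ymin + yfrac[1] * (grid_ymax(grid) - grid$ymin)
  y1 <- grid$ymin + yfrac[2] * (grid_ymax(grid) - grid$ymin)
  range_area(species,
             rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)),
             buffer_m = buffer_m)
}
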