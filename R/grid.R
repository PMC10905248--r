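#' Define a raster grid
#'
#' A `raster_grid` is the shared coordinate frame of every layer, mask and
#' suitability surface in an analysis: a regular lattice of square cells in a
#' geographic CRS. Rows are stored top-down (row 1 is the northernmost row),
#' matching the on-disk convention of ESRI ASCII grids.
#'
#' @param nrow,ncol grid dimensions (cells).
#' @param xmin,ymin coordinates of the lower-left corner (degrees).
#' @param cellsize cell edge length (degrees); cells are square.
#' @param crs CRS identifier; only geographic WGS84 is exercised.
#' @param nodata sentinel written to file for missing cells; in memory,
#'   missing cells are `NA`.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(nrow, ncol, xmin = 0, ymin = 0, cellsize = 1,
                        crs = "EPSG:4326", nodata = -9999) {
  stopifnot(nrow >= 1, ncol >= 1, cellsize > 0)
  structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol),
         xmin = xmin, ymin = ymin, cellsize = cellsize,
         crs = crs, nodata = nodata),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d cells, cellsize %g, origin (%g, %g), %s\n",
              x$nrow, x$ncol, x$cellsize, x$xmin, x$ymin, x$crs))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-9) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol && identical(a$crs, b$crs)
}

grid_xmax <- function(g) g$xmin + g$ncol * g$cellsize
grid_ymax <- function(g) g$ymin + g$nrow * g$cellsize

#' Cell-center coordinates of a grid
#'
#' @param grid a `raster_grid`.
#' @return a list with matrices `x` and `y` (nrow x ncol) of cell-center
#'   longitudes and latitudes.
#' @export
cell_centers <- function(grid) {
  xs <- grid$xmin + (seq_len(grid$ncol) - 0.5) * grid$cellsize
  ys <- grid_ymax(grid) - (seq_len(grid$nrow) - 0.5) * grid$cellsize
  list(x = matrix(xs, grid$nrow, grid$ncol, byrow = TRUE),
       y = matrix(ys, grid$nrow, grid$ncol))
}

# row/col indices (top-down rows) for lon/lat points; NA outside the extent
cell_index <- function(grid, lon, lat) {
  col <- floor((lon - grid$xmin) / grid$cellsize) + 1
  row <- floor((grid_ymax(grid) - lat) / grid$cellsize) + 1
  # points exactly on the max edge belong to the last cell
  col[lon == grid_xmax(grid)] <- grid$ncol
  row[lat == grid$ymin] <- grid$nrow
  bad <- col < 1 | col > grid$ncol | row < 1 | row > grid$nrow |
    is.na(lon) | is.na(lat)
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Assemble a raster stack
#'
#' A `raster_stack` bundles named single-band layers sharing one grid. Missing
#' cells are `NA`; after [harmonize_mask()] or [buffer_and_mask()] the NA
#' pattern is identical across layers.
#'
#' @param grid a `raster_grid`.
#' @param layers named list of numeric matrices (`grid$nrow` x `grid$ncol`).
#' @return an object of class `raster_stack`.
#' @export
raster_stack <- function(grid, layers) {
  stopifnot(inherits(grid, "raster_grid"), is.list(layers),
            length(layers) >= 1, !is.null(names(layers)),
            all(nzchar(names(layers))), !anyDuplicated(names(layers)))
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (!is.matrix(m) || nrow(m) != grid$nrow || ncol(m) != grid$ncol)
      stop("layer '", nm, "' does not match the grid dimensions")
    storage.mode(layers[[nm]]) <- "double"
  }
  structure(list(grid = grid, layers = layers), class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("<raster_stack> %d layer(s) on %d x %d grid: %s\n",
              length(x$layers), x$grid$nrow, x$grid$ncol,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' @export
names.raster_stack <- function(x) names(x$layers)

#' Number of layers in a stack
#' @param stack a `raster_stack`.
#' @export
n_layers <- function(stack) length(stack$layers)

#' Shared validity mask of a stack
#'
#' @param stack a `raster_stack`.
#' @return logical matrix, `TRUE` where every layer has a finite value.
#' @export
stack_mask <- function(stack) {
  m <- !is.na(stack$layers[[1]])
  for (l in stack$layers[-1]) m <- m & !is.na(l)
  m
}

#' Force a common NA pattern across layers
#'
#' Cells missing in any layer become `NA` in all layers, so downstream
#' statistics are computed over one footprint.
#'
#' @param stack a `raster_stack`.
#' @export
harmonize_mask <- function(stack) {
  keep <- stack_mask(stack)
  stack$layers <- lapply(stack$layers, function(l) { l[!keep] <- NA_real_; l })
  stack
}

subset_stack <- function(stack, names) {
  raster_stack(stack$grid, stack$layers[names])
}

#' Combine stacks on a shared grid
#'
#' @param ... `raster_stack` objects on identical grids with disjoint layer
#'   names.
#' @export
merge_stacks <- function(...) {
  stacks <- list(...)
  g <- stacks[[1]]$grid
  layers <- list()
  for (s in stacks) {
    if (!grids_equal(g, s$grid)) stop("stacks are not on the same grid")
    layers <- c(layers, s$layers)
  }
  if (anyDuplicated(names(layers))) stop("duplicate layer names across stacks")
  raster_stack(g, layers)
}

#' Per-cell habitat suitability on a declared scale
#'
#' @param grid a `raster_grid`.
#' @param values numeric matrix of per-cell suitability (`NA` outside the
#'   modeled footprint).
#' @param scale `"raw"` (sums to 1 over valid cells) or `"cloglog"`
#'   (bounded in \[0, 1\]).
#' @return an object of class `suitability_map`.
#' @export
suitability_map <- function(grid, values, scale = c("raw", "cloglog")) {
  scale <- match.arg(scale)
  stopifnot(inherits(grid, "raster_grid"), is.matrix(values),
            nrow(values) == grid$nrow, ncol(values) == grid$ncol)
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values, scale = scale),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<suitability_map> scale=%s, %d valid cells, sum=%.6g\n",
              x$scale, length(v), sum(v)))
  invisible(x)
}

#' Sum of suitability over valid cells (the H statistic)
#'
#' The quantity entering the vulnerability assessment: the sum of per-cell
#' suitability over a footprint, optionally restricted by `mask`.
#'
#' @param map a `suitability_map`.
#' @param mask optional logical matrix; only cells where it is `TRUE` count.
#' @export
suitability_sum <- function(map, mask = NULL) {
  v <- map$values
  if (!is.null(mask)) v[!mask] <- NA_real_
  sum(v, na.rm = TRUE)
}

# ---- ESRI ASCII grid I/O ----------------------------------------------------

#' Write a layer as an ESRI ASCII grid
#'
#' Plain-text single-band raster interchange: a six-line header followed by
#' rows of cell values, northernmost row first.
#'
#' @param values numeric matrix on `grid`.
#' @param grid a `raster_grid`.
#' @param path output file path (conventionally `.asc`).
#' @export
write_ascii_grid <- function(values, grid, path) {
  stopifnot(is.matrix(values), nrow(values) == grid$nrow,
            ncol(values) == grid$ncol)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$ncol),
    sprintf("nrows %d", grid$nrow),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymin),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", grid$nodata)), con)
  v <- values
  v[is.na(v)] <- grid$nodata
  writeLines(apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path path to an `.asc` file.
#' @param crs CRS to record on the resulting grid.
#' @return list with elements `grid` (a `raster_grid`) and `values`
#'   (numeric matrix, nodata replaced by `NA`).
#' @export
read_ascii_grid <- function(path, crs = "EPSG:4326") {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  g <- raster_grid(hdr$nrows, hdr$ncols, hdr$xllcorner, hdr$yllcorner,
                   hdr$cellsize, crs = crs, nodata = hdr$nodata_value)
  vals <- matrix(scan(text = lines[-(1:6)], quiet = TRUE),
                 nrow = g$nrow, ncol = g$ncol, byrow = TRUE)
  vals[vals == g$nodata] <- NA_real_
  list(grid = g, values = vals)
}

#' Write every layer of a stack to a directory
#'
#' One `.asc` file per layer plus a JSON manifest mapping layer name to file.
#'
#' @param stack a `raster_stack`.
#' @param dir output directory (created if needed).
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(stack$layers)) {
    f <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(stack$layers[[nm]], stack$grid, f)
    files[nm] <- basename(f)
  }
  jsonlite::write_json(as.list(files), file.path(dir, "stack.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a stack written by [write_stack()]
#'
#' @param dir directory containing `stack.json` and the `.asc` layers.
#' @export
read_stack <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "stack.json"))
  layers <- list()
  g <- NULL
  for (nm in names(manifest)) {
    r <- read_ascii_grid(file.path(dir, manifest[[nm]]))
    if (is.null(g)) g <- r$grid
    else if (!grids_equal(g, r$grid)) stop("layer '", nm, "' grid mismatch")
    layers[[nm]] <- r$values
  }
  raster_stack(g, layers)
}
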