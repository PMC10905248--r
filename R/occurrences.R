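#' Clean raw occurrence records
#'
#' Applies the three standard presence-record filters: drop rows with a
#' missing coordinate, drop rows whose taxon rank marks a subspecies (when
#' `drop_subspecies` is set), and drop exact duplicates of
#' (species, longitude, latitude), keeping the first. Survivor order is
#' preserved. Datum conversion (e.g. NAD27 to WGS84) is not performed here;
#' supply a `transform` function if records need one.
#'
#' @param raw data.frame with columns `decimalLongitude`, `decimalLatitude`,
#'   and optionally `species` and `taxonRank`.
#' @param drop_subspecies drop rows with `taxonRank == "subspecies"`
#'   (case-insensitive)? Default `TRUE`.
#' @param transform optional function(df) -> df applied first, the hook for a
#'   standard datum transform.
#' @return the cleaned data.frame with a `flag` column set to `"cleaned"`.
#'   Zero survivors produce a warning, not an error.
#' @export
clean_records <- function(raw, drop_subspecies = TRUE, transform = NULL) {
  stopifnot(is.data.frame(raw),
            all(c("decimalLongitude", "decimalLatitude") %in% names(raw)))
  if (!is.null(transform)) raw <- transform(raw)
  keep <- !is.na(raw$decimalLongitude) & !is.na(raw$decimalLatitude)
  if (drop_subspecies && "taxonRank" %in% names(raw))
    keep <- keep & !(tolower(trimws(as.character(raw$taxonRank))) == "subspecies" &
                     !is.na(raw$taxonRank))
  out <- raw[keep, , drop = FALSE]
  sp <- if ("species" %in% names(out)) out$species else ""
  dup <- duplicated(paste(sp, out$decimalLongitude, out$decimalLatitude,
                          sep = "\r"))
  out <- out[!dup, , drop = FALSE]
  if (nrow(out) == 0)
    warning("no records survived cleaning; returning an empty set")
  out$flag <- rep("cleaned", nrow(out))
  rownames(out) <- NULL
  out
}

# thinning-grid cell key for each record
thin_cell_key <- function(occ, anchor, cell_deg_x, cell_deg_y) {
  cx <- floor((occ$decimalLongitude - anchor[1]) / cell_deg_x)
  cy <- floor((occ$decimalLatitude - anchor[2]) / cell_deg_y)
  paste(cx, cy)
}

#' Thin occurrences on a coarse grid
#'
#' Lays a temporary thinning grid (default 5 km x 5 km) over the points and
#' keeps at most one record per occupied cell, chosen uniformly at random
#' under `seed`. This removes the clustering produced by heavily surveyed
#' localities. The grid is anchored at the raster grid origin when `grid` is
#' supplied (at (0, 0) otherwise) and the kilometer size is converted to
#' degrees at the mid-latitude of the data.
#'
#' @param occ cleaned occurrence data.frame.
#' @param grid optional `raster_grid` providing the anchor and mid-latitude.
#' @param cell_km thinning cell edge in kilometers (default 5).
#' @param cell_deg optional fixed cell size in degrees, overriding `cell_km`.
#' @param seed integer seed for the per-cell choice.
#' @return the thinned subset, `flag` set to `"thinned"`, original order
#'   preserved.
#' @export
thin_by_grid <- function(occ, grid = NULL, cell_km = 5, cell_deg = NULL,
                         seed = 1) {
  stopifnot(is.data.frame(occ), cell_km > 0)
  if (nrow(occ) == 0) return(occ)
  if (is.null(cell_deg)) {
    mid_lat <- if (!is.null(grid)) (grid$ymin + grid_ymax(grid)) / 2
               else mean(occ$decimalLatitude, na.rm = TRUE)
    dy <- cell_km * 1000 / METERS_PER_DEG_LAT
    dx <- cell_km * 1000 / (METERS_PER_DEG_LAT * cos(mid_lat * pi / 180))
  } else {
    dx <- dy <- cell_deg
  }
  anchor <- if (!is.null(grid)) c(grid$xmin, grid$ymin) else c(0, 0)
  key <- thin_cell_key(occ, anchor, dx, dy)
  keep_idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(occ)), key), function(idx) {
      if (length(idx) == 1) idx else idx[sample.int(length(idx), 1)]
    }), use.names = FALSE)
  })
  out <- occ[sort(keep_idx), , drop = FALSE]
  out$flag <- rep("thinned", nrow(out))
  rownames(out) <- NULL
  out
}

#' Target-group sampling-effort surface
#'
#' Rasterizes target-group occurrence records (records of similarly surveyed
#' taxa) into per-cell counts, the standard proxy for spatial sampling
#' effort. Optional Gaussian smoothing spreads the effort while preserving
#' its total mass.
#'
#' @param target_group data.frame of target-group records
#'   (`decimalLongitude` / `decimalLatitude`).
#' @param grid the model `raster_grid`.
#' @param smooth_cells Gaussian bandwidth in cells (0 = raw counts).
#' @param floor_eps optional small weight added to every cell, the escape
#'   hatch for sparse target groups (default 0: unvisited cells get zero
#'   background weight).
#' @return an object of class `bias_surface` (grid + nonnegative weights).
#' @export
build_bias_surface <- function(target_group, grid, smooth_cells = 0,
                               floor_eps = 0) {
  stopifnot(is.data.frame(target_group), inherits(grid, "raster_grid"),
            smooth_cells >= 0, floor_eps >= 0)
  idx <- cell_index(grid, target_group$decimalLongitude,
                    target_group$decimalLatitude)
  ok <- !is.na(idx$row)
  if (!any(ok))
    stop("no target-group records fall on the grid; ",
         "use a uniform background (equal weights) instead")
  w <- matrix(0, grid$nrow, grid$ncol)
  tab <- table(factor(paste(idx$row[ok], idx$col[ok])))
  rc <- do.call(rbind, strsplit(names(tab), " "))
  w[cbind(as.integer(rc[, 1]), as.integer(rc[, 2]))] <- as.numeric(tab)
  if (smooth_cells > 0) {
    total <- sum(w)
    w <- smooth_matrix(w, smooth_cells, renormalize = FALSE)
    w <- w * (total / sum(w))  # edge truncation renormalized
  }
  w <- w + floor_eps
  structure(list(grid = grid, weights = w), class = "bias_surface")
}

#' @export
print.bias_surface <- function(x, ...) {
  cat(sprintf("<bias_surface> %d x %d, total weight %.6g, %d nonzero cells\n",
              x$grid$nrow, x$grid$ncol, sum(x$weights), sum(x$weights > 0)))
  invisible(x)
}

#' Draw weighted background points (pseudo-absences)
#'
#' Samples `n` background points with cell membership multinomial in the
#' bias weights (with replacement: a heavily surveyed cell can host many
#' points) and uniform placement within each chosen cell, so the background
#' reproduces the presence records' spatial sampling bias.
#'
#' @param bias a `bias_surface`.
#' @param n number of points (default 10000).
#' @param seed integer seed.
#' @param species label for the output rows (default `"background"`).
#' @return data.frame with `species`, `decimalLongitude`, `decimalLatitude`,
#'   `flag = "background"`.
#' @export
sample_background <- function(bias, n = 10000, seed = 1,
                              species = "background") {
  stopifnot(inherits(bias, "bias_surface"))
  if (n <= 0) stop("n must be a positive integer")
  w <- as.vector(bias$weights)
  w[is.na(w)] <- 0
  if (sum(w) <= 0) stop("bias surface has no positive weight")
  g <- bias$grid
  with_seed(seed, {
    cells <- sample.int(length(w), n, replace = TRUE, prob = w)
    row <- ((cells - 1) %% g$nrow) + 1          # column-major unfold
    col <- ((cells - 1) %/% g$nrow) + 1
    lon <- g$xmin + (col - 1 + stats::runif(n)) * g$cellsize
    lat <- grid_ymax(g) - (row - 1 + stats::runif(n)) * g$cellsize
    data.frame(species = species, decimalLongitude = lon,
               decimalLatitude = lat, flag = "background",
               stringsAsFactors = FALSE)
  })
}

#' Write / read occurrence CSV
#'
#' Standard Darwin-Core-ish columns: `species`, `decimalLongitude`,
#' `decimalLatitude`, `taxonRank`, plus any flag columns present.
#'
#' @param occ occurrence data.frame.
#' @param path CSV path.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
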