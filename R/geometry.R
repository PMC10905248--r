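# Planar polygon utilities used by range masking and intersection. Polygons
# are stored as a list of rings, each ring a two-column matrix of (x, y)
# vertices; the first ring is the outer boundary (holes are not supported,
# which the constructors enforce). Coordinates are lon/lat degrees; metric
# operations convert to a local equirectangular frame first.

METERS_PER_DEG_LAT <- 111320

polygon_ring <- function(coords) {
  m <- as.matrix(coords)
  if (ncol(m) != 2 || nrow(m) < 3) stop("a ring needs >= 3 (x, y) vertices")
  # drop an explicit closing vertex; rings are implicitly closed
  if (all(m[1, ] == m[nrow(m), ]) && nrow(m) > 3) m <- m[-nrow(m), , drop = FALSE]
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y")
  m
}

#' Species range polygon with a dispersal buffer
#'
#' @param species species label.
#' @param rings a single (x, y) vertex matrix, or a list of such matrices for
#'   a multi-part range. Rings need not be closed. Holes are not supported.
#' @param buffer_m buffer distance in meters applied outward from the
#'   boundary when masking (e.g. 1500 for a snake home-range buffer, 36 for a
#'   kangaroo-rat activity-shift buffer).
#' @return an object of class `range_area`.
#' @export
range_area <- function(species, rings, buffer_m = 0) {
  stopifnot(is.character(species), length(species) == 1, buffer_m >= 0)
  if (!is.list(rings)) rings <- list(rings)
  rings <- lapply(rings, polygon_ring)
  for (r in rings) {
    if (abs(ring_area(r)) <= 0) stop("degenerate ring with zero area")
  }
  structure(list(species = species, rings = rings, buffer_m = buffer_m),
            class = "range_area")
}

#' @export
print.range_area <- function(x, ...) {
  cat(sprintf("<range_area> %s: %d part(s), buffer %g m, area %.6g deg^2\n",
              x$species, length(x$rings), x$buffer_m, range_geom_area(x)))
  invisible(x)
}

# signed shoelace area of one ring
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Planar area of a range polygon (square degrees)
#' @param range_ a `range_area`.
#' @export
range_geom_area <- function(range_) {
  sum(vapply(range_$rings, function(r) abs(ring_area(r)), numeric(1)))
}

# even-odd ray casting; px, py vectors -> logical. Boundary points count as
# inside (they are within distance 0 of the boundary anyway).
points_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

points_in_polygon <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (r in rings) inside <- inside | points_in_ring(px, py, r)
  inside
}

# min distance (in the units of the coordinates) from points to a ring's edges
dist_to_ring <- function(px, py, ring) {
  n <- nrow(ring)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- ring[j, 1]; ay <- ring[j, 2]
    bx <- ring[i, 1]; by <- ring[i, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 > 0) pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2)) else 0
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
    j <- i
  }
  sqrt(d2)
}

# TRUE for points inside the polygon or within buffer_m of its boundary.
# Distances are evaluated in a local equirectangular frame anchored at
# mid_lat (meters per degree of longitude shrink with cos(latitude)).
points_in_buffered <- function(px, py, range_, mid_lat) {
  inside <- points_in_polygon(px, py, range_$rings)
  if (range_$buffer_m > 0 && !all(inside)) {
    mx <- METERS_PER_DEG_LAT * cos(mid_lat * pi / 180)
    my <- METERS_PER_DEG_LAT
    idx <- which(!inside)
    d <- rep(Inf, length(idx))
    for (r in range_$rings) {
      rx <- r[, 1] * mx; ry <- r[, 2] * my
      d <- pmin(d, dist_to_ring(px[idx] * mx, py[idx] * my, cbind(rx, ry)))
    }
    inside[idx] <- d <= range_$buffer_m
  }
  inside
}

ring_is_convex <- function(ring) {
  n <- nrow(ring)
  if (n < 3) return(FALSE)
  s <- 0
  for (i in seq_len(n)) {
    a <- ring[i, ]; b <- ring[(i %% n) + 1, ]; c <- ring[((i + 1) %% n) + 1, ]
    cr <- (b[1] - a[1]) * (c[2] - b[2]) - (b[2] - a[2]) * (c[1] - b[1])
    if (abs(cr) < 1e-14) next
    if (s == 0) s <- sign(cr)
    else if (sign(cr) != s) return(FALSE)
  }
  TRUE
}

# Sutherland-Hodgman: clip `subject` ring by convex `clip` ring.
# Returns a vertex matrix (possibly with 0 rows).
clip_ring_convex <- function(subject, clip) {
  if (ring_area(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  n <- nrow(clip)
  for (i in seq_len(n)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]; b <- clip[(i %% n) + 1, ]
    # inside = left of directed edge a->b (clip is CCW)
    side <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    inp <- out
    out <- matrix(numeric(0), 0, 2)
    m <- nrow(inp)
    for (k in seq_len(m)) {
      cur <- inp[k, ]; prv <- inp[if (k == 1) m else k - 1, ]
      sc <- side(cur); sp <- side(prv)
      if (sc >= -1e-14) {
        if (sp < -1e-14) out <- rbind(out, seg_line_isect(prv, cur, a, b))
        out <- rbind(out, cur)
      } else if (sp >= -1e-14) {
        out <- rbind(out, seg_line_isect(prv, cur, a, b))
      }
    }
  }
  out
}

seg_line_isect <- function(p, q, a, b) {
  # intersection of segment p-q with the infinite line through a-b
  d1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  d2 <- (b[1] - a[1]) * (q[2] - a[2]) - (b[2] - a[2]) * (q[1] - a[1])
  t <- d1 / (d1 - d2)
  p + t * (q - p)
}

# ---- GeoJSON I/O ------------------------------------------------------------

#' Write range polygons as GeoJSON
#'
#' @param ranges a `range_area` or list of them.
#' @param path output `.geojson` path.
#' @export
write_ranges_geojson <- function(ranges, path) {
  if (inherits(ranges, "range_area")) ranges <- list(ranges)
  feats <- lapply(ranges, function(r) {
    coords <- lapply(r$rings, function(ring) {
      closed <- rbind(ring, ring[1, , drop = FALSE])
      lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1], closed[i, 2]))
    })
    list(type = "Feature",
         properties = list(species = r$species, buffer_m = r$buffer_m),
         geometry = list(type = "MultiPolygon",
                         coordinates = lapply(coords, function(cc) list(cc))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read range polygons from GeoJSON
#'
#' Accepts Polygon and MultiPolygon features; holes are rejected.
#'
#' @param path a `.geojson` file written by [write_ranges_geojson()] or any
#'   FeatureCollection with `species` / `buffer_m` properties.
#' @return list of `range_area` objects.
#' @export
read_ranges_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    geom <- f$geometry
    polys <- if (identical(geom$type, "Polygon")) list(geom$coordinates)
             else geom$coordinates
    rings <- lapply(polys, function(p) {
      if (length(p) > 1) stop("polygon holes are not supported")
      do.call(rbind, lapply(p[[1]], function(pt) c(pt[[1]], pt[[2]])))
    })
    range_area(species = f$properties$species %||% "unknown",
               rings = rings,
               buffer_m = f$properties$buffer_m %||% 0)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
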