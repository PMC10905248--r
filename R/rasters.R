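#' Mask a stack to a buffered species range
#'
#' Cells whose centers fall outside the range polygon, extended outward by
#' the range's dispersal buffer, become `NA` in every layer; cells inside are
#' untouched. The buffer test runs in a local equirectangular metric frame
#' anchored at the grid's mid-latitude, so `buffer_m` is honest meters.
#'
#' @param stack a `raster_stack`.
#' @param range_ a `range_area` (polygon + `buffer_m`).
#' @return the masked `raster_stack`.
#' @export
buffer_and_mask <- function(stack, range_) {
  stopifnot(inherits(stack, "raster_stack"), inherits(range_, "range_area"))
  cc <- cell_centers(stack$grid)
  mid_lat <- (stack$grid$ymin + grid_ymax(stack$grid)) / 2
  keep <- points_in_buffered(as.vector(cc$x), as.vector(cc$y), range_, mid_lat)
  keep <- matrix(keep, stack$grid$nrow, stack$grid$ncol)
  if (!any(keep & stack_mask(stack)))
    stop("range polygon does not intersect any valid cell of the stack")
  stack$layers <- lapply(stack$layers, function(l) { l[!keep] <- NA_real_; l })
  stack
}

#' Terrain ruggedness index from an elevation layer
#'
#' TRI(cell) = sqrt(sum over the 8 neighbors of (z_neighbor - z_center)^2),
#' the root-sum-of-squares neighborhood heterogeneity of Riley et al. Edge
#' cells use their available neighbors; `NA` elevation propagates to `NA`
#' TRI, and `NA` neighbors are simply excluded (like edges). An alternative
#' mean-absolute-difference index is available via `method`.
#'
#' @param elevation numeric matrix of elevations.
#' @param method `"riley"` (root sum of squares, default) or
#'   `"mean_abs"` (mean absolute neighbor difference).
#' @return matrix of the same shape.
#' @export
compute_tri <- function(elevation, method = c("riley", "mean_abs")) {
  method <- match.arg(method)
  stopifnot(is.matrix(elevation))
  nr <- nrow(elevation); nc <- ncol(elevation)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0L, nr, nc)
  pad <- matrix(NA_real_, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- elevation
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    d <- nb - elevation
    ok <- !is.na(d)
    if (method == "riley") acc[ok] <- acc[ok] + d[ok]^2
    else acc[ok] <- acc[ok] + abs(d[ok])
    cnt[ok] <- cnt[ok] + 1L
  }
  out <- if (method == "riley") sqrt(acc) else acc / pmax(cnt, 1L)
  out[is.na(elevation)] <- NA_real_
  out[cnt == 0L & !is.na(elevation)] <- 0
  out
}

#' Drop highly correlated predictors
#'
#' Computes pairwise Pearson correlations over jointly valid cells, then
#' greedily scans pairs by descending |r|: whenever a pair meets the
#' threshold, the lower-priority member is dropped, until all remaining
#' pairwise |r| are below the threshold. The priority list replaces the
#' expert's ecological choice with a deterministic, user-stated preference
#' order (earlier = keep).
#'
#' @param stack a `raster_stack` with at least 2 layers.
#' @param threshold correlation magnitude at or above which a pair is pruned
#'   (default 0.8).
#' @param priority character vector ordering all layer names from most to
#'   least preferred; defaults to the stack's layer order.
#' @return the pruned `raster_stack`; attribute `"dropped"` lists removals.
#' @export
select_uncorrelated <- function(stack, threshold = 0.8, priority = NULL) {
  stopifnot(inherits(stack, "raster_stack"), n_layers(stack) >= 2,
            threshold > 0)
  nms <- names(stack$layers)
  if (is.null(priority)) priority <- nms
  if (!all(nms %in% priority))
    stop("priority must contain every layer name")
  vals <- sapply(stack$layers, as.vector)  # cells x layers
  sds <- apply(vals, 2, stats::sd, na.rm = TRUE)
  degenerate <- nms[is.na(sds) | sds == 0]
  if (length(degenerate)) {
    warning("zero-variance layer(s) excluded (correlation undefined): ",
            paste(degenerate, collapse = ", "))
    nms <- setdiff(nms, degenerate)
    vals <- vals[, nms, drop = FALSE]
  }
  keep <- nms
  prio <- match(keep, priority)
  names(prio) <- keep
  repeat {
    if (length(keep) < 2) break
    cm <- abs(stats::cor(vals[, keep, drop = FALSE],
                         use = "pairwise.complete.obs"))
    diag(cm) <- 0
    if (max(cm, na.rm = TRUE) < threshold) break
    ij <- which(cm == max(cm, na.rm = TRUE), arr.ind = TRUE)[1, ]
    a <- keep[ij[1]]; b <- keep[ij[2]]
    drop <- if (prio[a] <= prio[b]) b else a
    keep <- setdiff(keep, drop)
  }
  out <- subset_stack(stack, keep)
  attr(out, "dropped") <- setdiff(names(stack$layers), keep)
  out
}

#' Resample a stack onto a target grid
#'
#' Bilinear interpolation for continuous layers, nearest-neighbor for
#' categorical ones; used to harmonize coarser paleoclimate layers with the
#' model grid. Identical source/target grids short-circuit to a bit-identical
#' copy. Target cells outside the source extent, or whose neighborhood is
#' all nodata, become `NA`; bilinear weights are renormalized over the
#' non-missing corners.
#'
#' @param stack a `raster_stack`.
#' @param target a `raster_grid` on the same CRS.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return a `raster_stack` on `target`.
#' @export
resample_to_grid <- function(stack, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  src <- stack$grid
  if (!identical(src$crs, target$crs))
    stop("source and target CRS differ; reprojection is out of scope")
  if (grids_equal(src, target)) return(stack)
  if (grid_xmax(src) <= target$xmin || src$xmin >= grid_xmax(target) ||
      grid_ymax(src) <= target$ymin || src$ymin >= grid_ymax(target))
    stop("source and target extents are disjoint")
  cc <- cell_centers(target)
  px <- as.vector(cc$x); py <- as.vector(cc$y)
  # fractional position in source cell-center coordinates
  fx <- (px - (src$xmin + 0.5 * src$cellsize)) / src$cellsize
  fy <- ((grid_ymax(src) - 0.5 * src$cellsize) - py) / src$cellsize
  out_layers <- lapply(stack$layers, function(l) {
    v <- if (method == "nearest") {
      r <- pmin(pmax(round(fy) + 1, 1), src$nrow)
      c <- pmin(pmax(round(fx) + 1, 1), src$ncol)
      inb <- px >= src$xmin & px <= grid_xmax(src) &
             py >= src$ymin & py <= grid_ymax(src)
      res <- l[cbind(r, c)]
      res[!inb] <- NA_real_
      res
    } else {
      r0 <- floor(fy); c0 <- floor(fx)
      wy <- fy - r0; wx <- fx - c0
      val <- numeric(length(px)); wsum <- numeric(length(px))
      for (dr in 0:1) for (dc in 0:1) {
        r <- r0 + dr + 1; c <- c0 + dc + 1
        ok <- r >= 1 & r <= src$nrow & c >= 1 & c <= src$ncol
        w <- (if (dr == 0) 1 - wy else wy) * (if (dc == 0) 1 - wx else wx)
        idx <- which(ok & w > 0)
        if (length(idx)) {
          z <- l[cbind(r[idx], c[idx])]
          fin <- !is.na(z)
          val[idx[fin]] <- val[idx[fin]] + w[idx[fin]] * z[fin]
          wsum[idx[fin]] <- wsum[idx[fin]] + w[idx[fin]]
        }
      }
      res <- ifelse(wsum > 0, val / wsum, NA_real_)
      inb <- px >= src$xmin & px <= grid_xmax(src) &
             py >= src$ymin & py <= grid_ymax(src)
      res[!inb] <- NA_real_
      res
    }
    matrix(v, target$nrow, target$ncol)
  })
  raster_stack(target, out_layers)
}
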