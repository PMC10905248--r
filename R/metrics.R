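#' Normalize a suitability map to a probability surface
#'
#' Divides by the sum over the shared validity mask so the surface sums to
#' 1, the precondition of both niche-overlap metrics. Cells outside the mask
#' are excluded.
#'
#' @param map a `suitability_map`.
#' @param shared_mask optional logical matrix restricting the footprint
#'   (typically the intersection of two species' valid cells).
#' @return an object of class `prob_surface` (grid, `p` matrix, mask).
#' @export
normalize_surface <- function(map, shared_mask = NULL) {
  stopifnot(inherits(map, "suitability_map"))
  v <- map$values
  mask <- !is.na(v)
  if (!is.null(shared_mask)) mask <- mask & shared_mask
  v[!mask] <- NA_real_
  tot <- sum(v, na.rm = TRUE)
  if (!any(mask) || tot <= 0)
    stop("suitability is zero or missing everywhere on the mask")
  structure(list(grid = map$grid, p = v / tot, mask = mask),
            class = "prob_surface")
}

check_surface_pair <- function(px, py) {
  stopifnot(inherits(px, "prob_surface"), inherits(py, "prob_surface"))
  if (!grids_equal(px$grid, py$grid))
    stop("probability surfaces are on different grids")
  if (!identical(px$mask, py$mask))
    stop("probability surfaces have different validity masks; ",
         "normalize both over the shared mask first")
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum |pX - pY|` over the shared mask: 0 for disjoint
#' surfaces, 1 for identical ones. The older of the two overlap metrics; it
#' reads the normalized suitability as a species density.
#'
#' @param px,py `prob_surface` objects on one grid and mask.
#' @return overlap in \[0, 1\].
#' @export
schoener_d <- function(px, py) {
  check_surface_pair(px, py)
  1 - 0.5 * sum(abs(px$p - py$p), na.rm = TRUE)
}

#' Warren's I niche overlap
#'
#' `I = 1 - 0.5 * sum (sqrt(pX) - sqrt(pY))^2`, i.e. one minus half the
#' squared Hellinger distance. Carries no density assumption and always
#' satisfies `I >= D`.
#'
#' @param px,py `prob_surface` objects on one grid and mask.
#' @return overlap in \[0, 1\].
#' @export
warren_i <- function(px, py) {
  check_surface_pair(px, py)
  1 - 0.5 * sum((sqrt(px$p) - sqrt(py$p))^2, na.rm = TRUE)
}

#' Geometric intersection of two range polygons
#'
#' Sutherland-Hodgman clipping; at least one operand must be convex (the
#' convex one is used as the clip polygon). Multi-part ranges are
#' intersected part-by-part. An empty intersection is allowed and warned
#' about, not an error.
#'
#' @param a,b `range_area` objects.
#' @param species label for the result (default `"overlap"`).
#' @return a `range_area` for the overlap region, or `NULL` (with a
#'   warning) when the ranges are disjoint.
#' @export
intersect_ranges <- function(a, b, species = "overlap") {
  stopifnot(inherits(a, "range_area"), inherits(b, "range_area"))
  pieces <- list()
  for (ra in a$rings) for (rb in b$rings) {
    clip <- NULL; subj <- NULL
    if (ring_is_convex(rb)) { clip <- rb; subj <- ra }
    else if (ring_is_convex(ra)) { clip <- ra; subj <- rb }
    else stop("intersection of two non-convex rings is not supported; ",
              "split one range into convex parts")
    out <- clip_ring_convex(subj, clip)
    if (nrow(out) >= 3 && abs(ring_area(polygon_ring(out))) > 1e-12)
      pieces[[length(pieces) + 1]] <- out
  }
  if (!length(pieces)) {
    warning("ranges do not overlap; intersection is empty")
    return(NULL)
  }
  range_area(species, pieces, buffer_m = 0)
}

#' Percent change in summed habitat suitability
#'
#' `100 * (H_new - H_ref) / H_ref`, where each H is the sum of suitability
#' values over the relevant masked raster. Negative = habitat loss. For a
#' future scenario the reference is the current map; for a past-to-current
#' comparison the reference is the past map.
#'
#' @param h_new,h_ref summed suitability values; `h_ref` must be positive.
#' @return percent change.
#' @export
habitat_change <- function(h_new, h_ref) {
  if (!is.finite(h_ref) || h_ref <= 0)
    stop("reference suitability sum must be positive; change is undefined")
  100 * (h_new - h_ref) / h_ref
}

#' Combined percent change over the co-occurrence area
#'
#' Pools both species' suitability sums over the intersection of their
#' ranges: `100 * ((HP_new + HO_new) - (HP_ref + HO_ref)) / (HP_ref +
#' HO_ref)`, HP and HO being the two species' summed suitabilities.
#'
#' @param hp_new,ho_new,hp_ref,ho_ref summed suitabilities over the
#'   intersection mask for the two species, new and reference period.
#' @return percent change.
#' @export
combined_change <- function(hp_new, ho_new, hp_ref, ho_ref) {
  ref <- hp_ref + ho_ref
  if (!is.finite(ref) || ref <= 0)
    stop("reference suitability sum must be positive; change is undefined")
  100 * ((hp_new + ho_new) - ref) / ref
}

#' Threshold-free vulnerability assessment
#'
#' For every species and scenario, the percent change in summed habitat
#' suitability relative to current conditions (future scenarios:
#' `100 (Hf - Hc)/Hc`; past scenarios: `100 (Hc - Hp)/Hp`, change from past
#' to current), plus the combined change over the geographic intersection of
#' the two ranges. No suitability threshold is applied anywhere. All H
#' values are retained for audit.
#'
#' @param current named list (per species) of current `suitability_map`.
#' @param scenarios named list (per scenario label) of named lists (per
#'   species) of ensemble-averaged `suitability_map`.
#' @param ranges named list (per species) of `range_area`; required for the
#'   combined row (omit to skip it).
#' @param scenario_kind named character, `"future"` or `"past"` per
#'   scenario label (default: all future).
#' @return an object of class `vulnerability_report`: `table` (rows =
#'   species + `"Overlap area"`, columns = scenarios, percent values),
#'   `h_values` (audit data.frame), `intersection` (the overlap
#'   `range_area` or NULL).
#' @export
vulnerability_report <- function(current, scenarios, ranges = NULL,
                                 scenario_kind = NULL) {
  species <- names(current)
  stopifnot(length(species) >= 1)
  scen_labels <- names(scenarios)
  if (is.null(scenario_kind))
    scenario_kind <- stats::setNames(rep("future", length(scen_labels)),
                                     scen_labels)
  g <- current[[1]]$grid
  sc <- current[[1]]$scale
  for (sp in species) {
    if (!grids_equal(g, current[[sp]]$grid)) stop("current maps grid mismatch")
    if (!identical(sc, current[[sp]]$scale))
      stop("suitability scale mismatch across current maps")
  }
  for (lab in scen_labels) for (sp in species) {
    m <- scenarios[[lab]][[sp]]
    if (!grids_equal(g, m$grid))
      stop("scenario '", lab, "' map grid mismatch for ", sp)
    if (!identical(sc, m$scale))
      stop("suitability scale mismatch in scenario '", lab, "'")
  }
  inter <- NULL
  inter_mask <- NULL
  if (!is.null(ranges) && length(species) == 2) {
    inter <- intersect_ranges(ranges[[species[1]]], ranges[[species[2]]])
    if (!is.null(inter)) {
      cc <- cell_centers(g)
      inter_mask <- matrix(points_in_polygon(as.vector(cc$x),
                                             as.vector(cc$y), inter$rings),
                           g$nrow, g$ncol)
    }
  }
  h_rows <- list()
  tab <- matrix(NA_real_, length(species) + as.integer(!is.null(inter_mask)),
                length(scen_labels),
                dimnames = list(c(species,
                                  if (!is.null(inter_mask)) "Overlap area"),
                                scen_labels))
  h_cur <- vapply(species, function(sp) suitability_sum(current[[sp]]),
                  numeric(1))
  for (lab in scen_labels) {
    past <- identical(scenario_kind[[lab]], "past")
    for (sp in species) {
      h_scen <- suitability_sum(scenarios[[lab]][[sp]])
      tab[sp, lab] <- if (past) habitat_change(h_cur[[sp]], h_scen)
                      else habitat_change(h_scen, h_cur[[sp]])
      h_rows[[length(h_rows) + 1]] <- data.frame(
        scenario = lab, species = sp, area = "range",
        H_current = h_cur[[sp]], H_scenario = h_scen)
    }
    if (!is.null(inter_mask)) {
      hc <- vapply(species, function(sp)
        suitability_sum(current[[sp]], inter_mask), numeric(1))
      hs <- vapply(species, function(sp)
        suitability_sum(scenarios[[lab]][[sp]], inter_mask), numeric(1))
      tab["Overlap area", lab] <- if (past)
        combined_change(hc[1], hc[2], hs[1], hs[2])
      else combined_change(hs[1], hs[2], hc[1], hc[2])
      h_rows[[length(h_rows) + 1]] <- data.frame(
        scenario = lab, species = paste(species, collapse = "+"),
        area = "overlap", H_current = sum(hc), H_scenario = sum(hs))
    }
  }
  structure(list(table = tab,
                 h_values = do.call(rbind, h_rows),
                 intersection = inter,
                 scenario_kind = scenario_kind,
                 scale = sc),
            class = "vulnerability_report")
}

#' @export
print.vulnerability_report <- function(x, digits = 2, ...) {
  cat("Vulnerability assessment (percent change in summed suitability,",
      "negative = loss)\n")
  print(round(x$table, digits))
  invisible(x)
}

#' Write a vulnerability report as CSV and JSON
#'
#' @param report a `vulnerability_report`.
#' @param stem output path stem; writes `<stem>.csv` and `<stem>.json`.
#' @export
write_vulnerability_report <- function(report, stem) {
  df <- data.frame(area = rownames(report$table),
                   round(report$table, 2), check.names = FALSE)
  utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(percent_change = apply(report$table, 1, as.list),
         h_values = report$h_values,
         scale = report$scale),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
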