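#' Bundle per-GCM climate stacks with shared static layers
#'
#' A scenario (one RCP or paleoclimate period) carries one climate stack per
#' global circulation model plus the static layers (terrain and soil) held
#' constant across time periods.
#'
#' @param label scenario label (e.g. `"RCP8.5"`, `"LGM"`).
#' @param gcm_stacks named list of `raster_stack`, one per GCM (>= 1).
#' @param static_layers optional `raster_stack` of time-invariant layers on
#'   the same grid.
#' @param kind `"future"` or `"past"`; decides which direction the
#'   vulnerability percent change is reported in.
#' @return an object of class `scenario_set`.
#' @export
scenario_set <- function(label, gcm_stacks, static_layers = NULL,
                         kind = c("future", "past")) {
  kind <- match.arg(kind)
  stopifnot(is.list(gcm_stacks), length(gcm_stacks) >= 1,
            !is.null(names(gcm_stacks)))
  g <- gcm_stacks[[1]]$grid
  for (s in gcm_stacks)
    if (!grids_equal(g, s$grid)) stop("GCM stacks are not on one grid")
  if (!is.null(static_layers) && !grids_equal(g, static_layers$grid))
    stop("static layers are not on the GCM grid")
  structure(list(label = label, gcm_stacks = gcm_stacks,
                 static_layers = static_layers, kind = kind),
            class = "scenario_set")
}

#' Project a fitted model onto a scenario
#'
#' For each GCM, merges its climate layers with the scenario's static layers
#' and predicts a suitability map. Errors name the GCM and the missing layer
#' when a model variable is not covered.
#'
#' @param model a fitted `maxent_model`.
#' @param scenario a `scenario_set`.
#' @param clamp truncate variables to the training range (default `TRUE`)?
#' @param scale output scale, `"cloglog"` (default) or `"raw"`.
#' @return named list of `suitability_map`, one per GCM.
#' @export
project_scenario <- function(model, scenario, clamp = TRUE,
                             scale = c("cloglog", "raw")) {
  scale <- match.arg(scale)
  stopifnot(inherits(scenario, "scenario_set"))
  lapply(stats::setNames(names(scenario$gcm_stacks),
                         names(scenario$gcm_stacks)), function(gcm) {
    stack <- scenario$gcm_stacks[[gcm]]
    if (!is.null(scenario$static_layers))
      stack <- merge_stacks(stack, scenario$static_layers)
    missing <- setdiff(model$features$variables, names(stack$layers))
    if (length(missing))
      stop("scenario '", scenario$label, "', GCM '", gcm,
           "': missing layer(s) ", paste(missing, collapse = ", "))
    predict_map(model, stack, clamp = clamp, scale = scale)
  })
}

#' Ensemble-average suitability maps across GCMs
#'
#' Cell-wise arithmetic mean; a cell is nodata iff it is nodata in any input
#' (strict intersection), so scenario sums are never computed over unequal
#' footprints.
#'
#' @param maps named list of `suitability_map` on one grid and one scale.
#' @return a `suitability_map`.
#' @export
average_gcms <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 1)
  g <- maps[[1]]$grid
  sc <- maps[[1]]$scale
  for (m in maps) {
    if (!grids_equal(g, m$grid)) stop("maps are not on one grid")
    if (!identical(sc, m$scale))
      stop("maps mix scales (", sc, " vs ", m$scale, ")")
  }
  acc <- maps[[1]]$values
  for (m in maps[-1]) acc <- acc + m$values   # NA in any input -> NA
  suitability_map(g, acc / length(maps), scale = sc)
}
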