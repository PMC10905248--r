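#' Build a pipeline run configuration
#'
#' A declarative description of a full two-species analysis on synthetic
#' data: generator settings, occurrence handling, predictor filtering,
#' estimator settings, climate scenarios, and output scales. Every default
#' mirrors the analysis design this package implements: a 5-km thinning
#' grid, 10,000-style target-group-weighted background (scaled to the
#' configured size), a Pearson |r| >= 0.8 predictor filter, an rm grid of
#' 0.5 to 3 in steps of 0.5 scored by AICc, 5-fold cross-validation with
#' replicate-averaged projections, three-GCM ensemble means per scenario,
#' cloglog suitability sums for the vulnerability assessment and raw-scale
#' normalization for the overlap metrics.
#'
#' @param seed master seed; every stochastic stage derives its own sub-seed
#'   from it.
#' @param out_dir run directory for all outputs.
#' @param grid list(nrow, ncol, xmin, ymin, cellsize) for the model grid.
#' @param n_layers,pairwise_corr,kernel_cells synthetic layer settings (see
#'   [make_env_stack()]).
#' @param species named list of two species specs: each
#'   `list(coefficients =, quad_coefficients =, n_presence =, xfrac =,
#'   yfrac =, buffer_m =)`.
#' @param bias_strength sampling-effort gradient strength.
#' @param n_target synthetic target-group records used to build the bias
#'   surface.
#' @param n_background pseudo-absences per species.
#' @param thin_cell_km thinning grid size (km).
#' @param corr_threshold,priority predictor-filter settings.
#' @param classes,n_hinge_knots feature settings.
#' @param rm_grid candidate regularization multipliers (AICc-scored);
#'   set a single value to skip selection.
#' @param k_folds cross-validation folds.
#' @param scenarios list of scenario specs: each `list(label =, kind =
#'   "future"|"past", layers = list(name = list(shift =, factor =)),
#'   gcm_spread = named numeric)`; each GCM's delta is the spec's shifts
#'   scaled by its spread factor.
#' @param map_scale suitability scale for maps and H sums (`"cloglog"`).
#' @param overlap_scale scale normalized for D and I (`"raw"`).
#' @param jackknife run the jackknife importance refits (default `FALSE`;
#'   percent contribution is always reported)?
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       out_dir = tempfile("nicheshift_run_"),
                       grid = list(nrow = 30, ncol = 30, xmin = -105,
                                   ymin = 35, cellsize = 0.05),
                       n_layers = 6, pairwise_corr = 0.9, kernel_cells = 2,
                       species = default_species_pair(),
                       bias_strength = 1, n_target = 4000,
                       n_background = 2000, thin_cell_km = 5,
                       corr_threshold = 0.8, priority = NULL,
                       classes = c("linear", "quadratic", "hinge"),
                       n_hinge_knots = 8,
                       rm_grid = seq(0.5, 3, by = 0.5), k_folds = 5,
                       scenarios = default_scenarios(),
                       map_scale = "cloglog", overlap_scale = "raw",
                       jackknife = FALSE) {
  cfg <- as.list(environment())
  if (length(cfg$species) != 2 || is.null(names(cfg$species)))
    stop("config needs exactly two named species")
  structure(cfg, class = "run_config")
}

#' Default synthetic species pair
#'
#' Species A is the ectotherm-analogue: its thermal optimum on the
#' temperature-like layer `env01` sits at the current mean climate (a pure
#' negative quadratic), so any warming shift pushes habitat off the optimum
#' and costs it suitability; a secondary positive response to `env05` gives
#' the niche some breadth. Species B is the endotherm-analogue: driven
#' mainly by `env03` with a weak positive linear response to `env01`, so
#' warming leaves it flat-to-gaining — the predator-loss / prey-gain
#' contrast the vulnerability assessment is built to expose.
#'
#' @export
default_species_pair <- function() {
  list(
    species_A = list(coefficients = c(env05 = 0.6),
                     quad_coefficients = c(env01 = -1.2),
                     n_presence = 600,
                     xfrac = c(0, 0.75), yfrac = c(0, 1), buffer_m = 1500),
    species_B = list(coefficients = c(env03 = 1.5, env01 = 0.7),
                     quad_coefficients = c(env03 = -0.5),
                     n_presence = 500,
                     xfrac = c(0.25, 1), yfrac = c(0, 1), buffer_m = 36))
}

#' Default scenario suite
#'
#' Three warming scenarios of increasing strength (shifts on the
#' temperature-like layer, three pseudo-GCMs spreading each shift by +-10%)
#' and two cooler past periods, one strongly colder (glacial-like) and one
#' slightly colder (mid-Holocene-like). The latitudinal gradient layer is
#' never perturbed: it is the static terrain stand-in.
#'
#' @export
default_scenarios <- function() {
  spread <- c(gcm1 = 0.9, gcm2 = 1.0, gcm3 = 1.1)
  list(
    list(label = "warm_low", kind = "future",
         layers = list(env01 = list(shift = 0.5)), gcm_spread = spread),
    list(label = "warm_mid", kind = "future",
         layers = list(env01 = list(shift = 1.0)), gcm_spread = spread),
    list(label = "warm_high", kind = "future",
         layers = list(env01 = list(shift = 1.5)), gcm_spread = spread),
    list(label = "glacial", kind = "past",
         layers = list(env01 = list(shift = -2.5)), gcm_spread = spread),
    list(label = "mid_holocene", kind = "past",
         layers = list(env01 = list(shift = -0.3)), gcm_spread = spread))
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  h <- fnv1a(as.character(
    jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)))
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

scenario_deltas_for_gcm <- function(scen, spread_factor) {
  scenario_delta(lapply(scen$layers, function(d) {
    list(shift = (d$shift %||% 0) * spread_factor,
         factor = 1 + ((d$factor %||% 1) - 1) * spread_factor)
  }), label = scen$label)
}

# replicate-averaged prediction: cell-wise mean over the k fold models
predict_replicates <- function(models, stack, scale) {
  average_gcms(lapply(models, predict_map, stack = stack, clamp = TRUE,
                      scale = scale))
}

#' Run the full analysis pipeline
#'
#' generate -> clean -> thin -> bias -> background -> filter layers ->
#' select rm -> fit + cross-validate -> project scenarios -> GCM-average ->
#' niche overlap -> vulnerability report. Both species go through identical
#' settings. All outputs (occurrence tables, bias surface, maps, AUC and
#' importance tables, the report, a JSON manifest with seeds and a config
#' hash) are written under `config$out_dir`; re-running with the same master
#' seed reproduces every output bit-identically.
#'
#' @param config a `run_config`.
#' @param quiet suppress progress messages?
#' @return (invisibly) a list with the fitted models, maps, overlap metrics
#'   and the `vulnerability_report`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[nicheshift] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  gspec <- config$grid
  grid <- raster_grid(gspec$nrow, gspec$ncol, gspec$xmin, gspec$ymin,
                      gspec$cellsize)
  seeds <- list()
  sub <- function(stage) { s <- derive_seed(config$seed, stage); seeds[[stage]] <<- s; s }

  say("generating environmental layers")
  stack <- make_env_stack(grid, config$n_layers, config$pairwise_corr,
                          seed = sub("env_stack"),
                          kernel_cells = config$kernel_cells)
  write_stack(stack, file.path(config$out_dir, "layers"))

  say("filtering correlated predictors")
  filtered <- select_uncorrelated(stack, threshold = config$corr_threshold,
                                  priority = config$priority)
  kept <- names(filtered$layers)

  say("building sampling-effort bias surface")
  effort <- make_effort_surface(grid, config$bias_strength,
                                seed = sub("effort"))
  target_group <- sample_background(effort, n = config$n_target,
                                    seed = sub("target_group"),
                                    species = "target_group")
  bias <- build_bias_surface(target_group, grid, smooth_cells = 1)
  write_ascii_grid(bias$weights, grid, file.path(config$out_dir, "bias.asc"))

  species <- names(config$species)
  ranges <- list(); models <- list(); cv <- list(); rm_sel <- list()
  current_maps <- list(); current_raw <- list(); masked_stacks <- list()
  occ_all <- list()
  for (sp in species) {
    spec <- config$species[[sp]]
    say("species ", sp, ": occurrences")
    ranges[[sp]] <- make_range_polygon(grid, spec$xfrac, spec$yfrac,
                                       species = sp,
                                       buffer_m = spec$buffer_m)
    sp_stack <- buffer_and_mask(subset_stack(stack, kept), ranges[[sp]])
    masked_stacks[[sp]] <- sp_stack
    truth <- truth_spec(names(stack$layers),
                        coefficients = spec$coefficients,
                        quad_coefficients = spec$quad_coefficients %||% numeric(0),
                        bias_strength = config$bias_strength,
                        seed = sub(paste0("sample_", sp)))
    sp_bias <- bias
    sp_bias$weights[!stack_mask(sp_stack)] <- 0
    ts <- make_truth_and_sample(sp_stack, truth, spec$n_presence,
                                bias = sp_bias, species = sp)
    raw_occ <- ts$occurrences
    cleaned <- clean_records(raw_occ)
    thinned <- thin_by_grid(cleaned, grid = grid,
                            cell_km = config$thin_cell_km,
                            seed = sub(paste0("thin_", sp)))
    occ_all[[sp]] <- thinned
    write_occurrences(raw_occ,
                      file.path(config$out_dir, paste0("occ_raw_", sp, ".csv")))
    write_occurrences(thinned,
                      file.path(config$out_dir, paste0("occ_thinned_", sp, ".csv")))

    say("species ", sp, ": background")
    bg <- sample_background(sp_bias, n = config$n_background,
                            seed = sub(paste0("background_", sp)))
    presence_env <- extract_values(sp_stack, thinned$decimalLongitude,
                                   thinned$decimalLatitude)
    background_env <- extract_values(sp_stack, bg$decimalLongitude,
                                     bg$decimalLatitude)

    say("species ", sp, ": regularization selection")
    if (length(config$rm_grid) > 1) {
      sel <- select_rm(presence_env, background_env,
                       rm_grid = config$rm_grid, classes = config$classes,
                       n_hinge_knots = config$n_hinge_knots)
      rm_sel[[sp]] <- sel
      best_rm <- sel$best_rm
      models[[sp]] <- sel$best_model
    } else {
      best_rm <- config$rm_grid
      models[[sp]] <- train_maxent(presence_env, background_env,
                                   rm = best_rm, classes = config$classes,
                                   n_hinge_knots = config$n_hinge_knots)
    }

    say("species ", sp, ": cross-validation at rm = ", best_rm)
    cv[[sp]] <- cross_validate(presence_env, background_env,
                               k = config$k_folds, rm = best_rm,
                               seed = sub(paste0("cv_", sp)),
                               classes = config$classes,
                               n_hinge_knots = config$n_hinge_knots)
    imp <- variable_importance(
      models[[sp]],
      if (config$jackknife) presence_env else NULL,
      if (config$jackknife) background_env else NULL)
    utils::write.csv(imp$contribution,
                     file.path(config$out_dir,
                               paste0("contribution_", sp, ".csv")),
                     row.names = FALSE)
    if (!is.null(imp$jackknife))
      utils::write.csv(imp$jackknife,
                       file.path(config$out_dir,
                                 paste0("jackknife_", sp, ".csv")),
                       row.names = FALSE)
    models[[sp]]$importance <- imp

    current_maps[[sp]] <- predict_replicates(cv[[sp]]$models, sp_stack,
                                             config$map_scale)
    current_raw[[sp]] <- predict_replicates(cv[[sp]]$models, sp_stack,
                                            config$overlap_scale)
    write_ascii_grid(current_maps[[sp]]$values, grid,
                     file.path(config$out_dir,
                               paste0("current_", sp, ".asc")))
  }

  say("projecting scenarios")
  scenario_maps <- list()
  scenario_kind <- character(0)
  for (scen in config$scenarios) {
    lab <- scen$label
    scenario_kind[lab] <- scen$kind %||% "future"
    per_species <- list()
    for (sp in species) {
      gcm_stacks <- lapply(scen$gcm_spread, function(f)
        make_scenario(masked_stacks[[sp]], scenario_deltas_for_gcm(scen, f)))
      names(gcm_stacks) <- names(scen$gcm_spread)
      sset <- scenario_set(lab, gcm_stacks, kind = scenario_kind[lab])
      per_gcm <- lapply(gcm_stacks, function(stk)
        predict_replicates(cv[[sp]]$models, stk, config$map_scale))
      avg <- average_gcms(per_gcm)
      per_species[[sp]] <- avg
      write_ascii_grid(avg$values, grid,
                       file.path(config$out_dir,
                                 paste0("scenario_", lab, "_", sp, ".asc")))
      diffm <- avg$values - current_maps[[sp]]$values
      write_ascii_grid(diffm, grid,
                       file.path(config$out_dir,
                                 paste0("diff_", lab, "_", sp, ".asc")))
    }
    scenario_maps[[lab]] <- per_species
  }

  say("niche overlap")
  shared <- !is.na(current_raw[[species[1]]]$values) &
            !is.na(current_raw[[species[2]]]$values)
  p1 <- normalize_surface(current_raw[[species[1]]], shared)
  p2 <- normalize_surface(current_raw[[species[2]]], shared)
  overlap <- list(schoener_d = schoener_d(p1, p2),
                  warren_i = warren_i(p1, p2))

  say("vulnerability assessment")
  report <- vulnerability_report(current_maps, scenario_maps, ranges,
                                 scenario_kind = scenario_kind)
  write_vulnerability_report(report, file.path(config$out_dir, "report"))
  write_ranges_geojson(c(ranges,
                         if (!is.null(report$intersection))
                           list(report$intersection)),
                       file.path(config$out_dir, "ranges.geojson"))

  auc_tab <- do.call(rbind, lapply(species, function(sp)
    data.frame(species = sp, fold = seq_along(cv[[sp]]$auc),
               auc = cv[[sp]]$auc)))
  utils::write.csv(auc_tab, file.path(config$out_dir, "auc.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "nicheshift",
    version = as.character(utils::packageVersion("nicheshift")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    master_seed = config$seed,
    config_hash = config_hash(config),
    stage_seeds = seeds,
    species = species,
    kept_layers = kept,
    selected_rm = lapply(rm_sel, function(s) s$best_rm),
    mean_auc = lapply(cv, function(x) x$mean_auc),
    overlap = overlap,
    scenarios = names(scenario_maps))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(config = config, stack = stack, filtered_layers = kept,
                 ranges = ranges, occurrences = occ_all, models = models,
                 rm_selection = rm_sel, cv = cv,
                 current_maps = current_maps, scenario_maps = scenario_maps,
                 overlap = overlap, report = report,
                 out_dir = config$out_dir))
}

#' Render a run directory into a plain-text summary
#'
#' Reads the machine outputs of a completed [run_pipeline()] run and writes
#' `summary.txt`: cross-validated AUCs, overlap metrics, and the
#' vulnerability table (one row per species plus the overlap area). Runs
#' without scenarios get current-only diagnostics.
#'
#' @param run_dir a completed run directory.
#' @return (invisibly) the summary lines.
#' @export
render_report <- function(run_dir) {
  man_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(man_path))
    stop("no manifest.json in ", run_dir, "; run is incomplete")
  man <- jsonlite::read_json(man_path)
  lines <- c(
    sprintf("nicheshift run %s (seed %s, config %s)",
            basename(run_dir), man$master_seed, man$config_hash),
    sprintf("layers kept after |r| filter: %s",
            paste(unlist(man$kept_layers), collapse = ", ")),
    "")
  for (sp in names(man$mean_auc))
    lines <- c(lines, sprintf("  %s: mean cross-validated AUC = %.3f%s",
                              sp, man$mean_auc[[sp]],
                              if (length(man$selected_rm[[sp]]))
                                sprintf(" (rm = %g)", man$selected_rm[[sp]])
                              else ""))
  lines <- c(lines, "",
             sprintf("  niche overlap: Schoener's D = %.3f, Warren's I = %.3f",
                     man$overlap$schoener_d, man$overlap$warren_i), "")
  rep_path <- file.path(run_dir, "report.json")
  if (file.exists(rep_path) && length(man$scenarios)) {
    rep <- jsonlite::read_json(rep_path)
    lines <- c(lines,
               "  vulnerability (percent change in summed suitability):")
    for (area in names(rep$percent_change)) {
      vals <- rep$percent_change[[area]]
      lines <- c(lines, sprintf("    %-14s %s", area,
                                paste(sprintf("%s=%+.2f%%", names(vals),
                                              unlist(vals)),
                                      collapse = "  ")))
    }
  } else {
    lines <- c(lines, "  (no scenarios: current-only diagnostics)")
  }
  writeLines(lines, file.path(run_dir, "summary.txt"))
  invisible(lines)
}
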