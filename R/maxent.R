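# Native maximum-entropy estimator: an L1-regularized log-linear (Gibbs)
# density over background cells whose feature expectations match the
# presence sample. The penalized objective
#
#   J(lambda) = -sum_j fbar_j lambda_j + log Z(lambda) + sum_j b_j |lambda_j|
#
# (fbar = presence feature means, Z = sum over background of exp(eta)) is
# minimized by cyclic coordinate descent: per-coordinate Newton steps with
# soft-thresholding for the L1 term and a halving line search that makes the
# objective provably non-increasing. lambda starts at 0 and there is no
# random initialization, so fits are deterministic.

soft_threshold <- function(a, b) sign(a) * pmax(abs(a) - b, 0)

#' Fit a maximum-entropy suitability model
#'
#' @param fp presence feature matrix (rows = presences), as produced by
#'   [build_features()] / [apply_features()].
#' @param fb background feature matrix with identical columns.
#' @param rm regularization multiplier (>= 0); scales every per-feature
#'   penalty. `rm = 0` disables the penalty entirely (accepted, with an
#'   overfitting warning).
#' @param features optional `feature_set`; stored on the model so
#'   [predict_map()] and [response_curve()] can re-expand raw variables.
#' @param beta optional per-feature penalty weights; by default class-level
#'   constants (interpolated by presence sample size) times the feature's
#'   presence standard deviation over sqrt(n_presence).
#' @param tol convergence tolerance on the max KKT violation (default 1e-6).
#' @param max_iter maximum coordinate-descent sweeps (default 10000).
#' @param lambda_init optional coefficient vector to warm-start from (used
#'   by [maxent_rm_path()]); defaults to all zeros.
#' @return an object of class `maxent_model`: coefficients `lambda`, the
#'   normalizer `log_z` over training background (raw outputs sum to 1 by
#'   construction), the cloglog offset, per-variable gain trace, and
#'   training metadata.
#' @export
fit_maxent <- function(fp, fb, rm = 1, features = NULL, beta = NULL,
                       tol = 1e-6, max_iter = 10000, lambda_init = NULL) {
  fp <- as.matrix(fp); fb <- as.matrix(fb)
  if (!all(is.finite(fp)) || !all(is.finite(fb)))
    stop("non-finite feature values")
  if (rm < 0) stop("regularization multiplier must be >= 0")
  if (rm == 0)
    warning("rm = 0: unpenalized fit, overfitting risk on small samples")
  m <- nrow(fp); n <- nrow(fb)
  if (m < 1 || n < 2) stop("need >= 1 presence and >= 2 background rows")
  p <- ncol(fp)
  if (ncol(fb) != p) stop("presence/background feature matrices differ")
  fbar <- colMeans(fp)
  if (is.null(beta)) {
    kinds <- if (!is.null(features)) features$defs$kind else rep("linear", p)
    cls <- vapply(kinds, beta_class_default, numeric(1), m = m)
    s <- apply(fp, 2, stats::sd)
    s0 <- apply(fb, 2, stats::sd)
    s[!is.finite(s) | s == 0] <- s0[!is.finite(s) | s == 0]
    s[!is.finite(s) | s == 0] <- 1e-6
    beta <- cls * s / sqrt(m)
  }
  b <- rm * beta
  lambda <- if (is.null(lambda_init)) numeric(p) else as.numeric(lambda_init)
  stopifnot(length(lambda) == p)
  eta <- as.vector(fb %*% lambda)
  cshift <- max(eta)
  w <- exp(eta - cshift)
  logZ <- cshift + log(sum(w))
  obj <- -sum(fbar * lambda) + logZ + sum(b * abs(lambda))
  srcs <- if (!is.null(features)) feature_sources(features$defs)
          else as.list(rep(NA_character_, p))
  gain_by_var <- structure(numeric(0), names = character(0))
  converged <- FALSE
  iters <- 0L
  trace_obj <- numeric(0)
  for (sweep in seq_len(max_iter)) {
    iters <- sweep
    for (j in seq_len(p)) {
      fj <- fb[, j]
      Z <- sum(w)
      Ef <- sum(w * fj) / Z
      Ef2 <- sum(w * fj * fj) / Z
      g <- Ef - fbar[j]
      h <- max(Ef2 - Ef * Ef, 1e-12)
      lam_new <- soft_threshold(lambda[j] * h - g, b[j]) / h
      d <- lam_new - lambda[j]
      if (abs(d) < 1e-13) next
      # halving line search on the true penalized objective
      accepted <- FALSE
      for (half in 1:40) {
        w_try <- w * exp(d * fj)
        logZ_try <- cshift + log(sum(w_try))
        lam_try <- lambda[j] + d
        obj_try <- obj - logZ + logZ_try -
          fbar[j] * d + b[j] * (abs(lam_try) - abs(lambda[j]))
        if (is.finite(obj_try) && obj_try <= obj + 1e-12) {
          improvement <- obj - obj_try
          lambda[j] <- lam_try
          eta <- eta + d * fj
          w <- w_try
          logZ <- logZ_try
          obj <- obj_try
          for (v in srcs[[j]]) {
            if (is.na(v)) next
            cur <- gain_by_var[v]
            gain_by_var[v] <- (if (is.na(cur)) 0 else cur) +
              improvement / length(srcs[[j]])
          }
          accepted <- TRUE
          break
        }
        d <- d / 2
      }
      if (!accepted) next
    }
    # refresh weights against drift, then check KKT optimality
    cshift <- max(eta)
    w <- exp(eta - cshift)
    logZ <- cshift + log(sum(w))
    obj <- -sum(fbar * lambda) + logZ + sum(b * abs(lambda))
    trace_obj <- c(trace_obj, obj)
    Ef_all <- as.vector(crossprod(fb, w)) / sum(w)
    g_all <- Ef_all - fbar
    viol <- ifelse(lambda == 0, pmax(0, abs(g_all) - b),
                   abs(g_all + b * sign(lambda)))
    if (max(viol) < tol) { converged <- TRUE; break }
  }
  raw <- w / sum(w)
  entropy <- -sum(raw * log(pmax(raw, 1e-300)))
  model <- structure(list(
    lambda = stats::setNames(lambda, colnames(fp)),
    features = features,
    beta = beta, rm = rm,
    n_presence = m, n_background = n,
    log_z = logZ,
    entropy = entropy,
    cloglog_offset = logZ - entropy,
    gain_trace = gain_by_var,
    objective_trace = trace_obj,
    converged = converged, iterations = iters,
    fbar = fbar), class = "maxent_model")
  model
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(paste0("<maxent_model> %d feature(s), %d nonzero, rm = %g, ",
                     "%d presences / %d background, gain %.4f%s\n"),
              length(x$lambda), sum(x$lambda != 0), x$rm,
              x$n_presence, x$n_background, model_gain(x),
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Training gain of a fitted model
#'
#' Mean presence log-raw-output minus the log of the uniform background
#' density: 0 for the null model, larger when presences concentrate where
#' the model predicts.
#'
#' @param model a `maxent_model`.
#' @export
model_gain <- function(model) {
  sum(model$fbar * model$lambda) - model$log_z + log(model$n_background)
}

# linear predictor for a feature matrix
model_eta <- function(model, fmat) as.vector(fmat %*% model$lambda)

#' Fit a warm-started regularization path
#'
#' Fits one model per candidate regularization multiplier, sweeping from the
#' strongest penalty to the weakest and warm-starting every fit at the
#' previous solution. Warm-started path fitting is the standard way to sweep
#' an L1 penalty: it is faster than independent fits and keeps the active
#' sets nested, so the number of nonzero coefficients is non-increasing in
#' the multiplier.
#'
#' @inheritParams train_maxent
#' @param rm_grid candidate regularization multipliers.
#' @param ... passed to [fit_maxent()].
#' @return named list of `maxent_model`, in the order of `rm_grid`.
#' @export
maxent_rm_path <- function(presence_env, background_env, rm_grid,
                           classes = c("linear", "quadratic", "hinge"),
                           n_hinge_knots = 20, ...) {
  presence_env <- as.data.frame(presence_env)
  background_env <- as.data.frame(background_env)
  pooled <- rbind(presence_env, background_env)
  ftr <- build_features(pooled, classes = classes,
                        n_hinge_knots = n_hinge_knots)
  np <- nrow(presence_env)
  fp <- ftr$matrix[seq_len(np), , drop = FALSE]
  fb <- ftr$matrix[-seq_len(np), , drop = FALSE]
  ord <- order(rm_grid, decreasing = TRUE)
  models <- vector("list", length(rm_grid))
  lam <- NULL
  for (i in ord) {
    m <- fit_maxent(fp, fb, rm = rm_grid[i], features = ftr$features,
                    lambda_init = lam, ...)
    m$classes <- classes
    m$n_hinge_knots <- n_hinge_knots
    m$background_means <- colMeans(background_env[ftr$features$variables])
    models[[i]] <- m
    lam <- m$lambda
  }
  names(models) <- paste0("rm_", rm_grid)
  models
}

#' Train a model from raw environmental values
#'
#' Convenience wrapper: builds the feature basis on the pooled training rows
#' (presences + background), fits via [fit_maxent()], and records what is
#' needed for prediction and diagnostics (training variable bounds,
#' background variable means, feature classes).
#'
#' @param presence_env data.frame of environmental values at presence points.
#' @param background_env data.frame at background points (same columns).
#' @param rm regularization multiplier.
#' @param classes feature classes (default linear + quadratic + hinge).
#' @param n_hinge_knots hinge knots per variable.
#' @param ... passed to [fit_maxent()].
#' @return a fitted `maxent_model` carrying its `feature_set`.
#' @export
train_maxent <- function(presence_env, background_env, rm = 1,
                         classes = c("linear", "quadratic", "hinge"),
                         n_hinge_knots = 20, ...) {
  presence_env <- as.data.frame(presence_env)
  background_env <- as.data.frame(background_env)
  stopifnot(identical(names(presence_env), names(background_env)))
  pooled <- rbind(presence_env, background_env)
  ftr <- build_features(pooled, classes = classes,
                        n_hinge_knots = n_hinge_knots)
  np <- nrow(presence_env)
  fp <- ftr$matrix[seq_len(np), , drop = FALSE]
  fb <- ftr$matrix[-seq_len(np), , drop = FALSE]
  model <- fit_maxent(fp, fb, rm = rm, features = ftr$features, ...)
  model$classes <- classes
  model$n_hinge_knots <- n_hinge_knots
  model$background_means <- colMeans(background_env[ftr$features$variables])
  model
}

#' Extract layer values at point locations
#'
#' @param stack a `raster_stack`.
#' @param lon,lat point coordinates.
#' @param na_omit drop points falling on nodata or outside the grid
#'   (default `TRUE`).
#' @return data.frame with one column per layer (attribute `"kept"` gives
#'   the surviving row indices when `na_omit`).
#' @export
extract_values <- function(stack, lon, lat, na_omit = TRUE) {
  idx <- cell_index(stack$grid, lon, lat)
  out <- as.data.frame(lapply(stack$layers, function(l) {
    v <- rep(NA_real_, length(lon))
    ok <- !is.na(idx$row)
    v[ok] <- l[cbind(idx$row[ok], idx$col[ok])]
    v
  }))
  if (na_omit) {
    keep <- stats::complete.cases(out)
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "kept") <- which(keep)
  }
  out
}

#' Predict a suitability map from a fitted model
#'
#' Evaluates the model over every valid cell of `stack`. On the `raw` scale
#' the output is exp(eta)/Z normalized over the prediction extent's valid
#' cells (sums to 1); on the `cloglog` scale it is
#' `1 - exp(-exp(eta - r))` with the entropy-based offset `r` fixed at
#' training, giving a bounded relative-suitability display in \[0, 1\].
#'
#' @param model a `maxent_model` trained via [train_maxent()] (it must carry
#'   a `feature_set`).
#' @param stack a `raster_stack` providing every model variable.
#' @param clamp truncate variables to their training range first (default
#'   `TRUE`)?
#' @param scale `"cloglog"` (default) or `"raw"`.
#' @return a `suitability_map` on the stack's grid.
#' @export
predict_map <- function(model, stack, clamp = TRUE,
                        scale = c("cloglog", "raw")) {
  scale <- match.arg(scale)
  stopifnot(inherits(model, "maxent_model"))
  if (is.null(model$features))
    stop("model has no feature set; train via train_maxent()")
  missing <- setdiff(model$features$variables, names(stack$layers))
  if (length(missing))
    stop("stack is missing model variable(s): ",
         paste(missing, collapse = ", "))
  stack <- harmonize_mask(subset_stack(stack, model$features$variables))
  mask <- stack_mask(stack)
  vals <- as.data.frame(lapply(stack$layers, function(l) l[mask]))
  fmat <- apply_features(model$features, vals, clamp = clamp)
  eta <- model_eta(model, fmat)
  out <- matrix(NA_real_, stack$grid$nrow, stack$grid$ncol)
  if (scale == "raw") {
    e <- exp(eta - max(eta))
    out[mask] <- e / sum(e)
  } else {
    out[mask] <- 1 - exp(-exp(eta - model$cloglog_offset))
  }
  suitability_map(stack$grid, out, scale = scale)
}

# linear predictor at raw-variable rows (used by evaluation / curves)
predict_eta <- function(model, data, clamp = TRUE) {
  fmat <- apply_features(model$features, data, clamp = clamp)
  model_eta(model, fmat)
}
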