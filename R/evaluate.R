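#' Presence-background AUC (Mann-Whitney form)
#'
#' Rank discrimination between presence and background scores: the
#' probability that a random presence outscores a random background point,
#' ties counted one half. Invariant under any strictly monotone transform of
#' the scores, so raw and cloglog outputs give identical AUC.
#'
#' @param presence_scores,background_scores numeric score vectors (nonempty).
#' @return AUC in \[0, 1\].
#' @export
evaluate_auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np == 0 || nb == 0) stop("both score sets must be nonempty")
  if (anyNA(presence_scores) || anyNA(background_scores))
    stop("scores must not contain NA")
  r <- rank(c(presence_scores, background_scores))
  u <- sum(r[seq_len(np)]) - np * (np + 1) / 2
  u / (np * nb)
}

#' Cross-validated model replicates
#'
#' Partitions the presences into `k` seeded folds; each replicate trains on
#' the other k-1 folds against the full background and is scored by test-AUC
#' of its held-out presences versus the background. The fold models are
#' returned so the projection stage can average the replicates.
#'
#' @param presence_env,background_env environmental values at points
#'   (data.frames with identical columns).
#' @param k number of folds (default 5).
#' @param rm regularization multiplier passed to the fits.
#' @param seed integer seed controlling the fold assignment.
#' @param ... passed to [train_maxent()] (feature classes etc.).
#' @return list with `folds` (per-presence fold id), `auc` (per-fold test
#'   AUC), `mean_auc`, and `models` (the k fitted replicates).
#' @export
cross_validate <- function(presence_env, background_env, k = 5, rm = 1,
                           seed = 1, ...) {
  presence_env <- as.data.frame(presence_env)
  m <- nrow(presence_env)
  if (k < 2) stop("k must be >= 2")
  if (m < k) stop("fewer presences (", m, ") than folds (", k, ")")
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = m)))
  models <- vector("list", k)
  auc <- numeric(k)
  for (f in seq_len(k)) {
    train_idx <- folds != f
    mod <- train_maxent(presence_env[train_idx, , drop = FALSE],
                        background_env, rm = rm, ...)
    models[[f]] <- mod
    test_scores <- predict_eta(mod, presence_env[!train_idx, , drop = FALSE])
    bg_scores <- predict_eta(mod, background_env)
    auc[f] <- evaluate_auc(test_scores, bg_scores)
  }
  list(folds = folds, auc = auc, mean_auc = mean(auc), models = models)
}

#' Small-sample corrected AIC
#'
#' `AICc = 2k - 2 lnL + 2k(k+1)/(n - k - 1)`, with `k` the number of nonzero
#' coefficients and `n` the presence count; non-finite when `n <= k + 1`
#' (the correction term's pole).
#'
#' @param lnL model log-likelihood (sum over presences of log raw output).
#' @param k number of nonzero coefficients.
#' @param n presence sample size.
#' @export
aicc <- function(lnL, k, n) {
  if (n <= k + 1) return(NA_real_)
  2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
}

#' Select the regularization multiplier by AICc
#'
#' Fits one model per candidate `rm` on all presences, computes each fit's
#' log-likelihood over the presences (log raw output, normalized over the
#' training background), counts its nonzero coefficients, and returns the
#' candidate minimizing AICc. Candidates with `n <= k + 1` are reported
#' non-finite and excluded.
#'
#' @param presence_env,background_env environmental values at points.
#' @param rm_grid candidate multipliers (default `seq(0.5, 3, by = 0.5)`).
#' @param ... passed to [train_maxent()].
#' @return list with `best_rm`, `best_model`, and `table`
#'   (rm, k, lnL, AICc, delta_AICc).
#' @export
select_rm <- function(presence_env, background_env,
                      rm_grid = seq(0.5, 3, by = 0.5), ...) {
  if (!length(rm_grid)) stop("rm_grid must be nonempty")
  presence_env <- as.data.frame(presence_env)
  n <- nrow(presence_env)
  models <- maxent_rm_path(presence_env, background_env, rm_grid, ...)
  rows <- vector("list", length(rm_grid))
  for (i in seq_along(rm_grid)) {
    mod <- models[[i]]
    lnL <- sum(predict_eta(mod, presence_env) - mod$log_z)
    k <- sum(mod$lambda != 0)
    rows[[i]] <- data.frame(rm = rm_grid[i], k = k, lnL = lnL,
                            AICc = aicc(lnL, k, n))
  }
  tab <- do.call(rbind, rows)
  if (all(!is.finite(tab$AICc)))
    stop("AICc non-finite for every candidate (n <= k + 1 throughout); ",
         "use more presences or stronger regularization")
  tab$delta_AICc <- tab$AICc - min(tab$AICc, na.rm = TRUE)
  best <- which.min(tab$AICc)
  list(best_rm = tab$rm[best], best_model = models[[best]], table = tab)
}

#' Percent contribution and jackknife variable importance
#'
#' Percent contribution allocates the training-gain improvements accumulated
#' during coordinate descent to each feature's source variable and
#' normalizes to 100. The jackknife refits the model with only / without
#' each variable and reports the resulting training gains.
#'
#' @param model a fitted `maxent_model` from [train_maxent()].
#' @param presence_env,background_env the training environmental values
#'   (required for the jackknife refits; omit to get contributions only).
#' @return list with `contribution` (data.frame variable / percent, summing
#'   to 100) and, when data is supplied, `jackknife` (variable,
#'   gain_only, gain_without) and `full_gain`.
#' @export
variable_importance <- function(model, presence_env = NULL,
                                background_env = NULL) {
  stopifnot(inherits(model, "maxent_model"))
  if (is.null(model$gain_trace) || is.null(model$features))
    stop("model has no gain trace; fit it via train_maxent() first")
  vars <- model$features$variables
  g <- stats::setNames(numeric(length(vars)), vars)
  tr <- model$gain_trace
  g[names(tr)] <- tr
  pct <- if (sum(g) > 0) 100 * g / sum(g)
         else stats::setNames(rep(100 / length(vars), length(vars)), vars)
  contribution <- data.frame(variable = vars, percent = as.numeric(pct[vars]))
  contribution <- contribution[order(-contribution$percent), ]
  rownames(contribution) <- NULL
  out <- list(contribution = contribution)
  if (!is.null(presence_env) && !is.null(background_env)) {
    jk <- lapply(vars, function(v) {
      only <- train_maxent(presence_env[, v, drop = FALSE],
                           background_env[, v, drop = FALSE],
                           rm = model$rm, classes = model$classes,
                           n_hinge_knots = model$n_hinge_knots)
      rest <- setdiff(vars, v)
      without_gain <- if (length(rest)) {
        wo <- train_maxent(presence_env[, rest, drop = FALSE],
                           background_env[, rest, drop = FALSE],
                           rm = model$rm, classes = model$classes,
                           n_hinge_knots = model$n_hinge_knots)
        model_gain(wo)
      } else 0
      data.frame(variable = v, gain_only = model_gain(only),
                 gain_without = without_gain)
    })
    out$jackknife <- do.call(rbind, jk)
    out$full_gain <- model_gain(model)
  }
  out
}

#' Marginal response curve of one variable
#'
#' Sweeps the variable across its training range with every other variable
#' fixed at its background mean and reports the model's cloglog suitability,
#' the standard partial-dependence diagnostic.
#'
#' @param model a fitted `maxent_model` from [train_maxent()].
#' @param variable variable name.
#' @param n_points sweep resolution (default 100).
#' @return data.frame with columns `value` and `suitability`.
#' @export
response_curve <- function(model, variable, n_points = 100) {
  stopifnot(inherits(model, "maxent_model"))
  if (is.null(model$features)) stop("model has no feature set")
  if (!variable %in% model$features$variables)
    stop("unknown variable: ", variable)
  grid_vals <- seq(model$features$var_min[[variable]],
                   model$features$var_max[[variable]],
                   length.out = n_points)
  data <- as.data.frame(lapply(model$background_means, rep, n_points))
  data[[variable]] <- grid_vals
  eta <- predict_eta(model, data, clamp = TRUE)
  data.frame(value = grid_vals,
             suitability = 1 - exp(-exp(eta - model$cloglog_offset)))
}
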