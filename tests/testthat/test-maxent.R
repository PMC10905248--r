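# closed-form moment-matching fixture: one binary feature, 50/50 background,
# presence mean 0.8 -> unpenalized lambda solves
# e^l / (e^l + 1) = 0.8, i.e. lambda = ln 4
binary_fixture <- function(pbar = 0.8, np = 10, nb = 100) {
  fp <- matrix(c(rep(1, round(pbar * np)), rep(0, np - round(pbar * np))),
               ncol = 1, dimnames = list(NULL, "f"))
  fb <- matrix(c(rep(1, nb / 2), rep(0, nb / 2)), ncol = 1,
               dimnames = list(NULL, "f"))
  list(fp = fp, fb = fb)
}

test_that("unpenalized fit solves the moment-matching equation in closed form", {
  fx <- binary_fixture()
  m <- suppressWarnings(fit_maxent(fx$fp, fx$fb, rm = 0))
  expect_equal(unname(m$lambda), log(4), tolerance = 1e-4)
  # raw outputs over the training background sum to 1
  raw <- exp(as.vector(fx$fb %*% m$lambda) - m$log_z)
  expect_equal(sum(raw), 1, tolerance = 1e-6)
  expect_true(m$converged)
})

test_that("rm = 0 warns about overfitting and negative rm errors", {
  fx <- binary_fixture()
  expect_warning(fit_maxent(fx$fp, fx$fb, rm = 0), "overfitting")
  expect_error(fit_maxent(fx$fp, fx$fb, rm = -1), ">= 0")
  expect_error(fit_maxent(fx$fp * NA, fx$fb, rm = 1), "non-finite")
})

test_that("extreme regularization shrinks every coefficient to zero", {
  d <- signal_dataset(seed = 21, n_presence = 150, n_background = 800)
  m <- train_maxent(d$presence_env, d$background_env, rm = 1e6,
                    n_hinge_knots = 5)
  expect_true(all(m$lambda == 0))
  pred <- predict_map(m, d$stack, scale = "raw")
  v <- pred$values[!is.na(pred$values)]
  expect_equal(max(v) - min(v), 0)
  expect_equal(sum(v), 1, tolerance = 1e-9)
})

test_that("a presence distribution identical to the background yields no signal", {
  # exact distributional identity: the optimum is lambda = 0, and the
  # optimizer must find it (or stay within numerical dust of it)
  set.seed(5)
  nb <- 5000
  bg <- data.frame(a = runif(nb), b = rnorm(nb), c = runif(nb, -2, 2))
  m <- train_maxent(bg, bg, rm = 1, n_hinge_knots = 8)
  expect_lte(max(abs(m$lambda)), 0.05)
  expect_equal(model_gain(m), 0, tolerance = 1e-6)
  # independently sampled uniform presences: coefficients stay at the
  # sampling-noise scale, far below any real signal
  pr <- bg[sample(nb, 5000, replace = TRUE), ]
  m2 <- train_maxent(pr, bg, rm = 1, n_hinge_knots = 8)
  expect_lte(max(abs(m2$lambda)), 0.5)
  expect_lte(model_gain(m2), 0.05)
})

test_that("the penalized objective is non-increasing across sweeps", {
  d <- signal_dataset(seed = 22, n_presence = 200, n_background = 1000)
  m <- train_maxent(d$presence_env, d$background_env, rm = 0.5,
                    n_hinge_knots = 6)
  expect_true(all(diff(m$objective_trace) <= 1e-10))
})

test_that("the fit satisfies the KKT optimality conditions of the L1 problem", {
  # independent optimality check: gradient computed from scratch
  d <- signal_dataset(seed = 23, n_presence = 150, n_background = 900)
  pooled <- rbind(d$presence_env, d$background_env)
  ftr <- build_features(pooled, classes = c("linear", "quadratic"))
  np <- nrow(d$presence_env)
  fp <- ftr$matrix[seq_len(np), ]; fb <- ftr$matrix[-seq_len(np), ]
  m <- fit_maxent(fp, fb, rm = 1, features = ftr$features)
  eta <- as.vector(fb %*% m$lambda)
  w <- exp(eta - max(eta)); w <- w / sum(w)
  grad <- as.vector(crossprod(fb, w)) - colMeans(fp)
  b <- m$rm * m$beta
  viol <- ifelse(m$lambda == 0, pmax(0, abs(grad) - b),
                 abs(grad + b * sign(m$lambda)))
  expect_lt(max(viol), 1e-5)
})

test_that("the warm-started path keeps sparsity non-increasing in rm", {
  d <- signal_dataset(seed = 24, n_presence = 250, n_background = 1200)
  path <- maxent_rm_path(d$presence_env, d$background_env,
                         rm_grid = seq(0.5, 3, by = 0.5),
                         classes = c("linear", "quadratic"))
  ks <- vapply(path, function(m) sum(m$lambda != 0), numeric(1))
  expect_true(all(diff(ks) <= 0))
  # every path fit satisfies its own normalization invariant
  for (m in path)
    expect_equal(sum(exp(predict_eta(m, d$background_env) - m$log_z)), 1,
                 tolerance = 1e-9)
})

test_that("raw predictions normalize over the prediction extent", {
  d <- signal_dataset(seed = 25, n_presence = 200, n_background = 1000)
  m <- train_maxent(d$presence_env, d$background_env, rm = 1,
                    n_hinge_knots = 5)
  pred <- predict_map(m, d$stack, scale = "raw")
  expect_equal(sum(pred$values, na.rm = TRUE), 1, tolerance = 1e-9)
  cl <- predict_map(m, d$stack, scale = "cloglog")
  v <- cl$values[!is.na(cl$values)]
  expect_true(all(v >= 0 & v <= 1))
})

test_that("a positive linear-only model predicts monotonically in its variable", {
  # gradient fixture: single layer increasing left to right
  g <- tiny_grid(10, 10, cellsize = 0.1, xmin = 0, ymin = 0)
  vals <- matrix(rep(seq(0, 1, length.out = 10), each = 10), 10, 10)
  st <- one_layer_stack(vals, g, name = "v")
  pres <- data.frame(v = c(0.8, 0.9, 0.95))
  bg <- data.frame(v = seq(0, 1, length.out = 100))
  m <- train_maxent(pres, bg, rm = 0.5, classes = "linear")
  expect_gt(m$lambda[["lin_v"]], 0)
  pred <- predict_map(m, st, scale = "raw")
  rowvals <- pred$values[5, ]
  expect_true(all(diff(rowvals) > 0))
})

test_that("clamped prediction beyond the training range equals the range edge", {
  pres <- data.frame(v = c(2, 3))
  bg <- data.frame(v = seq(1, 4, length.out = 50))
  m <- train_maxent(pres, bg, rm = 0.5, classes = "linear")
  eta_beyond <- predict_eta(m, data.frame(v = 99), clamp = TRUE)
  eta_edge <- predict_eta(m, data.frame(v = 4), clamp = TRUE)
  expect_equal(eta_beyond, eta_edge)
})

test_that("an all-zero-coefficient model yields a uniform raw map", {
  d <- signal_dataset(seed = 26, n_presence = 100, n_background = 500)
  m <- train_maxent(d$presence_env, d$background_env, rm = 1e6,
                    n_hinge_knots = 4)
  pred <- predict_map(m, d$stack, scale = "raw")
  v <- pred$values[!is.na(pred$values)]
  expect_equal(diff(range(v)), 0)
})

test_that("prediction errors name the missing layer", {
  d <- signal_dataset(seed = 27, n_presence = 100, n_background = 500)
  m <- train_maxent(d$presence_env, d$background_env, rm = 1,
                    n_hinge_knots = 4)
  partial <- subset_stack(d$stack, c("env01", "env02"))
  expect_error(predict_map(m, partial), "env03")
})
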