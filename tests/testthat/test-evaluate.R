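test_that("AUC handles perfect separation, partial overlap and total ties", {
  expect_equal(evaluate_auc(c(0.9, 0.8), c(0.5, 0.3, 0.1)), 1.0)
  expect_equal(evaluate_auc(c(0.9, 0.4), c(0.5, 0.3)), 0.75)
  expect_equal(evaluate_auc(rep(0.5, 4), rep(0.5, 6)), 0.5)
  expect_error(evaluate_auc(numeric(0), 1), "nonempty")
})

test_that("rank-based AUC matches exhaustive pair counting with ties", {
  set.seed(31)
  for (i in 1:25) {
    p <- sample(seq(0, 1, by = 0.1), sample(2:20, 1), replace = TRUE)
    b <- sample(seq(0, 1, by = 0.1), sample(2:30, 1), replace = TRUE)
    expect_equal(evaluate_auc(p, b), brute_auc(p, b), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(32)
  p <- rnorm(40); b <- rnorm(60)
  a1 <- evaluate_auc(p, b)
  expect_equal(evaluate_auc(exp(p), exp(b)), a1, tolerance = 1e-12)
  expect_equal(evaluate_auc(1 - exp(-exp(p)), 1 - exp(-exp(b))), a1,
               tolerance = 1e-12)
})

test_that("cross-validation folds are exhaustive, disjoint and seed-stable", {
  d <- signal_dataset(seed = 33, n_presence = 100, n_background = 600)
  cv1 <- cross_validate(d$presence_env, d$background_env, k = 5, rm = 1,
                        seed = 4, n_hinge_knots = 4)
  expect_equal(as.vector(table(cv1$folds)), rep(20, 5))
  cv2 <- cross_validate(d$presence_env, d$background_env, k = 5, rm = 1,
                        seed = 4, n_hinge_knots = 4)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$auc, cv2$auc)
  # signal-bearing data discriminates above chance in every fold summary
  expect_gt(cv1$mean_auc, 0.5)
  expect_error(cross_validate(d$presence_env[1:3, ], d$background_env, k = 5),
               "fewer presences")
})

test_that("AICc reproduces hand arithmetic and its small-sample pole", {
  expect_equal(aicc(-20, 2, 10), 4 + 40 + 12 / 7, tolerance = 1e-12)
  expect_equal(aicc(-20, 0, 10), 40)        # k = 0 -> -2 lnL exactly
  expect_true(is.na(aicc(-20, 9, 10)))      # n = k + 1
  expect_true(is.na(aicc(-20, 12, 10)))     # n < k + 1
})

test_that("rm selection scores candidates by AICc and excludes n <= k + 1", {
  d <- signal_dataset(seed = 34, n_presence = 120, n_background = 700)
  sel <- select_rm(d$presence_env, d$background_env, rm_grid = c(0.5, 1, 2),
                   n_hinge_knots = 4)
  tab <- sel$table
  expect_equal(nrow(tab), 3)
  # AICc recomputable from the reported lnL and k
  for (i in 1:3)
    expect_equal(tab$AICc[i], aicc(tab$lnL[i], tab$k[i], 120),
                 tolerance = 1e-9)
  expect_equal(sel$best_rm, tab$rm[which.min(tab$AICc)])
  expect_equal(min(tab$delta_AICc, na.rm = TRUE), 0)
  # unpenalized candidates with more coefficients than presences drop out,
  # and the best rm comes from the finite candidates
  tiny <- d$presence_env[1:12, ]
  sel2 <- suppressWarnings(
    select_rm(tiny, d$background_env, rm_grid = c(0, 3), n_hinge_knots = 6))
  t0 <- sel2$table[sel2$table$rm == 0, ]
  expect_gt(t0$k, 11)                 # saturated unpenalized fit
  expect_true(is.na(t0$AICc))
  expect_equal(sel2$best_rm, 3)
  # every candidate non-finite is an error with actionable advice
  expect_error(suppressWarnings(
    select_rm(d$presence_env[1:3, ], d$background_env,
              rm_grid = 0, n_hinge_knots = 6)),
    "non-finite for every candidate")
})

test_that("percent contributions are normalized and find the true driver", {
  d <- signal_dataset(seed = 35, n_presence = 400, n_background = 2500,
                      coefficients = c(env02 = 2),
                      quad_coefficients = c(env02 = -1))
  m <- train_maxent(d$presence_env, d$background_env, rm = 1,
                    n_hinge_knots = 6)
  imp <- variable_importance(m, d$presence_env, d$background_env)
  expect_equal(sum(imp$contribution$percent), 100, tolerance = 1e-6)
  expect_identical(imp$contribution$variable[1], "env02")
  # jackknife: the only-variable gain is highest for the true driver
  jk <- imp$jackknife
  expect_identical(jk$variable[which.max(jk$gain_only)], "env02")
})

test_that("a single-variable model attributes 100 percent contribution", {
  d <- signal_dataset(seed = 36, n_presence = 150, n_background = 800)
  m <- train_maxent(d$presence_env[, "env01", drop = FALSE],
                    d$background_env[, "env01", drop = FALSE],
                    rm = 1, n_hinge_knots = 5)
  imp <- variable_importance(m)
  expect_equal(imp$contribution$percent, 100, tolerance = 1e-6)
})

test_that("response curves are flat without signal and monotone with it", {
  pres <- data.frame(v = c(2.5, 2.8), w = c(1, 2))
  bg <- data.frame(v = seq(0, 3, length.out = 200),
                   w = seq(-1, 4, length.out = 200))
  m <- train_maxent(pres, bg, rm = 0.5, classes = "linear")
  rc <- response_curve(m, "v", n_points = 50)
  expect_equal(nrow(rc), 50)
  expect_true(all(diff(rc$suitability) >= 0))
  m0 <- train_maxent(pres, bg, rm = 1e6, classes = "linear")
  rc0 <- response_curve(m0, "v", n_points = 20)
  expect_equal(diff(range(rc0$suitability)), 0)
  expect_error(response_curve(m, "nope"), "unknown variable")
})

test_that("response-curve endpoints agree with direct prediction at those values", {
  d <- signal_dataset(seed = 37, n_presence = 150, n_background = 800)
  m <- train_maxent(d$presence_env, d$background_env, rm = 1,
                    n_hinge_knots = 4)
  rc <- response_curve(m, "env01", n_points = 10)
  probe <- as.data.frame(lapply(m$background_means, rep, 2))
  probe$env01 <- c(rc$value[1], rc$value[10])
  eta <- predict_eta(m, probe, clamp = TRUE)
  direct <- 1 - exp(-exp(eta - m$cloglog_offset))
  expect_equal(c(rc$suitability[1], rc$suitability[10]), direct,
               tolerance = 1e-12)
})
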