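# Feature expansion for the maximum-entropy estimator. Every feature maps
# the training rows into [0, 1]; scaling bounds come from the training data
# only and are stored so prediction (optionally clamped) reuses them.

beta_lqp_table <- cbind(m = c(0, 10, 17, 30, 100), beta = c(1, 1, 0.5, 0.25, 0.05))

# class-level default penalty constants, interpolated by presence sample
# size (the published auto-feature defaults of the estimator family)
beta_class_default <- function(kind, m) {
  if (kind %in% c("linear", "quadratic", "product")) {
    stats::approx(beta_lqp_table[, "m"], beta_lqp_table[, "beta"],
                  xout = min(max(m, 0), 100), rule = 2)$y
  } else if (kind == "hinge") 0.5
  else stop("unknown feature class: ", kind)
}

#' Build a feature set and training feature matrix
#'
#' Expands raw environmental variables into the estimator's feature basis:
#' `linear` = min-max scaled variable, `quadratic` = scaled square,
#' `product` = scaled pairwise product, `hinge` = `max(0, x - k) / (max - k)`
#' at evenly spaced knots. Constant variables are dropped with a warning
#' (their features carry no information and their scaling is undefined).
#'
#' @param train data.frame or matrix of variable values on the training rows
#'   (presences plus background).
#' @param classes subset of `c("linear", "quadratic", "product", "hinge")`.
#' @param n_hinge_knots hinge knots per variable (default 20).
#' @return list with `features` (a `feature_set`: definitions + bounds) and
#'   `matrix` (training feature matrix, all values in \[0, 1\]).
#' @export
build_features <- function(train, classes = c("linear", "quadratic", "hinge"),
                           n_hinge_knots = 20) {
  classes <- match.arg(classes,
                       c("linear", "quadratic", "product", "hinge"),
                       several.ok = TRUE)
  train <- as.data.frame(train)
  if (!all(vapply(train, is.numeric, logical(1))))
    stop("all variables must be numeric")
  if (any(!vapply(train, function(v) all(is.finite(v)), logical(1))))
    stop("non-finite values in training variables")
  vars <- names(train)
  rng <- vapply(train, range, numeric(2))
  const <- vars[rng[1, ] == rng[2, ]]
  if (length(const)) {
    warning("constant variable(s) dropped: ", paste(const, collapse = ", "))
    vars <- setdiff(vars, const)
  }
  if (!length(vars)) stop("no non-constant variables remain")
  defs <- list()
  add <- function(kind, v1, v2 = NA_character_, knot = NA_real_,
                  fmin = NA_real_, fmax = NA_real_) {
    defs[[length(defs) + 1]] <<- data.frame(
      kind = kind, var1 = v1, var2 = v2, knot = knot,
      fmin = fmin, fmax = fmax, stringsAsFactors = FALSE)
  }
  for (v in vars) {
    lo <- rng[1, v]; hi <- rng[2, v]
    if ("linear" %in% classes) add("linear", v, fmin = lo, fmax = hi)
    if ("quadratic" %in% classes) {
      q <- train[[v]]^2
      add("quadratic", v, fmin = min(q), fmax = max(q))
    }
    if ("hinge" %in% classes) {
      knots <- seq(lo, hi, length.out = n_hinge_knots + 1)[seq_len(n_hinge_knots)]
      for (k in knots) add("hinge", v, knot = k, fmin = k, fmax = hi)
    }
  }
  if ("product" %in% classes && length(vars) >= 2) {
    for (i in seq_len(length(vars) - 1)) for (j in (i + 1):length(vars)) {
      pr <- train[[vars[i]]] * train[[vars[j]]]
      add("product", vars[i], vars[j], fmin = min(pr), fmax = max(pr))
    }
  }
  defs <- do.call(rbind, defs)
  defs$name <- feature_names(defs)
  fs <- structure(list(variables = vars,
                       var_min = rng[1, vars], var_max = rng[2, vars],
                       defs = defs),
                  class = "feature_set")
  list(features = fs, matrix = apply_features(fs, train, clamp = FALSE))
}

feature_names <- function(defs) {
  nm <- character(nrow(defs))
  hi <- 0L
  for (i in seq_len(nrow(defs))) {
    nm[i] <- switch(defs$kind[i],
      linear = paste0("lin_", defs$var1[i]),
      quadratic = paste0("quad_", defs$var1[i]),
      product = paste0("prod_", defs$var1[i], "_", defs$var2[i]),
      hinge = {
        hi <- if (i > 1 && defs$kind[i - 1] == "hinge" &&
                  defs$var1[i - 1] == defs$var1[i]) hi + 1L else 1L
        sprintf("hinge_%s_%02d", defs$var1[i], hi)
      })
  }
  nm
}

#' Evaluate a feature set on new rows
#'
#' @param features a `feature_set` from [build_features()].
#' @param data data.frame of variable values (must contain every variable
#'   the feature set references).
#' @param clamp truncate variables to their training min/max before feature
#'   evaluation (the standard transfer-safe behavior when projecting onto
#'   novel climates)?
#' @return numeric feature matrix (rows x features).
#' @export
apply_features <- function(features, data, clamp = FALSE) {
  stopifnot(inherits(features, "feature_set"))
  data <- as.data.frame(data)
  missing <- setdiff(features$variables, names(data))
  if (length(missing))
    stop("data is missing required variable(s): ",
         paste(missing, collapse = ", "))
  x <- data[features$variables]
  if (clamp) {
    for (v in features$variables)
      x[[v]] <- pmin(pmax(x[[v]], features$var_min[[v]]), features$var_max[[v]])
  }
  defs <- features$defs
  out <- matrix(0, nrow(x), nrow(defs), dimnames = list(NULL, defs$name))
  scale01 <- function(v, lo, hi) if (hi > lo) (v - lo) / (hi - lo) else v * 0
  for (i in seq_len(nrow(defs))) {
    d <- defs[i, ]
    out[, i] <- switch(d$kind,
      linear = scale01(x[[d$var1]], d$fmin, d$fmax),
      quadratic = scale01(x[[d$var1]]^2, d$fmin, d$fmax),
      product = scale01(x[[d$var1]] * x[[d$var2]], d$fmin, d$fmax),
      hinge = if (d$fmax > d$knot)
        pmax(0, x[[d$var1]] - d$knot) / (d$fmax - d$knot)
      else x[[d$var1]] * 0)
  }
  out
}

# source variables of each feature (1 or 2), for gain attribution
feature_sources <- function(defs) {
  lapply(seq_len(nrow(defs)), function(i) {
    v <- c(defs$var1[i], defs$var2[i])
    v[!is.na(v)]
  })
}
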