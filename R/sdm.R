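## The three base species-distribution learners under one fit/predict
## contract:
##   maxent_like   L1-regularised logistic regression (glmnet) on linear +
##                 quadratic expansions of the continuous covariates — the
##                 standard presence/background logistic equivalent of
##                 MaxEnt's feature-class model.
##   random_forest in-package CART forest (Rcpp), Gini splits, bootstrap,
##                 sqrt-mtry, vote-fraction probabilities.
##   svm           in-package RBF-kernel L2 (squared-hinge) machine with
##                 Platt-scaled probabilities.
## All stochastic elements consume the supplied seed; fits are deterministic
## given (X, y, hyperparams, seed).

SDM_ALGORITHMS <- c("maxent_like", "random_forest", "svm")

default_hyperparams <- function(algorithm) {
  switch(algorithm,
    maxent_like   = list(nfolds = 5L, nlambda = 30L),
    random_forest = list(ntree = 500L, mtry = NA_integer_, min_node = 5L),
    svm           = list(C = 1, gamma = NA_real_, platt_frac = 0.25, maxit = 150L))
}

# Standardize continuous columns with training statistics; indicators pass
# through. Returns matrix + the constants needed to reproduce the transform.
standardize_design <- function(X, cont, center = NULL, scale_ = NULL) {
  m <- as.matrix(X)
  storage.mode(m) <- "double"
  if (is.null(center)) {
    center <- rep(0, ncol(m)); scale_ <- rep(1, ncol(m))
    names(center) <- names(scale_) <- colnames(m)
    for (nm in cont) {
      center[nm] <- mean(m[, nm])
      s <- stats::sd(m[, nm])
      scale_[nm] <- if (is.na(s) || s == 0) 1 else s
    }
  }
  for (nm in colnames(m)) m[, nm] <- (m[, nm] - center[nm]) / scale_[nm]
  list(m = m, center = center, scale = scale_)
}

# Append squared terms of the continuous columns (already standardized).
quadratic_expand <- function(m, cont) {
  if (!length(cont)) return(m)
  sq <- m[, cont, drop = FALSE]^2
  colnames(sq) <- paste0(cont, "_sq")
  cbind(m, sq)
}

#' Fit one base species-distribution model
#'
#' @param algorithm one of `"maxent_like"`, `"random_forest"`, `"svm"`.
#' @param X design data frame from [extract_covariates()] (carries the
#'   `continuous` attribute); at least 20 rows.
#' @param y 0/1 labels, both classes present.
#' @param hyperparams named list overriding the documented defaults.
#' @param seed integer seed consumed by every stochastic element.
#' @return an object of class `sdm_fit` with the algorithm tag, fitted
#'   parameters, feature schema (column names and standardization
#'   constants), the seed, and the training AUC.
#' @export
fit_sdm <- function(algorithm, X, y, hyperparams = list(), seed = 1L) {
  algorithm <- match.arg(algorithm, SDM_ALGORITHMS)
  if (nrow(X) < 20) stop("need at least 20 training rows")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (any(!is.finite(as.matrix(X)))) stop("non-finite features")
  hp <- utils::modifyList(default_hyperparams(algorithm), hyperparams)
  cont <- attr(X, "continuous")
  if (is.null(cont)) cont <- colnames(X)
  std <- standardize_design(X, cont)
  fit <- switch(algorithm,
    maxent_like   = fit_maxent_like(std$m, y, cont, hp, seed),
    random_forest = fit_rf(std$m, y, hp, seed),
    svm           = fit_svm(std$m, y, hp, seed))
  obj <- structure(list(algorithm = algorithm, fit = fit,
                        schema = list(columns = colnames(std$m), continuous = cont,
                                      center = std$center, scale = std$scale),
                        hyperparams = hp, seed = as.integer(seed)),
                   class = "sdm_fit")
  obj$training_auc <- auc_score(y, predict_design(obj, X))
  obj
}

fit_maxent_like <- function(m, y, cont, hp, seed) {
  mx <- quadratic_expand(m, cont)
  varying <- apply(mx, 2, stats::sd) > 0
  if (sum(varying) < 2)                   # degenerate design: intercept-only
    return(list(intercept_only = TRUE, p = mean(y)))
  foldid <- with_seed(seed, sample(rep_len(seq_len(hp$nfolds), nrow(mx))))
  cv <- glmnet::cv.glmnet(mx[, varying, drop = FALSE], y, family = "binomial",
                          alpha = 1, nlambda = hp$nlambda, foldid = foldid,
                          standardize = FALSE)
  list(cv = cv, lambda = cv$lambda.min, varying = varying)
}

fit_rf <- function(m, y, hp, seed) {
  mtry <- hp$mtry
  if (is.na(mtry)) mtry <- max(1L, floor(sqrt(ncol(m))))
  list(forest = .rf_fit_cpp(m, as.integer(y), as.integer(hp$ntree),
                            as.integer(mtry), as.integer(hp$min_node),
                            as.integer(seed)))
}

rbf_kernel <- function(A, B, gamma) {
  # ||a-b||^2 = |a|^2 + |b|^2 - 2 a.b, clamped at 0 for rounding noise
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

# Primal solve of the kernel-expansion L2-SVM (squared hinge):
#   min_alpha 1/2 a'Ka + C sum max(0, 1 - y (Ka + b))^2
solve_l2svm <- function(K, ys, C, maxit) {
  n <- length(ys)
  obj <- function(par) {
    a <- par[1:n]; b <- par[n + 1]
    f <- drop(K %*% a) + b
    h <- pmax(0, 1 - ys * f)
    0.5 * sum(a * drop(K %*% a)) + C * sum(h^2)
  }
  grad <- function(par) {
    a <- par[1:n]; b <- par[n + 1]
    f <- drop(K %*% a) + b
    h <- pmax(0, 1 - ys * f)
    c(drop(K %*% (a - 2 * C * ys * h)), -2 * C * sum(ys * h))
  }
  res <- stats::optim(rep(0, n + 1), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  list(alpha = res$par[1:n], b = res$par[n + 1])
}

fit_svm <- function(m, y, hp, seed) {
  gamma <- hp$gamma
  if (is.na(gamma)) gamma <- 1 / ncol(m)
  ys <- ifelse(y == 1, 1, -1)
  n <- nrow(m)
  # Platt scaling on an internal split: sigmoid fitted to decision values of
  # a model trained on the complement, then applied to the full-data model.
  cal <- with_seed(seed, sample(n, max(2L, round(hp$platt_frac * n))))
  # guard: both classes must appear on both sides of the split
  if (length(unique(y[cal])) < 2 || length(unique(y[-cal])) < 2)
    cal <- c(which(y == 1)[1:2], which(y == 0)[1:2])
  K_sub <- rbf_kernel(m[-cal, , drop = FALSE], m[-cal, , drop = FALSE], gamma)
  sub <- solve_l2svm(K_sub, ys[-cal], hp$C, hp$maxit)
  f_cal <- drop(rbf_kernel(m[cal, , drop = FALSE], m[-cal, , drop = FALSE], gamma) %*%
                  sub$alpha) + sub$b
  # a separable calibration split trips glm's perfect-separation warning;
  # the fitted sigmoid is still a valid monotone calibration there
  platt <- suppressWarnings(stats::glm(y[cal] ~ f_cal, family = stats::binomial()))
  K <- rbf_kernel(m, m, gamma)
  full <- solve_l2svm(K, ys, hp$C, hp$maxit)
  # squared-hinge solutions are sparse at the optimum (alpha ~ 2C*y*h, h = 0
  # off the margin): drop negligible expansion coefficients for prediction
  keep <- abs(full$alpha) > 1e-6 * max(abs(full$alpha))
  if (!any(keep)) keep <- rep(TRUE, length(full$alpha))
  list(alpha = full$alpha[keep], b = full$b, sv = m[keep, , drop = FALSE],
       gamma = gamma, platt = stats::coef(platt))
}

# predict suitability for new design rows (data frame on the training
# layer set) — the single internal path shared by predict_sdm and the
# evaluation code.
predict_design <- function(fit, X) {
  stopifnot(inherits(fit, "sdm_fit"))
  if (!identical(colnames(X), fit$schema$columns))
    stop("design columns do not match the fitted schema")
  m <- standardize_design(X, fit$schema$continuous,
                          fit$schema$center, fit$schema$scale)$m
  switch(fit$algorithm,
    maxent_like = {
      if (isTRUE(fit$fit$intercept_only)) return(rep(fit$fit$p, nrow(m)))
      mx <- quadratic_expand(m, fit$schema$continuous)[, fit$fit$varying, drop = FALSE]
      drop(stats::predict(fit$fit$cv, newx = mx, s = fit$fit$lambda,
                          type = "response"))
    },
    random_forest = .rf_predict_cpp(fit$fit$forest, m),
    svm = {
      f <- svm_decision(fit$fit, m)
      stats::plogis(fit$fit$platt[1] + fit$fit$platt[2] * f)
    })
}

svm_decision <- function(sf, m, chunk = 4000L) {
  n <- nrow(m)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    out[s:e] <- drop(rbf_kernel(m[s:e, , drop = FALSE], sf$sv, sf$gamma) %*%
                       sf$alpha) + sf$b
  }
  out
}

#' Predict a suitability raster from a fitted model
#'
#' Applies the fitted model to every valid cell of the stack; nodata cells
#' propagate. Output values lie in \[0, 1\].
#'
#' @param fit an `sdm_fit`.
#' @param stack an [env_stack()] covering the fit's layer set.
#' @param layers layer subset matching the one used at fit time (default:
#'   reconstructed from the schema is not attempted — pass the same subset).
#' @return an [env_layer()] of suitabilities (a suitability map).
#' @export
predict_sdm <- function(fit, stack, layers = NULL) {
  cells <- which_cells_valid(stack)
  X <- extract_covariates(cells, stack, layers)
  if (!identical(colnames(X), fit$schema$columns))
    stop("stack does not provide the fitted feature schema")
  p <- pmin(pmax(predict_design(fit, X), 0), 1)
  map_from_cells(stack$grid, cells, p, name = paste0("suitability_", fit$algorithm))
}

# valid cells in row-major order
which_cells_valid <- function(stack) {
  which(as.vector(t(stack$valid_mask)))
}

# build a raster layer from per-cell values (row-major cell indices)
map_from_cells <- function(grid, cells, values, name = "suitability") {
  m <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  rc <- cell_to_rowcol(grid, cells)
  m[rc] <- values
  env_layer(name, m, grid, "continuous")
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("sdm_fit [%s]: %d features, training AUC %.3f (seed %d)\n",
              x$algorithm, length(x$schema$columns), x$training_auc, x$seed))
  invisible(x)
}
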