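## Replicate evaluation (AUC, TSS), the AUC-threshold admission rule,
## AUC-proportional ensemble weights, ensemble prediction, and jackknife
## variable contributions.

#' Repeated stratified-holdout evaluation of the base learners
#'
#' `n_rep` stratified 80/20 splits (stratification on the presence/absence
#' label; the holdout takes `ceiling(holdout * n)` records of each class).
#' One fit + holdout evaluation per algorithm per replicate. Replicate seeds
#' are derived deterministically from the master seed.
#'
#' @param occ an `occurrence_set` with pseudo-absences attached (>= 10 of
#'   each class).
#' @param stack an [env_stack()].
#' @param algorithms character vector of base learners.
#' @param n_rep number of replicates (default 20).
#' @param holdout holdout fraction (default 0.2).
#' @param seed master seed.
#' @param layers optional layer subset.
#' @param hyperparams optional named list (per algorithm) of overrides.
#' @return data frame with columns algorithm, replicate, auc, tss,
#'   threshold, plus a `holdout_scores` attribute (per replicate, the
#'   holdout labels and per-algorithm scores — consumed by the ensemble
#'   metric pooling).
#' @export
evaluate_replicates <- function(occ, stack, algorithms = SDM_ALGORITHMS,
                                n_rep = 20L, holdout = 0.2, seed = 1L,
                                layers = NULL, hyperparams = list()) {
  dt <- design_table(occ, stack, layers)
  n_pos <- sum(dt$y == 1); n_neg <- sum(dt$y == 0)
  if (n_pos < 10 || n_neg < 10) stop("need at least 10 presences and 10 absences")
  algorithms <- match.arg(algorithms, SDM_ALGORITHMS, several.ok = TRUE)
  rep_seeds <- derive_seeds(seed, n_rep)
  rows <- list(); scores <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    split <- with_seed(rep_seeds[r], {
      te_pos <- sample(which(dt$y == 1), ceiling(holdout * n_pos))
      te_neg <- sample(which(dt$y == 0), ceiling(holdout * n_neg))
      c(te_pos, te_neg)
    })
    tr <- setdiff(seq_along(dt$y), split)
    Xtr <- dt$X[tr, , drop = FALSE]; attr(Xtr, "continuous") <- attr(dt$X, "continuous")
    Xte <- dt$X[split, , drop = FALSE]; attr(Xte, "continuous") <- attr(dt$X, "continuous")
    sc <- list(labels = dt$y[split])
    for (alg in algorithms) {
      fit <- fit_sdm(alg, Xtr, dt$y[tr], hyperparams[[alg]] %||% list(),
                     seed = rep_seeds[r])
      s <- predict_design(fit, Xte)
      ts <- tss_score(dt$y[split], s)
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = alg, replicate = r, auc = auc_score(dt$y[split], s),
        tss = ts$tss, threshold = ts$threshold)
      sc[[alg]] <- s
    }
    scores[[r]] <- sc
  }
  out <- do.call(rbind, rows)
  attr(out, "holdout_scores") <- scores
  attr(out, "rep_seeds") <- rep_seeds
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' AUC-proportional ensemble weights with an admission cutoff
#'
#' Models whose AUC falls below the cutoff are excluded; each admitted model
#' i gets weight `W_i = r_i / sum_j r_j` over the `h` admitted models, so
#' the weights sum to 1.
#'
#' @param mean_auc_by_model named numeric vector of per-model AUC values
#'   (conventionally the mean holdout AUC over replicates).
#' @param cutoff admission threshold (default 0.85).
#' @param strict if TRUE the rule is `> cutoff`; default FALSE (`>=`), so a
#'   model printed as exactly 0.85 is admitted.
#' @return named numeric vector of weights over the admitted models.
#' @export
ensemble_weights <- function(mean_auc_by_model, cutoff = 0.85, strict = FALSE) {
  r <- unlist(mean_auc_by_model)
  keep <- if (strict) r > cutoff else r >= cutoff
  if (!any(keep))
    stop("no admissible model: all AUC values below the cutoff ", cutoff)
  w <- r[keep] / sum(r[keep])
  w
}

#' Build the AUC-weighted ensemble and its suitability map
#'
#' Runs on the output of [evaluate_replicates()]: mean holdout AUC per
#' algorithm is the admission statistic r_i; admitted algorithms are refit
#' on all occurrence data and their maps combined per-cell with the
#' ensemble weights. Ensemble AUC/TSS are computed by applying the weighted
#' combination to each replicate's holdout predictions and averaging over
#' replicates; the AUC-weighted averages of the member metrics are also
#' reported.
#'
#' @inheritParams evaluate_replicates
#' @param eval_table output of [evaluate_replicates()] (computed if NULL).
#' @param cutoff AUC admission cutoff (default 0.85).
#' @param strict admission strictness, see [ensemble_weights()].
#' @return list of class `ensemble_model`: `weights`, `h`, `cutoff`,
#'   `mean_auc`, `fits` (refits on all data), `map` (suitability raster),
#'   `metrics` (ensemble and weighted-member AUC/TSS), `eval_table`.
#' @export
build_ensemble <- function(occ, stack, algorithms = SDM_ALGORITHMS,
                           n_rep = 20L, holdout = 0.2, seed = 1L,
                           layers = NULL, hyperparams = list(),
                           cutoff = 0.85, strict = FALSE,
                           eval_table = NULL) {
  if (is.null(eval_table))
    eval_table <- evaluate_replicates(occ, stack, algorithms, n_rep, holdout,
                                      seed, layers, hyperparams)
  mean_auc <- tapply(eval_table$auc, eval_table$algorithm, mean)
  mean_auc <- mean_auc[intersect(algorithms, names(mean_auc))]
  w <- ensemble_weights(as.list(mean_auc), cutoff, strict)
  dt <- design_table(occ, stack, layers)
  fit_seed <- derive_seeds(seed, 1L)
  fits <- lapply(names(w), function(alg)
    fit_sdm(alg, dt$X, dt$y, hyperparams[[alg]] %||% list(), seed = fit_seed))
  names(fits) <- names(w)
  maps <- lapply(fits, predict_sdm, stack = stack, layers = layers)
  vals <- Reduce(`+`, Map(function(m, wi) wi * m$values, maps, w))
  map <- env_layer("suitability_ensemble", vals, stack$grid, "continuous")
  # pooled holdout metrics of the weighted combination
  hs <- attr(eval_table, "holdout_scores")
  ens <- vapply(hs, function(sc) {
    comb <- Reduce(`+`, Map(function(alg, wi) wi * sc[[alg]], names(w), w))
    c(auc = auc_score(sc$labels, comb), tss = tss_score(sc$labels, comb)$tss)
  }, c(auc = 0, tss = 0))
  mean_tss <- tapply(eval_table$tss, eval_table$algorithm, mean)
  metrics <- list(
    ensemble_auc = mean(ens["auc", ]), ensemble_tss = mean(ens["tss", ]),
    weighted_member_auc = sum(w * mean_auc[names(w)]),
    weighted_member_tss = sum(w * mean_tss[names(w)]))
  structure(list(weights = w, h = length(w), cutoff = cutoff,
                 mean_auc = mean_auc, fits = fits, map = map,
                 metrics = metrics, eval_table = eval_table,
                 seed = as.integer(seed), layers = layers),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("ensemble_model: h = %d of %d algorithms admitted (AUC cutoff %g)\n",
              x$h, length(x$mean_auc), x$cutoff))
  for (nm in names(x$weights))
    cat(sprintf("  %-14s r = %.3f  W = %.3f\n", nm, x$mean_auc[nm], x$weights[nm]))
  cat(sprintf("  ensemble AUC %.3f, TSS %.3f\n",
              x$metrics$ensemble_auc, x$metrics$ensemble_tss))
  invisible(x)
}

#' Jackknife variable contributions
#'
#' For each variable v in the kept set, the ensemble prediction is rebuilt
#' with v removed (admitted algorithms refit on the reduced design, same
#' seeds and weights) and the raw importance is `s_v = max(0, 1 -
#' Pearson r(full map, reduced map))` over valid cells; contributions are
#' `100 * s_v / sum_u s_u` and sum to 100.
#'
#' @param ensemble an `ensemble_model` from [build_ensemble()].
#' @param occ,stack the inputs the ensemble was built from.
#' @param kept_variables character vector (>= 2) of layer names to assess;
#'   defaults to the layers the ensemble was fit on.
#' @param hyperparams optional per-algorithm overrides (must match the
#'   ensemble's).
#' @return named numeric vector of percent contributions.
#' @export
jackknife_contribution <- function(ensemble, occ, stack,
                                   kept_variables = NULL, hyperparams = list()) {
  if (is.null(kept_variables))
    kept_variables <- ensemble$layers %||% layer_names(stack)
  if (length(kept_variables) < 2) stop("need at least 2 variables")
  full <- ensemble$map$values[stack$valid_mask]
  fit_seed <- derive_seeds(ensemble$seed, 1L)
  raw <- vapply(kept_variables, function(v) {
    red_layers <- setdiff(kept_variables, v)
    dt <- design_table(occ, stack, red_layers)
    red_maps <- lapply(names(ensemble$weights), function(alg) {
      fit <- fit_sdm(alg, dt$X, dt$y, hyperparams[[alg]] %||% list(),
                     seed = fit_seed)
      predict_sdm(fit, stack, layers = red_layers)$values
    })
    red <- Reduce(`+`, Map(`*`, red_maps, ensemble$weights))[stack$valid_mask]
    if (stats::sd(full) == 0 || stats::sd(red) == 0) {
      warning("constant map in jackknife for variable ", v, "; score set to 0")
      return(0)
    }
    max(0, 1 - stats::cor(full, red))
  }, 0)
  if (sum(raw) == 0) stop("all jackknife scores are zero")
  100 * raw / sum(raw)
}
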