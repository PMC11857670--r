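## Collinearity screening: pairwise Pearson filter then iterative VIF, both
## over valid-mask cells only. Categorical layers are exempt and always kept.

# Matrix of continuous-layer values over valid cells (one column per layer).
continuous_matrix <- function(stack, layer_subset = NULL) {
  nms <- layer_names(stack)
  cont <- nms[vapply(stack$layers, function(l) l$kind == "continuous", TRUE)]
  if (!is.null(layer_subset)) {
    missing <- setdiff(layer_subset, nms)
    if (length(missing)) stop("unknown layers: ", paste(missing, collapse = ", "))
    cont <- intersect(layer_subset, cont)
  }
  idx <- which(stack$valid_mask)
  m <- vapply(cont, function(nm) stack$layers[[nm]]$values[idx],
              numeric(length(idx)))
  colnames(m) <- cont
  m
}

#' Pairwise Pearson correlations of continuous layers
#'
#' Computed over valid-mask cells only; categorical layers are excluded. A
#' layer constant over the valid cells has undefined correlations, reported
#' as `NA` and flagged via the `"constant_layers"` attribute.
#'
#' @param stack an [env_stack()].
#' @param layer_subset optional character vector restricting the layers.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(stack, layer_subset = NULL) {
  m <- continuous_matrix(stack, layer_subset)
  if (ncol(m) < 2) stop("need at least 2 continuous layers")
  sds <- apply(m, 2, stats::sd)
  const <- colnames(m)[sds == 0]
  r <- suppressWarnings(stats::cor(m))
  diag(r) <- 1
  attr(r, "constant_layers") <- const
  r
}

screening_report <- function(kept, dropped, r_max, vif_max) {
  structure(list(kept = kept, dropped = dropped,
                 thresholds = list(r_max = r_max, vif_max = vif_max)),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("screening_report: %d kept, %d dropped (|r| < %g, VIF < %g)\n",
              length(x$kept), nrow(x$dropped), x$thresholds$r_max, x$thresholds$vif_max))
  if (nrow(x$dropped)) print(x$dropped)
  invisible(x)
}

#' Greedy pairwise-correlation filter
#'
#' While any remaining pair of continuous layers has `|r| >= r_max`, the
#' worst pair (largest `|r|`; ties broken by input order) is found and the
#' member with the larger mean absolute correlation to all remaining layers
#' is dropped (ties: the later layer in input order). Categorical layers are
#' exempt and always kept.
#'
#' @param stack an [env_stack()].
#' @param r_max absolute-correlation threshold (default 0.7).
#' @return a `screening_report` with elements `kept`, `dropped`, `thresholds`.
#' @export
correlation_filter <- function(stack, r_max = 0.7) {
  r <- pearson_matrix(stack)
  keep <- colnames(r)
  dropped <- data.frame(layer = character(), reason = character(),
                        statistic = numeric(), partner = character(),
                        stringsAsFactors = FALSE)
  # constant layers cannot be screened meaningfully; drop them up front
  for (cl in attr(r, "constant_layers")) {
    dropped <- rbind(dropped, data.frame(layer = cl, reason = "pearson",
                                         statistic = NA_real_, partner = ""))
    keep <- setdiff(keep, cl)
  }
  repeat {
    if (length(keep) < 2) break
    sub <- abs(r[keep, keep, drop = FALSE])
    diag(sub) <- 0
    if (all(sub < r_max, na.rm = TRUE)) break
    worst <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)
    # first pair in input order among ties
    worst <- worst[order(pmin(worst[, 1], worst[, 2]), pmax(worst[, 1], worst[, 2])), ,
                   drop = FALSE][1, ]
    pair <- keep[sort(worst)]
    mean_abs <- rowMeans(sub[pair, , drop = FALSE])
    drop_nm <- if (abs(diff(mean_abs)) < 1e-12) pair[2]    # tie: later in input order
               else pair[which.max(mean_abs)]
    partner <- setdiff(pair, drop_nm)
    dropped <- rbind(dropped, data.frame(layer = drop_nm, reason = "pearson",
                                         statistic = r[drop_nm, partner],
                                         partner = partner))
    keep <- setdiff(keep, drop_nm)
  }
  cats <- layer_names(stack)[vapply(stack$layers,
                                    function(l) l$kind == "categorical", TRUE)]
  kept <- intersect(layer_names(stack), c(keep, cats))
  screening_report(kept, dropped, r_max, NA_real_)
}

#' Variance inflation factors of a set of continuous layers
#'
#' `VIF_j = 1 / (1 - R^2_j)` from the ordinary least squares regression of
#' layer j on all the others (standardized, intercept included), over valid
#' cells. Perfect collinearity yields `Inf`.
#'
#' @param stack an [env_stack()].
#' @param layers character vector of continuous layer names (>= 2).
#' @return named numeric vector of VIFs.
#' @export
vif_values <- function(stack, layers) {
  m <- continuous_matrix(stack, layers)
  if (ncol(m) < 2) stop("need at least 2 layers for VIF")
  m <- scale(m)
  vapply(seq_len(ncol(m)), function(j) {
    fit <- stats::lm.fit(cbind(1, m[, -j, drop = FALSE]), m[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((m[, j] - mean(m[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0) |> stats::setNames(colnames(m))
}

#' Iterative VIF filter
#'
#' Repeatedly drops the continuous layer with the largest VIF while the
#' maximum exceeds `vif_max` (ties broken by input order; infinite VIFs are
#' dropped first). Intended to run after [correlation_filter()]; categorical
#' layers are exempt.
#'
#' @param stack an [env_stack()].
#' @param vif_max VIF threshold (default 10).
#' @param layers optional starting set (default: all continuous layers).
#' @return a `screening_report`.
#' @export
vif_filter <- function(stack, vif_max = 10, layers = NULL) {
  nms <- layer_names(stack)
  cont <- nms[vapply(stack$layers, function(l) l$kind == "continuous", TRUE)]
  keep <- if (is.null(layers)) cont else intersect(layers, cont)
  dropped <- data.frame(layer = character(), reason = character(),
                        statistic = numeric(), partner = character(),
                        stringsAsFactors = FALSE)
  while (length(keep) >= 2) {
    v <- vif_values(stack, keep)
    if (max(v) < vif_max) break
    j <- which(v == max(v))[1]                       # input-order tie-break
    dropped <- rbind(dropped, data.frame(layer = keep[j], reason = "vif",
                                         statistic = v[j], partner = ""))
    keep <- keep[-j]
  }
  cats <- nms[vapply(stack$layers, function(l) l$kind == "categorical", TRUE)]
  screening_report(intersect(nms, c(keep, cats)), dropped, NA_real_, vif_max)
}

#' Full collinearity screen: Pearson filter then iterative VIF
#'
#' @param stack an [env_stack()].
#' @param r_max,vif_max thresholds (defaults 0.7 and 10).
#' @return a `screening_report` whose `kept` set satisfies both criteria;
#'   `dropped` records each removal with its reason and statistic.
#' @export
screen_stack <- function(stack, r_max = 0.7, vif_max = 10) {
  rep1 <- correlation_filter(stack, r_max)
  cont_kept <- rep1$kept[vapply(rep1$kept,
                                function(nm) stack$layers[[nm]]$kind == "continuous", TRUE)]
  if (length(cont_kept) >= 2) {
    rep2 <- vif_filter(stack, vif_max, layers = cont_kept)
    dropped <- rbind(rep1$dropped, rep2$dropped)
    kept <- rep2$kept
  } else {
    dropped <- rep1$dropped
    kept <- rep1$kept
  }
  screening_report(kept, dropped, r_max, vif_max)
}
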