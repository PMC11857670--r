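## Synthetic landscapes and virtual species with known truth. The generator
## emulates the structure of the real covariate set — spatially
## autocorrelated continuous fields, one categorical land-class layer,
## correlated layer pairs to exercise collinearity screening — and defines
## virtual species whose true suitability is a known logistic function of a
## subset of layers, with presences sampled proportionally to truth.

#' Specify a synthetic landscape
#'
#' @param grid a [grid_spec()].
#' @param layers list of layer specs, each a list with `name` and
#'   `generator` plus generator parameters:
#'   \describe{
#'     \item{gradient}{deterministic west-east linear gradient.}
#'     \item{gaussian_field}{white noise smoothed to `corr_length` cells
#'       (separable Gaussian smoothing), standardized to mean 0, sd 1.}
#'     \item{categorical}{`k` spatially coherent integer classes obtained by
#'       quantile-slicing a smoothed field (`corr_length` cells).}
#'     \item{copy_of}{`source` layer mixed with fresh noise:
#'       `mix * source + (1 - mix) * noise`, then standardized; the implied
#'       Pearson correlation with the source is
#'       `mix / sqrt(mix^2 + (1 - mix)^2)`.}
#'   }
#' @param seed integer seed.
#' @return a `landscape_spec` object.
#' @export
landscape_spec <- function(grid, layers, seed = 1L) {
  nms <- vapply(layers, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate layer names in landscape spec")
  for (i in seq_along(layers)) {
    ls <- layers[[i]]
    if (identical(ls$generator, "copy_of")) {
      if (!ls$source %in% nms[seq_len(i - 1)])
        stop("copy_of layer '", ls$name, "' references missing earlier layer '",
             ls$source, "'")
      if (ls$mix < 0 || ls$mix > 1) stop("mix coefficient must be in [0,1]")
    }
  }
  structure(list(grid = grid, layers = layers, seed = as.integer(seed)),
            class = "landscape_spec")
}

# separable Gaussian smoothing of a matrix, kernel sd = len cells
smooth_field <- function(m, len) {
  if (len <= 0) return(m)
  half <- max(1L, ceiling(3 * len))
  k <- stats::dnorm(seq(-half, half), sd = len)
  k <- k / sum(k)
  pad_conv <- function(v) {
    # edge-replicated 1-D convolution
    vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
    stats::filter(vp, k, sides = 2)[(half + 1):(half + length(v))]
  }
  m <- apply(m, 2, pad_conv)
  t(apply(t(m), 2, pad_conv))
}

standardize_matrix <- function(m) (m - mean(m)) / stats::sd(m)

#' Generate a synthetic environmental stack
#'
#' Deterministic given the spec's seed.
#'
#' @param spec a [landscape_spec()].
#' @return an [env_stack()].
#' @export
generate_landscape <- function(spec) {
  g <- spec$grid
  seeds <- derive_seeds(spec$seed, length(spec$layers))
  made <- list()
  for (i in seq_along(spec$layers)) {
    ls <- spec$layers[[i]]
    vals <- switch(ls$generator,
      gradient = {
        m <- matrix(rep(seq_len(g$n_cols), each = g$n_rows), g$n_rows)
        standardize_matrix(m)
      },
      gaussian_field = {
        noise <- with_seed(seeds[i], matrix(stats::rnorm(g$n_rows * g$n_cols), g$n_rows))
        standardize_matrix(smooth_field(noise, ls$corr_length %||% 3))
      },
      categorical = {
        noise <- with_seed(seeds[i], matrix(stats::rnorm(g$n_rows * g$n_cols), g$n_rows))
        f <- smooth_field(noise, ls$corr_length %||% 5)
        k <- ls$k %||% 3L
        cuts <- stats::quantile(f, probs = seq(0, 1, length.out = k + 1))
        cuts[1] <- -Inf; cuts[k + 1] <- Inf
        matrix(as.integer(cut(f, cuts, labels = FALSE)), g$n_rows)
      },
      copy_of = {
        src <- made[[ls$source]]$values
        noise <- with_seed(seeds[i], matrix(stats::rnorm(g$n_rows * g$n_cols), g$n_rows))
        noise <- standardize_matrix(smooth_field(noise, ls$corr_length %||% 0))
        standardize_matrix(ls$mix * standardize_matrix(src) + (1 - ls$mix) * noise)
      },
      stop("unknown generator: ", ls$generator))
    kind <- if (identical(ls$generator, "categorical")) "categorical" else "continuous"
    made[[ls$name]] <- env_layer(ls$name, vals, g, kind)
  }
  env_stack(unname(made))
}

#' Define a virtual species
#'
#' True suitability is `plogis(intercept + sum_l weight_l * response_l)`,
#' where each response is `linear` (the layer value itself) or
#' `gaussian(center, width)` (`exp(-((x - center) / width)^2)`, a unimodal
#' niche).
#'
#' @param responses named list, one entry per layer:
#'   `list(type = "linear", weight = w)` or
#'   `list(type = "gaussian", center = c, width = s, weight = w)`.
#' @param intercept numeric intercept on the logit scale.
#' @return a `virtual_species` object.
#' @export
virtual_species <- function(responses, intercept = 0) {
  stopifnot(length(responses) >= 1)
  w <- vapply(responses, `[[`, 0, "weight")
  if (all(w == 0)) stop("at least one response weight must be nonzero")
  structure(list(responses = responses, intercept = intercept),
            class = "virtual_species")
}

#' True suitability raster of a virtual species
#'
#' @param vs a [virtual_species()].
#' @param stack an [env_stack()] containing every referenced layer
#'   (continuous).
#' @return an [env_layer()] named `"true_suitability"`, values in (0, 1).
#' @export
true_suitability <- function(vs, stack) {
  eta <- matrix(vs$intercept, stack$grid$n_rows, stack$grid$n_cols)
  for (nm in names(vs$responses)) {
    l <- stack$layers[[nm]]
    if (is.null(l)) stop("virtual species references missing layer '", nm, "'")
    if (l$kind != "continuous")
      stop("virtual species responses require continuous layers ('", nm, "')")
    r <- vs$responses[[nm]]
    resp <- switch(r$type,
      linear = l$values,
      gaussian = exp(-((l$values - r$center) / r$width)^2),
      stop("unknown response type: ", r$type))
    eta <- eta + r$weight * resp
  }
  vals <- stats::plogis(eta)
  vals[!stack$valid_mask] <- NA
  env_layer("true_suitability", vals, stack$grid, "continuous")
}

#' Sample virtual presences proportionally to true suitability
#'
#' Cells are drawn with replacement with probability proportional to true
#' suitability, then deduplicated to unique cells — so the returned count
#' can be below `n_presence`. Presence coordinates are the cell centers.
#'
#' @param vs a [virtual_species()].
#' @param stack an [env_stack()].
#' @param n_presence number of draws (>= 1).
#' @param seed integer seed.
#' @param species species name for the occurrence set.
#' @return an `occurrence_set` (presences only).
#' @export
sample_virtual_occurrences <- function(vs, stack, n_presence, seed,
                                       species = "virtual") {
  stopifnot(n_presence >= 1)
  truth <- true_suitability(vs, stack)
  cells <- which_cells_valid(stack)
  p <- truth$values[cell_to_rowcol(stack$grid, cells)]
  if (sum(p) <= 0) stop("zero suitability everywhere")
  draw <- with_seed(seed, sample(cells, n_presence, replace = TRUE, prob = p))
  draw <- unique(draw)
  xy <- cell_center(stack$grid, draw)
  occurrence_set(species, data.frame(x = xy[, "x"], y = xy[, "y"], cell = draw))
}
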