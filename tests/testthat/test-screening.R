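# independent greedy oracle over a correlation matrix (enumeration of the
# greedy steps, kept deliberately separate from the package implementation)
greedy_oracle <- function(r, r_max = 0.7) {
  keep <- colnames(r)
  repeat {
    if (length(keep) < 2) return(keep)
    s <- abs(r[keep, keep, drop = FALSE]); diag(s) <- 0
    if (max(s) < r_max) return(keep)
    w <- which(s == max(s), arr.ind = TRUE)
    w <- w[order(pmin(w[, 1], w[, 2]), pmax(w[, 1], w[, 2])), , drop = FALSE][1, ]
    pair <- keep[sort(w)]
    ma <- rowMeans(s[pair, , drop = FALSE])
    drop_nm <- if (abs(ma[1] - ma[2]) < 1e-12) pair[2] else pair[which.max(ma)]
    keep <- setdiff(keep, drop_nm)
  }
}

test_that("pearson_matrix matches direct correlation arithmetic", {
  st <- vector_stack(a = c(1, 2, 3), b = c(1, 2, 4), c = c(-1, -2, -3))
  r <- pearson_matrix(st)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(r["a", "c"], -1)
  expect_equal(r["a", "b"], stats::cor(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(r["a", "b"], 0.982, tolerance = 5e-4)
  expect_equal(r, t(r))
  # constant layer flagged, correlations NA
  st2 <- vector_stack(a = c(1, 2, 3), k = c(5, 5, 5))
  r2 <- pearson_matrix(st2)
  expect_identical(attr(r2, "constant_layers"), "k")
  expect_true(is.na(r2["a", "k"]))
})

test_that("correlation_filter follows the greedy rule", {
  # duplicated layer: exactly one of the pair dropped, reason pearson
  g <- grid_spec(6, 6, 1)
  v <- matrix(rnorm(36), 6, 6)
  st <- env_stack(list(env_layer("a", v, g), env_layer("b", v, g),
                       env_layer("c", matrix(rnorm(36), 6, 6), g)))
  rep <- correlation_filter(st)
  expect_equal(rep$dropped$reason, "pearson")
  expect_equal(nrow(rep$dropped), 1)
  expect_true(rep$dropped$layer %in% c("a", "b"))

  # independent layers all kept
  st <- small_stack(side = 25, n_layers = 4, seed = 9)
  rep <- correlation_filter(st)
  expect_equal(rep$kept, layer_names(st))

  # exact r(A,B) = 0.9, r(A,C) = 0.8, r(B,C) = 0.5 (the smallest round
  # r(B,C) that keeps the matrix positive-definite): A has the largest mean
  # |r| so it is dropped first, then B and C (r = 0.5 < 0.7) are kept
  R <- matrix(c(1, 0.9, 0.8, 0.9, 1, 0.5, 0.8, 0.5, 1), 3, 3)
  set.seed(7)
  Z <- qr.Q(qr(scale(matrix(rnorm(60 * 3), 60), scale = FALSE)))  # orthonormal, mean 0
  X <- Z %*% chol(R)
  st <- vector_stack(A = X[, 1], B = X[, 2], C = X[, 3])
  r <- pearson_matrix(st)
  expect_equal(r["A", "B"], 0.9, tolerance = 1e-10)
  expect_equal(r["B", "C"], 0.5, tolerance = 1e-10)
  rep <- correlation_filter(st)
  expect_identical(rep$dropped$layer, "A")
  expect_identical(rep$kept, c("B", "C"))
  expect_identical(rep$kept, greedy_oracle(r))

  # oracle agreement on 20 random stacks with planted correlated pairs
  gg <- grid_spec(40, 40, 1)
  for (s in 1:20) {
    spec <- landscape_spec(gg, list(
      list(name = "x1", generator = "gaussian_field", corr_length = 2),
      list(name = "x2", generator = "gaussian_field", corr_length = 3),
      list(name = "x3", generator = "copy_of", source = "x1",
           mix = runif(1, 0.3, 0.95), corr_length = 2),
      list(name = "x4", generator = "copy_of", source = "x2",
           mix = runif(1, 0.3, 0.95), corr_length = 3)
    ), seed = 100 + s)
    st <- generate_landscape(spec)
    kept <- correlation_filter(st)$kept
    expect_identical(kept, greedy_oracle(pearson_matrix(st)))
  }
})

test_that("vif_values match the correlation-matrix-inverse oracle", {
  # orthogonal designs give VIF 1
  st <- vector_stack(a = c(1, -1, 1, -1, 1, -1, 1, -1),
                     b = c(1, 1, -1, -1, 1, 1, -1, -1),
                     c = c(1, 1, 1, 1, -1, -1, -1, -1))
  expect_equal(unname(vif_values(st, c("a", "b", "c"))), rep(1, 3))

  # exact linear dependence: infinite VIF, dropped first
  a <- rnorm(30); b <- rnorm(30)
  g <- grid_spec(1, 30, 1)
  st <- env_stack(list(env_layer("a", matrix(a, 1), g),
                       env_layer("b", matrix(b, 1), g),
                       env_layer("c", matrix(a + b, 1), g)))
  v <- vif_values(st, c("a", "b", "c"))
  expect_true(any(is.infinite(v)))
  rep <- vif_filter(st)
  expect_equal(nrow(rep$dropped), 1)
  expect_true(is.infinite(rep$dropped$statistic))

  # random designs: VIF_j equals diag of inverse correlation matrix
  set.seed(42)
  for (k in 1:10) {
    n <- 40
    x1 <- rnorm(n); x2 <- rnorm(n); x3 <- 0.7 * x1 + 0.5 * rnorm(n)
    st <- vector_stack(x1 = x1, x2 = x2, x3 = x3)
    v <- vif_values(st, c("x1", "x2", "x3"))
    oracle <- diag(solve(stats::cor(cbind(x1, x2, x3))))
    expect_equal(unname(v), unname(oracle), tolerance = 1e-8)
  }
})

test_that("screening invariants hold on random stacks with planted pairs", {
  gg <- grid_spec(30, 30, 1)
  for (s in 1:15) {
    spec <- landscape_spec(gg, list(
      list(name = "x1", generator = "gaussian_field", corr_length = 2),
      list(name = "x2", generator = "gaussian_field", corr_length = 3),
      list(name = "x3", generator = "copy_of", source = "x1",
           mix = runif(1, 0.5, 0.95), corr_length = 2),
      list(name = "x4", generator = "copy_of", source = "x2",
           mix = runif(1, 0.5, 0.95), corr_length = 3),
      list(name = "x5", generator = "gaussian_field", corr_length = 2)
    ), seed = 300 + s)
    st <- generate_landscape(spec)
    rep <- screen_stack(st)
    if (length(rep$kept) >= 2) {
      r <- pearson_matrix(st, rep$kept); diag(r) <- 0
      expect_lt(max(abs(r)), 0.7)
      expect_lt(max(vif_values(st, rep$kept)), 10)
    }
    # determinism
    expect_identical(rep$kept, screen_stack(st)$kept)
  }
})

test_that("screening is invariant to affine rescaling and keeps categoricals", {
  fx <- small_species_fixture(side = 30, n_presence = 40)
  st <- fx$stack
  rep1 <- screen_stack(st)
  rescaled <- env_stack(lapply(st$layers, function(l)
    env_layer(l$name, 3.7 * l$values - 11, l$grid, l$kind)))
  expect_identical(screen_stack(rescaled)$kept, rep1$kept)

  g <- st$grid
  withcat <- env_stack(c(unname(st$layers),
                         list(env_layer("landuse",
                                        matrix(sample(1:3, g$n_rows * g$n_cols, TRUE),
                                               g$n_rows), g, "categorical"))))
  expect_true("landuse" %in% screen_stack(withcat)$kept)
})
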