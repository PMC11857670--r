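test_that("ASCII raster I/O round-trips values, grid metadata and nodata", {
  g <- grid_spec(2, 2, 30, origin_x = 100, origin_y = 460)
  l <- env_layer("t", matrix(c(1, 3, 2, 4), 2, 2), g)
  p <- withr::local_tempfile(fileext = ".asc")
  write_ascii_raster(l, p)
  back <- read_ascii_raster(p, name = "t")
  expect_identical(back$values, l$values)
  expect_true(grids_aligned(back$grid, g))

  # nodata cell excluded from the stack's valid mask
  l2 <- env_layer("u", matrix(c(1, NA, 2, 4), 2, 2), g)
  write_ascii_raster(l2, p)
  st <- env_stack(list(read_ascii_raster(p, name = "u")))
  expect_identical(st$valid_mask, matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2))

  # write(read(write(x))) is bit-identical
  vals <- matrix(stats::runif(12, -5, 5), 3, 4)
  l3 <- env_layer("w", vals, grid_spec(3, 4, 2.5))
  write_ascii_raster(l3, p)
  r1 <- read_ascii_raster(p)
  p2 <- withr::local_tempfile(fileext = ".asc")
  write_ascii_raster(r1, p2)
  expect_identical(read_ascii_raster(p2)$values, r1$values)
})

test_that("align_stack is identity on matching grids and exact for nearest", {
  st <- small_stack(side = 12, seed = 2)
  aligned <- align_stack(st$layers, st$grid, "nearest")
  for (nm in layer_names(st))
    expect_identical(aligned$layers[[nm]]$values, st$layers[[nm]]$values)

  # constant layer resamples to a constant under either method
  # target centers are offset from the midpoints between source centers so
  # nearest-neighbour lookups are tie-free
  g_src <- grid_spec(10, 10, 2)
  g_tgt <- grid_spec(18, 18, 1, origin_x = 0.3, origin_y = 18.3)
  const <- env_layer("c", matrix(7, 10, 10), g_src)
  for (m in c("nearest", "bilinear"))
    expect_true(all(align_stack(list(const), g_tgt, m)$layers$c$values == 7))

  # 2x-coarser source, nearest: brute-force nearest-center oracle
  src_vals <- matrix(seq_len(100), 10, 10)
  src <- env_layer("s", src_vals, g_src)
  got <- align_stack(list(src), g_tgt, "nearest")$layers$s$values
  for (i in seq_len(g_tgt$n_rows)) for (j in seq_len(g_tgt$n_cols)) {
    tx <- g_tgt$origin_x + (j - 0.5) * g_tgt$cell_size
    ty <- g_tgt$origin_y - (i - 0.5) * g_tgt$cell_size
    sx <- g_src$origin_x + (seq_len(10) - 0.5) * g_src$cell_size
    sy <- g_src$origin_y - (seq_len(10) - 0.5) * g_src$cell_size
    expect_equal(got[i, j],
                 src_vals[which.min(abs(sy - ty)), which.min(abs(sx - tx))])
  }

  expect_error(align_stack(list(env_layer("k", matrix(1L, 10, 10), g_src, "categorical")),
                           g_tgt, "bilinear"), "nearest")
  off <- grid_spec(4, 4, 1, origin_x = 1000, origin_y = 1000)
  expect_error(align_stack(list(src), off), "cover")
})

test_that("Horn slope matches analytic planes and the hand-computed kernel", {
  g <- grid_spec(5, 5, 1)
  expect_true(all(compute_slope(env_layer("d", matrix(3, 5, 5), g))$values == 0))

  # plane z = x with unit cells: gradient 1 -> 45 degrees at interior cells
  plane <- env_layer("d", matrix(rep(0:4, each = 5), 5, 5), g)
  sl <- compute_slope(plane)$values
  expect_equal(sl[2:4, 2:4], matrix(45, 3, 3))

  # 3x3 hand-computed Horn kernel at the center
  dem <- env_layer("d", matrix(c(0, 0, 0, 1, 1, 1, 2, 2, 2), 3, 3), grid_spec(3, 3, 1))
  # dz/dx = ((2+4+2)-(0+0+0))/8 = 1, dz/dy = 0 -> atan(1) = 45
  expect_equal(compute_slope(dem)$values[2, 2], 45)

  expect_error(compute_slope(env_layer("k", matrix(1L, 3, 3), grid_spec(3, 3, 1),
                                       "categorical")), "continuous")
})

test_that("slope is bounded, shift-invariant, and propagates nodata", {
  st <- small_stack(side = 15, n_layers = 1, seed = 4)
  dem <- st$layers$l1
  dem <- env_layer("dem", dem$values * 50, dem$grid)
  s1 <- compute_slope(dem)$values
  expect_true(all(s1 >= 0 & s1 < 90))
  s2 <- compute_slope(env_layer("dem", dem$values + 123.4, dem$grid))$values
  expect_equal(s1, s2)
  v <- dem$values; v[5, 5] <- NA
  expect_true(is.na(compute_slope(env_layer("dem", v, dem$grid))$values[5, 5]))
})

test_that("aspect follows the compass convention and rotation equivariance", {
  g <- grid_spec(5, 5, 1)
  expect_true(all(compute_aspect(env_layer("d", matrix(0, 5, 5), g))$values == -1))

  # plane rising due south (rows increase southward): downslope points north
  south_up <- env_layer("d", matrix(rep(1:5, times = 5), 5, 5), g)
  expect_equal(compute_aspect(south_up)$values[3, 3], 0)

  # plane z = x (east-up): downslope west -> 270
  east_up <- env_layer("d", matrix(rep(1:5, each = 5), 5, 5), g)
  expect_equal(compute_aspect(east_up)$values[3, 3], 270)

  # rotating the DEM 90 degrees rotates interior aspect by 90 (mod 360)
  dem <- small_stack(side = 9, n_layers = 1, seed = 5)$layers$l1
  a1 <- compute_aspect(dem)$values
  rot <- t(dem$values)[, nrow(dem$values):1]        # 90 deg clockwise
  a2 <- compute_aspect(env_layer("r", rot, grid_spec(9, 9, dem$grid$cell_size)))$values
  a1r <- t(a1)[, nrow(a1):1]
  interior <- 2:8
  flat <- a1r[interior, interior] == -1
  expect_equal(((a1r[interior, interior] + 90) %% 360)[!flat],
               a2[interior, interior][!flat], tolerance = 1e-9)
})

test_that("distance_to_features is exact against the brute-force oracle", {
  g <- grid_spec(10, 10, 30)
  feats <- c(rowcol_to_cell(g, 3, 4), rowcol_to_cell(g, 8, 9))
  d <- distance_to_features(g, feats)$values
  expect_equal(d[3, 4], 0)
  expect_equal(d[8, 9], 0)
  expect_equal(d[2, 4], 30)   # 4-neighbour of a feature cell
  frc <- cell_to_rowcol(g, feats)
  for (i in 1:10) for (j in 1:10)
    expect_equal(d[i, j],
                 min(sqrt((i - frc[, "row"])^2 + (j - frc[, "col"])^2)) * 30)
  # Lipschitz: |d(a) - d(b)| <= dist(a, b), spot-checked on random pairs
  set.seed(1)
  for (k in 1:50) {
    a <- c(sample(10, 1), sample(10, 1)); b <- c(sample(10, 1), sample(10, 1))
    expect_lte(abs(d[a[1], a[2]] - d[b[1], b[2]]),
               sqrt(sum((a - b)^2)) * 30 + 1e-9)
  }
  expect_error(distance_to_features(g, integer(0)), "non-empty")
})

test_that("rasterize_segments traces lines through the expected cells", {
  g <- grid_spec(10, 10, 1, origin_x = 0, origin_y = 10)
  # horizontal segment through row 5 (y = 5.5), columns 2..8
  cells <- rasterize_segments(g, data.frame(x1 = 1.5, y1 = 5.5, x2 = 7.5, y2 = 5.5))
  expect_setequal(cells, rowcol_to_cell(g, rep(5L, 7), 2:8))
  # diagonal touches every step once
  cells <- rasterize_segments(g, data.frame(x1 = 0.5, y1 = 9.5, x2 = 9.5, y2 = 0.5))
  expect_setequal(cells, rowcol_to_cell(g, 1:10, 1:10))
})
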