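test_that("landscape generators honour their contracts", {
  g <- grid_spec(10, 10, 1)
  st <- generate_landscape(landscape_spec(g, list(
    list(name = "grad", generator = "gradient"),
    list(name = "gf", generator = "gaussian_field", corr_length = 2),
    list(name = "lu", generator = "categorical", k = 3, corr_length = 2),
    list(name = "dup", generator = "copy_of", source = "gf", mix = 1)
  ), seed = 2))
  # gradient strictly increasing along columns
  expect_true(all(diff(st$layers$grad$values[1, ]) > 0))
  # gaussian field standardized
  expect_equal(mean(st$layers$gf$values), 0, tolerance = 1e-10)
  expect_equal(stats::sd(st$layers$gf$values), 1, tolerance = 1e-10)
  # categorical codes
  expect_setequal(unique(as.vector(st$layers$lu$values)), 1:3)
  expect_equal(st$layers$lu$kind, "categorical")
  # copy_of with mix = 1 is perfectly correlated with its source
  expect_equal(stats::cor(as.vector(st$layers$dup$values),
                          as.vector(st$layers$gf$values)), 1)
  # determinism
  st2 <- generate_landscape(landscape_spec(g, list(
    list(name = "grad", generator = "gradient"),
    list(name = "gf", generator = "gaussian_field", corr_length = 2),
    list(name = "lu", generator = "categorical", k = 3, corr_length = 2),
    list(name = "dup", generator = "copy_of", source = "gf", mix = 1)
  ), seed = 2))
  expect_identical(st$layers$gf$values, st2$layers$gf$values)
  expect_error(landscape_spec(g, list(
    list(name = "x", generator = "copy_of", source = "missing", mix = 0.5))),
    "missing earlier layer")
})

test_that("copy_of mixtures realise the closed-form correlation", {
  g <- grid_spec(100, 100, 1)
  st <- generate_landscape(landscape_spec(g, list(
    list(name = "src", generator = "gaussian_field", corr_length = 3),
    list(name = "mix", generator = "copy_of", source = "src", mix = 0.8,
         corr_length = 3)
  ), seed = 31))
  r <- stats::cor(as.vector(st$layers$src$values), as.vector(st$layers$mix$values))
  expect_equal(r, 0.8 / sqrt(0.8^2 + 0.2^2), tolerance = 0.05)
})

test_that("true_suitability is the logistic of the linear predictor", {
  g <- grid_spec(3, 3, 1)
  vals <- matrix(c(-1, 0, 1, 2, -2, 0.5, 1.5, -0.5, 0), 3, 3)
  st <- env_stack(list(env_layer("L", vals, g)))
  vs <- virtual_species(list(L = list(type = "linear", weight = 2)), intercept = -1)
  tr <- true_suitability(vs, st)
  expect_equal(tr$values, stats::plogis(-1 + 2 * vals), tolerance = 1e-15)
  # saturation: large weight approaches the indicator of layer > 0.5
  vs2 <- virtual_species(list(L = list(type = "linear", weight = 1000)), intercept = -500)
  ind <- stats::plogis(1000 * (vals - 0.5))
  expect_equal(true_suitability(vs2, st)$values, ind, tolerance = 1e-12)
  # gaussian response peaks at its center
  vsg <- virtual_species(list(L = list(type = "gaussian", center = 0.5,
                                       width = 1, weight = 3)), intercept = -2)
  trg <- true_suitability(vsg, st)$values
  expect_equal(max(trg), trg[3, 2])          # cell with value exactly 0.5
  expect_error(virtual_species(list(L = list(type = "linear", weight = 0))),
               "nonzero")
})

test_that("virtual presence sampling is truth-proportional and reproducible", {
  g <- grid_spec(4, 4, 1)
  # concentrate all suitability mass on one cell via a huge peaked response
  vals <- matrix(0, 4, 4); vals[2, 3] <- 1
  st <- env_stack(list(env_layer("L", vals, g)))
  vs <- virtual_species(list(L = list(type = "linear", weight = 60)), intercept = -30)
  occ <- sample_virtual_occurrences(vs, st, 50, seed = 3)
  expect_equal(occ$presences$cell, rowcol_to_cell(g, 2L, 3L))
  expect_identical(sample_virtual_occurrences(vs, st, 50, seed = 3)$presences,
                   occ$presences)

  # uniform suitability: cell frequencies within 3 sigma of uniform
  stu <- env_stack(list(env_layer("L", matrix(1, 4, 4), g)))
  vsu <- virtual_species(list(L = list(type = "linear", weight = 1e-9)))
  counts <- integer(16)
  for (s in 1:500) {
    d <- sample_virtual_occurrences(vsu, stu, 20, seed = s)$presences$cell
    counts[d] <- counts[d] + 1L
  }
  # each cell is hit in a draw-set of 20 with p = 1 - (1 - 1/16)^20
  p <- 1 - (1 - 1 / 16)^20
  expect_true(all(abs(counts - 500 * p) <= 3 * sqrt(500 * p * (1 - p))))
})
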