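# Synthetic climate stacks: determinism, spatial structure, correlation
# targets, scenario deltas, known-range dilation.

test_that("a spec generates bit-identical stacks on repeated runs", {
  spec <- landscape_spec(25, 30, n_layers = 4, autocorrelation_range = 3,
                         seed = 11)
  s1 <- generate_climate_stack(spec)
  s2 <- generate_climate_stack(spec)
  expect_identical(s1$values, s2$values)
  s3 <- generate_climate_stack(landscape_spec(25, 30, n_layers = 4,
                                              autocorrelation_range = 3,
                                              seed = 12))
  expect_false(identical(s1$values, s3$values))
})

test_that("zero autocorrelation range yields spatially white noise", {
  spec <- landscape_spec(50, 50, n_layers = 1, layer_roles = "precipitation",
                         autocorrelation_range = 0, seed = 5)
  st <- generate_climate_stack(spec)
  expect_lt(abs(brute_moran_i(st$values[, , 1])), 0.05)
  smooth <- generate_climate_stack(landscape_spec(
    50, 50, n_layers = 1, layer_roles = "precipitation",
    autocorrelation_range = 4, seed = 5))
  expect_gt(brute_moran_i(smooth$values[, , 1]), 0.5)
})

test_that("generated layers hit the target inter-layer correlation", {
  C <- matrix(c(1, 0.9, 0.9, 1), 2)
  spec <- landscape_spec(200, 200, n_layers = 2,
                         layer_roles = rep("precipitation", 2),
                         autocorrelation_range = 3, target_correlation = C,
                         seed = 21)
  st <- generate_climate_stack(spec)
  r <- cor(as.vector(st$values[, , 1]), as.vector(st$values[, , 2]))
  expect_lt(abs(r - 0.9), 0.05)
})

test_that("invalid correlation matrices are rejected", {
  bad <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.99, -0.99, 0.99, 1), 3)
  expect_error(landscape_spec(10, 10, n_layers = 3, target_correlation = bad),
               "positive semidefinite")
  asym <- matrix(c(1, 0.2, 0.5, 1), 2)
  expect_error(landscape_spec(10, 10, n_layers = 2, target_correlation = asym),
               "symmetric")
})

test_that("scenario deltas are additive and leave the input untouched", {
  st <- tiny_stack(20, 3)
  zero <- scenario_delta("g", "c", 2020, numeric(3))
  expect_identical(apply_scenario(st, zero)$values, st$values)
  d <- scenario_delta("g", "c", 2020, c(2, 0, 0))
  fut <- apply_scenario(st, d)
  expect_equal(fut$values[, , 1], st$values[, , 1] + 2)
  expect_identical(fut$values[, , 2:3], st$values[, , 2:3])
  expect_error(apply_scenario(st, scenario_delta("g", "c", 2020, 1:2)),
               "layers")
})

test_that("uniform warming shrinks the range of a cool-adapted species", {
  st <- tiny_stack(40, 2, seed = 9)
  temp <- st$values[, , 1]
  sp <- niche_species("cool", optimum = c(quantile(temp, 0.3), NA),
                      breadth = c(sd(temp) * 0.6, Inf))
  a0 <- range_area(true_range(sp, st))
  warmed <- apply_scenario(st, scenario_delta("g", "c", 2050, c(1.5, 0)))
  expect_lt(range_area(true_range(sp, warmed)), a0)
  # monotone-decreasing response: positive deltas never grow the true range
  mono <- virtual_species("mono", linear = c(-1, 0))
  areas <- vapply(c(0, 0.5, 1, 2, 4), function(dd) {
    range_area(true_range(mono, apply_scenario(st, scenario_delta("g", "c", 1, c(dd, 0)))))
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("known ranges dilate the true range onto county-like blocks", {
  st <- tiny_stack(40, 3, seed = 14)
  sp <- random_virtual_species(st, seed = 2)
  truth <- true_range(sp, st)
  expect_identical(generate_known_range(sp, st, 1)$values, truth$values)
  for (k in c(3, 5)) {
    kr <- generate_known_range(sp, st, k)
    expect_true(all(kr$values >= truth$values))
    # every true cell's whole block must be lit
    for (cell in which(truth$values == 1)) {
      rc <- nichecast:::index_to_rowcol(st$grid, cell)
      rows <- (((rc$row - 1) %/% k) * k + 1):min(40, ((rc$row - 1) %/% k + 1) * k)
      cols <- (((rc$col - 1) %/% k) * k + 1):min(40, ((rc$col - 1) %/% k + 1) * k)
      expect_true(all(kr$values[rows, cols] == 1))
    }
  }
})
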