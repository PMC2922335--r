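# Virtual species truth surfaces, occurrence sampling, background pooling.

test_that("true suitability follows the logistic of the predictor", {
  st <- tiny_stack(20, 2)
  flat <- virtual_species("flat", numeric(2))
  expect_true(all(true_suitability(flat, st)$logistic == 0.5))
  nowhere <- virtual_species("none", numeric(2), intercept = -60)
  expect_true(all(true_suitability(nowhere, st)$logistic < 1e-15))
  expect_error(true_suitability(virtual_species("bad", numeric(3)), st),
               "layers")
})

test_that("a negative-curvature response peaks at the analytic vertex", {
  st <- tiny_stack(35, 1, seed = 8,
                   layer_roles = "precipitation")
  x <- st$values[, , 1]
  sp <- niche_species("quad", optimum = median(x), breadth = sd(x) / 2,
                      peak = 0.9)
  expect_lt(sp$quadratic, 0)
  suit <- true_suitability(sp, st)$logistic
  vertex <- -sp$linear / (2 * sp$quadratic)   # closed-form optimum
  expect_equal(vertex, median(x))
  best_cell <- which.max(suit)
  # the argmax cell's covariate is the closest achievable to the vertex
  expect_equal(abs(x[best_cell] - vertex), min(abs(x - vertex)))
})

test_that("true range area has a single source of truth", {
  st <- tiny_stack(30, 3, seed = 4)
  sp <- random_virtual_species(st, seed = 6)
  suit <- true_suitability(sp, st)$logistic
  expect_identical(range_area(true_range(sp, st)),
                   sum(suit >= sp$suitability_threshold))
})

test_that("occurrence sampling follows suitability-times-bias weights", {
  st <- tiny_stack(10, 2, seed = 3)
  sp <- random_virtual_species(st, seed = 5)
  occ <- sample_occurrences(sp, st, 20000, seed = 77)
  suit <- true_suitability(sp, st)$logistic
  counts <- tabulate(occ$points$cell, nbins = length(suit))
  keep <- suit / sum(suit) > 1e-6
  gof <- suppressWarnings(
    stats::chisq.test(counts[keep], p = suit[keep] / sum(suit[keep]),
                      rescale.p = TRUE))
  expect_gt(gof$p.value, 0.01)
  # degenerate bias: all mass in one cell
  bias <- matrix(0, 10, 10); bias[4, 7] <- 1
  occ1 <- sample_occurrences(sp, st, 50, bias = bias, seed = 1)
  expect_true(all(occ1$points$row == 4 & occ1$points$col == 7))
  expect_error(sample_occurrences(sp, st, 5, bias = matrix(0, 10, 10)),
               "zero")
})

test_that("sampling is deterministic and modelling sets need over 30 records", {
  st <- tiny_stack(15, 2)
  sp <- random_virtual_species(st, seed = 1)
  o1 <- sample_occurrences(sp, st, 40, seed = 9)
  o2 <- sample_occurrences(sp, st, 40, seed = 9)
  expect_identical(o1$points, o2$points)
  expect_error(sample_occurrences(sp, st, 29, for_modelling = TRUE),
               "more than 30")
  expect_error(sample_occurrences(sp, st, 30, for_modelling = TRUE),
               "more than 30")
  expect_s3_class(sample_occurrences(sp, st, 31, for_modelling = TRUE),
                  "occurrence_set")
})

test_that("target-group background pools and deduplicates by cell", {
  st <- tiny_stack(20, 2)
  sp <- random_virtual_species(st, seed = 2)
  # two disjoint handmade sets of 10 points each
  mk <- function(cells) {
    rc <- nichecast:::index_to_rowcol(st$grid, cells)
    structure(list(points = data.frame(
      species = "x", lon = cell_center_lon(st$grid, rc$col),
      lat = cell_center_lat(st$grid, rc$row), row = rc$row, col = rc$col,
      cell = cells), species = "x", n = length(cells), grid = st$grid),
      class = "occurrence_set")
  }
  bg <- build_target_group_background(list(mk(1:10), mk(11:20)))
  expect_equal(bg$n, 20)
  # a cell present in both sets counts once
  bg2 <- build_target_group_background(list(mk(1:10), mk(10:15)))
  expect_equal(bg2$n, 15)
  expect_error(build_target_group_background(list()), "at least one")
  # pool cap: seeded subsample without replacement
  bg3 <- build_target_group_background(list(mk(1:200)), pool_size = 50,
                                       seed = 3)
  expect_equal(bg3$n, 50)
  expect_true(all(bg3$points$cell %in% 1:200))
})
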