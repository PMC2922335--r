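# Threshold binarization, buffering, clipping, overlap and percent change.

test_that("the strict rule cuts the cumulative scale at 10, inclusive", {
  g <- grid_meta(1, 3, 1)
  s <- suitability_surface(g, cumulative = matrix(c(5, 10, 50), 1))
  b <- binarize(s, threshold_rule("strict"))
  expect_equal(as.vector(b$values), c(0, 1, 1))
})

test_that("the liberal rule keeps every training presence suitable", {
  g <- grid_meta(1, 5, 1)
  s <- suitability_surface(g, raw = matrix(c(0.1, 0.2, 0.3, 0.4, 0.5), 1))
  b <- binarize(s, threshold_rule("liberal"),
                training_presence_scores = c(0.2, 0.4))
  expect_equal(as.vector(b$values), c(0, 1, 1, 1, 1))
  expect_error(binarize(s, threshold_rule("liberal")), "training presence")
})

test_that("liberal ranges nest strict ranges when the condition holds", {
  st <- tiny_stack(30, 3, seed = 23)
  bg <- make_pool(st, 4, 100, seed = 900)
  for (seed in 1:3) {
    sp <- random_virtual_species(st, seed = seed)
    occ <- sample_occurrences(sp, st, 80, seed = seed + 50)
    fit <- fit_maxent(occ, bg, st)
    surf <- to_cumulative(predict_raw(fit, st))
    min_cum <- nichecast:::cumulative_from_raw(min(fit$training_presence_raw),
                                               fit$bg_raw)
    if (min_cum < 10) {
      lib <- binarize(surf, threshold_rule("liberal"),
                      fit$training_presence_raw)
      str <- binarize(surf, threshold_rule("strict"))
      expect_true(all(lib$values >= str$values))
    }
  }
})

test_that("buffering matches an exhaustive haversine scan", {
  g <- grid_meta(30, 30, 0.0083, origin = c(-83, 35))
  m <- matrix(0, 30, 30)
  m[14:16, 14:15] <- 1; m[4, 25] <- 1
  known <- binary_range(m, g)
  expect_identical(buffer_mask(known, 0)$values, known$values)
  allt <- binary_range(matrix(1, 30, 30), g)
  expect_identical(buffer_mask(allt, 25)$values, allt$values)
  for (d in c(2, 10)) {
    buf <- buffer_mask(known, d)
    expect_true(all(buf$values >= known$values))
    src <- which(known$values == 1)
    src_rc <- nichecast:::index_to_rowcol(g, src)
    slon <- cell_center_lon(g, src_rc$col); slat <- cell_center_lat(g, src_rc$row)
    oracle <- matrix(0L, 30, 30)
    for (cell in seq_along(oracle)) {
      rc <- nichecast:::index_to_rowcol(g, cell)
      dk <- brute_haversine_km(cell_center_lon(g, rc$col),
                               cell_center_lat(g, rc$row), slon, slat)
      if (min(dk) <= d) oracle[cell] <- 1L
    }
    expect_identical(buf$values, oracle)
  }
  expect_error(buffer_mask(known, -1), "nonnegative")
})

test_that("clipping is a cell-wise intersection", {
  g <- grid_meta(4, 4, 1)
  set.seed(2)
  r <- binary_range(matrix(rbinom(16, 1, 0.5), 4), g)
  allt <- binary_range(matrix(1, 4, 4), g)
  expect_identical(clip_range(r, allt)$values, r$values)
  disj <- binary_range(1 - r$values, g)
  expect_equal(range_area(clip_range(r, disj)), 0)
  m <- binary_range(matrix(rbinom(16, 1, 0.5), 4), g)
  expect_lte(range_area(clip_range(r, m)),
             min(range_area(r), range_area(m)))
  expect_error(clip_range(r, binary_range(matrix(1, 5, 5), grid_meta(5, 5, 1))),
               "same grid")
})

test_that("percent overlap counts the captured share of the known range", {
  g <- grid_meta(2, 5, 1)
  known <- binary_range(matrix(c(rep(1, 6), rep(0, 4)), 2), g)
  expect_equal(percent_overlap(known, known), 100)
  off <- binary_range(matrix(c(rep(0, 6), rep(1, 4)), 2), g)
  expect_equal(percent_overlap(off, known), 0)
  half <- binary_range(matrix(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), 2), g)
  expect_equal(percent_overlap(half, known), 50)
  empty <- binary_range(matrix(0, 2, 5), g)
  expect_error(percent_overlap(known, empty), "empty")
})

test_that("percent change follows the loss formula and flags empty currents", {
  g <- grid_meta(10, 10, 1)
  mk <- function(n) {
    v <- matrix(0, 10, 10); if (n > 0) v[seq_len(n)] <- 1
    binary_range(v, g)
  }
  expect_equal(percent_change(mk(40), mk(40))$percent_change, 0)
  expect_equal(percent_change(mk(40), mk(0))$percent_change, 100)
  expect_equal(percent_change(mk(50), mk(60))$percent_change, -20)
  expect_error(percent_change(mk(0), mk(5)), "empty")
  expect_lte(percent_change(mk(30), mk(90))$percent_change, 100)
})

test_that("range centroids average suitable cell-center latitudes", {
  g <- grid_meta(10, 4, 1, origin = c(0, 40))
  one <- matrix(0, 10, 4); one[3, 2] <- 1
  expect_equal(range_centroid_latitude(binary_range(one, g)),
               cell_center_lat(g, 3))
  two <- matrix(0, 10, 4); two[c(2, 6)] <- 1   # rows 2 and 6, col 1
  expect_equal(range_centroid_latitude(binary_range(two, g)),
               mean(cell_center_lat(g, c(2, 6))))
  set.seed(8)
  blk <- matrix(rbinom(40, 1, 0.4), 10, 4)
  idx <- which(blk == 1)
  rc <- nichecast:::index_to_rowcol(g, idx)
  expect_equal(range_centroid_latitude(binary_range(blk, g)),
               mean(cell_center_lat(g, rc$row)))
  expect_error(range_centroid_latitude(binary_range(matrix(0, 10, 4), g)),
               "empty")
})
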