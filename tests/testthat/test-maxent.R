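# Feature construction and the maximum-entropy fit: moment matching,
# oracle agreement, output transforms and their invariants.

test_that("feature classes follow the sample-size rule and scale to [0,1]", {
  set.seed(1)
  Xb <- cbind(a = runif(60, 2, 9), b = rnorm(60))
  fs10 <- build_features(Xb, 10)
  expect_setequal(fs10$classes, c("linear", "quadratic"))
  fs100 <- build_features(Xb, 100)
  expect_setequal(fs100$classes,
                  c("linear", "quadratic", "hinge", "product", "threshold"))
  Fb <- evaluate_features(fs100, Xb)
  expect_true(all(Fb >= 0 & Fb <= 1))
  # single layer, linear class only
  fs1 <- build_features(Xb[, 1, drop = FALSE], 5)
  expect_equal(nrow(fs1$defs), 1L)
  f1 <- evaluate_features(fs1, Xb[, 1, drop = FALSE])
  expect_equal(range(f1), c(0, 1))
  # one product feature per unordered pair
  X3 <- cbind(Xb, c = runif(60))
  fs3 <- build_features(X3, 200, classes = "product")
  expect_equal(nrow(fs3$defs), 3L)
  # constant layers lose their quadratic/product features with a warning
  Xc <- cbind(u = runif(30), k = rep(2, 30))
  expect_warning(fsc <- build_features(Xc, 12), "constant")
  expect_false(any(fsc$defs$class == "quadratic" & fsc$defs$layer1 == 2))
})

test_that("matched presence and background means give the uniform model", {
  set.seed(2)
  Xb <- matrix(runif(80), 40, 2)
  fit <- maxent_fit_core(Xb, Xb, beta = 0, add_samples_to_background = FALSE)
  expect_true(all(fit$lambdas == 0))
  expect_equal(fit$bg_raw, rep(1 / 40, 40))
})

test_that("a one-feature fit matches the root-finding oracle to 1e-6", {
  Xb <- matrix(c(0, 1, 2, 3), ncol = 1)
  Xp <- matrix(2)
  fs <- build_features(Xb, 1, classes = "linear")
  fit <- maxent_fit_core(Xp, Xb, features = fs, beta = 0, tol = 1e-12)
  # oracle: moment condition on the scaled feature f = x/3, target 2/3
  f <- c(0, 1, 2, 3) / 3
  moment <- function(l) sum(f * exp(l * f)) / sum(exp(l * f)) - 2 / 3
  l_star <- uniroot(moment, c(-50, 50), tol = 1e-12)$root
  expect_equal(unname(fit$lambdas), l_star, tolerance = 1e-6)
})

test_that("unpenalized fits match presence feature means to 1e-6", {
  for (seed in 1:3) {
    set.seed(seed)
    Xb <- matrix(rnorm(90), 30, 3)
    Xp <- Xb[sample(30, 12), ] + rnorm(36, 0, 0.05)
    fit <- maxent_fit_core(Xp, Xb, beta = 0, tol = 1e-10,
                           sample_size = 12)
    Fb <- evaluate_features(fit$features, fit$bg_X, clamp = FALSE)
    Fp <- evaluate_features(fit$features, Xp, clamp = FALSE)
    model_expect <- as.vector(crossprod(Fb, fit$bg_raw))
    expect_lt(max(abs(model_expect - colMeans(Fp))), 1e-6)
  }
})

test_that("the fitted distribution matches a generic simplex solver (KL <= 1e-4)", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- c(20, 35, 50)[seed]
    Xb <- matrix(rnorm(n * 2), n, 2)
    Xp <- Xb[sample(n, 8), , drop = FALSE]
    fs <- build_features(Xb, 8, classes = "linear")
    fit <- maxent_fit_core(Xp, Xb, features = fs, beta = 0, tol = 1e-12,
                           add_samples_to_background = FALSE)
    Fb <- evaluate_features(fs, Xb, clamp = FALSE)
    q_oracle <- simplex_maxent_oracle(Fb, colMeans(evaluate_features(fs, Xp, clamp = FALSE)))
    expect_lt(kl_div(fit$bg_raw, q_oracle), 1e-4)
  }
})

test_that("raw predictions normalize over the background and respect weights", {
  st <- tiny_stack(25, 3, seed = 6)
  sp <- random_virtual_species(st, seed = 3)
  occ <- sample_occurrences(sp, st, 120, seed = 4, for_modelling = TRUE)
  bg <- make_pool(st, 4, 120, seed = 300)
  fit <- fit_maxent(occ, bg, st)
  expect_equal(sum(fit$bg_raw), 1, tolerance = 1e-8)
  surf <- predict_raw(fit, st)
  # projecting the training stack plus a zero delta is the identity
  surf0 <- predict_raw(fit, apply_scenario(st, scenario_delta("g", "c", 1, numeric(3))))
  expect_identical(surf$raw, surf0$raw)
  # all-zero weights give a constant surface
  fit0 <- maxent_fit_core(matrix(colMeans(fit$bg_X), 1), fit$bg_X, beta = 1e6)
  expect_true(all(fit0$lambdas == 0))
  expect_error(predict_raw(fit, tiny_stack(25, 2)), "match")
  expect_error(maxent_fit_core(matrix(c(1, NA), 1), matrix(rnorm(10), 5)),
               "finite")
})

test_that("cumulative transform follows the inclusive tie rule with max 100", {
  g <- grid_meta(1, 3, 1)
  s1 <- suitability_surface(g, raw = matrix(c(0.5, 0.3, 0.2), 1),
                            bg_raw = c(0.5, 0.3, 0.2))
  expect_equal(as.vector(to_cumulative(s1)$cumulative), c(100, 50, 20))
  s2 <- suitability_surface(g, raw = matrix(c(0.25, 0.25, 0.5), 1),
                            bg_raw = c(0.25, 0.25, 0.5))
  expect_equal(as.vector(to_cumulative(s2)$cumulative), c(50, 50, 100))
  # random surface: highest-raw cell always scores exactly 100
  set.seed(3)
  r <- runif(40); r <- r / sum(r)
  s3 <- to_cumulative(suitability_surface(grid_meta(4, 10, 1),
                                          raw = matrix(r, 4), bg_raw = r))
  expect_equal(max(s3$cumulative), 100)
})

test_that("logistic output is the entropy-calibrated monotone transform", {
  n <- 25
  g <- grid_meta(5, 5, 1)
  uni <- suitability_surface(g, raw = matrix(1 / n, 5, 5), entropy = log(n))
  expect_true(all(abs(to_logistic(uni)$logistic - 0.5) < 1e-12))
  set.seed(4)
  r <- sort(runif(n)); r <- r / sum(r)
  s <- suitability_surface(g, raw = matrix(r, 5), bg_raw = r,
                           entropy = -sum(r * log(r)))
  s <- to_logistic(to_cumulative(s))
  expect_true(all(diff(as.vector(s$logistic)) > 0))
  # ranks agree across all three scales
  expect_identical(rank(as.vector(s$raw)), rank(as.vector(s$logistic)))
  expect_identical(rank(as.vector(s$raw)), rank(as.vector(s$cumulative)))
})

test_that("stronger regularization never grows the weight norm", {
  set.seed(9)
  Xb <- matrix(rnorm(120), 40, 3)
  Xp <- Xb[sample(40, 15), ] + 0.3
  norms <- vapply(c(0, 0.25, 0.5, 1, 2, 4), function(mult) {
    f <- maxent_fit_core(Xp, Xb, sample_size = 15, beta_multiplier = mult,
                         beta = if (mult == 0) 0 else NULL)
    sum(abs(f$lambdas))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("background cell order does not affect the fit", {
  set.seed(10)
  Xb <- matrix(rnorm(60), 30, 2)
  Xp <- Xb[1:10, ] + 0.1
  f1 <- maxent_fit_core(Xp, Xb, sample_size = 10,
                        add_samples_to_background = FALSE)
  perm <- sample(30)
  f2 <- maxent_fit_core(Xp, Xb[perm, ], sample_size = 10,
                        add_samples_to_background = FALSE)
  expect_equal(f1$lambdas, f2$lambdas, tolerance = 1e-6)
  expect_equal(f1$bg_raw, f2$bg_raw[order(perm)], tolerance = 1e-6)
})
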