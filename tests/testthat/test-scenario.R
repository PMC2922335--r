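# Scenario enumeration, the factorial GLM and latitude-band summaries.

test_that("scenario enumeration yields the factorial counts", {
  s <- enumerate_scenarios()
  expect_equal(attr(s, "per_species_scenarios"), 8)
  s3 <- enumerate_scenarios(years = c(2020, 2050, 2080))
  expect_equal(attr(s3, "richness_scenarios"), 24)
  expect_equal(nrow(s3), 24)
  one <- enumerate_scenarios("g", "c", "t", 2020)
  expect_equal(nrow(one), 1)
  expect_equal(attr(one, "per_species_scenarios"), 1)
})

test_that("the factorial GLM reproduces the design's degrees of freedom", {
  lt <- simulate_loss_table(n_units = 35, seed = 3)
  expect_equal(nrow(lt[lt$year == 2020, ]), 35 * 8)
  at <- fit_factorial_glm(lt, 2020)
  # independent df oracle: n minus the rank of the design matrix
  d <- lt[lt$year == 2020, ]
  d$sqrt_loss <- sqrt(pmax(d$percent_change, 0))
  X <- model.matrix(~ (gcm + co2 + threshold + centroid_latitude + range_size)^3,
                    data = transform(d, gcm = factor(gcm), co2 = factor(co2),
                                     threshold = factor(threshold)))
  expect_equal(attr(at, "error_df"), nrow(d) - qr(X)$rank)
  expect_equal(attr(at, "error_df"), 254)
  terms <- at$term[at$term != "Error"]
  expect_length(terms, 25)            # 5 main + 10 two-way + 10 three-way
  expect_true(all(at$df[at$term != "Error"] == 1))
})

test_that("a constant response puts zero sum of squares on every term", {
  lt <- simulate_loss_table(n_units = 10, seed = 1,
                            effects = list(latitude = 0, log_range = 0,
                                           co2_high = 0, threshold_strict = 0,
                                           gcm_CGCM3 = 0, year_step = 0,
                                           sigma = 0))
  at <- suppressWarnings(fit_factorial_glm(lt, 2020))
  expect_true(all(abs(at$sum_sq[at$term != "Error"]) < 1e-10))
})

test_that("an injected latitude effect dominates and is recovered", {
  lt <- simulate_loss_table(n_units = 35, seed = 7,
                            effects = list(intercept = 6, latitude = -0.5,
                                           log_range = 0, co2_high = 0,
                                           threshold_strict = 0, gcm_CGCM3 = 0,
                                           year_step = 0, sigma = 0.15))
  at <- fit_factorial_glm(lt, 2020)
  expect_equal(at$term[which.max(at$F)], "centroid_latitude")
  fit <- attr(at, "fit")
  est <- coef(summary(fit))["centroid_latitude", ]
  expect_lt(abs(est["Estimate"] - (-0.5)), 2 * est["Std. Error"])
})

test_that("an injected CO2 contrast is recovered within 2 SE in most seeds", {
  hits <- 0
  for (seed in 1:20) {
    lt <- simulate_loss_table(n_units = 35, seed = seed,
                              effects = list(intercept = 5, co2_high = 0.6,
                                             co2_fade = 1))
    at <- fit_factorial_glm(lt, 2020)
    est <- coef(summary(attr(at, "fit")))["co21", ]
    # sum coding: high = +1, low = -1, so the level contrast is 2 * beta
    if (abs(2 * est["Estimate"] - 0.6) <= 2 * 2 * est["Std. Error"]) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 18)
})

test_that("sequential sums of squares decompose the total exactly", {
  lt <- simulate_loss_table(n_units = 20, seed = 9)
  at <- fit_factorial_glm(lt, 2050, ss = "sequential")
  d <- lt[lt$year == 2050, ]
  total <- sum((sqrt(pmax(d$percent_change, 0)) -
                  mean(sqrt(pmax(d$percent_change, 0))))^2)
  expect_equal(sum(at$sum_sq), total, tolerance = 1e-8)
})

test_that("latitude bands summarize the loss table correctly", {
  toy <- data.frame(species = letters[1:6], gcm = "g", co2 = "c",
                    threshold = rep(c("strict", "liberal"), 3), year = 2020,
                    current_area = 10, future_area = 5,
                    percent_change = c(10, 20, 30, 40, 80, 90),
                    range_size = 10,
                    centroid_latitude = c(33, 33, 37, 37, 33, 43))
  out <- summarize_by_latitude_band(toy, bands = list(c(32, 34), c(36, 38)))
  s1 <- out[out$band == "[32,34)" & out$threshold == "strict", ]
  expect_equal(s1$mean, mean(c(10, 80)))
  expect_equal(c(s1$min, s1$max), c(10, 80))
  l2 <- out[out$band == "[36,38)" & out$threshold == "liberal", ]
  expect_equal(l2$mean, 40)
  # bands covering no species come back missing, not as an error
  none <- summarize_by_latitude_band(toy, bands = list(c(20, 22)))
  expect_true(all(is.na(none$mean)))
  expect_true(all(none$n == 0))
  # single band holding everything reproduces the table mean
  allb <- summarize_by_latitude_band(toy, bands = list(c(30, 45)))
  expect_equal(sum(allb$mean * allb$n) / sum(allb$n), mean(toy$percent_change))
})

test_that("rank-deficient designs fail loudly", {
  lt <- simulate_loss_table(n_units = 12, seed = 2)
  lt$range_size <- lt$centroid_latitude   # alias the continuous covariates
  expect_error(fit_factorial_glm(lt, 2020), "aliased|rank")
})
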