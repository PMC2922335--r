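# Species x scenario loss table, the factorial general linear model of
# square-root percent habitat loss, and latitude-band summaries.

#' Enumerate the scenario grid
#'
#' Full cross-product of circulation models, emissions levels and threshold
#' rules. Year is handled as separate analyses for the per-species loss GLM,
#' so the per-species scenario count excludes `years` while the richness-map
#' scenario count includes it (2 x 2 x 2 = 8 per species; with 3 years, 24
#' richness-map scenarios).
#'
#' @param gcms,co2_levels,thresholds Non-empty character vectors of levels.
#' @param years Optional numeric vector of horizons.
#' @return Data frame of combinations with attributes
#'   `per_species_scenarios` and `richness_scenarios`.
#' @export
enumerate_scenarios <- function(gcms = c("CGCM3", "HADCM3"),
                                co2_levels = c("high", "low"),
                                thresholds = c("strict", "liberal"),
                                years = NULL) {
  stopifnot(length(gcms) >= 1, length(co2_levels) >= 1, length(thresholds) >= 1)
  args <- list(gcm = gcms, co2 = co2_levels, threshold = thresholds)
  if (!is.null(years)) args$year <- years
  out <- expand.grid(args, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  per_species <- length(gcms) * length(co2_levels) * length(thresholds)
  attr(out, "per_species_scenarios") <- per_species
  attr(out, "richness_scenarios") <- per_species * max(1L, length(years))
  out
}

#' Assemble a loss table from change records
#'
#' One row per species-unit x scenario with the covariates the factorial GLM
#' uses: current range size (cells) and range centroid latitude.
#'
#' @param records List of `change_record`s.
#' @param year Year of each record (vector or scalar, recycled).
#' @param centroid_latitude Centroid latitude of each record's current range
#'   (vector or scalar, recycled).
#' @param gcm,co2 Scenario labels per record (recycled).
#' @return A `loss_table` data frame.
#' @export
build_loss_table <- function(records, year, centroid_latitude, gcm, co2) {
  stopifnot(length(records) >= 1)
  out <- data.frame(
    species = vapply(records, function(r) as.character(r$species), character(1)),
    gcm = rep_len(as.character(gcm), length(records)),
    co2 = rep_len(as.character(co2), length(records)),
    threshold = vapply(records, function(r) as.character(r$threshold), character(1)),
    year = rep_len(year, length(records)),
    current_area = vapply(records, `[[`, numeric(1), "current_area"),
    future_area = vapply(records, `[[`, numeric(1), "future_area"),
    percent_change = vapply(records, `[[`, numeric(1), "percent_change"),
    range_size = vapply(records, `[[`, numeric(1), "current_area"),
    centroid_latitude = rep_len(centroid_latitude, length(records)))
  class(out) <- c("loss_table", class(out))
  out
}

#' Simulate a loss table with known effects
#'
#' Design-structure generator: `n_units` species units crossed with the full
#' 2 GCM x 2 CO2 x 2 threshold grid per year, percent loss built on the
#' square-root scale from configurable unit-level covariate effects plus
#' Gaussian noise, then squared back and capped at 100. Southern and
#' small-ranged units lose more by default, with an emissions effect that
#' fades for later horizons.
#'
#' @param n_units Number of species units (default 35).
#' @param years Horizons (default 2020/2050/2080).
#' @param seed Integer seed.
#' @param effects Named list of coefficients on the square-root-loss scale:
#'   `intercept`, `latitude` (per degree north), `log_range` (per log-cell),
#'   `co2_high`, `threshold_strict`, `gcm_CGCM3`, `year_step` (per horizon
#'   index), `co2_fade` (decay of the CO2 effect per horizon step), `sigma`
#'   (noise SD).
#' @return A `loss_table` data frame with `n_units * 8 * length(years)` rows.
#' @export
simulate_loss_table <- function(n_units = 35, years = c(2020, 2050, 2080),
                                seed = 1L, effects = list()) {
  e <- modifyList(list(intercept = 7, latitude = -0.45, log_range = -0.25,
                       co2_high = 0.6, threshold_strict = 0.3,
                       gcm_CGCM3 = 0.1, year_step = 0.8, co2_fade = 0.5,
                       sigma = 0.6), effects)
  set.seed(seed)
  lat <- runif(n_units, 32, 44)
  size <- round(rlnorm(n_units, meanlog = 9, sdlog = 1))
  grid <- expand.grid(unit = seq_len(n_units), gcm = c("CGCM3", "HADCM3"),
                      co2 = c("high", "low"),
                      threshold = c("strict", "liberal"), year = years,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  yi <- match(grid$year, sort(unique(grid$year))) - 1
  mu <- e$intercept +
    e$latitude * (lat[grid$unit] - 38) +
    e$log_range * (log(size[grid$unit]) - 9) +
    e$co2_high * (grid$co2 == "high") * e$co2_fade^yi +
    e$threshold_strict * (grid$threshold == "strict") +
    e$gcm_CGCM3 * (grid$gcm == "CGCM3") +
    e$year_step * yi
  sqrt_loss <- pmax(mu + rnorm(nrow(grid), 0, e$sigma), 0)
  out <- data.frame(species = paste0("unit_", grid$unit), gcm = grid$gcm,
                    co2 = grid$co2, threshold = grid$threshold,
                    year = grid$year,
                    current_area = size[grid$unit],
                    future_area = NA_real_,
                    percent_change = pmin(sqrt_loss^2, 100),
                    range_size = size[grid$unit],
                    centroid_latitude = lat[grid$unit])
  out$future_area <- round(out$current_area * (1 - out$percent_change / 100))
  class(out) <- c("loss_table", class(out))
  out
}

#' Factorial general linear model of percent habitat loss
#'
#' For one projection year, fits square-root-transformed percent loss
#' (negative changes, i.e. gains, clamped to 0 before the root) on GCM, CO2
#' level and threshold as 2-level factors plus current range size and range
#' centroid latitude as continuous covariates, with all main effects and all
#' two- and three-way interactions (25 single-df terms). F tests use partial
#' (Type III) sums of squares under sum-to-zero contrasts; a sequential
#' (Type I) table is available instead.
#'
#' @param table A loss table (as from [build_loss_table()] or
#'   [simulate_loss_table()]).
#' @param year Which year's rows to analyse.
#' @param ss `"partial"` (Type III, default) or `"sequential"` (Type I).
#' @param sqrt_transform `"clamp"` (default, \eqn{\sqrt{\max(x,0)}}) or
#'   `"signed"` (\eqn{sign(x)\sqrt{|x|}}).
#' @param center Center the continuous covariates (affects interaction
#'   interpretation, not the error df).
#' @return An object of class `anova_table`: data frame with one row per
#'   term (df, sum_sq, mean_sq, F, p) plus an `Error` row, the fitted `lm`
#'   in attribute `fit`, and `n_clamped` gains clamped by the transform.
#' @export
fit_factorial_glm <- function(table, year, ss = c("partial", "sequential"),
                              sqrt_transform = c("clamp", "signed"),
                              center = FALSE) {
  ss <- match.arg(ss)
  sqrt_transform <- match.arg(sqrt_transform)
  d <- table[table$year == year, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for year ", year)
  n_clamped <- sum(d$percent_change < 0)
  d$sqrt_loss <- if (sqrt_transform == "clamp") {
    sqrt(pmax(d$percent_change, 0))
  } else {
    sign(d$percent_change) * sqrt(abs(d$percent_change))
  }
  for (v in c("gcm", "co2", "threshold")) d[[v]] <- factor(d[[v]])
  if (center) {
    d$centroid_latitude <- d$centroid_latitude - mean(d$centroid_latitude)
    d$range_size <- d$range_size - mean(d$range_size)
  }
  fml <- sqrt_loss ~ (gcm + co2 + threshold + centroid_latitude + range_size)^3
  contr <- lapply(c(gcm = 1, co2 = 1, threshold = 1), function(i) "contr.sum")
  fit <- lm(fml, data = d, contrasts = contr)
  p <- length(coef(fit))
  if (fit$rank < p) {
    al <- alias(fit)$Complete
    stop("rank-deficient design; aliased terms: ",
         paste(rownames(al), collapse = ", "))
  }
  if (var(d$sqrt_loss) < 1e-20) {
    # constant response: every term carries zero sum of squares
    tl <- attr(fit$terms, "term.labels")
    terms_df <- data.frame(term = c(tl, "Residuals"),
                           df = c(rep(1L, length(tl)), fit$df.residual),
                           sum_sq = 0, mean_sq = 0, F = NA_real_,
                           p = NA_real_)
  } else if (ss == "partial") {
    a3 <- car::Anova(fit, type = "III")
    a3 <- a3[!rownames(a3) %in% c("(Intercept)"), ]
    terms_df <- data.frame(term = rownames(a3), df = a3$Df,
                           sum_sq = a3[["Sum Sq"]],
                           mean_sq = a3[["Sum Sq"]] / a3$Df,
                           F = a3$`F value`, p = a3$`Pr(>F)`)
  } else {
    a1 <- anova(fit)
    terms_df <- data.frame(term = rownames(a1), df = a1$Df,
                           sum_sq = a1[["Sum Sq"]],
                           mean_sq = a1[["Mean Sq"]],
                           F = a1$`F value`, p = a1$`Pr(>F)`)
  }
  err <- terms_df$term == "Residuals"
  terms_df$term[err] <- "Error"
  terms_df$F[err] <- NA_real_
  terms_df$p[err] <- NA_real_
  out <- terms_df[c(which(!err), which(err)), ]
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  attr(out, "year") <- year
  attr(out, "n_clamped") <- n_clamped
  attr(out, "error_df") <- as.integer(out$df[out$term == "Error"])
  class(out) <- c("anova_table", class(out))
  out
}

#' Summaries of percent loss by latitude band
#'
#' Mean and min-max of percent habitat change per latitude band x year x
#' threshold (the quantities typically displayed against centroid latitude).
#' Bands with no species are reported as missing rows, not errors.
#'
#' @param table A loss table.
#' @param bands List of `c(lo, hi)` latitude intervals (degrees, inclusive
#'   lower / exclusive upper bound; must be disjoint).
#' @return Data frame with band, year, threshold, n, mean, min, max.
#' @export
summarize_by_latitude_band <- function(table,
                                       bands = list(c(32, 34), c(36, 38),
                                                    c(42, 44))) {
  lo <- vapply(bands, `[`, numeric(1), 1)
  hi <- vapply(bands, `[`, numeric(1), 2)
  o <- order(lo)
  if (any(lo >= hi) || any(head(hi[o], -1) > lo[o][-1])) {
    stop("latitude bands must be disjoint intervals c(lo, hi)")
  }
  combos <- expand.grid(band = seq_along(bands),
                        year = sort(unique(table$year)),
                        threshold = sort(unique(table$threshold)),
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    b <- combos$band[i]
    sel <- table$centroid_latitude >= lo[b] & table$centroid_latitude < hi[b] &
      table$year == combos$year[i] & table$threshold == combos$threshold[i]
    x <- table$percent_change[sel]
    data.frame(band = sprintf("[%g,%g)", lo[b], hi[b]),
               year = combos$year[i], threshold = combos$threshold[i],
               n = sum(sel),
               mean = if (length(x)) mean(x) else NA_real_,
               min = if (length(x)) min(x) else NA_real_,
               max = if (length(x)) max(x) else NA_real_)
  })
  do.call(rbind, rows)
}
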