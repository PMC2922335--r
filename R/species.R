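# Virtual species with a known deterministic climate response, plus
# occurrence / target-group background sampling and coarse known-range masks.

#' Virtual species with a known climate response
#'
#' True suitability is the logistic of a linear + quadratic function of the
#' covariates, so the truth is deterministic, bounded in \[0, 1\], and serves
#' as the oracle for recovery tests downstream.
#'
#' @param name Species label.
#' @param linear,quadratic Numeric coefficient vectors, one entry per
#'   covariate layer (the quadratic term multiplies the squared covariate).
#' @param intercept Scalar intercept of the linear predictor.
#' @param suitability_threshold Suitability value defining the species' true
#'   range (cells with true suitability at or above it).
#' @return An object of class `virtual_species`.
#' @export
virtual_species <- function(name, linear, quadratic = NULL, intercept = 0,
                            suitability_threshold = 0.5) {
  if (is.null(quadratic)) quadratic <- numeric(length(linear))
  stopifnot(length(linear) == length(quadratic), is.finite(intercept),
            suitability_threshold > 0, suitability_threshold < 1)
  structure(list(name = as.character(name), linear = linear,
                 quadratic = quadratic, intercept = intercept,
                 suitability_threshold = suitability_threshold),
            class = "virtual_species")
}

#' Unimodal niche species from optima and breadths
#'
#' Convenience constructor: suitability
#' \eqn{\mathrm{logit}^{-1}(a - \sum_l (x_l - \mu_l)^2 / (2\sigma_l^2))}
#' expanded into the linear/quadratic form of [virtual_species()]. Layers with
#' `breadth = Inf` (or NA optimum) do not enter the niche.
#'
#' @param name Species label.
#' @param optimum Per-layer niche optimum (covariate units; NA = unused layer).
#' @param breadth Per-layer niche breadth \eqn{\sigma_l} (covariate units).
#' @param peak Suitability at the optimum (0-1).
#' @param suitability_threshold Passed to [virtual_species()].
#' @return A `virtual_species`.
#' @export
niche_species <- function(name, optimum, breadth, peak = 0.95,
                          suitability_threshold = 0.5) {
  stopifnot(length(optimum) == length(breadth), peak > 0, peak < 1)
  d <- ifelse(is.na(optimum) | !is.finite(breadth), 0, 1 / (2 * breadth^2))
  mu <- ifelse(is.na(optimum), 0, optimum)
  virtual_species(name,
                  linear = 2 * d * mu,
                  quadratic = -d,
                  intercept = qlogis(peak) - sum(d * mu^2),
                  suitability_threshold = suitability_threshold)
}

#' Random virtual species adapted to a landscape
#'
#' Draws a unimodal niche whose optima sit at random quantiles of the
#' landscape's covariates, with breadths proportional to the covariate
#' standard deviations, on `n_active` randomly chosen layers. The quantile
#' window and breadth range control how range-restricted the species is.
#'
#' @param stack A `climate_stack`.
#' @param seed Integer seed.
#' @param n_active Number of covariates the species responds to.
#' @param name Species label.
#' @param optimum_quantiles Range of quantiles the optima are drawn from.
#' @param breadth_range Breadth as a multiple of the layer SD (range).
#' @param peak,suitability_threshold Passed to [niche_species()].
#' @return A `virtual_species`.
#' @export
random_virtual_species <- function(stack, seed, n_active = 3,
                                   name = paste0("vsp_", seed),
                                   optimum_quantiles = c(0.15, 0.85),
                                   breadth_range = c(0.35, 0.8),
                                   peak = 0.95, suitability_threshold = 0.5) {
  set.seed(seed)
  L <- n_layers(stack)
  n_active <- min(n_active, L)
  act <- sample(L, n_active)
  optimum <- rep(NA_real_, L); breadth <- rep(Inf, L)
  for (l in act) {
    v <- stack$values[, , l]
    optimum[l] <- quantile(v, runif(1, optimum_quantiles[1], optimum_quantiles[2]),
                           na.rm = TRUE, names = FALSE)
    breadth[l] <- runif(1, breadth_range[1], breadth_range[2]) * sd(v, na.rm = TRUE)
  }
  niche_species(name, optimum, breadth, peak, suitability_threshold)
}

#' True suitability of a virtual species on a landscape
#'
#' Per-cell logistic of the species' linear + quadratic predictor; the truth
#' oracle every recovery test compares against.
#'
#' @param species A `virtual_species` whose coefficient count matches the
#'   stack's layer count.
#' @param stack A `climate_stack`.
#' @return A `suitability_surface` with the `logistic` slot filled (values in
#'   \[0, 1\]) and `source = "truth"`.
#' @export
true_suitability <- function(species, stack) {
  stopifnot(inherits(species, "virtual_species"), inherits(stack, "climate_stack"))
  if (length(species$linear) != n_layers(stack)) {
    stop("species has ", length(species$linear), " coefficients but the stack has ",
         n_layers(stack), " layers")
  }
  g <- stack$grid
  eta <- matrix(species$intercept, g$n_rows, g$n_cols)
  for (l in seq_len(n_layers(stack))) {
    v <- stack$values[, , l]
    eta <- eta + species$linear[l] * v + species$quadratic[l] * v^2
  }
  suitability_surface(grid = g, logistic = plogis(eta), source = "truth")
}

#' True binary range of a virtual species
#'
#' Single source of truth for range area: cells whose true suitability is at
#' or above the species' threshold.
#'
#' @inheritParams true_suitability
#' @return A `binary_range`.
#' @export
true_range <- function(species, stack) {
  suit <- true_suitability(species, stack)$logistic
  binary_range(suit >= species$suitability_threshold, stack$grid,
               provenance = list(species = species$name, scenario = "truth",
                                 threshold = "true_suitability"))
}

#' Collection-bias surface
#'
#' Emulates museum-record bias: sampling intensity concentrated around a few
#' collection foci (Gaussian bumps) on top of a uniform floor.
#'
#' @param stack A `climate_stack`.
#' @param n_foci Number of collection foci.
#' @param sd_cells Gaussian radius of each focus, in cells.
#' @param strength Peak intensity of a focus relative to the uniform floor.
#' @param seed Integer seed.
#' @return Matrix of nonnegative sampling weights.
#' @export
collection_bias_surface <- function(stack, n_foci = 3, sd_cells = 8,
                                    strength = 9, seed = 1L) {
  g <- stack$grid
  set.seed(seed)
  fr <- sample(g$n_rows, n_foci, replace = TRUE)
  fc <- sample(g$n_cols, n_foci, replace = TRUE)
  b <- matrix(1, g$n_rows, g$n_cols)
  rows <- matrix(seq_len(g$n_rows), g$n_rows, g$n_cols)
  cols <- matrix(seq_len(g$n_cols), g$n_rows, g$n_cols, byrow = TRUE)
  for (k in seq_len(n_foci)) {
    b <- b + strength * exp(-((rows - fr[k])^2 + (cols - fc[k])^2) / (2 * sd_cells^2))
  }
  b
}

#' Sample presence points for a virtual species
#'
#' Cells are drawn (with replacement) with probability proportional to true
#' suitability times the bias surface; points are snapped to cell centers.
#' Sets intended for model fitting must carry more than 30 records, mirroring
#' the minimum-sample rule applied to museum occurrence data.
#'
#' @param species A `virtual_species`.
#' @param stack A `climate_stack`.
#' @param n Number of presence records (>= 1).
#' @param bias Optional nonnegative weight matrix (default uniform).
#' @param seed Integer seed.
#' @param for_modelling If `TRUE`, reject sets of 30 or fewer records.
#' @return An `occurrence_set`: data frame `points` (species, lon, lat, row,
#'   col, cell) plus metadata.
#' @export
sample_occurrences <- function(species, stack, n, bias = NULL, seed = 1L,
                               for_modelling = FALSE) {
  stopifnot(n >= 1)
  if (for_modelling && n <= 30) {
    stop("sets used for modelling need more than 30 point locations (got ", n, ")")
  }
  g <- stack$grid
  suit <- true_suitability(species, stack)$logistic
  if (is.null(bias)) bias <- matrix(1, g$n_rows, g$n_cols)
  stopifnot(all(dim(bias) == dim(suit)))
  if (any(bias < 0, na.rm = TRUE)) stop("bias surface must be nonnegative")
  w <- suit * bias
  w[!valid_cell_mask(stack)] <- 0
  w[is.na(w)] <- 0
  if (sum(w) <= 0) stop("all sampling weights are zero")
  set.seed(seed)
  idx <- sample.int(length(w), n, replace = TRUE, prob = as.vector(w))
  rc <- index_to_rowcol(g, idx)
  pts <- data.frame(species = species$name,
                    lon = cell_center_lon(g, rc$col),
                    lat = cell_center_lat(g, rc$row),
                    row = rc$row, col = rc$col, cell = as.integer(idx))
  structure(list(points = pts, species = species$name, n = n, grid = g,
                 for_modelling = for_modelling),
            class = "occurrence_set")
}

#' Pooled target-group background
#'
#' Unions all species' occurrence cells (deduplicated by cell) into the single
#' background set every model fit uses, so sampling bias shared by the
#' presences and the background cancels. An optional `pool_size` caps the pool
#' by seeded subsampling without replacement (the study mirroring the original
#' design uses 4215).
#'
#' @param all_occurrences Non-empty list of `occurrence_set`s on one grid.
#' @param pool_size Optional target pool size.
#' @param seed Seed used only when subsampling to `pool_size`.
#' @return A `background_set` (points at cell centers, one per unique cell).
#' @export
build_target_group_background <- function(all_occurrences, pool_size = NULL,
                                          seed = 1L) {
  if (length(all_occurrences) == 0) stop("need at least one occurrence set")
  stopifnot(all(vapply(all_occurrences, inherits, TRUE, "occurrence_set")))
  g <- all_occurrences[[1]]$grid
  for (o in all_occurrences) stop_if_grid_mismatch(g, o$grid, "occurrence sets")
  cells <- unique(unlist(lapply(all_occurrences, function(o) o$points$cell)))
  if (length(cells) == 0) stop("occurrence sets are all empty")
  cells <- sort(cells)
  if (!is.null(pool_size) && length(cells) > pool_size) {
    set.seed(seed)
    cells <- sort(sample(cells, pool_size))
  }
  rc <- index_to_rowcol(g, cells)
  pts <- data.frame(species = "background",
                    lon = cell_center_lon(g, rc$col),
                    lat = cell_center_lat(g, rc$row),
                    row = rc$row, col = rc$col, cell = cells)
  structure(list(points = pts, n = length(cells), grid = g),
            class = "background_set")
}

#' Synthetic known range at county-like resolution
#'
#' Dilates the species' true range onto coarse blocks of `coarsening` cells a
#' side (anchored at the NW corner): a block containing any true-range cell is
#' wholly included. Emulates the over-coverage of county-level distribution
#' maps; always a superset of the true range.
#'
#' @param species A `virtual_species`.
#' @param stack A `climate_stack`.
#' @param coarsening Integer block size in cells (>= 1; 1 = exact true range).
#' @return A `binary_range`.
#' @export
generate_known_range <- function(species, stack, coarsening = 5) {
  stopifnot(coarsening >= 1)
  coarsening <- as.integer(coarsening)
  truth <- true_range(species, stack)
  if (coarsening == 1L) {
    truth$provenance$threshold <- "known_range"
    return(truth)
  }
  m <- truth$values
  g <- stack$grid
  br <- ((seq_len(g$n_rows) - 1L) %/% coarsening) + 1L
  bc <- ((seq_len(g$n_cols) - 1L) %/% coarsening) + 1L
  # block occupancy: any true cell lights the whole block
  occ <- rowsum(t(rowsum(m, br)), bc)   # blocks_c x blocks_r counts
  block_on <- t(occ) > 0                # blocks_r x blocks_c
  out <- block_on[br, bc, drop = FALSE] * 1L
  binary_range(out, g, provenance = list(species = species$name,
                                         scenario = "current",
                                         threshold = "known_range"))
}
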