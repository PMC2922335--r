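# Synthetic climate landscapes: correlated, spatially autocorrelated
# covariate stacks that stand in for gridded bioclimatic layers.

#' Specification of a synthetic climate landscape
#'
#' Defines the grid, the number of bioclimatic covariates, their roles
#' (temperature-like layers receive a monotone north-south gradient,
#' precipitation-like layers do not), the spatial autocorrelation range of the
#' smoothed Gaussian fields, and the target inter-layer correlation matrix.
#'
#' The defaults emulate an 11-variable bioclimatic stack (6 temperature-like,
#' 5 precipitation-like summaries) on a 0.0083-degree (~1 km) WGS84 grid.
#'
#' @param n_rows,n_cols Grid size in cells (each at least 2).
#' @param cell_size Cell size in decimal degrees.
#' @param origin NW-corner `c(lon, lat)`.
#' @param n_layers Number of covariate layers (>= 1).
#' @param layer_roles Character vector (`"temperature"` / `"precipitation"`),
#'   one per layer; default: first `ceiling(6/11 * n_layers)` temperature.
#' @param autocorrelation_range Gaussian smoothing range in cells (>= 0;
#'   0 gives spatially white noise).
#' @param target_correlation Symmetric PSD correlation matrix
#'   (`n_layers x n_layers`, unit diagonal); default AR(1)-like with
#'   \eqn{\rho = 0.55^{|i-j|}}.
#' @param gradient_strength North-south gradient amplitude added to
#'   temperature-like layers, in units of the field's standard deviation.
#' @param seed Integer RNG seed; the generated stack is a pure function of
#'   the spec (including the seed).
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(n_rows, n_cols, cell_size = 0.0083,
                           origin = c(-85, 42), n_layers = 11,
                           layer_roles = NULL, autocorrelation_range = 5,
                           target_correlation = NULL,
                           gradient_strength = 1.5, seed = 1L) {
  stopifnot(n_rows >= 2, n_cols >= 2, cell_size > 0, n_layers >= 1,
            autocorrelation_range >= 0)
  if (is.null(layer_roles)) {
    n_temp <- max(1L, ceiling(6 / 11 * n_layers))
    layer_roles <- c(rep("temperature", n_temp),
                     rep("precipitation", n_layers - n_temp))
  }
  stopifnot(length(layer_roles) == n_layers,
            all(layer_roles %in% c("temperature", "precipitation")))
  if (is.null(target_correlation)) {
    target_correlation <- 0.55^abs(outer(seq_len(n_layers), seq_len(n_layers), "-"))
  }
  C <- target_correlation
  if (!is.matrix(C) || nrow(C) != n_layers || ncol(C) != n_layers ||
      max(abs(C - t(C))) > 1e-8 || max(abs(diag(C) - 1)) > 1e-8) {
    stop("target_correlation must be a symmetric correlation matrix with unit diagonal")
  }
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("target_correlation must be positive semidefinite")
  }
  structure(list(grid = grid_meta(n_rows, n_cols, cell_size, origin),
                 n_layers = as.integer(n_layers), layer_roles = layer_roles,
                 autocorrelation_range = autocorrelation_range,
                 target_correlation = C,
                 gradient_strength = gradient_strength,
                 seed = as.integer(seed)),
            class = "landscape_spec")
}

# banded row-normalized Gaussian smoothing matrix; r = 0 -> identity
gaussian_kernel_matrix <- function(n, r) {
  if (r <= 0) return(diag(n))
  half <- ceiling(3 * r)
  d <- outer(seq_len(n), seq_len(n), "-")
  K <- exp(-d^2 / (2 * r^2))
  K[abs(d) > half] <- 0
  K / rowSums(K)
}

#' Generate a synthetic climate stack
#'
#' Builds `n_layers` spatially autocorrelated covariate fields: Gaussian white
#' noise is cross-correlated across layers through the symmetric square root
#' of the target correlation matrix, smoothed with a separable Gaussian
#' kernel, standardized, given a monotone north-south gradient on
#' temperature-like layers (warmer toward the south), and mapped to
#' plausible units (degrees C-like for temperature, mm-like for
#' precipitation). Deterministic given the spec.
#'
#' Note the shared gradient raises the realized correlation between
#' temperature-like layers above the target; the target is matched for
#' gradient-free layers.
#'
#' @param spec A [landscape_spec()].
#' @return An object of class `climate_stack`: a `n_rows x n_cols x n_layers`
#'   array plus grid metadata, layer names and roles.
#' @export
generate_climate_stack <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  g <- spec$grid
  nr <- g$n_rows; nc <- g$n_cols; L <- spec$n_layers
  set.seed(spec$seed)
  eig <- eigen(spec$target_correlation, symmetric = TRUE)
  Csqrt <- eig$vectors %*% (sqrt(pmax(eig$values, 0)) * t(eig$vectors))
  W <- matrix(rnorm(nr * nc * L), nrow = nr * nc, ncol = L) %*% Csqrt
  Kr <- gaussian_kernel_matrix(nr, spec$autocorrelation_range)
  Kc <- gaussian_kernel_matrix(nc, spec$autocorrelation_range)
  lat <- cell_center_lat(g, seq_len(nr))
  southness <- (mean(lat) - lat) / (diff(range(lat)) / 2)  # -1 (N) .. +1 (S)
  vals <- array(NA_real_, dim = c(nr, nc, L))
  names_out <- character(L)
  idx_role <- c(temperature = 0L, precipitation = 0L)
  for (l in seq_len(L)) {
    M <- Kr %*% matrix(W[, l], nr, nc) %*% t(Kc)
    M <- (M - mean(M)) / sd(M)
    role <- spec$layer_roles[l]
    if (role == "temperature") {
      M <- M + spec$gradient_strength * southness  # recycles down columns
      M <- 15 + 4 * M
    } else {
      M <- 1000 + 300 * M
    }
    idx_role[role] <- idx_role[role] + 1L
    names_out[l] <- paste0(substr(role, 1, 4), "_", idx_role[role])
    vals[, , l] <- M
  }
  structure(list(values = vals, grid = g, layer_names = names_out,
                 layer_roles = spec$layer_roles, nodata_mask = NULL),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("climate_stack: %d layers on %d x %d grid (%s)\n",
              dim(x$values)[3], x$grid$n_rows, x$grid$n_cols,
              paste(x$layer_names, collapse = ", ")))
  invisible(x)
}

n_layers <- function(stack) dim(stack$values)[3]

# logical matrix of usable cells (shared NODATA convention: a cell missing in
# any layer is excluded everywhere)
valid_cell_mask <- function(stack) {
  ok <- !apply(is.na(stack$values), c(1, 2), any)
  if (!is.null(stack$nodata_mask)) ok <- ok & !stack$nodata_mask
  ok
}

# covariates of selected cells (linear indices); cells x layers matrix
stack_values_at <- function(stack, idx) {
  nrnc <- prod(dim(stack$values)[1:2])
  out <- vapply(seq_len(n_layers(stack)),
                function(l) stack$values[(l - 1) * nrnc + idx],
                numeric(length(idx)))
  if (length(idx) == 1L) out <- matrix(out, nrow = 1)
  colnames(out) <- stack$layer_names
  out
}

#' Future climate scenario as additive layer offsets
#'
#' @param gcm,co2,year Scenario labels (e.g. `"CGCM3"`, `"high"`, `2050`).
#' @param offsets Numeric vector of per-layer additive offsets, in each
#'   layer's units; a zero vector leaves a stack unchanged.
#' @return An object of class `scenario_delta`.
#' @export
scenario_delta <- function(gcm, co2, year, offsets) {
  stopifnot(is.numeric(offsets))
  structure(list(gcm = as.character(gcm), co2 = as.character(co2),
                 year = year, offsets = offsets),
            class = "scenario_delta")
}

#' Apply a scenario delta to a climate stack
#'
#' @param stack A `climate_stack`.
#' @param delta A [scenario_delta()] whose offset count matches the stack's
#'   layer count.
#' @return A new `climate_stack`; the input is untouched.
#' @export
apply_scenario <- function(stack, delta) {
  stopifnot(inherits(stack, "climate_stack"), inherits(delta, "scenario_delta"))
  if (length(delta$offsets) != n_layers(stack)) {
    stop("scenario delta has ", length(delta$offsets),
         " offsets but the stack has ", n_layers(stack), " layers")
  }
  out <- stack
  for (l in seq_len(n_layers(stack))) {
    out$values[, , l] <- stack$values[, , l] + delta$offsets[l]
  }
  out
}

#' Synthetic scenario ensemble
#'
#' Builds additive deltas for every circulation model x emissions x horizon
#' combination. Temperature-like layers warm and precipitation-like layers dry
#' progressively with the horizon index; the `gcm_warming` and
#' `co2_multiplier` arguments set the per-GCM and per-emissions scaling, so
#' the ensemble brackets milder and harsher futures the way a small GCM/SRES
#' ensemble does.
#'
#' @param layer_roles Character vector of layer roles (as in the stack).
#' @param years Numeric vector of horizons (ordered; index drives magnitude).
#' @param gcm_warming Named per-GCM warming at the first horizon (layer units).
#' @param co2_multiplier Named per-emissions multiplicative factor.
#' @param precip_drying Precipitation offset at the first horizon for the
#'   *first* named GCM (layer units; second GCM dries half as much).
#' @return List of [scenario_delta()] objects, one per combination.
#' @export
default_scenario_deltas <- function(layer_roles,
                                    years = c(2020, 2050, 2080),
                                    gcm_warming = c(CGCM3 = 1.0, HADCM3 = 0.8),
                                    co2_multiplier = c(high = 1.3, low = 0.9),
                                    precip_drying = -40) {
  is_temp <- layer_roles == "temperature"
  out <- list()
  for (yi in seq_along(years)) for (g in names(gcm_warming))
    for (cc in names(co2_multiplier)) {
      off <- numeric(length(layer_roles))
      warm <- gcm_warming[[g]] * co2_multiplier[[cc]] * yi
      dry <- precip_drying * co2_multiplier[[cc]] * yi *
        (if (g == names(gcm_warming)[1]) 1 else 0.5)
      off[is_temp] <- warm
      off[!is_temp] <- dry
      out[[length(out) + 1L]] <- scenario_delta(g, cc, years[yi], off)
    }
  out
}
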