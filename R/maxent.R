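# The maximum-entropy presence-background model: the fitted raw (Gibbs)
# distribution over background cells, plus the cumulative and logistic
# output transforms.

#' Continuous suitability surface
#'
#' Container for the three monotone output scales of a maxent model (or for
#' the known truth of a virtual species, which fills only `logistic`). The
#' model's background raw values and raw-distribution entropy ride along so
#' the cumulative and logistic transforms are self-contained.
#'
#' @param grid A [grid_meta()].
#' @param raw,cumulative,logistic Optional value matrices on the grid.
#' @param bg_raw Raw values at the model's background cells.
#' @param entropy Entropy of the raw distribution over the background.
#' @param source `"model"` or `"truth"`.
#' @return An object of class `suitability_surface`.
#' @export
suitability_surface <- function(grid, raw = NULL, cumulative = NULL,
                                logistic = NULL, bg_raw = NULL,
                                entropy = NULL, source = "model") {
  structure(list(grid = grid, raw = raw, cumulative = cumulative,
                 logistic = logistic, bg_raw = bg_raw, entropy = entropy,
                 source = source),
            class = "suitability_surface")
}

#' @export
print.suitability_surface <- function(x, ...) {
  scales <- c("raw", "cumulative", "logistic")
  have <- scales[!vapply(x[scales], is.null, TRUE)]
  cat(sprintf("suitability_surface (%s): %d x %d, scales: %s\n", x$source,
              x$grid$n_rows, x$grid$n_cols, paste(have, collapse = ", ")))
  invisible(x)
}

#' Fit a maxent model from covariate matrices
#'
#' Low-level fitting interface: maximizes the penalized log-likelihood
#' \deqn{\frac1m\sum_{presences}\log q(x_i) - \sum_j \beta_j|\lambda_j|}
#' of the Gibbs distribution \eqn{q(x)\propto e^{\lambda\cdot f(x)}} over the
#' background cells, by cyclic coordinate descent with soft-thresholding
#' (compiled core). With all \eqn{\beta = 0} the fit matches the presence
#' feature means exactly (the minimum-relative-entropy solution).
#'
#' @param Xp Presence covariate matrix (records x layers).
#' @param Xb Background covariate matrix (cells x layers).
#' @param features Optional [build_features()] result; built from `Xb` with
#'   the sample-size rule when omitted.
#' @param sample_size Presence count used for the feature rule and default
#'   regularization (defaults to `nrow(Xp)`).
#' @param beta_multiplier Global multiplier on the default per-feature
#'   regularization.
#' @param beta Optional explicit per-feature regularization vector
#'   (overrides the defaults; use 0 for an unpenalized fit).
#' @param add_samples_to_background Include presence records among the
#'   background cells of the fitted distribution (default, as in the
#'   reference implementation; guarantees the moment constraints are
#'   feasible).
#' @param tol Convergence tolerance on the penalized log-likelihood
#'   improvement per sweep.
#' @param max_sweeps Maximum coordinate-descent sweeps; hitting it raises a
#'   warning and returns the best iterate.
#' @return An object of class `maxent_model`.
#' @export
maxent_fit_core <- function(Xp, Xb, features = NULL,
                            sample_size = nrow(Xp), beta_multiplier = 1,
                            beta = NULL, add_samples_to_background = TRUE,
                            tol = 1e-6, max_sweeps = 2000L) {
  Xp <- as.matrix(Xp); Xb <- as.matrix(Xb)
  stopifnot(nrow(Xp) >= 1, nrow(Xb) >= 2, ncol(Xp) == ncol(Xb))
  if (anyNA(Xp) || anyNA(Xb) || !all(is.finite(Xp)) || !all(is.finite(Xb))) {
    stop("covariates must be finite")
  }
  Xbg <- Xb
  if (add_samples_to_background) {
    Xbg <- rbind(Xb, Xp)
    Xbg <- Xbg[!duplicated(Xbg), , drop = FALSE]
  }
  # presences added to the background are part of it, so feature scaling and
  # clamp ranges come from the combined background; this keeps training-stack
  # predictions at background cells identical to the fitted distribution
  if (is.null(features)) features <- build_features(Xbg, sample_size)
  Fb <- evaluate_features(features, Xbg, clamp = FALSE)
  Fp <- evaluate_features(features, Xp, clamp = FALSE)
  pbar <- colMeans(Fp)
  if (is.null(beta)) {
    beta <- feature_betas(features, Fp, Fb, sample_size, beta_multiplier)
  } else if (length(beta) == 1L) {
    beta <- rep(beta, ncol(Fb))
  }
  stopifnot(length(beta) == ncol(Fb), all(beta >= 0))
  fit <- maxent_cd(Fb, pbar, beta, tol, as.integer(max_sweeps))
  if (!fit$converged) {
    warning("maxent fit did not converge in ", max_sweeps,
            " sweeps; returning the best iterate")
  }
  # re-evaluate the linear predictor from the final weights: the optimizer's
  # incrementally updated eta carries rounding that spuriously breaks exact
  # ties between cells with identical weighted feature sums
  eta <- as.vector(Fb %*% fit$lambda)
  fit$logZ <- logsumexp(eta)
  q <- exp(eta - fit$logZ)
  H <- -sum(q * log(pmax(q, 1e-300)))
  training_raw <- as.vector(exp(Fp %*% fit$lambda - fit$logZ))
  structure(list(lambdas = setNames(fit$lambda, features$defs$name),
                 features = features, logZ = fit$logZ, entropy = H,
                 beta = beta, beta_multiplier = beta_multiplier,
                 sample_size = sample_size,
                 bg_raw = q, bg_X = Xbg,
                 training_presence_raw = training_raw,
                 converged = fit$converged, sweeps = fit$sweeps,
                 objective = fit$objective,
                 clamp_on_project = TRUE, grid = NULL, layer_names = colnames(Xb)),
            class = "maxent_model")
}

#' Fit a maxent model to an occurrence set
#'
#' Extracts covariates at the (cell-deduplicated) presence cells and at the
#' target-group background cells and calls [maxent_fit_core()]. Duplicate
#' presences within a cell are collapsed before fitting, mirroring the
#' intersection of museum records with a raster grid.
#'
#' @param presences An `occurrence_set`.
#' @param background A `background_set` (the pooled target-group background).
#' @param stack The training `climate_stack`.
#' @inheritParams maxent_fit_core
#' @param ... Passed to [maxent_fit_core()] (e.g. `beta_multiplier`, `beta`).
#' @return A `maxent_model` carrying the training grid.
#' @export
fit_maxent <- function(presences, background, stack, features = NULL, ...) {
  stopifnot(inherits(presences, "occurrence_set"),
            inherits(background, "background_set"),
            inherits(stack, "climate_stack"))
  stop_if_grid_mismatch(presences$grid, stack$grid, "presences and stack")
  stop_if_grid_mismatch(background$grid, stack$grid, "background and stack")
  pcells <- unique(presences$points$cell)
  Xp <- stack_values_at(stack, pcells)
  Xb <- stack_values_at(stack, background$points$cell)
  model <- maxent_fit_core(Xp, Xb, features = features,
                           sample_size = length(pcells), ...)
  model$grid <- stack$grid
  model$species <- presences$species
  model$presence_cells <- pcells
  model
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(paste0("maxent_model%s: %d features (%d nonzero), %d background",
                     " cells, m = %d, %sconverged in %d sweeps\n"),
              if (is.null(x$species)) "" else paste0(" [", x$species, "]"),
              length(x$lambdas), sum(x$lambdas != 0), length(x$bg_raw),
              x$sample_size, if (x$converged) "" else "NOT ", x$sweeps))
  invisible(x)
}

#' Predict the raw suitability surface
#'
#' \eqn{raw(x) = e^{\lambda\cdot f(x)}/Z} with \eqn{Z} the training-background
#' normalizer, so raw values over the training background sum to 1 on any
#' stack that reproduces the training climates. When projecting, covariates
#' are clamped to the training background range by default.
#'
#' @param model A `maxent_model`.
#' @param stack A `climate_stack` with the model's layers.
#' @param clamp Clamp covariates to training ranges (default `TRUE`).
#' @return A `suitability_surface` with `raw` filled.
#' @export
predict_raw <- function(model, stack, clamp = model$clamp_on_project) {
  stopifnot(inherits(model, "maxent_model"), inherits(stack, "climate_stack"))
  if (!identical(unname(model$layer_names), unname(stack$layer_names))) {
    stop("stack layers do not match the model's feature sources")
  }
  g <- stack$grid
  ok <- valid_cell_mask(stack)
  idx <- which(ok)
  X <- stack_values_at(stack, idx)
  Fx <- evaluate_features(model$features, X, clamp = clamp)
  eta <- matrix(NA_real_, g$n_rows, g$n_cols)
  eta[idx] <- as.vector(Fx %*% model$lambdas) - model$logZ
  out <- suitability_surface(grid = g, raw = exp(eta), bg_raw = model$bg_raw,
                             entropy = model$entropy, source = "model")
  # log-raw kept alongside: exp() underflows for strongly unsuitable cells,
  # which would collapse distinct scores into ties in rank-based statistics
  out$log_raw <- eta
  out
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# cumulative transform of arbitrary values against a background raw vector
cumulative_from_raw <- function(values, bg_raw) {
  o <- order(bg_raw)
  sorted <- bg_raw[o]
  csum <- cumsum(sorted)
  # ties inclusive: all background mass at raw <= value counts
  nas <- is.na(values)
  pos <- findInterval(values, sorted)
  pos[nas] <- 0L
  out <- numeric(length(values))
  out[pos > 0] <- csum[pos[pos > 0]]
  out[nas] <- NA_real_
  100 * out / sum(bg_raw)
}

#' Cumulative output scale
#'
#' The cumulative value of a cell is 100 times the total raw probability mass
#' of background cells whose raw value does not exceed the cell's (inclusive
#' tie rule: equal raw values share one cumulative value, and the
#' highest-raw cell scores exactly 100).
#'
#' @param surface A `suitability_surface` with `raw` and `bg_raw`.
#' @return The surface with `cumulative` filled (0-100).
#' @export
to_cumulative <- function(surface) {
  stopifnot(inherits(surface, "suitability_surface"))
  if (is.null(surface$raw) || is.null(surface$bg_raw)) {
    stop("cumulative transform needs raw values and the model background")
  }
  cum <- cumulative_from_raw(as.vector(surface$raw), surface$bg_raw)
  surface$cumulative <- matrix(cum, surface$grid$n_rows, surface$grid$n_cols)
  surface
}

#' Logistic output scale
#'
#' \eqn{logistic(x) = r e^H / (1 + r e^H)} with \eqn{r} the raw value and
#' \eqn{H} the entropy of the raw distribution over the background; a strictly
#' increasing transform of raw, in (0, 1), equal to 0.5 everywhere for a
#' uniform raw distribution.
#'
#' @param surface A `suitability_surface` with `raw`.
#' @param entropy Raw-distribution entropy (defaults to the surface's own).
#' @return The surface with `logistic` filled.
#' @export
to_logistic <- function(surface, entropy = surface$entropy) {
  stopifnot(inherits(surface, "suitability_surface"))
  if (is.null(surface$raw) || is.null(entropy)) {
    stop("logistic transform needs raw values and the model entropy")
  }
  re <- surface$raw * exp(entropy)
  surface$logistic <- re / (1 + re)
  surface
}
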