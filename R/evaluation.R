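# AUC against background and the null-model significance test built from
# random draws of the target-group background pool.

#' Rank-based presence-background AUC
#'
#' Mann-Whitney form: the fraction of (presence, background) score pairs in
#' which the presence outscores the background point, ties counted 0.5.
#' Invariant under strictly monotone transforms of the scores, so raw,
#' cumulative and logistic scales give the same value.
#'
#' @param presence_scores,background_scores Non-empty numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc_scores <- function(presence_scores, background_scores) {
  n1 <- length(presence_scores); n2 <- length(background_scores)
  if (n1 == 0 || n2 == 0) stop("both score sets must be non-empty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' AUC of a suitability surface at point sets
#'
#' Extracts surface scores at presence and background point locations and
#' computes the presence-vs-background AUC ([auc_scores()]); this is the
#' training AUC when evaluated at the training points.
#'
#' @param surface A `suitability_surface` (any scale; raw preferred).
#' @param presences An `occurrence_set` (or data frame with `row`/`col`).
#' @param background A `background_set` (or data frame with `row`/`col`).
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(surface, presences, background) {
  stopifnot(inherits(surface, "suitability_surface"))
  vals <- surface$log_raw   # underflow-safe ordering of the raw scale
  if (is.null(vals)) vals <- surface$raw
  if (is.null(vals)) vals <- surface$logistic
  if (is.null(vals)) vals <- surface$cumulative
  if (is.null(vals)) stop("surface carries no values")
  pts <- function(x) if (is.data.frame(x)) x else x$points
  p <- pts(presences); b <- pts(background)
  if (nrow(p) == 0 || nrow(b) == 0) stop("point sets must be non-empty")
  sp <- vals[cbind(p$row, p$col)]
  sb <- vals[cbind(b$row, b$col)]
  auc_scores(sp, sb)
}

#' Null AUC distribution from the background pool
#'
#' For each replicate, draws `sample_size` points from the target-group
#' background pool without replacement, fits the full maxent pipeline
#' treating them as presences (same feature rule and regularization as real
#' fits), and records the training AUC. The observed AUC of a real species is
#' later compared against the 95th percentile of this distribution.
#'
#' @param background_pool A `background_set`.
#' @param stack The `climate_stack` supplying covariates.
#' @param sample_size Points per null replicate (at most the pool size).
#' @param n_replicates Number of replicates (>= 1).
#' @param config Optional list overriding pipeline settings: `classes`,
#'   `n_hinge_knots`, `n_threshold_knots`, `beta_multiplier`, `tol`,
#'   `max_sweeps`.
#' @param seed Integer seed; the distribution is deterministic given it.
#' @return An object of class `null_distribution` with `auc_values` and
#'   `percentile_95` (empirical 95th percentile).
#' @export
build_null_distribution <- function(background_pool, stack, sample_size,
                                    n_replicates, config = list(), seed = 1L) {
  stopifnot(inherits(background_pool, "background_set"),
            inherits(stack, "climate_stack"), n_replicates >= 1)
  n_pool <- background_pool$n
  if (sample_size > n_pool) {
    stop("sample_size (", sample_size, ") exceeds the background pool (",
         n_pool, ")")
  }
  prep <- null_fit_context(background_pool, stack, sample_size, config)
  set.seed(seed)
  auc <- vapply(seq_len(n_replicates), function(rep) {
    idx <- sample.int(n_pool, sample_size)
    null_fit_auc(prep, idx)
  }, numeric(1))
  structure(list(sample_size = sample_size, n_replicates = n_replicates,
                 auc_values = auc,
                 percentile_95 = quantile(auc, 0.95, names = FALSE),
                 seed = seed),
            class = "null_distribution")
}

# shared precomputation for null replicates and null-calibration trials:
# features and their background evaluation depend only on (pool, sample_size)
null_fit_context <- function(background_pool, stack, sample_size, config = list()) {
  Xb <- stack_values_at(stack, background_pool$points$cell)
  fs <- build_features(Xb, sample_size,
                       classes = config$classes,
                       n_hinge_knots = config$n_hinge_knots %||% 4,
                       n_threshold_knots = config$n_threshold_knots %||% 4)
  Fb <- evaluate_features(fs, Xb, clamp = FALSE)
  list(features = fs, Fb = Fb, sample_size = sample_size,
       beta_multiplier = config$beta_multiplier %||% 1,
       tol = config$tol %||% 1e-6,
       max_sweeps = config$max_sweeps %||% 2000L)
}

# fit one draw of pool cells as presences; returns its training AUC
null_fit_auc <- function(prep, idx) {
  Fp <- prep$Fb[idx, , drop = FALSE]
  pbar <- colMeans(Fp)
  beta <- feature_betas(prep$features, Fp, prep$Fb, prep$sample_size,
                        prep$beta_multiplier)
  fit <- maxent_cd(prep$Fb, pbar, beta, prep$tol, as.integer(prep$max_sweeps))
  # score on the cleanly re-evaluated linear predictor (exact tie structure)
  eta <- as.vector(prep$Fb %*% fit$lambda)
  auc_scores(eta[idx], eta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution: %d replicates at n = %d, mean AUC %.3f, 95th pct %.3f\n",
              x$n_replicates, x$sample_size, mean(x$auc_values), x$percentile_95))
  invisible(x)
}

#' Match a species' presence count to a configured null size
#'
#' Nearest configured size, ties resolved toward the larger size.
#'
#' @param n_presences Species presence count.
#' @param sizes Configured null sample sizes (default the four sizes used
#'   for the museum-record study: 50, 205, 405, 695).
#' @return One element of `sizes`.
#' @export
match_null_size <- function(n_presences, sizes = c(50, 205, 405, 695)) {
  d <- abs(sizes - n_presences)
  max(sizes[d == min(d)])
}

#' Null-model significance of an observed AUC
#'
#' Significant if and only if the observed AUC strictly exceeds the empirical
#' 95th percentile of the null distribution.
#'
#' @param observed_auc Observed (training) AUC.
#' @param null A [build_null_distribution()] result matched to the species'
#'   presence count.
#' @return List with `significant` (logical) and `percentile_95`.
#' @export
test_significance <- function(observed_auc, null) {
  stopifnot(inherits(null, "null_distribution"), is.finite(observed_auc))
  list(significant = observed_auc > null$percentile_95,
       percentile_95 = null$percentile_95)
}
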