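# Maxent feature construction: linear, quadratic, product, hinge and
# threshold features, scaled to [0,1] on the background, with clamp ranges
# taken from the background covariate extremes.

#' Feature classes active at a given presence count
#'
#' Mirrors the "auto features" rule of the reference maxent implementation:
#' fewer than 10 presences use linear features only, 10-14 add quadratic,
#' 15-79 add hinge, and 80 or more add product and threshold features.
#'
#' @param n Presence record count.
#' @return Character vector of feature class names.
#' @export
auto_feature_classes <- function(n) {
  cl <- "linear"
  if (n >= 10) cl <- c(cl, "quadratic")
  if (n >= 15) cl <- c(cl, "hinge")
  if (n >= 80) cl <- c(cl, "product", "threshold")
  cl
}

# published per-class default regularization, interpolated over sample size
beta_default <- function(class, n) {
  tab <- switch(class,
    linear = , quadratic = , product =
      list(x = c(0, 10, 17, 30, 100), y = c(1, 1, 0.6, 0.5, 0.05)),
    hinge = list(x = c(0, 1), y = c(0.5, 0.5)),
    threshold = list(x = c(0, 100), y = c(2, 1)),
    stop("unknown feature class: ", class))
  approx(tab$x, tab$y, xout = n, rule = 2)$y
}

#' Build a maxent feature set from background covariates
#'
#' Feature classes are chosen by the sample-size rule
#' ([auto_feature_classes()]) unless given explicitly; every scaling constant
#' (and the clamp range of each source layer) comes from the background only.
#' Hinge and threshold knots sit at interior background quantiles of their
#' source layer. Quadratic and product features of constant layers are
#' dropped with a warning.
#'
#' @param background_X Numeric matrix of background covariates
#'   (cells x layers), column names = layer names.
#' @param sample_size Presence count driving the class rule and default
#'   regularization.
#' @param classes Optional explicit feature class vector.
#' @param n_hinge_knots Knots per layer and direction for hinge features.
#' @param n_threshold_knots Knots per layer for threshold features.
#' @return An object of class `feature_set`.
#' @export
build_features <- function(background_X, sample_size, classes = NULL,
                           n_hinge_knots = 4, n_threshold_knots = 4) {
  stopifnot(is.matrix(background_X), nrow(background_X) >= 1)
  if (anyNA(background_X)) stop("background covariates contain missing values")
  if (is.null(classes)) classes <- auto_feature_classes(sample_size)
  stopifnot(all(classes %in% c("linear", "quadratic", "product", "hinge", "threshold")))
  L <- ncol(background_X)
  lnames <- colnames(background_X)
  if (is.null(lnames)) lnames <- paste0("layer_", seq_len(L))
  lo <- apply(background_X, 2, min)
  hi <- apply(background_X, 2, max)
  const <- (hi - lo) < 1e-12

  defs <- list()
  add <- function(class, l1, l2 = NA_integer_, knot = NA_real_,
                  dir = NA_character_, mn, mx, name) {
    defs[[length(defs) + 1L]] <<- data.frame(
      class = class, layer1 = l1, layer2 = l2, knot = knot, dir = dir,
      mn = mn, mx = mx, name = name, stringsAsFactors = FALSE)
  }
  for (l in seq_len(L)) {
    if ("linear" %in% classes) {
      add("linear", l, mn = lo[l], mx = hi[l], name = paste0("l_", lnames[l]))
    }
    if ("quadratic" %in% classes) {
      if (const[l]) next
      x2 <- background_X[, l]^2
      add("quadratic", l, mn = min(x2), mx = max(x2), name = paste0("q_", lnames[l]))
    }
  }
  if ("quadratic" %in% classes && any(const)) {
    warning("dropping quadratic features of constant layer(s): ",
            paste(lnames[const], collapse = ", "))
  }
  if ("product" %in% classes && L >= 2) {
    dropped <- FALSE
    for (a in seq_len(L - 1)) for (b in seq((a + 1), L)) {
      if (const[a] || const[b]) { dropped <- TRUE; next }
      pv <- background_X[, a] * background_X[, b]
      add("product", a, b, mn = min(pv), mx = max(pv),
          name = paste0("p_", lnames[a], ".", lnames[b]))
    }
    if (dropped) warning("dropping product features involving constant layer(s)")
  }
  if ("hinge" %in% classes) {
    probs <- seq_len(n_hinge_knots) / (n_hinge_knots + 1)
    for (l in seq_len(L)) {
      if (const[l]) next
      knots <- unique(quantile(background_X[, l], probs, names = FALSE))
      for (k in knots) {
        if (hi[l] - k > 1e-12) {
          add("hinge", l, knot = k, dir = "fwd", mn = lo[l], mx = hi[l],
              name = sprintf("hf_%s_%.6g", lnames[l], k))
        }
        if (k - lo[l] > 1e-12) {
          add("hinge", l, knot = k, dir = "rev", mn = lo[l], mx = hi[l],
              name = sprintf("hr_%s_%.6g", lnames[l], k))
        }
      }
    }
  }
  if ("threshold" %in% classes) {
    probs <- seq_len(n_threshold_knots) / (n_threshold_knots + 1)
    for (l in seq_len(L)) {
      if (const[l]) next
      knots <- unique(quantile(background_X[, l], probs, names = FALSE))
      for (k in knots) {
        if (k > lo[l] && k < hi[l]) {
          add("threshold", l, knot = k, mn = lo[l], mx = hi[l],
              name = sprintf("t_%s_%.6g", lnames[l], k))
        }
      }
    }
  }
  defs <- do.call(rbind, defs)
  structure(list(defs = defs, classes = classes, layer_names = lnames,
                 clamp_lo = lo, clamp_hi = hi, sample_size = sample_size),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set: %d features (%s) over %d layers\n",
              nrow(x$defs), paste(x$classes, collapse = "+"),
              length(x$layer_names)))
  invisible(x)
}

#' Evaluate a feature set on covariates
#'
#' @param features A [build_features()] result.
#' @param X Covariate matrix (cells x layers, same layer order).
#' @param clamp Clamp covariates to the background (training) range before
#'   evaluating, as done when projecting onto novel climates.
#' @return Numeric matrix (cells x features); each feature lies in \[0, 1\]
#'   on the background itself.
#' @export
evaluate_features <- function(features, X, clamp = TRUE) {
  stopifnot(inherits(features, "feature_set"), is.matrix(X),
            ncol(X) == length(features$layer_names))
  if (clamp) {
    for (l in seq_len(ncol(X))) {
      X[, l] <- pmin(pmax(X[, l], features$clamp_lo[l]), features$clamp_hi[l])
    }
  }
  d <- features$defs
  out <- matrix(0, nrow(X), nrow(d))
  colnames(out) <- d$name
  for (j in seq_len(nrow(d))) {
    l1 <- d$layer1[j]; mn <- d$mn[j]; mx <- d$mx[j]
    rng <- mx - mn
    out[, j] <- switch(d$class[j],
      linear = if (rng > 1e-12) (X[, l1] - mn) / rng else 0,
      quadratic = (X[, l1]^2 - mn) / rng,
      product = (X[, l1] * X[, d$layer2[j]] - mn) / rng,
      hinge = if (d$dir[j] == "fwd") {
        pmax(0, X[, l1] - d$knot[j]) / (mx - d$knot[j])
      } else {
        pmax(0, d$knot[j] - X[, l1]) / (d$knot[j] - mn)
      },
      threshold = as.numeric(X[, l1] > d$knot[j]))
  }
  out
}

# per-feature regularization beta_j = mult * beta_class(m) * s_j / sqrt(m),
# s_j the presence-sample SD of the feature (background SD as fallback)
feature_betas <- function(features, Fp, Fb, sample_size, beta_multiplier = 1) {
  m <- max(sample_size, 1)
  s <- if (nrow(Fp) > 1) apply(Fp, 2, sd) else rep(NA_real_, ncol(Fp))
  sb <- apply(Fb, 2, sd)
  s[!is.finite(s) | s < 1e-8] <- sb[!is.finite(s) | s < 1e-8]
  s[!is.finite(s) | s < 1e-8] <- 1e-4
  bclass <- vapply(features$defs$class, beta_default, numeric(1), n = m)
  beta_multiplier * bclass * s / sqrt(m)
}
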