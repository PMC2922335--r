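# Threshold binarization, dispersal-buffer clipping, overlap diagnostics
# and percent habitat change.

#' Binary presence/absence range
#'
#' @param values 0/1 (or logical) matrix on the grid.
#' @param grid A [grid_meta()].
#' @param provenance Optional list (species, scenario, threshold rule).
#' @return An object of class `binary_range`.
#' @export
binary_range <- function(values, grid, provenance = list()) {
  v <- matrix(as.integer(values != 0 & !is.na(values)),
              nrow(values), ncol(values))
  stopifnot(nrow(v) == grid$n_rows, ncol(v) == grid$n_cols)
  structure(list(values = v, grid = grid, provenance = provenance),
            class = "binary_range")
}

#' @export
print.binary_range <- function(x, ...) {
  cat(sprintf("binary_range: %d suitable of %d cells%s\n", range_area(x),
              length(x$values),
              if (length(x$provenance)) {
                paste0(" (", paste(unlist(x$provenance), collapse = " / "), ")")
              } else ""))
  invisible(x)
}

#' Suitable-cell count of a binary range
#'
#' Area as an unweighted cell count (the grids are fixed-cell-size WGS84); a
#' cosine-latitude-weighted variant is available for sensitivity checks.
#'
#' @param range A `binary_range`.
#' @param latitude_weighted Weight each cell by the cosine of its center
#'   latitude (relative area units) instead of counting cells.
#' @return Cell count (or weighted sum).
#' @export
range_area <- function(range, latitude_weighted = FALSE) {
  stopifnot(inherits(range, "binary_range"))
  if (!latitude_weighted) return(sum(range$values))
  w <- cos(cell_center_lat(range$grid, seq_len(range$grid$n_rows)) * pi / 180)
  sum(rowSums(range$values) * w)
}

#' Threshold rule for binarization
#'
#' `"strict"`: suitable iff cumulative value >= the cutoff (default 10,
#' inclusive). `"liberal"`: suitable iff the score is at or above the minimum
#' score over training presences (minimum training presence; scale-invariant,
#' applied on the raw scale).
#'
#' @param kind `"strict"` or `"liberal"`.
#' @param cumulative_cutoff Cutoff for the strict rule.
#' @return An object of class `threshold_rule`.
#' @export
threshold_rule <- function(kind = c("strict", "liberal"),
                           cumulative_cutoff = 10) {
  kind <- match.arg(kind)
  structure(list(kind = kind, cumulative_cutoff = cumulative_cutoff),
            class = "threshold_rule")
}

#' Binarize a suitability surface
#'
#' @param surface A `suitability_surface` (the strict rule needs, or
#'   computes, the cumulative scale; the liberal rule needs `raw`).
#' @param rule A [threshold_rule()].
#' @param training_presence_scores Raw-scale scores at the training
#'   presences; required by the liberal rule (every training presence cell
#'   is then suitable by construction).
#' @param provenance Optional provenance list for the result.
#' @return A `binary_range`.
#' @export
binarize <- function(surface, rule, training_presence_scores = NULL,
                     provenance = list()) {
  stopifnot(inherits(surface, "suitability_surface"),
            inherits(rule, "threshold_rule"))
  provenance$threshold <- rule$kind
  if (rule$kind == "strict") {
    if (is.null(surface$cumulative)) surface <- to_cumulative(surface)
    suit <- surface$cumulative >= rule$cumulative_cutoff
  } else {
    if (is.null(training_presence_scores)) {
      stop("the liberal (minimum training presence) rule requires training presence scores")
    }
    if (is.null(surface$raw)) stop("liberal rule requires the raw scale")
    suit <- surface$raw >= min(training_presence_scores)
  }
  binary_range(suit, surface$grid, provenance)
}

#' Dilate a known range by a great-circle distance
#'
#' Every cell whose center lies within `distance_km` (haversine) of any
#' known-range cell center is included; always a superset of the input.
#' Implements the fixed-distance dispersal buffer applied to documented
#' ranges before clipping model predictions.
#'
#' @param known A `binary_range`.
#' @param distance_km Buffer distance in kilometres (>= 0; 0 = identity).
#' @return A `binary_range`.
#' @export
buffer_mask <- function(known, distance_km) {
  stopifnot(inherits(known, "binary_range"))
  if (distance_km < 0) stop("buffer distance must be nonnegative")
  if (distance_km == 0 || sum(known$values) == 0 ||
      all(known$values == 1L)) {
    return(known)
  }
  g <- known$grid
  cs <- g$cell_size
  lat <- cell_center_lat(g, seq_len(g$n_rows))
  # conservative row window: 1 degree of latitude is at least 110.57 km
  dr_max <- min(g$n_rows - 1L, ceiling(distance_km / (cs * 110.57)) + 1L)
  src_rows <- which(rowSums(known$values) > 0)
  out <- known$values
  lon0 <- cell_center_lon(g, 1)
  for (r1 in src_rows) {
    cols1 <- which(known$values[r1, ] > 0)
    for (dr in -dr_max:dr_max) {
      r2 <- r1 + dr
      if (r2 < 1 || r2 > g$n_rows) next
      # widest admissible column offset at this row pair
      k <- -1L
      repeat {
        d <- geosphere::distHaversine(c(lon0, lat[r1]),
                                      c(lon0 + (k + 1) * cs, lat[r2])) / 1000
        if (d > distance_km) break
        k <- k + 1L
        if (k >= g$n_cols) break
      }
      if (k < 0L) next
      row_out <- out[r2, ]
      for (c1 in cols1) {
        a <- max(1L, c1 - k); b <- min(g$n_cols, c1 + k)
        row_out[a:b] <- 1L
      }
      out[r2, ] <- row_out
    }
  }
  binary_range(out, g, known$provenance)
}

#' Cell-wise intersection of a range with a mask
#'
#' @param range,mask `binary_range`s on the same grid.
#' @return A `binary_range` (the range's provenance is kept).
#' @export
clip_range <- function(range, mask) {
  stopifnot(inherits(range, "binary_range"), inherits(mask, "binary_range"))
  stop_if_grid_mismatch(range$grid, mask$grid, "range and mask")
  binary_range(range$values * mask$values, range$grid, range$provenance)
}

#' Percent of a known range captured by a model
#'
#' `100 * |modeled intersect known| / |known|` by default (how much of the
#' documented range the model captures); set `denominator = "modeled"` for
#' the share of the modeled range inside the documented one.
#'
#' @param modeled,known `binary_range`s on one grid; `known` non-empty.
#' @param denominator `"known"` (default) or `"modeled"`.
#' @return Percentage in \[0, 100\].
#' @export
percent_overlap <- function(modeled, known,
                            denominator = c("known", "modeled")) {
  denominator <- match.arg(denominator)
  stop_if_grid_mismatch(modeled$grid, known$grid, "ranges")
  inter <- sum(modeled$values * known$values)
  den <- if (denominator == "known") sum(known$values) else sum(modeled$values)
  if (den == 0) stop("the denominator range is empty")
  100 * inter / den
}

#' Percent habitat change between current and future ranges
#'
#' `percent_change = 100 * (current - future) / current` on suitable-cell
#' counts: positive = loss, negative = gain, never above 100. Both ranges are
#' expected to be clipped by the same buffered known-range mask.
#'
#' @param current,future `binary_range`s on one grid; `current` non-empty.
#' @param species,scenario Optional provenance recorded on the result.
#' @return An object of class `change_record`: list with `species`,
#'   `scenario`, `current_area`, `future_area`, `percent_change`.
#' @export
percent_change <- function(current, future, species = NULL, scenario = NULL) {
  stop_if_grid_mismatch(current$grid, future$grid, "ranges")
  ca <- range_area(current); fa <- range_area(future)
  if (ca == 0) stop("current range is empty; percent loss is undefined")
  structure(list(species = species %||% current$provenance$species,
                 scenario = scenario %||% future$provenance$scenario,
                 threshold = current$provenance$threshold,
                 current_area = ca, future_area = fa,
                 percent_change = 100 * (ca - fa) / ca),
            class = "change_record")
}

#' Mean latitude of a range's suitable cell centers
#'
#' Unweighted mean over suitable cells; the "distribution centroid latitude"
#' covariate of the scenario analysis.
#'
#' @param range A non-empty `binary_range`.
#' @return Latitude in decimal degrees.
#' @export
range_centroid_latitude <- function(range) {
  stopifnot(inherits(range, "binary_range"))
  n_by_row <- rowSums(range$values)
  if (sum(n_by_row) == 0) stop("range is empty; centroid undefined")
  lat <- cell_center_lat(range$grid, seq_len(range$grid$n_rows))
  sum(lat * n_by_row) / sum(n_by_row)
}
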