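# Grid convention shared by every module: row 1 is the northernmost row,
# cell (1,1) sits at the NW origin, cell centers carry coordinates, and
# point-in-cell tests use half-open extents [west, east) x (south, north].

#' Regular lon/lat grid metadata
#'
#' Describes a regular WGS84 grid by its cell counts, cell size and the
#' longitude/latitude of the north-west corner of cell (1, 1).
#'
#' @param n_rows,n_cols Number of rows (north to south) and columns (west to
#'   east); both at least 1.
#' @param cell_size Cell edge length in decimal degrees (> 0).
#' @param origin Numeric length-2 vector `c(lon, lat)` of the grid's NW corner.
#' @return An object of class `grid_meta`.
#' @export
grid_meta <- function(n_rows, n_cols, cell_size = 0.0083,
                      origin = c(-85, 42)) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0, length(origin) == 2)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size,
                 origin = c(lon = unname(origin[1]), lat = unname(origin[2]))),
            class = "grid_meta")
}

#' @export
print.grid_meta <- function(x, ...) {
  cat(sprintf("grid_meta: %d x %d cells of %g deg, NW corner (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2]))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(a$n_rows == b$n_rows) && isTRUE(a$n_cols == b$n_cols) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(unname(a$origin), unname(b$origin)))
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b)) stop(what, " are not on the same grid", call. = FALSE)
  invisible(TRUE)
}

#' Cell-center coordinates
#'
#' @param grid A [grid_meta()].
#' @param row,col Integer vectors of row / column indices.
#' @return Numeric vector of center latitudes (for rows) or longitudes (for
#'   columns).
#' @export
cell_center_lat <- function(grid, row) {
  unname(grid$origin["lat"]) - (row - 0.5) * grid$cell_size
}

#' @rdname cell_center_lat
#' @export
cell_center_lon <- function(grid, col) {
  unname(grid$origin["lon"]) + (col - 0.5) * grid$cell_size
}

#' Locate points on the grid
#'
#' Maps lon/lat points to row/col indices under the half-open cell convention
#' `[west, east) x (south, north]`. Points outside the grid get `NA`.
#'
#' @param grid A [grid_meta()].
#' @param lon,lat Numeric coordinate vectors of equal length.
#' @return A data frame with integer columns `row` and `col`.
#' @export
point_to_cell <- function(grid, lon, lat) {
  col <- floor((lon - grid$origin["lon"]) / grid$cell_size) + 1
  # north edge belongs to the cell below it, south edge to the next cell
  row <- floor((grid$origin["lat"] - lat) / grid$cell_size) + 1
  at_north <- abs(lat - grid$origin["lat"]) < 1e-12
  row[at_north] <- 1L
  bad <- row < 1 | row > grid$n_rows | col < 1 | col > grid$n_cols
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

# linear (column-major) cell index <-> row/col
cell_index <- function(grid, row, col) (col - 1L) * grid$n_rows + row
index_to_rowcol <- function(grid, idx) {
  idx <- as.integer(idx)
  data.frame(row = ((idx - 1L) %% grid$n_rows) + 1L,
             col = ((idx - 1L) %/% grid$n_rows) + 1L)
}
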