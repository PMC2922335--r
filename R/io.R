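# Plain-text file formats: ESRI ASCII grids (one per layer), occurrence
# CSVs, and the "lambdas"-style maxent model file. All coordinates are
# WGS84 decimal degrees.

#' Write / read an ESRI ASCII grid
#'
#' Rows are written north to south, matching the in-memory matrix layout.
#' Values round-trip at full double precision; `NA` cells are written as the
#' NODATA value.
#'
#' @param values Numeric matrix on the grid.
#' @param grid A [grid_meta()].
#' @param file Path.
#' @param nodata NODATA sentinel (default -9999).
#' @return `write_ascii_grid`: the path, invisibly. `read_ascii_grid`: a list
#'   with `values` (matrix, NODATA as `NA`) and `grid`.
#' @export
write_ascii_grid <- function(values, grid, file, nodata = -9999) {
  stopifnot(is.matrix(values), nrow(values) == grid$n_rows,
            ncol(values) == grid$n_cols)
  v <- values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", grid$n_cols),
           sprintf("nrows %d", grid$n_rows),
           sprintf("xllcorner %.10f", grid$origin["lon"]),
           sprintf("yllcorner %.10f",
                   grid$origin["lat"] - grid$n_rows * grid$cell_size),
           sprintf("cellsize %.12f", grid$cell_size),
           sprintf("NODATA_value %g", nodata))
  body <- apply(v, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                               scientific = TRUE),
                                        collapse = " "))
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(file) {
  lines <- readLines(file)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, character(1), 1))
  vals <- as.numeric(vapply(hdr, `[`, character(1), 2))
  names(vals) <- keys
  nr <- vals[["nrows"]]; nc <- vals[["ncols"]]
  cs <- vals[["cellsize"]]; nodata <- vals[["nodata_value"]]
  grid <- grid_meta(nr, nc, cs,
                    origin = c(vals[["xllcorner"]], vals[["yllcorner"]] + nr * cs))
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nr * nc) stop("grid body has wrong cell count")
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(values = m, grid = grid)
}

#' Write / read a climate stack as per-layer ASCII grids
#'
#' One `<prefix>_<layer>.asc` per layer plus a `<prefix>_stack.json` header
#' recording layer order and roles. A cell NODATA in any layer is masked in
#' every layer on reading (shared NODATA convention).
#'
#' @param stack A `climate_stack`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return `write_climate_stack`: the JSON header path, invisibly;
#'   `read_climate_stack`: a `climate_stack`.
#' @export
write_climate_stack <- function(stack, dir, prefix = "stack") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(n_layers(stack))
  for (l in seq_len(n_layers(stack))) {
    files[l] <- file.path(dir, paste0(prefix, "_", stack$layer_names[l], ".asc"))
    write_ascii_grid(stack$values[, , l], stack$grid, files[l])
  }
  hdr <- file.path(dir, paste0(prefix, "_stack.json"))
  jsonlite::write_json(list(layer_names = stack$layer_names,
                            layer_roles = stack$layer_roles,
                            files = basename(files)),
                       hdr, auto_unbox = FALSE, pretty = TRUE)
  invisible(hdr)
}

#' @rdname write_climate_stack
#' @export
read_climate_stack <- function(header_file) {
  hdr <- jsonlite::read_json(header_file, simplifyVector = TRUE)
  dir <- dirname(header_file)
  layers <- lapply(file.path(dir, hdr$files), read_ascii_grid)
  g <- layers[[1]]$grid
  for (l in layers) stop_if_grid_mismatch(g, l$grid, "stack layers")
  vals <- array(NA_real_, dim = c(g$n_rows, g$n_cols, length(layers)))
  for (i in seq_along(layers)) vals[, , i] <- layers[[i]]$values
  anyna <- apply(is.na(vals), c(1, 2), any)
  for (i in seq_along(layers)) {
    v <- vals[, , i]; v[anyna] <- NA_real_; vals[, , i] <- v
  }
  structure(list(values = vals, grid = g, layer_names = hdr$layer_names,
                 layer_roles = hdr$layer_roles, nodata_mask = NULL),
            class = "climate_stack")
}

#' Write / read point sets as `species,lon,lat` CSV
#'
#' @param x An `occurrence_set` or `background_set`.
#' @param file Path.
#' @param grid A [grid_meta()] used to re-snap points to cells on reading.
#' @return `write_occurrences`: the path, invisibly; `read_occurrences`: an
#'   `occurrence_set` (points outside the grid are dropped).
#' @export
write_occurrences <- function(x, file) {
  stopifnot(inherits(x, "occurrence_set") || inherits(x, "background_set"))
  write.csv(x$points[, c("species", "lon", "lat")], file, row.names = FALSE,
            quote = FALSE)
  invisible(file)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(file, grid) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "lon", "lat") %in% names(d)))
  rc <- point_to_cell(grid, d$lon, d$lat)
  keep <- !is.na(rc$row)
  pts <- data.frame(species = d$species[keep],
                    lon = cell_center_lon(grid, rc$col[keep]),
                    lat = cell_center_lat(grid, rc$row[keep]),
                    row = rc$row[keep], col = rc$col[keep],
                    cell = cell_index(grid, rc$row[keep], rc$col[keep]))
  structure(list(points = pts, species = unique(pts$species), n = nrow(pts),
                 grid = grid, for_modelling = FALSE),
            class = "occurrence_set")
}

#' Write / read a maxent model as a plain-text lambdas file
#'
#' One line per feature (name, class, layers, knot, direction, scaling range,
#' weight) followed by a footer with the clamp ranges, the log normalizer and
#' the raw-distribution entropy. The file supports raw/logistic prediction on
#' new stacks; the cumulative transform additionally needs the background
#' (not stored in the file), as in the reference lambdas format.
#'
#' @param model A `maxent_model`.
#' @param file Path.
#' @return `write_lambdas`: the path, invisibly; `read_lambdas`: a
#'   `maxent_model` without background slots.
#' @export
write_lambdas <- function(model, file) {
  stopifnot(inherits(model, "maxent_model"))
  d <- model$features$defs
  lines <- c(
    sprintf("# nichecast lambdas v1"),
    sprintf("layers %s", paste(model$layer_names, collapse = ",")),
    sprintf("classes %s", paste(model$features$classes, collapse = ",")),
    sprintf("clamp_lo %s", paste(format(model$features$clamp_lo, digits = 17),
                                 collapse = ",")),
    sprintf("clamp_hi %s", paste(format(model$features$clamp_hi, digits = 17),
                                 collapse = ",")),
    vapply(seq_len(nrow(d)), function(j) {
      paste(d$name[j], d$class[j], d$layer1[j], d$layer2[j],
            format(d$knot[j], digits = 17), d$dir[j],
            format(d$mn[j], digits = 17), format(d$mx[j], digits = 17),
            format(model$lambdas[j], digits = 17), sep = "\t")
    }, character(1)),
    sprintf("logZ %s", format(model$logZ, digits = 17)),
    sprintf("entropy %s", format(model$entropy, digits = 17)),
    sprintf("sample_size %d", as.integer(model$sample_size)))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_lambdas
#' @export
read_lambdas <- function(file) {
  lines <- readLines(file)
  kv <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)[1]
    sub(paste0("^", key, " "), "", ln)
  }
  layer_names <- strsplit(kv("layers"), ",")[[1]]
  classes <- strsplit(kv("classes"), ",")[[1]]
  clamp_lo <- as.numeric(strsplit(kv("clamp_lo"), ",")[[1]])
  clamp_hi <- as.numeric(strsplit(kv("clamp_hi"), ",")[[1]])
  feat <- grep("\t", lines, value = TRUE)
  parts <- strsplit(feat, "\t")
  fld <- function(i) {
    v <- trimws(vapply(parts, `[`, character(1), i))
    v[v == "NA"] <- NA_character_
    v
  }
  d <- data.frame(
    class = fld(2),
    layer1 = as.integer(fld(3)),
    layer2 = as.integer(fld(4)),
    knot = as.numeric(fld(5)),
    dir = fld(6),
    mn = as.numeric(fld(7)),
    mx = as.numeric(fld(8)),
    name = fld(1),
    stringsAsFactors = FALSE)
  fs <- structure(list(defs = d, classes = classes, layer_names = layer_names,
                       clamp_lo = setNames(clamp_lo, layer_names),
                       clamp_hi = setNames(clamp_hi, layer_names),
                       sample_size = as.integer(kv("sample_size"))),
                  class = "feature_set")
  structure(list(lambdas = setNames(as.numeric(vapply(parts, `[`, character(1), 9)),
                                    d$name),
                 features = fs, logZ = as.numeric(kv("logZ")),
                 entropy = as.numeric(kv("entropy")),
                 sample_size = as.integer(kv("sample_size")),
                 bg_raw = NULL, bg_X = NULL, training_presence_raw = NULL,
                 converged = NA, clamp_on_project = TRUE, grid = NULL,
                 layer_names = layer_names),
            class = "maxent_model")
}

#' Write a binary range or richness map as an ASCII grid
#'
#' @param x A `binary_range` or `richness_map`.
#' @param file Path.
#' @return The path, invisibly.
#' @export
write_range <- function(x, file) {
  stopifnot(inherits(x, "binary_range") || inherits(x, "richness_map"))
  write_ascii_grid(x$values + 0, x$grid, file)
}

#' @rdname write_range
#' @export
read_range <- function(file) {
  r <- read_ascii_grid(file)
  binary_range(r$values, r$grid)
}
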