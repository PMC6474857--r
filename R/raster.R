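#' Single-band raster grid
#'
#' The unit of all spatial layers in the package: a 2D numeric matrix with a
#' simple geographic georeference (top-left corner origin, square cells in
#' decimal degrees) and a logical nodata mask. Row 1 is the northernmost row;
#' all indexing is (row, col).
#'
#' @param values Numeric matrix of cell values.
#' @param origin_lon,origin_lat Coordinates (degrees) of the top-left corner
#'   of the grid (i.e. of cell \[1, 1\]'s upper-left vertex).
#' @param cell_size Cell edge length in degrees; must be positive.
#' @param nodata_mask Logical matrix, same shape as \code{values}; \code{TRUE}
#'   marks nodata cells. Defaults to non-finite entries of \code{values}.
#' @return An object of class \code{raster_grid}.
#' @export
raster_grid <- function(values, origin_lon = 0, origin_lat = 0,
                        cell_size = 0.01, nodata_mask = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid dimensions must be positive", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a positive scalar", call. = FALSE)
  if (is.null(nodata_mask)) nodata_mask <- !is.finite(values)
  if (!is.logical(nodata_mask) || !identical(dim(nodata_mask), dim(values)))
    stop("`nodata_mask` must be a logical matrix matching `values`", call. = FALSE)
  if (any(!is.finite(values[!nodata_mask])))
    stop("non-finite values outside the nodata mask", call. = FALSE)
  structure(
    list(values = values, origin_lon = origin_lon, origin_lat = origin_lat,
         cell_size = cell_size, nodata_mask = nodata_mask),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!x$nodata_mask]
  cat(sprintf("<raster_grid> %d x %d cells, %.4g deg/cell, origin (%.4g, %.4g)\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin_lon, x$origin_lat))
  cat(sprintf("  valid cells: %d (%.1f%%), range [%.4g, %.4g]\n",
              length(v), 100 * length(v) / length(x$values),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

stopifnot_aligned <- function(a, b) {
  if (!same_geometry(a, b))
    stop("raster grids are not aligned (geometry mismatch)", call. = FALSE)
  invisible(TRUE)
}

#' Cell-centre coordinates
#'
#' Longitude/latitude of the centres of the given (row, col) cells.
#'
#' @param grid A \code{raster_grid}.
#' @param rows,cols Integer vectors of 1-based cell indices.
#' @return Data frame with columns \code{lon}, \code{lat}.
#' @export
cell_centres <- function(grid, rows, cols) {
  data.frame(
    lon = grid$origin_lon + (cols - 0.5) * grid$cell_size,
    lat = grid$origin_lat - (rows - 0.5) * grid$cell_size)
}

#' Locate points on a grid
#'
#' Map lon/lat points to 1-based (row, col) indices; points outside the grid
#' extent get NA indices.
#'
#' @param grid A \code{raster_grid}.
#' @param lon,lat Numeric coordinate vectors.
#' @return Data frame with columns \code{row}, \code{col}.
#' @export
locate_cells <- function(grid, lon, lat) {
  col <- floor((lon - grid$origin_lon) / grid$cell_size) + 1L
  row <- floor((grid$origin_lat - lat) / grid$cell_size) + 1L
  bad <- row < 1L | row > nrow(grid$values) | col < 1L | col > ncol(grid$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Named stack of co-registered raster layers
#'
#' Holds the environmental predictors (bioclim analogues) on one common grid.
#' All layers must share geometry and nodata mask.
#'
#' @param layers Named list of \code{raster_grid} objects.
#' @return An object of class \code{predictor_stack}.
#' @export
predictor_stack <- function(layers) {
  if (length(layers) < 1L) stop("a stack needs at least one layer", call. = FALSE)
  nm <- names(layers)
  if (is.null(nm) || anyNA(nm) || any(nm == "") || anyDuplicated(nm))
    stop("layers must have unique non-empty names", call. = FALSE)
  ref <- layers[[1L]]
  for (l in layers) {
    stopifnot_aligned(ref, l)
    if (!identical(ref$nodata_mask, l$nodata_mask))
      stop("all layers must share one nodata mask", call. = FALSE)
  }
  structure(list(layers = layers), class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  g <- x$layers[[1L]]
  cat(sprintf("<predictor_stack> %d layers on %d x %d grid: %s\n",
              length(x$layers), nrow(g$values), ncol(g$values),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' @export
names.predictor_stack <- function(x) names(x$layers)

stack_geometry <- function(stack) stack$layers[[1L]]

#' Flatten a stack to a cell-by-layer matrix
#'
#' One row per grid cell in column-major matrix order; nodata cells carry NA.
#' Used internally to predict over whole grids.
#'
#' @param stack A \code{predictor_stack}.
#' @return Numeric matrix, one column per layer.
#' @export
stack_as_matrix <- function(stack) {
  m <- vapply(stack$layers, function(l) {
    v <- l$values
    v[l$nodata_mask] <- NA_real_
    as.vector(v)
  }, numeric(length(stack$layers[[1L]]$values)))
  colnames(m) <- names(stack$layers)
  m
}

# ---- plain-text raster I/O (Esri ASCII grid + JSON stack manifest) ----

#' Write a raster as an Esri ASCII grid
#'
#' Plain-text single-band export (\code{.asc}); nodata written as -9999.
#'
#' @param grid A \code{raster_grid}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  v <- grid$values
  v[grid$nodata_mask] <- -9999
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$origin_lon),
    sprintf("yllcorner %.10g", grid$origin_lat - nrow(v) * grid$cell_size),
    sprintf("cellsize %.10g", grid$cell_size),
    "NODATA_value -9999")
  body <- apply(v, 1L, function(r) paste(format(r, trim = TRUE, digits = 10),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an Esri ASCII grid
#'
#' @param path Path to a \code{.asc} file written by \code{write_ascii_grid}
#'   or any conforming GIS export.
#' @return A \code{raster_grid}.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  body <- lines[i:length(lines)]
  vals <- matrix(scan(text = paste(body, collapse = "\n"), quiet = TRUE),
                 nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nd <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  mask <- vals == nd
  vals[mask] <- NA_real_
  raster_grid(vals,
              origin_lon = hdr$xllcorner,
              origin_lat = hdr$yllcorner + hdr$nrows * hdr$cellsize,
              cell_size = hdr$cellsize,
              nodata_mask = mask)
}

#' Write a predictor stack to a directory
#'
#' One ASCII grid per layer plus a JSON manifest mapping layer names to files.
#'
#' @param stack A \code{predictor_stack}.
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(names(stack$layers), function(nm) {
    f <- paste0(nm, ".asc")
    write_ascii_grid(stack$layers[[nm]], file.path(dir, f))
    f
  }, character(1))
  manifest <- file.path(dir, "stack.json")
  jsonlite::write_json(as.list(files), manifest, auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a predictor stack from a directory manifest
#'
#' @param dir Directory containing \code{stack.json} and the layer files.
#' @return A \code{predictor_stack}.
#' @export
read_stack <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "stack.json"),
                                  simplifyVector = TRUE)
  layers <- lapply(manifest, function(f) read_ascii_grid(file.path(dir, f)))
  names(layers) <- names(manifest)
  predictor_stack(layers)
}
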