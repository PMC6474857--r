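#' Labelled occurrence points
#'
#' A set of presence records (id, clade, lon, lat) with a provenance note.
#' Coordinates are decimal degrees; ids must be unique.
#'
#' @param records Data frame with columns \code{id}, \code{clade},
#'   \code{lon}, \code{lat}.
#' @param provenance Free-text description of where the records came from.
#' @return An object of class \code{occurrence_set} (a data frame).
#' @export
occurrence_set <- function(records, provenance = "") {
  req <- c("id", "clade", "lon", "lat")
  if (!is.data.frame(records) || !all(req %in% names(records)))
    stop("`records` must have columns id, clade, lon, lat", call. = FALSE)
  records <- records[req]
  if (nrow(records)) {
    if (anyDuplicated(records$id)) stop("ids must be unique", call. = FALSE)
    if (any(records$lon < -180 | records$lon > 180) ||
        any(records$lat < -90 | records$lat > 90))
      stop("coordinates out of range", call. = FALSE)
  }
  structure(records, provenance = provenance,
            class = c("occurrence_set", "data.frame"))
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %d records, %d clade(s)\n",
              nrow(x), length(unique(x$clade))))
  if (nrow(x)) print(table(clade = x$clade))
  invisible(x)
}

#' Read/write occurrences as CSV
#'
#' CSV format: header \code{id,clade,lon,lat}.
#'
#' @param path File path.
#' @return \code{read_occurrences}: an \code{occurrence_set}.
#' @export
read_occurrences <- function(path) {
  occurrence_set(utils::read.csv(path, stringsAsFactors = FALSE),
                 provenance = path)
}

#' @rdname read_occurrences
#' @param occs An \code{occurrence_set}.
#' @export
write_occurrences <- function(occs, path) {
  utils::write.csv(as.data.frame(occs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371) # km
}

#' Spatially thin occurrence records
#'
#' Enforces a pairwise minimum great-circle distance by greedy acceptance
#' over a seeded random permutation: records are visited in random order and
#' kept only if no previously kept record lies within \code{radius_km}
#' (haversine, Earth radius 6371 km). Mirrors the practice of randomly
#' sub-selecting one point per fixed-radius buffer, and is idempotent: a set
#' that already satisfies the constraint is returned unchanged.
#'
#' @param occs An \code{occurrence_set}.
#' @param radius_km Minimum pairwise distance in km (> 0).
#' @param seed Integer RNG seed for the permutation.
#' @return The thinned \code{occurrence_set} (a subset of the input).
#' @export
thin_occurrences <- function(occs, radius_km = 10, seed = 1) {
  if (radius_km <= 0) stop("`radius_km` must be > 0", call. = FALSE)
  n <- nrow(occs)
  if (n == 0L) return(occs)
  set.seed(seed)
  ord <- sample.int(n)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0L ||
        all(haversine_km(occs$lon[i], occs$lat[i],
                         occs$lon[kept], occs$lat[kept]) >= radius_km))
      kept <- c(kept, i)
  }
  out <- occs[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  occurrence_set(out, provenance = attr(occs, "provenance"))
}

# Ray-casting point-in-polygon; points on the boundary count as inside.
point_in_polygon <- function(lon, lat, poly_lon, poly_lat) {
  n <- length(poly_lon)
  inside <- logical(length(lon))
  for (p in seq_along(lon)) {
    x <- lon[p]; y <- lat[p]
    on_edge <- FALSE
    cross <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- poly_lon[i]; yi <- poly_lat[i]
      xj <- poly_lon[j]; yj <- poly_lat[j]
      # boundary check: point on segment (i, j)
      d <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
      if (abs(d) < 1e-12 &&
          x >= min(xi, xj) - 1e-12 && x <= max(xi, xj) + 1e-12 &&
          y >= min(yi, yj) - 1e-12 && y <= max(yi, yj) + 1e-12) {
        on_edge <- TRUE
        break
      }
      if ((yi > y) != (yj > y) &&
          x < (xj - xi) * (y - yi) / (yj - yi) + xi)
        cross <- !cross
      j <- i
    }
    inside[p] <- on_edge || cross
  }
  inside
}

#' Pool occurrences into phylogeographic clades
#'
#' Maps species labels to clade labels and splits the records into one set
#' per clade. Optional per-clade exclusion polygons drop points falling
#' inside them (boundary counts as inside) — e.g. removing a sub-clade's
#' occurrences from a geographic region that belongs to another clade's
#' model.
#'
#' @param occs An \code{occurrence_set} whose \code{clade} column holds
#'   species labels.
#' @param clade_map Named character vector or list: species label -> clade
#'   label. Every species label in \code{occs} must be mapped.
#' @param exclusions Optional named list: clade label -> list of polygons,
#'   each a list/data frame with \code{lon} and \code{lat} vertex vectors.
#' @return Named list of \code{occurrence_set}, one per clade.
#' @export
pool_by_clade <- function(occs, clade_map, exclusions = list()) {
  labels <- unique(occs$clade)
  unmapped <- setdiff(labels, names(clade_map))
  if (length(unmapped))
    stop("unmapped species labels: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  clade <- unlist(clade_map)[occs$clade]
  out <- list()
  for (cl in unique(clade)) {
    sub <- as.data.frame(occs)[clade == cl, , drop = FALSE]
    sub$clade <- cl
    for (poly in if (cl %in% names(exclusions)) exclusions[[cl]] else list()) {
      drop <- point_in_polygon(sub$lon, sub$lat, poly$lon, poly$lat)
      sub <- sub[!drop, , drop = FALSE]
    }
    rownames(sub) <- NULL
    out[[cl]] <- occurrence_set(sub, provenance = attr(occs, "provenance"))
  }
  out
}
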