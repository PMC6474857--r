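#' Enumerate projection tasks for a scenario plan
#'
#' Full Cartesian product of algorithm x replicate x GCM x RCP x period, in
#' that (deterministic) nesting order. With the classic design of 4
#' algorithms, 10 replicates, 4 GCMs, 2 RCPs and 2 periods this yields 640
#' projection tasks per clade.
#'
#' @param algorithms,gcms,rcps,periods Character vectors (non-empty).
#' @param replicates Number of replicates (>= 1).
#' @return Data frame, one row per projection task.
#' @export
enumerate_projections <- function(algorithms, replicates, gcms, rcps,
                                  periods) {
  replicates <- check_count(replicates, "replicates")
  for (comp in list(algorithms = algorithms, gcms = gcms, rcps = rcps,
                    periods = periods))
    if (length(comp) == 0L)
      stop("every plan component must be non-empty", call. = FALSE)
  out <- expand.grid(period = periods, rcp = rcps, gcm = gcms,
                     replicate = seq_len(replicates),
                     algorithm = algorithms,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("algorithm", "replicate", "gcm", "rcp", "period")]
  out <- out[order(match(out$algorithm, algorithms), out$replicate,
                   match(out$gcm, gcms), match(out$rcp, rcps),
                   match(out$period, periods)), ]
  rownames(out) <- NULL
  out
}

#' Minimal-predicted-area threshold
#'
#' The minimum ensemble suitability observed at the occurrence points: the
#' largest threshold at which every occurrence cell is still classified
#' suitable, so the binary range is the minimal predicted area containing
#' all occurrences. No marginal occurrences are removed.
#'
#' @param suitability A suitability \code{raster_grid}.
#' @param occs An \code{occurrence_set}.
#' @return The threshold (numeric scalar).
#' @export
mpa_threshold <- function(suitability, occs) {
  rc <- locate_cells(suitability, occs$lon, occs$lat)
  ok <- !is.na(rc$row)
  vals <- rep(NA_real_, nrow(occs))
  vals[ok] <- suitability$values[cbind(rc$row[ok], rc$col[ok])]
  vals[ok][suitability$nodata_mask[cbind(rc$row[ok], rc$col[ok])]] <- NA
  if (all(is.na(vals)))
    stop("no occurrence falls on a valid suitability cell", call. = FALSE)
  min(vals, na.rm = TRUE)
}

#' Binarize a suitability map
#'
#' A cell is suitable iff its suitability is >= the threshold (ties count
#' as suitable); nodata cells are unsuitable and stay flagged in the mask.
#'
#' @param suitability A suitability \code{raster_grid}.
#' @param threshold Threshold in \[0, 1\].
#' @return A \code{binary_range}: logical matrix + geometry + threshold.
#' @export
binarize <- function(suitability, threshold) {
  if (threshold < 0 || threshold > 1)
    stop("`threshold` must be in [0, 1]", call. = FALSE)
  suit <- !suitability$nodata_mask & suitability$values >= threshold
  suit[is.na(suit)] <- FALSE
  structure(list(values = suit, origin_lon = suitability$origin_lon,
                 origin_lat = suitability$origin_lat,
                 cell_size = suitability$cell_size,
                 nodata_mask = suitability$nodata_mask,
                 threshold_used = threshold, masked = FALSE),
            class = "binary_range")
}

#' @export
print.binary_range <- function(x, ...) {
  cat(sprintf("<binary_range> %d / %d cells suitable (threshold %.4g%s)\n",
              sum(x$values), sum(!x$nodata_mask), x$threshold_used,
              if (x$masked) ", footprint-masked" else ""))
  invisible(x)
}

#' Mask developed areas out of a binary range
#'
#' Cells whose human-footprint value is strictly greater than the cutoff
#' are treated as developed and set unsuitable. The same mask must be
#' applied to current and future ranges alike.
#'
#' @param binary A \code{binary_range}.
#' @param footprint A \code{raster_grid} of footprint values (0-100),
#'   aligned with \code{binary}.
#' @param cutoff Development cutoff (default 50, strict inequality).
#' @return The masked \code{binary_range}.
#' @export
apply_footprint_mask <- function(binary, footprint, cutoff = 50) {
  stopifnot_aligned(binary, footprint)
  developed <- !footprint$nodata_mask & footprint$values > cutoff
  binary$values <- binary$values & !developed
  binary$masked <- TRUE
  binary
}

#' Average suitability maps across GCMs
#'
#' Cellwise unweighted mean, used for display/consensus maps. Change
#' statistics are computed per GCM and then summarized, not on the average.
#'
#' @param maps List of aligned suitability \code{raster_grid}s.
#' @return A \code{raster_grid}.
#' @export
average_over_gcms <- function(maps) {
  if (length(maps) < 1L) stop("need at least one map", call. = FALSE)
  ref <- maps[[1L]]
  for (m in maps) stopifnot_aligned(ref, m)
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (m in maps) {
    v <- m$values; v[m$nodata_mask] <- 0
    acc <- acc + v / length(maps)
  }
  mask <- Reduce(`|`, lapply(maps, function(m) m$nodata_mask))
  acc[mask] <- NA_real_
  raster_grid(acc, origin_lon = ref$origin_lon, origin_lat = ref$origin_lat,
              cell_size = ref$cell_size, nodata_mask = mask)
}

#' Apply a dispersal scenario
#'
#' Under no dispersal the species cannot colonize newly suitable cells, so
#' the future range is the intersection of future and current suitability;
#' under unlimited dispersal the future range is taken as projected.
#'
#' @param current,future Aligned \code{binary_range}s.
#' @param scenario "none" or "unlimited".
#' @return The future \code{binary_range} under the scenario.
#' @export
apply_dispersal <- function(current, future, scenario = c("none",
                                                          "unlimited")) {
  scenario <- match.arg(scenario)
  stopifnot_aligned(current, future)
  if (scenario == "none") future$values <- future$values & current$values
  future
}

#' Range change between current and future binary ranges
#'
#' Percentages are relative to the current range size:
#' loss = current-only cells, gain = future-only cells, stable = shared
#' cells; stable + loss = 100 and net change = gain - loss.
#'
#' @param current,future Aligned \code{binary_range}s; current non-empty.
#' @return One-row data frame with stable_pct, loss_pct, gain_pct,
#'   net_change_pct, current_cells, future_cells.
#' @export
range_change <- function(current, future) {
  stopifnot_aligned(current, future)
  n_cur <- sum(current$values)
  if (n_cur == 0L)
    stop("current range is empty; change percentages undefined",
         call. = FALSE)
  stable <- sum(current$values & future$values)
  loss <- sum(current$values & !future$values)
  gain <- sum(!current$values & future$values)
  data.frame(stable_pct = 100 * stable / n_cur,
             loss_pct = 100 * loss / n_cur,
             gain_pct = 100 * gain / n_cur,
             net_change_pct = 100 * (gain - loss) / n_cur,
             current_cells = n_cur, future_cells = sum(future$values))
}

#' Mean altitude of a binary range
#'
#' Unweighted mean DEM elevation over the suitable cells.
#'
#' @param binary A \code{binary_range} (non-empty).
#' @param dem An aligned elevation \code{raster_grid} (metres).
#' @return Mean elevation in metres.
#' @export
mean_range_altitude <- function(binary, dem) {
  stopifnot_aligned(binary, dem)
  if (!any(binary$values))
    stop("empty range: mean altitude undefined", call. = FALSE)
  mean(dem$values[binary$values])
}
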