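#' IUCN-style threat level from projected range loss
#'
#' Four loss-based categories: level 1 for a complete (100\%) loss of
#' projected area of occupancy, level 2 for losses in \[80, 100), level 3
#' for \[50, 80), level 4 for \[30, 50), and level 0 ("below assessment
#' thresholds") for losses under 30\%. Boundaries are inclusive at the
#' lower end of each category.
#'
#' @param loss_pct Projected loss percentage(s) in \[0, 100\]; vectorized.
#' @return Integer level(s) 0-4.
#' @export
threat_level <- function(loss_pct) {
  if (any(!is.finite(loss_pct)) || any(loss_pct < 0) || any(loss_pct > 100))
    stop("`loss_pct` must be in [0, 100]", call. = FALSE)
  ifelse(loss_pct == 100, 1L,
    ifelse(loss_pct >= 80, 2L,
      ifelse(loss_pct >= 50, 3L,
        ifelse(loss_pct >= 30, 4L, 0L))))
}

#' Label connected habitat patches
#'
#' Connected-component labelling of the suitable cells under rook
#' (4-neighbour, default) or queen (8-neighbour) adjacency, by union-find
#' over cell adjacencies. Patch ids are 1..NP in first-encounter order.
#'
#' @param binary A \code{binary_range} (or logical matrix).
#' @param connectivity "rook" or "queen".
#' @return List with \code{labels} (integer matrix, 0 = unsuitable),
#'   \code{sizes} (cells per patch), \code{np}.
#' @export
label_patches <- function(binary, connectivity = c("rook", "queen")) {
  connectivity <- match.arg(connectivity)
  v <- if (is.matrix(binary)) binary else binary$values
  nr <- nrow(v); nc <- ncol(v)
  parent <- seq_len(nr * nc)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  idx <- function(r, c) (c - 1L) * nr + r
  suit <- which(v)
  for (i in suit) {
    r <- ((i - 1L) %% nr) + 1L
    c <- ((i - 1L) %/% nr) + 1L
    if (r < nr && v[r + 1L, c]) union_(i, idx(r + 1L, c))
    if (c < nc && v[r, c + 1L]) union_(i, idx(r, c + 1L))
    if (connectivity == "queen") {
      if (r < nr && c < nc && v[r + 1L, c + 1L]) union_(i, idx(r + 1L, c + 1L))
      if (r > 1L && c < nc && v[r - 1L, c + 1L]) union_(i, idx(r - 1L, c + 1L))
    }
  }
  labels <- matrix(0L, nr, nc)
  if (length(suit)) {
    roots <- vapply(suit, find, integer(1))
    ids <- match(roots, unique(roots))
    labels[suit] <- ids
  }
  sizes <- if (length(suit)) as.integer(tabulate(labels[suit])) else integer(0)
  list(labels = labels, sizes = sizes, np = length(sizes))
}

#' Number of patches and proportion of landscape
#'
#' NP is the number of connected suitable patches; PL is the fraction of
#' valid (non-nodata) landscape cells that are suitable.
#'
#' @param binary A \code{binary_range}.
#' @param connectivity Patch adjacency rule (default rook).
#' @return List with \code{np} and \code{pl}.
#' @export
np_pl <- function(binary, connectivity = "rook") {
  lp <- label_patches(binary, connectivity)
  n_valid <- sum(!binary$nodata_mask)
  if (n_valid < 1L) stop("no valid landscape cells", call. = FALSE)
  list(np = lp$np, pl = sum(binary$values) / n_valid)
}

#' Aggregation index
#'
#' Class-level AI: 100 * g / g_max, where g is the number of rook
#' adjacencies between suitable cells (each shared edge counted once) and
#' g_max is the largest adjacency count achievable by A cells packed into
#' the most compact (near-square) arrangement. With n = floor(sqrt(A)) and
#' m = A - n^2: g_max = 2n(n-1) when m = 0; 2n(n-1) + 2m - 1 when
#' 0 < m <= n; 2n(n-1) + 2m - 2 when m > n. AI is 100 for a maximally
#' compact class and undefined (NA) when g_max = 0 (a single cell).
#'
#' @param binary A \code{binary_range} (or logical matrix) with >= 1
#'   suitable cell.
#' @return AI in \[0, 100\], or NA when undefined.
#' @export
aggregation_index <- function(binary) {
  v <- if (is.matrix(binary)) binary else binary$values
  a <- sum(v)
  if (a < 1L) stop("empty class: AI undefined", call. = FALSE)
  nr <- nrow(v); nc <- ncol(v)
  g <- 0L
  if (nr > 1L) g <- g + sum(v[-nr, ] & v[-1L, ])
  if (nc > 1L) g <- g + sum(v[, -nc] & v[, -1L])
  n <- floor(sqrt(a))
  m <- a - n^2
  g_max <- if (m == 0) 2 * n * (n - 1)
           else if (m <= n) 2 * n * (n - 1) + 2 * m - 1
           else 2 * n * (n - 1) + 2 * m - 2
  if (g_max == 0) return(NA_real_)
  100 * g / g_max
}

#' Splitting index
#'
#' SI = A_L^2 / sum(a_i^2), where A_L is the total valid landscape cell
#' count and a_i the patch sizes: the effective number of equal-sized
#' patches the landscape is subdivided into. SI = 1 when one patch covers
#' the whole landscape and grows as suitable habitat fragments.
#'
#' @param binary A \code{binary_range} with >= 1 suitable cell.
#' @param connectivity Patch adjacency rule (default rook).
#' @param denominator "landscape" (default; A_L = all valid cells) or
#'   "class" (A_L = suitable cells only).
#' @return SI >= 1.
#' @export
splitting_index <- function(binary, connectivity = "rook",
                            denominator = c("landscape", "class")) {
  denominator <- match.arg(denominator)
  lp <- label_patches(binary, connectivity)
  if (lp$np == 0L) stop("empty class: SI undefined", call. = FALSE)
  a_l <- if (denominator == "landscape") sum(!binary$nodata_mask)
         else sum(binary$values)
  a_l^2 / sum(as.numeric(lp$sizes)^2)
}

#' All landscape metrics of a binary range
#'
#' Convenience wrapper computing NP, PL, AI and SI together; AI and SI are
#' NA when the class is empty (and AI also for a single-cell class).
#'
#' @param binary A \code{binary_range}.
#' @param connectivity Patch adjacency rule (default rook).
#' @return One-row data frame with np, pl, ai, si.
#' @export
landscape_metrics <- function(binary, connectivity = "rook") {
  if (!any(binary$values))
    return(data.frame(np = 0L, pl = 0, ai = NA_real_, si = NA_real_))
  m <- np_pl(binary, connectivity)
  data.frame(np = m$np, pl = m$pl,
             ai = aggregation_index(binary),
             si = splitting_index(binary, connectivity))
}

#' Join range change, threat level and landscape metrics per scenario
#'
#' Takes the per-scenario range-change rows for one clade, attaches the
#' threat classification of each loss percentage and the landscape metrics
#' of each future range, and returns the combined risk table plus deltas
#' against the current-range metrics.
#'
#' @param clade Clade label.
#' @param changes Data frame of range-change rows with scenario id columns
#'   (gcm, rcp, period, dispersal) as produced by the pipeline.
#' @param current_binary The current-climate \code{binary_range}.
#' @param future_binaries Named list of future \code{binary_range}s, one
#'   per row of \code{changes} (names = scenario ids).
#' @param dem Optional aligned DEM for mean-altitude columns.
#' @param connectivity Patch adjacency rule (default rook).
#' @return Data frame of class \code{risk_report}, one row per scenario,
#'   with attribute \code{current} holding the current-range metrics.
#' @export
assess_risk <- function(clade, changes, current_binary, future_binaries,
                        dem = NULL, connectivity = "rook") {
  cur_m <- landscape_metrics(current_binary, connectivity)
  rows <- lapply(seq_len(nrow(changes)), function(i) {
    ch <- changes[i, , drop = FALSE]
    key <- if (!is.null(names(future_binaries))) {
      paste(ch$gcm, ch$rcp, ch$period, ch$dispersal, sep = "|")
    } else NULL
    fb <- if (!is.null(key) && key %in% names(future_binaries))
      future_binaries[[key]] else future_binaries[[i]]
    fm <- landscape_metrics(fb, connectivity)
    alt <- if (!is.null(dem) && any(fb$values))
      mean_range_altitude(fb, dem) else NA_real_
    cbind(data.frame(clade = clade), ch,
          data.frame(threat_level = threat_level(ch$loss_pct),
                     np = fm$np, pl = fm$pl, ai = fm$ai, si = fm$si,
                     mean_altitude_m = alt,
                     delta_np = fm$np - cur_m$np,
                     delta_pl = fm$pl - cur_m$pl))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "current") <- cur_m
  class(out) <- c("risk_report", "data.frame")
  out
}

#' Write a risk report as CSV
#'
#' Undefined metrics (NA) are serialized as empty fields.
#'
#' @param report A \code{risk_report}.
#' @param path Output path.
#' @export
write_risk_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE,
                   na = "", quote = FALSE)
  invisible(path)
}
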