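#' Sample pseudo-absence points
#'
#' Draws \code{n} distinct non-nodata cells uniformly at random over the
#' whole study grid (background contrast sampling) and returns their
#' cell-centre coordinates. Presence cells are not excluded.
#'
#' @param stack A \code{predictor_stack}.
#' @param n Number of pseudo-absences.
#' @param seed Integer RNG seed.
#' @return Data frame with columns \code{lon}, \code{lat}.
#' @export
sample_pseudo_absences <- function(stack, n = 10000, seed = 1) {
  n <- check_count(n, "n")
  g <- stack_geometry(stack)
  valid <- which(!g$nodata_mask)
  if (n > length(valid))
    stop(sprintf("requested %d pseudo-absences but only %d valid cells",
                 n, length(valid)), call. = FALSE)
  set.seed(seed)
  idx <- if (n == length(valid)) valid else valid[sample.int(length(valid), n)]
  rc <- arrayInd(idx, dim(g$values))
  cell_centres(g, rc[, 1L], rc[, 2L])
}

#' Extract predictor values at points
#'
#' Values of every layer at each point's containing cell. Points outside the
#' grid extent or on nodata cells are dropped with a warning.
#'
#' @param stack A \code{predictor_stack}.
#' @param points Data frame with \code{lon}, \code{lat}.
#' @return Data frame of predictor columns, one row per retained point, with
#'   attribute \code{kept} giving the retained row indices of \code{points}.
#' @export
extract_values <- function(stack, points) {
  g <- stack_geometry(stack)
  rc <- locate_cells(g, points$lon, points$lat)
  outside <- is.na(rc$row)
  idx <- (rc$col - 1L) * nrow(g$values) + rc$row
  nodata <- !outside & g$nodata_mask[cbind(rc$row, rc$col)]
  drop <- outside | nodata
  if (any(drop))
    warning(sprintf("dropped %d point(s): %d outside extent, %d on nodata",
                    sum(drop), sum(outside), sum(nodata, na.rm = TRUE)),
            call. = FALSE)
  keep <- which(!drop)
  out <- as.data.frame(lapply(stack$layers, function(l) l$values[idx[keep]]))
  names(out) <- names(stack$layers)
  attr(out, "kept") <- keep
  out
}

#' Build a presence / pseudo-absence training table
#'
#' Combines extracted presence and background rows into the model training
#' table with class labels and balancing weights (see \code{case_weights}).
#'
#' @param presence_values,absence_values Data frames of predictor values
#'   (from \code{extract_values}).
#' @return Data frame with columns \code{label} (1/0), \code{weight}, then
#'   the predictors; class \code{training_table}.
#' @export
build_training_table <- function(presence_values, absence_values) {
  if (nrow(presence_values) < 1L || nrow(absence_values) < 1L)
    stop("need at least one presence and one absence row", call. = FALSE)
  stopifnot(identical(names(presence_values), names(absence_values)))
  tab <- rbind(
    cbind(data.frame(label = 1, weight = NA_real_), presence_values),
    cbind(data.frame(label = 0, weight = NA_real_), absence_values))
  rownames(tab) <- NULL
  class(tab) <- c("training_table", "data.frame")
  case_weights(tab)
}

predictor_names <- function(table) setdiff(names(table), c("label", "weight"))

#' Class-balancing case weights
#'
#' Presences keep weight 1; each pseudo-absence gets weight
#' n_presences / n_absences, so the two classes contribute equal total
#' weight (sum of presence weights = sum of absence weights).
#'
#' @param table A training table with a \code{label} column.
#' @return The table with its \code{weight} column filled.
#' @export
case_weights <- function(table) {
  n1 <- sum(table$label == 1)
  n0 <- sum(table$label == 0)
  if (n1 < 1L || n0 < 1L)
    stop("need at least one row of each class", call. = FALSE)
  table$weight <- ifelse(table$label == 1, 1, n1 / n0)
  table
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), where R^2_j comes from the ordinary
#' least-squares regression of predictor j on all the others (with
#' intercept). Perfectly collinear predictors get \code{Inf}.
#'
#' @param table Training table (or any data frame of predictors).
#' @param predictors Character vector of columns to assess; defaults to all
#'   predictor columns.
#' @return Named numeric vector of VIFs (>= 1).
#' @export
vif <- function(table, predictors = NULL) {
  if (is.null(predictors)) predictors <- predictor_names(table)
  if (length(predictors) < 2L)
    stop("VIF needs at least two predictors", call. = FALSE)
  x <- as.matrix(as.data.frame(table)[predictors])
  if (nrow(x) <= ncol(x))
    stop("VIF needs more rows than predictors", call. = FALSE)
  out <- vapply(seq_along(predictors), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    tss <- sum((x[, j] - mean(x[, j]))^2)
    rss <- sum(fit$residuals^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- predictors
  pmax(out, 1)
}

#' Collinearity-based predictor selection
#'
#' Two-stage iterative screen. Stage A: while any predictor pair has
#' |Pearson r| above \code{cor_threshold}, take the worst pair and drop the
#' member with the higher mean absolute correlation to all remaining
#' predictors. Stage B: while any VIF exceeds \code{vif_threshold}, drop the
#' predictor with the largest VIF. Ties broken by name (lexicographic), so
#' the result is independent of input column order. The final set satisfies
#' both criteria.
#'
#' @param table Training table.
#' @param vif_threshold Maximum allowed VIF (default 6).
#' @param cor_threshold Maximum allowed absolute pairwise correlation
#'   (default 0.75).
#' @return Character vector of retained predictor names (input order), with
#'   attribute \code{log}: data frame of (dropped, reason, value) rows.
#' @export
select_predictors <- function(table, vif_threshold = 6, cor_threshold = 0.75) {
  if (vif_threshold <= 0 || cor_threshold <= 0)
    stop("thresholds must be > 0", call. = FALSE)
  all_names <- predictor_names(table)
  keep <- sort(all_names)
  x <- as.matrix(as.data.frame(table)[keep])
  log <- data.frame(dropped = character(0), reason = character(0),
                    value = numeric(0))
  drop_one <- function(nm, reason, value) {
    keep <<- setdiff(keep, nm)
    log <<- rbind(log, data.frame(dropped = nm, reason = reason, value = value))
  }
  # stage A: pairwise correlation
  repeat {
    if (length(keep) < 2L) break
    r <- abs(stats::cor(x[, keep, drop = FALSE]))
    diag(r) <- 0
    if (max(r) <= cor_threshold) break
    worst <- which(r == max(r), arr.ind = TRUE)[1L, ]
    pair <- keep[worst]                       # alphabetical within the pair
    mean_abs <- rowMeans(r[pair, , drop = FALSE])
    # drop the member more correlated with everything else; ties -> later name
    victim <- if (mean_abs[1L] > mean_abs[2L]) pair[1L] else
      if (mean_abs[2L] > mean_abs[1L]) pair[2L] else max(pair)
    drop_one(victim, "pairwise_correlation", max(r))
  }
  # stage B: VIF
  repeat {
    if (length(keep) < 2L) break
    v <- vif(table, keep)
    if (max(v) <= vif_threshold) break
    worst <- max(v)
    victim <- min(names(v)[v == worst])       # lexicographic tie-break
    drop_one(victim, "vif", worst)
  }
  if (length(keep) == 0L)
    stop("all predictors removed by collinearity screening", call. = FALSE)
  out <- all_names[all_names %in% keep]       # restore input order
  attr(out, "log") <- log
  out
}

#' Write a predictor-selection report
#'
#' JSON report of retained predictors and the removal log.
#'
#' @param selection Result of \code{select_predictors}.
#' @param path Output path.
#' @export
write_selection_report <- function(selection, path) {
  jsonlite::write_json(
    list(retained = as.character(selection),
         dropped = attr(selection, "log")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
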