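#' Generate a synthetic climate predictor stack
#'
#' Builds spatially autocorrelated pseudo-bioclim layers on a regular
#' lon/lat grid: each layer is a smoothed Gaussian random field (unit
#' variance) plus a gentle directional gradient emulating the latitudinal /
#' elevational structure of real climate surfaces. The last
#' \code{collinear_pairs} layers are scaled copies of the first base layers
#' with small added noise, so exactly that many layer pairs are strongly
#' collinear (|Pearson r| > 0.8) by construction — the situation the
#' VIF/correlation screen must resolve.
#'
#' @param seed Integer RNG seed; the stack is a pure function of its
#'   arguments and this seed.
#' @param n_layers Total number of layers (>= 2).
#' @param n_rows,n_cols Grid dimensions (positive).
#' @param autocorr_range_cells Spatial autocorrelation range, in cells
#'   (Gaussian smoothing kernel width; >= 1).
#' @param collinear_pairs Number of collinear layer pairs to build in
#'   (0 <= collinear_pairs < n_layers).
#' @param origin_lon,origin_lat,cell_size Grid georeference.
#' @return A \code{predictor_stack} with layers named bio1, bio4, bio5,
#'   bio12, bio14, bio15, then bio16, bio17, ... for extra layers.
#' @export
make_climate_stack <- function(seed, n_layers = 6, n_rows = 100, n_cols = 100,
                               autocorr_range_cells = 10, collinear_pairs = 0,
                               origin_lon = 35, origin_lat = 40,
                               cell_size = 0.01) {
  n_layers <- check_count(n_layers, "n_layers", 2L)
  n_rows <- check_count(n_rows, "n_rows")
  n_cols <- check_count(n_cols, "n_cols")
  collinear_pairs <- check_count(collinear_pairs, "collinear_pairs", 0L)
  if (autocorr_range_cells < 1)
    stop("`autocorr_range_cells` must be >= 1", call. = FALSE)
  n_base <- n_layers - collinear_pairs
  if (n_base < 1L || collinear_pairs > n_base)
    stop("`collinear_pairs` must be < n_layers and <= n_layers - collinear_pairs",
         call. = FALSE)

  base_names <- c("bio1", "bio4", "bio5", "bio12", "bio14", "bio15")
  if (n_layers > length(base_names))
    base_names <- c(base_names, paste0("bio", 15 + seq_len(n_layers - 6)))
  nms <- base_names[seq_len(n_layers)]

  set.seed(seed)
  rowg <- matrix(seq(-1, 1, length.out = n_rows), n_rows, n_cols)
  colg <- matrix(seq(-1, 1, length.out = n_cols), n_rows, n_cols, byrow = TRUE)
  layers <- vector("list", n_layers)
  for (i in seq_len(n_base)) {
    ang <- 2 * pi * (i - 1) / max(1L, n_base)
    grad <- cos(ang) * rowg + sin(ang) * colg
    f <- gaussian_field(n_rows, n_cols, autocorr_range_cells) + 0.6 * grad
    layers[[i]] <- (f - mean(f)) / stats::sd(f)
  }
  # collinear copies: scaled base plus small independent noise, |r| ~ 0.99,
  # so a model keeping either member of a pair sees the same signal
  collinear_info <- data.frame(copy = character(0), base = character(0),
                               slope = numeric(0))
  for (j in seq_len(collinear_pairs)) {
    src <- layers[[j]]
    eps <- gaussian_field(n_rows, n_cols, autocorr_range_cells)
    f <- 1.5 * src + 0.15 * eps
    layers[[n_base + j]] <- (f - mean(f)) / stats::sd(f)
    collinear_info <- rbind(collinear_info,
                            data.frame(copy = nms[n_base + j], base = nms[j],
                                       slope = 1.5 / stats::sd(f)))
  }
  names(layers) <- nms
  out <- predictor_stack(lapply(layers, raster_grid,
                                origin_lon = origin_lon,
                                origin_lat = origin_lat,
                                cell_size = cell_size))
  attr(out, "collinear_info") <- collinear_info
  out
}

#' Expand a layer shift coherently over collinear copies
#'
#' Climate variables that are strongly collinear under current climate move
#' together under warming; a perturbation that shifts a base layer must
#' shift its built-in collinear copies proportionally, or models that
#' retained the copy (rather than the base) after collinearity screening
#' would see no change at all. Uses the copy structure recorded by
#' \code{make_climate_stack}.
#'
#' @param stack A stack from \code{make_climate_stack}.
#' @param shift Named numeric vector of base-layer shifts.
#' @return The shift vector with entries added/augmented for collinear
#'   copies of the shifted layers.
#' @export
expand_shift <- function(stack, shift) {
  info <- attr(stack, "collinear_info")
  if (is.null(info) || !nrow(info)) return(shift)
  for (k in seq_len(nrow(info))) {
    b <- info$base[k]
    if (b %in% names(shift)) {
      add <- info$slope[k] * shift[[b]]
      cp <- info$copy[k]
      shift[cp] <- if (cp %in% names(shift)) shift[[cp]] + add else add
    }
  }
  shift
}

#' Generate a synthetic mountainous DEM
#'
#' Smooth ridged elevation surface in metres, non-negative, with total relief
#' (max - min) within 10\% of \code{relief_m}.
#'
#' @param seed Integer RNG seed.
#' @param n_rows,n_cols Grid dimensions.
#' @param relief_m Target elevation range in metres (> 0).
#' @param origin_lon,origin_lat,cell_size Grid georeference.
#' @return A \code{raster_grid} of elevations.
#' @export
make_dem <- function(seed, n_rows = 100, n_cols = 100, relief_m = 3000,
                     origin_lon = 35, origin_lat = 40, cell_size = 0.01) {
  n_rows <- check_count(n_rows, "n_rows")
  n_cols <- check_count(n_cols, "n_cols")
  if (!is.numeric(relief_m) || relief_m <= 0)
    stop("`relief_m` must be > 0", call. = FALSE)
  set.seed(seed)
  f <- gaussian_field(n_rows, n_cols, max(2, min(n_rows, n_cols) / 8))
  ridged <- abs(f)                        # fold the field into ridge lines
  elev <- (max(ridged) - ridged)          # ridges high, folds low
  elev <- (elev - min(elev)) / (max(elev) - min(elev)) * relief_m
  raster_grid(elev, origin_lon = origin_lon, origin_lat = origin_lat,
              cell_size = cell_size)
}

#' Generate a synthetic human-footprint layer
#'
#' Integer 0-100 human-pressure index with spatially clustered developed
#' areas. The fraction of cells exceeding 50 ("developed") matches
#' \code{developed_fraction} to within 0.02 by quantile construction.
#'
#' @param seed Integer RNG seed.
#' @param grid Reference \code{raster_grid} supplying the geometry.
#' @param developed_fraction Target fraction of cells with value > 50,
#'   in \[0, 1\].
#' @return A \code{raster_grid} of integers in \[0, 100\].
#' @export
make_footprint <- function(seed, grid, developed_fraction = 0.1) {
  if (!inherits(grid, "raster_grid")) stop("`grid` must be a raster_grid",
                                           call. = FALSE)
  if (developed_fraction < 0 || developed_fraction > 1)
    stop("`developed_fraction` must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  f <- gaussian_field(nrow(grid$values), ncol(grid$values),
                      max(2, min(dim(grid$values)) / 10))
  # map the field through its empirical CDF so the >50 fraction is exact at
  # the cut, then rescale: cells above the (1 - fraction) quantile land in
  # (50, 100], the rest in [0, 50]
  r <- rank(f, ties.method = "first") / length(f)
  cut <- 1 - developed_fraction
  v <- ifelse(r > cut,
              50 + (r - cut) / max(developed_fraction, 1e-12) * 50,
              r / max(cut, 1e-12) * 50)
  vals <- matrix(as.numeric(pmin(100L, pmax(0L, round(v)))),
                 nrow(grid$values), ncol(grid$values))
  # rounding can push boundary cells across 50; nudge to honour the target
  if (developed_fraction == 0) vals[vals > 50] <- 50
  raster_grid(vals, origin_lon = grid$origin_lon, origin_lat = grid$origin_lat,
              cell_size = grid$cell_size)
}

#' Define a virtual species
#'
#' A known quadratic-logistic suitability surface used as ground truth:
#' suitability = logistic(intercept + sum(linear * x + quadratic * x^2))
#' over named predictors. Quadratic coefficients must be <= 0 so the niche
#' is unimodal.
#'
#' @param coefficients Named list; each element a numeric pair
#'   (linear, quadratic) for one predictor.
#' @param intercept Intercept on the logit scale.
#' @param prevalence_target Optional fraction in (0, 1); when given,
#'   \code{true_suitability} shifts the intercept so mean suitability matches
#'   it to within 0.02.
#' @return An object of class \code{virtual_species}.
#' @export
virtual_species <- function(coefficients, intercept = 0,
                            prevalence_target = NULL) {
  if (length(coefficients) < 1L || is.null(names(coefficients)))
    stop("`coefficients` must be a named list", call. = FALSE)
  for (cf in coefficients) {
    if (length(cf) != 2L || !is.numeric(cf))
      stop("each coefficient must be a (linear, quadratic) pair", call. = FALSE)
    if (cf[2L] > 0)
      stop("quadratic coefficients must be <= 0 (unimodal niche)", call. = FALSE)
  }
  if (all(vapply(coefficients, function(cf) all(cf == 0), logical(1))))
    stop("at least one coefficient must be nonzero", call. = FALSE)
  if (!is.null(prevalence_target) &&
      (prevalence_target <= 0 || prevalence_target >= 1))
    stop("`prevalence_target` must be in (0, 1)", call. = FALSE)
  structure(list(coefficients = coefficients, intercept = intercept,
                 prevalence_target = prevalence_target),
            class = "virtual_species")
}

#' True suitability surface of a virtual species
#'
#' Evaluates the quadratic-logistic niche cellwise over a predictor stack.
#' When the species carries a prevalence target, the intercept is adjusted by
#' bisection so mean suitability over valid cells is within 0.02 of it.
#'
#' @param stack A \code{predictor_stack} containing every predictor the
#'   species references.
#' @param species A \code{virtual_species}.
#' @return A \code{raster_grid} of suitabilities in (0, 1).
#' @export
true_suitability <- function(stack, species) {
  miss <- setdiff(names(species$coefficients), names(stack$layers))
  if (length(miss))
    stop("species references predictors missing from the stack: ",
         paste(miss, collapse = ", "), call. = FALSE)
  g <- stack_geometry(stack)
  eta <- matrix(species$intercept, nrow(g$values), ncol(g$values))
  for (nm in names(species$coefficients)) {
    cf <- species$coefficients[[nm]]
    x <- stack$layers[[nm]]$values
    eta <- eta + cf[1L] * x + cf[2L] * x^2
  }
  valid <- !g$nodata_mask
  if (!is.null(species$prevalence_target)) {
    target <- species$prevalence_target
    prev <- function(d) mean(logistic(eta[valid] + d))
    lo <- -50; hi <- 50
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (prev(mid) < target) lo <- mid else hi <- mid
      if (abs(prev(mid) - target) < 1e-4) break
    }
    eta <- eta + (lo + hi) / 2
  }
  suit <- logistic(eta)
  suit[g$nodata_mask] <- NA_real_
  raster_grid(suit, origin_lon = g$origin_lon, origin_lat = g$origin_lat,
              cell_size = g$cell_size, nodata_mask = g$nodata_mask)
}

#' Sample virtual occurrences from a suitability surface
#'
#' Draws \code{n} distinct cells without replacement with probability
#' proportional to suitability (one occurrence per cell, mimicking spatially
#' thinned field records) and returns their cell-centre coordinates.
#'
#' @param suitability A \code{raster_grid} of suitabilities.
#' @param n Number of occurrences (>= 1).
#' @param seed Integer RNG seed.
#' @param clade Clade label to attach to the points.
#' @return An \code{occurrence_set}.
#' @export
sample_occurrences <- function(suitability, n, seed, clade = "virtual") {
  n <- check_count(n, "n")
  v <- as.vector(suitability$values)
  v[as.vector(suitability$nodata_mask)] <- 0
  v[is.na(v)] <- 0
  pos <- which(v > 0)
  if (n > length(pos))
    stop(sprintf("cannot sample %d occurrences: only %d cells have positive suitability",
                 n, length(pos)), call. = FALSE)
  set.seed(seed)
  idx <- pos[sample.int(length(pos), n, prob = v[pos])]
  rc <- arrayInd(idx, dim(suitability$values))
  pts <- cell_centres(suitability, rc[, 1L], rc[, 2L])
  occurrence_set(data.frame(id = sprintf("occ%04d", seq_len(n)),
                            clade = clade, lon = pts$lon, lat = pts$lat,
                            stringsAsFactors = FALSE),
                 provenance = sprintf("synthetic (seed %d)", seed))
}

#' Freeze a virtual species' intercept on a reference stack
#'
#' Resolves the prevalence-targeted intercept against the given (current)
#' stack and returns a species with that intercept fixed and no prevalence
#' target. Needed before evaluating truth on perturbed stacks: otherwise the
#' prevalence adjustment would re-calibrate on the future climate and cancel
#' the perturbation.
#'
#' @param stack Reference \code{predictor_stack}.
#' @param species A \code{virtual_species}.
#' @return A \code{virtual_species} with fixed intercept.
#' @export
freeze_intercept <- function(stack, species) {
  if (is.null(species$prevalence_target)) return(species)
  suit <- true_suitability(stack, species)
  v <- suit$values[!suit$nodata_mask]
  # recover the shifted intercept from any one cell's logit
  g <- stack_geometry(stack)
  eta0 <- matrix(0, nrow(g$values), ncol(g$values))
  for (nm in names(species$coefficients)) {
    cf <- species$coefficients[[nm]]
    x <- stack$layers[[nm]]$values
    eta0 <- eta0 + cf[1L] * x + cf[2L] * x^2
  }
  cell <- which(!g$nodata_mask)[1L]
  intercept <- stats::qlogis(suit$values[cell]) - eta0[cell]
  virtual_species(species$coefficients, intercept = intercept,
                  prevalence_target = NULL)
}

#' Define a future-climate scenario perturbation
#'
#' Phenomenological stand-in for one GCM x RCP x period projection: each
#' named layer is shifted additively, plus a smooth Gaussian noise field of
#' standard deviation \code{noise_sd} representing between-GCM disagreement.
#'
#' @param gcm_name,rcp_name,period Scenario labels.
#' @param additive_shift Named numeric vector of per-layer shifts (layer
#'   units).
#' @param noise_sd Standard deviation of the smooth noise field (>= 0).
#' @return An object of class \code{scenario_perturbation}.
#' @export
scenario_perturbation <- function(gcm_name, rcp_name = "rcp85",
                                  period = "2070", additive_shift,
                                  noise_sd = 0) {
  if (is.null(names(additive_shift)) || any(names(additive_shift) == ""))
    stop("`additive_shift` must be a named vector", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(gcm_name = gcm_name, rcp_name = rcp_name, period = period,
                 additive_shift = additive_shift, noise_sd = noise_sd),
            class = "scenario_perturbation")
}

#' Apply a scenario perturbation to a predictor stack
#'
#' Shifts each named layer by its additive term plus (if \code{noise_sd} > 0)
#' a smooth zero-mean noise field. The noise stream is derived from the seed
#' and the scenario labels, so different GCM names give distinct fields under
#' one master seed. Geometry and nodata mask are preserved.
#'
#' @param current A \code{predictor_stack}.
#' @param pert A \code{scenario_perturbation}; perturbed names must be a
#'   subset of the stack's layer names.
#' @param seed Integer master seed.
#' @return A perturbed \code{predictor_stack}.
#' @export
make_future_stack <- function(current, pert, seed) {
  miss <- setdiff(names(pert$additive_shift), names(current$layers))
  if (length(miss))
    stop("perturbation names not in stack: ", paste(miss, collapse = ", "),
         call. = FALSE)
  set.seed(derive_seed(seed, pert$gcm_name, pert$rcp_name, pert$period))
  layers <- current$layers
  for (nm in names(pert$additive_shift)) {
    g <- layers[[nm]]
    v <- g$values + pert$additive_shift[[nm]]
    if (pert$noise_sd > 0) {
      noise <- gaussian_field(nrow(v), ncol(v), max(2, min(dim(v)) / 10))
      v <- v + pert$noise_sd * noise
    }
    v[g$nodata_mask] <- NA_real_
    layers[[nm]] <- raster_grid(v, origin_lon = g$origin_lon,
                                origin_lat = g$origin_lat,
                                cell_size = g$cell_size,
                                nodata_mask = g$nodata_mask)
  }
  predictor_stack(layers)
}

#' Calibrate a perturbation to a target true range loss
#'
#' Finds the scalar multiple of a shift direction whose perturbed true
#' suitability, thresholded at \code{cutoff}, loses the target percentage of
#' the current true range (no-dispersal loss). This gives synthetic scenarios
#' with known ground-truth losses against which the full estimation pipeline
#' can be scored.
#'
#' @param stack Current-climate \code{predictor_stack}.
#' @param species A \code{virtual_species}.
#' @param target_loss_pct Desired true loss percentage in (0, 100).
#' @param direction Named numeric vector: per-unit layer shifts defining the
#'   perturbation direction.
#' @param cutoff Suitability threshold defining the true range (default 0.5).
#' @param max_scale Upper bound for the search.
#' @return List with elements \code{scale}, \code{shift} (named vector),
#'   \code{achieved_loss_pct}.
#' @export
calibrate_perturbation <- function(stack, species, target_loss_pct,
                                   direction, cutoff = 0.5, max_scale = 20) {
  if (target_loss_pct <= 0 || target_loss_pct >= 100)
    stop("`target_loss_pct` must be in (0, 100)", call. = FALSE)
  species <- freeze_intercept(stack, species)
  cur <- true_suitability(stack, species)
  cur_bin <- !cur$nodata_mask & cur$values >= cutoff
  if (!any(cur_bin)) stop("current true range is empty at this cutoff",
                          call. = FALSE)
  loss_at <- function(s) {
    pert <- scenario_perturbation("calib", "na", "na", s * direction,
                                  noise_sd = 0)
    fut <- true_suitability(make_future_stack(stack, pert, seed = 1), species)
    fut_bin <- !fut$nodata_mask & fut$values >= cutoff
    100 * sum(cur_bin & !fut_bin) / sum(cur_bin)
  }
  if (loss_at(max_scale) < target_loss_pct)
    stop("target loss not reachable within `max_scale`", call. = FALSE)
  root <- stats::uniroot(function(s) loss_at(s) - target_loss_pct,
                         lower = 0, upper = max_scale, tol = 1e-4)
  list(scale = root$root, shift = root$root * direction,
       achieved_loss_pct = loss_at(root$root))
}
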