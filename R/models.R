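new_enm_fit <- function(algorithm, predictors, scaling, payload, settings) {
  structure(list(algorithm = algorithm, predictors = predictors,
                 scaling = scaling, payload = payload, settings = settings),
            class = "enm_fit")
}

#' @export
print.enm_fit <- function(x, ...) {
  cat(sprintf("<enm_fit> %s on %d predictor(s): %s\n", x$algorithm,
              length(x$predictors), paste(x$predictors, collapse = ", ")))
  invisible(x)
}

scaling_from <- function(table, predictors) {
  x <- as.data.frame(table)[predictors]
  list(center = vapply(x, mean, numeric(1)),
       scale = vapply(x, function(v) {
         s <- stats::sd(v); if (is.na(s) || s == 0) 1 else s
       }, numeric(1)))
}

standardize <- function(df, scaling) {
  out <- df
  for (nm in names(scaling$center))
    out[[nm]] <- (df[[nm]] - scaling$center[[nm]]) / scaling$scale[[nm]]
  out
}

check_table <- function(table, predictors) {
  miss <- setdiff(predictors, names(table))
  if (length(miss))
    stop("training table lacks predictors: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(c(0, 1) %in% table$label))
    stop("training table needs both classes", call. = FALSE)
  invisible(TRUE)
}

#' Fit a weighted binomial GLM with stepwise AIC selection
#'
#' Candidate terms are the standardized predictors and their squares; the
#' model starts from the full set and bidirectional stepwise selection
#' (drop or re-add one term per move) minimizes AIC, so the selected model's
#' AIC never exceeds the full model's. Rows are weighted by the table's
#' class-balancing weights.
#'
#' @param table A training table (\code{build_training_table}).
#' @param predictors Predictor columns to use; default all.
#' @return An \code{enm_fit} of algorithm \code{"GLM"}.
#' @export
fit_glm <- function(table, predictors = NULL) {
  if (is.null(predictors)) predictors <- predictor_names(table)
  check_table(table, predictors)
  scaling <- scaling_from(table, predictors)
  dat <- standardize(as.data.frame(table), scaling)
  terms <- unlist(lapply(predictors, function(p) c(p, sprintf("I(%s^2)", p))))
  full_formula <- stats::reformulate(terms, response = "label")
  dat$.w <- table$weight
  fit <- suppressWarnings(
    stats::glm(full_formula, family = stats::binomial(), data = dat,
               weights = .w))
  if (!fit$converged)
    stop("GLM fitting failed to converge", call. = FALSE)
  sel <- suppressWarnings(
    stats::step(fit, scope = list(lower = stats::as.formula("label ~ 1"),
                                  upper = full_formula),
                direction = "both", trace = 0))
  new_enm_fit("GLM", predictors, scaling,
              payload = list(model = sel,
                             full_aic = stats::AIC(fit),
                             selected_aic = stats::AIC(sel)),
              settings = list())
}

#' Fit stochastic gradient-boosted classification trees
#'
#' Bernoulli-loss boosted trees honouring the classic SDM settings: up to
#' \code{n_trees} trees, small learning rate, bagging of half the rows per
#' tree, and the table's class-balancing row weights. Tree growth is
#' deterministic for a fixed seed.
#'
#' @param table A training table.
#' @param predictors Predictor columns; default all.
#' @param n_trees Maximum number of trees (default 2500).
#' @param learning_rate Shrinkage per tree (default 0.001).
#' @param bag_fraction Row subsample fraction per tree (default 0.5).
#' @param max_depth Tree depth (default 3).
#' @param seed Integer seed for the subsampling stream.
#' @return An \code{enm_fit} of algorithm \code{"GBM"}.
#' @export
fit_gbm <- function(table, predictors = NULL, n_trees = 2500,
                    learning_rate = 0.001, bag_fraction = 0.5,
                    max_depth = 3, seed = 1) {
  if (is.null(predictors)) predictors <- predictor_names(table)
  check_table(table, predictors)
  x <- as.matrix(as.data.frame(table)[predictors])
  d <- xgboost::xgb.DMatrix(x, label = table$label, weight = table$weight)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = learning_rate,
                  subsample = bag_fraction, max_depth = max_depth,
                  nthread = 1, seed = as.integer(seed)),
    data = d, nrounds = n_trees, verbose = 0)
  new_enm_fit("GBM", predictors, scaling = NULL,
              payload = list(booster = booster),
              settings = list(n_trees = n_trees, learning_rate = learning_rate,
                              bag_fraction = bag_fraction,
                              max_depth = max_depth, seed = seed))
}

#' Fit a surface range envelope (BIOCLIM-style)
#'
#' Builds, from the presence rows only, a per-predictor interval
#' \[quantile(q/2), quantile(1 - q/2)\] where q = \code{trim_quantile}
#' (linear-interpolation quantiles), trimming the most extreme presence
#' values. A point is predicted suitable (1) iff every predictor falls
#' inside its interval, else 0.
#'
#' @param table A training table with >= 2 presence rows.
#' @param predictors Predictor columns; default all.
#' @param trim_quantile Total tail mass to trim, split across both tails
#'   (default 0.05); must be < 1.
#' @return An \code{enm_fit} of algorithm \code{"SRE"}.
#' @export
fit_sre <- function(table, predictors = NULL, trim_quantile = 0.05) {
  if (is.null(predictors)) predictors <- predictor_names(table)
  check_table(table, predictors)
  if (trim_quantile < 0 || trim_quantile >= 1)
    stop("`trim_quantile` must be in [0, 1)", call. = FALSE)
  pres <- as.data.frame(table)[table$label == 1, predictors, drop = FALSE]
  if (nrow(pres) < 2L)
    stop("SRE needs at least two presence rows", call. = FALSE)
  bounds <- lapply(pres, function(v)
    stats::quantile(v, c(trim_quantile / 2, 1 - trim_quantile / 2),
                    names = FALSE, type = 7))
  new_enm_fit("SRE", predictors, scaling = NULL,
              payload = list(bounds = bounds),
              settings = list(trim_quantile = trim_quantile))
}

# MaxEnt-style feature expansion: linear, quadratic, pairwise product and
# (forward + reverse) hinge features at data-derived knots, all on the
# standardized scale.
maxent_features <- function(df, predictors, knots) {
  n <- nrow(df)
  cols <- list()
  for (p in predictors) {
    x <- df[[p]]
    cols[[p]] <- x
    cols[[paste0(p, "^2")]] <- x^2
  }
  if (length(predictors) > 1L) {
    cmb <- utils::combn(predictors, 2L)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1L, k]; b <- cmb[2L, k]
      cols[[paste0(a, "*", b)]] <- df[[a]] * df[[b]]
    }
  }
  for (p in predictors) {
    x <- df[[p]]
    for (k in knots[[p]]) {
      cols[[sprintf("h(%s>%.3g)", p, k)]] <- pmax(0, x - k)
      cols[[sprintf("h(%s<%.3g)", p, k)]] <- pmax(0, k - x)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- NULL
  m
}

#' Fit a MaxEnt-style penalized presence-background model
#'
#' L1-regularized weighted logistic regression over an expanded feature
#' basis (linear, quadratic, pairwise products and hinge features at
#' data-derived quantile knots) — the penalized presence-background logistic
#' equivalent of maximum-entropy niche modelling. The penalty is chosen by
#' BIC along the regularization path and scaled by
#' \code{reg_multiplier}; optimization is capped at \code{max_iterations}
#' passes.
#'
#' @param table A training table.
#' @param predictors Predictor columns; default all.
#' @param max_iterations Iteration cap for the optimizer (default 200).
#' @param n_knots Hinge knots per predictor per direction (default 4).
#' @param reg_multiplier Multiplier on the BIC-selected penalty (default 1).
#' @return An \code{enm_fit} of algorithm \code{"MAXENT"}.
#' @export
fit_maxent_like <- function(table, predictors = NULL, max_iterations = 200,
                            n_knots = 4, reg_multiplier = 1) {
  if (is.null(predictors)) predictors <- predictor_names(table)
  check_table(table, predictors)
  scaling <- scaling_from(table, predictors)
  dat <- standardize(as.data.frame(table), scaling)
  knots <- lapply(dat[predictors], function(x)
    unique(stats::quantile(x, seq_len(n_knots) / (n_knots + 1),
                           names = FALSE, type = 7)))
  feats <- maxent_features(dat, predictors, knots)
  keep <- apply(feats, 2L, function(v) stats::sd(v) > 0)
  w <- table$weight
  if (!any(keep)) {
    # degenerate basis: intercept-only model at the weighted prevalence
    p0 <- sum(w * table$label) / sum(w)
    return(new_enm_fit("MAXENT", predictors, scaling,
                       payload = list(constant = p0, knots = knots),
                       settings = list(max_iterations = max_iterations,
                                       n_knots = n_knots,
                                       reg_multiplier = reg_multiplier)))
  }
  feats <- feats[, keep, drop = FALSE]
  fit <- suppressWarnings(
    glmnet::glmnet(feats, table$label, family = "binomial", weights = w,
                   alpha = 1, maxit = max_iterations * 1000))
  # BIC over the path: deviance + log(effective n) * active features
  n_eff <- sum(w)
  dev <- (1 - fit$dev.ratio) * fit$nulldev
  bic <- dev + log(n_eff) * fit$df
  lambda <- fit$lambda[which.min(bic)] * reg_multiplier
  new_enm_fit("MAXENT", predictors, scaling,
              payload = list(glmnet = fit, lambda = lambda,
                             feature_names = colnames(feats), knots = knots),
              settings = list(max_iterations = max_iterations,
                              n_knots = n_knots,
                              reg_multiplier = reg_multiplier))
}

# Predict suitability for rows of raw (unstandardized) predictor values.
predict_rows <- function(model, df) {
  df <- as.data.frame(df)
  switch(model$algorithm,
    GLM = {
      nd <- standardize(df, model$scaling)
      as.numeric(stats::predict(model$payload$model, newdata = nd,
                                type = "response"))
    },
    GBM = {
      x <- as.matrix(df[model$predictors])
      as.numeric(stats::predict(model$payload$booster,
                                xgboost::xgb.DMatrix(x)))
    },
    SRE = {
      inside <- rep(TRUE, nrow(df))
      for (p in model$predictors) {
        b <- model$payload$bounds[[p]]
        inside <- inside & df[[p]] >= b[1L] & df[[p]] <= b[2L]
      }
      as.numeric(inside)
    },
    MAXENT = {
      if (!is.null(model$payload$constant))
        return(rep(model$payload$constant, nrow(df)))
      nd <- standardize(df, model$scaling)
      feats <- maxent_features(nd, model$predictors, model$payload$knots)
      feats <- feats[, model$payload$feature_names, drop = FALSE]
      as.numeric(stats::predict(model$payload$glmnet, newx = feats,
                                s = model$payload$lambda, type = "response"))
    },
    stop("unknown algorithm: ", model$algorithm, call. = FALSE))
}

#' Predict suitability over a predictor stack
#'
#' Cellwise model prediction in \[0, 1\]; nodata cells propagate as nodata.
#' Standardization constants stored at training time are reused.
#'
#' @param object An \code{enm_fit}.
#' @param newdata A \code{predictor_stack} (returns a suitability
#'   \code{raster_grid}) or a data frame of predictor columns (returns a
#'   numeric vector).
#' @param ... Unused.
#' @return A \code{raster_grid} suitability map, or a numeric vector.
#' @export
predict.enm_fit <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) return(predict_rows(object, newdata))
  if (!inherits(newdata, "predictor_stack"))
    stop("`newdata` must be a predictor_stack or data frame", call. = FALSE)
  miss <- setdiff(object$predictors, names(newdata$layers))
  if (length(miss))
    stop("stack lacks model predictors: ", paste(miss, collapse = ", "),
         call. = FALSE)
  g <- stack_geometry(newdata)
  m <- stack_as_matrix(newdata)[, object$predictors, drop = FALSE]
  valid <- stats::complete.cases(m)
  p <- rep(NA_real_, nrow(m))
  if (any(valid))
    p[valid] <- pmin(1, pmax(0, predict_rows(object,
                                             as.data.frame(m[valid, ,
                                                             drop = FALSE]))))
  vals <- matrix(p, nrow(g$values), ncol(g$values))
  raster_grid(vals, origin_lon = g$origin_lon, origin_lat = g$origin_lat,
              cell_size = g$cell_size,
              nodata_mask = g$nodata_mask | is.na(vals))
}
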