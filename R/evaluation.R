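#' Stratified split-sample partition
#'
#' Splits a training table into train and test sets, stratified by class:
#' each class is split at \code{train_fraction} (rounded to nearest, at
#' least one row per side). The two parts are disjoint and exhaustive.
#'
#' @param table A training table.
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.75).
#' @param seed Integer RNG seed.
#' @return List with elements \code{train} and \code{test}.
#' @export
split_sample <- function(table, train_fraction = 0.75, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  set.seed(seed)
  train_idx <- integer(0)
  for (cls in c(0, 1)) {
    rows <- which(table$label == cls)
    if (length(rows) < 2L)
      stop("each class needs at least 2 rows to split", call. = FALSE)
    k <- round(length(rows) * train_fraction)
    k <- min(max(k, 1L), length(rows) - 1L)
    train_idx <- c(train_idx, sample(rows, k))
  }
  train <- table[sort(train_idx), , drop = FALSE]
  test <- table[setdiff(seq_len(nrow(table)), train_idx), , drop = FALSE]
  list(train = case_weights(train), test = test)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' presence scores higher than a randomly chosen absence, counting ties as
#' one half, over all presence x absence pairs. Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels, both classes present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("AUC needs both classes", call. = FALSE)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' True skill statistic
#'
#' Maximizes sensitivity + specificity - 1 over candidate thresholds (all
#' distinct score values), with a cell predicted present when its score is
#' >= the threshold. Returns the maximum and the smallest threshold
#' achieving it.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels, both classes present.
#' @return List with \code{tss} and \code{threshold}.
#' @export
tss <- function(scores, labels) {
  pos <- labels == 1
  if (!any(pos) || all(pos)) stop("TSS needs both classes", call. = FALSE)
  cand <- sort(unique(scores))
  n1 <- sum(pos); n0 <- sum(!pos)
  best <- -Inf; best_thr <- cand[1L]
  for (thr in cand) {
    pred <- scores >= thr
    val <- sum(pred & pos) / n1 + sum(!pred & !pos) / n0 - 1
    if (val > best + 1e-12) { best <- val; best_thr <- thr }
  }
  list(tss = best, threshold = best_thr)
}

algorithm_settings_defaults <- function() {
  list(GLM = list(),
       GBM = list(n_trees = 2500, learning_rate = 0.001, bag_fraction = 0.5,
                  max_depth = 3),
       SRE = list(trim_quantile = 0.05),
       MAXENT = list(max_iterations = 200, n_knots = 4, reg_multiplier = 1))
}

fit_algorithm <- function(table, algorithm, predictors = NULL,
                          settings = list(), seed = 1) {
  s <- utils::modifyList(algorithm_settings_defaults()[[algorithm]],
                         settings)
  switch(algorithm,
    GLM = fit_glm(table, predictors),
    GBM = fit_gbm(table, predictors, n_trees = s$n_trees,
                  learning_rate = s$learning_rate,
                  bag_fraction = s$bag_fraction, max_depth = s$max_depth,
                  seed = seed),
    SRE = fit_sre(table, predictors, trim_quantile = s$trim_quantile),
    MAXENT = fit_maxent_like(table, predictors,
                             max_iterations = s$max_iterations,
                             n_knots = s$n_knots,
                             reg_multiplier = s$reg_multiplier),
    stop("unknown algorithm: ", algorithm, call. = FALSE))
}

#' Repeated split-sample evaluation
#'
#' Runs \code{n_replicates} stratified splits; within a replicate every
#' algorithm is fit on the same training part and scored (unweighted AUC and
#' TSS) on the same held-out part. Fitting failures are recorded as a
#' warning and the algorithm's record for that replicate is skipped.
#'
#' @param table A training table.
#' @param algorithms Character vector from \{"GLM", "GBM", "SRE",
#'   "MAXENT"\}.
#' @param n_replicates Number of split-sample replicates (default 10).
#' @param train_fraction Training fraction per split (default 0.75).
#' @param seed Integer master seed.
#' @param settings Optional named list of per-algorithm setting overrides.
#' @param predictors Predictor columns; default all.
#' @return Data frame with columns algorithm, replicate, auc, tss,
#'   tss_threshold.
#' @export
evaluate_replicates <- function(table, algorithms = c("GLM", "GBM", "SRE",
                                                      "MAXENT"),
                                n_replicates = 10, train_fraction = 0.75,
                                seed = 1, settings = list(),
                                predictors = NULL) {
  out <- list()
  for (rep in seq_len(n_replicates)) {
    parts <- split_sample(table, train_fraction,
                          seed = derive_seed(seed, "split", rep))
    for (alg in algorithms) {
      rec <- tryCatch({
        m <- fit_algorithm(parts$train, alg, predictors,
                           settings = if (alg %in% names(settings))
                             settings[[alg]] else list(),
                           seed = derive_seed(seed, "fit", alg, rep))
        sc <- predict_rows(m, parts$test)
        t <- tss(sc, parts$test$label)
        data.frame(algorithm = alg, replicate = rep,
                   auc = auc(sc, parts$test$label),
                   tss = t$tss, tss_threshold = t$threshold)
      }, error = function(e) {
        warning(sprintf("replicate %d: %s fit failed (%s); skipped",
                        rep, alg, conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (!is.null(rec)) out[[length(out) + 1L]] <- rec
    }
  }
  do.call(rbind, out)
}

#' Build an AUC-weighted ensemble from fitted members
#'
#' Member weights are proportional to each algorithm's mean AUC over the
#' evaluation replicates and normalized to sum to one.
#'
#' @param models Named list of \code{enm_fit} objects (names = algorithms).
#' @param eval_records Evaluation data frame from
#'   \code{evaluate_replicates}.
#' @return An object of class \code{enm_ensemble}.
#' @export
build_ensemble <- function(models, eval_records) {
  algs <- names(models)
  mean_auc <- vapply(algs, function(a) {
    v <- eval_records$auc[eval_records$algorithm == a]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  if (anyNA(mean_auc) || any(mean_auc <= 0))
    stop("every ensemble member needs a positive mean AUC", call. = FALSE)
  structure(list(members = models, weights = mean_auc / sum(mean_auc),
                 mean_auc = mean_auc),
            class = "enm_ensemble")
}

#' Predict an ensemble suitability map
#'
#' Cellwise weighted mean of the member predictions; bounded by the member
#' min/max at every cell.
#'
#' @param object An \code{enm_ensemble}.
#' @param newdata A \code{predictor_stack} or data frame.
#' @param ... Unused.
#' @return A \code{raster_grid} suitability map, or numeric vector.
#' @export
predict.enm_ensemble <- function(object, newdata, ...) {
  preds <- lapply(object$members, predict, newdata = newdata)
  if (is.data.frame(newdata)) {
    out <- 0
    for (i in seq_along(preds)) out <- out + object$weights[i] * preds[[i]]
    return(as.numeric(out))
  }
  g <- preds[[1L]]
  vals <- matrix(0, nrow(g$values), ncol(g$values))
  for (i in seq_along(preds)) {
    v <- preds[[i]]$values
    v[preds[[i]]$nodata_mask] <- 0
    vals <- vals + object$weights[i] * v
  }
  mask <- Reduce(`|`, lapply(preds, function(p) p$nodata_mask))
  vals[mask] <- NA_real_
  raster_grid(vals, origin_lon = g$origin_lon, origin_lat = g$origin_lat,
              cell_size = g$cell_size, nodata_mask = mask)
}

#' @export
print.enm_ensemble <- function(x, ...) {
  cat("<enm_ensemble>\n")
  for (i in seq_along(x$members))
    cat(sprintf("  %-7s weight %.3f (mean AUC %.3f)\n",
                names(x$members)[i], x$weights[i], x$mean_auc[i]))
  invisible(x)
}

#' Fit an ensemble ecological niche model
#'
#' The package's central fitting function. Given a presence /
#' pseudo-absence training table it (1) evaluates each requested algorithm
#' by repeated stratified split-sample tests (AUC, TSS), (2) refits every
#' algorithm on the full table, and (3) combines the full-data fits into an
#' ensemble weighted proportionally to mean AUC.
#'
#' @param table A training table from \code{build_training_table}.
#' @param algorithms Subset of \{"GLM", "GBM", "SRE", "MAXENT"\}.
#' @param n_replicates Split-sample replicates (default 10).
#' @param train_fraction Training fraction per split (default 0.75).
#' @param seed Integer master seed; all randomness derives from it.
#' @param settings Optional named list of per-algorithm setting overrides,
#'   e.g. \code{list(GBM = list(n_trees = 500))}.
#' @param predictors Predictor columns to use; default all in the table.
#' @return An object of class \code{enm}: list with \code{ensemble}
#'   (\code{enm_ensemble}), \code{evaluation} (replicate records),
#'   \code{table_summary}, \code{seed}, \code{call}.
#' @seealso \code{\link{predict.enm}}, \code{\link{summary.enm}},
#'   \code{\link{mpa_threshold}}
#' @export
enm <- function(table, algorithms = c("GLM", "GBM", "SRE", "MAXENT"),
                n_replicates = 10, train_fraction = 0.75, seed = 1,
                settings = list(), predictors = NULL) {
  algorithms <- match.arg(algorithms, c("GLM", "GBM", "SRE", "MAXENT"),
                          several.ok = TRUE)
  ev <- evaluate_replicates(table, algorithms, n_replicates, train_fraction,
                            seed, settings, predictors)
  full <- lapply(algorithms, function(alg)
    fit_algorithm(table, alg, predictors,
                  settings = if (alg %in% names(settings))
                    settings[[alg]] else list(),
                  seed = derive_seed(seed, "full", alg)))
  names(full) <- algorithms
  structure(
    list(ensemble = build_ensemble(full, ev), evaluation = ev,
         table_summary = c(n_presence = sum(table$label == 1),
                           n_absence = sum(table$label == 0)),
         seed = seed, call = match.call()),
    class = "enm")
}

#' @export
print.enm <- function(x, ...) {
  cat(sprintf("Ensemble niche model: %d presences, %d pseudo-absences\n",
              x$table_summary["n_presence"], x$table_summary["n_absence"]))
  print(x$ensemble)
  invisible(x)
}

#' Summarize an ensemble niche model
#'
#' Per-algorithm mean and standard deviation of AUC and TSS over the
#' split-sample replicates, plus ensemble weights.
#'
#' @param object An \code{enm}.
#' @param ... Unused.
#' @return Data frame, one row per algorithm.
#' @export
summary.enm <- function(object, ...) {
  ev <- object$evaluation
  algs <- names(object$ensemble$members)
  out <- do.call(rbind, lapply(algs, function(a) {
    e <- ev[ev$algorithm == a, ]
    data.frame(algorithm = a, n_replicates = nrow(e),
               mean_auc = mean(e$auc), sd_auc = stats::sd(e$auc),
               mean_tss = mean(e$tss), sd_tss = stats::sd(e$tss),
               weight = unname(object$ensemble$weights[a]))
  }))
  rownames(out) <- NULL
  out
}

#' @rdname predict.enm_ensemble
#' @export
predict.enm <- function(object, newdata, ...) {
  predict(object$ensemble, newdata, ...)
}

#' Coefficients of the ensemble's GLM member
#'
#' @param object An \code{enm}.
#' @param ... Unused.
#' @return Named coefficient vector of the stepwise-selected GLM, or NULL
#'   when the ensemble has no GLM member.
#' @export
coef.enm <- function(object, ...) {
  m <- object$ensemble$members[["GLM"]]
  if (is.null(m)) return(NULL)
  stats::coef(m$payload$model)
}

#' Plot replicate evaluation scores
#'
#' Boxplots of AUC and TSS per algorithm over the split-sample replicates.
#'
#' @param x An \code{enm}.
#' @param ... Passed to \code{boxplot}.
#' @export
plot.enm <- function(x, ...) {
  ev <- x$evaluation
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::boxplot(auc ~ algorithm, data = ev, ylab = "AUC",
                    main = "Split-sample AUC", ...)
  graphics::abline(h = 0.8, lty = 2)
  graphics::boxplot(tss ~ algorithm, data = ev, ylab = "TSS",
                    main = "Split-sample TSS", ...)
  graphics::abline(h = 0.6, lty = 2)
  invisible(x)
}
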