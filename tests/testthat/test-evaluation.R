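test_that("stratified splits partition each class at the training fraction", {
  tab <- build_training_table(as.data.frame(matrix(rnorm(16), 8)),
                              as.data.frame(matrix(rnorm(16), 8)))
  parts <- split_sample(tab, 0.75, seed = 1)
  expect_equal(sum(parts$train$label == 1), 6L)
  expect_equal(sum(parts$train$label == 0), 6L)
  expect_equal(nrow(parts$test), 4L)
  expect_equal(nrow(parts$train) + nrow(parts$test), nrow(tab))
  expect_identical(split_sample(tab, 0.75, 5), split_sample(tab, 0.75, 5))
  too_small <- tab[c(1, 9:16), ]
  expect_error(split_sample(too_small, 0.75, 1), "at least 2")
})

test_that("AUC follows the Mann-Whitney pairwise definition", {
  expect_equal(auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  # worked 4-point set: 3 wins, 1 loss over 4 pairs
  expect_equal(auc(c(0.8, 0.6, 0.55, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_error(auc(c(0.2, 0.4), c(1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  for (seed in 1:10) {
    set.seed(seed)
    sc <- round(runif(40), 2)
    lab <- rbinom(40, 1, 0.4)
    if (length(unique(lab)) < 2) next
    a0 <- auc(sc, lab)
    expect_equal(auc(exp(3 * sc), lab), a0)
    expect_equal(auc(rank(sc, ties.method = "average"), lab), a0)
  }
})

test_that("TSS maximizes sensitivity + specificity - 1 over thresholds", {
  sep <- tss(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(sep$tss, 1.0)
  flat <- tss(rep(0.3, 8), c(1, 0, 1, 0, 1, 0, 1, 0))
  expect_equal(flat$tss, 0.0)
  # exhaustive scan oracle on random score sets; threshold reproduces tss
  for (seed in 1:20) {
    set.seed(seed)
    sc <- round(runif(12), 1)
    lab <- c(rep(1, 5), rep(0, 7))
    got <- tss(sc, lab)
    best <- max(vapply(unique(sc), function(t)
      mean(sc[lab == 1] >= t) + mean(sc[lab == 0] < t) - 1, numeric(1)))
    expect_equal(got$tss, best)
    pred <- sc >= got$threshold
    expect_equal(mean(pred[lab == 1]) + mean(!pred[lab == 0]) - 1, got$tss)
  }
})

test_that("replicate evaluation produces one record per algorithm and split", {
  tab <- tiny_setup(seed = 2, n = 30, n_presences = 60, n_pa = 200)$table
  ev <- evaluate_replicates(tab, c("GLM", "SRE"), n_replicates = 4, seed = 3,
                            settings = list())
  expect_equal(nrow(ev), 8L)
  expect_true(all(ev$auc >= 0 & ev$auc <= 1))
  expect_true(all(ev$tss >= -1 & ev$tss <= 1))
  expect_equal(sort(unique(ev$replicate)), 1:4)
})

test_that("ensemble weights are proportional to mean AUC", {
  tab <- separable_table()
  models <- list(GLM = fit_algorithm(tab, "GLM"),
                 SRE = fit_algorithm(tab, "SRE"))
  ev <- data.frame(algorithm = c("GLM", "SRE"), replicate = 1,
                   auc = c(0.9, 0.6), tss = c(0.8, 0.5), tss_threshold = 0.5)
  ens <- build_ensemble(models, ev)
  expect_equal(unname(ens$weights), c(0.6, 0.4))
  ev$auc <- c(0.7, 0.7)
  expect_equal(unname(build_ensemble(models, ev)$weights), c(0.5, 0.5))
  ev$auc <- c(0.9, 0)
  expect_error(build_ensemble(models, ev), "positive mean AUC")
})

test_that("ensemble prediction is the weighted member mean, bounded cellwise", {
  fx <- tiny_setup(seed = 5, n = 25, n_presences = 50, n_pa = 150)
  m_glm <- fit_algorithm(fx$table, "GLM")
  m_sre <- fit_algorithm(fx$table, "SRE")
  ev <- data.frame(algorithm = c("GLM", "SRE"), replicate = 1,
                   auc = c(0.5, 0.5), tss = 0, tss_threshold = 0.5)
  ens <- build_ensemble(list(GLM = m_glm, SRE = m_sre), ev)
  map <- predict(ens, fx$stack)
  g <- predict(m_glm, fx$stack)$values
  s <- predict(m_sre, fx$stack)$values
  expect_equal(map$values, 0.5 * g + 0.5 * s, tolerance = 1e-12)
  expect_true(all(map$values >= pmin(g, s) - 1e-12))
  expect_true(all(map$values <= pmax(g, s) + 1e-12))
  # single-member ensemble reproduces the member
  solo <- build_ensemble(list(GLM = m_glm),
                         ev[ev$algorithm == "GLM", ])
  expect_equal(predict(solo, fx$stack)$values, g)
})

test_that("the enm fitting function ties evaluation, refit and weights
           together", {
  fx <- tiny_setup(seed = 7, n = 30, n_presences = 80, n_pa = 300)
  fit <- enm(fx$table, algorithms = c("GLM", "SRE"), n_replicates = 2,
             seed = 9)
  expect_s3_class(fit, "enm")
  s <- summary(fit)
  expect_equal(s$algorithm, c("GLM", "SRE"))
  expect_equal(sum(s$weight), 1)
  expect_equal(unname(s$weight),
               unname(s$mean_auc / sum(s$mean_auc)), tolerance = 1e-12)
  expect_type(coef(fit), "double")       # stepwise GLM coefficients
  map <- predict(fit, fx$stack)
  expect_true(all(map$values >= 0 & map$values <= 1))
  # soft sanity check, logged only: ensemble held-out AUC vs members
  parts <- split_sample(fx$table, 0.75, 11)
  ens_auc <- auc(predict(fit, as.data.frame(parts$test)), parts$test$label)
  message(sprintf("ensemble held-out AUC: %.3f", ens_auc))
  succeed()
})
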