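test_that("climate stacks honour the collinearity construction", {
  st <- make_climate_stack(1, n_layers = 6, n_rows = 100, n_cols = 100,
                           autocorr_range_cells = 10, collinear_pairs = 2)
  expect_length(st$layers, 6L)
  r <- abs(stats::cor(stack_as_matrix(st)))
  diag(r) <- 0
  expect_gte(sum(r > 0.8) / 2, 2)

  st0 <- make_climate_stack(2, n_layers = 2, n_rows = 50, n_cols = 50,
                            autocorr_range_cells = 5, collinear_pairs = 0)
  r0 <- stats::cor(stack_as_matrix(st0))
  expect_lt(abs(r0[1, 2]), 0.8)
})

test_that("generators are pure functions of their seeds", {
  expect_identical(make_climate_stack(1, 4, 30, 30, 5, 1),
                   make_climate_stack(1, 4, 30, 30, 5, 1))
  expect_identical(make_dem(3, 30, 30, 2000), make_dem(3, 30, 30, 2000))
  g <- make_dem(1, 20, 20, 1000)
  expect_identical(make_footprint(5, g, 0.3), make_footprint(5, g, 0.3))
  expect_false(identical(make_climate_stack(1, 4, 30, 30, 5, 1),
                         make_climate_stack(2, 4, 30, 30, 5, 1)))
})

test_that("generator argument checks reject degenerate inputs", {
  expect_error(make_climate_stack(1, n_layers = 6, n_rows = 0, n_cols = 10),
               "n_rows")
  expect_error(make_dem(1, 50, 50, relief_m = 0), "relief_m")
  expect_error(make_footprint(1, make_dem(1, 10, 10, 100),
                              developed_fraction = 1.5), "developed_fraction")
})

test_that("DEM has the requested relief and non-negative elevations", {
  dem <- make_dem(1, 50, 50, 3000)
  expect_gte(min(dem$values), 0)
  rng <- diff(range(dem$values))
  expect_gte(rng, 2700)
  expect_lte(rng, 3300)
})

test_that("footprint layers hit the developed fraction and stay in range", {
  g <- make_dem(1, 100, 100, 1000)
  fp0 <- make_footprint(2, g, 0)
  expect_true(all(fp0$values <= 50))
  fp <- make_footprint(2, g, 0.2)
  expect_true(all(fp$values >= 0 & fp$values <= 100))
  n_dev <- sum(fp$values > 50)
  expect_gte(n_dev, 1800)
  expect_lte(n_dev, 2200)
})

test_that("true suitability evaluates the quadratic-logistic niche", {
  # hand-worked case: one predictor x in {0,1,2,3}, lin 1, quad -1
  x <- matrix(c(0, 1, 2, 3), 2, 2)
  st <- predictor_stack(list(p = raster_grid(x)))
  sp <- virtual_species(list(p = c(1, -1)), intercept = 0)
  suit <- true_suitability(st, sp)
  expect_equal(as.vector(suit$values),
               1 / (1 + exp(-c(0, 0, -2, -6))))
  # unimodal: maximal at the predictor optimum lin/(2*|quad|)
  xs <- matrix(seq(-3, 3, length.out = 100), 10, 10)
  st2 <- predictor_stack(list(p = raster_grid(xs)))
  sp2 <- virtual_species(list(p = c(1, -1)))
  s2 <- true_suitability(st2, sp2)
  best <- xs[which.max(s2$values)]
  expect_equal(best, xs[which.min(abs(xs - 0.5))])
  expect_error(true_suitability(st, virtual_species(list(q = c(1, 0)))),
               "missing")
  expect_error(virtual_species(list(p = c(0, 0))), "nonzero")
  expect_error(virtual_species(list(p = c(1, 2))), "quadratic")
})

test_that("prevalence calibration holds across seeds", {
  for (seed in 1:10) {
    st <- make_climate_stack(seed, 4, 40, 40, 5, 0)
    sp <- virtual_species(list(bio1 = c(0, -30), bio12 = c(0, -30)),
                          prevalence_target = 0.15)
    suit <- true_suitability(st, sp)
    expect_lte(abs(mean(suit$values) - 0.15), 0.02)
  }
})

test_that("occurrence sampling is suitability-weighted and seeded", {
  v <- matrix(0, 5, 5); v[3, 4] <- 1
  suit <- raster_grid(v)
  occ <- sample_occurrences(suit, 1, 1)
  expect_equal(nrow(occ), 1L)
  rc <- locate_cells(suit, occ$lon, occ$lat)
  expect_equal(c(rc$row, rc$col), c(3L, 4L))
  expect_error(sample_occurrences(suit, 2, 1), "positive suitability")

  u <- raster_grid(matrix(1, 20, 20))
  o1 <- sample_occurrences(u, 200, 9)
  expect_identical(o1, sample_occurrences(u, 200, 9))
  # uniform suitability -> counts per grid quadrant consistent with uniform
  rc <- locate_cells(u, o1$lon, o1$lat)
  quad <- paste(rc$row > 10, rc$col > 10)
  p <- stats::chisq.test(table(quad), p = rep(0.25, 4))$p.value
  expect_gt(p, 0.01)
})

test_that("future stacks apply shifts and preserve geometry", {
  st <- make_climate_stack(1, 3, 30, 30, 5, 0)
  id <- make_future_stack(st, scenario_perturbation("g", "r", "p",
                                                    c(bio1 = 0)), 1)
  expect_equal(stack_as_matrix(id), stack_as_matrix(st))
  sh <- make_future_stack(st, scenario_perturbation("g", "r", "p",
                                                    c(bio1 = 2)), 1)
  d <- stack_as_matrix(sh)[, "bio1"] - stack_as_matrix(st)[, "bio1"]
  expect_equal(mean(d), 2, tolerance = 1e-10)
  expect_equal(stack_as_matrix(sh)[, "bio4"], stack_as_matrix(st)[, "bio4"])
  # different GCM labels draw distinct noise fields under one seed policy
  a <- make_future_stack(st, scenario_perturbation("gcmA", "r", "p",
                                                   c(bio1 = 1), 0.5), 1)
  b <- make_future_stack(st, scenario_perturbation("gcmB", "r", "p",
                                                   c(bio1 = 1), 0.5), 1)
  expect_false(identical(stack_as_matrix(a)[, "bio1"],
                         stack_as_matrix(b)[, "bio1"]))
  expect_error(make_future_stack(st, scenario_perturbation("g", "r", "p",
                                                           c(nope = 1)), 1),
               "not in stack")
})

test_that("coherent shift expansion covers collinear copies", {
  st <- make_climate_stack(4, 6, 40, 40, 5, 2)
  info <- attr(st, "collinear_info")
  expect_equal(nrow(info), 2L)
  sh <- expand_shift(st, c(bio1 = 1))
  expect_true(info$copy[info$base == "bio1"] %in% names(sh))
  # shifting the base by 1 moves the standardized copy by its slope
  expect_equal(sh[[info$copy[info$base == "bio1"]]],
               info$slope[info$base == "bio1"])
})

test_that("calibrated perturbations achieve their target true loss", {
  st <- make_climate_stack(3, 4, 50, 50, 8, 0)
  sp <- virtual_species(list(bio1 = c(0, -30), bio12 = c(0, -30)),
                        prevalence_target = 0.15)
  cal <- calibrate_perturbation(st, sp, 50, c(bio1 = 1))
  expect_lt(abs(cal$achieved_loss_pct - 50), 1)
  expect_gt(cal$scale, 0)
})
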