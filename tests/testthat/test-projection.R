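test_that("projection enumeration is the full Cartesian product", {
  plan <- enumerate_projections(c("GLM", "GBM", "SRE", "MAXENT"), 10,
                                paste0("gcm", 1:4), c("rcp45", "rcp85"),
                                c("2050", "2070"))
  expect_equal(nrow(plan), 640L)
  expect_equal(nrow(unique(plan)), 640L)
  expect_equal(nrow(enumerate_projections("GLM", 1, "g", "r", "p")), 1L)
  # multiplicative in every component
  expect_equal(nrow(enumerate_projections(c("a", "b"), 3, c("g1", "g2"),
                                          "r", c("p1", "p2"))), 24L)
  expect_error(enumerate_projections(character(0), 1, "g", "r", "p"),
               "non-empty")
})

test_that("MPA threshold is the minimum suitability at occurrences", {
  v <- matrix(0.05, 5, 5)
  v[1, 1] <- 0.31; v[2, 2] <- 0.74; v[3, 3] <- 0.90
  suit <- raster_grid(v)
  pts <- cell_centres(suit, 1:3, 1:3)
  occs <- occurrence_set(data.frame(id = as.character(1:3), clade = "c",
                                    lon = pts$lon, lat = pts$lat))
  expect_equal(mpa_threshold(suit, occs), 0.31)
  one <- occurrence_set(data.frame(id = "1", clade = "c",
                                   lon = pts$lon[2], lat = pts$lat[2]))
  expect_equal(mpa_threshold(suit, one), 0.74)
  # binarizing at the MPA marks every occurrence cell suitable
  bin <- binarize(suit, mpa_threshold(suit, occs))
  rc <- locate_cells(suit, occs$lon, occs$lat)
  expect_true(all(bin$values[cbind(rc$row, rc$col)]))
})

test_that("binarization applies the >= tie rule and handles extremes", {
  suit <- raster_grid(matrix(c(0.2, 0.5, 0.8, 0.5), 2, 2))
  expect_true(all(binarize(suit, 0)$values))
  expect_false(any(binarize(suit, 0.9)$values))
  at <- binarize(suit, 0.5)
  expect_equal(sum(at$values), 3L)          # cells exactly at threshold kept
  expect_error(binarize(suit, 1.5), "threshold")
})

test_that("footprint masking removes strictly developed cells only", {
  bin <- as_range(matrix(TRUE, 3, 3))
  fp0 <- raster_grid(matrix(0, 3, 3))
  expect_equal(apply_footprint_mask(bin, fp0)$values, bin$values)
  fp100 <- raster_grid(matrix(100, 3, 3))
  expect_false(any(apply_footprint_mask(bin, fp100)$values))
  fp50 <- raster_grid(matrix(50, 3, 3))
  expect_true(all(apply_footprint_mask(bin, fp50)$values))  # strict >
  tall <- as_range(matrix(TRUE, 4, 3))
  expect_error(apply_footprint_mask(tall, fp0), "aligned")
})

test_that("GCM averaging is the cellwise mean within member bounds", {
  a <- raster_grid(matrix(0.2, 2, 2))
  b <- raster_grid(matrix(0.6, 2, 2))
  expect_equal(average_over_gcms(list(a, b))$values, matrix(0.4, 2, 2))
  expect_equal(average_over_gcms(list(a, a))$values, a$values)
})

test_that("dispersal scenarios bound the future range correctly", {
  cur <- as_range(rbind(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE)))
  fut <- as_range(rbind(c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE)))
  none <- apply_dispersal(cur, fut, "none")
  expect_true(all(which(none$values) %in% which(cur$values)))
  expect_equal(sum(none$values), 1L)        # only the shared cell survives
  unlim <- apply_dispersal(cur, fut, "unlimited")
  expect_equal(unlim$values, fut$values)
})

test_that("range change percentages follow the set definitions", {
  cur <- as_range(matrix(rep(c(TRUE, FALSE), c(100, 44)), 12, 12))
  same <- range_change(cur, cur)
  expect_equal(same$stable_pct, 100)
  expect_equal(same$loss_pct, 0)
  expect_equal(same$gain_pct, 0)
  # keep 20 of 100, add none
  fut1 <- as_range(matrix(rep(c(TRUE, FALSE), c(20, 124)), 12, 12))
  ch1 <- range_change(cur, fut1)
  expect_equal(ch1$loss_pct, 80)
  expect_equal(ch1$stable_pct, 20)
  expect_equal(threat_level(ch1$loss_pct), 2L)
  # keep 50 of 100, add 10 new
  m <- matrix(FALSE, 12, 12); m[1:50] <- TRUE; m[101:110] <- TRUE
  ch2 <- range_change(cur, as_range(m))
  expect_equal(ch2$stable_pct, 50)
  expect_equal(ch2$loss_pct, 50)
  expect_equal(ch2$gain_pct, 10)
  expect_equal(ch2$net_change_pct, -40)
  expect_equal(ch2$stable_pct + ch2$loss_pct, 100)
  empty <- as_range(matrix(FALSE, 12, 12))
  expect_error(range_change(empty, cur), "empty")
})

test_that("mean range altitude averages the DEM over suitable cells", {
  dem <- raster_grid(matrix(c(1746, 1000, 2000, 500), 2, 2))
  one <- as_range(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_equal(mean_range_altitude(one, dem), 1746)
  two <- as_range(matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
  expect_equal(mean_range_altitude(two, dem), 1500)
  # moving the suitable set uphill raises the mean
  low <- as_range(matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2))
  high <- as_range(matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))
  expect_gt(mean_range_altitude(high, dem), mean_range_altitude(low, dem))
  expect_error(mean_range_altitude(as_range(matrix(FALSE, 2, 2)), dem),
               "empty")
})
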