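test_that("threat levels follow the loss-threshold table exactly", {
  expect_equal(threat_level(97), 2L)
  expect_equal(threat_level(78), 3L)
  expect_equal(threat_level(64), 3L)
  expect_equal(threat_level(100), 1L)
  expect_equal(threat_level(80), 2L)
  expect_equal(threat_level(50), 3L)
  expect_equal(threat_level(30), 4L)
  expect_equal(threat_level(29.9), 0L)
  expect_error(threat_level(101), "loss_pct")
  expect_error(threat_level(-1), "loss_pct")
})

test_that("threat level is a monotone step function over the loss range", {
  losses <- seq(0, 100, by = 0.1)
  lv <- threat_level(losses)
  # category severity: map level to rank (0 least severe ... 1 most severe)
  severity <- c(`0` = 0, `4` = 1, `3` = 2, `2` = 3, `1` = 4)
  sev <- severity[as.character(lv)]
  expect_true(all(diff(sev) >= 0))
  expect_setequal(unique(lv), c(0L, 4L, 3L, 2L, 1L))
})

test_that("patch labelling distinguishes rook and queen adjacency", {
  m <- matrix(FALSE, 3, 3); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(label_patches(m, "rook")$np, 2L)
  expect_equal(label_patches(m, "queen")$np, 1L)
  expect_equal(label_patches(matrix(FALSE, 4, 4))$np, 0L)
})

test_that("patch labelling matches a flood-fill oracle on random grids", {
  for (seed in 1:50) {
    set.seed(seed)
    v <- matrix(runif(144) < 0.45, 12, 12)
    for (conn in c("rook", "queen")) {
      got <- label_patches(v, conn)
      want <- flood_fill_patches(v, queen = conn == "queen")
      expect_equal(got$np, max(want))
      # same partition up to id permutation
      if (got$np > 0) {
        pairs <- table(got$labels[v], want[v])
        expect_equal(sum(pairs > 0), got$np)
      }
      expect_equal(sum(got$sizes), sum(v))
    }
  }
})

test_that("NP and PL count patches and landscape proportion", {
  full <- as_range(matrix(TRUE, 10, 10))
  expect_equal(np_pl(full), list(np = 1L, pl = 1))
  m <- matrix(FALSE, 10, 10); m[1:25] <- TRUE
  expect_equal(np_pl(as_range(m))$pl, 0.25)
  expect_equal(landscape_metrics(as_range(matrix(FALSE, 5, 5)))$np, 0L)
})

test_that("aggregation index reproduces the g_max case formulas", {
  m <- matrix(FALSE, 4, 4); m[1:2, 1:2] <- TRUE
  expect_equal(aggregation_index(m), 100)
  d <- matrix(FALSE, 4, 4); d[1, 1] <- TRUE; d[2, 2] <- TRUE
  expect_equal(aggregation_index(d), 0)
  strip <- matrix(FALSE, 4, 4); strip[1, 1:3] <- TRUE
  expect_equal(aggregation_index(strip), 100)  # A=3: g=2, g_max=2
  expect_true(is.na(aggregation_index(matrix(c(TRUE, FALSE, FALSE, FALSE),
                                             2, 2))))
})

test_that("aggregation index matches brute-force adjacency counting", {
  for (seed in 1:100) {
    set.seed(seed)
    v <- matrix(runif(100) < runif(1, 0.1, 0.9), 10, 10)
    if (!any(v)) next
    expect_equal(aggregation_index(v), ai_oracle(v), tolerance = 1e-9)
  }
})

test_that("no arrangement of A <= 6 cells exceeds the g_max bound", {
  cells <- seq_len(16)
  for (a in 1:6) {
    combos <- utils::combn(cells, a)
    g_seen <- integer(0)
    for (k in seq_len(ncol(combos))) {
      v <- matrix(FALSE, 4, 4)
      v[combos[, k]] <- TRUE
      g <- sum(v[-4, ] & v[-1, ]) + sum(v[, -4] & v[, -1])
      g_seen <- c(g_seen, g)
    }
    n <- floor(sqrt(a)); m <- a - n^2
    gmax <- if (m == 0) 2 * n * (n - 1) else if (m <= n)
      2 * n * (n - 1) + 2 * m - 1 else 2 * n * (n - 1) + 2 * m - 2
    expect_equal(max(g_seen), gmax)   # bound is attained and never exceeded
  }
})

test_that("splitting index follows the subdivision formula", {
  expect_equal(splitting_index(as_range(matrix(TRUE, 10, 10))), 1)
  g <- matrix(FALSE, 10, 10); g[1:5, 1:5] <- TRUE; g[6:10, 6:10] <- TRUE
  expect_equal(splitting_index(as_range(g)), 8)       # 10000 / 1250
  expect_equal(splitting_index(as_range(g), denominator = "class"),
               50^2 / 1250)
  # brute-force oracle on random grids
  for (seed in 1:50) {
    set.seed(seed)
    v <- matrix(runif(100) < 0.4, 10, 10)
    if (!any(v)) next
    lab <- flood_fill_patches(v)
    sizes <- tabulate(lab[lab > 0])
    expect_equal(splitting_index(as_range(v)),
                 100^2 / sum(sizes^2), tolerance = 1e-9)
  }
})

test_that("merging two patches strictly decreases the splitting index", {
  v <- matrix(FALSE, 8, 8)
  v[2, 2:3] <- TRUE; v[2, 6:7] <- TRUE
  before <- splitting_index(as_range(v))
  v[2, 4:5] <- TRUE                          # connect them
  after <- splitting_index(as_range(v))
  expect_lt(after, before)
})

test_that("risk assessment joins change, threat and metrics per scenario", {
  cur <- as_range(matrix(rep(c(TRUE, FALSE), c(40, 60)), 10, 10))
  m <- matrix(FALSE, 10, 10); m[1:10] <- TRUE
  fut <- as_range(m)
  ch <- cbind(data.frame(gcm = "g1", rcp = "rcp85", period = "2070",
                         dispersal = "none"),
              range_change(cur, fut))
  dem <- raster_grid(matrix(seq(500, 2500, length.out = 100), 10, 10))
  rep_ <- assess_risk("cladeA", ch, cur,
                      list(`g1|rcp85|2070|none` = fut), dem)
  expect_equal(nrow(rep_), 1L)
  expect_equal(rep_$threat_level, threat_level(rep_$loss_pct))
  expect_equal(rep_$np, label_patches(fut)$np)
  expect_equal(rep_$mean_altitude_m, mean_range_altitude(fut, dem))
  # identical current and future -> zero deltas
  same <- assess_risk("cladeA",
                      cbind(data.frame(gcm = "g1", rcp = "r", period = "p",
                                       dispersal = "none"),
                            range_change(cur, cur)),
                      cur, list(`g1|r|p|none` = cur), dem)
  expect_equal(same$delta_np, 0L)
  expect_equal(same$delta_pl, 0)
})

test_that("risk report CSV serializes undefined metrics as empty fields", {
  cur <- as_range(matrix(rep(c(TRUE, FALSE), c(4, 12)), 4, 4))
  fut <- as_range(matrix(FALSE, 4, 4))
  fut$values[1] <- TRUE                       # single cell: AI undefined
  ch <- cbind(data.frame(gcm = "g", rcp = "r", period = "p",
                         dispersal = "none"),
              range_change(cur, fut))
  rep_ <- assess_risk("c", ch, cur, list(`g|r|p|none` = fut))
  path <- withr::local_tempfile(fileext = ".csv")
  write_risk_report(rep_, path)
  expect_true(any(grepl(",,", readLines(path)[2])))
})
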