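test_that("spike simulation follows the lattice-distance rate model", {
  gm <- grid_model(spacing = 30, orientation = 0.3, phase = c(5, 9))
  # nodes of the lattice are at distance zero
  expect_equal(grid_node_distance(5, 9, gm), 0, tolerance = 1e-9)
  # distances never exceed the lattice circumradius
  set.seed(1)
  d <- grid_node_distance(runif(2000, -60, 60), runif(2000, -60, 60), gm)
  expect_true(all(d <= 30 / sqrt(3) + 1e-9))
  # zero peak rate emits no spikes
  pos <- cbind(runif(500, -30, 30), runif(500, -30, 30))
  none <- simulate_spikes(pos, pos, grid_model(lambda_max = 0), dt = 0.5,
                          seed = 2)
  expect_equal(nrow(none), 0)
  # spikes are georeferenced to the TRUE positions
  est <- pos; true_pos <- pos + 100
  sp <- simulate_spikes(est, true_pos, gm, dt = 0.5, seed = 3)
  expect_true(all(sp$x > 60))
})

test_that("rate maps normalize spikes by occupancy", {
  # single spike in one pixel with uniform occupancy: single-pixel peak
  pos <- as.matrix(expand.grid(x = seq(-9, 9, by = 2), y = seq(-9, 9, by = 2)))
  spikes <- data.frame(t = 1, x = 1, y = 1)
  rm0 <- rate_map(spikes, pos, dt = 0.5, pixel_size = 2, smoothing_sd = 0)
  expect_equal(sum(rm0$counts), 1)
  expect_equal(sum(rm0$rate > 0, na.rm = TRUE), 1)
  # doubling occupancy and spikes leaves the rate unchanged
  rm1 <- rate_map(rbind(spikes, spikes), rbind(pos, pos), dt = 0.5,
                  pixel_size = 2, smoothing_sd = 0)
  expect_equal(rm1$rate, rm0$rate)
  expect_error(rate_map(spikes, pos[0, ], dt = 0.5))

  # Poisson consistency: known rate field recovered within 10% per pixel
  lam <- function(x, y) 8 + 3 * sin(x / 6) * cos(y / 6)
  reps <- 1000  # 500 s occupancy per position sample
  pos_rep <- pos[rep(seq_len(nrow(pos)), reps), ]
  set.seed(5)
  counts <- rpois(nrow(pos_rep), lam(pos_rep[, 1], pos_rep[, 2]) * 0.5)
  idx <- rep(seq_len(nrow(pos_rep)), counts)
  sp <- data.frame(t = 1, x = pos_rep[idx, 1], y = pos_rep[idx, 2])
  rmp <- rate_map(sp, pos_rep, dt = 0.5, pixel_size = 2, smoothing_sd = 0)
  want <- lam(pos[, 1], pos[, 2])
  got <- rmp$rate[cbind(findInterval(pos[, 1], seq(rmp$x0, by = 2, length.out = nrow(rmp$rate) + 1)),
                        findInterval(pos[, 2], seq(rmp$y0, by = 2, length.out = ncol(rmp$rate) + 1)))]
  expect_lt(max(abs(got - want) / want), 0.1)
})

test_that("gridness separates hexagonal, square and unstructured fields", {
  gm <- grid_model(spacing = 30, orientation = 0.2, phase = c(3, 4))
  hex <- synthetic_rate_map(function(x, y)
    20 * exp(-grid_node_distance(x, y, gm)^2 / 72))
  expect_gt(gridness(hex), 1)
  sqlat <- synthetic_rate_map(function(x, y) {
    dx <- pmin(abs(x %% 30), 30 - abs(x %% 30))
    dy <- pmin(abs(y %% 30), 30 - abs(y %% 30))
    20 * exp(-(dx^2 + dy^2) / 72)
  })
  expect_lt(gridness(sqlat), 0)
  # spatially white noise: |score| small for nearly all seeds
  scores <- vapply(1:100, function(i) {
    set.seed(i)
    g <- gridness(synthetic_rate_map(function(x, y) runif(length(x))))
    if (is.na(g)) 0 else g
  }, numeric(1))
  expect_gte(mean(abs(scores) < 0.2), 0.95)
  # too few peaks: undefined with a reason
  flat <- synthetic_rate_map(function(x, y) exp(-(x^2 + y^2) / 200))
  expect_true(is.na(gridness(flat)))
})

test_that("spatial information matches closed forms", {
  unif <- synthetic_rate_map(function(x, y) rep(5, length(x)))
  expect_equal(spatial_information(unif), 0)
  # all firing in one of k equally occupied pixels: log2(k) bits/spike
  xs <- seq(1, 16, by = 1)
  k <- length(xs)^2
  hot <- synthetic_rate_map(function(x, y) ifelse(x == 1 & y == 1, 7, 0),
                            xs = xs, ys = xs)
  expect_equal(spatial_information(hot), log2(k))
  zero <- synthetic_rate_map(function(x, y) rep(0, length(x)))
  expect_error(spatial_information(zero))
  # information decreases as fields widen
  gm <- grid_model(spacing = 30)
  si <- vapply(c(4, 6, 9), function(sf) {
    m <- synthetic_rate_map(function(x, y)
      20 * exp(-grid_node_distance(x, y, gm)^2 / (2 * sf^2)))
    spatial_information(m)
  }, numeric(1))
  expect_true(all(diff(si) < 0))
})

test_that("optimal rescaling recovers constructed stretches", {
  gm <- grid_model(spacing = 30, orientation = 0.2, phase = c(3, 4))
  ref <- synthetic_rate_map(function(x, y)
    20 * exp(-grid_node_distance(x, y, gm)^2 / 72))
  self <- optimal_rescaling(ref, ref)
  expect_equal(c(self$sx, self$sy), c(1, 1))
  expect_equal(self$correlation, 1)
  test <- synthetic_rate_map(function(x, y)
    20 * exp(-grid_node_distance(x / 1.1, y, gm)^2 / 72))
  st <- optimal_rescaling(test, ref)
  expect_equal(c(st$sx, st$sy), c(1.1, 1), tolerance = 0.011)
  # independent noise maps correlate weakly at their optimum
  set.seed(9)
  n1 <- synthetic_rate_map(function(x, y) runif(length(x)))
  n2 <- synthetic_rate_map(function(x, y) runif(length(x)))
  ns <- optimal_rescaling(n1, n2)
  expect_lt(ns$correlation, 0.2)
  # flat maps are flagged undefined
  flat <- synthetic_rate_map(function(x, y) rep(1, length(x)))
  expect_true(is.na(optimal_rescaling(flat, ref)$sx))
})

test_that("localization quality controls grid expression", {
  kite <- std_arena("kite")
  traj <- generate_trajectory(kite, motion_config(), duration = 1440,
                              seed = 11)
  gm <- grid_model(spacing = 30, orientation = 0.3, phase = c(5, 9))
  truth <- traj$pose[-1, 1:2]
  # perfect position estimate: hexagonal structure, high information
  sp <- simulate_spikes(truth, truth, gm, dt = 0.5, seed = 12)
  rm_good <- rate_map(sp, traj, pixel_size = 2)
  expect_gt(gridness(rm_good), 0.5)
  expect_gt(spatial_information(rm_good), 0.2)
  # estimate independent of the truth: flat field, near-zero information
  set.seed(13)
  est_bad <- random_inside(kite, nrow(truth))
  sp_bad <- simulate_spikes(est_bad, truth, gm, dt = 0.5, seed = 14)
  rm_bad <- rate_map(sp_bad, traj, pixel_size = 2)
  expect_lt(spatial_information(rm_bad), 0.05)
  g_bad <- gridness(rm_bad)
  expect_true(is.na(g_bad) || abs(g_bad) < 0.3)
})
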