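test_that("ensemble initialization matches the oriented/disoriented priors", {
  kite <- std_arena("kite")
  cfg <- filter_config(kite, N = 10000)
  pose0 <- c(5, -3, 1.2)
  ens_o <- init_ensemble(cfg, "oriented", true_pose = pose0, seed = 1)
  expect_equal(place_stability_index(ens_o, pose0[1:2], kite), 1)
  est <- estimate_pose(ens_o)
  expect_equal(c(est$x, est$y, est$theta), pose0, tolerance = 1e-12)

  ens_d <- init_ensemble(cfg, "disoriented", seed = 2)
  expect_true(all(contains(kite, ens_d$pose[, 1:2])))
  expect_equal(place_stability_index(ens_d, pose0[1:2], kite), 0.5,
               tolerance = 0.02)
  expect_gt(circular_variance(ens_d$pose[, 3]), 0.98)
  expect_identical(ens_d$lineage, seq_len(cfg$N))
})

test_that("the filter tracks exactly at zero noise and keeps particles inside", {
  kite <- std_arena("kite")
  traj <- generate_trajectory(kite, motion_config(), duration = 240, seed = 3)
  em0 <- error_model(sigma_theta = 0, sigma_step = 0)
  stream <- corrupt(traj, em0, seed = 4)
  cfg <- filter_config(kite, N = 200)
  ens0 <- init_ensemble(cfg, "oriented", true_pose = traj$pose[1, ], seed = 5)
  res <- run_filter(ens0, stream, cfg, em0, truth = traj, seed = 6)
  expect_lt(max(res$series$dpost), 1e-8)
  expect_equal(res$n_reinit, 0)

  # with noise, every particle still satisfies containment after the run
  em <- default_error_model()
  stream2 <- corrupt(traj, em, seed = 7)
  ens1 <- init_ensemble(cfg, "disoriented", seed = 8)
  res2 <- run_filter(ens1, stream2, cfg, em, truth = traj, seed = 9)
  expect_true(all(contains(kite, res2$ensemble$pose[, 1:2])))
  expect_equal(res2$ensemble$N, 200L)
})

test_that("hypothesis culling matches a brute-force enumeration", {
  kite <- std_arena("kite")
  # 2 positions x 20 directions tracked over zero-noise steps
  pos2 <- rbind(c(-15, 5), c(18, -8))
  dirs <- 2 * pi * (0:19) / 20
  hyp <- cbind(pos2[rep(1:2, each = 20), ], rep(dirs, 2))
  traj <- generate_trajectory(kite, motion_config(dt = 1.5), duration = 4.5,
                              seed = 77)  # 3 steps
  em0 <- error_model(sigma_theta = 0, sigma_step = 0)
  stream <- corrupt(traj, em0, seed = 1)
  # oracle: propagate all 40 hypotheses, cull those whose path crosses
  ok <- rep(TRUE, 40); p <- hyp
  for (s in seq_along(stream$dhead)) {
    th <- p[, 3] + stream$dhead[s]
    q <- cbind(p[, 1] + stream$step_hat[s] * cos(th),
               p[, 2] + stream$step_hat[s] * sin(th))
    ok <- ok & !segment_crosses(kite, p[, 1:2], q)
    p <- cbind(q, th)
  }
  expect_lt(sum(ok), 40)  # some hypotheses are culled
  ens <- idioloc:::new_ensemble(hyp)
  cfg <- filter_config(kite, N = 100, record_every = 1)
  cfg$N <- 40L
  res <- run_filter(ens, stream, cfg, em0, seed = 5)
  expect_identical(sort(unique(res$ensemble$lineage)), which(ok))
  # surviving clones reproduce the oracle's surviving poses exactly
  expect_equal(sort(unique(res$ensemble$pose[, 1])), sort(unique(p[ok, 1])))
})

test_that("boundary modes differ on interior barriers", {
  cb <- std_arena("circle_barrier")
  bar <- cb$barriers[[1]]
  mid <- (bar[1, ] + bar[2, ]) / 2
  dir <- (bar[2, ] - bar[1, ]) / sqrt(sum((bar[2, ] - bar[1, ])^2))
  nrm <- c(-dir[2], dir[1])
  start <- mid + 3 * nrm
  # one step straight across the barrier
  d <- list(dtheta_hat = 0, step_hat = 6, dt = 0.5)
  ens <- idioloc:::new_ensemble(matrix(c(start, atan2(-nrm[2], -nrm[1])),
                                       1, 3))
  for (mode in c("crossing", "discrete_endpoint")) {
    cfg <- filter_config(cb, N = 100, boundary_mode = mode, record_every = 1)
    cfg$N <- 1L
    out <- pf_step(ens, d, cfg)
    if (mode == "crossing") {
      expect_true(is.na(out$lineage[1]))  # total cull -> reinitialized
    } else {
      expect_identical(out$lineage[1], 1L)  # endpoint is traversable
    }
  }
})

test_that("pure path integration diverges without the boundary map", {
  kite <- std_arena("kite")
  em <- default_error_model()
  cfg <- filter_config(kite, N = 500, boundary_mode = "none")
  # average the cloud-truth distance over several streams: growth is
  # monotone in expectation (single trials fluctuate with the drift)
  sds <- rowMeans(sapply(1:8, function(i) {
    traj <- generate_trajectory(kite, motion_config(), duration = 600,
                                seed = 20 + i)
    stream <- corrupt(traj, em, seed = 120 + i)
    ens0 <- init_ensemble(cfg, "oriented", true_pose = traj$pose[1, ],
                          seed = 220 + i)
    run_filter(ens0, stream, cfg, em, truth = traj,
               seed = 320 + i)$series$dpost
  }))
  expect_gt(cor(seq_along(sds), sds, method = "spearman"), 0.9)
  expect_gt(tail(sds, 1), 3 * sds[1])
})

test_that("compass observations sharpen the heading posterior", {
  kite <- std_arena("kite")
  cfg <- filter_config(kite, N = 5000)
  ens <- init_ensemble(cfg, "disoriented", seed = 31)
  v0 <- circular_variance(ens$pose[, 3])
  upd <- apply_compass(ens, obs = 0, sd = 15 * pi / 180, seed = 32)
  expect_lt(circular_variance(upd$pose[, 3]), v0 - 0.5)
  expect_lt(abs(angle_diff(estimate_pose(upd)$theta, 0)), 0.1)
  # an ensemble already at the observed heading is unchanged
  at_obs <- idioloc:::new_ensemble(cbind(ens$pose[, 1:2], 1.0))
  upd2 <- apply_compass(at_obs, obs = 1.0, sd = 0.2, seed = 33)
  expect_equal(sort(upd2$pose[, 1]), sort(at_obs$pose[, 1]))
})

test_that("contact observations cull by distance to the boundary", {
  circ <- std_arena("circle")
  cfg <- filter_config(circ, N = 1000)
  ens <- init_ensemble(cfg, "disoriented", seed = 41)
  d0 <- boundary_distance(circ, ens$pose[, 1:2])
  near <- apply_contact(ens, TRUE, circ, tol = 3, seed = 42)
  expect_true(all(boundary_distance(circ, near$pose[, 1:2]) <= 3))
  far <- apply_contact(ens, FALSE, circ, tol = 3, seed = 43)
  expect_true(all(boundary_distance(circ, far$pose[, 1:2]) > 3))
  # all particles at the wall + contact observed: unchanged set
  wall_pose <- near$pose
  wall_ens <- idioloc:::new_ensemble(wall_pose)
  upd <- apply_contact(wall_ens, TRUE, circ, tol = 3, seed = 44)
  expect_equal(sort(upd$pose[, 1]), sort(wall_pose[, 1]))
  # all particles at the centroid + contact observed: total-cull path
  cen_ens <- idioloc:::new_ensemble(matrix(c(0, 0, 1), 1000, 3, byrow = TRUE))
  expect_message(out <- apply_contact(cen_ens, TRUE, circ, tol = 3, seed = 45),
                 "total cull")
  expect_equal(out$N, 1000L)
  expect_true(all(is.na(out$lineage)))
})

test_that("pose estimates summarize the ensemble sensibly", {
  delta <- idioloc:::new_ensemble(matrix(c(3, 4, 2), 50, 3, byrow = TRUE))
  est <- estimate_pose(delta)
  expect_equal(c(est$x, est$y, est$theta), c(3, 4, 2))
  expect_true(est$heading_defined)
  # two symmetric clusters average to the midpoint
  two <- idioloc:::new_ensemble(rbind(matrix(c(-20, 0, 0), 50, 3, byrow = TRUE),
                                      matrix(c(20, 0, 0), 50, 3, byrow = TRUE)))
  expect_equal(estimate_pose(two)$x, 0, tolerance = 1e-12)
  # uniform headings: resultant near zero, heading flagged undefined
  unif <- idioloc:::new_ensemble(cbind(0, 0, 2 * pi * (0:999) / 1000))
  expect_false(estimate_pose(unif)$heading_defined)
})

test_that("reverse replay recovers the initial pose", {
  kite <- std_arena("kite")
  em0 <- error_model(sigma_theta = 0, sigma_step = 0)
  traj <- generate_trajectory(kite, motion_config(), duration = 120, seed = 51)
  stream <- corrupt(traj, em0, seed = 52)
  cfg <- filter_config(kite, N = 100, record_every = 5)
  ens0 <- init_ensemble(cfg, "oriented", true_pose = traj$pose[1, ], seed = 53)
  fwd <- run_filter(ens0, stream, cfg, em0, seed = 54)
  back <- reverse_replay(stream, fwd$ensemble, cfg, em0, seed = 55)
  expect_equal(back$ensemble$pose[1, 1:2], unname(traj$pose[1, 1:2]),
               tolerance = 1e-6)

  # disoriented: replayed time-0 estimate beats the real-time one (chance)
  em <- default_error_model()
  cfgN <- filter_config(kite, N = 2000)
  ip_rt <- ip_rp <- numeric(10)
  for (i in 1:10) {
    tr <- generate_trajectory(kite, motion_config(), duration = 120,
                              seed = 500 + i)
    st <- corrupt(tr, em, seed = 600 + i)
    e0 <- init_ensemble(cfgN, "disoriented", seed = 700 + i)
    ip_rt[i] <- place_stability_index(e0, tr$pose[1, 1:2], kite)
    fw <- run_filter(e0, st, cfgN, em, seed = 800 + i)
    rp <- reverse_replay(st, fw$ensemble, cfgN, em, seed = 900 + i)
    ip_rp[i] <- place_stability_index(rp$ensemble, tr$pose[1, 1:2], kite)
  }
  expect_equal(median(ip_rt), 0.5, tolerance = 0.05)
  expect_gt(median(ip_rp), median(ip_rt) + 0.2)
})

test_that("online backward inference refines the time-0 estimate as data accrue", {
  kite <- std_arena("kite")
  em <- default_error_model()
  cfg <- filter_config(kite, N = 2000, record_every = 40)
  first_ip <- last_ip <- numeric(6)
  for (i in 1:6) {
    tr <- generate_trajectory(kite, motion_config(), duration = 240,
                              seed = 60 + i)
    st <- corrupt(tr, em, seed = 70 + i)
    e0 <- init_ensemble(cfg, "disoriented", seed = 80 + i)
    bi <- backward_inference_online(e0, st, cfg, em, truth = tr, seed = 80 + i)
    ips <- vapply(seq_len(nrow(bi$series)), function(k)
      place_stability_index(initial_pose_ensemble(bi, k), tr$pose[1, 1:2],
                            kite), numeric(1))
    first_ip[i] <- ips[1]; last_ip[i] <- tail(ips, 1)
    # nondecreasing up to sampling noise
    expect_gt(min(diff(ips)), -0.2)
  }
  expect_gt(median(last_ip), median(first_ip))
  # oriented start: the time-0 estimate is exact and constant
  tr <- generate_trajectory(kite, motion_config(), duration = 60, seed = 90)
  st <- corrupt(tr, em, seed = 91)
  e0 <- init_ensemble(cfg, "oriented", true_pose = tr$pose[1, ], seed = 92)
  bi <- backward_inference_online(e0, st, cfg, em, seed = 92)
  for (k in c(1, nrow(bi$series))) {
    ie <- initial_pose_ensemble(bi, k)
    expect_equal(unique(ie$pose[, 1]), unname(tr$pose[1, 1]))
  }
})

test_that("a total cull reinitializes from the disoriented prior", {
  kite <- std_arena("kite")
  # a step far longer than the arena kills every hypothesis
  ens <- init_ensemble(filter_config(kite, N = 300), "disoriented", seed = 95)
  cfg <- filter_config(kite, N = 300, record_every = 1)
  out <- pf_step(ens, list(dtheta_hat = 0, step_hat = 500, dt = 0.5), cfg)
  expect_equal(out$N, 300L)
  expect_true(all(is.na(out$lineage)))
  expect_true(all(contains(kite, out$pose[, 1:2])))
})
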