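#' Particle filter configuration
#'
#' @param map_arena the remembered boundary map (an `arena`); may differ from
#'   the arena the true trajectory was generated in.
#' @param N particle count (>= 100). Default 10^4.
#' @param boundary_mode how the map constrains pose hypotheses:
#'   "crossing" culls particles whose step crosses any boundary (outer,
#'   barrier or void); "discrete_endpoint" only requires the step endpoint to
#'   lie in traversable space (barriers are invisible); "none" disables the
#'   map (pure path integration).
#' @param body `body_shape` the filter assumes for the agent (NULL = point).
#' @param body_points_n perimeter sample points used for body collision
#'   tests inside the filter.
#' @param record_every record metrics every this many steps.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(map_arena, N = 10000,
                          boundary_mode = c("crossing", "discrete_endpoint",
                                            "none"),
                          body = NULL, body_points_n = 8,
                          record_every = 10) {
  stopifnot(N >= 100)
  structure(list(map_arena = map_arena, N = as.integer(N),
                 boundary_mode = match.arg(boundary_mode),
                 body = body, body_points_n = body_points_n,
                 record_every = as.integer(record_every)),
            class = "filter_config")
}

boundary_mode_code <- function(mode) {
  switch(mode, none = 0L, discrete_endpoint = 1L, crossing = 2L)
}

#' Initialize a particle ensemble
#'
#' Oriented: perfect initial pose information, all particles at the true
#' pose. Disoriented: no initial pose information, positions uniform over
#' the traversable space of the remembered map and headings uniform on
#' [0, 2*pi). Each particle records its ancestral initial pose (lineage).
#'
#' @param cfg a `filter_config`.
#' @param mode "oriented" or "disoriented".
#' @param true_pose length-3 pose (x, y, theta); required when oriented.
#' @param seed optional integer seed.
#' @return object of class `particle_ensemble`.
#' @export
init_ensemble <- function(cfg, mode = c("oriented", "disoriented"),
                          true_pose = NULL, seed = NULL) {
  mode <- match.arg(mode)
  with_seed(seed, {
    if (mode == "oriented") {
      stopifnot(length(true_pose) == 3)
      pose <- matrix(rep(as.numeric(true_pose), each = cfg$N), cfg$N, 3)
    } else {
      pose <- sample_poses(cfg$map_arena, cfg$N, cfg$body)
    }
    new_ensemble(pose, t = 0)
  })
}

new_ensemble <- function(pose, t = 0, lineage = seq_len(nrow(pose)),
                         init_pose = pose, weights = NULL) {
  dimnames(pose) <- NULL
  structure(list(pose = pose, N = nrow(pose),
                 weights = weights %||% rep(1 / nrow(pose), nrow(pose)),
                 lineage = as.integer(lineage), init_pose = init_pose,
                 t = t),
            class = "particle_ensemble")
}

#' @export
print.particle_ensemble <- function(x, ...) {
  est <- estimate_pose(x)
  cat(sprintf("<particle_ensemble> N = %d, t = %s, estimate (%.1f, %.1f, %.0f deg)\n",
              x$N, fmt_mmss(x$t), est$x, est$y, est$theta * 180 / pi))
  invisible(x)
}

# assemble the C++ kernel arguments shared by every filter entry point;
# `max_step` (cm) sizes the spatial edge index (longer steps fall back to a
# full edge scan inside the kernel)
pf_kernel_args <- function(cfg, em, dt, max_step = 30 * dt) {
  mode <- boundary_mode_code(cfg$boundary_mode)
  arena <- cfg$map_arena
  bp <- body_points(cfg$body, n = cfg$body_points_n)
  body_r <- if (nrow(bp)) max(sqrt(rowSums(bp^2))) else 0
  pool <- traversable_points(arena, 2e4)
  if (mode == 2L) {
    edges <- arena_edges(arena)
    reach <- max_step * (1 + 4 * em$filter_sigma_step) + body_r + 2
    idx <- arena_edge_index(arena, reach)
    dgrid <- arena_dist_grid(arena)
  } else {
    edges <- matrix(numeric(0), 0, 4)
    idx <- list()
    dgrid <- list()
  }
  list(mode = mode, rings = arena_rings(arena), edges = edges, idx = idx,
       dgrid = dgrid, body = bp,
       sig_th = em$filter_sigma_theta * sqrt(dt),
       sig_step = em$filter_sigma_step,
       pool = pool)
}

#' Run the particle filter over a displacement stream
#'
#' Each particle independently tracks the reported displacements, adding its
#' own process noise drawn from the filter's assumed error model; particles
#' whose motion is inconsistent with the remembered map (per
#' `cfg$boundary_mode`) are culled and the survivors are cloned back to N
#' (systematic resampling), preserving lineage. If every particle is culled
#' the ensemble is reinitialized from the disoriented prior over the map.
#' Compass and contact observations embedded in the stream are fused where
#' present.
#'
#' @param ens initial `particle_ensemble`.
#' @param stream a `displacement_stream`.
#' @param cfg a `filter_config`.
#' @param em the `error_model` (its `filter_sigma_*` values set the process
#'   noise).
#' @param truth optional true trajectory (a `trajectory` or pose matrix with
#'   one more row than the stream has steps) for metric recording.
#' @param record_lineage record per-particle ancestry at each recording time
#'   (needed for online backward inference).
#' @param seed optional integer seed.
#' @return list with `ensemble` (final), `series` (data.frame of recorded
#'   times, mean particle-truth distance, ensemble mean heading/position),
#'   `n_reinit`, and optionally `lineage`.
#' @export
run_filter <- function(ens, stream, cfg, em, truth = NULL,
                       record_lineage = FALSE, seed = NULL) {
  ka <- pf_kernel_args(cfg, em, stream$dt,
                       max_step = max(stream$step_hat, 1))
  truth_m <- truth_matrix(truth, length(stream$dhead) + 1)
  with_seed(seed, {
    res <- cpp_pf_run(ens$pose, ens$lineage, stream$dhead, stream$step_hat,
                      stream$mode == "aPI", FALSE,
                      ka$sig_th, ka$sig_step, ka$mode,
                      ka$rings, ka$edges, ka$idx, ka$dgrid, ka$body,
                      truth_m, cfg$record_every, record_lineage, ka$pool,
                      stream$compass_obs %||% numeric(0), em$compass_sd,
                      stream$contact_obs %||% numeric(0), em$contact_tol)
    pack_pf_result(res, ens, stream, cfg)
  })
}

truth_matrix <- function(truth, n_expected) {
  if (is.null(truth)) return(matrix(numeric(0), 0, 3))
  m <- if (inherits(truth, "trajectory")) truth$pose else as.matrix(truth)
  stopifnot(nrow(m) == n_expected)
  m
}

pack_pf_result <- function(res, ens, stream, cfg, reverse = FALSE) {
  t_rec <- if (reverse) {
    max(stream$t) - res$rec_steps * stream$dt
  } else {
    res$rec_steps * stream$dt
  }
  series <- data.frame(step = res$rec_steps, t = t_rec,
                       dpost = res$dpost,
                       head_c = res$head_c, head_s = res$head_s,
                       mean_x = res$mean_x, mean_y = res$mean_y)
  final <- new_ensemble(res$pose,
                        t = if (reverse) 0 else ens$t + max(stream$t),
                        lineage = res$anc, init_pose = ens$init_pose)
  out <- list(ensemble = final, series = series, n_reinit = res$n_reinit,
              n_compass_degenerate = res$n_compass_degenerate)
  if (nrow(res$lineage) > 0) out$lineage <- res$lineage
  out
}

#' Advance an ensemble by a single displacement estimate
#'
#' One predict-cull-clone cycle of the filter (see [run_filter()]).
#'
#' @param ens a `particle_ensemble`.
#' @param d a single displacement estimate: list with `step_hat` and either
#'   `dtheta_hat` (iPI) or `theta_hat` (aPI), and optionally `dt`.
#' @param cfg a `filter_config`.
#' @param em the `error_model` for process noise (default: no noise).
#' @return updated `particle_ensemble`.
#' @export
pf_step <- function(ens, d, cfg,
                    em = error_model(sigma_theta = 0, sigma_step = 0)) {
  api <- !is.null(d$theta_hat)
  stream <- structure(list(dhead = if (api) d$theta_hat else d$dtheta_hat,
                           step_hat = d$step_hat, dt = d$dt %||% 0.5,
                           t = d$dt %||% 0.5,
                           mode = if (api) "aPI" else "iPI",
                           compass_obs = NA_real_, contact_obs = NA_real_),
                      class = "displacement_stream")
  cfg$record_every <- 1L
  res <- run_filter(ens, stream, cfg, em)
  res$ensemble$t <- ens$t + stream$dt
  res$ensemble
}

#' Ensemble pose estimate
#'
#' Weighted mean of particle positions and circular mean of headings. For a
#' multimodal cloud the mean may fall outside traversable space; it is
#' reported as-is. When the heading resultant length is near zero the
#' heading is flagged as undefined.
#'
#' @param ens a `particle_ensemble`.
#' @return list with `x`, `y`, `theta`, `resultant` (mean resultant length)
#'   and `heading_defined`.
#' @export
estimate_pose <- function(ens) {
  w <- ens$weights / sum(ens$weights)
  cm <- circ_mean(ens$pose[, 3], w)
  list(x = sum(w * ens$pose[, 1]), y = sum(w * ens$pose[, 2]),
       theta = wrap_angle(cm$mean), resultant = cm$R,
       heading_defined = cm$R > 0.05)
}

# systematic resampling of an ensemble back to uniform weights
resample_ensemble <- function(ens, w) {
  W <- sum(w)
  u <- runif(1) / ens$N
  targets <- u + (seq_len(ens$N) - 1) / ens$N
  idx <- findInterval(targets, cumsum(w / W)) + 1L
  idx[idx > ens$N] <- ens$N
  new_ensemble(ens$pose[idx, , drop = FALSE], t = ens$t,
               lineage = ens$lineage[idx], init_pose = ens$init_pose)
}

#' Fuse a compass observation into an ensemble
#'
#' Multiplies particle weights by a circular-normal likelihood of the
#' heading mismatch, then resamples to uniform weights. No position reset is
#' involved: the compass only breaks rotational symmetry.
#'
#' @param ens a `particle_ensemble`.
#' @param obs observed absolute heading, radians.
#' @param sd compass measurement SD, radians (> 0).
#' @param seed optional integer seed.
#' @return updated `particle_ensemble`.
#' @export
apply_compass <- function(ens, obs, sd, seed = NULL) {
  stopifnot(sd > 0)
  d <- angle_diff(ens$pose[, 3], obs)
  w <- ens$weights * exp(-0.5 * d^2 / sd^2)
  if (sum(w) <= 0 || !is.finite(sum(w))) {
    warning("degenerate compass update: resampling from prior weights")
    w <- ens$weights
  }
  with_seed(seed, resample_ensemble(ens, w))
}

#' Fuse a boundary-contact observation into an ensemble
#'
#' contact = TRUE culls particles whose body is farther than `tol` from any
#' boundary; contact = FALSE culls particles within `tol`. Survivors are
#' cloned back to N. A total cull reinitializes from the disoriented prior.
#'
#' @param ens a `particle_ensemble`.
#' @param contact logical observation.
#' @param arena the remembered map.
#' @param body `body_shape` or NULL.
#' @param tol contact distance, cm (> 0).
#' @param seed optional integer seed.
#' @return updated `particle_ensemble`.
#' @export
apply_contact <- function(ens, contact, arena, body = NULL, tol = 2,
                          seed = NULL) {
  stopifnot(tol > 0)
  edges <- arena_edges(arena)
  d <- cpp_min_edge_dist(ens$pose[, 1], ens$pose[, 2], edges)
  bp <- body_points(body, 16)
  if (nrow(bp) > 0) {
    th <- ens$pose[, 3]
    for (k in seq_len(nrow(bp))) {
      px <- ens$pose[, 1] + cos(th) * bp[k, 1] - sin(th) * bp[k, 2]
      py <- ens$pose[, 2] + sin(th) * bp[k, 1] + cos(th) * bp[k, 2]
      d <- pmin(d, cpp_min_edge_dist(px, py, edges))
    }
  }
  keep <- if (contact) d <= tol else d > tol
  with_seed(seed, {
    if (!any(keep)) {
      message("total cull in apply_contact: reinitializing from map prior")
      pose <- sample_poses(arena, ens$N, body)
      return(new_ensemble(pose, t = ens$t, lineage = rep(NA_integer_, ens$N),
                          init_pose = ens$init_pose))
    }
    resample_ensemble(ens, as.numeric(keep) * ens$weights)
  })
}

#' Retrospective initial-pose estimation by reverse replay
#'
#' Treats the final pose estimate as the initial estimate of the same
#' trajectory replayed backward, offline: for each stored step in reverse
#' order, particles move backward by the reported step length along their
#' current heading and then un-apply the reported heading change, with
#' boundary culling identical to the forward pass. The returned ensemble
#' estimates the pose at time 0.
#'
#' @param stream the stored `displacement_stream`, in forward order.
#' @param final_ens the `particle_ensemble` at the end of the forward pass.
#' @param cfg a `filter_config`.
#' @param em the `error_model` for process noise.
#' @param truth optional true trajectory for metric recording (forward
#'   order; metrics are recorded against the pose the replay is passing).
#' @param seed optional integer seed.
#' @return list as [run_filter()]; `ensemble` is the time-0 estimate.
#' @export
reverse_replay <- function(stream, final_ens, cfg, em, truth = NULL,
                           seed = NULL) {
  ka <- pf_kernel_args(cfg, em, stream$dt,
                       max_step = max(stream$step_hat, 1))
  truth_m <- truth_matrix(truth, length(stream$dhead) + 1)
  with_seed(seed, {
    res <- cpp_pf_run(final_ens$pose, final_ens$lineage,
                      stream$dhead, stream$step_hat,
                      stream$mode == "aPI", TRUE,
                      ka$sig_th, ka$sig_step, ka$mode,
                      ka$rings, ka$edges, ka$idx, ka$dgrid, ka$body,
                      truth_m, cfg$record_every, FALSE, ka$pool,
                      numeric(0), em$compass_sd, numeric(0), em$contact_tol)
    pack_pf_result(res, final_ens, stream, cfg, reverse = TRUE)
  })
}

#' Online backward inference of the initial pose via particle lineages
#'
#' Runs the forward filter with lineage tracking: at each recorded time the
#' estimate of the time-0 pose is the distribution of ancestral initial
#' poses among surviving particles (multiplicity acts as weight). No stored
#' displacement sequence is required to form the retrospective estimate.
#'
#' @param ens initial `particle_ensemble` (lineage records are set at
#'   initialization).
#' @param stream a `displacement_stream`.
#' @param cfg a `filter_config`.
#' @param em the `error_model`.
#' @param truth optional true trajectory.
#' @param seed optional integer seed.
#' @return list as [run_filter()], plus `lineage` (recorded ancestor matrix)
#'   and helper-ready `init_pose`.
#' @export
backward_inference_online <- function(ens, stream, cfg, em, truth = NULL,
                                      seed = NULL) {
  out <- run_filter(ens, stream, cfg, em, truth = truth,
                    record_lineage = TRUE, seed = seed)
  out$init_pose <- ens$init_pose
  out
}

#' Extract the time-0 pose ensemble at a recorded time of a backward
#' inference run
#'
#' @param bi result of [backward_inference_online()].
#' @param i recorded-time index (row of `bi$series`).
#' @return a `particle_ensemble` over initial poses (particles whose lineage
#'   was lost to a total-cull reinitialization are dropped).
#' @export
initial_pose_ensemble <- function(bi, i) {
  anc <- bi$lineage[i, ]
  anc <- anc[!is.na(anc)]
  if (length(anc) == 0) {
    return(new_ensemble(bi$init_pose, t = 0))  # no information retained
  }
  new_ensemble(bi$init_pose[anc, , drop = FALSE], t = 0,
               lineage = anc, init_pose = bi$init_pose)
}
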