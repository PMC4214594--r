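#' Motion policy configuration
#'
#' @param dt step interval, seconds.
#' @param speed_mean mean running speed, cm/s.
#' @param speed_sd per-step speed SD, cm/s (speeds are truncated at 0).
#' @param turn_sd per-step turning SD in radians (random policy tortuosity).
#' @param policy "random" (correlated random walk, heading redrawn inward at
#'   wall encounters) or "thigmotactic" (wall following at `wall_offset`).
#' @param wall_offset preferred distance from the outer wall, cm.
#' @param steer_gain proportional steering gain toward `wall_offset`
#'   (radians per cm of offset error).
#' @return object of class `motion_config`.
#' @export
motion_config <- function(dt = 0.5, speed_mean = 15, speed_sd = 4,
                          turn_sd = 30 * pi / 180,
                          policy = c("random", "thigmotactic"),
                          wall_offset = 5, steer_gain = 0.15) {
  stopifnot(dt > 0, speed_mean >= 0, speed_sd >= 0, turn_sd >= 0)
  structure(list(dt = dt, speed_mean = speed_mean, speed_sd = speed_sd,
                 turn_sd = turn_sd, policy = match.arg(policy),
                 wall_offset = wall_offset, steer_gain = steer_gain),
            class = "motion_config")
}

#' Self-motion error model
#'
#' Heading error accumulates as a Wiener process with intensity
#' `sigma_theta` (rad per sqrt second): each reported heading change carries
#' an independent N(0, sigma_theta^2 * dt) increment (iPI mode). In aPI mode
#' the reported heading is the exact absolute heading each step (a compass
#' resets orientation error), and only step lengths are noisy. Step lengths
#' are corrupted multiplicatively: reported = true * (1 + N(0, sigma_step^2)).
#'
#' The filter's assumed noise (`filter_sigma_theta`, `filter_sigma_step`)
#' defaults to the generative values but may be set independently to study
#' matched versus mismatched uncertainty.
#'
#' @param sigma_theta Wiener heading-drift intensity, rad * s^(-1/2).
#' @param sigma_step fractional step-length noise SD.
#' @param mode "iPI" (idiothetic heading changes) or "aPI" (absolute compass
#'   heading each step).
#' @param compass_rate mean rate of intermittent compass observations,
#'   events/s (0 = never).
#' @param compass_sd compass measurement error SD, radians.
#' @param contact_enabled if TRUE, emit a boundary-contact flag each step.
#' @param contact_tol body-boundary distance defining contact, cm.
#' @param filter_sigma_theta,filter_sigma_step the filter's assumed noise
#'   (NULL = same as generative).
#' @return object of class `error_model`.
#' @export
error_model <- function(sigma_theta = 0.15, sigma_step = 0.2,
                        mode = c("iPI", "aPI"),
                        compass_rate = 0, compass_sd = 15 * pi / 180,
                        contact_enabled = FALSE, contact_tol = 2,
                        filter_sigma_theta = NULL, filter_sigma_step = NULL) {
  mode <- match.arg(mode)
  stopifnot(sigma_theta >= 0, sigma_step >= 0, compass_rate >= 0,
            compass_sd >= 0)
  structure(list(sigma_theta = sigma_theta, sigma_step = sigma_step,
                 mode = mode, compass_rate = compass_rate,
                 compass_sd = compass_sd, contact_enabled = contact_enabled,
                 contact_tol = contact_tol,
                 filter_sigma_theta = filter_sigma_theta %||% sigma_theta,
                 filter_sigma_step = filter_sigma_step %||% sigma_step),
            class = "error_model")
}

#' Calibrated default error model
#'
#' The packaged noise defaults. `sigma_theta` and `sigma_step` were selected
#' by [calibrate_noise()] (see `scripts/calibrate.R` in the source
#' repository) such that, in the standard kite arena starting oriented at the
#' centre, path-integration-only median place stability crosses below chance
#' (0.5) within 3 simulated minutes using iPI and within 6 minutes using aPI.
#'
#' @param ... overrides passed to [error_model()].
#' @return an `error_model`.
#' @export
default_error_model <- function(...) {
  error_model(sigma_theta = 0.05, sigma_step = 0.15, ...)
}

#' Generate a true trajectory
#'
#' Simulates agent movement inside an arena at `dt` spacing. The random
#' policy is a correlated random walk with normal turning noise; steps that
#' would cross a boundary are truncated at the wall and the heading is
#' redrawn uniformly from directions that lead inward. The thigmotactic
#' policy steers along the outer wall at `wall_offset`.
#'
#' @param arena an `arena`.
#' @param cfg a `motion_config`.
#' @param body `body_shape` or NULL for a point body.
#' @param duration trajectory duration in seconds (at least `dt`).
#' @param seed optional integer seed.
#' @param start "random" (uniform contained pose), "center" (arena centroid,
#'   random heading), or a length-3 pose (x, y, theta).
#' @return object of class `trajectory`: pose matrix plus timing metadata.
#' @export
generate_trajectory <- function(arena, cfg = motion_config(), body = NULL,
                                duration = 480, seed = NULL,
                                start = "random") {
  stopifnot(duration >= cfg$dt)
  n_steps <- round(duration / cfg$dt)
  with_seed(seed, {
    if (is.character(start)) {
      start <- match.arg(start, c("random", "center"))
      if (start == "center") {
        cen <- arena_centroid(arena)
        pose0 <- c(cen, runif(1, 0, 2 * pi))
        if (!contains(arena, pose0[1:2], body, pose0[3]))
          stop("body does not fit at the arena centre")
      } else {
        pose0 <- drop(sample_poses(arena, 1, body))
      }
    } else {
      pose0 <- start
      if (!contains(arena, pose0[1:2], body, pose0[3]))
        stop("start pose is not contained in the arena")
    }
    pose <- cpp_gen_traj(arena_rings(arena), arena_edges(arena),
                         arena_outer_edges(arena), body_points(body),
                         n_steps, cfg$dt, cfg$speed_mean, cfg$speed_sd,
                         cfg$turn_sd,
                         if (cfg$policy == "thigmotactic") 1L else 0L,
                         cfg$wall_offset, cfg$steer_gain,
                         pose0[1], pose0[2], pose0[3])
    structure(list(pose = pose, dt = cfg$dt,
                   t = seq(0, by = cfg$dt, length.out = n_steps + 1)),
              class = "trajectory")
  })
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d poses, dt = %gs, duration %s\n",
              nrow(x$pose), x$dt, fmt_mmss(max(x$t))))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(t = x$t, x = x$pose[, 1], y = x$pose[, 2], theta = x$pose[, 3])
}

#' Corrupt a trajectory into a self-motion estimate stream
#'
#' Converts true per-step displacements into the noisy stream the navigation
#' system receives. iPI: reported heading change = true change plus a Wiener
#' increment N(0, sigma_theta^2 * dt). aPI: the reported absolute heading is
#' the exact true heading each step. Both modes: reported step length =
#' true length * (1 + N(0, sigma_step^2)), truncated at 0. Intermittent
#' compass observations are emitted as a Poisson process at `compass_rate`,
#' with value true heading + N(0, compass_sd^2). When `em$contact_enabled`,
#' per-step boundary-contact flags are computed from the true trajectory
#' (requires `arena`).
#'
#' @param traj a `trajectory`.
#' @param em an `error_model`.
#' @param seed optional integer seed.
#' @param arena arena for contact flags (only if `em$contact_enabled`).
#' @param body body shape for contact flags.
#' @return object of class `displacement_stream`.
#' @export
corrupt <- function(traj, em = default_error_model(), seed = NULL,
                    arena = NULL, body = NULL) {
  stopifnot(nrow(traj$pose) >= 2)
  dt <- traj$dt
  n <- nrow(traj$pose) - 1
  dx <- diff(traj$pose[, 1]); dy <- diff(traj$pose[, 2])
  step_true <- sqrt(dx^2 + dy^2)
  theta_true <- traj$pose[-1, 3]
  dtheta_true <- angle_diff(traj$pose[-1, 3], traj$pose[-(n + 1), 3])
  with_seed(seed, {
    step_hat <- pmax(0, step_true * (1 + rnorm(n, 0, em$sigma_step)))
    if (em$mode == "iPI") {
      dhead <- dtheta_true + rnorm(n, 0, em$sigma_theta * sqrt(dt))
    } else {
      dhead <- theta_true  # exact absolute heading each step
    }
    compass_obs <- rep(NA_real_, n)
    if (em$compass_rate > 0) {
      hit <- rpois(n, em$compass_rate * dt) > 0
      compass_obs[hit] <- theta_true[hit] + rnorm(sum(hit), 0, em$compass_sd)
    }
    contact_obs <- rep(NA_real_, n)
    if (isTRUE(em$contact_enabled)) {
      if (is.null(arena)) stop("contact_enabled requires `arena`")
      flags <- detect_contacts(traj, arena, body = body, tol = em$contact_tol)
      contact_obs <- as.numeric(flags[-1])  # flag at the end of each step
    }
    structure(list(dhead = dhead, step_hat = step_hat,
                   t = traj$t[-1], dt = dt, mode = em$mode,
                   compass_obs = compass_obs, contact_obs = contact_obs),
              class = "displacement_stream")
  })
}

#' @export
print.displacement_stream <- function(x, ...) {
  cat(sprintf("<displacement_stream> %d steps (%s), dt = %gs, %d compass obs, %d contact flags\n",
              length(x$dhead), x$mode, x$dt, sum(!is.na(x$compass_obs)),
              sum(!is.na(x$contact_obs))))
  invisible(x)
}

#' @export
as.data.frame.displacement_stream <- function(x, ...) {
  df <- data.frame(t = x$t, step_hat = x$step_hat,
                   compass_obs = x$compass_obs, contact_obs = x$contact_obs)
  if (x$mode == "iPI") df$dtheta_hat <- x$dhead else df$theta_hat <- x$dhead
  df
}

#' Detect boundary contacts along a trajectory
#'
#' TRUE at poses where the body perimeter (or the centre, for a point body)
#' is within `tol` of any boundary.
#'
#' @param traj a `trajectory`.
#' @param arena an `arena`.
#' @param body `body_shape` or NULL.
#' @param tol contact distance, cm.
#' @return logical vector, one per pose.
#' @export
detect_contacts <- function(traj, arena, body = NULL, tol = 2) {
  stopifnot(tol > 0)
  edges <- arena_edges(arena)
  p <- traj$pose
  d <- cpp_min_edge_dist(p[, 1], p[, 2], edges)
  bp <- body_points(body)
  if (nrow(bp) > 0) {
    for (k in seq_len(nrow(bp))) {
      px <- p[, 1] + cos(p[, 3]) * bp[k, 1] - sin(p[, 3]) * bp[k, 2]
      py <- p[, 2] + sin(p[, 3]) * bp[k, 1] + cos(p[, 3]) * bp[k, 2]
      d <- pmin(d, cpp_min_edge_dist(px, py, edges))
    }
  }
  d <= tol
}

# serialize streams/trajectories for the CLI
write_stream_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
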