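#' Experiment configuration
#'
#' Bundles everything needed to run a batch of localization trials: the test
#' arena (where the true trajectory lives), the remembered map (defaults to
#' the test arena), the motion policy, the error model, and the filter
#' settings.
#'
#' @param arena test `arena`.
#' @param em `error_model`.
#' @param motion `motion_config`.
#' @param map_arena remembered map (default: the test arena).
#' @param body `body_shape` or NULL.
#' @param N particle count.
#' @param boundary_mode filter boundary mode (see [filter_config()]).
#' @param init_mode "oriented" or "disoriented".
#' @param start trajectory start ("random", "center", or a pose).
#' @param duration trial duration, seconds.
#' @param trials number of independent trials.
#' @param master_seed master seed; per-trial seeds are derived from it.
#' @param record_every record metrics every this many steps.
#' @param name label recorded in the manifest.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(arena, em = default_error_model(),
                              motion = motion_config(),
                              map_arena = NULL, body = NULL,
                              N = 2000,
                              boundary_mode = "crossing",
                              init_mode = "disoriented",
                              start = "random",
                              duration = 2880, trials = 100,
                              master_seed = 1, record_every = 10,
                              name = "custom") {
  stopifnot(trials >= 1, duration >= motion$dt)
  structure(list(arena = arena, em = em, motion = motion,
                 map_arena = map_arena %||% arena, body = body,
                 N = N, boundary_mode = boundary_mode,
                 init_mode = init_mode, start = start,
                 duration = duration, trials = trials,
                 master_seed = master_seed, record_every = record_every,
                 name = name),
            class = "experiment_config")
}

#' Run a localization experiment
#'
#' Per trial: generate a true trajectory, corrupt it into a self-motion
#' stream, run the particle filter, and score localization. Results are
#' aggregated across trials on the shared recording time grid: the median
#' and IQR of the place stability index I_p, and the circular variance
#' V(theta) of the across-trial heading errors.
#'
#' @param config an `experiment_config`.
#' @param output_dir optional directory; when given, the metric series
#'   (CSV), kinetics (JSON) and a manifest with the full configuration and
#'   seeds are written there.
#' @param keep_ensembles keep each trial's final `particle_ensemble`.
#' @param keep_estimates keep each trial's estimated/true position series
#'   (needed for grid-cell simulation).
#' @param progress print per-trial progress at INFO granularity.
#' @return object of class `experiment_result`: `series` (t, Ip_median,
#'   Ip_q25, Ip_q75, V_theta), `kinetics` ([t90()]), per-trial matrices
#'   `Ip` and `heading_err`, reinit counts, seeds, and the config.
#' @export
run_experiment <- function(config, output_dir = NULL,
                           keep_ensembles = FALSE, keep_estimates = FALSE,
                           progress = FALSE) {
  cfg <- filter_config(config$map_arena, N = config$N,
                       boundary_mode = config$boundary_mode,
                       body = config$body,
                       record_every = config$record_every)
  seeds <- derive_seeds(config$master_seed, 3L * config$trials)
  seeds <- matrix(seeds, ncol = 3)
  dint <- d_unif_interp(config$arena)
  Ip <- NULL; herr <- NULL; t_rec <- NULL
  finals <- list(); estimates <- list()
  n_reinit <- 0
  ip0 <- numeric(config$trials)
  for (tr in seq_len(config$trials)) {
    traj <- generate_trajectory(config$arena, config$motion, config$body,
                                config$duration, seed = seeds[tr, 1],
                                start = config$start)
    stream <- corrupt(traj, config$em, seed = seeds[tr, 2],
                      arena = if (isTRUE(config$em$contact_enabled)) config$arena,
                      body = config$body)
    ens0 <- init_ensemble(cfg, config$init_mode, true_pose = traj$pose[1, ],
                          seed = seeds[tr, 3])
    res <- run_filter(ens0, stream, cfg, config$em, truth = traj,
                      seed = seeds[tr, 3])
    s <- res$series
    if (is.null(t_rec)) {
      t_rec <- s$t
      Ip <- matrix(NA_real_, config$trials, length(t_rec))
      herr <- matrix(NA_real_, config$trials, length(t_rec))
    }
    truth_rows <- s$step + 1L
    Ip[tr, ] <- 1 - s$dpost /
      (2 * dint(traj$pose[truth_rows, 1], traj$pose[truth_rows, 2]))
    herr[tr, ] <- angle_diff(atan2(s$head_s, s$head_c),
                             traj$pose[truth_rows, 3])
    d0 <- mean(sqrt((ens0$pose[, 1] - traj$pose[1, 1])^2 +
                    (ens0$pose[, 2] - traj$pose[1, 2])^2))
    ip0[tr] <- 1 - d0 / (2 * dint(traj$pose[1, 1], traj$pose[1, 2]))
    n_reinit <- n_reinit + res$n_reinit
    if (keep_ensembles) finals[[tr]] <- res$ensemble
    if (keep_estimates) {
      estimates[[tr]] <- list(t = s$t, est = cbind(s$mean_x, s$mean_y),
                              true_pos = traj$pose[truth_rows, 1:2,
                                                   drop = FALSE])
    }
    if (progress) {
      message(sprintf("[trial %d/%d] seed=%d final Ip=%.3f reinit=%d",
                      tr, config$trials, seeds[tr, 1],
                      Ip[tr, ncol(Ip)], res$n_reinit))
    }
  }
  # prepend the t = 0 point (initial ensembles; disoriented starts at chance)
  herr0 <- rep(0, config$trials)
  series <- data.frame(
    t = c(0, t_rec),
    Ip_median = c(median(ip0), apply(Ip, 2, median)),
    Ip_q25 = c(quantile(ip0, 0.25), apply(Ip, 2, quantile, 0.25)),
    Ip_q75 = c(quantile(ip0, 0.75), apply(Ip, 2, quantile, 0.75)),
    V_theta = c(if (config$init_mode == "oriented") 0 else 1,
                apply(herr, 2, circular_variance)))
  out <- structure(
    list(series = series, kinetics = t90(series),
         Ip = Ip, Ip0 = ip0, heading_err = herr,
         n_reinit = n_reinit, seeds = seeds, config = config,
         finals = if (keep_ensembles) finals,
         estimates = if (keep_estimates) estimates),
    class = "experiment_result")
  if (!is.null(output_dir)) write_experiment(out, output_dir)
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  k <- x$kinetics
  last <- x$series[nrow(x$series), ]
  cat(sprintf(paste0("<experiment_result '%s'> %d trials, %s simulated\n",
                     "  final Ip_median = %.3f, V(theta) = %.3f, t90 = %s\n"),
              x$config$name, x$config$trials, fmt_mmss(last$t),
              last$Ip_median, last$V_theta, fmt_mmss(k$t90)))
  invisible(x)
}

write_experiment <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$series, file.path(dir, "metric_series.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$kinetics, file.path(dir, "kinetics.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- res$config
  manifest <- list(name = cfg$name, arena = cfg$arena$name,
                   map_arena = cfg$map_arena$name,
                   trials = cfg$trials, duration_s = cfg$duration,
                   N = cfg$N, boundary_mode = cfg$boundary_mode,
                   init_mode = cfg$init_mode,
                   error_model = unclass(cfg$em),
                   motion = unclass(cfg$motion),
                   master_seed = cfg$master_seed,
                   trial_seeds = as.vector(res$seeds),
                   record_every = cfg$record_every,
                   n_reinit = res$n_reinit)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' First time the median place stability index crosses below a level
#' @param series a metric series (with `t` and `Ip_median`).
#' @param level threshold (default chance, 0.5).
#' @return time in seconds, or NA if never crossed.
#' @export
first_crossing_below <- function(series, level = 0.5) {
  hit <- which(series$Ip_median < level & series$t > 0)
  if (length(hit) == 0) return(NA_real_)
  series$t[hit[1]]
}

#' Preset experiment configurations
#'
#' Named protocols at configurable scale. Single-condition presets return an
#' `experiment_config` for [run_experiment()]; use the dedicated runners for
#' multi-condition protocols (asymmetry sweep, barrier dichotomy,
#' thigmotaxis comparison, replay).
#'
#' @param preset one of "fig1_ipi", "fig1_api", "fig2", "fig2_oriented",
#'   "fig3_barrier_crossing", "fig3_barrier_endpoint", "fig4_random",
#'   "fig4_thigmotactic", "fig4_expand" (test arena expanded 10 percent in x,
#'   kite map in memory), "fig5_replay", "s1_mismatch" (filter assumes 4x the
#'   generative noise), "s2_contact" (boundary-contact flags fused every
#'   step), "s3_scale" (kite at 4x area), "s4_compass". The asymmetry sweep
#'   is [run_asymmetry_sweep()].
#' @param trials,duration,N,master_seed scale overrides.
#' @param ... further overrides passed to [experiment_config()].
#' @return an `experiment_config`.
#' @export
preset_config <- function(preset, trials = 100, duration = 2880, N = 2000,
                          master_seed = 1, ...) {
  kite <- make_standard_arena("kite")
  egg <- make_standard_arena("egg")
  base <- list(trials = trials, duration = duration, N = N,
               master_seed = master_seed, name = preset)
  args <- switch(preset,
    fig1_ipi = list(arena = kite, em = default_error_model(mode = "iPI"),
                    boundary_mode = "none", init_mode = "oriented",
                    start = "center"),
    fig1_api = list(arena = kite, em = default_error_model(mode = "aPI"),
                    boundary_mode = "none", init_mode = "oriented",
                    start = "center"),
    fig2 = list(arena = kite, init_mode = "disoriented"),
    fig2_oriented = list(arena = kite, init_mode = "oriented"),
    fig3_barrier_crossing = list(arena = make_standard_arena("circle_barrier"),
                                 boundary_mode = "crossing"),
    fig3_barrier_endpoint = list(arena = make_standard_arena("circle_barrier"),
                                 boundary_mode = "discrete_endpoint"),
    fig4_random = list(arena = egg, body = body_shape(7.5, 3.5),
                       motion = motion_config(policy = "random")),
    fig4_thigmotactic = list(arena = egg, body = body_shape(7.5, 3.5),
                             motion = motion_config(policy = "thigmotactic")),
    fig5_replay = list(arena = kite),
    fig4_expand = list(arena = expand_arena(kite, 1.1, 1.0),
                       map_arena = kite),
    s1_mismatch = list(arena = kite,
                       em = default_error_model(
                         filter_sigma_theta = 4 * default_error_model()$sigma_theta,
                         filter_sigma_step = 4 * default_error_model()$sigma_step)),
    s2_contact = list(arena = kite,
                      em = default_error_model(contact_enabled = TRUE)),
    s3_scale = list(arena = make_standard_arena("kite", scale = 2)),
    s4_compass = list(arena = make_standard_arena("circle"),
                      em = default_error_model(compass_rate = 1 / 30)),
    stop("unknown preset: ", preset))
  do.call(experiment_config,
          utils::modifyList(utils::modifyList(base, args), list(...)))
}

#' Rotational-asymmetry sweep
#'
#' Runs disoriented idiothetic localization in a family of equal-area arenas
#' and tabulates the mean rotational asymmetry against the median adjusted
#' place stability index at the end of the trials (distances taken to the
#' nearest rotationally equivalent image of the truth).
#'
#' @param arenas list of `arena` objects (default: kite, egg and regular
#'   3..6-gons, all area-matched).
#' @param trials,duration,N,master_seed scale parameters.
#' @return data.frame with columns `arena`, `mean_asymmetry`,
#'   `symmetry_order`, `adjusted_Ip`.
#' @export
run_asymmetry_sweep <- function(arenas = NULL, trials = 12, duration = 720,
                                N = 1000, master_seed = 1) {
  if (is.null(arenas)) {
    arenas <- c(list(make_standard_arena("kite"), make_standard_arena("egg")),
                lapply(3:6, function(k)
                  make_standard_arena("regular_polygon", k = k)))
  }
  rows <- lapply(seq_along(arenas), function(ai) {
    a <- arenas[[ai]]
    prof <- mean_rotational_asymmetry(a, step_deg = 5, resolution = 0.5)
    n_rs <- if (is.finite(prof$symmetry_order)) prof$symmetry_order else 1L
    cfg <- experiment_config(a, trials = trials, duration = duration, N = N,
                             master_seed = master_seed + ai,
                             name = paste0("asym_", a$name))
    seeds <- derive_seeds(cfg$master_seed, 3L * trials)
    seeds <- matrix(seeds, ncol = 3)
    fc <- filter_config(a, N = N, record_every = 10)
    ips <- vapply(seq_len(trials), function(tr) {
      traj <- generate_trajectory(a, cfg$motion, NULL, duration,
                                  seed = seeds[tr, 1])
      stream <- corrupt(traj, cfg$em, seed = seeds[tr, 2])
      ens0 <- init_ensemble(fc, "disoriented", seed = seeds[tr, 3])
      res <- run_filter(ens0, stream, fc, cfg$em, seed = seeds[tr, 3])
      adjusted_place_stability(res$ensemble,
                               traj$pose[nrow(traj$pose), 1:2], a, n_rs)
    }, numeric(1))
    data.frame(arena = a$name, mean_asymmetry = prof$mean_asymmetry,
               symmetry_order = n_rs, adjusted_Ip = median(ips))
  })
  do.call(rbind, rows)
}

#' Calibrate the default noise model
#'
#' Selects the smallest (sigma_theta, sigma_step) on a grid such that, in
#' the standard kite arena starting oriented at the centre with the boundary
#' test disabled (pure path integration), the across-trial median place
#' stability index falls below chance (0.5) no later than the target times.
#' sigma_step is chosen first from the aPI condition (heading exact, only
#' step noise matters), then sigma_theta from the iPI condition given that
#' sigma_step.
#'
#' @param target_times list with elements `iPI` and `aPI`, crossing-time
#'   targets in seconds.
#' @param sigma_theta_grid,sigma_step_grid ascending candidate grids.
#' @param trials,N,master_seed simulation scale.
#' @param duration simulated seconds per condition.
#' @return an `error_model` with the selected values, with attribute
#'   `crossings` (achieved crossing times). Errors if no grid point
#'   satisfies a target (the closest candidate is reported).
#' @export
calibrate_noise <- function(target_times = list(iPI = 180, aPI = 360),
                            sigma_theta_grid = seq(0.025, 0.3, by = 0.025),
                            sigma_step_grid = seq(0.05, 0.4, by = 0.05),
                            trials = 100, N = 1000, master_seed = 20,
                            duration = 900) {
  stopifnot(length(sigma_theta_grid) > 0, length(sigma_step_grid) > 0)
  kite <- make_standard_arena("kite")
  crossing_for <- function(em) {
    cfg <- experiment_config(kite, em = em, boundary_mode = "none",
                             init_mode = "oriented", start = "center",
                             trials = trials, duration = duration, N = N,
                             master_seed = master_seed, name = "calibration")
    first_crossing_below(run_experiment(cfg)$series)
  }
  pick <- function(grid, make_em, target, label) {
    times <- rep(NA_real_, length(grid))
    for (i in seq_along(grid)) {
      times[i] <- crossing_for(make_em(grid[i]))
      if (!is.na(times[i]) && times[i] <= target) {
        return(list(value = grid[i], time = times[i]))
      }
    }
    closest <- if (all(is.na(times))) "never" else
      format(min(times, na.rm = TRUE))
    stop(sprintf(
      "no %s grid point meets the %.0f s target; closest crossing: %s",
      label, target, closest))
  }
  st <- pick(sigma_step_grid,
             function(s) error_model(sigma_theta = 0, sigma_step = s,
                                     mode = "aPI"),
             target_times$aPI, "sigma_step")
  th <- pick(sigma_theta_grid,
             function(s) error_model(sigma_theta = s, sigma_step = st$value,
                                     mode = "iPI"),
             target_times$iPI, "sigma_theta")
  structure(error_model(sigma_theta = th$value, sigma_step = st$value),
            crossings = list(iPI = th$time, aPI = st$time))
}
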