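# mean distance from a uniformly distributed point in the traversable region
# to `p`, by quadrature over ~1e5 cached grid points
d_unif <- function(arena, p) {
  pts <- traversable_points(arena, 1e5)
  p <- if (is.matrix(p)) p else matrix(p, ncol = 2)
  cpp_mean_dist(p[, 1], p[, 2], pts[, 1], pts[, 2])
}

# lookup table of d_unif over the arena bounding box (2 cm grid) with
# bilinear interpolation, for fast per-time-step evaluation of metric series
d_unif_interp <- function(arena, cell = 2) {
  key <- paste0("dunif_", arena_hash(arena), "_", cell)
  tab <- cache_get(key, function() {
    bb <- arena_bbox(arena)
    xs <- seq(bb[1, 1] - cell, bb[2, 1] + cell, by = cell)
    ys <- seq(bb[1, 2] - cell, bb[2, 2] + cell, by = cell)
    g <- expand.grid(x = xs, y = ys)
    pts <- traversable_points(arena, 1e5)
    v <- cpp_mean_dist(g$x, g$y, pts[, 1], pts[, 2])
    list(xs = xs, ys = ys, z = matrix(v, length(xs), length(ys)))
  })
  function(x, y) {
    ix <- pmin(pmax(findInterval(x, tab$xs), 1L), length(tab$xs) - 1L)
    iy <- pmin(pmax(findInterval(y, tab$ys), 1L), length(tab$ys) - 1L)
    fx <- (x - tab$xs[ix]) / diff(tab$xs[1:2])
    fy <- (y - tab$ys[iy]) / diff(tab$ys[1:2])
    tab$z[cbind(ix, iy)] * (1 - fx) * (1 - fy) +
      tab$z[cbind(ix + 1L, iy)] * fx * (1 - fy) +
      tab$z[cbind(ix, iy + 1L)] * (1 - fx) * fy +
      tab$z[cbind(ix + 1L, iy + 1L)] * fx * fy
  }
}

#' Place stability index
#'
#' I_p = 1 - D_post / (2 * D_unif), where D_post is the weighted mean
#' Euclidean distance from the particles to the true position and D_unif is
#' the mean distance from a uniformly distributed point in the traversable
#' region to the true position. An ensemble uniform over the arena scores
#' 0.5 (chance); a delta ensemble at the truth scores 1 (perfect
#' localization). Values below 0 (worse than chance) are not clamped.
#'
#' @param ens a `particle_ensemble`, or an n x 2 matrix of positions.
#' @param true_pos length-2 true position.
#' @param arena the arena the index is referenced to.
#' @param weights optional weights when `ens` is a matrix.
#' @return I_p, a unitless score <= 1.
#' @export
place_stability_index <- function(ens, true_pos, arena, weights = NULL) {
  if (inherits(ens, "particle_ensemble")) {
    pos <- ens$pose[, 1:2, drop = FALSE]
    w <- ens$weights
  } else {
    pos <- as.matrix(ens)
    w <- weights %||% rep(1 / nrow(pos), nrow(pos))
  }
  if (nrow(pos) == 0) stop("empty ensemble")
  w <- w / sum(w)
  dpost <- sum(w * sqrt((pos[, 1] - true_pos[1])^2 +
                        (pos[, 2] - true_pos[2])^2))
  1 - dpost / (2 * d_unif(arena, true_pos))
}

# distance to the nearest of the n rotational images of `true_pos` about the
# arena centroid
rot_min_dist <- function(px, py, true_pos, cen, n) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  d <- rep(Inf, length(px))
  for (a in ang) {
    tx <- cen[1] + cos(a) * (true_pos[1] - cen[1]) - sin(a) * (true_pos[2] - cen[2])
    ty <- cen[2] + sin(a) * (true_pos[1] - cen[1]) + cos(a) * (true_pos[2] - cen[2])
    d <- pmin(d, sqrt((px - tx)^2 + (py - ty)^2))
  }
  d
}

#' Adjusted place stability index for n-fold rotationally symmetric arenas
#'
#' As [place_stability_index()], but distances are taken to the nearest of
#' the n rotational images of the true position about the arena centroid
#' (within each of the n geometrically equivalent sectors localization is
#' possible, so credit is given for localizing to any image). The uniform
#' normalizer is recomputed with the same distance. n = 1 reduces to the
#' plain index.
#'
#' @param ens a `particle_ensemble` or n x 2 position matrix.
#' @param true_pos length-2 true position.
#' @param arena the arena.
#' @param n symmetry order (>= 1).
#' @param weights optional weights when `ens` is a matrix.
#' @return adjusted I_p.
#' @export
adjusted_place_stability <- function(ens, true_pos, arena, n,
                                     weights = NULL) {
  stopifnot(n >= 1)
  if (n == 1) return(place_stability_index(ens, true_pos, arena, weights))
  if (inherits(ens, "particle_ensemble")) {
    pos <- ens$pose[, 1:2, drop = FALSE]
    w <- ens$weights
  } else {
    pos <- as.matrix(ens)
    w <- weights %||% rep(1 / nrow(pos), nrow(pos))
  }
  w <- w / sum(w)
  cen <- arena_centroid(arena)
  dpost <- sum(w * rot_min_dist(pos[, 1], pos[, 2], true_pos, cen, n))
  pts <- traversable_points(arena, 1e5)
  dunif <- mean(rot_min_dist(pts[, 1], pts[, 2], true_pos, cen, n))
  1 - dpost / (2 * dunif)
}

#' Circular variance of heading errors
#'
#' V = 1 - R where R is the length of the mean unit vector of the errors:
#' 0 when every error is zero, approaching 1 for uniformly random errors.
#'
#' @param heading_errors angular errors in radians (across trials).
#' @return V in [0, 1].
#' @export
circular_variance <- function(heading_errors) {
  stopifnot(length(heading_errors) >= 1)
  1 - circ_mean(heading_errors)$R
}

#' Convergence kinetics of a metric series
#'
#' The plateau is the median of the last 10 percent of the median-I_p
#' series; t90 is the first time at which the series has completed 90
#' percent of its change from the starting value to the plateau. A flat
#' series returns t90 = 0.
#'
#' @param series data.frame with columns `t` and `Ip_median` (a
#'   `metric_series` from [run_experiment()] works directly).
#' @return list with `t90` (seconds), `start_value`, `plateau_value`.
#' @export
t90 <- function(series) {
  stopifnot(nrow(series) >= 10)
  ip <- series$Ip_median
  tt <- series$t
  ntail <- max(1, ceiling(0.1 * length(ip)))
  plateau <- median(ip[(length(ip) - ntail + 1):length(ip)])
  start <- ip[1]
  change <- abs(plateau - start)
  if (change == 0) {
    return(list(t90 = 0, start_value = start, plateau_value = plateau))
  }
  hit <- which(abs(ip - start) >= 0.9 * change)
  list(t90 = if (length(hit)) tt[hit[1]] else tt[length(tt)],
       start_value = start, plateau_value = plateau)
}
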