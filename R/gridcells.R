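#' Grid-cell model
#'
#' A stochastic spiking model: the cell's preferred firing locations form a
#' hexagonal lattice, and spike probability decreases with the distance of
#' the *estimated* position from the nearest lattice node,
#' lambda = lambda_max * exp(-d^2 / (2 * sigma_f^2)).
#'
#' @param spacing lattice spacing, cm (default 30).
#' @param orientation lattice orientation, radians.
#' @param phase length-2 lattice offset, cm.
#' @param lambda_max peak firing rate, Hz.
#' @param sigma_f firing-field width, cm (default 0.2 * spacing).
#' @return object of class `grid_model`.
#' @export
grid_model <- function(spacing = 30, orientation = 0, phase = c(0, 0),
                       lambda_max = 20, sigma_f = 0.2 * spacing) {
  stopifnot(spacing > 0, sigma_f > 0, lambda_max >= 0)
  structure(list(spacing = spacing, orientation = orientation,
                 phase = phase, lambda_max = lambda_max, sigma_f = sigma_f),
            class = "grid_model")
}

#' Randomly phased/oriented grid model
#' @param spacing lattice spacing, cm.
#' @param seed optional integer seed.
#' @param ... passed to [grid_model()].
#' @return a `grid_model`.
#' @export
random_grid_model <- function(spacing = 30, seed = NULL, ...) {
  with_seed(seed, grid_model(spacing = spacing,
                             orientation = runif(1, 0, pi / 3),
                             phase = runif(2, 0, spacing), ...))
}

#' Distance from points to the nearest node of the hexagonal lattice
#' @param x,y coordinates in cm.
#' @param gm a `grid_model`.
#' @return numeric vector of distances (cm).
#' @export
grid_node_distance <- function(x, y, gm) {
  co <- cos(-gm$orientation); so <- sin(-gm$orientation)
  px <- co * (x - gm$phase[1]) - so * (y - gm$phase[2])
  py <- so * (x - gm$phase[1]) + co * (y - gm$phase[2])
  s <- gm$spacing
  # lattice basis (s,0) and (s/2, s*sqrt(3)/2); fractional coordinates
  v <- py / (s * sqrt(3) / 2)
  u <- px / s - v / 2
  d2 <- rep(Inf, length(px))
  for (iu in -1:2) for (iv in -1:2) {
    nu <- floor(u) + iu; nv <- floor(v) + iv
    nx <- s * nu + s / 2 * nv
    ny <- s * sqrt(3) / 2 * nv
    d2 <- pmin(d2, (px - nx)^2 + (py - ny)^2)
  }
  sqrt(d2)
}

#' Simulate grid-cell spikes from an estimated-position stream
#'
#' Per step the spike count is Poisson with rate lambda(d) * dt, where d is
#' the distance from the *estimated* position to the nearest lattice node.
#' Spikes are georeferenced to the *true* position, so spatial structure in
#' the resulting firing field appears only when the estimate tracks the
#' truth.
#'
#' @param est_pos n x 2 estimated positions.
#' @param true_pos n x 2 true positions (aligned with `est_pos`).
#' @param gm a `grid_model`.
#' @param dt step interval, seconds.
#' @param seed optional integer seed.
#' @param t optional time stamps (defaults to step index * dt).
#' @return data.frame of spikes: `t`, `x`, `y` (true position).
#' @export
simulate_spikes <- function(est_pos, true_pos, gm, dt, seed = NULL,
                            t = NULL) {
  est_pos <- as.matrix(est_pos); true_pos <- as.matrix(true_pos)
  stopifnot(nrow(est_pos) == nrow(true_pos))
  d <- grid_node_distance(est_pos[, 1], est_pos[, 2], gm)
  lambda <- gm$lambda_max * exp(-d^2 / (2 * gm$sigma_f^2))
  t <- t %||% (seq_len(nrow(est_pos)) * dt)
  with_seed(seed, {
    counts <- rpois(length(lambda), lambda * dt)
    idx <- rep(seq_along(counts), counts)
    data.frame(t = t[idx], x = true_pos[idx, 1], y = true_pos[idx, 2])
  })
}

#' Occupancy-normalized firing rate map
#'
#' Bins spike counts and occupancy time on a square pixel grid, smooths both
#' with a Gaussian kernel, and divides. Unvisited pixels are masked (NA).
#'
#' @param spikes data.frame with `x`, `y` (as from [simulate_spikes()]).
#' @param traj a `trajectory`, or an n x 2 matrix of visited positions.
#' @param dt occupancy time per position sample, seconds (taken from `traj`
#'   when it is a `trajectory`).
#' @param pixel_size pixel side, cm.
#' @param smoothing_sd Gaussian smoothing SD in pixels (0 = none).
#' @param extent optional 2 x 2 matrix rbind(c(xmin, ymin), c(xmax, ymax));
#'   defaults to the bounding box of the visited positions.
#' @return object of class `rate_map`.
#' @export
rate_map <- function(spikes, traj, dt = NULL, pixel_size = 2,
                     smoothing_sd = 1, extent = NULL) {
  stopifnot(pixel_size > 0)
  if (inherits(traj, "trajectory")) {
    pos <- traj$pose[, 1:2, drop = FALSE]
    dt <- dt %||% traj$dt
  } else {
    pos <- as.matrix(traj)
    if (is.null(dt)) stop("dt required when traj is a position matrix")
  }
  if (nrow(pos) == 0) stop("empty trajectory")
  if (is.null(extent)) {
    extent <- rbind(apply(pos, 2, min) - pixel_size,
                    apply(pos, 2, max) + pixel_size)
  }
  xs <- seq(extent[1, 1], extent[2, 1] + pixel_size, by = pixel_size)
  ys <- seq(extent[1, 2], extent[2, 2] + pixel_size, by = pixel_size)
  nx <- length(xs) - 1; ny <- length(ys) - 1
  bin2 <- function(x, y) {
    ix <- pmin(pmax(findInterval(x, xs), 1L), nx)
    iy <- pmin(pmax(findInterval(y, ys), 1L), ny)
    m <- matrix(0, nx, ny)
    tb <- table(factor(ix + (iy - 1L) * nx, levels = seq_len(nx * ny)))
    m[] <- as.numeric(tb)
    m
  }
  occ <- bin2(pos[, 1], pos[, 2]) * dt
  cnt <- if (nrow(spikes)) bin2(spikes$x, spikes$y) else matrix(0, nx, ny)
  mask <- occ > 0
  occ_s <- gauss_smooth(occ, smoothing_sd)
  cnt_s <- gauss_smooth(cnt, smoothing_sd)
  rate <- cnt_s / occ_s
  rate[!mask] <- NA_real_
  structure(list(rate = rate, counts = cnt, occupancy = occ, mask = mask,
                 pixel_size = pixel_size, x0 = xs[1], y0 = ys[1],
                 n_spikes = nrow(spikes)),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map> %d x %d px (%g cm), %d spikes, peak %.2f Hz\n",
              nrow(x$rate), ncol(x$rate), x$pixel_size, x$n_spikes,
              suppressWarnings(max(x$rate, na.rm = TRUE))))
  invisible(x)
}

gauss_smooth <- function(m, sd_px) {
  if (sd_px <= 0) return(m)
  r <- ceiling(3 * sd_px)
  k <- exp(-(-r:r)^2 / (2 * sd_px^2))
  k <- k / sum(k)
  # separable convolution with edge renormalization via a ones-pass
  conv1 <- function(a, along) {
    out <- matrix(0, nrow(a), ncol(a))
    for (o in -r:r) {
      w <- k[o + r + 1]
      if (along == 1) {
        src <- seq_len(nrow(a)) + o
        ok <- src >= 1 & src <= nrow(a)
        out[ok, ] <- out[ok, ] + w * a[src[ok], , drop = FALSE]
      } else {
        src <- seq_len(ncol(a)) + o
        ok <- src >= 1 & src <= ncol(a)
        out[, ok] <- out[, ok] + w * a[, src[ok], drop = FALSE]
      }
    }
    out
  }
  sm <- conv1(conv1(m, 1), 2)
  ones <- conv1(conv1(matrix(1, nrow(m), ncol(m)), 1), 2)
  sm / ones
}

# full cross-correlation sum xc(a,b)[tau] = sum_x a(x) * b(x + tau) over all
# integer lags tau in [-(n-1), n-1] per axis, via zero-padded FFT
xcorr2_sum <- function(a, b) {
  na <- nrow(a); ma <- ncol(a)
  P <- 2 * na - 1; Q <- 2 * ma - 1
  pa <- matrix(0, P, Q); pb <- matrix(0, P, Q)
  pa[1:na, 1:ma] <- a; pb[1:na, 1:ma] <- b
  r <- Re(fft(Conj(fft(pa)) * fft(pb), inverse = TRUE)) / (P * Q)
  # index tau >= 0 at r[tau + 1]; tau < 0 wrapped at the end
  ix <- c(P - ((na - 1):1) + 1, 1:na)
  iy <- c(Q - ((ma - 1):1) + 1, 1:ma)
  r[ix, iy]
}

#' Spatial autocorrelogram of a rate map
#'
#' Pearson correlation of the map with itself at every integer pixel lag,
#' computed over the pixels valid in both copies; lags with fewer than 20
#' overlapping pixels are NA.
#'
#' @param map a `rate_map`, or a numeric matrix (NA = invalid).
#' @param min_overlap minimum overlapping pixels per lag.
#' @return matrix of size (2*nx-1) x (2*ny-1), centre = zero lag.
#' @export
autocorrelogram <- function(map, min_overlap = 20) {
  z <- if (inherits(map, "rate_map")) map$rate else map
  m <- !is.na(z) * 1
  z0 <- z; z0[is.na(z0)] <- 0
  n <- xcorr2_sum(m, m)
  sxy <- xcorr2_sum(z0, z0)
  sx <- xcorr2_sum(z0, m)
  sy <- xcorr2_sum(m, z0)
  sx2 <- xcorr2_sum(z0^2, m)
  sy2 <- xcorr2_sum(m, z0^2)
  num <- n * sxy - sx * sy
  den2 <- (n * sx2 - sx^2) * (n * sy2 - sy^2)
  r <- num / sqrt(pmax(den2, 0))
  r[n < min_overlap | den2 <= 1e-12] <- NA_real_
  r
}

# sample a matrix at fractional indices by bilinear interpolation
bilinear_at <- function(m, fi, fj) {
  n <- nrow(m); q <- ncol(m)
  i0 <- floor(fi); j0 <- floor(fj)
  ok <- i0 >= 1 & i0 <= n - 1 & j0 >= 1 & j0 <= q - 1
  out <- rep(NA_real_, length(fi))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]
  di <- fi[ok] - i0; dj <- fj[ok] - j0
  v <- m[cbind(i0, j0)] * (1 - di) * (1 - dj) +
    m[cbind(i0 + 1, j0)] * di * (1 - dj) +
    m[cbind(i0, j0 + 1)] * (1 - di) * dj +
    m[cbind(i0 + 1, j0 + 1)] * di * dj
  out[ok] <- v
  out
}

#' Gridness score of a rate map
#'
#' Standard rotational score on an annulus of the spatial autocorrelogram:
#' the annulus excludes the central peak (inner radius = first zero crossing
#' of the radial profile) and extends to 1.25 x the modal distance of the
#' surrounding peaks. The score is min(corr at 60, 120 degrees) - max(corr
#' at 30, 90, 150 degrees); hexagonal fields score high positive, square
#' lattices negative. Returns NA (with attribute `reason`) when fewer than
#' 3 peaks are detectable.
#'
#' @param map a `rate_map` or autocorrelogram matrix (odd dimensions,
#'   centre = zero lag).
#' @param is_autocorr set TRUE when `map` is already an autocorrelogram.
#' @return gridness score (typically in [-1.5, 1.5]), or NA.
#' @export
gridness <- function(map, is_autocorr = FALSE) {
  ac <- if (is_autocorr) map else autocorrelogram(map)
  n <- nrow(ac); q <- ncol(ac)
  ci <- (n + 1) / 2; cj <- (q + 1) / 2
  ii <- matrix(seq_len(n), n, q) - ci
  jj <- matrix(seq_len(q), n, q, byrow = TRUE) - cj
  rr <- sqrt(ii^2 + jj^2)
  # radial profile -> first zero crossing = central peak extent
  rmax <- floor(min(ci, cj)) - 1
  prof <- vapply(seq_len(rmax), function(r)
    mean(ac[rr >= r - 0.5 & rr < r + 0.5], na.rm = TRUE), numeric(1))
  zc <- which(prof <= 0)[1]
  inner <- if (is.na(zc)) max(2, rmax %/% 4) else zc
  # peaks: local maxima outside the central peak
  peaks <- find_peaks(ac, exclude_r = inner, rr = rr)
  if (nrow(peaks) < 3) {
    return(structure(NA_real_, reason = "fewer than 3 detectable peaks"))
  }
  modal <- median(sort(peaks$r)[seq_len(min(6, nrow(peaks)))])
  outer <- min(1.25 * modal, rmax)
  sel <- rr >= inner & rr <= outer & !is.na(ac)
  base <- ac[sel]
  rot_corr <- function(deg) {
    a <- deg * pi / 180
    si <- ci + cos(a) * ii[sel] - sin(a) * jj[sel]
    sj <- cj + sin(a) * ii[sel] + cos(a) * jj[sel]
    v <- bilinear_at(ac, si, sj)
    ok <- !is.na(v)
    if (sum(ok) < 20) return(NA_real_)
    cor(base[ok], v[ok])
  }
  cs <- vapply(c(30, 60, 90, 120, 150), rot_corr, numeric(1))
  min(cs[c(2, 4)]) - max(cs[c(1, 3, 5)])
}

find_peaks <- function(ac, exclude_r, rr, thresh = 0.1) {
  n <- nrow(ac); q <- ncol(ac)
  z <- ac; z[is.na(z)] <- -Inf
  res <- NULL
  for (i in 2:(n - 1)) for (j in 2:(q - 1)) {
    v <- z[i, j]
    if (v < thresh || rr[i, j] <= exclude_r) next
    nb <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (v >= max(nb)) res <- rbind(res, c(i, j, rr[i, j]))
  }
  if (is.null(res)) return(data.frame(i = integer(0), j = integer(0),
                                      r = numeric(0)))
  data.frame(i = res[, 1], j = res[, 2], r = res[, 3])
}

#' Spatial information content of a rate map
#'
#' sum_i p_i * (lambda_i / lambda_bar) * log2(lambda_i / lambda_bar), with
#' p_i the occupancy probability of pixel i and lambda_bar the
#' occupancy-weighted mean rate. Uniform firing gives 0 bits/spike.
#'
#' @param map a `rate_map`.
#' @return information in bits per spike.
#' @export
spatial_information <- function(map) {
  ok <- map$mask & !is.na(map$rate)
  p <- map$occupancy[ok] / sum(map$occupancy[ok])
  lam <- map$rate[ok]
  lbar <- sum(p * lam)
  if (lbar <= 0) stop("zero mean rate")
  pos <- lam > 0
  sum(p[pos] * (lam[pos] / lbar) * log2(lam[pos] / lbar))
}

#' Optimal rescaling between two rate maps
#'
#' Finds the scale factors (sx, sy) maximizing the normalized
#' cross-correlation between the reference map and the test map rescaled
#' about its centre, over a grid of candidate factors: the result is the
#' stretch embodied in the test map relative to the reference (a test map
#' recorded in an arena expanded 10 percent in x gives sx near 1.1).
#'
#' @param test_map,reference_map `rate_map` objects on the same pixel size.
#' @param s_range candidate scale factors (applies to both axes).
#' @return list with `sx`, `sy`, `correlation`, and the full correlation
#'   matrix (`grid`); flat maps give an NA result with attribute `reason`.
#' @export
optimal_rescaling <- function(test_map, reference_map,
                              s_range = seq(0.8, 1.3, by = 0.01)) {
  stopifnot(isTRUE(all.equal(test_map$pixel_size, reference_map$pixel_size)))
  ref <- reference_map$rate
  tz <- test_map$rate
  if (sd(ref, na.rm = TRUE) == 0 || sd(tz, na.rm = TRUE) == 0) {
    return(structure(list(sx = NA_real_, sy = NA_real_,
                          correlation = NA_real_, grid = NULL),
                     reason = "flat map"))
  }
  nri <- nrow(ref); nrj <- ncol(ref)
  cri <- (nri + 1) / 2; crj <- (nrj + 1) / 2
  cti <- (nrow(tz) + 1) / 2; ctj <- (ncol(tz) + 1) / 2
  ii <- matrix(seq_len(nri), nri, nrj) - cri
  jj <- matrix(seq_len(nrj), nri, nrj, byrow = TRUE) - crj
  refv <- as.vector(ref)
  best <- c(NA, NA, -Inf)
  cm <- matrix(NA_real_, length(s_range), length(s_range))
  for (a in seq_along(s_range)) for (b in seq_along(s_range)) {
    sx <- s_range[a]; sy <- s_range[b]
    v <- bilinear_at(tz, cti + as.vector(ii) * sx, ctj + as.vector(jj) * sy)
    ok <- !is.na(v) & !is.na(refv)
    if (sum(ok) < 50) next
    r <- suppressWarnings(cor(refv[ok], v[ok]))
    if (is.na(r)) next
    cm[a, b] <- r
    if (r > best[3]) best <- c(sx, sy, r)
  }
  list(sx = best[1], sy = best[2], correlation = best[3],
       grid = cm, s_range = s_range)
}
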