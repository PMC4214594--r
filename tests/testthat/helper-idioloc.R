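# Shared fixtures and independent oracles for the test suite.  Oracles are
# deliberately implemented through different code paths than the package
# (mgcv::in.out for containment, dense sampling for crossings, direct
# orientation predicates for barrier intersections).

std_arena <- local({
  cache <- list()
  function(name, ...) {
    key <- paste(name, ..., sep = "_")
    if (is.null(cache[[key]])) cache[[key]] <<- make_standard_arena(name, ...)
    cache[[key]]
  }
})

# independent containment oracle (mgcv's in/out test, even-odd with voids)
pip_oracle <- function(arena, x, y) {
  close_ring <- function(m) rbind(m, m[1, ])
  inside <- mgcv::in.out(close_ring(arena$outer), cbind(x, y))
  for (v in arena$voids) {
    inside <- inside & !mgcv::in.out(close_ring(v), cbind(x, y))
  }
  inside
}

# dense point-sampling crossing oracle (valid for arenas without barriers):
# a segment "crosses" iff any sampled point leaves traversable space
seg_cross_sampling_oracle <- function(arena, p0, p1, n = 2000) {
  tt <- seq(0, 1, length.out = n)
  pts <- cbind(p0[1] + tt * (p1[1] - p0[1]), p0[2] + tt * (p1[2] - p0[2]))
  any(!contains(arena, pts))
}

# orientation-predicate segment intersection (proper crossings only)
ccw3 <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}
seg_int_oracle <- function(p, q, a, b) {
  d1 <- ccw3(a[1], a[2], b[1], b[2], p[1], p[2])
  d2 <- ccw3(a[1], a[2], b[1], b[2], q[1], q[2])
  d3 <- ccw3(p[1], p[2], q[1], q[2], a[1], a[2])
  d4 <- ccw3(p[1], p[2], q[1], q[2], b[1], b[2])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# uniform random points in the traversable region (rejection sampling)
random_inside <- function(arena, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bb <- rbind(apply(arena$outer, 2, min), apply(arena$outer, 2, max))
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < n) {
    m <- 3 * n
    p <- cbind(runif(m, bb[1, 1], bb[2, 1]), runif(m, bb[1, 2], bb[2, 2]))
    out <- rbind(out, p[contains(arena, p), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# synthetic rate_map built from a rate function on a pixel grid
synthetic_rate_map <- function(f, xs = seq(-41, 41, by = 2),
                               ys = seq(-35, 35, by = 2), occupancy = 1) {
  g <- expand.grid(x = xs, y = ys)
  nx <- length(xs); ny <- length(ys)
  structure(list(rate = matrix(f(g$x, g$y), nx, ny),
                 occupancy = matrix(occupancy, nx, ny),
                 counts = matrix(0, nx, ny),
                 mask = matrix(TRUE, nx, ny),
                 pixel_size = xs[2] - xs[1], x0 = xs[1], y0 = ys[1],
                 n_spikes = 0L),
            class = "rate_map")
}
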