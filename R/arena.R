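#' Construct an arena
#'
#' An arena is a traversable 2D region bounded by a simple closed outer
#' polygon, possibly with interior voids (closed holes excluded from
#' traversable space) and barriers (open polylines that block movement but
#' have no area). Coordinates are in centimetres; by convention arenas are
#' centred on the centroid of their traversable region.
#'
#' @param outer n x 2 matrix of outer boundary vertices (open ring, i.e.
#'   first vertex not repeated).
#' @param voids list of m x 2 matrices, closed holes strictly inside the
#'   outer boundary.
#' @param barriers list of k x 2 matrices, open polyline obstacles.
#' @param name label for the arena.
#' @param center if TRUE (default), translate so the centroid of the
#'   traversable region is at the origin.
#' @return object of class `arena`.
#' @export
arena <- function(outer, voids = list(), barriers = list(),
                  name = "custom", center = TRUE) {
  outer <- as_ring(outer)
  voids <- lapply(voids, as_ring)
  barriers <- lapply(barriers, function(b) {
    b <- as.matrix(b)
    storage.mode(b) <- "double"
    dimnames(b) <- NULL
    stopifnot(ncol(b) == 2, nrow(b) >= 2)
    b
  })
  a <- structure(
    list(outer = outer, voids = voids, barriers = barriers,
         name = name, units = "cm"),
    class = "arena")
  if (arena_area(a) <= 0) stop("arena has non-positive traversable area")
  if (center) {
    cen <- arena_centroid(a)
    a$outer <- sweep(a$outer, 2, cen)
    a$voids <- lapply(a$voids, function(v) sweep(v, 2, cen))
    a$barriers <- lapply(a$barriers, function(b) sweep(b, 2, cen))
  }
  a
}

# ensure an open, counter-clockwise ring stored as a double matrix
as_ring <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  stopifnot(ncol(m) == 2, nrow(m) >= 3)
  if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  if (ring_area(m) < 0) m <- m[nrow(m):1, , drop = FALSE]
  m
}

# signed (shoelace) area of an open ring
ring_area <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

ring_centroid <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' @export
print.arena <- function(x, ...) {
  cat(sprintf("<arena '%s'> area %.1f cm^2, %d outer vertices, %d void(s), %d barrier(s)\n",
              x$name, arena_area(x), nrow(x$outer), length(x$voids),
              length(x$barriers)))
  invisible(x)
}

#' Traversable area of an arena (outer area minus voids), cm^2
#' @param arena an `arena`.
#' @return area in cm^2.
#' @export
arena_area <- function(arena) {
  abs(ring_area(arena$outer)) - sum(vapply(arena$voids, function(v)
    abs(ring_area(v)), numeric(1)))
}

#' Centroid of the traversable region
#' @param arena an `arena`.
#' @return length-2 numeric (x, y).
#' @export
arena_centroid <- function(arena) {
  a0 <- abs(ring_area(arena$outer))
  cen <- ring_centroid(arena$outer) * a0
  tot <- a0
  for (v in arena$voids) {
    av <- abs(ring_area(v))
    cen <- cen - ring_centroid(v) * av
    tot <- tot - av
  }
  cen / tot
}

arena_bbox <- function(arena) {
  rbind(apply(arena$outer, 2, min), apply(arena$outer, 2, max))
}

arena_hash <- function(arena) {
  rlang::hash(list(arena$outer, arena$voids, arena$barriers))
}

# rings (outer + voids) as a list of matrices, for containment queries
arena_rings <- function(arena) c(list(arena$outer), arena$voids)

# all boundary edges (outer + voids closed, barriers open) as an
# (n x 4) matrix of segments
arena_edges <- function(arena) {
  key <- paste0("edges_", arena_hash(arena))
  cache_get(key, function() {
    close_ring <- function(m) cbind(m, rbind(m[-1, , drop = FALSE], m[1, , drop = FALSE]))
    open_line <- function(m) cbind(m[-nrow(m), , drop = FALSE], m[-1, , drop = FALSE])
    parts <- c(lapply(arena_rings(arena), close_ring),
               lapply(arena$barriers, open_line))
    e <- do.call(rbind, parts)
    dimnames(e) <- NULL
    e
  })
}

# outer boundary edges only (wall-following uses the outer wall)
arena_outer_edges <- function(arena) {
  m <- arena$outer
  e <- cbind(m, rbind(m[-1, , drop = FALSE], m[1, , drop = FALSE]))
  dimnames(e) <- NULL
  e
}

# spatial index over all edges, reach must cover max step + body radius
arena_edge_index <- function(arena, reach) {
  reach <- 5 * ceiling(reach / 5)
  key <- paste0("idx_", arena_hash(arena), "_", reach)
  cache_get(key, function() {
    bb <- arena_bbox(arena)
    h <- 4
    pad <- reach + 2 * h
    x0 <- bb[1, 1] - pad; y0 <- bb[1, 2] - pad
    nx <- ceiling((bb[2, 1] + pad - x0) / h)
    ny <- ceiling((bb[2, 2] + pad - y0) / h)
    cpp_build_edge_index(arena_edges(arena), x0, y0, h, nx, ny,
                         reach + h * 0.7072)
  })
}

# coarse distance-to-boundary lookup grid (fast interior short-circuit in
# the filter kernel)
arena_dist_grid <- function(arena, cell = 2) {
  key <- paste0("dgrid_", arena_hash(arena), "_", cell)
  cache_get(key, function() {
    bb <- arena_bbox(arena)
    pad <- 4 * cell
    xs <- seq(bb[1, 1] - pad, bb[2, 1] + pad, by = cell)
    ys <- seq(bb[1, 2] - pad, bb[2, 2] + pad, by = cell)
    g <- expand.grid(x = xs + cell / 2, y = ys + cell / 2)
    d <- cpp_min_edge_dist(g$x, g$y, arena_edges(arena))
    list(x0 = xs[1], y0 = ys[1], cell = cell,
         d = matrix(d, length(xs), length(ys)))
  })
}

# deterministic quadrature points covering the traversable region
# (approximately n points on a square grid)
traversable_points <- function(arena, n = 1e5) {
  key <- paste0("unif_", arena_hash(arena), "_", n)
  cache_get(key, function() {
    bb <- arena_bbox(arena)
    cell <- sqrt(arena_area(arena) / n)
    xs <- seq(bb[1, 1] + cell / 2, bb[2, 1], by = cell)
    ys <- seq(bb[1, 2] + cell / 2, bb[2, 2], by = cell)
    g <- expand.grid(x = xs, y = ys)
    keep <- cpp_points_in_rings(g$x, g$y, arena_rings(arena))
    as.matrix(g[keep, ])
  })
}

# random uniform poses in the traversable region (optionally requiring the
# body to fit)
sample_poses <- function(arena, n, body = NULL, max_tries = 500L) {
  bb <- arena_bbox(arena)
  out <- matrix(NA_real_, 0, 3)
  rings <- arena_rings(arena)
  tries <- 0L
  while (nrow(out) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not sample a contained pose: body cannot fit in the arena")
    }
    m <- max(2L * (n - nrow(out)), 100L)
    x <- runif(m, bb[1, 1], bb[2, 1])
    y <- runif(m, bb[1, 2], bb[2, 2])
    th <- runif(m, 0, 2 * pi)
    keep <- cpp_points_in_rings(x, y, rings)
    if (!is.null(body)) {
      idx <- which(keep)
      if (length(idx)) {
        fit <- vapply(idx, function(i)
          contains(arena, c(x[i], y[i]), body = body, theta = th[i]),
          logical(1))
        keep[idx] <- fit
      }
    }
    out <- rbind(out, cbind(x, y, th)[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Elliptic body shape
#'
#' The navigating agent's body perimeter, an ellipse with semi-axes `a >= b`.
#' A point body is represented by `NULL` wherever a body is accepted.
#'
#' @param a,b semi-axes in cm, `a >= b >= 0`.
#' @return object of class `body_shape`.
#' @export
body_shape <- function(a, b) {
  stopifnot(a >= b, b >= 0)
  structure(list(a = a, b = b), class = "body_shape")
}

# perimeter sample points in the body frame (n x 2); empty matrix for a
# point body
body_points <- function(body, n = 72) {
  if (is.null(body) || (body$a == 0 && body$b == 0))
    return(matrix(numeric(0), 0, 2))
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(body$a * cos(phi), body$b * sin(phi))
}

#' Containment test
#'
#' Is the body, placed at position `p` with heading `theta`, wholly inside
#' the traversable space (inside the outer boundary and outside all voids)?
#' For a point body this is a point-in-region test. For an elliptic body the
#' centre plus 72 perimeter sample points are tested.
#'
#' @param arena an `arena`.
#' @param p numeric length-2 position, or an n x 2 matrix of positions.
#' @param body `body_shape` or NULL for a point body.
#' @param theta heading(s) in radians (recycled).
#' @return logical vector.
#' @export
contains <- function(arena, p, body = NULL, theta = 0) {
  p <- if (is.matrix(p)) p else matrix(p, ncol = 2)
  rings <- arena_rings(arena)
  inside <- cpp_points_in_rings(p[, 1], p[, 2], rings)
  bp <- body_points(body)
  if (nrow(bp) > 0) {
    theta <- rep_len(theta, nrow(p))
    for (i in which(inside)) {
      ct <- cos(theta[i]); st <- sin(theta[i])
      px <- p[i, 1] + ct * bp[, 1] - st * bp[, 2]
      py <- p[i, 2] + st * bp[, 1] + ct * bp[, 2]
      if (!all(cpp_points_in_rings(px, py, rings))) inside[i] <- FALSE
    }
  }
  inside
}

#' Does a segment cross any boundary?
#'
#' TRUE iff the segment p0 -> p1 intersects the outer boundary, any barrier
#' or any void boundary; endpoints outside traversable space also count as
#' crossing.
#'
#' @param arena an `arena`.
#' @param p0,p1 length-2 positions or n x 2 matrices.
#' @return logical vector.
#' @export
segment_crosses <- function(arena, p0, p1) {
  p0 <- if (is.matrix(p0)) p0 else matrix(p0, ncol = 2)
  p1 <- if (is.matrix(p1)) p1 else matrix(p1, ncol = 2)
  cross <- cpp_segments_cross(p0[, 1], p0[, 2], p1[, 1], p1[, 2],
                              arena_edges(arena))
  rings <- arena_rings(arena)
  cross | !cpp_points_in_rings(p0[, 1], p0[, 2], rings) |
    !cpp_points_in_rings(p1[, 1], p1[, 2], rings)
}

#' Distance from point(s) to the nearest boundary
#' @param arena an `arena`.
#' @param p length-2 position or n x 2 matrix.
#' @return numeric vector of distances (cm).
#' @export
boundary_distance <- function(arena, p) {
  p <- if (is.matrix(p)) p else matrix(p, ncol = 2)
  cpp_min_edge_dist(p[, 1], p[, 2], arena_edges(arena))
}

# rasterization grid for rotational-asymmetry computation: a square grid of
# points centred on the traversable centroid, wide enough to cover every
# rotation of the region, plus the cached membership mask
asym_grid <- function(arena, resolution = 0.25) {
  key <- paste0("asym_", arena_hash(arena), "_", resolution)
  cache_get(key, function() {
    cen <- arena_centroid(arena)
    bb <- arena_bbox(arena)
    r <- sqrt(max((bb[, 1] - cen[1])^2) + max((bb[, 2] - cen[2])^2))
    xs <- seq(-r, r, by = resolution)
    nx <- length(xs)
    g <- expand.grid(x = xs + cen[1], y = xs + cen[2])
    mask <- cpp_points_in_rings(g$x, g$y, arena_rings(arena))
    list(cen = cen, x0 = xs[1], res = resolution, n = nx,
         mask = matrix(mask, nx, nx))
  })
}

# look up mask membership at arbitrary coordinates (relative to centroid)
# by nearest grid point; coordinates outside the grid are outside the region
asym_lookup <- function(g, rx, ry) {
  ix <- round((rx - g$x0) / g$res) + 1L
  iy <- round((ry - g$x0) / g$res) + 1L
  ok <- ix >= 1L & ix <= g$n & iy >= 1L & iy <= g$n
  out <- logical(length(rx))
  out[ok] <- g$mask[cbind(ix[ok], iy[ok])]
  out
}

#' Rotational asymmetry of an arena
#'
#' A(phi) is the area of the symmetric difference between the traversable
#' region and its rotation by `phi` about the region centroid, divided by
#' twice the traversable area. A(phi) = 0 iff rotation by phi maps the
#' region onto itself; a circle gives 0 for every phi. Computed on a
#' rasterized membership mask (default 0.25 cm grid).
#'
#' @param arena an `arena`.
#' @param phi rotation angle(s) in radians.
#' @param resolution raster cell size in cm.
#' @return numeric vector of asymmetry fractions in [0, 1].
#' @export
rotational_asymmetry <- function(arena, phi, resolution = 0.25) {
  g <- asym_grid(arena, resolution)
  idx <- seq_len(g$n) - 1L
  rx <- g$x0 + rep(idx, times = g$n) * g$res
  ry <- g$x0 + rep(idx, each = g$n) * g$res
  inside <- as.vector(g$mask)
  n_in <- sum(inside)
  vapply(phi, function(a) {
    # membership of the region rotated by a == membership of the point
    # rotated by -a in the original region
    ca <- cos(-a); sa <- sin(-a)
    rot_in <- asym_lookup(g, ca * rx - sa * ry, sa * rx + ca * ry)
    sum(inside != rot_in) / (2 * n_in)
  }, numeric(1))
}

#' Rotational asymmetry profile
#'
#' Samples A(phi) at 1 degree resolution over (0, 360) degrees and reports
#' the mean asymmetry and the rotational symmetry order.
#'
#' @param arena an `arena`.
#' @param step_deg sampling step in degrees.
#' @param resolution raster cell size in cm.
#' @param tol symmetry tolerance passed to [symmetry_order()].
#' @return list with `angles` (radians), `values`, `mean_asymmetry`,
#'   `symmetry_order` (Inf for a circle).
#' @export
mean_rotational_asymmetry <- function(arena, step_deg = 1, resolution = 0.25,
                                      tol = 0.02) {
  ang <- seq(step_deg, 360 - step_deg, by = step_deg) * pi / 180
  vals <- rotational_asymmetry(arena, ang, resolution = resolution)
  structure(list(angles = ang, values = vals,
                 mean_asymmetry = mean(vals),
                 symmetry_order = symmetry_order_from_profile(ang, vals, tol)),
            class = "asymmetry_profile")
}

symmetry_order_from_profile <- function(ang, vals, tol) {
  if (max(vals) <= tol) return(Inf)
  for (n in 12:2) {
    ks <- 2 * pi * seq_len(n - 1) / n
    v <- vapply(ks, function(k) vals[which.min(abs(ang - k))], numeric(1))
    if (all(v <= tol)) return(n)
  }
  1L
}

#' Rotational symmetry order of an arena
#'
#' Largest n such that rotation by 2*pi*k/n leaves the traversable region
#' unchanged (asymmetry at most `tol`) for all k = 1..n-1. A circle (no
#' angle changes it) is reported as `Inf`.
#'
#' @param arena an `arena`.
#' @param tol asymmetry tolerance, in (0, 0.05].
#' @param resolution raster cell size in cm.
#' @return integer order, or Inf.
#' @export
symmetry_order <- function(arena, tol = 0.02, resolution = 0.25) {
  stopifnot(tol > 0, tol <= 0.05)
  # a circle is invariant under any rotation; test two generic angles
  probe <- rotational_asymmetry(arena, c(1, sqrt(2)), resolution = resolution)
  if (all(probe <= tol)) return(Inf)
  for (n in 12:2) {
    ks <- 2 * pi * seq_len(n - 1) / n
    if (all(rotational_asymmetry(arena, ks, resolution = resolution) <= tol))
      return(n)
  }
  1L
}

#' Expand an arena about its centroid
#'
#' @param arena an `arena`.
#' @param sx,sy positive scale factors for x and y.
#' @return expanded `arena` (area scales by sx * sy).
#' @export
expand_arena <- function(arena, sx, sy = sx) {
  stopifnot(sx > 0, sy > 0)
  cen <- arena_centroid(arena)
  sc <- function(m) cbind(cen[1] + (m[, 1] - cen[1]) * sx,
                          cen[2] + (m[, 2] - cen[2]) * sy)
  arena(sc(arena$outer), lapply(arena$voids, sc), lapply(arena$barriers, sc),
        name = sprintf("%s_x%.2f_y%.2f", arena$name, sx, sy), center = FALSE)
}

# ---- standard arenas -------------------------------------------------------

# canonical kite: interior angles 60 (acute), 90, 120 (obtuse), 90 degrees,
# longest diagonal 80 cm
kite_vertices <- function() {
  L <- 80
  rbind(c(0, 0),
        c(0.75 * L, -sqrt(3) / 4 * L),
        c(L, 0),
        c(0.75 * L, sqrt(3) / 4 * L))
}

regular_polygon_vertices <- function(k, area) {
  R <- sqrt(2 * area / (k * sin(2 * pi / k)))
  a <- 2 * pi * (seq_len(k) - 1) / k + pi / k
  cbind(R * cos(a), R * sin(a))
}

# polygon vertex count for discretizing a curve of radius r so the sagitta
# stays below `tol` (0.1 mm default), capped at 360
arc_segments <- function(r, tol = 0.01) {
  n <- ceiling(pi / acos(1 - min(tol / r, 0.5)))
  as.integer(min(max(n, 90), 360))
}

circle_vertices <- function(diameter, n = arc_segments(diameter / 2)) {
  a <- 2 * pi * (seq_len(n) - 1) / n
  cbind(diameter / 2 * cos(a), diameter / 2 * sin(a))
}

# egg: ellipse with a linear taper along x -- one reflective axis, no
# straight edges, no rotational symmetry; scaled to the target area
egg_vertices <- function(area, n = NULL) {
  shape <- function(n) {
    t <- 2 * pi * (seq_len(n) - 1) / n
    cbind(cos(t), 0.78 * sin(t) * (1 + 0.35 * cos(t)))
  }
  raw <- shape(256)
  s <- sqrt(area / abs(ring_area(raw)))
  n <- n %||% arc_segments(s)  # curvature radius of order the long axis
  shape(n) * sqrt(area / abs(ring_area(shape(n))))
}

tmaze_vertices <- function(area) {
  # two 20 cm corridors: 80 x 20 cross-bar + 20 x 60 stem (area 2800)
  v <- rbind(c(-10, 0), c(10, 0), c(10, 60), c(40, 60), c(40, 80),
             c(-40, 80), c(-40, 60), c(-10, 60))
  v * sqrt(area / 2800)
}

teardrop_vertices <- function(center = c(14, 0), r = 6, apex = c(28, 0)) {
  t <- seq(0.6, 2 * pi - 0.6, length.out = 40)
  rbind(cbind(center[1] + r * cos(t), center[2] + r * sin(t)), apex)
}

#' Standard arenas
#'
#' Constructs the built-in arenas at canonical dimensions times `scale`.
#' The reference shapes: `kite` (1-fold rotational symmetry, interior angles
#' 60/90/120/90 degrees, longest diagonal 80 cm), `egg` (one reflective axis,
#' no straight edges), `tmaze` (two 20 cm corridors), `circle` (diameter
#' 76 cm, discretized to a 360-gon), `circle_barrier` (76 cm circle with an
#' asymmetrically placed bent 25 cm barrier), `void_landmark` (76 cm circle
#' with an off-centre teardrop void), `square`, and `regular_polygon` with
#' `k` edges. Kite, egg, T-maze, square and regular polygons are matched in
#' area to the canonical kite (about 2771 cm^2).
#'
#' @param name one of "kite", "egg", "tmaze", "circle", "circle_barrier",
#'   "void_landmark", "square", "regular_polygon".
#' @param scale positive linear scale factor.
#' @param k number of edges for `regular_polygon`.
#' @return an `arena`.
#' @export
make_standard_arena <- function(name = c("kite", "egg", "tmaze", "circle",
                                         "circle_barrier", "void_landmark",
                                         "square", "regular_polygon"),
                                scale = 1, k = NULL) {
  name <- match.arg(name)
  if (!is.numeric(scale) || scale <= 0) stop("scale must be positive")
  ref_area <- abs(ring_area(kite_vertices()))
  a <- switch(name,
    kite = arena(kite_vertices(), name = "kite"),
    egg = arena(egg_vertices(ref_area), name = "egg"),
    tmaze = arena(tmaze_vertices(ref_area), name = "tmaze"),
    circle = arena(circle_vertices(76), name = "circle"),
    circle_barrier = arena(circle_vertices(76),
                           barriers = list(rbind(c(2, -6), c(12, 2), c(8, 14))),
                           name = "circle_barrier", center = FALSE),
    void_landmark = arena(circle_vertices(76),
                          voids = list(teardrop_vertices()),
                          name = "void_landmark"),
    square = arena(regular_polygon_vertices(4, ref_area), name = "square"),
    regular_polygon = {
      if (is.null(k) || k < 3) stop("regular_polygon requires k >= 3")
      arena(regular_polygon_vertices(k, ref_area),
            name = sprintf("regular_%d_gon", k))
    })
  if (scale != 1) {
    a <- expand_arena(a, scale, scale)
    a$name <- sprintf("%s_x%g", name, scale)
  }
  a
}

# ---- arena file I/O --------------------------------------------------------

#' Write an arena to a JSON file
#'
#' Vertex lists round-trip exactly (full double precision).
#' @param arena an `arena`.
#' @param path output file path.
#' @export
write_arena <- function(arena, path) {
  obj <- list(name = arena$name, units = arena$units,
              outer = unname(arena$outer),
              voids = lapply(arena$voids, unname),
              barriers = lapply(arena$barriers, unname))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

# normalize a JSON-simplified list of vertex matrices (may come back as a
# single matrix or a 3-d array)
as_ring_list <- function(x) {
  if (is.null(x) || length(x) == 0) return(list())
  if (is.array(x) && length(dim(x)) == 3)
    return(lapply(seq_len(dim(x)[1]), function(i) x[i, , ]))
  if (is.matrix(x)) return(list(x))
  lapply(x, as.matrix)
}

#' Read an arena from a JSON file
#' @param path file written by [write_arena()], or a compatible config with
#'   `outer` as a vertex list or `{"circle": {"center": [x,y], "diameter": d}}`.
#' @return an `arena`.
#' @export
read_arena <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  outer <- obj$outer
  if (is.list(outer) && !is.null(outer$circle)) {
    cen <- outer$circle$center %||% c(0, 0)
    outer <- sweep(circle_vertices(outer$circle$diameter), 2, -cen)
  }
  arena(outer, voids = as_ring_list(obj$voids),
        barriers = as_ring_list(obj$barriers),
        name = obj$name %||% "from_file", center = FALSE)
}
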