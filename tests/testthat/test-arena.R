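test_that("standard arenas have the documented canonical dimensions", {
  kite <- std_arena("kite")
  v <- kite$outer
  n <- nrow(v)
  angles <- sapply(seq_len(n), function(i) {
    p <- v[(i - 2) %% n + 1, ]; q <- v[i, ]; r <- v[i %% n + 1, ]
    acos(sum((p - q) * (r - q)) /
           sqrt(sum((p - q)^2) * sum((r - q)^2))) * 180 / pi
  })
  expect_equal(sort(round(angles)), c(60, 90, 90, 120))
  # longest diagonal 80 cm
  dmax <- max(dist(v))
  expect_equal(dmax, 80, tolerance = 1e-9)

  circ <- std_arena("circle")
  bb <- apply(circ$outer, 2, range)
  expect_equal(diff(bb[, 1]), 76, tolerance = 0.05)
  big <- make_standard_arena("circle", scale = 2)
  expect_equal(diff(apply(big$outer, 2, range)[, 1]), 152, tolerance = 0.1)

  # egg / tmaze / square / regular polygons are area-matched to the kite
  ka <- arena_area(kite)
  for (nm in c("egg", "tmaze", "square")) {
    expect_equal(arena_area(std_arena(nm)), ka, tolerance = 0.01)
  }
  expect_equal(arena_area(make_standard_arena("regular_polygon", k = 5)),
               ka, tolerance = 0.01)

  expect_error(make_standard_arena("pentagon"))
  expect_error(make_standard_arena("kite", scale = -1))
  expect_error(make_standard_arena("regular_polygon"))
})

test_that("containment agrees with an independent point-in-region oracle", {
  skip_if_not_installed("mgcv")
  for (nm in c("kite", "tmaze", "void_landmark")) {
    a <- std_arena(nm)
    bb <- rbind(apply(a$outer, 2, min) - 5, apply(a$outer, 2, max) + 5)
    set.seed(41)
    x <- runif(500, bb[1, 1], bb[2, 1])
    y <- runif(500, bb[1, 2], bb[2, 2])
    expect_equal(unname(contains(a, cbind(x, y))),
                 unname(pip_oracle(a, x, y)))
  }
})

test_that("elliptic-body containment respects the body perimeter", {
  sq <- std_arena("square")
  half <- max(sq$outer[, 1])
  body <- body_shape(7.5, 3.5)
  p <- c(half - 5, 0)  # centre 5 cm from a straight wall
  # long axis perpendicular to the wall: tip (7.5 cm) protrudes
  expect_false(contains(sq, p, body, theta = 0))
  # long axis parallel: half-width 3.5 cm < 5 cm clearance
  expect_true(contains(sq, p, body, theta = pi / 2))
  # dense perimeter oracle (3600 points) agrees at both poses
  for (th in c(0, pi / 2)) {
    phi <- seq(0, 2 * pi, length.out = 3601)[-3601]
    px <- p[1] + cos(th) * 7.5 * cos(phi) - sin(th) * 3.5 * sin(phi)
    py <- p[2] + sin(th) * 7.5 * cos(phi) + cos(th) * 3.5 * sin(phi)
    expect_equal(contains(sq, p, body, theta = th),
                 all(contains(sq, cbind(px, py))))
  }
  expect_true(contains(std_arena("circle"), c(0, 0)))
  expect_false(contains(std_arena("circle"), c(39, 0)))
})

test_that("segment crossing matches a dense sampling oracle on random segments", {
  set.seed(7)
  for (nm in c("kite", "square", "circle", "tmaze", "void_landmark")) {
    a <- std_arena(nm)
    bb <- rbind(apply(a$outer, 2, min) - 10, apply(a$outer, 2, max) + 10)
    p0 <- cbind(runif(300, bb[1, 1], bb[2, 1]), runif(300, bb[1, 2], bb[2, 2]))
    p1 <- cbind(runif(300, bb[1, 1], bb[2, 1]), runif(300, bb[1, 2], bb[2, 2]))
    got <- segment_crosses(a, p0, p1)
    want <- vapply(seq_len(300), function(i)
      seg_cross_sampling_oracle(a, p0[i, ], p1[i, ]), logical(1))
    expect_gte(mean(got == want), 0.997)
  }
  circ <- std_arena("circle")
  expect_false(segment_crosses(circ, c(-20, 5), c(25, -10)))  # interior chord
  expect_true(segment_crosses(circ, c(0, 0), c(100, 0)))      # exits the arena
})

test_that("interior barriers block crossing but not containment", {
  cb <- std_arena("circle_barrier")
  bar <- cb$barriers[[1]]
  # two traversable points on opposite sides of the barrier
  mid <- (bar[1, ] + bar[2, ]) / 2
  dir <- (bar[2, ] - bar[1, ]) / sqrt(sum((bar[2, ] - bar[1, ])^2))
  nrm <- c(-dir[2], dir[1])
  p0 <- mid + 4 * nrm; p1 <- mid - 4 * nrm
  expect_true(contains(cb, p0) && contains(cb, p1))
  expect_true(segment_crosses(cb, p0, p1))
  # agreement with an orientation-predicate oracle on random interior segments
  set.seed(13)
  inner <- random_inside(std_arena("circle"), 400)
  q0 <- inner[1:200, ]; q1 <- inner[201:400, ]
  edges <- cbind(bar[-nrow(bar), , drop = FALSE], bar[-1, , drop = FALSE])
  want <- vapply(1:200, function(i) {
    any(vapply(seq_len(nrow(edges)), function(j)
      seg_int_oracle(q0[i, ], q1[i, ], edges[j, 1:2], edges[j, 3:4]),
      logical(1)))
  }, logical(1))
  # restrict to segments that do not graze the outer wall
  ok <- !segment_crosses(std_arena("circle"), q0, q1)
  expect_equal(unname(segment_crosses(cb, q0, q1)[ok]), unname(want[ok]))
})

test_that("rotational asymmetry behaves like an area symmetric difference", {
  circ <- std_arena("circle")
  expect_lt(max(rotational_asymmetry(circ, c(0.4, 1.1, 2.7))), 0.01)
  sq <- std_arena("square")
  expect_lt(rotational_asymmetry(sq, pi / 2), 0.01)
  expect_gt(rotational_asymmetry(sq, pi / 4), 0.1)

  # kite profile matches a 1 mm rasterized symmetric-difference oracle
  kite <- std_arena("kite")
  angs <- seq(15, 345, by = 30) * pi / 180
  impl <- rotational_asymmetry(kite, angs)
  cen <- arena_centroid(kite)
  bb <- rbind(apply(kite$outer, 2, min), apply(kite$outer, 2, max))
  r <- sqrt(max((bb[, 1] - cen[1])^2) + max((bb[, 2] - cen[2])^2))
  xs <- seq(-r, r, by = 0.1)
  g <- expand.grid(x = xs + cen[1], y = xs + cen[2])
  inside <- contains(kite, as.matrix(g))
  oracle <- vapply(angs, function(a) {
    rx <- g$x - cen[1]; ry <- g$y - cen[2]
    rot <- contains(kite, cbind(cen[1] + cos(-a) * rx - sin(-a) * ry,
                                cen[2] + sin(-a) * rx + cos(-a) * ry))
    sum(inside != rot) / (2 * sum(inside))
  }, numeric(1))
  expect_equal(mean(impl), mean(oracle), tolerance = 0.01)
  expect_lt(max(abs(impl - oracle) / oracle), 0.01)

  # invariance to rigid translation; mirror symmetry A(phi) = A(2*pi - phi)
  shifted <- arena(sweep(kite$outer, 2, c(-12, 7)), name = "kite_shifted",
                   center = FALSE)
  expect_equal(rotational_asymmetry(shifted, angs), impl, tolerance = 0.02)
  expect_equal(rotational_asymmetry(kite, 2 * pi - angs), impl,
               tolerance = 0.02)
})

test_that("symmetry order identifies n-fold rotational symmetry", {
  expect_identical(symmetry_order(std_arena("kite")), 1L)
  expect_identical(symmetry_order(std_arena("square")), 4L)
  expect_identical(symmetry_order(std_arena("circle")), Inf)
  expect_identical(symmetry_order(std_arena("egg")), 1L)
  expect_identical(symmetry_order(std_arena("void_landmark")), 1L)
  for (k in c(3, 5, 6, 7, 8, 9, 10)) {
    expect_identical(symmetry_order(make_standard_arena("regular_polygon",
                                                        k = k)), as.integer(k))
  }
  expect_error(symmetry_order(std_arena("kite"), tol = 0.2))
})

test_that("arena expansion scales area and preserves containment", {
  kite <- std_arena("kite")
  expect_equal(arena_area(expand_arena(kite, 1.1, 1)) / arena_area(kite), 1.1)
  expect_equal(arena_area(expand_arena(kite, 2, 2)) / arena_area(kite), 4)
  same <- expand_arena(kite, 1, 1)
  expect_equal(same$outer, kite$outer)
  expect_error(expand_arena(kite, 0, 1))
  # containment is monotone under expansion
  pts <- random_inside(kite, 200, seed = 3)
  expect_true(all(contains(expand_arena(kite, 1.25, 1.1), pts)))
})

test_that("arena files round-trip exactly", {
  path <- tempfile(fileext = ".json")
  for (nm in c("kite", "circle_barrier", "void_landmark")) {
    a <- std_arena(nm)
    write_arena(a, path)
    b <- read_arena(path)
    expect_identical(b$outer, a$outer)
    expect_equal(b$voids, a$voids, tolerance = 0)
    expect_equal(b$barriers, a$barriers, tolerance = 0)
  }
  # circle shorthand
  writeLines('{"name":"c","units":"cm","outer":{"circle":{"center":[0,0],"diameter":76}}}',
             path)
  cc <- read_arena(path)
  expect_equal(arena_area(cc), arena_area(std_arena("circle")), tolerance = 1)
})
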