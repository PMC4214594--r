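#' @useDynLib idioloc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rpois runif median quantile fft sd cor mad
NULL

# package-local cache for derived arena geometry (edge tables, quadrature
# points, distance lookup tables), keyed by a hash of the arena coordinates
.idioloc_cache <- new.env(parent = emptyenv())

cache_get <- function(key, fn) {
  if (!exists(key, envir = .idioloc_cache, inherits = FALSE)) {
    assign(key, fn(), envir = .idioloc_cache)
  }
  get(key, envir = .idioloc_cache, inherits = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles into [0, 2*pi)
#' @param a angles in radians.
#' @return wrapped angles.
#' @export
wrap_angle <- function(a) {
  a <- a %% (2 * pi)
  a[a < 0] <- a[a < 0] + 2 * pi
  a
}

#' Signed angular difference a - b wrapped into (-pi, pi]
#' @param a,b angles in radians.
#' @return wrapped differences.
#' @export
angle_diff <- function(a, b) {
  d <- (a - b + pi) %% (2 * pi)
  d[d < 0] <- d[d < 0] + 2 * pi
  d - pi
}

# circular mean and resultant length of a set of angles (optionally weighted)
circ_mean <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1 / length(theta), length(theta))
  w <- w / sum(w)
  c_ <- sum(w * cos(theta))
  s_ <- sum(w * sin(theta))
  list(mean = atan2(s_, c_), R = sqrt(c_^2 + s_^2))
}

# Deterministic per-trial seeds derived from one master seed.
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

# mm:ss formatting used in logs
fmt_mmss <- function(seconds) {
  m <- floor(seconds / 60)
  s <- round(seconds - 60 * m)
  sprintf("%d:%02d", m, s)
}
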