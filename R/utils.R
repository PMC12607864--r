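# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Check a scalar is a finite number satisfying a predicate
#' @noRd
check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0 (got %g)", name, x), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0 (got %g)", name, x), call. = FALSE)
  invisible(x)
}

#' Lognormal multiplicative noise factors with mean 1 and coefficient of
#' variation cv (cv = 0 returns exact 1s)
#' @noRd
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Centered moving average with shrinking symmetric windows at the edges
#' @noRd
moving_average <- function(y, window = 5L) {
  stopifnot(window %% 2 == 1)
  n <- length(y)
  k <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    kk <- min(k, i - 1L, n - i)
    mean(y[(i - kk):(i + kk)])
  }, numeric(1))
}

#' Points strictly inside a closed polygon (vertices as n x 2 matrix)
#' @noRd
points_in_polygon <- function(poly, pts) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  mgcv::in.out(rbind(poly, poly[1L, ]), pts)
}

#' Bilinear interpolation of a pixel-grid image at physical coordinates.
#' Pixel (r, c) of `img` has its center at ((c - 0.5), (r - 0.5)) * pixel_size.
#' @noRd
interp_bilinear <- function(img, x, y, pixel_size) {
  rc <- y / pixel_size + 0.5
  cc <- x / pixel_size + 0.5
  r0 <- pmin(pmax(floor(rc), 1), nrow(img) - 1L)
  c0 <- pmin(pmax(floor(cc), 1), ncol(img) - 1L)
  fr <- pmin(pmax(rc - r0, 0), 1)
  fc <- pmin(pmax(cc - c0, 0), 1)
  v00 <- img[cbind(r0, c0)]
  v10 <- img[cbind(r0 + 1L, c0)]
  v01 <- img[cbind(r0, c0 + 1L)]
  v11 <- img[cbind(r0 + 1L, c0 + 1L)]
  v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
}

#' Signed polygon area (positive = counter-clockwise)
#' @noRd
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Resample a closed polygon to n points equally spaced in arclength
#' @noRd
resample_closed <- function(p, n) {
  if (sqrt(sum((p[1, ] - p[nrow(p), ])^2)) < 1e-9) p <- p[-nrow(p), , drop = FALSE]
  q <- rbind(p, p[1, ])
  seg <- sqrt(rowSums(diff(q)^2))
  cs <- c(0, cumsum(seg))
  total <- cs[length(cs)]
  s_new <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  cbind(stats::approx(cs, q[, 1], xout = s_new)$y,
        stats::approx(cs, q[, 2], xout = s_new)$y)
}

#' Cumulative arclength of an open polyline
#' @noRd
polyline_arclength <- function(p) {
  c(0, cumsum(sqrt(rowSums(diff(p)^2))))
}

#' Shortest distance from points to a segment ab (all physical coordinates)
#' @noRd
dist_to_segment <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  vv <- vx^2 + vy^2
  if (vv < 1e-300) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(pmax(((px - ax) * vx + (py - ay) * vy) / vv, 0), 1)
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

#' Minimum distance between two segments
#' @noRd
segment_distance <- function(a1, a2, b1, b2) {
  ts <- seq(0, 1, length.out = 33)
  pa <- cbind(a1[1] + ts * (a2[1] - a1[1]), a1[2] + ts * (a2[2] - a1[2]))
  pb <- cbind(b1[1] + ts * (b2[1] - b1[1]), b1[2] + ts * (b2[2] - b1[2]))
  d1 <- min(dist_to_segment(pa[, 1], pa[, 2], b1[1], b1[2], b2[1], b2[2]))
  d2 <- min(dist_to_segment(pb[, 1], pb[, 2], a1[1], a1[2], a2[1], a2[2]))
  min(d1, d2)
}
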