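# Segmentation of phase-contrast images, pill-mesh construction, and
# shape measurement in the midline coordinate system.
#
# Cells are modelled as spherocylinders (capsules): a cylinder of length
# L - 2R with hemispherical caps of radius R = W/2.  All outputs are in
# physical micrometers; pixel (r, c) of an image has its center at
# ((c - 0.5) * pixel_size, (r - 0.5) * pixel_size).

#' Spherocylinder volume from length and width
#'
#' `V = pi R^2 (L - 2R) + (4/3) pi R^3` with `R = W/2`: a cylinder with
#' hemispherical endcaps.  At `L = W` this is the volume of a sphere.
#'
#' @param length Cell length L (um), midline pole-to-pole.
#' @param width Cell width W (um).
#' @return Volume in um^3.  Vectorized; `length < width` is an error
#'   (such a cell is not a rod and must be flagged, not silently approximated).
#' @export
spherocylinder_volume <- function(length, width) {
  if (any(!is.finite(length)) || any(!is.finite(width)) || any(width <= 0))
    stop("length and width must be finite with width > 0", call. = FALSE)
  if (any(length < width))
    stop("length < width: cell is round, not a spherocylinder", call. = FALSE)
  r <- width / 2
  pi * r^2 * (length - 2 * r) + 4 / 3 * pi * r^3
}

#' Segment a phase-contrast frame into subpixel cell contours
#'
#' Dark cells on a bright background are thresholded (Otsu on the inverted
#' image, or a user-supplied threshold on the inverted, 0-1 normalized
#' image), labelled, filtered by area, optionally stripped of
#' border-touching components, and each component's Gaussian-smoothed mask
#' is contoured at the 0.5 level with marching squares and resampled to a
#' fixed number of points.
#'
#' @param image Numeric matrix (grayscale phase image).
#' @param pixel_size Pixel size (um/px).
#' @param min_area Minimum enclosed area (um^2) for a valid cell.
#' @param threshold Optional manual threshold in `[0, 1]` applied to the
#'   inverted normalized image; default Otsu.
#' @param exclude_border Drop components touching the image border
#'   (default TRUE; they are flagged otherwise).
#' @param n_points Number of contour points after resampling.
#' @return List of contours.  Each contour is an `n_points x 2` matrix of
#'   (x, y) um, counter-clockwise, with attributes `label`, `area`
#'   (um^2), `centroid`, `touches_border`, and `pixel_size`.  A blank
#'   frame returns an empty list.
#' @export
segment_frame <- function(image, pixel_size, min_area = 0.5,
                          threshold = NULL, exclude_border = TRUE,
                          n_points = 200L) {
  stopifnot(is.matrix(image))
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  rng <- range(image)
  if (diff(rng) < 1e-9 * max(abs(rng), 1)) return(list())  # blank frame
  inv <- (rng[2] - image) / diff(rng)                      # cells bright
  th <- if (is.null(threshold)) EBImage::otsu(inv, range = c(0, 1)) else threshold
  fg <- inv > th
  # a frame whose two threshold classes barely separate carries no cells
  # (noise-only background); a threshold claiming most of the frame as
  # foreground indicates an effectively unimodal histogram
  sd_within <- sqrt(mean(c(stats::var(image[fg]), stats::var(image[!fg])),
                         na.rm = TRUE))
  contrast <- abs(mean(image[fg]) - mean(image[!fg])) /
    max(sd_within, .Machine$double.eps)
  if (!is.finite(contrast) || contrast < 4) return(list())
  if (mean(fg) > 0.5)
    stop("threshold failure: foreground covers most of the image ",
         "(histogram likely unimodal)", call. = FALSE)
  lab <- EBImage::bwlabel(fg)
  nlab <- max(lab)
  if (nlab == 0) return(list())
  out <- list()
  for (l in seq_len(nlab)) {
    idx <- which(lab == l, arr.ind = TRUE)
    area_px <- nrow(idx)
    if (area_px * pixel_size^2 < min_area) next
    touches <- any(idx[, 1] %in% c(1L, nrow(image))) ||
      any(idx[, 2] %in% c(1L, ncol(image)))
    if (touches && exclude_border) next
    contour <- component_contour(idx, dim(image), pixel_size, n_points)
    if (is.null(contour)) next
    attr(contour, "label") <- l
    attr(contour, "area") <- abs(polygon_area(contour))
    attr(contour, "centroid") <- colMeans(contour)
    attr(contour, "touches_border") <- touches
    attr(contour, "pixel_size") <- pixel_size
    class(contour) <- c("cell_contour", class(contour))
    out[[length(out) + 1L]] <- contour
  }
  out
}

# Subpixel contour of one labelled component: crop with padding, smooth
# the binary mask (Gaussian sigma = 1 px), marching squares at 0.5,
# resample to n points in global um coordinates, enforce CCW.
component_contour <- function(idx, dims, pixel_size, n_points) {
  pad <- 4L
  r0 <- max(min(idx[, 1]) - pad, 1L); r1 <- min(max(idx[, 1]) + pad, dims[1])
  c0 <- max(min(idx[, 2]) - pad, 1L); c1 <- min(max(idx[, 2]) + pad, dims[2])
  m <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
  m[cbind(idx[, 1] - r0 + 1L, idx[, 2] - c0 + 1L)] <- 1
  ms <- EBImage::gblur(m, sigma = 1)
  # grid of physical coordinates of pixel centers (global frame)
  yr <- (seq(r0, r1) - 0.5) * pixel_size
  xc <- (seq(c0, c1) - 0.5) * pixel_size
  cl <- grDevices::contourLines(x = yr, y = xc, z = ms, levels = 0.5)
  if (length(cl) == 0) return(NULL)
  lens <- vapply(cl, function(p) length(p$x), numeric(1))
  p <- cl[[which.max(lens)]]
  poly <- cbind(p$y, p$x)  # contourLines x follows rows (our y); swap
  if (nrow(poly) < 8) return(NULL)
  poly <- resample_closed(poly, n_points)
  if (polygon_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  poly
}

# Approximate min/max caliper widths over sampled directions
caliper_ratio <- function(p, n_dir = 90L) {
  ang <- seq(0, pi, length.out = n_dir + 1L)[-(n_dir + 1L)]
  ext <- vapply(ang, function(a) {
    proj <- p[, 1] * cos(a) + p[, 2] * sin(a)
    diff(range(proj))
  }, numeric(1))
  max(ext) / min(ext)
}

# TRUE if the closed polygon intersects itself (non-adjacent edges cross)
is_self_intersecting <- function(p) {
  n <- nrow(p)
  a <- p; b <- p[c(2:n, 1L), ]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]
    d1x <- b[i, 1] - a[i, 1]; d1y <- b[i, 2] - a[i, 2]
    # orientation tests, vectorized over candidate edges
    o1 <- d1x * (a[js, 2] - a[i, 2]) - d1y * (a[js, 1] - a[i, 1])
    o2 <- d1x * (b[js, 2] - a[i, 2]) - d1y * (b[js, 1] - a[i, 1])
    d2x <- b[js, 1] - a[js, 1]; d2y <- b[js, 2] - a[js, 2]
    o3 <- d2x * (a[i, 2] - a[js, 2]) - d2y * (a[i, 1] - a[js, 1])
    o4 <- d2x * (b[i, 2] - a[js, 2]) - d2y * (b[i, 1] - a[js, 1])
    if (any(o1 * o2 < 0 & o3 * o4 < 0)) return(TRUE)
  }
  FALSE
}

#' Build the pill-mesh midline coordinate system of a cell contour
#'
#' Poles are the contour point pair with maximal separation (ties broken
#' by lowest index).  The contour is split at the poles into two sides,
#' paired by normalized arclength; the raw midline of rib midpoints is
#' smoothed with a moving average, and ribs are then re-projected
#' perpendicular to the smoothed midline, giving per-rib widths from the
#' two boundary crossings.
#'
#' @param contour Closed contour matrix (n x 2, um) as from
#'   [segment_frame()].
#' @param n_ribs Number of midline stations (including the poles);
#'   `NULL` (default) targets `rib_spacing` um between stations, with a
#'   floor of 51, so long filaments keep axial resolution.
#' @param rib_spacing Target distance between midline stations (um) when
#'   `n_ribs` is not given.
#' @param smooth_window Moving-average window (points) for the midline.
#' @return Object of class `pill_mesh`: list with `midline` (m x 2),
#'   `s` (cumulative arclength, um), `width` (per-station rib width, um;
#'   `NA` at the poles), `ribs` (left/right crossing points), and the
#'   originating `contour`.
#' @export
build_pillmesh <- function(contour, n_ribs = NULL, rib_spacing = 0.1,
                           smooth_window = 5L) {
  p <- unclass(contour)
  stopifnot(is.matrix(p), ncol(p) == 2, nrow(p) >= 8)
  if (is_self_intersecting(p))
    stop("non-simple contour: self-intersection detected", call. = FALSE)
  if (caliper_ratio(p) < 1.2)
    stop("degenerate mesh: cell is nearly round (max/min caliper < 1.2)",
         call. = FALSE)
  n <- nrow(p)
  d <- as.matrix(stats::dist(p))
  pole <- which(d == max(d), arr.ind = TRUE)
  pole <- pole[order(pole[, 1], pole[, 2]), , drop = FALSE][1L, ]
  i <- min(pole); j <- max(pole)
  if (is.null(n_ribs))
    n_ribs <- max(51L, as.integer(ceiling(max(d) / rib_spacing)) + 1L)
  side1 <- p[i:j, , drop = FALSE]
  side2 <- p[c(j:n, 1:i), , drop = FALSE]
  side2 <- side2[rev(seq_len(nrow(side2))), , drop = FALSE]  # run pole i -> pole j

  resample_open <- function(q, m) {
    s <- polyline_arclength(q)
    keep <- c(TRUE, diff(s) > 1e-12)     # drop coincident vertices
    q <- q[keep, , drop = FALSE]; s <- s[keep]
    u <- s / s[length(s)]
    uo <- seq(0, 1, length.out = m)
    cbind(stats::approx(u, q[, 1], xout = uo)$y,
          stats::approx(u, q[, 2], xout = uo)$y)
  }
  a <- resample_open(side1, n_ribs)
  b <- resample_open(side2, n_ribs)
  mid <- (a + b) / 2
  mid[, 1] <- moving_average(mid[, 1], smooth_window)
  mid[, 2] <- moving_average(mid[, 2], smooth_window)

  # re-project ribs perpendicular to the smoothed midline
  m <- nrow(mid)
  width <- rep(NA_real_, m)
  left <- matrix(NA_real_, m, 2); right <- matrix(NA_real_, m, 2)
  for (k in 2:(m - 1L)) {
    tg <- mid[k + 1L, ] - mid[k - 1L, ]
    tg <- tg / sqrt(sum(tg^2))
    nv <- c(-tg[2], tg[1])
    cr <- line_polygon_crossings(mid[k, ], nv, p)
    if (is.null(cr)) next
    left[k, ] <- cr$neg; right[k, ] <- cr$pos
    width[k] <- cr$pos_t - cr$neg_t
  }
  s <- polyline_arclength(mid)
  structure(list(midline = mid, s = s, width = width,
                 ribs = list(left = left, right = right),
                 contour = p),
            class = "pill_mesh")
}

# Intersections of the line point + t * dir with a closed polygon; returns
# the crossings with smallest |t| on each side of the point.
line_polygon_crossings <- function(point, dir, poly) {
  n <- nrow(poly)
  a <- poly; b <- poly[c(2:n, 1L), ]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  # solve point + t*dir = a + u*e for each edge
  det <- dir[1] * (-ey) - dir[2] * (-ex)
  ok <- abs(det) > 1e-12
  rx <- a[, 1] - point[1]; ry <- a[, 2] - point[2]
  t <- (rx * (-ey) - ry * (-ex)) / det
  u <- (dir[1] * ry - dir[2] * rx) / det
  hit <- ok & u >= 0 & u < 1
  tt <- t[hit]
  if (!length(tt)) return(NULL)
  neg <- tt[tt < 0]; pos <- tt[tt >= 0]
  if (!length(neg) || !length(pos)) return(NULL)
  tn <- max(neg); tp <- min(pos)
  list(neg = point + tn * dir, pos = point + tp * dir,
       neg_t = tn, pos_t = tp)
}

#' Measure length, width, radius and volume from a pill mesh
#'
#' Length is the total midline arclength; width is the mean rib width over
#' the central 60% of arclength (the hemispherical caps would bias the
#' mean low); volume is the spherocylinder formula.
#'
#' @param mesh A [build_pillmesh()] result.
#' @return List of class `shape_measure`: `length`, `width`, `radius`,
#'   `volume` (um, um, um, um^3), `orientation` (radians, pole-to-pole,
#'   in `[0, pi)`), `centroid` (um).
#' @export
measure_shape <- function(mesh) {
  stopifnot(inherits(mesh, "pill_mesh"))
  L <- mesh$s[length(mesh$s)]
  central <- which(mesh$s >= 0.2 * L & mesh$s <= 0.8 * L & !is.na(mesh$width))
  if (length(central) < 3)
    stop("fewer than 3 valid ribs in the central 60% of arclength",
         call. = FALSE)
  W <- mean(mesh$width[central])
  v <- mesh$midline[nrow(mesh$midline), ] - mesh$midline[1L, ]
  ang <- atan2(v[2], v[1]) %% pi
  structure(list(length = L, width = W, radius = W / 2,
                 volume = spherocylinder_volume(max(L, W), W),
                 orientation = ang,
                 centroid = colMeans(mesh$contour)),
            class = "shape_measure")
}
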