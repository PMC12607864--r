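# FtsZ-ring quantification: axial fluorescence profiles along the pill
# mesh, peak calling and scoring, ring spacing, rings-per-length slopes,
# volume-normalized cell fluorescence, and kymographs.
#
# A ring's intensity score follows the (max - min) x width convention:
# the difference between the peak maximum and the mean of its two
# flanking minima, times the full width at half prominence, on the
# background-subtracted profile.

#' Estimate the image background from pixels outside all cells
#'
#' Cell masks are dilated (default 3 px) to exclude the halo around each
#' cell; the background is the median of the remaining pixels, robust to
#' residual bright structures.
#'
#' @param image Numeric matrix (fluorescence channel).
#' @param contours List of cell contours (um coordinates) for the frame;
#'   may be empty.
#' @param pixel_size Pixel size (um/px).
#' @param dilate_px Dilation radius applied to the cell masks (pixels).
#' @return Background level (counts).
#' @export
estimate_background <- function(image, contours, pixel_size, dilate_px = 3L) {
  stopifnot(is.matrix(image))
  if (length(contours) == 0) return(stats::median(image))
  mask <- matrix(FALSE, nrow(image), ncol(image))
  for (ct in contours) {
    p <- unclass(ct)
    rr <- range(p[, 2] / pixel_size + 0.5); cc <- range(p[, 1] / pixel_size + 0.5)
    rs <- max(1L, floor(rr[1])):min(nrow(image), ceiling(rr[2]))
    cs <- max(1L, floor(cc[1])):min(ncol(image), ceiling(cc[2]))
    g <- expand.grid(r = rs, c = cs)
    inside <- points_in_polygon(p, cbind((g$c - 0.5) * pixel_size,
                                         (g$r - 0.5) * pixel_size))
    mask[cbind(g$r, g$c)[inside, , drop = FALSE]] <- TRUE
  }
  if (dilate_px > 0)
    mask <- EBImage::dilate(mask * 1,
                            EBImage::makeBrush(2L * dilate_px + 1L, "disc")) > 0
  outside <- !mask
  if (!any(outside)) stop("no pixels outside the dilated cell masks", call. = FALSE)
  stats::median(image[outside])
}

#' Axial fluorescence profile along a cell's midline
#'
#' One value per mesh rib: the mean of bilinearly interpolated image
#' samples along the rib between its two boundary crossings (sampled
#' slightly inside the contour), minus the background.  Positions are the
#' rib arclengths.
#'
#' @param mesh A [build_pillmesh()] result.
#' @param image Fluorescence image matrix.
#' @param background Background level to subtract (counts); see
#'   [estimate_background()].
#' @param pixel_size Pixel size (um/px).
#' @param n_samples Interpolation samples per rib.
#' @return Object of class `axial_profile`: data frame `s` (um), `value`
#'   (background-subtracted counts); attributes `background`, `length`
#'   (midline length), `endpoints` (2 x 2 matrix of pole coordinates).
#' @export
axial_profile <- function(mesh, image, background, pixel_size, n_samples = 7L) {
  stopifnot(inherits(mesh, "pill_mesh"), is.matrix(image))
  ok <- which(!is.na(mesh$width))
  xmax <- ncol(image) * pixel_size; ymax <- nrow(image) * pixel_size
  if (any(mesh$contour[, 1] < 0 | mesh$contour[, 1] > xmax |
          mesh$contour[, 2] < 0 | mesh$contour[, 2] > ymax))
    stop("mesh extends outside the image", call. = FALSE)
  tfr <- seq(0.1, 0.9, length.out = n_samples)  # stay inside the boundary
  vals <- vapply(ok, function(k) {
    l <- mesh$ribs$left[k, ]; r <- mesh$ribs$right[k, ]
    xs <- l[1] + tfr * (r[1] - l[1])
    ys <- l[2] + tfr * (r[2] - l[2])
    mean(interp_bilinear(image, xs, ys, pixel_size))
  }, numeric(1))
  out <- data.frame(s = mesh$s[ok], value = vals - background)
  attr(out, "background") <- background
  attr(out, "length") <- mesh$s[length(mesh$s)]
  attr(out, "endpoints") <- rbind(mesh$midline[1L, ],
                                  mesh$midline[nrow(mesh$midline), ])
  class(out) <- c("axial_profile", "data.frame")
  out
}

# Prominence of a local maximum at index i: height above the higher of
# the two minima separating it from higher terrain (or the profile ends).
peak_prominence <- function(v, i) {
  n <- length(v)
  left_min <- v[i]; j <- i
  while (j > 1L && v[j - 1L] <= v[i]) { j <- j - 1L; left_min <- min(left_min, v[j]) }
  if (j == 1L) left_min <- min(v[1:i])
  right_min <- v[i]; j <- i
  while (j < n && v[j + 1L] <= v[i]) { j <- j + 1L; right_min <- min(right_min, v[j]) }
  if (j == n) right_min <- min(v[i:n])
  v[i] - max(left_min, right_min)
}

#' Detect and score rings on an axial profile
#'
#' Local maxima with prominence above `max(prominence_frac * profile
#' maximum, noise_mult * noise SD)` (noise SD from the median absolute
#' successive difference), at least `min_separation` apart, and more than
#' `pole_margin` from either pole.  Per ring: the flanking minima are
#' located between adjacent peaks (or the pole margins), `min` is their
#' mean, the width is the full width at half prominence, and the score is
#' `(max - min) * width`.
#'
#' @param profile An [axial_profile()].
#' @param prominence_frac Fraction of the profile maximum used as the
#'   prominence threshold.
#' @param noise_mult Noise-floor multiplier.
#' @param min_separation Minimum inter-peak distance (um).
#' @param pole_margin Exclusion zone at each pole (um).
#' @param smooth_um Half-ring-scale moving-average smoothing applied to
#'   the profile before peak scanning (um); 0 disables.
#' @return Data frame of class `ring_calls`: `s`, `max`, `min`, `width`,
#'   `score`, `prominence`.  May have zero rows.
#' @export
detect_rings <- function(profile, prominence_frac = 0.2, noise_mult = 2,
                         min_separation = 0.5, pole_margin = 0.3,
                         smooth_um = 0.15) {
  stopifnot(inherits(profile, "axial_profile"))
  s <- profile$s; v <- profile$value
  n <- length(v)
  if (smooth_um > 0 && n > 3L) {
    ds <- stats::median(diff(s))
    w <- 2L * as.integer(ceiling(smooth_um / ds / 2)) + 1L
    if (w >= 3L) v <- moving_average(v, w)
  }
  empty <- data.frame(s = numeric(), max = numeric(), min = numeric(),
                      width = numeric(), score = numeric(),
                      prominence = numeric())
  class(empty) <- c("ring_calls", "data.frame")
  if (n < 5L) return(empty)
  L <- attr(profile, "length")
  noise_sd <- stats::mad(diff(v)) / sqrt(2)
  # all terrain analysis is restricted to the pole-margin window: the
  # hemispherical caps depress the profile and would distort prominences
  win <- which(s >= pole_margin & s <= L - pole_margin)
  if (length(win) < 5L) return(empty)
  s <- s[win]; v <- v[win]
  n <- length(v)
  lo <- 1L; hi <- n
  thr <- max(prominence_frac * max(v), noise_mult * noise_sd)
  cand <- which(diff(sign(diff(v))) < 0) + 1L
  if (!length(cand)) return(empty)
  prom <- vapply(cand, function(i) peak_prominence(v, i), numeric(1))
  keep <- prom >= thr
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty)
  # enforce minimum separation, keeping the taller peak
  ord <- order(v[cand], decreasing = TRUE)
  sel <- integer(0)
  for (k in ord)
    if (!length(sel) || all(abs(s[cand[k]] - s[cand[sel]]) >= min_separation))
      sel <- c(sel, k)
  cand <- cand[sort(sel)]; prom <- prom[sort(sel)]
  ords <- order(s[cand]); cand <- cand[ords]; prom <- prom[ords]

  # flanking minima between adjacent peaks / pole margins
  m <- length(cand)
  rows <- lapply(seq_len(m), function(q) {
    i <- cand[q]
    il <- if (q == 1L) lo else cand[q - 1L]
    ir <- if (q == m) hi else cand[q + 1L]
    vmin_l <- min(v[il:i]); vmin_r <- min(v[i:ir])
    vmin <- (vmin_l + vmin_r) / 2
    half <- v[i] - prom[q] / 2
    # full width at half prominence, linear interpolation of crossings
    jl <- i
    while (jl > il && v[jl - 1L] >= half) jl <- jl - 1L
    sl <- if (jl == i) s[i]
          else if (v[jl - 1L] < half && jl > 1L)
            s[jl - 1L] + (half - v[jl - 1L]) / (v[jl] - v[jl - 1L]) * (s[jl] - s[jl - 1L])
          else s[jl]
    jr <- i
    while (jr < ir && v[jr + 1L] >= half) jr <- jr + 1L
    sr <- if (jr == i) s[i]
          else if (jr < n && v[jr + 1L] < half)
            s[jr] + (v[jr] - half) / (v[jr] - v[jr + 1L]) * (s[jr + 1L] - s[jr])
          else s[jr]
    w <- sr - sl
    # parabolic sub-sample refinement of the peak position
    s_hat <- s[i]
    if (i > 1L && i < n) {
      den <- v[i - 1L] - 2 * v[i] + v[i + 1L]
      if (den < 0) {
        delta <- 0.5 * (v[i - 1L] - v[i + 1L]) / den
        if (abs(delta) <= 1)
          s_hat <- s[i] + delta * (s[min(i + 1L, n)] - s[max(i - 1L, 1L)]) / 2
      }
    }
    c(s = s_hat, max = v[i], min = vmin, width = w,
      score = (v[i] - vmin) * w, prominence = prom[q])
  })
  out <- as.data.frame(do.call(rbind, rows))
  class(out) <- c("ring_calls", "data.frame")
  out
}

#' Distances between adjacent rings of one cell
#'
#' @param calls A `ring_calls` data frame (or anything with column `s`).
#' @return Numeric vector of successive differences of the sorted
#'   positions (um); empty for fewer than two rings.
#' @export
ring_spacings <- function(calls) {
  if (is.null(calls) || nrow(calls) < 2L) return(numeric(0))
  diff(sort(calls$s))
}

#' Summed-cell-length vs ring-count slope across fields of view
#'
#' Least-squares slope of the summed cell length in a field (response) on
#' the total ring count (predictor), through the origin by default (a
#' field with no cells has neither length nor rings).  The slope is the
#' mean length per ring; its reciprocal is the ring density.
#'
#' @param fields Data frame with one row per field: `length` (summed cell
#'   length, um) and `n_rings` (total ring count).
#' @param through_origin Fit without intercept (default TRUE).
#' @return List: `slope` (um per ring), `rings_per_um`, `intercept`
#'   (0 for through-origin), `n_fields`.
#' @export
rings_per_length <- function(fields, through_origin = TRUE) {
  stopifnot(is.data.frame(fields), all(c("length", "n_rings") %in% names(fields)))
  if (nrow(fields) < 3L) stop("need >= 3 fields", call. = FALSE)
  if (all(fields$n_rings == 0)) stop("all fields have zero rings", call. = FALSE)
  if (through_origin) {
    slope <- sum(fields$length * fields$n_rings) / sum(fields$n_rings^2)
    intercept <- 0
  } else {
    fit <- stats::lm(length ~ n_rings, data = fields)
    slope <- unname(stats::coef(fit)[2L]); intercept <- unname(stats::coef(fit)[1L])
  }
  list(slope = slope, rings_per_um = 1 / slope, intercept = intercept,
       n_fields = nrow(fields))
}

#' Total and volume-normalized cell fluorescence
#'
#' Sums the pixels whose centers fall inside the contour, subtracts the
#' background times the pixel count, and normalizes by the cell volume.
#'
#' @param contour Cell contour (um coordinates).
#' @param image Fluorescence image matrix.
#' @param background Background level (counts/pixel).
#' @param volume Cell volume (um^3), positive.
#' @param pixel_size Pixel size (um/px).
#' @return List of class `cell_fluor`: `total` (background-subtracted
#'   counts), `normalized` (counts/um^3), `n_pixels`.
#' @export
cell_intensity <- function(contour, image, background, volume, pixel_size) {
  stopifnot(is.matrix(image))
  if (!is.numeric(volume) || volume <= 0)
    stop("volume must be positive", call. = FALSE)
  p <- unclass(contour)
  rr <- range(p[, 2] / pixel_size + 0.5); cc <- range(p[, 1] / pixel_size + 0.5)
  rs <- max(1L, floor(rr[1])):min(nrow(image), ceiling(rr[2]))
  cs <- max(1L, floor(cc[1])):min(ncol(image), ceiling(cc[2]))
  g <- expand.grid(r = rs, c = cs)
  inside <- points_in_polygon(p, cbind((g$c - 0.5) * pixel_size,
                                       (g$r - 0.5) * pixel_size))
  px <- cbind(g$r, g$c)[inside, , drop = FALSE]
  total <- sum(image[px]) - background * nrow(px)
  structure(list(total = total, normalized = total / volume,
                 n_pixels = nrow(px)),
            class = "cell_fluor")
}

#' Kymograph: axial profiles stacked over frames at normalized arclength
#'
#' Each frame's profile is resampled to a fixed number of bins of
#' normalized arclength (0 = one pole, 1 = the other).  Pole identity is
#' kept consistent across frames by endpoint proximity: if a profile's
#' first pole lies closer to the previous frame's last pole, the profile
#' is flipped.
#'
#' @param profiles List of [axial_profile()] objects (>= 2), one per
#'   frame, in temporal order.
#' @param n_bins Number of normalized-arclength bins.
#' @return Numeric matrix (frames x bins) of class `kymograph`.
#' @export
kymograph <- function(profiles, n_bins = 100L) {
  if (length(profiles) < 2L)
    stop("need profiles from >= 2 frames", call. = FALSE)
  prev_ends <- NULL
  rows <- lapply(profiles, function(pr) {
    stopifnot(inherits(pr, "axial_profile"))
    ends <- attr(pr, "endpoints")
    s <- pr$s; v <- pr$value; L <- attr(pr, "length")
    if (!is.null(prev_ends)) {
      same <- sum((ends[1L, ] - prev_ends[1L, ])^2) +
        sum((ends[2L, ] - prev_ends[2L, ])^2)
      flip <- sum((ends[1L, ] - prev_ends[2L, ])^2) +
        sum((ends[2L, ] - prev_ends[1L, ])^2)
      if (flip < same) {
        s <- L - rev(s); v <- rev(v)
        ends <- ends[2:1, ]
      }
    }
    prev_ends <<- ends
    u <- seq(0, 1, length.out = n_bins)
    stats::approx(s / L, v, xout = u, rule = 2)$y
  })
  out <- do.call(rbind, rows)
  class(out) <- c("kymograph", class(out))
  out
}
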