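# Rasterization of simulated cells into phase-contrast-like and
# fluorescence images.
#
# Cells are capsules (all points within W/2 of the centerline segment).
# Subpixel geometry is handled by 4x area supersampling; the optical PSF
# is an isotropic Gaussian applied after downsampling; noise order is
# Poisson on signal (optional), additive Gaussian read noise, clipping to
# the bit depth.

#' Imaging specification
#'
#' @param height,width Image size (pixels).
#' @param pixel_size Pixel size (um/px); default 0.065.
#' @param psf_sigma Gaussian PSF sigma (um); ~diffraction scale by default.
#' @param background_level Background intensity (counts).
#' @param read_noise_sd SD of additive Gaussian read noise (counts).
#' @param poisson_noise Apply Poisson noise to the signal before read noise.
#' @param bit_depth Output bit depth; values clipped to `[0, 2^bit_depth - 1]`.
#' @return Object of class `image_spec`.
#' @export
image_spec <- function(height, width, pixel_size = 0.065, psf_sigma = 0.1,
                       background_level = 500, read_noise_sd = 0,
                       poisson_noise = FALSE, bit_depth = 16L) {
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  check_scalar(psf_sigma, "psf_sigma", nonneg = TRUE)
  check_scalar(background_level, "background_level", nonneg = TRUE)
  check_scalar(read_noise_sd, "read_noise_sd", nonneg = TRUE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 pixel_size = pixel_size, psf_sigma = psf_sigma,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 poisson_noise = isTRUE(poisson_noise),
                 bit_depth = as.integer(bit_depth)),
            class = "image_spec")
}

#' Scene: cell geometry and optical parameters for one frame
#'
#' @param cells Data frame with one row per cell: `x`, `y` (centroid, um),
#'   `theta` (orientation, radians CCW from +x), `length`, `width` (um),
#'   and optionally `id`.
#' @param rings Optional data frame of ring positions: `id` (matching
#'   `cells$id`) and `s` (um along the midline from the pole at the
#'   `theta + pi` end).
#' @param cytoplasm_density Uniform cytoplasmic fluorescence surface
#'   density (counts/um^2).
#' @param ring_amplitude Peak ring surface density added on top of the
#'   cytoplasm (counts/um^2).
#' @param ring_axial_sigma Axial Gaussian sigma of a ring (um).
#' @param interior_fraction Phase-contrast interior intensity as a
#'   fraction of background.
#' @param check_overlap Error if any two capsules overlap.
#' @return Object of class `cell_scene`.
#' @export
make_scene <- function(cells, rings = NULL, cytoplasm_density = 2000,
                       ring_amplitude = 4000, ring_axial_sigma = 0.15,
                       interior_fraction = 0.35, check_overlap = TRUE) {
  cells <- as.data.frame(cells)
  stopifnot(all(c("x", "y", "theta", "length", "width") %in% names(cells)))
  if (is.null(cells$id)) cells$id <- seq_len(nrow(cells))
  if (any(cells$length < cells$width))
    stop("scene cells must have length >= width", call. = FALSE)
  if (check_overlap && nrow(cells) > 1L) {
    ep <- capsule_endpoints(cells)
    for (i in seq_len(nrow(cells) - 1L)) for (j in (i + 1L):nrow(cells)) {
      dmin <- segment_distance(ep$p1[i, ], ep$p2[i, ], ep$p1[j, ], ep$p2[j, ])
      if (dmin < (cells$width[i] + cells$width[j]) / 2)
        stop(sprintf("cells %s and %s overlap", cells$id[i], cells$id[j]),
             call. = FALSE)
    }
  }
  structure(list(cells = cells, rings = rings,
                 cytoplasm_density = cytoplasm_density,
                 ring_amplitude = ring_amplitude,
                 ring_axial_sigma = ring_axial_sigma,
                 interior_fraction = interior_fraction),
            class = "cell_scene")
}

# Endpoints of each capsule's centerline segment
capsule_endpoints <- function(cells) {
  a <- (cells$length - cells$width) / 2
  dx <- cos(cells$theta); dy <- sin(cells$theta)
  list(p1 = cbind(cells$x - a * dx, cells$y - a * dy),
       p2 = cbind(cells$x + a * dx, cells$y + a * dy))
}

# Rasterize per-cell quantities on the 4x supersampled grid and return the
# pixel-resolution matrix.  `fun(cell_row, rings_s, xs, ys)` returns the
# subpixel surface values for points (xs, ys).
rasterize_scene <- function(scene, spec, fun) {
  ss <- 4L
  H <- spec$height; W <- spec$width
  px <- spec$pixel_size
  fine <- matrix(0, H * ss, W * ss)
  fpx <- px / ss
  cells <- scene$cells
  ep <- capsule_endpoints(cells)
  for (i in seq_len(nrow(cells))) {
    rad <- cells$width[i] / 2
    margin <- rad + 2 * fpx
    xlim <- range(ep$p1[i, 1], ep$p2[i, 1]) + c(-margin, margin)
    ylim <- range(ep$p1[i, 2], ep$p2[i, 2]) + c(-margin, margin)
    cr <- max(1L, floor(ylim[1] / fpx)):min(H * ss, ceiling(ylim[2] / fpx))
    cc <- max(1L, floor(xlim[1] / fpx)):min(W * ss, ceiling(xlim[2] / fpx))
    if (!length(cr) || !length(cc)) next
    ys <- (cr - 0.5) * fpx
    xs <- (cc - 0.5) * fpx
    g <- expand.grid(y = ys, x = xs)
    rs <- if (!is.null(scene$rings)) scene$rings$s[scene$rings$id == cells$id[i]]
          else numeric(0)
    vals <- fun(cells[i, ], rs, g$x, g$y, ep$p1[i, ], ep$p2[i, ])
    fine[cr, cc] <- fine[cr, cc] + matrix(vals, length(cr), length(cc))
  }
  # block-average the supersampled grid down to pixel resolution
  ridx <- rep(seq_len(H), each = ss)
  cidx <- rep(seq_len(W), each = ss)
  m <- rowsum(fine, ridx)
  m <- t(rowsum(t(m), cidx)) / ss^2
  m
}

apply_psf_noise <- function(img, spec, seed, signal_only_background = NULL) {
  if (spec$psf_sigma > 0) {
    sig_px <- spec$psf_sigma / spec$pixel_size
    img <- EBImage::gblur(img, sigma = sig_px)
  }
  with_seed(seed, {
    if (spec$poisson_noise)
      img <- matrix(stats::rpois(length(img), pmax(img, 0)),
                    nrow(img), ncol(img))
    if (spec$read_noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, spec$read_noise_sd)
    img
  })
  }

finalize_image <- function(img, spec) {
  maxv <- 2^spec$bit_depth - 1
  img <- pmin(pmax(img, 0), maxv)
  img
}

#' Render a phase-contrast-like image of a scene
#'
#' Dark capsule silhouettes on a bright background: interior intensity is
#' `interior_fraction * background_level`, area-sampled at 4x
#' supersampling, blurred with the PSF, noise added, clipped.
#'
#' @param scene A [make_scene()].
#' @param spec An [image_spec()].
#' @param seed Optional RNG seed for the noise.
#' @return Numeric matrix `height x width` (counts).
#' @export
render_phase <- function(scene, spec, seed = NULL) {
  stopifnot(inherits(scene, "cell_scene"), inherits(spec, "image_spec"))
  cover <- rasterize_scene(scene, spec, function(cell, rs, xs, ys, p1, p2) {
    d <- dist_to_segment(xs, ys, p1[1], p1[2], p2[1], p2[2])
    as.numeric(d <= cell$width / 2)
  })
  cover <- pmin(cover, 1)
  img <- spec$background_level * (1 - (1 - scene$interior_fraction) * cover)
  img <- apply_psf_noise(img, spec, seed)
  finalize_image(img, spec)
}

#' Render a fluorescence image of a scene
#'
#' Each cell contributes a uniform cytoplasmic surface density over its
#' capsule footprint plus, per ring, a transverse band with Gaussian axial
#' profile centered at the ring's midline arclength.  Pixel counts are
#' surface density times pixel area; PSF and noise as in [render_phase()].
#'
#' @inheritParams render_phase
#' @return Numeric matrix `height x width` (counts), background at
#'   `background_level`.
#' @export
render_fluor <- function(scene, spec, seed = NULL) {
  stopifnot(inherits(scene, "cell_scene"), inherits(spec, "image_spec"))
  dens <- rasterize_scene(scene, spec, function(cell, rs, xs, ys, p1, p2) {
    d <- dist_to_segment(xs, ys, p1[1], p1[2], p2[1], p2[2])
    inside <- d <= cell$width / 2
    v <- scene$cytoplasm_density * as.numeric(inside)
    if (length(rs)) {
      ax <- c(p2[1] - p1[1], p2[2] - p1[2])
      na <- sqrt(sum(ax^2))
      u <- if (na > 0) ((xs - p1[1]) * ax[1] + (ys - p1[2]) * ax[2]) / na
           else rep(0, length(xs))
      s_pt <- u + cell$width / 2  # arclength from the pole
      band <- rowSums(vapply(rs, function(s0)
        exp(-(s_pt - s0)^2 / (2 * scene$ring_axial_sigma^2)),
        numeric(length(s_pt))))
      v <- v + scene$ring_amplitude * band * as.numeric(inside)
    }
    v
  })
  img <- spec$background_level + dens * spec$pixel_size^2
  img <- apply_psf_noise(img, spec, seed)
  finalize_image(img, spec)
}

#' Analytic integrated fluorescence flux of a scene (counts above background)
#'
#' Closed-form integral of the scene's surface-density model: cytoplasm
#' density times capsule area plus, per ring, the Gaussian band integral
#' `amplitude * sqrt(2 pi) * sigma * chord(s)` evaluated by numeric
#' quadrature of the capsule chord.  Used to verify flux conservation of
#' the renderer.
#'
#' @param scene A [make_scene()].
#' @return Total expected background-subtracted counts.
#' @export
scene_flux <- function(scene) {
  stopifnot(inherits(scene, "cell_scene"))
  total <- 0
  for (i in seq_len(nrow(scene$cells))) {
    cell <- scene$cells[i, ]
    Wd <- cell$width; L <- cell$length
    area <- (L - Wd) * Wd + pi * (Wd / 2)^2
    total <- total + scene$cytoplasm_density * area
    rs <- if (!is.null(scene$rings)) scene$rings$s[scene$rings$id == cell$id]
          else numeric(0)
    if (length(rs)) {
      chord <- function(s) {  # capsule footprint chord at arclength s
        r <- Wd / 2
        ifelse(s < r, 2 * sqrt(pmax(r^2 - (r - s)^2, 0)),
               ifelse(s > L - r, 2 * sqrt(pmax(r^2 - (s - (L - r))^2, 0)), Wd))
      }
      for (s0 in rs) {
        f <- stats::integrate(function(s)
          exp(-(s - s0)^2 / (2 * scene$ring_axial_sigma^2)) * chord(s),
          lower = 0, upper = L)$value
        total <- total + scene$ring_amplitude * f
      }
    }
  }
  total
}
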