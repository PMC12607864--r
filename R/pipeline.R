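# End-to-end orchestration: lay out simulated cells into scenes, render
# movies, segment and measure every frame, track, and compute cycle
# statistics — the full simulate -> render -> segment -> measure ->
# track -> cycles loop with known ground truth.
#
# Simulated populations are laid out as a one-dimensional colony chain:
# cells sit end to end along a common axis (as in dense agarose-pad
# microcolonies), daughters occupy their mother's two halves, and the
# chain re-spreads around its center as it elongates.  This keeps
# frame-to-frame displacements small so overlap-based tracking applies.

# Depth-first pre-order of the lineage forest; filtering the full order
# by the cells alive in a frame keeps daughters adjacent and in their
# mother's chain position.
lineage_order <- function(track) {
  info <- unique(track[, c("cell_id", "parent_id")])
  kids <- split(info$cell_id, info$parent_id)
  roots <- sort(info$cell_id[is.na(info$parent_id)])
  out <- integer(0)
  visit <- function(id) {
    out[[length(out) + 1L]] <<- id
    for (k in sort(kids[[as.character(id)]])) visit(k)
  }
  for (r in roots) visit(r)
  unlist(out)
}

#' Scene for one frame of a simulated track, chain layout
#'
#' @param track Track from [simulate_lineages()] (optionally with rings
#'   from [place_rings()]).
#' @param time Frame time (minutes) present in the track.
#' @param gap Gap between adjacent cells along the chain (um).
#' @param theta Chain orientation (radians).
#' @param origin Chain center (um, length-2 vector).
#' @param order Full lineage order from `lineage_order(track)`; computed
#'   if missing.
#' @param ... Passed to [make_scene()] (optical parameters).
#' @return A `cell_scene` for the frame.
#' @export
chain_scene <- function(track, time, gap = 0.4, theta = 0,
                        origin = c(0, 0), order = NULL, ...) {
  fr <- track[abs(track$time - time) < 1e-9, ]
  if (!nrow(fr)) stop("no cells at the requested time", call. = FALSE)
  if (is.null(order)) order <- lineage_order(track)
  fr <- fr[match(order[order %in% fr$cell_id], fr$cell_id), ]
  total <- sum(fr$length) + gap * (nrow(fr) - 1L)
  ends <- cumsum(fr$length + gap) - gap
  centers <- ends - fr$length / 2 - total / 2
  dx <- cos(theta); dy <- sin(theta)
  cells <- data.frame(id = fr$cell_id,
                      x = origin[1] + centers * dx,
                      y = origin[2] + centers * dy,
                      theta = theta, length = fr$length, width = fr$width)
  rings <- NULL
  if (!is.null(fr$rings)) {
    rl <- lapply(seq_len(nrow(fr)), function(i) {
      s <- fr$rings[[i]]
      if (length(s)) data.frame(id = fr$cell_id[i], s = s) else NULL
    })
    rl <- rl[!vapply(rl, is.null, logical(1))]
    if (length(rl)) rings <- do.call(rbind, rl)
  }
  make_scene(cells, rings = rings, ...)
}

#' Simulate, render, segment, measure and track one microcolony movie
#'
#' Runs the full pipeline on a single simulated chain colony and returns
#' every intermediate product.  Phase images only; fluorescence is
#' exercised separately by the ring pipeline.
#'
#' @param config A [sim_config()].
#' @param gap Inter-cell gap in the chain layout (um).
#' @param pixel_size,psf_sigma,background_level,read_noise_sd Imaging
#'   parameters (see [image_spec()]).
#' @param margin Clear margin around the final chain (um).
#' @param seed RNG seed for rendering noise (the simulation uses
#'   `config$seed`).
#' @return List: `truth` (simulated track), `cycles_true`, `frames`
#'   (contours per frame), `measures` (per frame/idx shape table),
#'   `tracking`, `cycles` (measured cycle records), `spec`.
#' @export
run_chain_experiment <- function(config, gap = 0.4, pixel_size = 0.065,
                                 psf_sigma = 0.1, background_level = 500,
                                 read_noise_sd = 8, margin = 2,
                                 seed = config$seed + 1000L) {
  sim <- simulate_lineages(config)
  track <- sim$track
  ord <- lineage_order(track)
  times <- sort(unique(track$time))
  last <- track[track$time == times[length(times)], ]
  total <- sum(last$length) + gap * (nrow(last) - 1L) + 2 * margin
  height_um <- max(track$width) + 2 * margin
  spec <- image_spec(height = ceiling(height_um / pixel_size),
                     width = ceiling(total / pixel_size),
                     pixel_size = pixel_size, psf_sigma = psf_sigma,
                     background_level = background_level,
                     read_noise_sd = read_noise_sd)
  origin <- c(total / 2, height_um / 2)
  frames <- vector("list", length(times))
  meas <- vector("list", length(times))
  for (f in seq_along(times)) {
    sc <- chain_scene(track, times[f], gap = gap, theta = 0,
                      origin = origin, order = ord, check_overlap = FALSE)
    img <- render_phase(sc, spec, seed = seed + f)
    cons <- segment_frame(img, pixel_size)
    frames[[f]] <- cons
    rows <- lapply(seq_along(cons), function(i) {
      ms <- tryCatch(measure_shape(build_pillmesh(cons[[i]])),
                     error = function(e) NULL)
      if (is.null(ms)) return(NULL)
      data.frame(frame = f, idx = i, time = times[f], length = ms$length,
                 width = ms$width, volume = ms$volume,
                 orientation = ms$orientation,
                 centroid_x = ms$centroid[1], centroid_y = ms$centroid[2])
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    meas[[f]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  measures <- do.call(rbind, meas[!vapply(meas, is.null, logical(1))])
  tracking <- track_cells(frames, times, dims = c(spec$height, spec$width),
                          pixel_size = pixel_size)
  cycles <- cycle_stats(tracking, measures)
  list(truth = track, cycles_true = sim$cycles, frames = frames,
       measures = measures, tracking = tracking, cycles = cycles,
       spec = spec)
}

#' Lay out division-inhibited filaments in a field and render both channels
#'
#' Simulates the filament scenario, takes the cells at the final frame,
#' arranges them in horizontal rows, places ground-truth rings every
#' `spacing` um, and renders phase and fluorescence images.
#'
#' @param config A [sim_config()] with `scenario = "filament"`.
#' @param time Frame time to take from the simulation (default: last).
#' @param row_gap Vertical gap between rows (um).
#' @param margin Border margin (um).
#' @param pixel_size,psf_sigma,background_level,read_noise_sd,poisson_noise
#'   Imaging parameters.
#' @param cytoplasm_density,ring_amplitude,ring_axial_sigma Fluorescence
#'   scene parameters (see [make_scene()]).
#' @param seed RNG seed for rendering noise.
#' @return List: `scene`, `spec`, `phase`, `fluor`, `truth` (data frame
#'   `id`, `length`, `s` of every true ring).
#' @export
filament_field <- function(config, time = NULL, row_gap = 2, margin = 2,
                           pixel_size = 0.065, psf_sigma = 0.1,
                           background_level = 300, read_noise_sd = 1,
                           poisson_noise = FALSE,
                           cytoplasm_density = 1500, ring_amplitude = 3000,
                           ring_axial_sigma = 0.15,
                           seed = config$seed + 2000L) {
  stopifnot(config$scenario == "filament")
  sim <- simulate_lineages(config)
  track <- place_rings(sim$track, mode = "filament",
                       spacing = config$ring_spacing)
  if (is.null(time)) time <- max(track$time)
  fr <- track[abs(track$time - time) < 1e-9, ]
  n <- nrow(fr)
  width_um <- max(fr$length) + 2 * margin
  height_um <- n * row_gap + 2 * margin
  cells <- data.frame(id = fr$cell_id,
                      x = width_um / 2,
                      y = margin + row_gap * (seq_len(n) - 0.5),
                      theta = 0, length = fr$length, width = fr$width)
  rings <- do.call(rbind, lapply(seq_len(n), function(i)
    if (length(fr$rings[[i]]))
      data.frame(id = fr$cell_id[i], s = fr$rings[[i]]) else NULL))
  scene <- make_scene(cells, rings = rings,
                      cytoplasm_density = cytoplasm_density,
                      ring_amplitude = ring_amplitude,
                      ring_axial_sigma = ring_axial_sigma)
  spec <- image_spec(height = ceiling(height_um / pixel_size),
                     width = ceiling(width_um / pixel_size),
                     pixel_size = pixel_size, psf_sigma = psf_sigma,
                     background_level = background_level,
                     read_noise_sd = read_noise_sd,
                     poisson_noise = poisson_noise)
  list(scene = scene, spec = spec,
       phase = render_phase(scene, spec, seed = seed),
       fluor = render_fluor(scene, spec, seed = seed + 1L),
       truth = merge(rings, data.frame(id = cells$id, length = cells$length)))
}

#' Detect rings on every cell of a rendered field
#'
#' Segments the phase channel, meshes each cell, extracts its axial
#' profile from the fluorescence channel (per-field background), and
#' calls rings.
#'
#' @param phase,fluor Phase and fluorescence image matrices.
#' @param pixel_size Pixel size (um/px).
#' @param ... Passed to [detect_rings()].
#' @return List: `cells` (per-cell list with `contour`, `mesh`,
#'   `measure`, `profile`, `calls`), `background`, `contours`.
#' @export
field_ring_calls <- function(phase, fluor, pixel_size, ...) {
  cons <- segment_frame(phase, pixel_size)
  bg <- estimate_background(fluor, cons, pixel_size)
  cells <- lapply(cons, function(ct) {
    mesh <- tryCatch(build_pillmesh(ct), error = function(e) NULL)
    if (is.null(mesh)) return(NULL)
    ms <- tryCatch(measure_shape(mesh), error = function(e) NULL)
    if (is.null(ms)) return(NULL)
    pr <- axial_profile(mesh, fluor, bg, pixel_size)
    list(contour = ct, mesh = mesh, measure = ms, profile = pr,
         calls = detect_rings(pr, ...))
  })
  cells <- cells[!vapply(cells, is.null, logical(1))]
  list(cells = cells, background = bg, contours = cons)
}

#' Write a list of image matrices as a multi-frame 16-bit TIFF stack
#'
#' @param images List of numeric matrices (counts).
#' @param path Output file path.
#' @param bit_depth Bit depth for scaling (default 16).
#' @export
save_stack <- function(images, path, bit_depth = 16L) {
  maxv <- 2^bit_depth - 1
  imgs <- lapply(images, function(m) t(m) / maxv)  # EBImage is x-major
  arr <- EBImage::Image(simplify2array(imgs))
  EBImage::writeImage(arr, path, type = "tiff", bits.per.sample = 16L)
  invisible(path)
}
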