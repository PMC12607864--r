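# Axial profiles, ring calling/scoring, spacings, cell fluorescence,
# kymographs.

# One rendered cell with a midcell ring, reused across tests
make_ring_cell <- function(theta = 0.3, L = 5, ring_s = 2.5,
                           amplitude = 6000, read_noise = 0, seed = 21) {
  cells <- data.frame(id = 1, x = 5, y = 4, theta = theta, length = L,
                      width = 1)
  rings <- if (is.null(ring_s)) NULL else data.frame(id = 1, s = ring_s)
  sc <- make_scene(cells, rings, cytoplasm_density = 1500,
                   ring_amplitude = amplitude, ring_axial_sigma = 0.15)
  spec <- image_spec(height = 124, width = 155, background_level = 300,
                     read_noise_sd = read_noise)
  list(scene = sc, spec = spec,
       phase = render_phase(sc, spec, seed = seed),
       fluor = render_fluor(sc, spec, seed = seed + 1))
}

test_that("background estimation is exact on constructed images", {
  expect_equal(estimate_background(matrix(120, 40, 40), list(), 0.065), 120)
  cc <- make_ring_cell()
  cons <- segment_frame(cc$phase, 0.065)
  bg <- estimate_background(cc$fluor, cons, 0.065)
  expect_equal(bg, 300, tolerance = 1e-6)
  bg2 <- estimate_background(cc$fluor + 55.5, cons, 0.065)
  expect_equal(bg2 - bg, 55.5)
  tiny <- matrix(1, 4, 4)
  big_ct <- capsule_contour(100, 50, center = c(0.1, 0.1))
  expect_error(estimate_background(tiny, list(big_ct), 0.065), "outside")
})

test_that("axial profile is flat for a uniform cell and peaks at the ring", {
  cc <- make_ring_cell(ring_s = NULL)
  cons <- segment_frame(cc$phase, 0.065)
  mesh <- build_pillmesh(cons[[1]])
  pr <- axial_profile(mesh, cc$fluor, 300, 0.065)
  L <- attr(pr, "length")
  mid <- pr$value[pr$s > 0.8 & pr$s < L - 0.8]
  expect_lt(stats::sd(mid) / mean(mid), 0.02)
  # with a midcell ring the profile maximum lands within 2 px of L/2
  cc2 <- make_ring_cell(ring_s = 2.5)
  cons2 <- segment_frame(cc2$phase, 0.065)
  mesh2 <- build_pillmesh(cons2[[1]])
  pr2 <- axial_profile(mesh2, cc2$fluor, 300, 0.065)
  s_max <- pr2$s[which.max(pr2$value)]
  L2 <- attr(pr2, "length")
  expect_lt(min(abs(s_max - L2 / 2)), 2 * 0.065)
  # background equal to the image zeroes the profile
  pr0 <- axial_profile(mesh, matrix(300, 124, 155), 300, 0.065)
  expect_equal(pr0$value, rep(0, nrow(pr0)))
  expect_error(axial_profile(mesh, matrix(300, 10, 10), 0, 0.065), "outside")
})

test_that("ring detection on constructed profiles follows the scoring rule", {
  # flat profile: no rings
  flat <- structure(data.frame(s = seq(0, 4, by = 0.05),
                               value = rep(5, 81)),
                    length = 4, class = c("axial_profile", "data.frame"))
  expect_equal(nrow(detect_rings(flat, smooth_um = 0)), 0)
  # single triangular peak: max - min = 50, half-prominence width 0.4
  s <- seq(0, 4, by = 0.05)
  v <- pmax(0, 50 - abs(s - 2) * 125)   # half height 25 at |s-2| = 0.2
  pr <- structure(data.frame(s = s, value = v), length = 4,
                  class = c("axial_profile", "data.frame"))
  calls <- detect_rings(pr, smooth_um = 0)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$s, 2, tolerance = 1e-9)
  expect_equal(calls$score, 50 * 0.4, tolerance = 1e-9)
})

test_that("ring score scales linearly with ring amplitude", {
  score_at <- function(amp) {
    cc <- make_ring_cell(amplitude = amp)
    cons <- segment_frame(cc$phase, 0.065)
    mesh <- build_pillmesh(cons[[1]])
    pr <- axial_profile(mesh, cc$fluor, 300, 0.065)
    calls <- detect_rings(pr)
    expect_equal(nrow(calls), 1)
    calls$score
  }
  s1 <- score_at(3000); s3 <- score_at(9000)
  expect_equal(s3 / s1, 3, tolerance = 0.02)
})

test_that("ring spacings are adjacent differences of sorted positions", {
  calls <- data.frame(s = c(5, 1, 3))
  expect_equal(ring_spacings(calls), c(2, 2))
  expect_length(ring_spacings(data.frame(s = 2)), 0)
})

test_that("rings-per-length slope matches construction and is homogeneous", {
  fields <- data.frame(length = c(40, 80, 120), n_rings = c(10, 20, 30))
  fit <- rings_per_length(fields)
  expect_equal(fit$slope, 4)
  expect_equal(fit$rings_per_um, 0.25)
  doubled <- data.frame(length = fields$length * 2,
                        n_rings = fields$n_rings * 2)
  expect_equal(rings_per_length(doubled)$slope, 4)
  expect_error(rings_per_length(fields[1:2, ]), ">= 3")
  expect_error(rings_per_length(data.frame(length = c(1, 2, 3),
                                           n_rings = c(0, 0, 0))), "zero")
})

test_that("cell fluorescence totals and volume normalization behave", {
  cc <- make_ring_cell(ring_s = NULL)
  cons <- segment_frame(cc$phase, 0.065)
  ct <- cons[[1]]
  # image equal to background everywhere: total 0
  z <- cell_intensity(ct, matrix(300, 124, 155), 300, volume = 3, pixel_size = 0.065)
  expect_equal(z$total, 0)
  # rendered cell of known integrated flux; no PSF so that the contour
  # captures the full signal (the summation convention is what is tested)
  sc <- make_scene(data.frame(id = 1, x = 5, y = 4, theta = 0.3,
                              length = 5, width = 1),
                   cytoplasm_density = 1500)
  spec_np <- image_spec(124, 155, psf_sigma = 0, background_level = 300)
  fl_np <- render_fluor(sc, spec_np)
  ci <- cell_intensity(ct, fl_np, 300, volume = 3, pixel_size = 0.065)
  expect_equal(ci$total, scene_flux(sc), tolerance = 0.02)
  ci2 <- cell_intensity(ct, fl_np, 300, volume = 6, pixel_size = 0.065)
  expect_equal(ci2$normalized, ci$normalized / 2)
  expect_error(cell_intensity(ct, cc$fluor, 300, volume = 0,
                              pixel_size = 0.065), "volume")
})

test_that("fluorescence scores are invariant to a constant background offset", {
  cc <- make_ring_cell(read_noise = 5)
  cons <- segment_frame(cc$phase, 0.065)
  mesh <- build_pillmesh(cons[[1]])
  run <- function(img) {
    bg <- estimate_background(img, cons, 0.065)
    pr <- axial_profile(mesh, img, bg, 0.065)
    ms <- measure_shape(mesh)
    list(calls = detect_rings(pr),
         fluor = cell_intensity(cons[[1]], img, bg, ms$volume, 0.065))
  }
  a <- run(cc$fluor)
  b <- run(cc$fluor + 123.4)
  expect_equal(b$calls$score, a$calls$score, tolerance = 1e-9)
  expect_equal(b$calls$s, a$calls$s, tolerance = 1e-9)
  expect_equal(b$fluor$total, a$fluor$total, tolerance = 1e-9)
})

test_that("kymographs keep pole identity and track ring multiplication", {
  # static cell, static ring: constant bright column
  cc <- make_ring_cell(ring_s = 1.5)
  cons <- segment_frame(cc$phase, 0.065)
  mesh <- build_pillmesh(cons[[1]])
  pr <- axial_profile(mesh, cc$fluor, 300, 0.065)
  ky <- kymograph(list(pr, pr, pr), n_bins = 50)
  peak_cols <- apply(ky, 1, which.max)
  expect_equal(length(unique(peak_cols)), 1)
  expect_error(kymograph(list(pr)), ">= 2")
  # growing filament with fixed spacing: number of ring columns grows
  cfg <- sim_config(scenario = "filament", elongation_rate = 1.5,
                    initial_length = 6, width_noise_cv = 0, timestep = 10,
                    duration = 40, ring_spacing = 2, seed = 5)
  n_peaks <- c()
  profs <- list()
  for (tm in c(0, 20, 40)) {
    ff <- filament_field(cfg, time = tm, ring_amplitude = 6000)
    fr <- field_ring_calls(ff$phase, ff$fluor, 0.065)
    profs[[length(profs) + 1L]] <- fr$cells[[1]]$profile
    n_peaks <- c(n_peaks, nrow(fr$cells[[1]]$calls))
  }
  expect_true(all(diff(n_peaks) >= 0) && n_peaks[3] > n_peaks[1])
  ky2 <- kymograph(profs, n_bins = 80)
  expect_equal(dim(ky2), c(3, 80))
})
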