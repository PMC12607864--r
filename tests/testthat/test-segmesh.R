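# Spherocylinder volume, segmentation, and pill-mesh measurement.

test_that("spherocylinder volume: sphere limit, cylinder increment, errors", {
  expect_equal(spherocylinder_volume(1, 1), 4 / 3 * pi * 0.5^3)
  # adding delta to L at fixed W adds exactly pi R^2 delta
  d <- 0.37
  expect_equal(spherocylinder_volume(3 + d, 1) - spherocylinder_volume(3, 1),
               pi * 0.25 * d)
  expect_error(spherocylinder_volume(0.8, 1), "round")
  expect_error(spherocylinder_volume(3, 0), "width")
  # strictly increasing in L and W over a rod-shaped grid
  Ls <- seq(1.5, 8, length.out = 6); Ws <- seq(0.8, 1.4, length.out = 4)
  for (W in Ws) expect_true(all(diff(spherocylinder_volume(Ls, W)) > 0))
  for (L in Ls) expect_true(all(diff(vapply(Ws, function(W)
    spherocylinder_volume(L, W), numeric(1))) > 0))
})

test_that("volume formula agrees with the voxelization oracle", {
  for (L in c(1.5, 3, 6)) for (W in c(0.8, 1.2)) {
    vf <- spherocylinder_volume(L, W)
    vv <- vox_capsule_volume(L, W, h = 0.01)
    expect_lt(abs(vf - vv) / vv, 1e-3)
  }
})

test_that("pill mesh recovers the geometry of an analytic capsule", {
  ct <- capsule_contour(4, 1, n = 200)
  mesh <- build_pillmesh(ct)
  L <- max(mesh$s)
  expect_equal(L, 4, tolerance = 0.01)
  # straight midline: RMS deviation from the x-axis below 0.01 um
  expect_lt(sqrt(mean(mesh$midline[, 2]^2)), 0.01)
  ms <- measure_shape(mesh)
  expect_equal(ms$width, 1, tolerance = 0.01)
  # rotation leaves L and W unchanged
  ct37 <- capsule_contour(4, 1, theta = 37 * pi / 180, center = c(5, 3))
  ms37 <- measure_shape(build_pillmesh(ct37))
  expect_equal(ms37$length / ms$length, 1, tolerance = 0.005)
  expect_equal(ms37$width / ms$width, 1, tolerance = 0.005)
  expect_equal(ms37$orientation, 37 * pi / 180, tolerance = 2 * pi / 180)
  # doubling all coordinates doubles L and W exactly (same mesh density)
  msf <- measure_shape(build_pillmesh(ct, n_ribs = 101))
  ms2 <- measure_shape(build_pillmesh(ct * 2, n_ribs = 101))
  expect_equal(ms2$length, 2 * msf$length, tolerance = 1e-9)
  expect_equal(ms2$width, 2 * msf$width, tolerance = 1e-9)
})

test_that("pill mesh follows a bent centerline", {
  Rc <- 4; span <- 1.0                       # arc length 4 um
  ct <- bent_capsule_contour(Rc, span, 1)
  mesh <- build_pillmesh(ct)
  # midline arclength ~ arc length; poles extend ~W/2 beyond each arc end
  expect_equal(max(mesh$s), Rc * span + 1, tolerance = 0.02 * (Rc * span + 1))
  ms <- measure_shape(mesh)
  expect_equal(ms$width, 1, tolerance = 0.02)
})

test_that("degenerate and malformed contours are rejected", {
  circle <- capsule_contour(1.05, 1, n = 200)  # nearly round
  expect_error(build_pillmesh(circle), "degenerate")
  bow <- cbind(c(0, 2, 0, 2), c(0, 1, 1, 0))  # self-intersecting bowtie
  expect_error(build_pillmesh(rbind(bow, bow + 1e-4, bow + 2e-4)),
               "non-simple|degenerate")
})

test_that("segmentation finds the rendered cells and only them", {
  spec <- image_spec(height = 120, width = 160, read_noise_sd = 5)
  sc <- make_scene(data.frame(x = 5.2, y = 3.9, theta = 0.6,
                              length = 4, width = 1))
  img <- render_phase(sc, spec, seed = 1)
  cons <- segment_frame(img, spec$pixel_size)
  expect_length(cons, 1)
  # empty and blank frames
  empty <- render_phase(make_scene(data.frame(x = numeric(), y = numeric(),
                                              theta = numeric(),
                                              length = numeric(),
                                              width = numeric())),
                        spec, seed = 2)
  expect_length(segment_frame(empty, spec$pixel_size), 0)
  expect_length(segment_frame(matrix(500, 50, 50), 0.065), 0)
  # border-touching cells are excluded by default, kept on request
  sc_b <- make_scene(data.frame(x = 0.5, y = 3.9, theta = 0,
                                length = 4, width = 1),
                     check_overlap = FALSE)
  img_b <- render_phase(sc_b, spec, seed = 3)
  expect_length(segment_frame(img_b, spec$pixel_size), 0)
  kept <- segment_frame(img_b, spec$pixel_size, exclude_border = FALSE)
  expect_length(kept, 1)
  expect_true(attr(kept[[1]], "touches_border"))
})

test_that("a field of twenty cells yields twenty contours", {
  set.seed(4)
  slots <- expand.grid(gx = 0:4, gy = 0:3)
  cells <- data.frame(x = 4 + slots$gx * 7, y = 4 + slots$gy * 7,
                      theta = stats::runif(20, 0, pi),
                      length = stats::runif(20, 2.5, 5),
                      width = stats::runif(20, 0.9, 1.2))
  spec <- image_spec(height = ceiling(29 / 0.065),
                     width = ceiling(36 / 0.065), read_noise_sd = 6)
  img <- render_phase(make_scene(cells), spec, seed = 5)
  cons <- segment_frame(img, spec$pixel_size)
  expect_length(cons, 20)
})

test_that("shape recovery on rendered cells meets the stated accuracy", {
  # 100 cells over 5 rendered fields, random sizes and orientations
  set.seed(6)
  rel_L <- c(); rel_W <- c()
  for (f in 1:5) {
    slots <- expand.grid(gx = 0:4, gy = 0:3)
    truth <- data.frame(x = 6 + slots$gx * 10, y = 6 + slots$gy * 10,
                        theta = stats::runif(20, 0, pi),
                        length = stats::runif(20, 2, 8),
                        width = stats::runif(20, 0.8, 1.6))
    spec <- image_spec(height = ceiling(42 / 0.065),
                       width = ceiling(52 / 0.065), read_noise_sd = 8)
    img <- render_phase(make_scene(truth), spec, seed = 100 + f)
    cons <- segment_frame(img, spec$pixel_size)
    expect_length(cons, 20)
    for (ct in cons) {
      ms <- measure_shape(build_pillmesh(ct))
      cen <- attr(ct, "centroid")
      k <- which.min((truth$x - cen[1])^2 + (truth$y - cen[2])^2)
      rel_L <- c(rel_L, abs(ms$length - truth$length[k]) / truth$length[k])
      rel_W <- c(rel_W, abs(ms$width - truth$width[k]) / truth$width[k])
    }
  }
  expect_gte(length(rel_L), 100)
  expect_lt(stats::median(rel_L), 0.03)
  expect_lt(stats::median(rel_W), 0.05)
})

test_that("measured silhouette orientation matches the scene", {
  spec <- image_spec(height = 140, width = 140, read_noise_sd = 5)
  for (th in c(0.2, 1.1, 2.6)) {
    sc <- make_scene(data.frame(x = 4.5, y = 4.5, theta = th,
                                length = 3.5, width = 1))
    img <- render_phase(sc, spec, seed = 8)
    ms <- measure_shape(build_pillmesh(segment_frame(img, spec$pixel_size)[[1]]))
    dd <- abs(ms$orientation - th %% pi)
    expect_lt(min(dd, pi - dd), 2 * pi / 180)
  }
})
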