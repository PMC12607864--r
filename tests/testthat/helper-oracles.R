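# Independent oracles used across the test suite.  These deliberately do
# not share code with the package implementation.

# Brute-force voxelization of a capsule (spherocylinder) of length L and
# width W on a cubic grid of spacing h: counts voxel centers inside the
# solid, exploiting rotational symmetry only for the lattice-disk count.
vox_capsule_volume <- function(L, W, h = 0.01) {
  R <- W / 2
  nx <- ceiling(L / h)
  u <- (seq_len(nx) - 0.5) * h            # axial voxel centers
  d_cap <- pmax(R - u, u - (L - R), 0)    # axial distance beyond cylinder
  rho2 <- R^2 - d_cap^2                   # squared radial limit
  total <- 0
  jmax <- ceiling(R / h)
  yj <- (seq_len(jmax) - 0.5) * h         # positive-half transverse centers
  for (i in seq_len(nx)) {
    if (rho2[i] <= 0) next
    t2 <- rho2[i] - yj^2
    ok <- t2 > 0
    t <- sqrt(t2[ok]) / h
    nz <- floor(t - 0.5) + floor(t + 0.5) + 1  # half-integer lattice count
    total <- total + 2 * sum(nz)
  }
  total * h^3
}

# Analytic capsule contour: length L, width W, centered at `center`,
# axis rotated by theta; n points before any resampling.
capsule_contour <- function(L, W, theta = 0, center = c(0, 0), n = 200L) {
  R <- W / 2
  a <- (L - W) / 2
  n_cap <- max(9L, round(n * (pi * R) / (2 * pi * R + 2 * (L - W)) ))
  if (n_cap %% 2L == 0L) n_cap <- n_cap + 1L  # keep the exact pole vertex
  n_side <- max(8L, (n - 2L * n_cap) %/% 2L)
  phi_r <- seq(-pi / 2, pi / 2, length.out = n_cap)
  right <- cbind(a + R * cos(phi_r), R * sin(phi_r))
  top <- cbind(seq(a, -a, length.out = n_side + 2L)[-c(1L, n_side + 2L)],
               rep(R, n_side))
  phi_l <- seq(pi / 2, 3 * pi / 2, length.out = n_cap)
  left <- cbind(-a + R * cos(phi_l), R * sin(phi_l))
  bot <- cbind(seq(-a, a, length.out = n_side + 2L)[-c(1L, n_side + 2L)],
               rep(-R, n_side))
  p <- rbind(right, top, left, bot)
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
  sweep(p %*% t(rot), 2L, center, "+")
}

# Capsule whose centerline is a circular arc of radius Rc spanning angle
# `span` (the midline arc length is Rc * span), constant half-width R.
bent_capsule_contour <- function(Rc, span, W, n = 240L) {
  R <- W / 2
  phi <- seq(-span / 2, span / 2, length.out = n %/% 2)
  outer_arc <- cbind((Rc + R) * sin(phi), Rc - (Rc + R) * cos(phi))
  inner_arc <- cbind((Rc - R) * sin(rev(phi)), Rc - (Rc - R) * cos(rev(phi)))
  # semicircular caps at the two ends, centered on the centerline ends
  cap_at <- function(phi0, sign) {
    ctr <- c(Rc * sin(phi0), Rc - Rc * cos(phi0))
    # local outward tangent direction of the centerline at phi0
    tang <- c(cos(phi0), sin(phi0)) * sign
    ang0 <- atan2(tang[2], tang[1])
    aa <- seq(ang0 - pi / 2, ang0 + pi / 2, length.out = 20L)
    cbind(ctr[1] + R * cos(aa), ctr[2] + R * sin(aa))
  }
  rbind(outer_arc, cap_at(span / 2, +1), inner_arc, cap_at(-span / 2, -1))
}

# Closed-form division interval of a noise-free adder with exponential
# elongation: time for L_b to reach L_b + dL at rate lam (per hour).
adder_tau_min <- function(L_b, dL, lam) log((L_b + dL) / L_b) / lam * 60

# Match detected ring positions against truth (both sorted, um); the mesh
# may run pole-to-pole in either direction, so the better of the two
# orientations is used.  Returns TP/FP/FN counts and matched errors.
match_rings <- function(calls_s, truth_s, L, tol = 0.5) {
  score <- function(cs) {
    used <- rep(FALSE, length(cs)); tp <- 0L; errs <- numeric(0)
    for (s in truth_s) {
      d <- abs(cs - s); d[used] <- Inf
      j <- if (length(d)) which.min(d) else integer(0)
      if (length(j) && d[j] < tol) { used[j] <- TRUE; tp <- tp + 1L
                                     errs <- c(errs, d[j]) }
    }
    list(tp = tp, fp = sum(!used), fn = length(truth_s) - tp, errs = errs)
  }
  a <- score(sort(calls_s)); b <- score(sort(L - calls_s))
  if (b$tp > a$tp || (b$tp == a$tp && sum(b$errs) < sum(a$errs))) b else a
}
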