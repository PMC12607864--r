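# Adder-based growth/division simulator for rod-shaped cells.
#
# Cells elongate exponentially, dL/dt = lambda(t) * L, and divide once the
# length added since birth reaches a per-cycle target increment (the adder
# principle).  Scenarios: steady-state growth, an envelope-stress-like ramp
# in which both the elongation rate and the adder increment fall over a
# configurable interval, and division-inhibited filamentation.

#' Simulation configuration for the adder growth model
#'
#' @param elongation_rate Exponential elongation rate lambda (per hour).
#' @param adder_increment Target length added per cell cycle (um).
#' @param adder_noise_cv CV of the per-cycle multiplicative noise on the
#'   adder increment (lognormal, mean 1).
#' @param width Mean cell width (um); each cell draws its width at birth
#'   and keeps it for life.
#' @param width_noise_cv CV of the per-cell width draw (lognormal, mean 1).
#' @param division_asymmetry_cv CV of the division fraction around 0.5
#'   (normal, clipped to `[0.3, 0.7]`).
#' @param initial_length Length of founder cells at time 0 (um).
#' @param timestep Ground-truth emission interval (minutes).
#' @param duration Total simulated time (minutes).
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#' @param scenario One of `"constant"`, `"ramp"`, `"filament"`.
#' @param rate_final,increment_final Final elongation rate / adder increment
#'   for the ramp scenario.  Defaults: a 40% linear fall.
#' @param ramp_start,ramp_duration Start time and duration of the linear
#'   ramp (minutes).
#' @param ring_spacing Inter-ring distance d (um) for the filament scenario.
#' @param n_initial Number of founder cells.
#' @param max_cells Population cap; exceeding it is an error.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(elongation_rate = 1.8,
                       adder_increment = 2,
                       adder_noise_cv = 0.1,
                       width = 1,
                       width_noise_cv = 0.03,
                       division_asymmetry_cv = 0.04,
                       initial_length = 2,
                       timestep = 2,
                       duration = 120,
                       seed = 1L,
                       scenario = c("constant", "ramp", "filament"),
                       rate_final = 0.6 * elongation_rate,
                       increment_final = 0.6 * adder_increment,
                       ramp_start = 0,
                       ramp_duration = 60,
                       ring_spacing = 2,
                       n_initial = 1L,
                       max_cells = 5000L) {
  scenario <- match.arg(scenario)
  check_scalar(elongation_rate, "elongation_rate", positive = TRUE)
  check_scalar(adder_increment, "adder_increment", positive = TRUE)
  check_scalar(width, "width", positive = TRUE)
  check_scalar(initial_length, "initial_length", positive = TRUE)
  check_scalar(timestep, "timestep", positive = TRUE)
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(adder_noise_cv, "adder_noise_cv", nonneg = TRUE)
  check_scalar(width_noise_cv, "width_noise_cv", nonneg = TRUE)
  check_scalar(division_asymmetry_cv, "division_asymmetry_cv", nonneg = TRUE)
  if (scenario == "ramp") {
    check_scalar(rate_final, "rate_final", positive = TRUE)
    check_scalar(increment_final, "increment_final", positive = TRUE)
    check_scalar(ramp_duration, "ramp_duration", positive = TRUE)
    check_scalar(ramp_start, "ramp_start", nonneg = TRUE)
  }
  if (scenario == "filament") check_scalar(ring_spacing, "ring_spacing", positive = TRUE)
  num <- as.numeric  # canonical storage type, robust to JSON round-trips
  cfg <- list(elongation_rate = num(elongation_rate),
              adder_increment = num(adder_increment),
              adder_noise_cv = num(adder_noise_cv), width = num(width),
              width_noise_cv = num(width_noise_cv),
              division_asymmetry_cv = num(division_asymmetry_cv),
              initial_length = num(initial_length), timestep = num(timestep),
              duration = num(duration), seed = as.integer(seed),
              scenario = scenario,
              rate_final = num(rate_final),
              increment_final = num(increment_final),
              ramp_start = num(ramp_start), ramp_duration = num(ramp_duration),
              ring_spacing = num(ring_spacing),
              n_initial = as.integer(n_initial),
              max_cells = as.integer(max_cells))
  class(cfg) <- "sim_config"
  cfg
}

#' Write / read a simulation configuration as JSON
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `read_sim_config` returns a validated `sim_config`;
#'   `write_sim_config` returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

# Elongation rate lambda(t) in h^-1 at time t (minutes)
lambda_at <- function(cfg, t) {
  if (cfg$scenario != "ramp") return(rep(cfg$elongation_rate, length(t)))
  f <- pmin(pmax((t - cfg$ramp_start) / cfg$ramp_duration, 0), 1)
  cfg$elongation_rate + f * (cfg$rate_final - cfg$elongation_rate)
}

# Adder target increment (um) for a cycle starting at time t (minutes)
increment_at <- function(cfg, t) {
  if (cfg$scenario != "ramp") return(rep(cfg$adder_increment, length(t)))
  f <- pmin(pmax((t - cfg$ramp_start) / cfg$ramp_duration, 0), 1)
  cfg$adder_increment + f * (cfg$increment_final - cfg$adder_increment)
}

# Integral of lambda(t)/60 dt over [t0, t1] (t in minutes, lambda per hour),
# exact for the piecewise-linear ramps used here.
lambda_integral <- function(cfg, t0, t1) {
  if (t1 <= t0) return(0)
  brk <- sort(unique(c(t0, t1,
                       if (cfg$scenario == "ramp")
                         c(cfg$ramp_start, cfg$ramp_start + cfg$ramp_duration))))
  brk <- brk[brk >= t0 & brk <= t1]
  g <- 0
  for (i in seq_len(length(brk) - 1L)) {
    a <- brk[i]; b <- brk[i + 1L]
    g <- g + (lambda_at(cfg, a) + lambda_at(cfg, b)) / 2 * (b - a) / 60
  }
  g
}

#' Simulate adder-based growth and division of a population of rod cells
#'
#' Cells elongate as `dL/dt = lambda(t) * L` and divide when the length
#' added since birth reaches `adder_increment * (1 + eps)`, with `eps`
#' drawn per cycle (lognormal, mean 1, configured CV).  Division splits
#' length at a fraction `0.5 + asymmetry noise` (clipped to `[0.3, 0.7]`).
#' The division instant inside a timestep is located by interpolating
#' `ln L` linearly (exact for exponential elongation at constant rate).
#' Ground truth is emitted at every timestep.
#'
#' @param config A [sim_config()].
#' @return A list with two data frames:
#' \describe{
#'   \item{track}{one row per cell per frame: `time` (min), `cell_id`,
#'     `parent_id` (`NA` for founders), `length`, `width` (um),
#'     `volume` (um^3), `birth_length`, `target_length` (um).}
#'   \item{cycles}{one row per completed cycle: `cell_id`, `birth_time`,
#'     `division_time`, `interval` (min), `birth_length`,
#'     `division_length`, `added_length` (um).}
#' }
#' @export
simulate_lineages <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    times <- seq(0, cfg$duration, by = cfg$timestep)
    next_id <- cfg$n_initial + 1L
    cells <- lapply(seq_len(cfg$n_initial), function(i) {
      list(id = i, parent = NA_integer_, L = cfg$initial_length,
           Lb = cfg$initial_length, t_birth = 0,
           Lth = cfg$initial_length +
             increment_at(cfg, 0) * lognormal_factor(1L, cfg$adder_noise_cv),
           W = cfg$width * lognormal_factor(1L, cfg$width_noise_cv))
    })

    track_rows <- vector("list", 4096L); nt <- 0L
    cycle_rows <- vector("list", 1024L); nc <- 0L
    push_track <- function(row) {
      nt <<- nt + 1L
      if (nt > length(track_rows)) length(track_rows) <<- 2L * nt
      track_rows[[nt]] <<- row
    }
    push_cycle <- function(row) {
      nc <<- nc + 1L
      if (nc > length(cycle_rows)) length(cycle_rows) <<- 2L * nc
      cycle_rows[[nc]] <<- row
    }
    emit <- function(cell, t) {
      push_track(c(t, cell$id, cell$parent, cell$L, cell$W, cell$Lb, cell$Lth))
    }
    for (cell in cells) emit(cell, 0)

    divide_allowed <- cfg$scenario != "filament"

    # Advance one cell from time t0 (length cell$L) to time t1, handling
    # any division events in between; returns the list of cells alive at t1.
    advance <- function(cell, t0, t1) {
      g <- lambda_integral(cfg, t0, t1)
      L1 <- cell$L * exp(g)
      if (!divide_allowed || L1 < cell$Lth) {
        cell$L <- L1
        return(list(cell))
      }
      # ln-linear interpolation of the threshold crossing inside the step
      frac <- (log(cell$Lth) - log(cell$L)) / (log(L1) - log(cell$L))
      t_div <- t0 + frac * (t1 - t0)
      tau <- t_div - cell$t_birth
      push_cycle(c(cell$id, cell$t_birth, t_div, tau,
                   cell$Lb, cell$Lth, cell$Lth - cell$Lb))
      f <- 0.5
      if (cfg$division_asymmetry_cv > 0)
        f <- min(max(stats::rnorm(1L, 0.5, 0.5 * cfg$division_asymmetry_cv), 0.3), 0.7)
      kids <- lapply(c(f, 1 - f), function(fr) {
        id <- next_id; next_id <<- next_id + 1L
        Lb <- fr * cell$Lth
        list(id = id, parent = cell$id, L = Lb, Lb = Lb, t_birth = t_div,
             Lth = Lb + increment_at(cfg, t_div) *
               lognormal_factor(1L, cfg$adder_noise_cv),
             W = cfg$width * lognormal_factor(1L, cfg$width_noise_cv))
      })
      c(advance(kids[[1L]], t_div, t1), advance(kids[[2L]], t_div, t1))
    }

    for (k in seq_len(length(times) - 1L)) {
      cells <- unlist(lapply(cells, advance, t0 = times[k], t1 = times[k + 1L]),
                      recursive = FALSE)
      if (length(cells) > cfg$max_cells)
        stop(sprintf("population cap exceeded: %d cells > max_cells = %d",
                     length(cells), cfg$max_cells), call. = FALSE)
      for (cell in cells) emit(cell, times[k + 1L])
    }

    tm <- matrix(unlist(track_rows[seq_len(nt)]), ncol = 7L, byrow = TRUE)
    track <- data.frame(time = tm[, 1], cell_id = as.integer(tm[, 2]),
                        parent_id = as.integer(tm[, 3]), length = tm[, 4],
                        width = tm[, 5],
                        volume = spherocylinder_volume(pmax(tm[, 4], tm[, 5]),
                                                       tm[, 5]),
                        birth_length = tm[, 6], target_length = tm[, 7])
    cycles <- if (nc > 0L) {
      cm <- matrix(unlist(cycle_rows[seq_len(nc)]), ncol = 7L, byrow = TRUE)
      data.frame(cell_id = as.integer(cm[, 1]), birth_time = cm[, 2],
                 division_time = cm[, 3], interval = cm[, 4],
                 birth_length = cm[, 5], division_length = cm[, 6],
                 added_length = cm[, 7])
    } else {
      data.frame(cell_id = integer(), birth_time = numeric(),
                 division_time = numeric(), interval = numeric(),
                 birth_length = numeric(), division_length = numeric(),
                 added_length = numeric())
    }
    track <- track[order(track$time, track$cell_id), ]
    rownames(track) <- NULL
    attr(track, "config") <- cfg
    list(track = track, cycles = cycles)
  })
}

#' Place FtsZ-ring ground-truth positions on a simulated track
#'
#' In `"normal"` mode each cell carries a single midcell ring once its
#' cycle progress (length added relative to its division target) exceeds
#' `fraction`.  In `"filament"` mode (division-inhibited cells) rings sit
#' at `d/2, 3d/2, ...` um from one pole, for a ground-truth density of one
#' ring per `d` um.
#'
#' @param track Track data frame from [simulate_lineages()].
#' @param mode `"normal"` or `"filament"`.
#' @param spacing Inter-ring distance d (um) for filament mode.
#' @param fraction Cell-cycle fraction from which the midcell ring is
#'   present in normal mode.
#' @return The track with an added list-column `rings` (numeric vector of
#'   positions, um along the midline from one pole).
#' @export
place_rings <- function(track, mode = c("normal", "filament"),
                        spacing = 2, fraction = 0.5) {
  mode <- match.arg(mode)
  if (mode == "filament") check_scalar(spacing, "spacing", positive = TRUE)
  rings <- vector("list", nrow(track))
  for (i in seq_len(nrow(track))) {
    L <- track$length[i]
    if (mode == "filament") {
      k <- floor(L / spacing)
      rings[[i]] <- if (k >= 1) spacing * (seq_len(k) - 0.5) else numeric(0)
    } else {
      prog <- (L - track$birth_length[i]) /
        (track$target_length[i] - track$birth_length[i])
      rings[[i]] <- if (is.finite(prog) && prog >= fraction) L / 2 else numeric(0)
    }
  }
  track$rings <- rings
  track
}

#' Simulate an optical-density growth curve with optional dilution events
#'
#' OD grows as `od0 * exp(rate * t)` with multiplicative lognormal
#' measurement noise of the stated CV.  When the (noise-free) culture OD
#' reaches `dilution_threshold` at a sampling time, the culture is diluted
#' to `dilution_target` and the event recorded, emulating serial passaging.
#'
#' @param rate Growth rate (per hour); 0 gives a constant series.
#' @param sampling_interval Sampling interval (minutes).
#' @param od0 Starting OD.
#' @param noise_cv CV of multiplicative measurement noise.
#' @param dilution_threshold,dilution_target OD at which to dilute and OD
#'   after dilution; `NULL` disables dilution.
#' @param duration Total time (minutes).
#' @param seed Optional RNG seed.
#' @return A data frame of class `od_series` with columns `time` (hours)
#'   and `od`, and attribute `dilutions` (data frame `time`, `factor`).
#' @export
simulate_od <- function(rate, sampling_interval = 7.5, od0 = 0.025,
                        noise_cv = 0, dilution_threshold = NULL,
                        dilution_target = NULL, duration = 180, seed = NULL) {
  check_scalar(rate, "rate", nonneg = TRUE)
  check_scalar(od0, "od0", positive = TRUE)
  check_scalar(noise_cv, "noise_cv", nonneg = TRUE)
  if (!is.null(dilution_threshold)) {
    check_scalar(dilution_threshold, "dilution_threshold", positive = TRUE)
    if (is.null(dilution_target)) dilution_target <- od0
    check_scalar(dilution_target, "dilution_target", positive = TRUE)
    if (dilution_threshold <= dilution_target)
      stop("dilution_threshold must exceed dilution_target", call. = FALSE)
  }
  with_seed(seed, {
    t_min <- seq(0, duration, by = sampling_interval)
    t_h <- t_min / 60
    n <- length(t_h)
    od_true <- numeric(n)
    cur <- od0
    ev_t <- numeric(0); ev_f <- numeric(0)
    for (i in seq_len(n)) {
      if (i > 1L) cur <- cur * exp(rate * (t_h[i] - t_h[i - 1L]))
      od_true[i] <- cur
      if (!is.null(dilution_threshold) && cur >= dilution_threshold) {
        ev_t <- c(ev_t, t_h[i])
        ev_f <- c(ev_f, dilution_target / cur)
        cur <- dilution_target
      }
    }
    od <- od_true * lognormal_factor(n, noise_cv)
    out <- data.frame(time = t_h, od = od)
    attr(out, "dilutions") <- data.frame(time = ev_t, factor = ev_f)
    class(out) <- c("od_series", "data.frame")
    out
  })
}
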