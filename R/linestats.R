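# Lineage tracking across frames and cell-cycle / population statistics.
#
# Tracking is overlap-based: greedy assignment by descending
# intersection-over-union (IoU) between consecutive frames, with division
# recognized when one predecessor is claimed by two successors of
# consistent summed area.  No gap closing: a cell absent from one frame
# terminates its track.

# Pixel index set of a contour on the image grid
contour_pixels <- function(contour, dims, pixel_size) {
  p <- unclass(contour)
  rr <- range(p[, 2] / pixel_size + 0.5); cc <- range(p[, 1] / pixel_size + 0.5)
  rs <- max(1L, floor(rr[1])):min(dims[1], ceiling(rr[2]))
  cs <- max(1L, floor(cc[1])):min(dims[2], ceiling(cc[2]))
  g <- expand.grid(r = rs, c = cs)
  inside <- points_in_polygon(p, cbind((g$c - 0.5) * pixel_size,
                                       (g$r - 0.5) * pixel_size))
  (g$c[inside] - 1L) * dims[1] + g$r[inside]
}

#' Track cells across frames by contour overlap
#'
#' Greedy one-to-one assignment by descending IoU (`iou_link` minimum)
#' links cells between consecutive frames; a predecessor claimed by two
#' successors, each with IoU at least `iou_division` and with summed area
#' within `area_tol` of the predecessor's, is tagged as a division.
#' Unmatched successors start new tracks; tracks end silently (no gap
#' closing).
#'
#' @param frames List (one element per frame) of lists of cell contours
#'   in shared physical um coordinates.
#' @param times Frame acquisition times (minutes), one per frame.
#' @param dims Image dimensions `c(rows, cols)` used for mask
#'   rasterization.
#' @param pixel_size Pixel size (um/px); must match the contours'.
#' @param iou_link Minimum IoU for a continuation link.
#' @param iou_division Minimum IoU of each daughter to the mother.
#' @param area_tol Relative tolerance on (daughter area sum) vs mother
#'   area.
#' @return Object of class `cell_tracking`: list with `nodes` (data frame
#'   `frame`, `idx`, `cell_id`, `parent_id`, `time`, `area`) and `edges`
#'   (data frame `frame_from`, `idx_from`, `idx_to`, `type` in
#'   `{"continuation", "division"}`).
#' @export
track_cells <- function(frames, times, dims, pixel_size,
                        iou_link = 0.3, iou_division = 0.15, area_tol = 0.3) {
  stopifnot(length(frames) >= 2L, length(times) == length(frames))
  for (f in seq_along(frames)) for (ct in frames[[f]]) {
    ps <- attr(ct, "pixel_size")
    if (!is.null(ps) && abs(ps - pixel_size) > 1e-12)
      stop("coordinate-unit mismatch: contour pixel_size differs", call. = FALSE)
  }
  pixsets <- lapply(frames, function(fr)
    lapply(fr, contour_pixels, dims = dims, pixel_size = pixel_size))
  nf <- length(frames)
  nodes <- list(); edges <- list()
  next_cell <- 1L
  ids_prev <- integer(0)
  for (f in seq_len(nf)) {
    n_here <- length(frames[[f]])
    ids_here <- rep(NA_integer_, n_here)
    parents_here <- rep(NA_integer_, n_here)
    if (f == 1L) {
      ids_here <- seq_len(n_here); next_cell <- n_here + 1L
    } else {
      np <- length(pixsets[[f - 1L]])
      if (np > 0L && n_here > 0L) {
        iou <- matrix(0, np, n_here)
        for (j in seq_len(np)) for (i in seq_len(n_here)) {
          a <- pixsets[[f - 1L]][[j]]; b <- pixsets[[f]][[i]]
          ov <- length(intersect(a, b))
          if (ov > 0) iou[j, i] <- ov / (length(a) + length(b) - ov)
        }
        succ_of <- vector("list", np)
        # pass 1: one-to-one continuation links
        cand <- which(iou >= iou_link, arr.ind = TRUE)
        if (nrow(cand)) {
          cand <- cand[order(iou[cand], decreasing = TRUE), , drop = FALSE]
          for (k in seq_len(nrow(cand))) {
            j <- cand[k, 1]; i <- cand[k, 2]
            if (is.na(ids_here[i]) && length(succ_of[[j]]) == 0L) {
              succ_of[[j]] <- i
              ids_here[i] <- ids_prev[j]
            }
          }
        }
        # pass 2: division candidates among unassigned successors
        area_prev <- vapply(pixsets[[f - 1L]], length, integer(1))
        area_here <- vapply(pixsets[[f]], length, integer(1))
        repeat {
          un <- which(is.na(ids_here))
          if (!length(un)) break
          best <- c(0, 0, 0)
          for (i in un) {
            j <- which.max(iou[, i])
            if (iou[j, i] > best[3]) best <- c(j, i, iou[j, i])
          }
          if (best[3] < iou_division) break
          j <- best[1]; i <- best[2]
          div_done <- FALSE
          if (length(succ_of[[j]]) == 1L) {
            i2 <- succ_of[[j]]
            asum <- area_here[i] + area_here[i2]
            if (abs(asum - area_prev[j]) / area_prev[j] <= area_tol &&
                iou[j, i2] >= iou_division) {
              # re-tag: predecessor divides into (i2, i)
              d1 <- next_cell; d2 <- next_cell + 1L; next_cell <- next_cell + 2L
              ids_here[i2] <- d1; parents_here[i2] <- ids_prev[j]
              ids_here[i] <- d2; parents_here[i] <- ids_prev[j]
              succ_of[[j]] <- c(i2, i)
              edges[[length(edges) + 1L]] <-
                data.frame(frame_from = f - 1L, idx_from = j,
                           idx_to = c(i2, i), type = "division")
              div_done <- TRUE
            }
          } else if (length(succ_of[[j]]) == 0L) {
            others <- un[un != i & iou[j, un] >= iou_division]
            if (length(others)) {
              i2 <- others[which.max(iou[j, others])]
              asum <- area_here[i] + area_here[i2]
              if (abs(asum - area_prev[j]) / area_prev[j] <= area_tol) {
                d1 <- next_cell; d2 <- next_cell + 1L; next_cell <- next_cell + 2L
                ids_here[i] <- d1; parents_here[i] <- ids_prev[j]
                ids_here[i2] <- d2; parents_here[i2] <- ids_prev[j]
                succ_of[[j]] <- c(i, i2)
                edges[[length(edges) + 1L]] <-
                  data.frame(frame_from = f - 1L, idx_from = j,
                             idx_to = c(i, i2), type = "division")
                div_done <- TRUE
              }
            }
          }
          if (!div_done) { iou[j, i] <- 0; next }
        }
        # record continuation edges
        for (j in seq_len(np))
          if (length(succ_of[[j]]) == 1L)
            edges[[length(edges) + 1L]] <-
              data.frame(frame_from = f - 1L, idx_from = j,
                         idx_to = succ_of[[j]], type = "continuation")
        # brand-new tracks for remaining successors
        for (i in which(is.na(ids_here))) {
          ids_here[i] <- next_cell; next_cell <- next_cell + 1L
        }
      } else {
        ids_here <- next_cell + seq_len(n_here) - 1L
        next_cell <- next_cell + n_here
      }
    }
    if (n_here > 0L)
      nodes[[length(nodes) + 1L]] <-
        data.frame(frame = f, idx = seq_len(n_here), cell_id = ids_here,
                   parent_id = parents_here, time = times[f],
                   area = vapply(pixsets[[f]], length, integer(1)) * pixel_size^2)
    ids_prev <- ids_here
  }
  nodes <- do.call(rbind, nodes)
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(frame_from = integer(), idx_from = integer(),
                           idx_to = integer(), type = character())
  structure(list(nodes = nodes, edges = edges), class = "cell_tracking")
}

#' Cell-cycle records from tracked lineages and shape measurements
#'
#' A complete cycle spans one division edge to the next along a lineage.
#' Division events are placed at the midpoint of the flanking frames; the
#' division length is the mean of the mother's last observed length and
#' the daughters' summed first lengths (the two bracket the true value
#' symmetrically at frame resolution), and each daughter's birth length
#' apportions that estimate by the daughters' first-frame length ratio.
#'
#' @param tracking A [track_cells()] result.
#' @param measures Data frame with one row per (frame, idx): columns
#'   `frame`, `idx`, `length` (um).
#' @return Data frame of class `cycle_records`: `cell_id`, `birth_time`,
#'   `division_time`, `interval` (min), `birth_length`,
#'   `division_length`, `added_length` (um), `complete`.  Incomplete
#'   cycles (birth or division unobserved) carry `NA` in the missing
#'   fields and `complete = FALSE`.
#' @export
cycle_stats <- function(tracking, measures) {
  stopifnot(inherits(tracking, "cell_tracking"))
  nd <- merge(tracking$nodes, measures[, c("frame", "idx", "length")],
              by = c("frame", "idx"), all.x = TRUE)
  nd <- nd[order(nd$cell_id, nd$frame), ]
  by_cell <- split(nd, nd$cell_id)
  cell_ids <- as.integer(names(by_cell))
  first_len <- vapply(by_cell, function(d) d$length[1L], numeric(1))
  last_len <- vapply(by_cell, function(d) d$length[nrow(d)], numeric(1))
  first_t <- vapply(by_cell, function(d) d$time[1L], numeric(1))
  last_t <- vapply(by_cell, function(d) d$time[nrow(d)], numeric(1))
  parent <- vapply(by_cell, function(d) d$parent_id[1L], integer(1))

  children <- split(cell_ids, factor(parent, levels = cell_ids))
  # division event of cell c: time and length estimate
  div_time <- rep(NA_real_, length(cell_ids))
  div_len <- rep(NA_real_, length(cell_ids))
  names(div_time) <- names(div_len) <- names(by_cell)
  for (k in seq_along(cell_ids)) {
    kids <- children[[k]]
    if (length(kids) == 2L) {
      kk <- as.character(kids)
      div_time[k] <- (last_t[k] + min(first_t[kk])) / 2
      div_len[k] <- (last_len[k] + sum(first_len[kk])) / 2
    }
  }
  rows <- lapply(seq_along(cell_ids), function(k) {
    pid <- parent[k]
    born <- !is.na(pid) && !is.na(div_time[as.character(pid)])
    if (!born) return(NULL)
    pk <- as.character(pid)
    sibs <- as.character(children[[pk]])
    frac <- first_len[as.character(cell_ids[k])] / sum(first_len[sibs])
    b_len <- frac * div_len[pk]
    b_time <- div_time[pk]
    divides <- !is.na(div_time[k])
    data.frame(cell_id = cell_ids[k], birth_time = b_time,
               division_time = if (divides) div_time[k] else NA_real_,
               interval = if (divides) div_time[k] - b_time else NA_real_,
               birth_length = b_len,
               division_length = if (divides) div_len[k] else NA_real_,
               added_length = if (divides) div_len[k] - b_len else NA_real_,
               complete = divides)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_id = integer(), birth_time = numeric(),
                      division_time = numeric(), interval = numeric(),
                      birth_length = numeric(), division_length = numeric(),
                      added_length = numeric(), complete = logical())
  class(out) <- c("cycle_records", "data.frame")
  out
}

#' Regression of division length on birth length (adder diagnostic)
#'
#' A pure adder gives slope 1 and intercept equal to the mean added
#' length; a timer (fixed fold growth) gives slope 2 through the origin.
#'
#' @param records `cycle_records` (complete cycles are used) or any data
#'   frame with `birth_length` and `division_length`.
#' @param min_records Minimum number of complete records.
#' @return List: `slope`, `intercept`, `n`, `r_squared`.
#' @export
adder_regression <- function(records, min_records = 10L) {
  d <- as.data.frame(records)
  if (!is.null(d$complete)) d <- d[d$complete, ]
  d <- d[is.finite(d$birth_length) & is.finite(d$division_length), ]
  if (nrow(d) < min_records)
    stop(sprintf("need >= %d complete records, got %d", min_records, nrow(d)),
         call. = FALSE)
  if (stats::var(d$birth_length) < 1e-12 * mean(d$birth_length)^2)
    stop("degenerate records: all birth lengths identical", call. = FALSE)
  fit <- stats::lm(division_length ~ birth_length, data = d)
  co <- stats::coef(fit)
  list(slope = unname(co[2L]), intercept = unname(co[1L]), n = nrow(d),
       r_squared = stats::cor(d$birth_length, d$division_length)^2)
}

#' Time-binned population summary of measured quantities
#'
#' @param data Data frame with a time column and one column per quantity.
#' @param value_cols Character vector of quantity column names.
#' @param bin_width Bin width (minutes).
#' @param time_col Name of the time column.
#' @return Long data frame: `quantity`, `time` (bin center), `mean`,
#'   `sd`, `n`, `cv` (= sd/mean).  Bins with no observations carry `NA`.
#' @export
summarize_population <- function(data, value_cols, bin_width = 10,
                                 time_col = "time") {
  stopifnot(all(c(time_col, value_cols) %in% names(data)))
  out <- lapply(value_cols, function(vc) {
    b <- bin_series(data[[time_col]], data[[vc]], bin_width)
    b$cv <- b$sd / b$mean
    b$quantity <- vc
    b
  })
  do.call(rbind, out)[, c("quantity", "time", "mean", "sd", "n", "cv")]
}
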