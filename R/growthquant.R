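# Growth-rate estimators: single-cell instantaneous rates from volume
# time series, and the two optical-density estimators (batch exponential
# fit below an OD ceiling; plate-reader moving-average ln(OD) slope).
#
# Rates are always reported per hour.  Natural logarithms throughout.

#' Instantaneous single-cell growth rate from a volume time series
#'
#' The forward-difference estimator `(1/V_t) (V_{t+dt} - V_t) / dt`,
#' unsmoothed, reported per hour.  On exact exponential data with rate
#' `lambda` this returns `(exp(lambda dt) - 1) / dt`, the estimator's
#' known first-order bias.
#'
#' @param times Sampling times (minutes by default), uniformly spaced.
#' @param volumes Cell volumes (um^3), positive.
#' @param time_unit `"minutes"` or `"hours"`.
#' @return Data frame `time`, `rate` (per hour), one row fewer than the
#'   input.
#' @export
instantaneous_rate <- function(times, volumes, time_unit = c("minutes", "hours")) {
  time_unit <- match.arg(time_unit)
  if (length(times) < 2L) stop("need at least 2 points", call. = FALSE)
  if (length(times) != length(volumes)) stop("length mismatch", call. = FALSE)
  if (any(volumes <= 0) || any(!is.finite(volumes)))
    stop("volumes must be positive and finite", call. = FALSE)
  dt <- diff(times)
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("non-uniform sampling: resample upstream", call. = FALSE)
  dt_h <- mean(dt) / if (time_unit == "minutes") 60 else 1
  n <- length(volumes)
  rate <- (volumes[-1L] - volumes[-n]) / volumes[-n] / dt_h
  data.frame(time = times[-n], rate = rate)
}

#' Time-binned population trajectory of per-cell rates
#'
#' @param rates Data frame with columns `time` (minutes), `rate`
#'   (per hour) and optionally `cell_id`.
#' @param bin_width Bin width (minutes).
#' @return Data frame `time` (bin center), `mean`, `sd`, `n`; bins inside
#'   the observed range with no data are reported with `NA`, never zero.
#' @export
population_rate_trajectory <- function(rates, bin_width = 10) {
  check_scalar(bin_width, "bin_width", positive = TRUE)
  bin_series(rates$time, rates$rate, bin_width)
}

# Shared binning helper: full grid over the observed range, NA for empty
bin_series <- function(time, value, bin_width) {
  keep <- is.finite(time) & is.finite(value)
  time <- time[keep]; value <- value[keep]
  if (!length(time))
    return(data.frame(time = numeric(), mean = numeric(), sd = numeric(),
                      n = integer()))
  b0 <- floor(min(time) / bin_width)
  b1 <- floor(max(time) / bin_width)
  idx <- floor(time / bin_width) - b0 + 1L
  nb <- b1 - b0 + 1L
  mean_v <- rep(NA_real_, nb); sd_v <- rep(NA_real_, nb); n_v <- integer(nb)
  agg_n <- tapply(value, idx, length)
  agg_m <- tapply(value, idx, mean)
  agg_s <- tapply(value, idx, stats::sd)
  at <- as.integer(names(agg_n))
  n_v[at] <- as.integer(agg_n); mean_v[at] <- agg_m; sd_v[at] <- agg_s
  data.frame(time = (seq_len(nb) - 1L + b0 + 0.5) * bin_width,
             mean = mean_v, sd = sd_v, n = n_v)
}

# Split an od_series into segments at recorded dilution events
od_segments <- function(series) {
  dil <- attr(series, "dilutions")
  cuts <- if (!is.null(dil) && nrow(dil)) sort(unique(dil$time)) else numeric(0)
  seg <- findInterval(series$time, cuts, left.open = TRUE) + 1L
  split(seq_len(nrow(series)), seg)
}

#' Batch-culture growth rate: exponential fit below an OD ceiling
#'
#' Least-squares line through `(t, ln OD)` using the measurements with
#' `OD < od_max` within one dilution segment (the longest qualifying
#' segment by default); requires at least 3 qualifying points.
#'
#' @param series An `od_series` (data frame `time` in hours, `od`), e.g.
#'   from [simulate_od()].  Dilution events, if recorded in the
#'   `dilutions` attribute, delimit the candidate segments.
#' @param od_max OD ceiling for qualifying points (exclusive).
#' @return List of class `growth_estimate`: `rate` (per hour), `method`,
#'   `n`, `residual_sd`, `segment`.
#' @export
batch_od_rate <- function(series, od_max = 0.4) {
  stopifnot(is.data.frame(series), all(c("time", "od") %in% names(series)))
  if (any(series$od <= 0)) stop("od must be positive", call. = FALSE)
  segs <- od_segments(series)
  qual <- lapply(segs, function(ix) ix[series$od[ix] < od_max])
  nq <- vapply(qual, length, integer(1))
  best <- which.max(nq)
  if (nq[best] < 3L)
    stop(sprintf("only %d measurements with OD < %g in the best segment; need >= 3",
                 nq[best], od_max), call. = FALSE)
  ix <- qual[[best]]
  fit <- stats::lm(log(od) ~ time, data = series[ix, ])
  structure(list(rate = unname(stats::coef(fit)[2L]), method = "batch_od",
                 n = length(ix),
                 residual_sd = stats::sigma(fit),
                 segment = as.integer(names(segs)[best])),
            class = "growth_estimate")
}

#' Plate-reader growth rate: moving-average ln(OD) slope
#'
#' `ln(OD)` is smoothed with a centered moving average of window 5
#' (shrinking symmetric windows at the edges); the pointwise rate is the
#' centered two-point finite difference of the smoothed series; the
#' maximum rate is taken over interior points whose difference stencil
#' uses only fully-windowed smoothed values.
#'
#' @param series An `od_series` (`time` in hours, `od`); at least 7 points.
#' @param window Moving-average window (odd).
#' @return List of class `growth_estimate`: `max_rate` and `rate` (both
#'   per hour, `rate == max_rate`), `rates` (data frame `time`, `rate`
#'   for every computable point), `method`, `n`.
#' @export
plate_od_rate <- function(series, window = 5L) {
  stopifnot(is.data.frame(series), all(c("time", "od") %in% names(series)))
  n <- nrow(series)
  if (n < 7L) stop(sprintf("need >= 7 points, got %d", n), call. = FALSE)
  if (any(series$od <= 0)) stop("od must be positive", call. = FALSE)
  y <- moving_average(log(series$od), window)
  t <- series$time
  i <- 2:(n - 1L)
  slope <- (y[i + 1L] - y[i - 1L]) / (t[i + 1L] - t[i - 1L])
  k <- (window - 1L) %/% 2L
  interior <- i >= (k + 2L) & i <= (n - k - 1L)
  max_rate <- max(slope[interior])
  structure(list(rate = max_rate, max_rate = max_rate,
                 rates = data.frame(time = t[i], rate = slope),
                 method = "plate_od", n = n),
            class = "growth_estimate")
}

#' @export
print.growth_estimate <- function(x, ...) {
  cat(sprintf("<growth_estimate> %s: %.4f h^-1 (n = %d)\n",
              x$method, x$rate, x$n))
  invisible(x)
}
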