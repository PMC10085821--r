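#' Static (gravitational) component of an acceleration trace
#'
#' Low-pass filters each axis with a zero-phase 4th-order Butterworth filter
#' (applied forward and backward), leaving the slowly varying orientation
#' component attributed to gravity. Subtracting it from the raw trace gives
#' the dynamic acceleration used by [vedba()] and [odba()].
#'
#' @param a an [accel_trace()].
#' @param cutoff_hz low-pass cutoff frequency; must be below the Nyquist
#'   frequency `fs / 2`.
#' @return An [accel_trace()] holding the static component, same length.
#' @export
static_acceleration <- function(a, cutoff_hz = 0.1) {
  stopifnot(inherits(a, "accel_trace"))
  if (a$fs <= 2 * cutoff_hz) {
    stop("sampling frequency (", a$fs, " Hz) must exceed twice the cutoff (",
         cutoff_hz, " Hz)")
  }
  bf <- signal::butter(4, cutoff_hz / (a$fs / 2), type = "low")
  n <- length(a$ax)
  # odd-reflection padding suppresses the zero-state edge transients of the
  # forward-backward pass; pad roughly three filter time constants
  np <- min(n - 1, ceiling(10 * a$fs / cutoff_hz))
  lp <- function(x) {
    xp <- c(2 * x[1] - x[np:1 + 1], x, 2 * x[n] - x[n - 1:np])
    as.numeric(signal::filtfilt(bf, xp))[np + seq_len(n)]
  }
  accel_trace(lp(a$ax), lp(a$ay), lp(a$az), a$fs, a$animal_id, a$t0)
}

dynamic_acceleration <- function(a, cutoff_hz = 0.1) {
  s <- static_acceleration(a, cutoff_hz)
  list(dx = a$ax - s$ax, dy = a$ay - s$ay, dz = a$az - s$az)
}

sample_times_h <- function(a) a$t0 + (seq_along(a$ax) - 1L) / a$fs / 3600

#' Vectorial dynamic body acceleration (VeDBA)
#'
#' The Euclidean norm of the dynamic acceleration (raw minus static
#' component), a standard proxy for energy expenditure.
#'
#' @inheritParams static_acceleration
#' @return A [metric_series()] at the raw sampling resolution.
#' @seealso [odba()] for the L1-norm variant, [aggregate_metric()] to reduce
#'   to minute or hourly means.
#' @export
vedba <- function(a, cutoff_hz = 0.1) {
  da <- dynamic_acceleration(a, cutoff_hz)
  metric_series(sample_times_h(a), sqrt(da$dx^2 + da$dy^2 + da$dz^2),
                "VeDBA", a$animal_id)
}

#' Overall dynamic body acceleration (ODBA)
#'
#' The L1 norm of the dynamic acceleration. For any sample,
#' `VeDBA <= ODBA <= sqrt(3) * VeDBA`.
#'
#' @inheritParams static_acceleration
#' @return A [metric_series()] at the raw sampling resolution.
#' @export
odba <- function(a, cutoff_hz = 0.1) {
  da <- dynamic_acceleration(a, cutoff_hz)
  metric_series(sample_times_h(a), abs(da$dx) + abs(da$dy) + abs(da$dz),
                "ODBA", a$animal_id)
}

#' Jerk: norm of the differential of raw acceleration
#'
#' First differences of each raw axis, scaled by the sampling frequency so
#' that units are per second and values are comparable across sampling
#' rates, combined as a Euclidean norm. A proxy for rapid movement.
#'
#' @param a an [accel_trace()] with at least two samples.
#' @return A [metric_series()] of length `length(a) - 1`, timestamped at the
#'   later sample of each difference.
#' @export
jerk <- function(a) {
  stopifnot(inherits(a, "accel_trace"))
  if (length(a$ax) < 2) stop("jerk needs at least two samples")
  j <- sqrt(diff(a$ax)^2 + diff(a$ay)^2 + diff(a$az)^2) * a$fs
  metric_series(sample_times_h(a)[-1], j, "jerk", a$animal_id)
}

#' Aggregate a metric series into block means
#'
#' Non-overlapping windows of `window_min` minutes, anchored at t = 0
#' (release); each window's samples are averaged and stamped at the window
#' end. Empty windows are dropped. Aggregating an already-aggregated series
#' at the same window is the identity.
#'
#' @param m a [metric_series()].
#' @param window_min window width in minutes.
#' @return A [metric_series()] with `aggregation_window_min` recorded.
#' @export
aggregate_metric <- function(m, window_min = 1) {
  stopifnot(inherits(m, "metric_series"), window_min > 0)
  prev <- attr(m, "aggregation_window_min")
  if (!is.na(prev) && prev == window_min) return(m)
  w_h <- window_min / 60
  # windows are (k-1, k] * w_h; a sample exactly at a window start belongs to
  # the previous window, so the first window is (0, w] and t = 0 maps into it
  idx <- ceiling(pmax(m$time_h, .Machine$double.eps) / w_h)
  val <- tapply(m$value, idx, mean)
  ks <- as.numeric(names(val))
  metric_series(ks * w_h, as.numeric(val), attr(m, "metric"),
                attr(m, "animal_id"), aggregation_window_min = window_min)
}
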