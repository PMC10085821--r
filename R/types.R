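#' Species-level processing configuration
#'
#' Bundles the constants that differ between study species: the surface
#' threshold separating dives from surface behaviour, the target-depth
#' category edges, the zero-offset (Luque) filter settings, the low-pass
#' cutoff used to extract static acceleration, and the relative-entropy
#' stage defaults (normal-region threshold `tN_h`, upper limit `T_h`,
#' bootstrap block width `block_h`).
#'
#' Presets: `"narwhal"` uses category edges 160/360 m, `tN_h = 40`,
#' `T_h = 80`, `block_h = 5`; `"bowhead"` uses edges 60/120 m, `tN_h = 10`,
#' `T_h = 20`, `block_h = 2`. Both share the 20 m surface threshold, the
#' 20 s median / 30 min 0.01-quantile depth filters and the 0.1 Hz low-pass
#' cutoff.
#'
#' @param species `"narwhal"`, `"bowhead"`, or `"custom"`.
#' @param ... named overrides of any field listed below.
#'
#' @return An object of class `species_config`: a list with fields
#'   `species`, `surface_threshold_m`, `category_edges_m` (length 2,
#'   strictly increasing), `lowpass_cutoff_hz`, `luque_window1_s`,
#'   `luque_window2_min`, `luque_q1`, `luque_q2`, `tN_h`, `T_h`, `block_h`.
#' @examples
#' cfg <- species_config("narwhal")
#' cfg$category_edges_m
#' species_config("bowhead", surface_threshold_m = 15)$surface_threshold_m
#' @export
species_config <- function(species = c("narwhal", "bowhead", "custom"), ...) {
  species <- match.arg(species)
  base <- list(
    species = species,
    surface_threshold_m = 20,
    category_edges_m = c(160, 360),
    lowpass_cutoff_hz = 0.1,
    luque_window1_s = 20,
    luque_window2_min = 30,
    luque_q1 = 0.5,
    luque_q2 = 0.01,
    tN_h = 40,
    T_h = 80,
    block_h = 5
  )
  if (species == "bowhead") {
    base$category_edges_m <- c(60, 120)
    base$tN_h <- 10
    base$T_h <- 20
    base$block_h <- 2
  }
  cfg <- modifyList(base, list(...))
  stopifnot(
    length(cfg$category_edges_m) == 2,
    diff(cfg$category_edges_m) > 0,
    cfg$category_edges_m[1] > cfg$surface_threshold_m,
    cfg$surface_threshold_m > 0
  )
  structure(cfg, class = "species_config")
}

#' @export
print.species_config <- function(x, ...) {
  cat("<species_config>", x$species, "\n")
  cat("  surface threshold:", x$surface_threshold_m, "m; category edges:",
      paste(x$category_edges_m, collapse = "/"), "m\n")
  cat("  depth filters: median", x$luque_window1_s, "s, q", x$luque_q2,
      "over", x$luque_window2_min, "min; accel low-pass",
      x$lowpass_cutoff_hz, "Hz\n")
  cat("  entropy stage: tN", x$tN_h, "h, T", x$T_h, "h, block",
      x$block_h, "h\n")
  invisible(x)
}

#' Depth trace
#'
#' A uniformly sampled depth record (metres, positive downwards), with time
#' zero at release.
#'
#' @param depth numeric vector of depths in metres.
#' @param fs sampling frequency in Hz.
#' @param animal_id identifier of the animal.
#' @param t0 release epoch (hours offset applied to sample times; normally 0).
#' @param corrected logical; has the zero-offset correction been applied?
#' @return Object of class `depth_trace`.
#' @seealso [zero_offset_correct()], [segment_dives()]
#' @export
depth_trace <- function(depth, fs, animal_id = "animal", t0 = 0,
                        corrected = FALSE) {
  depth <- as.numeric(depth)
  if (length(depth) == 0) stop("depth trace is empty")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)")
  }
  structure(
    list(depth = depth, fs = fs, animal_id = animal_id, t0 = t0,
         corrected = isTRUE(corrected)),
    class = "depth_trace"
  )
}

#' @export
print.depth_trace <- function(x, ...) {
  cat("<depth_trace>", x$animal_id, "-", length(x$depth), "samples @",
      x$fs, "Hz (", round(length(x$depth) / x$fs / 3600, 2), "h );",
      if (x$corrected) "zero-offset corrected" else "raw", "\n")
  invisible(x)
}

#' Tri-axial acceleration trace
#'
#' Raw tri-axial accelerometer record in consistent units (g or m/s^2),
#' with time zero at release.
#'
#' @param ax,ay,az numeric vectors, one per axis, equal length.
#' @param fs sampling frequency in Hz.
#' @param animal_id identifier of the animal.
#' @param t0 release epoch (normally 0).
#' @return Object of class `accel_trace`.
#' @seealso [static_acceleration()], [vedba()], [odba()], [jerk()]
#' @export
accel_trace <- function(ax, ay, az, fs, animal_id = "animal", t0 = 0) {
  n <- length(ax)
  if (length(ay) != n || length(az) != n) {
    stop("axes must have equal length")
  }
  if (n == 0) stop("acceleration trace is empty")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)")
  }
  structure(
    list(ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az),
         fs = fs, animal_id = animal_id, t0 = t0),
    class = "accel_trace"
  )
}

#' @export
print.accel_trace <- function(x, ...) {
  cat("<accel_trace>", x$animal_id, "-", length(x$ax), "samples @",
      x$fs, "Hz (", round(length(x$ax) / x$fs / 3600, 2), "h )\n")
  invisible(x)
}

#' Metric series
#'
#' A derived activity metric (VeDBA, ODBA or jerk) as a time series in hours
#' since release.
#'
#' @param time_h numeric, hours since release, strictly increasing.
#' @param value nonnegative metric values.
#' @param metric one of `"VeDBA"`, `"ODBA"`, `"jerk"`.
#' @param animal_id identifier of the animal.
#' @param aggregation_window_min width of the aggregation window in minutes,
#'   or `NA` for raw sampling resolution.
#' @return A tibble of class `metric_series` with columns `time_h`, `value`
#'   and attributes `metric`, `animal_id`, `aggregation_window_min`.
#' @export
metric_series <- function(time_h, value, metric, animal_id = "animal",
                          aggregation_window_min = NA_real_) {
  metric <- match.arg(metric, c("VeDBA", "ODBA", "jerk"))
  if (length(time_h) != length(value)) stop("time and value lengths differ")
  if (any(diff(time_h) <= 0)) stop("`time_h` must be strictly increasing")
  if (any(value < 0, na.rm = TRUE)) stop("metric values must be nonnegative")
  out <- tibble::tibble(time_h = as.numeric(time_h), value = as.numeric(value))
  attr(out, "metric") <- metric
  attr(out, "animal_id") <- animal_id
  attr(out, "aggregation_window_min") <- aggregation_window_min
  class(out) <- c("metric_series", class(out))
  out
}

#' Dive table
#'
#' One row per dive: an excursion below the surface threshold, with its
#' start time (hours since release), duration (seconds), target depth
#' (deepest depth attained, metres) and target-depth category.
#'
#' @param animal_id,start_h,duration_s,target_depth_m,category column vectors
#'   of equal length; `category` must be one of `"Shallow"`, `"Medium"`,
#'   `"Deep"`.
#' @return A tibble of class `dive_table`.
#' @seealso [segment_dives()], [hourly_distributions()]
#' @export
dive_table <- function(animal_id = character(), start_h = numeric(),
                       duration_s = numeric(), target_depth_m = numeric(),
                       category = character()) {
  stopifnot(all(category %in% c("Shallow", "Medium", "Deep")))
  if (any(duration_s <= 0)) stop("dive durations must be positive")
  out <- tibble::tibble(
    animal_id = as.character(animal_id),
    start_h = as.numeric(start_h),
    duration_s = as.numeric(duration_s),
    target_depth_m = as.numeric(target_depth_m),
    category = factor(category, levels = c("Shallow", "Medium", "Deep"))
  )
  class(out) <- c("dive_table", class(out))
  out
}

#' Assign target-depth categories
#'
#' Categories are left-open/right-closed at the configured edges:
#' Shallow is (threshold, e1], Medium is (e1, e2], Deep is > e2.
#'
#' @param depth_m numeric target depths (metres).
#' @param cfg a [species_config()].
#' @return factor with levels Shallow, Medium, Deep (`NA` for depths at or
#'   above the surface, i.e. not dives).
#' @examples
#' assign_depth_category(c(50, 200, 400), species_config("narwhal"))
#' @export
assign_depth_category <- function(depth_m, cfg) {
  e <- cfg$category_edges_m
  thr <- cfg$surface_threshold_m
  cut(depth_m, breaks = c(thr, e[1], e[2], Inf),
      labels = c("Shallow", "Medium", "Deep"), right = TRUE)
}

as_dive_table <- function(df) {
  dive_table(df$animal_id, df$start_h, df$duration_s, df$target_depth_m,
             as.character(df$category))
}
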