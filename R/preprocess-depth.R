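#' Zero-offset correct a depth trace
#'
#' Pressure transducers drift with temperature, so recorded depth at the
#' surface wanders away from zero. The correction is a two-pass recursive
#' moving-quantile (Luque) filter: the first pass is a running median over a
#' short window that removes surface noise, the second pass is a running
#' low quantile over a long window (longer than one diving cycle) that tracks
#' the drifting surface level. The adjusted depth is the first-pass output
#' minus the second-pass output (default), or the raw trace minus the
#' second-pass output via `method = "raw_minus_f2"`.
#'
#' Windows are centered; near the record edges they shrink symmetrically to
#' the available samples.
#'
#' @param d a [depth_trace()] (uncorrected).
#' @param cfg a [species_config()]; uses `luque_window1_s`,
#'   `luque_window2_min`, `luque_q1`, `luque_q2`.
#' @param method `"f1_minus_f2"` (default) or `"raw_minus_f2"`.
#' @return A corrected [depth_trace()] of the same length.
#' @examples
#' d <- depth_trace(rep(2, 3600), fs = 1)
#' range(zero_offset_correct(d, species_config("narwhal"))$depth)  # 0 0
#' @export
zero_offset_correct <- function(d, cfg = species_config(),
                                method = c("f1_minus_f2", "raw_minus_f2")) {
  stopifnot(inherits(d, "depth_trace"))
  method <- match.arg(method)
  x <- d$depth
  if (any(!is.finite(x))) stop("depth trace contains non-finite samples")
  k1 <- max(3L, as.integer(round(cfg$luque_window1_s * d$fs)))
  if (k1 %% 2L == 0L) k1 <- k1 + 1L
  k2 <- as.integer(round(cfg$luque_window2_min * 60 * d$fs))
  if (length(x) < k2) {
    stop("depth trace (", length(x), " samples) is shorter than the ",
         cfg$luque_window2_min, "-min filter window (", k2, " samples); ",
         "cannot zero-offset correct")
  }
  f1 <- if (abs(cfg$luque_q1 - 0.5) < 1e-12) {
    as.numeric(stats::runmed(x, k1, endrule = "median"))
  } else {
    zoo::rollapply(x, width = k1, FUN = quantile, probs = cfg$luque_q1,
                   names = FALSE, partial = TRUE, align = "center")
  }
  f2 <- zoo::rollapply(f1, width = k2, FUN = quantile, probs = cfg$luque_q2,
                       names = FALSE, partial = TRUE, align = "center")
  adj <- if (method == "f1_minus_f2") f1 - f2 else x - f2
  depth_trace(adj, d$fs, d$animal_id, d$t0, corrected = TRUE)
}

#' Resample a uniformly sampled series by an integer ratio
#'
#' Downsampling averages consecutive measurements in non-overlapping blocks;
#' upsampling duplicates each measurement. An incomplete final block is
#' truncated.
#'
#' @param x numeric vector.
#' @param fs_in,fs_out input and output sampling frequencies; their ratio
#'   (either way) must be a positive integer.
#' @return numeric vector of length `floor(length(x) * fs_out / fs_in)`.
#' @examples
#' resample(c(1, 2, 3, 4), 2, 1)  # 1.5 3.5
#' resample(c(1, 2), 1, 2)        # 1 1 2 2
#' @export
resample <- function(x, fs_in, fs_out) {
  stopifnot(fs_in > 0, fs_out > 0)
  if (fs_in == fs_out) return(x)
  if (fs_in > fs_out) {
    r <- fs_in / fs_out
    if (abs(r - round(r)) > 1e-8) {
      stop("fs_in/fs_out = ", r, " is not an integer")
    }
    r <- as.integer(round(r))
    n_full <- length(x) %/% r
    if (n_full == 0L) return(numeric(0))
    colMeans(matrix(x[seq_len(n_full * r)], nrow = r))
  } else {
    k <- fs_out / fs_in
    if (abs(k - round(k)) > 1e-8) {
      stop("fs_out/fs_in = ", k, " is not an integer")
    }
    rep(x, each = as.integer(round(k)))
  }
}

#' Segment a corrected depth trace into dives
#'
#' A dive is a maximal run of consecutive samples deeper than the surface
#' threshold. Its duration is the run length divided by the sampling
#' frequency, its target depth is the deepest depth attained in the run, and
#' its category follows the configured target-depth edges. Runs that are
#' still open at the start or end of the record are discarded, because their
#' true extent (and hence target depth) is unknown.
#'
#' @param d a corrected [depth_trace()]. A warning is issued if `d` is not
#'   flagged as corrected.
#' @param cfg a [species_config()].
#' @return A [dive_table()] (possibly empty), time-ordered.
#' @examples
#' d <- depth_trace(c(0, 5, 25, 40, 30, 10, 0), fs = 1, corrected = TRUE)
#' segment_dives(d, species_config("narwhal"))
#' @export
segment_dives <- function(d, cfg = species_config()) {
  stopifnot(inherits(d, "depth_trace"))
  if (!d$corrected) {
    warning("segmenting an uncorrected depth trace; run zero_offset_correct() first")
  }
  thr <- cfg$surface_threshold_m
  below <- d$depth > thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  # discard dives open at the record boundaries
  if (length(keep) > 0) {
    if (keep[1]) keep[1] <- FALSE
    if (keep[length(keep)]) keep[length(keep)] <- FALSE
  }
  idx <- which(keep)
  if (length(idx) == 0) return(dive_table())
  target <- vapply(idx, function(i) max(d$depth[starts[i]:ends[i]]), 0)
  dive_table(
    animal_id = rep(d$animal_id, length(idx)),
    start_h = d$t0 + (starts[idx] - 1L) / d$fs / 3600,
    duration_s = r$lengths[idx] / d$fs,
    target_depth_m = target,
    category = as.character(assign_depth_category(target, cfg))
  )
}
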