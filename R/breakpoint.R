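#' Cumulative sum of recovery labels
#'
#' Turns the noisy in/out-of-band label sequence into a trend whose kink
#' marks the recovery: while the animal is perturbed the sum drifts down
#' (labels -1), after recovery it drifts up (labels +1).
#'
#' @param labels a [label_series()] result, or an integer vector of +1/-1.
#' @return A tibble with columns `hour`, `csum`.
#' @export
label_cumsum <- function(labels) {
  if (is.data.frame(labels)) {
    hour <- labels$hour
    lab <- labels$label
  } else {
    lab <- labels
    hour <- seq_along(lab) - 1L
  }
  if (!all(lab %in% c(-1L, 1L))) stop("labels must be +1 or -1")
  tibble::tibble(hour = hour, csum = cumsum(lab))
}

#' Segmented (broken-stick) regression with one breakpoint
#'
#' Fits the continuous piecewise-linear model
#' `y = a + b1 * x + b2 * (x - psi)_+` by exhaustive search: every interior
#' observed `x` value is tried as the breakpoint `psi`, a least-squares fit
#' is computed at each candidate, and the candidate with the smallest sum of
#' squared residuals wins (ties go to the smallest `psi`). At these series
#' lengths the grid search is exact, so no iterative linearization is
#' needed.
#'
#' A fit is flagged `no_breakpoint` when the segmented model fails to
#' reduce the straight-line SSR by at least a relative factor
#' `rel_improve_min`, or when the line already fits exactly: a slope change
#' indistinguishable from zero does not identify a breakpoint. A genuine
#' recovery kink (slope flipping from -1 to +1) reduces the SSR by far more
#' than the default factor 0.5; a label series that stays in the recovery
#' band drifts along a line and rarely reaches it.
#'
#' @param x nondecreasing numeric vector (>= 5 points; ties allowed, as
#'   arise when bootstrap resamples duplicate a time block).
#' @param y numeric response, same length.
#' @param min_seg minimum number of points strictly on each side of a
#'   candidate breakpoint (default 2).
#' @param rel_improve_min relative SSR improvement below which the fit is
#'   flagged `no_breakpoint` (default 0.5; set to 0 to disable).
#' @param candidate_range optional length-2 numeric restricting breakpoint
#'   candidates to an interval of `x` (used by
#'   [block_bootstrap_breakpoint()] to refine locally around the
#'   cumulative-sum trough).
#' @return An object of class `segmented_fit`: list with `psi`, `a`, `b1`,
#'   `b2`, `ssr`, `ssr_linear`, `no_breakpoint`.
#' @examples
#' x <- 0:20
#' fit_segmented(x, abs(x - 10))  # psi = 10, b1 = -1, b2 = 2, ssr = 0
#' @export
fit_segmented <- function(x, y, min_seg = 2, rel_improve_min = 0.5,
                          candidate_range = NULL) {
  n <- length(x)
  stopifnot(n >= 5, length(y) == n, all(diff(x) >= 0))
  lin <- .lm.fit(cbind(1, x), y)
  ssr_lin <- sum(lin$residuals^2)
  ux <- unique(x)
  if (!is.null(candidate_range)) {
    ux <- ux[ux >= candidate_range[1] & ux <= candidate_range[2]]
  }
  cand <- ux[vapply(ux, function(p) {
    sum(x < p) >= min_seg && sum(x > p) >= min_seg
  }, TRUE)]
  if (length(cand) == 0) stop("no admissible breakpoint candidates")
  best <- list(ssr = Inf)
  for (psi in cand) {
    f <- .lm.fit(cbind(1, x, pmax(x - psi, 0)), y)
    ssr <- sum(f$residuals^2)
    if (ssr < best$ssr - 1e-12) {
      best <- list(psi = psi, coef = f$coefficients, ssr = ssr)
    }
  }
  scale <- sum(y^2) + 1
  no_bp <- ssr_lin < 1e-10 * scale ||
    (ssr_lin - best$ssr) < rel_improve_min * ssr_lin
  structure(
    list(psi = if (no_bp) NA_real_ else best$psi,
         a = best$coef[1], b1 = best$coef[2], b2 = best$coef[3],
         ssr = best$ssr, ssr_linear = ssr_lin, no_breakpoint = no_bp),
    class = "segmented_fit"
  )
}

#' @export
print.segmented_fit <- function(x, ...) {
  if (x$no_breakpoint) {
    cat("<segmented_fit> no breakpoint (ssr_linear =",
        format(x$ssr_linear, digits = 4), ")\n")
  } else {
    cat("<segmented_fit> psi =", format(x$psi, digits = 5),
        "; slopes", format(x$b1, digits = 4), "->",
        format(x$b1 + x$b2, digits = 4),
        "; ssr =", format(x$ssr, digits = 4), "\n")
  }
  invisible(x)
}

#' Rule-of-thumb bootstrap block width
#'
#' The `T^(1/3)` rule for the width (hours) of the disjoint bootstrap
#' blocks, given the length `T_h` of the label series.
#'
#' @param T_h series length in hours.
#' @return block width in hours (rounded, at least 1).
#' @export
block_width_rule <- function(T_h) max(1L, as.integer(round(T_h^(1 / 3))))

#' Block-bootstrap breakpoint estimate of the return time
#'
#' The estimator is two-stage. First, the trough of the full-series
#' cumulative label sum — the CUSUM changepoint locator for a minus-to-plus
#' regime change — anchors the breakpoint search: a recovery is only
#' entertained if the trough is interior and at least two net label-hours
#' deep. Second, the label series is partitioned into disjoint consecutive
#' blocks of `block_h` hours and blocks are resampled with replacement;
#' each drawn block keeps its original hour positions and the replicate
#' series is the drawn blocks ordered by those hours (duplicated blocks sit
#' adjacent), so the temporal location of the transition is preserved while
#' the weight of every stretch of hours varies. For each replicate the
#' cumulative sum is recomputed and [fit_segmented()] refines the
#' breakpoint within one block width of the anchor.
#'
#' A replicate contributes a breakpoint only when it shows the recovery
#' shape implied by the voting construction: its own cumulative-sum trough
#' is interior and at least two label-hours deep, and the fitted broken
#' stick falls before the kink (most hours outside the band) and rises
#' after it (most hours inside). Other replicates are dropped from the mean
#' and interval but counted; if they exceed half of `n_boot`, or the
#' full-series anchor itself fails the trough test, the estimate is
#' reported as "recovery not detected". The return time is the mean
#' replicate breakpoint and the confidence interval the percentile 95%
#' interval.
#'
#' @param labels a [label_series()] result (columns `hour`, `label`).
#' @param block_h block width in hours (5 for narwhal-scale series, 2 for
#'   shorter bowhead-scale series; see [block_width_rule()]).
#' @param n_boot bootstrap replicates, default 1000.
#' @param seed integer seed.
#' @param level confidence level, default 0.95.
#' @param min_trough_depth minimum depth (net label-hours below zero) of
#'   the cumulative-sum trough for a recovery to be entertained, default 2.
#' @return An object of class `breakpoint_estimate`: list with `t_R_h`,
#'   `ci_lower_h`, `ci_upper_h`, `n_boot`, `block_h`, `seed`, `samples`
#'   (replicate breakpoints), `n_dropped` (replicates without a
#'   breakpoint), `detected` (logical).
#' @export
block_bootstrap_breakpoint <- function(labels, block_h, n_boot = 1000,
                                       seed = 1, level = 0.95,
                                       min_trough_depth = 2) {
  stopifnot(is.data.frame(labels), all(c("hour", "label") %in% names(labels)))
  ord <- order(labels$hour)
  hour <- labels$hour[ord]
  lab <- labels$label[ord]
  n <- length(lab)
  blocks <- split(seq_len(n), floor((hour - hour[1]) / block_h))
  if (length(blocks) < 3) {
    stop("series spans fewer than 3 blocks of ", block_h, " h")
  }
  cs0 <- cumsum(lab)
  anchor <- hour[max(which(cs0 == min(cs0)))]
  anchored <- min(cs0) <= -min_trough_depth && anchor > hour[1]
  psi <- if (!anchored) rep(NA_real_, n_boot) else with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      draw <- sample(seq_along(blocks), length(blocks), replace = TRUE)
      take <- sort(unlist(blocks[draw], use.names = FALSE))
      x <- hour[take]
      cs <- cumsum(lab[take])
      trough <- x[max(which(cs == min(cs)))]
      if (min(cs) > -min_trough_depth || trough <= x[1]) return(NA_real_)
      f <- tryCatch(
        fit_segmented(x, cs, rel_improve_min = 0,
                      candidate_range = c(anchor - block_h, anchor + block_h)),
        error = function(e) NULL
      )
      if (is.null(f) || f$no_breakpoint ||
          !(f$b1 < 0 && f$b1 + f$b2 > 0)) return(NA_real_)
      f$psi
    }, 0)
  })
  n_dropped <- sum(is.na(psi))
  detected <- n_dropped <= n_boot / 2
  keep <- psi[!is.na(psi)]
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  structure(
    list(
      t_R_h = if (detected) mean(keep) else NA_real_,
      ci_lower_h = if (detected) unname(quantile(keep, pr[1], type = 7)) else NA_real_,
      ci_upper_h = if (detected) unname(quantile(keep, pr[2], type = 7)) else NA_real_,
      n_boot = n_boot, block_h = block_h, seed = seed,
      samples = psi, n_dropped = n_dropped, detected = detected
    ),
    class = "breakpoint_estimate"
  )
}

#' @export
print.breakpoint_estimate <- function(x, ...) {
  if (!x$detected) {
    cat("<breakpoint_estimate> recovery not detected (",
        x$n_dropped, "/", x$n_boot, "replicates without a breakpoint)\n")
  } else {
    cat("<breakpoint_estimate> t_R =", format(x$t_R_h, digits = 4),
        "h, 95% CI [", format(x$ci_lower_h, digits = 4), ",",
        format(x$ci_upper_h, digits = 4), "] (block", x$block_h, "h,",
        x$n_boot, "replicates,", x$n_dropped, "dropped)\n")
  }
  invisible(x)
}
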