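#' Hourly dive-profile distributions
#'
#' For each hour `[t, t+1)` since release, the distribution of dive time
#' over target-depth categories: `P_t(x)` is the total duration (default) or
#' count of dives starting in that hour with category `x`, divided by the
#' hour's total. Hours with no dives are omitted — they carry no
#' dive-profile information.
#'
#' @param dives a [dive_table()], typically pooled over the animals of one
#'   group.
#' @param weighting `"duration"` (default) or `"count"`.
#' @return A tibble of class `hourly_dist` with columns `hour`, `Shallow`,
#'   `Medium`, `Deep`, `n_dives`, `n_animals`, `total_s`. Each probability
#'   row sums to one.
#' @export
hourly_distributions <- function(dives, weighting = c("duration", "count")) {
  stopifnot(inherits(dives, "dive_table"))
  weighting <- match.arg(weighting)
  cats <- c("Shallow", "Medium", "Deep")
  if (nrow(dives) == 0) {
    out <- tibble::tibble(hour = integer(), Shallow = numeric(),
                          Medium = numeric(), Deep = numeric(),
                          n_dives = integer(), n_animals = integer(),
                          total_s = numeric())
    class(out) <- c("hourly_dist", class(out))
    return(out)
  }
  hr <- floor(dives$start_h)
  wt <- if (weighting == "duration") dives$duration_s else rep(1, nrow(dives))
  tot <- tapply(wt, hr, sum)
  mass <- tapply(wt, list(hr, factor(dives$category, levels = cats)), sum,
                 default = 0)
  hrs <- as.integer(rownames(mass))
  p <- mass / as.numeric(tot[rownames(mass)])
  n_dives <- as.integer(tapply(rep(1, nrow(dives)), hr, sum))
  n_animals <- as.integer(tapply(dives$animal_id, hr,
                                 function(a) length(unique(a))))
  total_s <- as.numeric(tapply(dives$duration_s, hr, sum))
  out <- tibble::tibble(
    hour = hrs,
    Shallow = p[, "Shallow"], Medium = p[, "Medium"], Deep = p[, "Deep"],
    n_dives = n_dives, n_animals = n_animals, total_s = total_s
  )
  out <- out[order(out$hour), ]
  class(out) <- c("hourly_dist", class(out))
  out
}

p_matrix <- function(hourly) {
  m <- as.matrix(hourly[, c("Shallow", "Medium", "Deep")])
  rownames(m) <- hourly$hour
  m
}

#' Drop-point schedule for the reference distribution
#'
#' Tags detach or fail at different times, so the pool of animals
#' contributing to late hours shrinks. The normal region `t > tN` is split
#' at the distinct record-end times ("drop points") `tN = t_0 < t_1 < ... <
#' t_M`, and segment `i` receives weight `w_i = n_i / sum_j n_j`, where
#' `n_i` is the number of animals still active before drop point `t_i`.
#' This exploits all normal-region hours while down-weighting stretches
#' observed on few animals.
#'
#' @param record_ends_h record end time (hours since release), one per
#'   animal.
#' @param tN normal-region threshold (hours).
#' @return An object of class `drop_schedule`: list with `tN`, `drops`
#'   (the `t_i`, increasing, ending at the maximum record duration), `n`,
#'   `w` (summing to one).
#' @examples
#' build_schedule(c(60, 100), tN = 40)$w  # 2/3, 1/3
#' @export
build_schedule <- function(record_ends_h, tN) {
  stopifnot(length(record_ends_h) > 0, tN >= 0)
  drops <- sort(unique(record_ends_h[record_ends_h > tN]))
  if (length(drops) == 0) {
    stop("no record extends beyond tN = ", tN, " h: normal region is empty")
  }
  n <- vapply(drops, function(ti) sum(record_ends_h >= ti), 0L)
  structure(list(tN = tN, drops = drops, n = n, w = n / sum(n)),
            class = "drop_schedule")
}

#' @export
print.drop_schedule <- function(x, ...) {
  cat("<drop_schedule> tN =", x$tN, "h;", length(x$drops), "segment(s)\n")
  cat("  drops:", paste(x$drops, collapse = ", "), "\n")
  cat("  weights:", paste(round(x$w, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Drop-time-weighted reference distribution
#'
#' The baseline dive-profile distribution `Q`: a weighted average of the
#' hourly distributions in the normal region, `Q = sum_i w_i * mean(P_t over
#' hours in (t_{i-1}, t_i])`, with weights from [build_schedule()]. Hours
#' with no dives are excluded from their segment's mean (the divisor is
#' renormalized); a segment with no available hours has its weight
#' redistributed proportionally over the others, with a warning.
#'
#' @param hourly an [hourly_distributions()] result covering the normal
#'   region.
#' @param schedule a [build_schedule()] result.
#' @param exclude_hour optional hour to leave out (for the leave-one-out
#'   reference `Q_{-t'}` used by [region_of_recovery()]).
#' @param warn_empty warn when a segment has no hours; default `TRUE`.
#' @return An object of class `reference_distribution`: list with `q`
#'   (named probability vector), `schedule`, `excluded_hour`.
#' @export
reference_distribution <- function(hourly, schedule, exclude_hour = NULL,
                                   warn_empty = TRUE) {
  stopifnot(inherits(hourly, "hourly_dist"), inherits(schedule, "drop_schedule"))
  P <- p_matrix(hourly)
  hrs <- hourly$hour
  bounds <- c(schedule$tN, schedule$drops)
  M <- length(schedule$drops)
  means <- matrix(NA_real_, M, 3)
  ok <- logical(M)
  for (i in seq_len(M)) {
    inseg <- hrs > bounds[i] & hrs <= bounds[i + 1]
    if (!is.null(exclude_hour)) inseg <- inseg & hrs != exclude_hour
    if (any(inseg)) {
      means[i, ] <- colMeans(P[inseg, , drop = FALSE])
      ok[i] <- TRUE
    }
  }
  if (!any(ok)) stop("no hourly distributions available in the normal region")
  w <- schedule$w
  if (any(!ok)) {
    if (warn_empty) {
      warning("segment(s) ", paste(which(!ok), collapse = ", "),
              " contain no hourly distributions; weight redistributed")
    }
    w <- w[ok] / sum(w[ok])
    means <- means[ok, , drop = FALSE]
  }
  q <- as.numeric(crossprod(w, means))
  names(q) <- c("Shallow", "Medium", "Deep")
  structure(list(q = q, schedule = schedule,
                 excluded_hour = exclude_hour %||% NA_real_),
            class = "reference_distribution")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.reference_distribution <- function(x, ...) {
  cat("<reference_distribution> Q = (",
      paste(round(x$q, 4), collapse = ", "), ")",
      if (!is.na(x$excluded_hour)) paste0(" [hour ", x$excluded_hour,
                                          " excluded]"), "\n")
  invisible(x)
}

#' Kullback-Leibler divergence (base 2)
#'
#' `K(p, q) = sum_x p(x) log2(p(x)/q(x))` with `0 log 0 = 0`. Nonnegative,
#' zero iff `p = q`, and infinite when `p` puts mass where `q` has none.
#'
#' @param p,q probability vectors on the same alphabet (sums within 1e-8 of
#'   one).
#' @return nonnegative scalar (possibly `Inf`), in bits.
#' @export
kl_divergence <- function(p, q) {
  check_prob(p); check_prob(q)
  if (length(p) != length(q)) stop("alphabets differ in size")
  pos <- p > 0
  if (any(pos & q == 0)) return(Inf)
  sum(p[pos] * log2(p[pos] / q[pos]))
}

check_prob <- function(p) {
  if (any(p < 0)) stop("probability vector has negative entries")
  if (abs(sum(p) - 1) > 1e-8) stop("probabilities must sum to 1")
  invisible(p)
}

#' Jensen-Shannon divergence (base 2)
#'
#' `J(p, q) = K(p, m)/2 + K(q, m)/2` with the mixture `m = (p + q)/2` and
#' base-2 logarithms, so that `J` lies in `[0, 1]`: zero iff `p = q`, one
#' for disjoint supports. Always finite and symmetric; its square root is a
#' metric.
#'
#' @inheritParams kl_divergence
#' @return scalar in `[0, 1]`.
#' @examples
#' js_divergence(c(1, 0, 0), c(0.5, 0.5, 0))  # 0.3113
#' @export
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  j <- kl_divergence(p, m) / 2 + kl_divergence(q, m) / 2
  min(max(j, 0), 1)  # clamp roundoff at the boundaries
}

#' Hourly Jensen-Shannon divergence series
#'
#' `J(P_t || Q)` for every available hour, measuring how far each hour's
#' dive profile sits from the baseline.
#'
#' @param hourly an [hourly_distributions()] result.
#' @param reference a [reference_distribution()].
#' @return A tibble of class `entropy_series` with columns `hour`, `J`.
#' @export
entropy_series <- function(hourly, reference) {
  stopifnot(inherits(hourly, "hourly_dist"),
            inherits(reference, "reference_distribution"))
  P <- p_matrix(hourly)
  out <- tibble::tibble(
    hour = hourly$hour,
    J = apply(P, 1, js_divergence, q = reference$q)
  )
  class(out) <- c("entropy_series", class(out))
  out
}

#' Region of recovery (RoR)
#'
#' The 95% band of "typical" divergence values inside the normal region,
#' built by leave-one-out cross-validation: for each hour `t'` in
#' `(tN, T]`, the reference distribution is recomputed without that hour
#' (`Q_{-t'}`) and `J_{-t'} = J(P_{t'} || Q_{-t'})` recorded. The region is
#' the closed empirical 2.5%-97.5% quantile interval of these values
#' (`stats::quantile` type 7). `T` should be an early drop point so that
#' late-hour distributions, computed on few animals, do not distort the
#' band.
#'
#' @param hourly an [hourly_distributions()] result.
#' @param schedule a [build_schedule()] result.
#' @param T_h upper limit of the hours used (must exceed `schedule$tN`).
#' @param level band level, default 0.95.
#' @return An object of class `ror`: list with `lo`, `hi`, `level`,
#'   `hours`, `j_loo` (the leave-one-out divergences), `tN`, `T_h`.
#' @export
region_of_recovery <- function(hourly, schedule, T_h, level = 0.95) {
  stopifnot(inherits(hourly, "hourly_dist"), inherits(schedule, "drop_schedule"))
  tN <- schedule$tN
  if (T_h <= tN) stop("T_h (", T_h, ") must exceed tN (", tN, ")")
  hrs <- hourly$hour[hourly$hour > tN & hourly$hour <= T_h]
  if (length(hrs) < 10) {
    warning("only ", length(hrs), " hours in (tN, T]: recovery band may be unstable")
  }
  if (length(hrs) == 0) stop("no hourly distributions in (tN, T]")
  P <- p_matrix(hourly)
  j_loo <- vapply(hrs, function(t1) {
    ref <- reference_distribution(hourly, schedule, exclude_hour = t1,
                                  warn_empty = FALSE)
    js_divergence(P[as.character(t1), ], ref$q)
  }, 0)
  band <- unname(quantile(j_loo, c((1 - level) / 2, 1 - (1 - level) / 2),
                          type = 7))
  structure(list(lo = band[1], hi = band[2], level = level, hours = hrs,
                 j_loo = j_loo, tN = tN, T_h = T_h),
            class = "ror")
}

#' Pool regions of recovery across groups
#'
#' For group comparisons the recovery band is computed from the combined
#' leave-one-out divergences of all groups, under the assumption that the
#' groups share a common distribution inside the normal region.
#'
#' @param ... [region_of_recovery()] results.
#' @param level band level, default 0.95.
#' @return An object of class `ror` built from the pooled values.
#' @export
combine_ror <- function(..., level = 0.95) {
  rors <- list(...)
  stopifnot(length(rors) > 0, all(vapply(rors, inherits, TRUE, "ror")))
  j <- unlist(lapply(rors, `[[`, "j_loo"))
  band <- unname(quantile(j, c((1 - level) / 2, 1 - (1 - level) / 2), type = 7))
  structure(list(lo = band[1], hi = band[2], level = level,
                 hours = unlist(lapply(rors, `[[`, "hours")), j_loo = j,
                 tN = rors[[1]]$tN, T_h = max(vapply(rors, `[[`, 0, "T_h"))),
            class = "ror")
}

#' @export
print.ror <- function(x, ...) {
  cat("<ror> [", format(x$lo, digits = 4), ",", format(x$hi, digits = 4),
      "] at level", x$level, "from", length(x$j_loo),
      "leave-one-out divergences, hours (", x$tN, ",", x$T_h, "]\n")
  invisible(x)
}

#' Label hours by the region of recovery
#'
#' `+1` when the hour's divergence lies inside the closed recovery band,
#' `-1` otherwise. Hours with no dive distribution carry no label.
#'
#' @param es an [entropy_series()].
#' @param ror a [region_of_recovery()] band.
#' @return A tibble with columns `hour`, `J`, `label` (+1 / -1).
#' @export
label_series <- function(es, ror) {
  stopifnot(inherits(es, "entropy_series"), inherits(ror, "ror"))
  tibble::tibble(
    hour = es$hour, J = es$J,
    label = ifelse(es$J >= ror$lo & es$J <= ror$hi, 1L, -1L)
  )
}
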