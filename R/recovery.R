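#' @keywords internal
#' Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

new_recovery_estimate <- function(tau, group, delta, t_R_h, ci_lower_h = NA_real_,
                                  ci_upper_h = NA_real_, method = "closed_form",
                                  capped = FALSE) {
  out <- tibble::tibble(
    tau = tau, group = group, delta = delta, t_R_h = t_R_h,
    ci_lower_h = ci_lower_h, ci_upper_h = ci_upper_h, method = method,
    capped = capped
  )
  class(out) <- c("recovery_estimate", class(out))
  out
}

#' Closed-form return time from a fitted quantile model
#'
#' The fitted quantile is displaced from baseline by the factor
#' `exp(alpha * z)` with `z = 1/(t + 1)`. The return time at threshold
#' `delta` is the time at which the displacement has shrunk to within a
#' factor `delta` of baseline, i.e. the solution of `exp(alpha z) = delta`:
#' `t_R = max(0, |alpha| / |log(delta)| - 1)`. The absolute value treats
#' suppressed (`alpha < 0`) and elevated (`alpha > 0`) responses
#' symmetrically.
#'
#' @param fit a [fit_quantile_model()] result.
#' @param group group whose slope to use; defaults to the only group.
#' @param delta recovery threshold in (0, 1); default 0.25 (the response is
#'   within 25% of baseline).
#' @return A one-row [tibble::tibble()] of class `recovery_estimate`
#'   (`t_R_h` in hours; CI columns `NA` — see [bootstrap_ci()]).
#' @examples
#' fit <- list(tau = 0.5, alpha = c(g = 2 * log(0.25)), groups = "g")
#' class(fit) <- "qr_fit"
#' recovery_time(fit, "g", 0.25)$t_R_h  # 1
#' @export
recovery_time <- function(fit, group = NULL, delta = 0.25) {
  stopifnot(inherits(fit, "qr_fit"), delta > 0, delta < 1)
  if (is.null(group)) {
    if (length(fit$groups) != 1) stop("specify `group`: fit has several")
    group <- fit$groups
  }
  if (!group %in% fit$groups) stop("unknown group: ", group)
  a <- unname(fit$alpha[group])
  t_R <- max(0, abs(a) / abs(log(delta)) - 1)
  new_recovery_estimate(fit$tau, group, delta, t_R)
}

#' Return-time curve over a grid of recovery thresholds
#'
#' Evaluates [recovery_time()] over a grid of `delta` values, producing the
#' curve `t_R(delta)`, nondecreasing in `delta`: reaching a fraction of
#' baseline closer to one takes longer. Values exceeding `t_max` (e.g. the
#' record length) are capped and flagged.
#'
#' @inheritParams recovery_time
#' @param delta_grid thresholds in (0, 1).
#' @param t_max cap for the reported return time (hours); default `Inf`.
#' @return A `recovery_estimate` tibble, one row per `delta`.
#' @export
recovery_curve <- function(fit, group = NULL, delta_grid = seq(0.05, 0.95, 0.05),
                           t_max = Inf) {
  stopifnot(all(delta_grid > 0 & delta_grid < 1))
  rows <- lapply(sort(delta_grid), function(d) recovery_time(fit, group, d))
  out <- do.call(rbind, rows)
  out$capped <- out$t_R_h > t_max
  out$t_R_h <- pmin(out$t_R_h, t_max)
  class(out) <- c("recovery_estimate", class(tibble::tibble()))
  out
}

# --- resampling machinery ---------------------------------------------------
#
# A cluster resample that draws animal k with multiplicity m is equivalent to
# a weighted fit with integer weight m on k's rows: duplicated copies of
# identical data share one optimal offset, and rho_tau(w r) = w rho_tau(r).
# The bootstrap therefore reuses a single design matrix, subsets the rows of
# animals actually drawn, and refits with weights -- much cheaper than
# rebuilding the data each replicate.

qr_boot_context <- function(obs, tau) {
  mm <- qr_model_matrix(obs)
  key <- paste(obs$group, obs$animal_id, sep = "/")
  idx <- split(seq_len(nrow(obs)), key)
  idx <- idx[mm$animals]  # column order
  group_of <- vapply(idx, function(i) obs$group[i[1]], "")
  list(X = mm$X, u = log(obs$y), animals = mm$animals, groups = mm$groups,
       idx = idx, group_of = group_of,
       alpha_cols = paste0("alpha:", mm$groups))
}

draw_animal_counts <- function(ctx) {
  counts <- setNames(integer(length(ctx$animals)), ctx$animals)
  for (g in unique(ctx$group_of)) {
    pool <- names(ctx$group_of)[ctx$group_of == g]
    draw <- sample(pool, length(pool), replace = TRUE)
    tab <- table(draw)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

weighted_alpha <- function(ctx, counts, tau, method) {
  present <- names(counts)[counts > 0]
  rows <- unlist(ctx$idx[present], use.names = FALSE)
  w <- rep(counts[present], lengths(ctx$idx[present]))
  cols <- c(present, ctx$alpha_cols)
  fit <- withCallingHandlers(
    quantreg::rq.wfit(ctx$X[rows, cols, drop = FALSE], ctx$u[rows],
                      tau = tau, weights = as.numeric(w), method = method),
    warning = function(wn) {
      if (grepl("nonunique", conditionMessage(wn))) invokeRestart("muffleWarning")
    }
  )
  a <- fit$coefficients[ctx$alpha_cols]
  names(a) <- ctx$groups
  a
}

# Resample disjoint within-animal time blocks of width block_h (hours),
# keeping each block's original times.
resample_by_block <- function(obs, block_h) {
  take <- integer(0)
  for (id in unique(obs$animal_id)) {
    rows <- which(obs$animal_id == id)
    blk <- split(rows, floor(obs$t_h[rows] / block_h))
    draw <- sample(seq_along(blk), length(blk), replace = TRUE)
    take <- c(take, unlist(blk[draw], use.names = FALSE))
  }
  obs[take, ]
}

refit_alpha <- function(obs, tau, method) {
  d <- structure(list(observations = obs, tau = tau, response = "boot"),
                 class = "qr_design")
  fit_quantile_model(d, tau = tau, method = method)$alpha
}

qr_fit_method <- function(n) if (n <= 20000) "br" else "fn"

#' Bootstrap confidence interval for the return time
#'
#' Percentile 95% interval of [recovery_time()] over resampled fits. The
#' default resampling unit is the animal (cluster bootstrap within each
#' group), which respects between-animal dependence; groups with fewer than
#' three animals fall back to within-animal time blocks, with a warning.
#' Seeded and reproducible; the caller's RNG state is left untouched.
#'
#' @param design a [qr_design()].
#' @param group group whose return time is wanted; default the only group.
#' @param delta recovery threshold, default 0.25.
#' @param n_boot number of bootstrap replicates (>= 200).
#' @param resample `"animal"` (cluster bootstrap, default) or `"block"`
#'   (within-animal time blocks).
#' @param block_h block width in hours for `resample = "block"`.
#' @param seed integer seed.
#' @param level confidence level, default 0.95.
#' @return A one-row `recovery_estimate` with percentile CI; bootstrap
#'   return times are attached as `attr(, "samples")`.
#' @export
bootstrap_ci <- function(design, group = NULL, delta = 0.25, n_boot = 1000,
                         resample = c("animal", "block"), block_h = 6,
                         seed = 1, level = 0.95) {
  stopifnot(inherits(design, "qr_design"), n_boot >= 200)
  resample <- match.arg(resample)
  obs <- design$observations
  tau <- design$tau
  method <- qr_fit_method(nrow(obs))
  fit <- fit_quantile_model(design, method = method)
  if (is.null(group)) {
    if (length(fit$groups) != 1) stop("specify `group`: design has several")
    group <- fit$groups
  }
  point <- recovery_time(fit, group, delta)
  if (resample == "animal" &&
      length(unique(obs$animal_id[obs$group == group])) < 3) {
    warning("fewer than 3 animals in group '", group,
            "'; falling back to within-animal block resampling")
    resample <- "block"
  }
  tR <- function(a) max(0, abs(a) / abs(log(delta)) - 1)
  ctx <- if (resample == "animal") qr_boot_context(obs, tau)
  samples <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      a <- if (resample == "animal") {
        weighted_alpha(ctx, draw_animal_counts(ctx), tau, method)
      } else {
        refit_alpha(resample_by_block(obs, block_h), tau, method)
      }
      tR(a[group])
    }, 0)
  })
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- unname(quantile(samples, pr, type = 7))
  out <- new_recovery_estimate(
    tau, group, delta, point$t_R_h, ci[1], ci[2],
    method = paste0("percentile_bootstrap(", resample, ", n=", n_boot, ")")
  )
  attr(out, "samples") <- samples
  out
}

#' Test equality of recovery slopes
#'
#' Wald-type test that two recovery slopes are equal, either between two
#' groups at the design's quantile level, or between two quantile levels
#' within one group. The standard error of the slope difference comes from
#' a cluster bootstrap by animal (the same resamples are used for both
#' quantile levels in a tau contrast), and the statistic is referred to a
#' Student t distribution with (number of animals - number of groups)
#' degrees of freedom.
#'
#' @param design a [qr_design()] containing all animals involved.
#' @param type `"group"` (compare two groups' slopes at `design$tau`) or
#'   `"tau"` (compare one group's slopes at two quantile levels).
#' @param groups length-2 character vector for `type = "group"`; defaults to
#'   the design's two groups.
#' @param taus length-2 numeric vector for `type = "tau"`.
#' @param group group for `type = "tau"`; defaults to the only group.
#' @param n_boot bootstrap replicates for the covariance, default 500.
#' @param seed integer seed.
#' @return An object of class `slope_test`: list with `contrast`,
#'   `estimate` (slope difference), `se`, `statistic`, `df`, `p_value`,
#'   `n_boot`, `degenerate` (TRUE when the bootstrap variance is zero with a
#'   nonzero difference, in which case `p_value` is `NA`).
#' @export
compare_slopes <- function(design, type = c("group", "tau"), groups = NULL,
                           taus = NULL, group = NULL, n_boot = 500, seed = 1) {
  stopifnot(inherits(design, "qr_design"))
  type <- match.arg(type)
  obs <- design$observations
  method <- qr_fit_method(nrow(obs))
  n_animals <- length(unique(obs$animal_id))
  n_groups <- length(unique(obs$group))
  ctx <- qr_boot_context(obs, design$tau)

  if (type == "group") {
    if (is.null(groups)) {
      groups <- unique(obs$group)
      if (length(groups) != 2) stop("specify `groups` (length 2)")
    }
    fit <- fit_quantile_model(design, method = method)
    est <- unname(fit$alpha[groups[1]] - fit$alpha[groups[2]])
    diff_fun <- function(counts) {
      a <- weighted_alpha(ctx, counts, design$tau, method)
      unname(a[groups[1]] - a[groups[2]])
    }
    contrast <- paste0("alpha[", groups[1], "] - alpha[", groups[2],
                       "] at tau=", design$tau)
  } else {
    if (is.null(taus) || length(taus) != 2) stop("specify `taus` (length 2)")
    if (is.null(group)) {
      group <- unique(obs$group)
      if (length(group) != 1) stop("specify `group`")
    }
    f1 <- fit_quantile_model(design, tau = taus[1], method = method)
    f2 <- fit_quantile_model(design, tau = taus[2], method = method)
    est <- unname(f1$alpha[group] - f2$alpha[group])
    diff_fun <- function(counts) {
      a1 <- weighted_alpha(ctx, counts, taus[1], method)[group]
      a2 <- weighted_alpha(ctx, counts, taus[2], method)[group]
      unname(a1 - a2)
    }
    contrast <- paste0("alpha[", group, "](tau=", taus[1], ") - alpha[",
                       group, "](tau=", taus[2], ")")
  }

  diffs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      diff_fun(draw_animal_counts(ctx))
    }, 0)
  })
  se <- sd(diffs)
  df <- max(1L, n_animals - n_groups)
  degenerate <- (se == 0 && est != 0)
  statistic <- if (se == 0) {
    if (est == 0) 0 else NA_real_
  } else {
    est / se
  }
  p <- if (degenerate) NA_real_ else if (se == 0) 1 else 2 * pt(-abs(statistic), df)
  structure(
    list(contrast = contrast, estimate = est, se = se, statistic = statistic,
         df = df, p_value = p, n_boot = n_boot, degenerate = degenerate),
    class = "slope_test"
  )
}

#' @export
print.slope_test <- function(x, ...) {
  cat("<slope_test>", x$contrast, "\n")
  cat("  diff =", format(x$estimate, digits = 4), " se =",
      format(x$se, digits = 4), " t =", format(x$statistic, digits = 4),
      " df =", x$df, " p =", format.pval(x$p_value, digits = 3), "\n")
  if (x$degenerate) cat("  [degenerate bootstrap variance: p undefined]\n")
  invisible(x)
}
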