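#' Scenario for synthetic accelerometer-metric observations
#'
#' Describes a cohort whose minute-scale log-metric observations follow the
#' decay model with quantile-dependent slopes:
#' `log y = beta_i + (a_g + b_g * eps) * z + eps`, with `z = 1/(t + 1)` and
#' `eps` i.i.d. standard normal. Because the noise enters both the level
#' and the slope, the true `tau`-quantile satisfies the recovery model with
#' slope `alpha_g(tau) = a_g + b_g * qnorm(tau)`: tail and median recover
#' at genuinely different rates, as observed in tagged whales.
#'
#' @param groups named list, one element per group, each a list with decay
#'   parameters `a` (slope at the median) and `b` (slope change per unit of
#'   the noise quantile). Default: a single group with `a = -2.5`,
#'   `b = -1`.
#' @param n_animals animals per group.
#' @param duration_h record duration (hours).
#' @param obs_per_h observations per hour (60 = minute means).
#' @param beta_range range of the uniform draw for per-animal baseline
#'   offsets `beta_i`.
#' @param seed default seed used by [simulate_accel()].
#' @return An object of class `accel_scenario`.
#' @export
accel_scenario <- function(groups = list(all = list(a = -2.5, b = -1)),
                           n_animals = 10, duration_h = 100, obs_per_h = 60,
                           beta_range = c(1, 2), seed = 1) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)),
            n_animals >= 1, duration_h > 0, obs_per_h > 0)
  structure(
    list(groups = groups, n_animals = n_animals, duration_h = duration_h,
         obs_per_h = obs_per_h, beta_range = beta_range, seed = seed),
    class = "accel_scenario"
  )
}

#' True quantile slope and return time of an accelerometer scenario
#'
#' @param sc an [accel_scenario()].
#' @param tau quantile level(s).
#' @param delta recovery threshold for [true_recovery_time()].
#' @return `true_alpha()`: matrix (groups x taus) of slopes
#'   `a_g + b_g * qnorm(tau)`; `true_recovery_time()`: matrix of
#'   `max(0, |alpha|/|log(delta)| - 1)`.
#' @export
true_alpha <- function(sc, tau) {
  stopifnot(inherits(sc, "accel_scenario"))
  out <- vapply(tau, function(tt) {
    vapply(sc$groups, function(g) g$a + g$b * qnorm(tt), 0)
  }, numeric(length(sc$groups)))
  out <- matrix(out, nrow = length(sc$groups),
                dimnames = list(names(sc$groups), tau))
  out
}

#' @rdname true_alpha
#' @export
true_recovery_time <- function(sc, tau, delta = 0.25) {
  a <- true_alpha(sc, tau)
  out <- pmax(0, abs(a) / abs(log(delta)) - 1)  # pmax drops the dim
  array(out, dim = dim(a), dimnames = dimnames(a))
}

#' Simulate accelerometer-metric observations
#'
#' Seeded and reproducible: a pure function of (scenario, seed).
#'
#' @param sc an [accel_scenario()].
#' @param seed integer seed; defaults to the scenario's.
#' @return List with `observations` (tibble: `animal_id`, `group`, `t_h`,
#'   `y`), and `truth` (list: `beta` named per animal, `alpha` and `t_R`
#'   functions of `tau` (and `delta`), `scenario`).
#' @export
simulate_accel <- function(sc, seed = sc$seed) {
  stopifnot(inherits(sc, "accel_scenario"))
  with_seed(seed, {
    t_h <- seq_len(sc$duration_h * sc$obs_per_h) / sc$obs_per_h
    z <- 1 / (t_h + 1)
    pieces <- list()
    beta_all <- numeric(0)
    k <- 0
    for (g in names(sc$groups)) {
      pars <- sc$groups[[g]]
      for (i in seq_len(sc$n_animals)) {
        k <- k + 1
        id <- sprintf("A%02d", k)
        beta <- runif(1, sc$beta_range[1], sc$beta_range[2])
        beta_all[id] <- beta
        eps <- rnorm(length(t_h))
        logy <- beta + (pars$a + pars$b * eps) * z + eps
        pieces[[k]] <- tibble::tibble(animal_id = id, group = g,
                                      t_h = t_h, y = exp(logy))
      }
    }
    list(
      observations = do.call(rbind, pieces),
      truth = list(
        beta = beta_all,
        alpha = function(tau) true_alpha(sc, tau),
        t_R = function(tau, delta = 0.25) true_recovery_time(sc, tau, delta),
        scenario = sc
      )
    )
  })
}

#' Scenario for synthetic dive records
#'
#' Hourly dive counts are Poisson(`dives_per_h`); each dive's target-depth
#' category is drawn from a mixture that relaxes from the perturbed
#' composition `pi0` to the baseline composition `pi_base` at the true
#' recovery hour `t_star` (a step, or an exponential approach with time
#' constant `kappa_h`); durations are lognormal with category-specific
#' medians. The depth ranges and duration parameters are synthetic defaults
#' chosen to be plausible for a deep-diving odontocete, not measured
#' values.
#'
#' @param n_animals number of animals.
#' @param duration_h maximum record duration (hours).
#' @param dives_per_h Poisson rate of dives per hour.
#' @param pi0 perturbed category probabilities (Shallow, Medium, Deep);
#'   shallow-dominated by default, matching the behaviour typically seen
#'   immediately after release.
#' @param pi_base baseline category probabilities.
#' @param t_star true recovery hour.
#' @param transition `"step"` or `"exponential"`.
#' @param kappa_h time constant for the exponential transition.
#' @param duration_medians_s lognormal duration medians per category.
#' @param duration_sdlog lognormal sdlog, shared across categories.
#' @param depth_ranges_m 3x2 matrix of (min, max] target-depth ranges per
#'   category; defaults to the narwhal partition with deep dives up to
#'   660 m.
#' @param drop_times_h record end per animal; default all `duration_h`.
#' @param seed default seed used by [simulate_dives()].
#' @return An object of class `dive_scenario`.
#' @export
dive_scenario <- function(n_animals = 10, duration_h = 100, dives_per_h = 6,
                          pi0 = c(0.90, 0.08, 0.02),
                          pi_base = c(0.40, 0.35, 0.25),
                          t_star = 12, transition = c("step", "exponential"),
                          kappa_h = 6,
                          duration_medians_s = c(120, 420, 720),
                          duration_sdlog = 0.4,
                          depth_ranges_m = rbind(c(20, 160), c(160, 360),
                                                 c(360, 660)),
                          drop_times_h = NULL, seed = 1) {
  transition <- match.arg(transition)
  stopifnot(abs(sum(pi0) - 1) < 1e-8, abs(sum(pi_base) - 1) < 1e-8,
            all(pi0 >= 0), all(pi_base >= 0), dives_per_h > 0,
            length(duration_medians_s) == 3, nrow(depth_ranges_m) == 3)
  if (is.null(drop_times_h)) drop_times_h <- rep(duration_h, n_animals)
  stopifnot(length(drop_times_h) == n_animals, all(drop_times_h <= duration_h))
  structure(
    list(n_animals = n_animals, duration_h = duration_h,
         dives_per_h = dives_per_h, pi0 = pi0, pi_base = pi_base,
         t_star = t_star, transition = transition, kappa_h = kappa_h,
         duration_medians_s = duration_medians_s,
         duration_sdlog = duration_sdlog, depth_ranges_m = depth_ranges_m,
         drop_times_h = drop_times_h, seed = seed),
    class = "dive_scenario"
  )
}

category_mixture <- function(sc, hour) {
  if (sc$transition == "step") {
    if (hour < sc$t_star) sc$pi0 else sc$pi_base
  } else {
    sc$pi_base + (sc$pi0 - sc$pi_base) * exp(-hour / sc$kappa_h)
  }
}

#' Simulate dive records
#'
#' Seeded and reproducible. Dives within an hour are laid out sequentially
#' with random surface gaps, so they never overlap; hours whose drawn
#' durations exceed the hour are thinned from the end.
#'
#' @param sc a [dive_scenario()].
#' @param seed integer seed; defaults to the scenario's.
#' @return List with `dives` (a [dive_table()] pooled over animals),
#'   `record_ends_h` (named per animal) and `truth` (list: `t_star`,
#'   `pi0`, `pi_base`, `scenario`).
#' @export
simulate_dives <- function(sc, seed = sc$seed) {
  stopifnot(inherits(sc, "dive_scenario"))
  cats <- c("Shallow", "Medium", "Deep")
  with_seed(seed, {
    rows <- vector("list", sc$n_animals)
    for (i in seq_len(sc$n_animals)) {
      id <- sprintf("A%02d", i)
      end_h <- floor(sc$drop_times_h[i])
      acc <- list()
      for (h in seq_len(end_h) - 1L) {
        n <- rpois(1, sc$dives_per_h)
        if (n == 0) next
        pi_t <- category_mixture(sc, h)
        ci <- sample.int(3, n, replace = TRUE, prob = pi_t)
        dur <- rlnorm(n, log(sc$duration_medians_s[ci]), sc$duration_sdlog)
        while (length(dur) > 0 && sum(dur) > 3500) {
          dur <- dur[-length(dur)]
          ci <- ci[-length(ci)]
        }
        n <- length(dur)
        if (n == 0) next
        slack <- 3600 - sum(dur)
        gaps <- runif(n + 1)
        gaps <- gaps / sum(gaps) * slack
        starts_s <- h * 3600 + cumsum(gaps[seq_len(n)] + c(0, dur[-n]))
        depth <- runif(n, sc$depth_ranges_m[ci, 1], sc$depth_ranges_m[ci, 2])
        acc[[length(acc) + 1]] <- tibble::tibble(
          animal_id = id, start_h = starts_s / 3600, duration_s = dur,
          target_depth_m = depth, category = cats[ci]
        )
      }
      rows[[i]] <- if (length(acc)) do.call(rbind, acc) else NULL
    }
    keep <- rows[!vapply(rows, is.null, TRUE)]
    df <- if (length(keep)) do.call(rbind, keep) else NULL
    ends <- setNames(sc$drop_times_h,
                     sprintf("A%02d", seq_len(sc$n_animals)))
    list(
      dives = if (is.null(df)) dive_table() else
        dive_table(df$animal_id, df$start_h, df$duration_s,
                   df$target_depth_m, df$category),
      record_ends_h = ends,
      truth = list(t_star = sc$t_star, pi0 = sc$pi0, pi_base = sc$pi_base,
                   scenario = sc)
    )
  })
}

#' Simulate a full cohort and write it in the pipeline's input formats
#'
#' Produces the CSV bundle consumed by [run_pipeline()]: combined
#' accelerometer-metric observations, a dive table, animal metadata and a
#' ground-truth JSON. Animal identities are shared between the two streams,
#' so the accelerometer scenario's total animal count must equal the dive
#' scenario's.
#'
#' @param accel_sc an [accel_scenario()].
#' @param dive_sc a [dive_scenario()] with
#'   `n_animals == length(accel_sc$groups) * accel_sc$n_animals`.
#' @param dir output directory (created if needed).
#' @param seed integer seed (drives both streams).
#' @return Invisibly, a named list of the written file paths.
#' @export
simulate_cohort <- function(accel_sc, dive_sc, dir, seed = 1) {
  n_total <- length(accel_sc$groups) * accel_sc$n_animals
  if (n_total != dive_sc$n_animals) {
    stop("animal counts differ: accel scenario has ", n_total,
         ", dive scenario has ", dive_sc$n_animals)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  acc <- simulate_accel(accel_sc, seed = seed)
  dv <- simulate_dives(dive_sc, seed = seed + 1)
  ids <- names(acc$truth$beta)
  group_of <- vapply(ids, function(id) {
    acc$observations$group[match(id, acc$observations$animal_id)]
  }, "")
  ht <- with_seed(seed + 2, {
    vapply(group_of, function(g) {
      if (tolower(g) %in% c("long")) round(runif(1, 58, 90))
      else round(runif(1, 18, 41))
    }, 0)
  })
  meta <- tibble::tibble(
    animal_id = ids, species = "synthetic", sex = rep_len(c("M", "F"),
                                                          length(ids)),
    handling_time_min = ht, group = group_of,
    record_h = unname(dv$record_ends_h[seq_along(ids)])
  )
  paths <- list(
    accel_obs = file.path(dir, "accel_obs.csv"),
    dives = file.path(dir, "dives.csv"),
    metadata = file.path(dir, "metadata.csv"),
    truth = file.path(dir, "truth.json")
  )
  write.csv(acc$observations, paths$accel_obs, row.names = FALSE)
  write.csv(as.data.frame(dv$dives), paths$dives, row.names = FALSE)
  write.csv(meta, paths$metadata, row.names = FALSE)
  truth <- list(
    alpha = true_alpha(accel_sc, c(0.5, 0.9)),
    t_R = true_recovery_time(accel_sc, c(0.5, 0.9)),
    beta = acc$truth$beta,
    t_star = dive_sc$t_star,
    seed = seed
  )
  jsonlite::write_json(truth, paths$truth, digits = NA, pretty = TRUE)
  invisible(paths)
}
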