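#' Read a pipeline run configuration
#'
#' Reads a YAML run configuration. Recognized keys (all paths relative to
#' `data_dir` unless absolute):
#' \preformatted{
#' species: narwhal           # preset for species_config()
#' seed: 1
#' data_dir: data
#' out_dir: out
#' groups:
#'   covariate: handling_time_min   # column of metadata used to group
#'   threshold: 58                  # < threshold -> "Short", else "Long"
#'   missing: Short                 # group for animals lacking the covariate
#' accel:
#'   observations: accel_obs.csv    # animal_id, group?, t_h, y [, metric]
#'   taus: [0.5, 0.9]
#'   delta: 0.25
#'   n_boot: 500
#' dive:
#'   dives: dives.csv               # dive_table columns
#'   tN: 40
#'   T: 80
#'   block_h: 5
#'   n_boot: 1000
#'   weighting: duration
#' metadata: metadata.csv
#' }
#' Animals whose grouping covariate is missing are assigned to
#' `groups$missing` explicitly — never silently dropped.
#'
#' @param path YAML file path.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$config_path <- normalizePath(path)
  structure(cfg, class = "run_config")
}

resolve_path <- function(p, data_dir) {
  if (is.null(p)) return(NULL)
  if (startsWith(p, "/")) p else file.path(data_dir %||% ".", p)
}

load_metadata <- function(cfg) {
  p <- resolve_path(cfg$metadata, cfg$data_dir)
  if (is.null(p) || !file.exists(p)) return(NULL)
  read.csv(p, stringsAsFactors = FALSE)
}

#' Assign group labels from a metadata covariate
#'
#' Animals are split at `gcfg$threshold` on `gcfg$covariate` (below:
#' `"Short"`, at or above: `"Long"`); animals whose covariate is missing are
#' assigned the explicit `gcfg$missing` group rather than dropped.
#'
#' @param meta metadata data frame with `animal_id` and the covariate column.
#' @param gcfg list with `covariate`, `threshold`, and optionally `missing`.
#' @return Named character vector of group labels, one per animal.
#' @export
assign_groups <- function(meta, gcfg) {
  if (is.null(gcfg) || is.null(meta)) {
    stop("no group assignment possible: provide a `group` column or a ",
         "`groups:` config with metadata")
  }
  cov <- meta[[gcfg$covariate]]
  g <- ifelse(cov < gcfg$threshold, "Short", "Long")
  g[is.na(cov)] <- gcfg$missing %||% "Short"
  setNames(g, meta$animal_id)
}

#' Run the accelerometer (quantile-regression) recovery stage
#'
#' For every metric and quantile level in the configuration: fit the decay
#' model jointly over groups, solve the closed-form return time at the
#' configured `delta`, attach a cluster-bootstrap confidence interval, and
#' test slope equality between groups (per tau) and between quantile
#' levels (per group). Deterministic given the configured seed.
#'
#' @param cfg a [read_run_config()] list (or equivalent list).
#' @return List of class `accel_results`: `estimates` (tibble: one row per
#'   metric x tau x group, Table-2 shaped), `tests` (list of
#'   [compare_slopes()] results), `fits`.
#' @export
run_accel_recovery <- function(cfg) {
  acfg <- cfg$accel
  if (is.null(acfg)) stop("config has no `accel` section")
  p <- resolve_path(acfg$observations, cfg$data_dir)
  if (is.null(p) || !file.exists(p)) {
    warning("accelerometer observations not found (", p %||% "<null>",
            "); skipping accel stage")
    return(NULL)
  }
  obs <- read.csv(p, stringsAsFactors = FALSE)
  if (!"metric" %in% names(obs)) obs$metric <- acfg$metric %||% "VeDBA"
  if (!"group" %in% names(obs)) {
    gmap <- assign_groups(load_metadata(cfg), cfg$groups)
    obs$group <- unname(gmap[as.character(obs$animal_id)])
  }
  taus <- acfg$taus %||% c(0.5, 0.9)
  delta <- acfg$delta %||% 0.25
  n_boot <- acfg$n_boot %||% 500
  seed <- cfg$seed %||% 1
  est <- list()
  tests <- list()
  fits <- list()
  sub_seed <- 0
  for (met in unique(obs$metric)) {
    mobs <- obs[obs$metric == met, ]
    groups <- unique(mobs$group)
    for (tau in taus) {
      design <- qr_design(mobs, tau = tau, response = met)
      fit <- fit_quantile_model(design)
      fits[[paste(met, tau)]] <- fit
      for (g in groups) {
        sub_seed <- sub_seed + 1
        ci <- if (n_boot > 0) {
          bootstrap_ci(design, group = g, delta = delta, n_boot = n_boot,
                       seed = seed + sub_seed)
        } else {
          recovery_time(fit, g, delta)
        }
        est[[length(est) + 1]] <- tibble::tibble(
          metric = met, tau = tau, group = g,
          alpha = unname(fit$alpha[g]), t_R_h = ci$t_R_h,
          ci_lower_h = ci$ci_lower_h, ci_upper_h = ci$ci_upper_h
        )
      }
      if (length(groups) == 2) {
        sub_seed <- sub_seed + 1
        tests[[paste0(met, ":tau", tau, ":group")]] <-
          compare_slopes(design, type = "group", groups = groups,
                         n_boot = max(200, n_boot), seed = seed + sub_seed)
      }
    }
    if (length(taus) == 2) {
      design <- qr_design(mobs, tau = taus[1], response = met)
      for (g in unique(mobs$group)) {
        sub_seed <- sub_seed + 1
        tests[[paste0(met, ":", g, ":tau")]] <-
          compare_slopes(design, type = "tau", taus = taus, group = g,
                         n_boot = max(200, n_boot), seed = seed + sub_seed)
      }
    }
  }
  structure(list(estimates = do.call(rbind, est), tests = tests,
                 fits = fits, delta = delta),
            class = "accel_results")
}

#' Run the dive-profile (relative-entropy) recovery stage
#'
#' Per group: pool the group's dives, build hourly distributions, the
#' drop-point schedule and the weighted reference distribution, compute the
#' hourly Jensen-Shannon divergence series and the leave-one-out region of
#' recovery, label hours, and estimate the return time by the
#' block-bootstrap breakpoint of the cumulative label sum. With several
#' groups the labelling band is the pooled region of recovery, and the
#' per-group bands are also returned for the individual-effect diagnostic
#' (similar band widths suggest the group contrast is not driven by
#' individual differences).
#'
#' @param cfg a [read_run_config()] list.
#' @return List of class `dive_results`: `estimates` (tibble, Table-3
#'   shaped: one row per group), `series` (per-group labelled entropy
#'   series), `ror` (pooled band), `ror_by_group`, `breakpoints`.
#' @export
run_dive_recovery <- function(cfg) {
  dcfg <- cfg$dive
  if (is.null(dcfg)) stop("config has no `dive` section")
  p <- resolve_path(dcfg$dives, cfg$data_dir)
  if (is.null(p) || !file.exists(p)) stop("dive table not found: ", p)
  df <- read.csv(p, stringsAsFactors = FALSE)
  dives <- dive_table(df$animal_id, df$start_h, df$duration_s,
                      df$target_depth_m, df$category)
  meta <- load_metadata(cfg)
  if (!is.null(meta) && "group" %in% names(meta)) {
    gmap <- setNames(meta$group, meta$animal_id)
  } else if (!is.null(meta) && !is.null(cfg$groups)) {
    gmap <- assign_groups(meta, cfg$groups)
  } else {
    gmap <- setNames(rep("all", length(unique(dives$animal_id))),
                     unique(dives$animal_id))
  }
  if (!is.null(meta)) {
    rec_ends <- setNames(meta$record_h, meta$animal_id)
  } else {
    rec_ends <- tapply(dives$start_h + dives$duration_s / 3600,
                       dives$animal_id, function(x) ceiling(max(x)))
  }
  tN <- dcfg$tN %||% 40
  T_h <- dcfg$T %||% 80
  block_h <- dcfg$block_h %||% 5
  n_boot <- dcfg$n_boot %||% 1000
  weighting <- dcfg$weighting %||% "duration"
  seed <- cfg$seed %||% 1
  if (!any(rec_ends > tN)) {
    stop("normal region empty: no record extends beyond tN = ", tN, " h")
  }
  groups <- unique(unname(gmap[unique(dives$animal_id)]))
  per_group <- list()
  for (g in groups) {
    ids <- names(gmap)[gmap == g]
    gd <- dives[dives$animal_id %in% ids, ]
    class(gd) <- class(dives)
    hourly <- hourly_distributions(gd, weighting = weighting)
    schedule <- build_schedule(unname(rec_ends[ids]), tN)
    ref <- reference_distribution(hourly, schedule)
    per_group[[g]] <- list(
      hourly = hourly, schedule = schedule, ref = ref,
      es = entropy_series(hourly, ref),
      ror = region_of_recovery(hourly, schedule, T_h)
    )
  }
  band <- if (length(groups) > 1) {
    do.call(combine_ror, lapply(per_group, `[[`, "ror"))
  } else {
    per_group[[1]]$ror
  }
  est <- list()
  series <- list()
  bps <- list()
  for (g in groups) {
    es <- per_group[[g]]$es
    labs <- label_series(es[es$hour <= T_h, ], band)
    bp <- block_bootstrap_breakpoint(labs, block_h = block_h,
                                     n_boot = n_boot,
                                     seed = (cfg$seed %||% 1) + match(g, groups))
    series[[g]] <- labs
    bps[[g]] <- bp
    est[[length(est) + 1]] <- tibble::tibble(
      group = g, t_R_h = bp$t_R_h, ci_lower_h = bp$ci_lower_h,
      ci_upper_h = bp$ci_upper_h, n_boot = bp$n_boot,
      n_dropped = bp$n_dropped, detected = bp$detected
    )
  }
  structure(
    list(estimates = do.call(rbind, est), series = series, ror = band,
         ror_by_group = lapply(per_group, `[[`, "ror"),
         breakpoints = bps, tN = tN, T_h = T_h),
    class = "dive_results"
  )
}

#' Write pipeline results to disk
#'
#' Emits Table-2-shaped (`accel_estimates.csv`) and Table-3-shaped
#' (`dive_estimates.csv`) CSVs, JSON result records, optional diagnostic
#' plots, and a run manifest (config echo, seed, package and R versions)
#' for reproducibility.
#'
#' @param results list with elements `accel` ([run_accel_recovery()]
#'   output or NULL) and `dive` ([run_dive_recovery()] output or NULL).
#' @param out_dir output directory (created if needed).
#' @param cfg the run configuration, echoed into the manifest.
#' @param plots logical: write ggplot diagnostics?
#' @return Invisibly, the vector of written paths.
#' @export
write_report <- function(results, out_dir, cfg = NULL, plots = FALSE) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  written <- character(0)
  wr <- function(p) {
    written <<- c(written, p)
    p
  }
  if (!is.null(results$accel)) {
    write.csv(results$accel$estimates,
              wr(file.path(out_dir, "accel_estimates.csv")), row.names = FALSE)
    tst <- lapply(results$accel$tests, function(t) {
      t[c("contrast", "estimate", "se", "statistic", "df", "p_value")]
    })
    jsonlite::write_json(
      list(estimates = results$accel$estimates, tests = tst,
           delta = results$accel$delta),
      wr(file.path(out_dir, "accel_results.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(results$dive)) {
    write.csv(results$dive$estimates,
              wr(file.path(out_dir, "dive_estimates.csv")), row.names = FALSE)
    jsonlite::write_json(
      list(estimates = results$dive$estimates,
           ror = results$dive$ror[c("lo", "hi", "level")],
           ror_by_group = lapply(results$dive$ror_by_group,
                                 function(r) r[c("lo", "hi")]),
           tN = results$dive$tN, T = results$dive$T_h),
      wr(file.path(out_dir, "dive_results.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (plots) {
      for (g in names(results$dive$series)) {
        gp <- plot_entropy_series(results$dive$series[[g]],
                                  results$dive$ror,
                                  results$dive$breakpoints[[g]])
        ggplot2::ggsave(wr(file.path(out_dir, paste0("entropy_", g, ".pdf"))),
                        gp, width = 8, height = 4)
      }
    }
  }
  manifest <- list(
    package = "tagrecover",
    version = as.character(packageVersion("tagrecover")),
    r_version = R.version.string,
    seed = cfg$seed %||% NA,
    config = unclass(cfg)
  )
  jsonlite::write_json(manifest, wr(file.path(out_dir, "manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(written)
}

#' Run the full recovery pipeline from a configuration
#'
#' Orchestrates simulate -> quantile-regression stage -> relative-entropy
#' stage -> report. Stages whose inputs or config sections are absent are
#' skipped with a message.
#'
#' @param config path to a YAML config, or a `run_config`-like list.
#' @param stage one of `"all"`, `"simulate"`, `"qr"`, `"entropy"`.
#' @param seed optional override of the config seed.
#' @param out_dir optional override of the config output directory.
#' @param plots write diagnostic plots, default `FALSE`.
#' @return List of class `pipeline_results` with `accel`, `dive`, and the
#'   paths written.
#' @export
run_pipeline <- function(config, stage = c("all", "simulate", "qr", "entropy"),
                         seed = NULL, out_dir = NULL, plots = FALSE) {
  stage <- match.arg(stage)
  cfg <- if (is.character(config)) read_run_config(config) else config
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (stage %in% c("all", "simulate") && !is.null(cfg$simulate)) {
    asc <- do.call(accel_scenario, cfg$simulate$accel %||% list())
    dsc <- do.call(dive_scenario, cfg$simulate$dive %||% list())
    simulate_cohort(asc, dsc, cfg$data_dir %||% ".", seed = cfg$seed %||% 1)
    message("simulated cohort written to ", cfg$data_dir %||% ".")
  }
  accel <- dive <- NULL
  if (stage %in% c("all", "qr") && !is.null(cfg$accel)) {
    accel <- run_accel_recovery(cfg)
  }
  if (stage %in% c("all", "entropy") && !is.null(cfg$dive)) {
    dive <- run_dive_recovery(cfg)
  }
  results <- list(accel = accel, dive = dive)
  paths <- if (!is.null(cfg$out_dir)) {
    write_report(results, cfg$out_dir, cfg = cfg, plots = plots)
  } else {
    character(0)
  }
  structure(c(results, list(paths = paths)), class = "pipeline_results")
}
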