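test_that("true quantile slopes follow the noise-quantile arithmetic", {
  sc <- accel_scenario()  # a = -2.5, b = -1
  expect_equal(true_alpha(sc, 0.5)[1, 1], -2.5)
  expect_equal(true_alpha(sc, 0.9)[1, 1], -2.5 - qnorm(0.9))
  expect_equal(true_alpha(sc, 0.9)[1, 1], -3.7816, tolerance = 1e-4)

  flat <- accel_scenario(groups = list(g = list(a = -2, b = 0)))
  expect_equal(true_alpha(flat, 0.5)[1, 1], true_alpha(flat, 0.9)[1, 1])

  none <- accel_scenario(groups = list(g = list(a = 0, b = 0)))
  expect_equal(true_recovery_time(none, c(0.5, 0.9))[1, ],
               setNames(c(0, 0), c(0.5, 0.9)))
})

test_that("a null accelerometer scenario yields near-zero fitted effects", {
  sc <- accel_scenario(groups = list(g = list(a = 0, b = 0)),
                       n_animals = 4, duration_h = 60, obs_per_h = 20)
  sim <- simulate_accel(sc, seed = 8)
  fit <- fit_quantile_model(qr_design(sim$observations, 0.5))
  expect_lt(abs(unname(fit$alpha)), 0.15)
  expect_lt(recovery_time(fit, "g", 0.25)$t_R_h, 0.2)
})

test_that("generators are pure functions of scenario and seed", {
  sc <- accel_scenario(n_animals = 3, duration_h = 10, obs_per_h = 10)
  s1 <- simulate_accel(sc, seed = 5)
  s2 <- simulate_accel(sc, seed = 5)
  expect_identical(s1$observations, s2$observations)
  s3 <- simulate_accel(sc, seed = 6)
  expect_false(identical(s1$observations$y, s3$observations$y))

  dsc <- dive_scenario(n_animals = 3, duration_h = 20)
  d1 <- simulate_dives(dsc, seed = 5)
  d2 <- simulate_dives(dsc, seed = 5)
  expect_identical(d1$dives, d2$dives)

  # the caller's RNG stream is not consumed
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_accel(sc, seed = 5)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("simulated dives respect their declared laws", {
  sc <- dive_scenario(n_animals = 10, duration_h = 40, t_star = 12,
                      dives_per_h = 6)
  sim <- simulate_dives(sc, seed = 9)
  dv <- sim$dives
  expect_true(all(dv$duration_s > 0))
  expect_true(all(dv$target_depth_m > 20))
  # non-overlap within animal
  for (id in unique(dv$animal_id)) {
    d <- dv[dv$animal_id == id, ]
    expect_true(all(diff(d$start_h) * 3600 >= head(d$duration_s, -1) - 1e-6))
  }
  # post-changepoint category proportions approach the baseline composition
  late <- dv[dv$start_h >= 12, ]
  props <- as.numeric(table(late$category) / nrow(late))
  expect_true(all(abs(props - sc$pi_base) < 0.05))
  # pre-changepoint proportions follow the perturbed composition
  early <- dv[dv$start_h < 12, ]
  expect_gt(mean(early$category == "Shallow"), 0.8)
  # Poisson rate within 3 standard errors
  n_hours <- 40 * 10
  rate <- nrow(dv) / n_hours
  expect_lt(abs(rate - 6), 3 * sqrt(6 / n_hours) + 0.35)  # small thinning loss
})

test_that("cohort simulation writes a readable, reproducible bundle", {
  dir1 <- file.path(tempdir(), "cohort1")
  dir2 <- file.path(tempdir(), "cohort2")
  asc <- accel_scenario(groups = list(Long = list(a = -3, b = -0.5),
                                      Short = list(a = -0.5, b = -0.2)),
                        n_animals = 2, duration_h = 12, obs_per_h = 4)
  dsc <- dive_scenario(n_animals = 4, duration_h = 12, t_star = 3,
                       drop_times_h = c(12, 12, 10, 8))
  p1 <- simulate_cohort(asc, dsc, dir1, seed = 3)
  p2 <- simulate_cohort(asc, dsc, dir2, seed = 3)
  for (f in c("accel_obs", "dives", "metadata")) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  obs <- read.csv(p1$accel_obs)
  expect_equal(length(unique(obs$animal_id)), 4L)
  expect_equal(max(obs$t_h), 12)
  meta <- read.csv(p1$metadata)
  expect_equal(nrow(meta), 4L)
  expect_equal(sort(unique(meta$group)), c("Long", "Short"))
  expect_true(all(meta$handling_time_min[meta$group == "Long"] >= 58))
  expect_true(all(meta$handling_time_min[meta$group == "Short"] < 58))
  expect_equal(meta$record_h, c(12, 12, 10, 8))
  # staggered drops reproduce the documented schedule weights
  s <- build_schedule(c(60, 100), tN = 40)
  expect_equal(s$w, c(2 / 3, 1 / 3))

  expect_error(simulate_cohort(asc, dive_scenario(n_animals = 3), tempdir()),
               "counts differ")
})
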