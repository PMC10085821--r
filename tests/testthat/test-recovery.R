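fake_fit <- function(alpha, tau = 0.5) {
  structure(list(tau = tau, alpha = setNames(alpha, "g"), groups = "g",
                 beta_ind = c(a = 0), loss = 0, n_obs = 0, method = "br",
                 response = "VeDBA"),
            class = "qr_fit")
}

test_that("closed-form return time matches the recovery equation", {
  expect_equal(recovery_time(fake_fit(log(0.25)), "g", 0.25)$t_R_h, 0)
  expect_equal(recovery_time(fake_fit(2 * log(0.25)), "g", 0.25)$t_R_h, 1)
  expect_equal(recovery_time(fake_fit(0), "g", 0.25)$t_R_h, 0)
  # elevated responses are treated symmetrically
  expect_equal(recovery_time(fake_fit(-3), "g", 0.25)$t_R_h,
               recovery_time(fake_fit(3), "g", 0.25)$t_R_h)
})

test_that("return-time curve follows the closed form and is monotone", {
  cur <- recovery_curve(fake_fit(-3), "g", c(0.1, 0.25, 0.5))
  expect_equal(cur$t_R_h, c(0.303, 1.164, 3.328), tolerance = 1e-3)
  # reaching a stricter fraction of baseline (delta closer to 1) takes longer
  grid <- recovery_curve(fake_fit(-2.2), "g", seq(0.05, 0.95, 0.05))
  expect_true(all(diff(grid$t_R_h) >= -1e-12))
  expect_equal(recovery_curve(fake_fit(-1.7), "g", exp(-1.7))$t_R_h, 0)
  capped <- recovery_curve(fake_fit(-4), "g", c(0.9, 0.99), t_max = 50)
  expect_true(capped$capped[2])
  expect_lte(max(capped$t_R_h), 50)
})

test_that("noiseless cohorts give a zero-width bootstrap interval", {
  t_h <- seq(0.5, 30, by = 0.5)
  obs <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(animal_id = paste0("a", i), group = "g", t_h = t_h,
               y = exp(0.5 * i - 2 / (t_h + 1)))
  }))
  ci <- bootstrap_ci(qr_design(obs, 0.5), delta = 0.25, n_boot = 200, seed = 3)
  expect_equal(ci$ci_lower_h, ci$ci_upper_h, tolerance = 1e-6)
  expect_equal(ci$t_R_h, 2 / abs(log(0.25)) - 1, tolerance = 1e-6)
})

test_that("bootstrap interval is reproducible for a fixed seed", {
  sim <- simulate_accel(accel_scenario(n_animals = 4, duration_h = 30,
                                       obs_per_h = 6), seed = 10)
  d <- qr_design(sim$observations, 0.5)
  c1 <- bootstrap_ci(d, delta = 0.25, n_boot = 200, seed = 99)
  c2 <- bootstrap_ci(d, delta = 0.25, n_boot = 200, seed = 99)
  expect_identical(c1$ci_lower_h, c2$ci_lower_h)
  expect_identical(c1$ci_upper_h, c2$ci_upper_h)
  c3 <- bootstrap_ci(d, delta = 0.25, n_boot = 200, seed = 100)
  expect_false(identical(attr(c3, "samples"), attr(c1, "samples")))
})

test_that("groups with too few animals fall back to block resampling", {
  sim <- simulate_accel(accel_scenario(n_animals = 2, duration_h = 30,
                                       obs_per_h = 6), seed = 12)
  d <- qr_design(sim$observations, 0.5)
  expect_warning(ci <- bootstrap_ci(d, delta = 0.25, n_boot = 200, seed = 1),
                 "fewer than 3")
  expect_match(ci$method, "block")
})

test_that("identical groups give a zero statistic and p-value one", {
  sim <- simulate_accel(accel_scenario(n_animals = 3, duration_h = 30,
                                       obs_per_h = 6), seed = 14)
  obs <- sim$observations
  twin <- rbind(transform(obs, group = "g1"), transform(obs, group = "g2"))
  st <- compare_slopes(qr_design(twin, 0.5), type = "group",
                       groups = c("g1", "g2"), n_boot = 200, seed = 5)
  expect_equal(st$statistic, 0)
  expect_equal(st$p_value, 1)
})

test_that("strongly different group slopes are detected", {
  sc <- accel_scenario(groups = list(long = list(a = -3, b = 0),
                                     short = list(a = -0.3, b = 0)),
                       n_animals = 6, duration_h = 36, obs_per_h = 6)
  hits <- 0
  for (r in 1:5) {
    sim <- simulate_accel(sc, seed = 500 + r)
    st <- compare_slopes(qr_design(sim$observations, 0.5), type = "group",
                         groups = c("long", "short"), n_boot = 200, seed = r)
    hits <- hits + (st$p_value < 0.05)
  }
  expect_gte(hits, 4)
})

test_that("tau contrasts reuse the same resamples and detect slope spread", {
  sc <- accel_scenario(groups = list(g = list(a = -2.5, b = -1)),
                       n_animals = 6, duration_h = 36, obs_per_h = 10)
  sim <- simulate_accel(sc, seed = 77)
  st <- compare_slopes(qr_design(sim$observations, 0.5), type = "tau",
                       taus = c(0.5, 0.9), group = "g", n_boot = 200, seed = 2)
  # true difference is -b * qnorm(0.9) = 1.28
  expect_lt(st$p_value, 0.05)
  expect_equal(st$estimate, qnorm(0.9), tolerance = 0.35)
})
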