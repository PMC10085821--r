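mk_dives <- function(hour, cats, durs, id = "a") {
  dive_table(animal_id = rep(id, length(cats)),
             start_h = hour + seq_along(cats) * 0.01,
             duration_s = durs, target_depth_m = c(Shallow = 50, Medium = 200,
                                                   Deep = 400)[cats],
             category = cats)
}

test_that("hourly distributions are duration-weighted proportions", {
  dv <- mk_dives(3, c("Shallow", "Medium", "Deep"), c(120, 60, 20))
  h <- hourly_distributions(dv)
  expect_equal(h$hour, 3L)
  expect_equal(c(h$Shallow, h$Medium, h$Deep), c(0.6, 0.3, 0.1))
  expect_equal(h$n_dives, 3L)

  single <- hourly_distributions(mk_dives(5, "Shallow", 300))
  expect_equal(c(single$Shallow, single$Medium, single$Deep), c(1, 0, 0))

  empty <- hourly_distributions(dive_table())
  expect_equal(nrow(empty), 0L)
})

test_that("count weighting differs from duration weighting when durations differ", {
  dv <- mk_dives(0, c("Shallow", "Shallow", "Deep"), c(10, 10, 80))
  dur <- hourly_distributions(dv, weighting = "duration")
  cnt <- hourly_distributions(dv, weighting = "count")
  expect_equal(c(dur$Shallow, dur$Medium, dur$Deep), c(0.2, 0, 0.8))
  expect_equal(c(cnt$Shallow, cnt$Medium, cnt$Deep), c(2 / 3, 0, 1 / 3))
})

test_that("drop schedules weight by the number of active animals", {
  s <- build_schedule(c(60, 100), tN = 40)
  expect_equal(s$drops, c(60, 100))
  expect_equal(s$n, c(2L, 1L))
  expect_equal(s$w, c(2 / 3, 1 / 3))

  single <- build_schedule(80, tN = 40)
  expect_equal(single$w, 1)

  s3 <- build_schedule(c(50, 50, 90), tN = 40)
  expect_equal(s3$drops, c(50, 90))
  expect_equal(s3$n, c(3L, 1L))
  expect_equal(s3$w, c(0.75, 0.25))

  expect_error(build_schedule(c(10, 20), tN = 40), "normal region")
})

hourly_from_p <- function(hours, p) {
  # build an hourly_dist with prescribed probability rows
  out <- tibble::tibble(hour = as.integer(hours),
                        Shallow = p[, 1], Medium = p[, 2], Deep = p[, 3],
                        n_dives = 10L, n_animals = 3L, total_s = 1000)
  class(out) <- c("hourly_dist", class(out))
  out
}

test_that("reference distribution is the drop-weighted segment average", {
  p_star <- c(0.5, 0.3, 0.2)
  h <- hourly_from_p(41:90, matrix(p_star, 50, 3, byrow = TRUE))
  s <- build_schedule(c(50, 50, 90), tN = 40)
  expect_equal(unname(reference_distribution(h, s)$q), p_star)

  # two equal-weight segments with different means (weights set by hand)
  h2 <- hourly_from_p(41:60, rbind(matrix(c(1, 0, 0), 10, 3, byrow = TRUE),
                                   matrix(c(0, 1, 0), 10, 3, byrow = TRUE)))
  s2 <- structure(list(tN = 40, drops = c(50, 60), n = c(1L, 1L),
                       w = c(0.5, 0.5)), class = "drop_schedule")
  expect_equal(unname(reference_distribution(h2, s2)$q), c(0.5, 0.5, 0))

  # staggered weights 0.75 / 0.25
  h3 <- hourly_from_p(41:90,
                      rbind(matrix(c(0.8, 0.1, 0.1), 10, 3, byrow = TRUE),
                            matrix(c(0.2, 0.4, 0.4), 40, 3, byrow = TRUE)))
  q3 <- reference_distribution(h3, s)$q
  expect_equal(unname(q3), c(0.65, 0.175, 0.175))
  expect_equal(sum(q3), 1)
})

test_that("segments without hours have their weight redistributed", {
  h <- hourly_from_p(81:90, matrix(c(0.2, 0.4, 0.4), 10, 3, byrow = TRUE))
  s <- build_schedule(c(50, 90), tN = 40)
  expect_warning(q <- reference_distribution(h, s)$q, "redistributed")
  expect_equal(unname(q), c(0.2, 0.4, 0.4))
})

test_that("leave-one-out exclusion removes exactly one hour", {
  h <- hourly_from_p(41:60, rbind(matrix(c(1, 0, 0), 1, 3),
                                  matrix(c(0.5, 0.25, 0.25), 19, 3,
                                         byrow = TRUE)))
  s <- build_schedule(60, tN = 40)
  q_all <- reference_distribution(h, s)$q
  q_loo <- reference_distribution(h, s, exclude_hour = 41)$q
  expect_equal(unname(q_loo), c(0.5, 0.25, 0.25))
  expect_gt(q_all[1], q_loo[1])
})

test_that("KL divergence follows the base-2 formula with its conventions", {
  p <- c(0.5, 0.5, 0)
  expect_equal(kl_divergence(p, p), 0)
  expect_equal(kl_divergence(p, c(0.25, 0.75, 0)), 0.2075, tolerance = 1e-4)
  expect_equal(kl_divergence(c(1, 0, 0), c(0, 1, 0)), Inf)
  expect_error(kl_divergence(c(0.5, 0.6, 0), p), "sum to 1")
})

test_that("JS divergence identities hold and match the hand-derived value", {
  p <- c(0.2, 0.5, 0.3)
  q <- c(0.6, 0.1, 0.3)
  expect_equal(js_divergence(p, p), 0)
  expect_equal(js_divergence(p, q), js_divergence(q, p))
  expect_equal(js_divergence(c(1, 0, 0), c(0, 1, 0)), 1)
  expect_equal(js_divergence(c(1, 0, 0), c(0.5, 0.5, 0)), 0.3113,
               tolerance = 1e-4)
})

test_that("JS divergence is bounded and its square root behaves as a metric", {
  set.seed(9)
  for (i in 1:50) {
    ps <- lapply(1:3, function(.) {
      x <- rexp(3)
      x / sum(x)
    })
    j12 <- js_divergence(ps[[1]], ps[[2]])
    j13 <- js_divergence(ps[[1]], ps[[3]])
    j23 <- js_divergence(ps[[2]], ps[[3]])
    expect_true(all(c(j12, j13, j23) >= 0 & c(j12, j13, j23) <= 1))
    expect_lte(sqrt(j12), sqrt(j13) + sqrt(j23) + 1e-12)
  }
})

test_that("region of recovery uses the empirical 95% band, closed at both ends", {
  h <- hourly_from_p(41:80, matrix(c(0.5, 0.3, 0.2), 40, 3, byrow = TRUE))
  s <- build_schedule(80, tN = 40)
  r <- region_of_recovery(h, s, 80)
  expect_equal(r$lo, r$hi)  # identical divergences collapse the band

  # the quantile rule on the synthetic sequence 0.01, 0.02, ..., 0.40
  vals <- 0.01 * (1:40)
  band <- unname(quantile(vals, c(0.025, 0.975), type = 7))
  # type-7 interpolation: lower 0.01 + 0.975 * 0.01, upper 0.39 + 0.025 * 0.01
  expect_equal(band, c(0.019750, 0.390250), tolerance = 1e-9)

  es <- entropy_series(h, reference_distribution(h, s))
  labs <- label_series(es, structure(list(lo = 0.01, hi = 0.1), class = "ror"))
  expect_true(all(labs$label == -1L))  # constant J = 0 below the band
  labs2 <- label_series(es, structure(list(lo = 0, hi = 0.1), class = "ror"))
  expect_true(all(labs2$label == 1L))
  # boundary values are inside (closed interval)
  es_fixed <- structure(tibble::tibble(hour = 1:2, J = c(0.1, 0.100001)),
                        class = c("entropy_series", class(tibble::tibble())))
  lb <- label_series(es_fixed, structure(list(lo = 0, hi = 0.1), class = "ror"))
  expect_equal(lb$label, c(1L, -1L))
})

test_that("widening the upper limit never loses source hours", {
  dv <- simulate_dives(dive_scenario(n_animals = 4, duration_h = 80,
                                     t_star = 5), seed = 30)
  h <- hourly_distributions(dv$dives)
  s <- build_schedule(dv$record_ends_h, 40)
  r60 <- region_of_recovery(h, s, 60)
  r80 <- region_of_recovery(h, s, 80)
  expect_gte(length(r80$hours), length(r60$hours))
  expect_true(all(r60$hours %in% r80$hours))
})

test_that("leave-one-out divergences converge to the plain-reference ones", {
  gap <- function(n_hours) {
    sc <- dive_scenario(n_animals = 6, duration_h = n_hours + 41,
                        pi0 = c(0.4, 0.35, 0.25), t_star = 0)
    dv <- simulate_dives(sc, seed = 44)
    h <- hourly_distributions(dv$dives)
    s <- build_schedule(dv$record_ends_h, 40)
    ref <- reference_distribution(h, s)
    r <- region_of_recovery(h, s, 41 + n_hours)
    es <- entropy_series(h, ref)
    j_ref <- es$J[match(r$hours, es$hour)]
    max(abs(r$j_loo - j_ref))
  }
  expect_lt(gap(80), gap(15))
})

test_that("pooled recovery bands cover the union of group divergences", {
  dv <- simulate_dives(dive_scenario(n_animals = 8, duration_h = 90,
                                     t_star = 8), seed = 51)
  dives <- dv$dives
  ids <- unique(dives$animal_id)
  gA <- dives[dives$animal_id %in% ids[1:4], ]; class(gA) <- class(dives)
  gB <- dives[dives$animal_id %in% ids[5:8], ]; class(gB) <- class(dives)
  mk <- function(g, ids_g) {
    h <- hourly_distributions(g)
    s <- build_schedule(dv$record_ends_h[ids_g], 40)
    region_of_recovery(h, s, 85)
  }
  rA <- mk(gA, ids[1:4]); rB <- mk(gB, ids[5:8])
  pooled <- combine_ror(rA, rB)
  expect_equal(length(pooled$j_loo), length(rA$j_loo) + length(rB$j_loo))
  expect_gte(pooled$hi, min(rA$hi, rB$hi) - 1e-12)
  expect_lte(pooled$lo, max(rA$lo, rB$lo) + 1e-12)
})
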