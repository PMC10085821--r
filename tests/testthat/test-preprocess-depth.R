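cfg <- species_config("narwhal")

test_that("zero-offset correction maps constant traces to zero and is shift-equivariant", {
  d <- depth_trace(rep(2, 3600), fs = 1)
  dc <- zero_offset_correct(d, cfg)
  expect_true(dc$corrected)
  expect_equal(dc$depth, rep(0, 3600))

  set.seed(42)
  depth <- pmax(0, cumsum(rnorm(3600, sd = 0.5)))
  a <- zero_offset_correct(depth_trace(depth, fs = 1), cfg)
  b <- zero_offset_correct(depth_trace(depth + 11.3, fs = 1), cfg)
  expect_equal(a$depth, b$depth, tolerance = 1e-12)
})

test_that("sawtooth surface noise around a slow drift is corrected to near zero", {
  n <- 21600  # 6 h @ 1 Hz, all surface
  depth <- seq(0, 3, length.out = n) + rep(c(-1, 0, 1, 0), length.out = n)
  dc <- zero_offset_correct(depth_trace(depth, fs = 1), cfg)
  interior <- 1801:(n - 1800)
  expect_lt(max(abs(dc$depth[interior])), 0.2)
})

test_that("surface level is recovered in records containing dives", {
  n <- 21600
  depth <- seq(0, 3, length.out = n) + rep(c(-1, 0, 1, 0), length.out = n)
  starts <- seq(2000, 20000, by = 3000)
  for (s in starts) depth[s:(s + 600)] <- depth[s:(s + 600)] + 150
  dc <- zero_offset_correct(depth_trace(depth, fs = 1), cfg)
  surf <- setdiff(which(depth < 50), unlist(lapply(starts, function(s)
    (s - 10):(s + 610))))
  surf <- surf[surf > 1800 & surf < n - 1800]
  expect_lt(max(abs(dc$depth[surf])), 0.2)
  # invariant: low quantile of corrected surface windows sits at ~0
  expect_lt(abs(quantile(dc$depth[2700:4500], 0.01)), 0.2)
})

test_that("correction rejects unusable traces", {
  expect_error(zero_offset_correct(depth_trace(rep(1, 100), fs = 1), cfg),
               "shorter")
  bad <- depth_trace(c(rep(1, 3599), NA), fs = 1)
  expect_error(zero_offset_correct(bad, cfg), "non-finite")
})

test_that("raw-minus-second-filter variant is offered", {
  d <- depth_trace(rep(2, 3600), fs = 1)
  dc <- zero_offset_correct(d, cfg, method = "raw_minus_f2")
  expect_equal(dc$depth, rep(0, 3600))
})

test_that("resampling averages down, duplicates up, truncates partial blocks", {
  expect_equal(resample(c(1, 2, 3, 4), 2, 1), c(1.5, 3.5))
  expect_equal(resample(c(1, 2), 1, 2), c(1, 1, 2, 2))
  expect_equal(resample(c(1, 2, 3, 4, 5), 2, 1), c(1.5, 3.5))
  expect_error(resample(1:10, 3, 2), "not an integer")
})

test_that("upsample then downsample by the same ratio is the identity", {
  set.seed(7)
  for (k in c(2, 3, 5)) {
    x <- rnorm(40)
    expect_equal(resample(resample(x, 1, k), k, 1), x)
  }
})

test_that("dive segmentation follows the run rule and discards open dives", {
  d <- depth_trace(c(0, 5, 25, 40, 30, 10, 0), fs = 1, corrected = TRUE)
  dt <- segment_dives(d, cfg)
  expect_equal(nrow(dt), 1L)
  expect_equal(dt$duration_s, 3)
  expect_equal(dt$target_depth_m, 40)
  expect_equal(as.character(dt$category), "Shallow")
  expect_equal(dt$start_h, 2 / 3600)

  shallow <- depth_trace(c(0, 5, 18, 20, 3), fs = 1, corrected = TRUE)
  expect_equal(nrow(segment_dives(shallow, cfg)), 0L)

  # dives open at the record boundaries are unusable
  open_ended <- depth_trace(c(30, 40, 5, 25, 30, 5, 100, 200), fs = 1,
                            corrected = TRUE)
  dt2 <- segment_dives(open_ended, cfg)
  expect_equal(nrow(dt2), 1L)
  expect_equal(dt2$target_depth_m, 30)

  expect_warning(segment_dives(depth_trace(c(0, 30, 0), fs = 1), cfg),
                 "uncorrected")
})

test_that("target-depth categories use the configured edges, right-closed", {
  expect_equal(as.character(assign_depth_category(c(160, 200, 360, 361), cfg)),
               c("Shallow", "Medium", "Medium", "Deep"))
  bw <- species_config("bowhead")
  expect_equal(as.character(assign_depth_category(c(59, 100, 150), bw)),
               c("Shallow", "Medium", "Deep"))
})

test_that("dive durations never exceed the record and depths exceed the threshold", {
  set.seed(13)
  depth <- 25 * pmax(0, sin(seq(0, 40 * pi, length.out = 5000))) +
    rnorm(5000, sd = 2)
  d <- depth_trace(depth, fs = 1, corrected = TRUE)
  dt <- segment_dives(d, cfg)
  expect_lte(sum(dt$duration_s), 5000)
  expect_true(all(dt$target_depth_m > cfg$surface_threshold_m))
  expect_true(all(diff(dt$start_h) > 0))
})
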