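# Synthetic generator: reproducibility, closed-form thermodynamics, target
# statistics, and ground-truth consistency.

test_that("generation is bit-reproducible per seed and preserves caller RNG", {
  cfg <- synthetic_config(seed = 5, duration_h = 6, sleep_blocks = NULL,
                          n_removals = 1)
  set.seed(999)
  before <- .Random.seed
  g1 <- generate_recording(cfg)
  expect_identical(.Random.seed, before)
  g2 <- generate_recording(cfg)
  expect_identical(g1$recording$accel, g2$recording$accel)
  expect_identical(g1$recording$temp, g2$recording$temp)
  expect_identical(as.data.frame(g1$truth), as.data.frame(g2$truth))
  g3 <- generate_recording(synthetic_config(seed = 6, duration_h = 6,
                                            sleep_blocks = NULL,
                                            n_removals = 1))
  expect_false(identical(g1$recording$temp, g3$recording$temp))
})

test_that("noise-free removal cooling matches the Newtonian closed form", {
  n <- 900
  state <- rep("sedentary", n)
  state[301:600] <- "nonwear"
  sch <- list(state = state, n = n, cell_s = 4,
              removals = data.frame(start = 301L, end = 601L),
              artifacts = data.frame(start = integer(0), end = integer(0),
                                     sd = numeric(0)))
  cfg <- synthetic_config(temp_noise_sd = 0, skin_c_sd = 0)
  temp <- simulate_temperature(sch, cfg, skin_c = 31, sleep_c = 31.5)
  t_min <- (0:299) * 4 / 60
  analytic <- 21 + (temp[300] - 21) * exp(-0.045 * (t_min + 4 / 60))
  expect_equal(temp[301:600], analytic, tolerance = 1e-10)
  # initial cooling slope ~ k * gap: 0.045/min at a 9 degC gap is -0.405
  slope <- (temp[316] - temp[301]) / 1          # one minute apart, degC/min
  expect_equal(slope, -(31 - 2 - 21) * (1 - exp(-0.045)), tolerance = 0.01)
  # wear-only schedule converges to skin - offset
  sch2 <- list(state = rep("sedentary", n), n = n, cell_s = 4,
               removals = sch$removals[0, ], artifacts = sch$artifacts)
  temp2 <- simulate_temperature(sch2, cfg, skin_c = 31, sleep_c = 31.5)
  expect_equal(tail(temp2, 1), 29, tolerance = 1e-6)
})

test_that("hotter starts cool faster (regression sign of the edge model)", {
  cfg <- synthetic_config(temp_noise_sd = 0)
  cool1 <- cooling_curve(76, 33, 21, 0.045)
  cool2 <- cooling_curve(76, 27, 21, 0.045)
  expect_lt((cool1[76] - cool1[1]) / 5, (cool2[76] - cool2[1]) / 5)
})

test_that("acceleration is near-still during undisturbed non-wear, on-target in bouts", {
  cfg <- synthetic_config(seed = 77, duration_h = 6, sleep_blocks = NULL,
                          removal_durations_min = 60, skin_c_sd = 0,
                          artifact_rate_per_h = 0)
  g <- generate_recording(cfg)
  f <- extract_features(g$recording)
  t0 <- as.numeric(g$recording$start_time)
  i0 <- round((as.numeric(g$truth$start[1]) - t0) / 4) + 1
  i1 <- round((as.numeric(g$truth$end[1]) - t0) / 4)
  interior <- (i0 + 2):(i1 - 16)
  sds <- cbind(f$sd_x, f$sd_y, f$sd_z)[interior, ]
  expect_true(all(sds < 1))
  # baseline norm ~ 1 g (gravity-oriented)
  norm <- sqrt(sum(colMeans(g$recording$accel[1:7500, ])^2))
  expect_equal(norm, 1, tolerance = 0.05)
})

test_that("removal durations hit the published distribution targets", {
  set.seed(1)
  d <- draw_removal_durations(500)
  expect_gt(median(d), 18)
  expect_lt(median(d), 28)
  frac_short <- mean(d < 60)
  expect_gt(frac_short, 0.855 - 0.05)
  expect_lt(frac_short, 0.855 + 0.05)
})

test_that("removal-edge statistics match the cohort targets", {
  cfgs <- lapply(1:5, function(i)
    synthetic_config(seed = 300 + i, duration_h = 12, sleep_blocks = NULL,
                     n_removals = 3))
  events <- do.call(rbind, lapply(cfgs, function(cf) {
    g <- generate_recording(cf)
    removal_edge_events(extract_features(g$recording), g$truth)
  }))
  expect_gte(nrow(events), 10)
  # start temperatures ~ 29 +/- 2 degC
  expect_gt(mean(events$start_temp), 27)
  expect_lt(mean(events$start_temp), 31)
  # steepest 1-min cooling rate within 5 min of onset: -0.40 +/- 0.10
  expect_gt(mean(events$roc_5), -0.50)
  expect_lt(mean(events$roc_5), -0.30)
})

test_that("ground truth is consistent with the generated signals", {
  # default artifact model: every interval interior is >= 95% quiet
  for (seed in 3:5) {
    g <- generate_recording(synthetic_config(seed = seed))
    f <- extract_features(g$recording)
    t0 <- as.numeric(g$recording$start_time)
    for (i in seq_len(nrow(g$truth))) {
      i0 <- round((as.numeric(g$truth$start[i]) - t0) / 4) + 1
      i1 <- round((as.numeric(g$truth$end[i]) - t0) / 4)
      interior <- (i0 + 1):(i1 - 16)    # clear of the donning look-ahead
      quiet <- rowSums(cbind(f$sd_x, f$sd_y, f$sd_z)[interior, ] < 8) >= 2
      expect_gte(mean(quiet), 0.95)
    }
  }
})

test_that("a zero-removal config yields an empty truth set", {
  g <- generate_recording(synthetic_config(seed = 2, duration_h = 6,
                                           sleep_blocks = NULL,
                                           n_removals = 0))
  expect_equal(nrow(g$truth), 0L)
})

test_that("scenario batteries echo their configurations", {
  b <- scenario_battery("standard", seed = 4, n_recordings = 2,
                        duration_h = 6)
  expect_length(b, 2L)
  expect_s3_class(b[[1]]$recording, "RawRecording")
  expect_equal(rec_duration(b[[1]]$recording), 6 * 3600)
  shorts <- scenario_configs("short_removals", seed = 4)
  expect_true(all(vapply(shorts, function(cf)
    cf$removal_dur_range_min[2] <= 15, TRUE)))
  colds <- scenario_configs("cold_ambient", seed = 4)
  expect_equal(colds[[1]]$ambient_c, 8)
  expect_gt(colds[[1]]$outdoor_n, 0)
  expect_error(scenario_configs("no_such_battery", seed = 1), "arg")
})

test_that("short-removal durations stay within their declared range", {
  cfg <- scenario_configs("short_removals", seed = 9, n_recordings = 1)[[1]]
  g <- generate_recording(cfg)
  durs <- (as.numeric(g$truth$end) - as.numeric(g$truth$start)) / 60
  expect_true(all(durs >= 4.9 & durs <= 15.1))
})

test_that("sleep blocks are quiet but warm with sub-threshold drift", {
  cfg <- scenario_configs("sleep_heavy", seed = 6, n_recordings = 1)[[1]]
  g <- generate_recording(cfg)
  f <- extract_features(g$recording)
  t0 <- as.numeric(g$recording$start_time)
  b <- g$sleep_blocks[3, ]
  i0 <- round(b$start_h * 900) + 300           # interior, past onset warming
  i1 <- round(b$end_h * 900) - 40
  seg <- as.data.frame(f)[i0:i1, ]
  expect_true(all(seg$temp_smooth > 28.5))     # warm relative to non-wear
  # never cools at anything near the non-wear rate signature
  expect_true(all(seg$roc_1min[!is.na(seg$roc_1min)] > -0.1))
  expect_true(all(cbind(seg$sd_x, seg$sd_y, seg$sd_z) < 8))
})
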