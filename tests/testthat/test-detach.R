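# DETACH rules on directly constructed feature tables, plus end-to-end
# detection on synthetic recordings.

test_that("quiet-start condition requires two quiet axes now and 90% of 5 min", {
  f <- fake_features(rep(29, 120), sd_x = 0)
  expect_true(accel_quiet_start(f, 10))
  # two quiet axes suffice even with one noisy axis
  f2 <- fake_features(rep(29, 120), sd_x = 5, sd_y = 5, sd_z = 20)
  expect_true(accel_quiet_start(f2, 10))
  # a 2-of-75-point bump is tolerated (97% >= 90%) ...
  sd_bump <- rep(2, 120); sd_bump[40:41] <- 20
  f3 <- fake_features(rep(29, 120), sd_x = sd_bump, sd_y = sd_bump,
                      sd_z = sd_bump)
  expect_true(accel_quiet_start(f3, 10))
  # ... an 8-of-75-point bump (89%) is not
  sd_big <- rep(2, 120); sd_big[40:47] <- 20
  f4 <- fake_features(rep(29, 120), sd_x = sd_big, sd_y = sd_big,
                      sd_z = sd_big)
  expect_false(accel_quiet_start(f4, 10))
  # truncated confirmation window is masked, not guessed
  expect_false(accel_quiet_start(f, 80))
})

test_that("start pathways follow the rate, absolute-gate and low-temperature rules", {
  # quiet accel, 29 degC falling at -0.4 degC/min: the rate pathway
  falling <- 29 - 0.4 * (0:119) * 4 / 60
  expect_identical(detect_start(fake_features(falling, sd_x = 2), 5),
                   "temp_rate")
  # sleep-like: quiet but 31 degC and flat fails both pathways
  expect_identical(detect_start(fake_features(rep(31, 120), sd_x = 2), 5),
                   "none")
  # ambient-adjacent: quiet at a constant 24 degC takes the low path
  expect_identical(detect_start(fake_features(rep(24, 120), sd_x = 2), 5),
                   "low_temp")
  # the rate pathway takes precedence when both fire
  cold_fall <- 25 - 0.4 * (0:119) * 4 / 60
  expect_identical(detect_start(fake_features(cold_fall, sd_x = 2), 5),
                   "temp_rate")
  # 29 degC falling but accel moving: nothing fires
  expect_identical(detect_start(fake_features(falling, sd_x = 20), 5),
                   "none")
})

test_that("end pathways require movement plus warming or high temperature", {
  n <- 150
  # movement from grid point 31 on; 60% of the end window active on 2 axes
  sd_all <- rep(2, n); sd_all[31:n] <- 20
  sd_z <- rep(2, n); sd_z[31:n] <- rep(c(20, 20, 20, 2, 2), length.out = n - 30)
  warming <- 24 + 0.36 * pmax(0, (0:(n - 1)) - 30) * 4 / 60
  f <- fake_features(warming, sd_x = sd_all, sd_y = sd_all, sd_z = sd_z)
  expect_identical(detect_end(f, 46), "temp_rate")   # one minute into movement
  # movement but flat and cold: end deferred
  f2 <- fake_features(rep(24, n), sd_x = sd_all, sd_y = sd_all, sd_z = sd_all)
  expect_identical(detect_end(f2, 46), "none")
  # movement, flat but already 27 degC: the high-temperature path
  f3 <- fake_features(rep(27, n), sd_x = sd_all, sd_y = sd_all, sd_z = sd_all)
  expect_identical(detect_end(f3, 46), "high_temp")
  # the previous-minute condition needs all three axes moving
  sd_two <- rep(2, n); sd_two[31:n] <- 20
  f4 <- fake_features(rep(27, n), sd_x = sd_two, sd_y = sd_two, sd_z = 2)
  expect_identical(detect_end(f4, 46), "none")
})

test_that("the scan assembles one interval per removal with matching pathways", {
  # 80 min: wear (active) / removal with exponential cooling / active again
  n <- 1200
  rem <- 301:750                               # 30 min removal
  temp <- rep(29, n)
  temp[rem] <- cooling_curve(length(rem), 29, 21, 0.045)
  after <- 751:n
  temp[after] <- tail(temp[rem], 1) +
    (29 - tail(temp[rem], 1)) * (1 - exp(-0.04 * (seq_along(after)) * 4 / 60))
  sd <- rep(50, n); sd[rem] <- 2
  f <- fake_features(temp, sd_x = sd, sd_y = sd, sd_z = sd)
  iv <- detect_nonwear(rec = NULL, features = f)
  expect_equal(nrow(iv), 1L)
  expect_identical(iv$start_path, "temp_rate")
  expect_identical(iv$end_path, "temp_rate")
  expect_lt(abs(as.numeric(iv$start) - (as.numeric(T0) + 300 * 4)), 120)
  expect_lt(abs(as.numeric(iv$end) - (as.numeric(T0) + 750 * 4)), 120)
})

test_that("a five-minute removal with a gentle re-donning is still detected", {
  # quiet continues ~30 s past the removal end (device back on the wrist
  # before movement resumes), then movement with warming
  n <- 600
  rem <- 151:225                               # 5 min
  temp <- rep(29, n)
  temp[rem] <- cooling_curve(length(rem), 29, 21, 0.045)
  rest <- 226:n
  temp[rest] <- tail(temp[rem], 1) +
    (29 - tail(temp[rem], 1)) * (1 - exp(-0.06 * seq_along(rest) * 4 / 60))
  sd <- rep(50, n); sd[c(rem, 226:233)] <- 2
  f <- fake_features(temp, sd_x = sd, sd_y = sd, sd_z = sd)
  iv <- detect_nonwear(rec = NULL, features = f)
  expect_equal(nrow(iv), 1L)
  expect_gt(interval_overlap_s(iv, T0 + 150 * 4, T0 + 225 * 4), 0)
})

test_that("sleep-like blocks never fire across 100 seeded replicates", {
  set.seed(123)
  for (r in 1:100) {
    n <- 450                                   # 30 min block
    drift <- runif(1, -0.05, 0.05)             # degC/min, below thresholds
    temp <- runif(1, 30, 33) + drift * (0:(n - 1)) * 4 / 60 +
      cumsum(rnorm(n, 0, 0.005))
    f <- fake_features(temp, sd_x = runif(n, 1, 7), sd_y = runif(n, 1, 7),
                       sd_z = runif(n, 1, 7))
    iv <- detect_nonwear(rec = NULL, features = f)
    expect_equal(nrow(iv), 0L)
  }
})

test_that("lengthening a removal never removes the detection", {
  detected <- logical(0)
  for (len_min in seq(6, 30, by = 4)) {
    n <- 600
    rem <- 151:(150 + len_min * 15)
    temp <- rep(29, n)
    temp[rem] <- cooling_curve(length(rem), 29, 21, 0.045)
    rest <- seq(max(rem) + 1, n)
    temp[rest] <- temp[max(rem)] +
      (29 - temp[max(rem)]) * (1 - exp(-0.05 * seq_along(rest) * 4 / 60))
    sd <- rep(50, n); sd[rem] <- 2
    f <- fake_features(temp, sd_x = sd, sd_y = sd, sd_z = sd)
    detected <- c(detected, nrow(detect_nonwear(rec = NULL, features = f)) > 0)
  }
  expect_true(all(detected))
})

test_that("a fully worn active day yields no intervals, and detection is deterministic", {
  g <- generate_recording(synthetic_config(seed = 21, duration_h = 12,
                                           skin_c_sd = 0, n_removals = 0,
                                           sleep_blocks = NULL))
  expect_equal(nrow(g$truth), 0L)
  iv1 <- detect_nonwear(g$recording)
  iv2 <- detect_nonwear(g$recording)
  expect_equal(nrow(iv1), 0L)
  expect_identical(iv1, iv2)
})

test_that("a single 30-minute removal is recovered within two minutes", {
  g <- generate_recording(synthetic_config(seed = 8, skin_c_sd = 0,
                                           removal_durations_min = 30))
  expect_equal(nrow(g$truth), 1L)
  iv <- detect_nonwear(g$recording)
  expect_equal(nrow(iv), 1L)
  errs <- boundary_errors_min(iv, g$truth)
  expect_true(all(errs <= 2))
})

test_that("an open interval at the recording end is emitted, not dropped", {
  n <- 600
  rem <- 301:n                                 # removal runs to the end
  temp <- rep(29, n)
  temp[rem] <- cooling_curve(length(rem), 29, 21, 0.045)
  sd <- rep(50, n); sd[rem] <- 2
  f <- fake_features(temp, sd_x = sd, sd_y = sd, sd_z = sd)
  iv <- detect_nonwear(rec = NULL, features = f)
  expect_equal(nrow(iv), 1L)
  expect_identical(iv$end_path, "recording_end")
  usage <- pathway_usage(iv)
  expect_equal(sum(usage$start), nrow(iv))
  expect_equal(sum(usage$end), nrow(iv))
})

test_that("detected intervals are sorted, non-overlapping and label-partitioning", {
  g <- generate_recording(synthetic_config(seed = 31, skin_c_sd = 0))
  iv <- detect_nonwear(g$recording)
  if (nrow(iv) > 1L) {
    expect_true(all(diff(as.numeric(iv$start)) > 0))
    expect_true(all(as.numeric(iv$start[-1]) >= as.numeric(iv$end[-nrow(iv)])))
  }
  lab <- labels_per_second(iv, g$recording)
  expect_equal(length(lab), floor(rec_duration(g$recording)))
})
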