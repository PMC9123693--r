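# Fixture builders shared across test files.  Everything is generated in
# code; no data files.

T0 <- as.POSIXct("2020-01-06 00:00:00", tz = "UTC")

# A small wear-like recording: still gravity baseline plus per-axis noise.
make_rec <- function(minutes = 10, fs_accel = 75, fs_temp = 0.25,
                     noise_g = 0.005, temp_c = 29, pid = "p1", seed = 1) {
  set.seed(seed)
  n_a <- round(minutes * 60 * fs_accel)
  n_t <- round(minutes * 60 * fs_temp)
  acc <- cbind(rnorm(n_a, 0, noise_g), rnorm(n_a, 0, noise_g),
               1 + rnorm(n_a, 0, noise_g))
  raw_recording(pid, T0, acc, rep(temp_c, n_t) + rnorm(n_t, 0, 0.01),
                fs_accel, fs_temp)
}

# Build a FeatureSeries directly from channel vectors, for rule-level tests
# that should not depend on the extraction pipeline.
fake_features <- function(temp, sd_x = 2, sd_y = sd_x, sd_z = sd_x,
                          period_s = 4, pid = "p1") {
  n <- length(temp)
  recycle <- function(x) rep_len(x, n)
  ts <- recycle(temp)
  structure(
    data.frame(time_s = (seq_len(n) - 1) * period_s,
               temp_smooth = ts,
               sd_x = recycle(sd_x), sd_y = recycle(sd_y),
               sd_z = recycle(sd_z),
               roc_1min = temp_rate_of_change(ts, 1 / period_s, 1),
               roc_5min = temp_rate_of_change(ts, 1 / period_s, 5)),
    start_time = T0, period_s = period_s, participant_id = pid,
    class = c("FeatureSeries", "data.frame"))
}

# Exponential cooling curve (Newtonian) sampled on the feature grid.
cooling_curve <- function(n, t0_c, ambient_c, k_per_min, period_s = 4) {
  t_min <- (seq_len(n) - 1) * period_s / 60
  ambient_c + (t0_c - ambient_c) * exp(-k_per_min * t_min)
}

# Independent two-pass population-SD oracle for the rolling-SD feature.
naive_rolling_sd <- function(x, fs, window_s = 60, rate = 0.25) {
  n_out <- floor(length(x) / fs * rate)
  w <- round(window_s * fs)
  vapply(seq_len(n_out), function(k) {
    i0 <- round((k - 1) / rate * fs) + 1
    i1 <- i0 + w - 1
    if (i1 > length(x)) return(NA_real_)
    seg <- x[i0:i1]
    m <- sum(seg) / w
    sqrt(sum((seg - m)^2) / w) * 1000
  }, 0)
}

# Interval helpers for battery-level assertions.
interval_overlap_s <- function(iv, s, e) {
  if (nrow(iv) == 0) return(0)
  sum(pmax(0, pmin(as.numeric(iv$end), as.numeric(e)) -
             pmax(as.numeric(iv$start), as.numeric(s))))
}

boundary_errors_min <- function(iv, truth) {
  errs <- numeric(0)
  for (i in seq_len(nrow(iv))) {
    ov <- which(as.numeric(truth$end) > as.numeric(iv$start[i]) &
                as.numeric(truth$start) < as.numeric(iv$end[i]))
    if (!length(ov)) { errs <- c(errs, Inf); next }
    j <- ov[1]
    errs <- c(errs,
              abs(as.numeric(iv$start[i]) - as.numeric(truth$start[j])) / 60,
              abs(as.numeric(iv$end[i]) - as.numeric(truth$end[j])) / 60)
  }
  errs
}

# Independent brute-force root-split oracle: scan every feature and every
# midpoint threshold, return the minimal weighted Gini impurity.
oracle_best_gini <- function(df) {
  y <- df$label
  feats <- names(df)[vapply(df, is.numeric, TRUE)]
  gini <- function(v) {
    p <- table(v) / length(v)
    1 - sum(p^2)
  }
  best <- Inf
  for (f in feats) {
    vals <- sort(unique(df[[f]]))
    if (length(vals) < 2) next
    for (thr in (vals[-1] + vals[-length(vals)]) / 2) {
      left <- y[df[[f]] <= thr]; right <- y[df[[f]] > thr]
      imp <- (length(left) * gini(left) + length(right) * gini(right)) /
        length(y)
      best <- min(best, imp)
    }
  }
  best
}

tree_root_impurity <- function(model) model$root$impurity
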