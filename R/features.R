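# Derived 0.25 Hz feature channels consumed by every detector: low-pass
# smoothed temperature, per-axis one-minute rolling SD of acceleration (mg),
# and forward temperature rates-of-change at 1- and 5-minute lags.

#' Preprocessing parameters for feature extraction
#'
#' @param butter_order Butterworth filter order for temperature smoothing.
#' @param butter_cutoff_hz low-pass cut-off frequency in Hz.  Must be below
#'   the temperature Nyquist frequency.
#' @param sd_window_s rolling-SD window length in seconds.
#' @param feature_rate_hz output grid rate in Hz.
#' @param zero_phase if `TRUE` (default) the temperature filter is applied
#'   forward-backward (zero phase, squared magnitude response); if `FALSE` a
#'   causal single pass is used, for streaming parity.
#' @return a `PreprocessParams` list.
#' @export
preprocess_params <- function(butter_order = 2, butter_cutoff_hz = 0.005,
                              sd_window_s = 60, feature_rate_hz = 0.25,
                              zero_phase = TRUE) {
  stopifnot(butter_order >= 1, butter_cutoff_hz > 0, sd_window_s > 0,
            feature_rate_hz > 0, is.logical(zero_phase))
  structure(list(butter_order = butter_order,
                 butter_cutoff_hz = butter_cutoff_hz,
                 sd_window_s = sd_window_s,
                 feature_rate_hz = feature_rate_hz,
                 zero_phase = zero_phase),
            class = "PreprocessParams")
}

#' Low-pass smooth a temperature series
#'
#' Applies an order-`butter_order` Butterworth low-pass filter (default
#' order 2, cut-off 0.005 Hz).  With `zero_phase = TRUE` the filter runs
#' forward and backward, so the effective magnitude response is the square
#' of the single-pass response and no phase delay is introduced; DC gain is
#' exactly 1 either way.
#'
#' @param temp numeric vector, degrees Celsius.
#' @param fs_temp sampling rate in Hz.
#' @param params a [preprocess_params()] object.
#' @return smoothed series on the same grid as the input.
#' @export
smooth_temperature <- function(temp, fs_temp = 0.25,
                               params = preprocess_params()) {
  if (params$butter_cutoff_hz >= fs_temp / 2)
    stop(sprintf("cut-off %g Hz must be below the Nyquist frequency %g Hz",
                 params$butter_cutoff_hz, fs_temp / 2))
  min_len <- 3L * (2L * params$butter_order + 1L)
  if (length(temp) < min_len)
    stop(sprintf("temperature series too short to filter (%d < %d samples)",
                 length(temp), min_len))
  bf <- signal::butter(params$butter_order,
                       params$butter_cutoff_hz / (fs_temp / 2), type = "low")
  if (params$zero_phase) {
    zero_phase_filter(bf$b, bf$a, temp)
  } else {
    iir_filter(bf$b, bf$a, temp, zi = lfilter_zi(bf$b, bf$a) * temp[1])
  }
}

# Steady-state initial filter state for a unit-step input (direct form II
# transposed), so that filtering a constant yields that constant from the
# first sample.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  if (n == 1L) return(numeric(0))
  A <- if (n == 2L) matrix(-a[2], 1, 1) else
    rbind(-a[2:n], cbind(diag(n - 2L), rep(0, n - 2L)))
  B <- b[2:n] - a[2:n] * b[1]
  as.numeric(solve(diag(n - 1L) - t(A), B))
}

# Direct form II transposed IIR filter with explicit initial state.
iir_filter <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  z <- if (is.null(zi)) rep(0, n - 1L) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    if (n > 2L)
      for (j in seq_len(n - 2L))
        z[j] <- b[j + 1] * x[i] + z[j + 1] - a[j + 1] * y[i]
    z[n - 1L] <- b[n] * x[i] - a[n] * y[i]
  }
  y
}

# Zero-phase (forward-backward) filtering with odd-reflection padding and
# steady-state initial conditions at both ends, so constants and slow ramps
# pass without edge transients.
zero_phase_filter <- function(b, a, x) {
  ntaps <- max(length(a), length(b))
  edge <- 3L * (ntaps - 1L)
  nx <- length(x)
  if (nx <= edge + 1L)
    stop(sprintf("series too short for zero-phase filtering (%d samples)", nx))
  ext <- c(2 * x[1] - x[(edge + 1L):2],
           x,
           2 * x[nx] - x[(nx - 1L):(nx - edge)])
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(edge + 1L):(edge + nx)]
}

#' One-minute rolling SD of acceleration on the feature grid
#'
#' For each feature grid point stamped at time `t` (grid period
#' `1 / feature_rate_hz`), the per-axis population standard deviation of the
#' raw acceleration samples in the forward-looking window `[t, t + W)` is
#' computed, where `W = sd_window_s`.  Values are reported in milligravity
#' (1 g = 1000 mg).  Grid points whose window extends past the end of the
#' recording are masked (`NA`).
#'
#' @param accel numeric N x 3 matrix in g.
#' @param fs_accel sampling rate in Hz (must be >= 1).
#' @param params a [preprocess_params()] object.
#' @param n_out number of feature grid points; defaults to
#'   `floor(duration * feature_rate_hz)`.
#' @return an `n_out` x 3 matrix (columns `sd_x`, `sd_y`, `sd_z`) in mg.
#' @export
rolling_accel_sd <- function(accel, fs_accel = 75,
                             params = preprocess_params(), n_out = NULL) {
  accel <- as.matrix(accel)
  stopifnot(ncol(accel) == 3L)
  if (fs_accel < 1) stop("`fs_accel` must be at least 1 Hz")
  n <- nrow(accel)
  w <- round(params$sd_window_s * fs_accel)
  if (n < w)
    stop(sprintf("recording shorter than one %g s rolling-SD window",
                 params$sd_window_s))
  step_s <- 1 / params$feature_rate_hz
  if (is.null(n_out)) n_out <- floor(n / fs_accel * params$feature_rate_hz)
  i0 <- round((seq_len(n_out) - 1L) * step_s * fs_accel) + 1L
  i1 <- i0 + w - 1L
  out <- matrix(NA_real_, n_out, 3L,
                dimnames = list(NULL, c("sd_x", "sd_y", "sd_z")))
  ok <- i1 <= n
  for (j in 1:3) {
    x <- accel[, j] - mean(accel[, j])   # centring improves cumsum precision
    cs <- cumsum(c(0, x))
    cs2 <- cumsum(c(0, x * x))
    s <- cs[i1[ok] + 1L] - cs[i0[ok]]
    s2 <- cs2[i1[ok] + 1L] - cs2[i0[ok]]
    v <- pmax(0, s2 / w - (s / w)^2)     # population variance
    out[ok, j] <- sqrt(v) * 1000
  }
  out
}

#' Forward temperature rate-of-change
#'
#' The value stamped at time `t` is `(T(t + lag) - T(t)) / lag` in degrees
#' Celsius per minute (forward difference quotient).  The last `lag` minutes
#' of the series, where the look-ahead leaves the recording, are masked.
#'
#' @param temp_smooth smoothed temperature series.
#' @param fs sampling rate of the series in Hz.
#' @param lag_min lag in minutes (1 and 5 are the lags used by the non-wear
#'   rules).
#' @return numeric vector of the same length, degrees C per minute.
#' @export
temp_rate_of_change <- function(temp_smooth, fs = 0.25, lag_min = 1) {
  n <- length(temp_smooth)
  L <- round(lag_min * 60 * fs)
  if (L < 1) stop("lag must cover at least one sample")
  out <- rep(NA_real_, n)
  if (L >= n) return(out)   # whole series masked: lag exceeds the recording
  idx <- seq_len(n - L)
  out[idx] <- (temp_smooth[idx + L] - temp_smooth[idx]) / lag_min
  out
}

#' Extract the full feature set from a recording
#'
#' Produces the 0.25 Hz (by default) feature table shared by all detectors:
#' smoothed temperature, per-axis rolling SD in mg, and 1- and 5-minute
#' forward temperature rates-of-change.  All channels sit on one grid
#' aligned to the recording start.  Recordings shorter than 5 minutes yield
#' an all-masked table with a warning.
#'
#' @param rec a `RawRecording`.
#' @param params a [preprocess_params()] object.
#' @return data.frame of class `FeatureSeries` with columns `time_s`,
#'   `temp_smooth`, `sd_x`, `sd_y`, `sd_z`, `roc_1min`, `roc_5min`;
#'   attributes `start_time`, `period_s`, `participant_id`.
#' @export
extract_features <- function(rec, params = preprocess_params()) {
  stopifnot(inherits(rec, "RawRecording"))
  rate <- params$feature_rate_hz
  dur <- min(rec_duration(rec), length(rec$temp) / rec$fs_temp)
  n_feat <- floor(dur * rate)
  time_s <- (seq_len(n_feat) - 1L) / rate
  empty <- function() {
    structure(data.frame(time_s = time_s, temp_smooth = NA_real_,
                         sd_x = NA_real_, sd_y = NA_real_, sd_z = NA_real_,
                         roc_1min = NA_real_, roc_5min = NA_real_),
              start_time = rec$start_time, period_s = 1 / rate,
              participant_id = rec$participant_id,
              class = c("FeatureSeries", "data.frame"))
  }
  if (dur < 300) {
    warning("recording shorter than 5 minutes: all features masked")
    return(empty())
  }
  ts <- smooth_temperature(rec$temp, rec$fs_temp, params)
  if (abs(rec$fs_temp - rate) > 1e-12) {
    ts <- stats::approx(x = (seq_along(ts) - 1L) / rec$fs_temp, y = ts,
                        xout = time_s, rule = 2)$y
  } else {
    ts <- ts[seq_len(min(n_feat, length(ts)))]
    length(ts) <- n_feat
  }
  sds <- rolling_accel_sd(rec$accel, rec$fs_accel, params, n_out = n_feat)
  out <- data.frame(time_s = time_s, temp_smooth = ts,
                    sd_x = sds[, 1], sd_y = sds[, 2], sd_z = sds[, 3],
                    roc_1min = temp_rate_of_change(ts, rate, 1),
                    roc_5min = temp_rate_of_change(ts, rate, 5))
  structure(out, start_time = rec$start_time, period_s = 1 / rate,
            participant_id = rec$participant_id,
            class = c("FeatureSeries", "data.frame"))
}

#' Write a feature table to CSV (one row per grid point)
#'
#' @param features a `FeatureSeries`.
#' @param path file path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}
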