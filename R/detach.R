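# The DETACH non-wear rules: start detection via the temperature
# rate-of-change pathway or the low-absolute-temperature pathway, end
# detection via the rate or high-absolute-temperature pathway, and the
# left-to-right scan that assembles validated non-wear intervals.

#' DETACH rule parameters
#'
#' Defaults are the final published rule set.  A non-wear *start* requires
#' quiet acceleration (rolling SD `< sd_crit` on at least `start_axes_min`
#' axes now, and on at least `start_window_frac` of the following
#' `confirm_window_min` minutes) together with either a 5-minute temperature
#' rate-of-change `<= start_rate_thresh` while the absolute temperature is
#' `< start_abs_temp_max`, or an absolute temperature `< low_temp_thresh`
#' (the low-temperature fallback for ambient-adjacent starts).  A non-wear
#' *end* requires movement (all-axes SD `> end_prev_sd` over the previous
#' minute and at least `end_axes_min` axes `> end_prev_sd` on at least
#' `end_window_frac` of the following 5 minutes) together with either a
#' 5-minute rate `> end_rate_thresh` or an absolute temperature
#' `> high_temp_thresh`.
#'
#' `cart_raw` records the unrounded thresholds the depth-3 decision-tree
#' analysis produced before the rules were generalized to multiple axes
#' (start rate -0.27 degC/min, x-axis SD <= 7 mg, absolute temperature
#' <= 29.5 degC; end x-axis SD >= 17 mg, z-axis SD >= 138 mg); they are kept
#' for provenance and are not used by the detector.
#'
#' @param sd_crit quiet threshold for rolling SD, mg.
#' @param start_axes_min axes that must be quiet at a start, count.
#' @param confirm_window_min confirmation window, minutes.
#' @param start_window_frac required quiet fraction of the confirmation
#'   window at a start.
#' @param start_rate_thresh start rate threshold, degC/min (negative).
#' @param start_abs_temp_max absolute temperature gate for the rate start
#'   pathway, degC.
#' @param low_temp_thresh low-temperature start pathway threshold, degC.
#' @param end_prev_sd movement threshold for the end rules, mg.
#' @param end_axes_min axes that must be moving in the end confirmation
#'   window, count.
#' @param end_window_frac required moving fraction of the end confirmation
#'   window.
#' @param end_rate_thresh end rate threshold, degC/min (positive).
#' @param high_temp_thresh high-temperature end pathway threshold, degC.
#' @param cart_raw named list of documented raw decision-tree constants.
#' @return a `DetachParams` list.
#' @export
detach_params <- function(sd_crit = 8, start_axes_min = 2,
                          confirm_window_min = 5, start_window_frac = 0.90,
                          start_rate_thresh = -0.2, start_abs_temp_max = 30,
                          low_temp_thresh = 26, end_prev_sd = 8,
                          end_axes_min = 2, end_window_frac = 0.50,
                          end_rate_thresh = 0.1, high_temp_thresh = 26,
                          cart_raw = list(start_rate = -0.27, start_sd_x = 7,
                                          start_abs_temp = 29.5,
                                          end_sd_x = 17, end_sd_z = 138)) {
  stopifnot(sd_crit > 0, end_prev_sd > 0,
            start_window_frac > 0, start_window_frac <= 1,
            end_window_frac > 0, end_window_frac <= 1,
            start_rate_thresh < 0, end_rate_thresh > 0,
            low_temp_thresh <= start_abs_temp_max)
  structure(list(sd_crit = sd_crit, start_axes_min = start_axes_min,
                 confirm_window_min = confirm_window_min,
                 start_window_frac = start_window_frac,
                 start_rate_thresh = start_rate_thresh,
                 start_abs_temp_max = start_abs_temp_max,
                 low_temp_thresh = low_temp_thresh,
                 end_prev_sd = end_prev_sd, end_axes_min = end_axes_min,
                 end_window_frac = end_window_frac,
                 end_rate_thresh = end_rate_thresh,
                 high_temp_thresh = high_temp_thresh, cart_raw = cart_raw),
            class = "DetachParams")
}

# Vectorized rule evaluation over the whole feature grid.  Returns a list of
# logical vectors; NA anywhere (masked features, truncated windows) is
# treated as "rule does not fire" except for the end confirmation fraction,
# which by design uses whatever part of the look-ahead window exists.
detach_rule_grid <- function(features, params) {
  rate <- 1 / attr(features, "period_s")
  w <- round(params$confirm_window_min * 60 * rate)     # 75 points at 0.25 Hz
  lag1 <- round(60 * rate)                              # one minute of grid
  sd <- cbind(features$sd_x, features$sd_y, features$sd_z)
  n <- nrow(sd)

  quiet_axes <- rowSums(sd < params$sd_crit)
  quiet_now <- !is.na(quiet_axes) & quiet_axes >= params$start_axes_min
  frac_quiet <- roll_mean_forward(quiet_now, w, partial = FALSE)
  accel_start <- quiet_now & !is.na(frac_quiet) &
    frac_quiet >= params$start_window_frac

  temp <- features$temp_smooth
  roc5 <- features$roc_5min
  start_rate <- accel_start & !is.na(roc5) & roc5 <= params$start_rate_thresh &
    !is.na(temp) & temp < params$start_abs_temp_max
  start_low <- accel_start & !is.na(temp) & temp < params$low_temp_thresh

  active_all <- rowSums(sd > params$end_prev_sd)
  prev_active <- c(rep(FALSE, lag1),
                   !is.na(active_all[seq_len(n - lag1)]) &
                     active_all[seq_len(n - lag1)] == 3L)
  active2 <- !is.na(active_all) & active_all >= params$end_axes_min
  frac_active <- roll_mean_forward(active2, w, partial = TRUE)
  accel_end <- prev_active & frac_active >= params$end_window_frac

  end_rate <- accel_end & !is.na(roc5) & roc5 > params$end_rate_thresh
  end_high <- accel_end & !is.na(temp) & temp > params$high_temp_thresh

  list(start_rate = start_rate, start_low = start_low,
       end_rate = end_rate, end_high = end_high,
       accel_start = accel_start, accel_end = accel_end, w = w)
}

#' Quiet-acceleration start condition at one grid point
#'
#' True iff at least `start_axes_min` axes have rolling SD below `sd_crit`
#' at grid point `i` *and* the fraction of grid points in the following
#' `confirm_window_min` minutes where that many axes are quiet is at least
#' `start_window_frac` (the tolerance that lets a brief bump during non-wear
#' pass).  Masked or window-truncated points return `FALSE`.
#'
#' @param features a `FeatureSeries`.
#' @param i grid index (1-based).
#' @param params a [detach_params()] object.
#' @return logical scalar.
#' @export
accel_quiet_start <- function(features, i, params = detach_params()) {
  g <- detach_rule_grid(features, params)
  isTRUE(g$accel_start[i])
}

#' Start / end pathway decision at one grid point
#'
#' `detect_start` returns `"temp_rate"`, `"low_temp"` or `"none"`; the rate
#' pathway takes precedence when both fire (the low-temperature fallback has
#' the higher false-positive rate).  `detect_end` returns `"temp_rate"`,
#' `"high_temp"` or `"none"`; both end pathways require the movement
#' conditions.
#'
#' @inheritParams accel_quiet_start
#' @return a single string naming the pathway.
#' @export
detect_start <- function(features, i, params = detach_params()) {
  g <- detach_rule_grid(features, params)
  if (isTRUE(g$start_rate[i])) "temp_rate"
  else if (isTRUE(g$start_low[i])) "low_temp"
  else "none"
}

#' @rdname detect_start
#' @export
detect_end <- function(features, i, params = detach_params()) {
  g <- detach_rule_grid(features, params)
  if (isTRUE(g$end_rate[i])) "temp_rate"
  else if (isTRUE(g$end_high[i])) "high_temp"
  else "none"
}

detach_scan <- function(features, params) {
  g <- detach_rule_grid(features, params)
  n <- nrow(features)
  start_any <- g$start_rate | g$start_low
  end_any <- g$end_rate | g$end_high
  starts <- integer(0); ends <- integer(0)
  start_path <- character(0); end_path <- character(0)
  i <- 1L
  while (i <= n) {
    if (!start_any[i]) { i <- i + 1L; next }
    sp <- if (g$start_rate[i]) "temp_rate" else "low_temp"
    j_min <- i + g$w
    j <- if (j_min <= n) {
      cand <- which(end_any[j_min:n])
      if (length(cand)) j_min + cand[1L] - 1L else NA_integer_
    } else NA_integer_
    starts <- c(starts, i)
    start_path <- c(start_path, sp)
    if (is.na(j)) {
      ends <- c(ends, NA_integer_)
      end_path <- c(end_path, "recording_end")
      break
    }
    ends <- c(ends, j)
    end_path <- c(end_path, if (g$end_rate[j]) "temp_rate" else "high_temp")
    i <- j + 1L
  }
  list(starts = starts, ends = ends, start_path = start_path,
       end_path = end_path)
}

#' Detect non-wear intervals with the DETACH rules
#'
#' Scans the feature grid left to right: at the first grid point where a
#' start pathway fires an interval is opened, the first end event at or
#' after `start + confirm_window_min` closes it, and scanning resumes after
#' the end.  An interval still open at the end of the recording is emitted
#' with `end_path = "recording_end"`.  Output intervals are half-open,
#' sorted, non-overlapping, and snapped to whole seconds.
#'
#' @param rec a `RawRecording`.
#' @param params a [detach_params()] object.
#' @param preprocess a [preprocess_params()] object.
#' @param features optionally, a precomputed `FeatureSeries` (skips
#'   extraction).
#' @return an `AnnotationSet` with extra columns `start_path`
#'   (`temp_rate` / `low_temp`) and `end_path` (`temp_rate` / `high_temp` /
#'   `recording_end`); attribute `algorithm = "detach"`.
#' @export
detect_nonwear <- function(rec, params = detach_params(),
                           preprocess = preprocess_params(),
                           features = NULL) {
  if (is.null(features)) features <- extract_features(rec, preprocess)
  step <- attr(features, "period_s")
  t0 <- attr(features, "start_time")
  pid <- attr(features, "participant_id") %||% "unknown"
  span_end <- t0 + floor(nrow(features) * step)
  sc <- detach_scan(features, params)
  if (length(sc$starts) == 0L) {
    out <- annotation_set(character(0), as_utc(character(0)),
                          as_utc(character(0)), source = "algorithm",
                          extra = NULL)
    out$start_path <- character(0)
    out$end_path <- character(0)
  } else {
    st <- t0 + (sc$starts - 1L) * step
    en <- ifelse(is.na(sc$ends), as.numeric(span_end),
                 as.numeric(t0) + (sc$ends - 1L) * step)
    en <- as.POSIXct(en, tz = "UTC", origin = "1970-01-01")
    out <- annotation_set(pid, st, en, source = "algorithm",
                          extra = data.frame(start_path = sc$start_path,
                                             end_path = sc$end_path))
  }
  attr(out, "algorithm") <- "detach"
  out
}

#' Tabulate detection-pathway usage
#'
#' @param intervals output of [detect_nonwear()].
#' @return named list with start- and end-pathway counts; each sums to the
#'   number of intervals.
#' @export
pathway_usage <- function(intervals) {
  list(start = table(factor(intervals$start_path,
                            levels = c("temp_rate", "low_temp"))),
       end = table(factor(intervals$end_path,
                          levels = c("temp_rate", "high_temp", "recording_end"))))
}
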