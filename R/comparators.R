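# Comparator algorithms: the van Hees acceleration-only detector
# (60-minute overlapping windows, 15-minute steps) and the Zhou combined
# temperature-acceleration detector (one-minute windows, 26 degC gate).

#' van Hees algorithm parameters
#'
#' @param window_min window length in minutes (60).
#' @param step_min step between window starts in minutes (15); must divide
#'   the window length.
#' @param sd_thresh per-axis SD threshold in mg (13).
#' @param range_thresh per-axis range (max - min) threshold in mg (50).
#' @param axes_required number of axes that must be quiet (2).
#' @param short_wear_rules list of `(max_len_h, frac)` pairs: a wear run
#'   shorter than `max_len_h` hours flanked by non-wear is reclassified as
#'   non-wear when it is shorter than `frac` of the summed bordering
#'   non-wear durations.  Applied once each, in order.
#' @param iterate_rules if `TRUE` the short-wear rules are iterated to a
#'   fixpoint instead of applied once (sensitivity analysis only).
#' @return a `VanHeesParams` list.
#' @export
vanhees_params <- function(window_min = 60, step_min = 15, sd_thresh = 13,
                           range_thresh = 50, axes_required = 2,
                           short_wear_rules = list(c(6, 0.30), c(3, 0.80)),
                           iterate_rules = FALSE) {
  stopifnot(window_min %% step_min == 0, sd_thresh > 0, range_thresh > 0)
  structure(list(window_min = window_min, step_min = step_min,
                 sd_thresh = sd_thresh, range_thresh = range_thresh,
                 axes_required = axes_required,
                 short_wear_rules = short_wear_rules,
                 iterate_rules = iterate_rules),
            class = "VanHeesParams")
}

#' Classify van Hees windows
#'
#' Each `window_min`-minute window starting every `step_min` minutes is
#' non-wear iff, on at least `axes_required` axes, the window's SD is below
#' `sd_thresh` mg *or* its range (max - min) is below `range_thresh` mg.  A
#' recording shorter than one window is evaluated as a single truncated
#' window and flagged via the `truncated` column.
#'
#' @param rec a `RawRecording`.
#' @param params a [vanhees_params()] object.
#' @return data.frame with columns `window_start_s`, `window_end_s`,
#'   `nonwear`, `truncated`.
#' @export
vanhees_classify_windows <- function(rec, params = vanhees_params()) {
  stopifnot(inherits(rec, "RawRecording"))
  fs <- rec$fs_accel
  n <- nrow(rec$accel)
  w <- round(params$window_min * 60 * fs)
  s <- round(params$step_min * 60 * fs)
  if (n < w) {
    starts <- 1L
    truncated <- TRUE
  } else {
    starts <- seq(1L, n - w + 1L, by = s)
    truncated <- rep(FALSE, length(starts))
  }
  ends <- pmin(starts + w - 1L, n)
  quiet <- matrix(FALSE, length(starts), 3L)
  for (j in 1:3) {
    x <- rec$accel[, j] - mean(rec$accel[, j])
    cs <- cumsum(c(0, x))
    cs2 <- cumsum(c(0, x * x))
    len <- ends - starts + 1L
    sm <- cs[ends + 1L] - cs[starts]
    sm2 <- cs2[ends + 1L] - cs2[starts]
    sds <- sqrt(pmax(0, sm2 / len - (sm / len)^2)) * 1000
    rng <- vapply(seq_along(starts), function(i) {
      diff(range(rec$accel[starts[i]:ends[i], j])) * 1000
    }, 0)
    quiet[, j] <- sds < params$sd_thresh | rng < params$range_thresh
  }
  data.frame(window_start_s = (starts - 1L) / fs,
             window_end_s = ends / fs,
             nonwear = rowSums(quiet) >= params$axes_required,
             truncated = truncated)
}

# Apply one short-wear reclassification rule in a single left-to-right pass
# over the wear/non-wear runs; merged non-wear blocks grow as the pass
# proceeds, so a later wear run sees the already-merged left border.
apply_short_wear_rule <- function(labels, max_len_h, frac) {
  r <- rle(labels)
  vals <- r$values
  lens <- r$lengths
  k <- 2L
  while (k <= length(vals) - 1L) {
    if (!vals[k] && vals[k - 1L] && vals[k + 1L] &&
        lens[k] < max_len_h * 3600 &&
        lens[k] < frac * (lens[k - 1L] + lens[k + 1L])) {
      lens[k - 1L] <- lens[k - 1L] + lens[k] + lens[k + 1L]
      lens <- lens[-c(k, k + 1L)]
      vals <- vals[-c(k, k + 1L)]
    } else {
      k <- k + 1L
    }
  }
  inverse.rle(list(lengths = lens, values = vals))
}

#' Detect non-wear with the van Hees algorithm
#'
#' Projects window classifications to a per-second label by the union rule
#' (a second is non-wear if any covering window is non-wear), converts
#' maximal runs to intervals, then applies the short-wear reclassification
#' rules (wear runs `< 6 h` reclassified when `< 30%` of bordering non-wear,
#' then `< 3 h` when `< 80%`), each rule in one left-to-right pass.
#'
#' @inheritParams vanhees_classify_windows
#' @return an `AnnotationSet`; attribute `algorithm = "vanhees"`.
#' @export
vanhees_detect <- function(rec, params = vanhees_params()) {
  wins <- vanhees_classify_windows(rec, params)
  n_sec <- floor(rec_duration(rec))
  labels <- rep(FALSE, n_sec)
  for (i in which(wins$nonwear)) {
    a <- floor(wins$window_start_s[i]) + 1L
    b <- min(ceiling(wins$window_end_s[i]), n_sec)
    if (a <= b) labels[a:b] <- TRUE
  }
  apply_rules <- function(lab) {
    for (rule in params$short_wear_rules)
      lab <- apply_short_wear_rule(lab, rule[1], rule[2])
    lab
  }
  labels <- apply_rules(labels)
  if (params$iterate_rules) {
    repeat {
      nxt <- apply_rules(labels)
      if (identical(nxt, labels)) break
      labels <- nxt
    }
  }
  iv <- runs_to_intervals(labels, rec$start_time, 1)
  out <- annotation_set(rep(rec$participant_id, length.out = nrow(iv)),
                        iv$start, iv$end, source = "algorithm")
  attr(out, "algorithm") <- "vanhees"
  out
}

#' Zhou algorithm parameters
#'
#' @param window_min non-overlapping classification window in minutes (1).
#' @param temp_thresh absolute temperature gate in degC (26).
#' @param sd_thresh per-axis SD threshold in mg (13).
#' @param smooth_span_min span of the moving-average temperature smoother in
#'   minutes (1), the smoothing variant used when re-creating this
#'   algorithm.
#' @return a `ZhouParams` list.
#' @export
zhou_params <- function(window_min = 1, temp_thresh = 26, sd_thresh = 13,
                        smooth_span_min = 1) {
  stopifnot(window_min > 0, temp_thresh > 0, sd_thresh > 0)
  structure(list(window_min = window_min, temp_thresh = temp_thresh,
                 sd_thresh = sd_thresh, smooth_span_min = smooth_span_min),
            class = "ZhouParams")
}

#' Detect non-wear with the Zhou combined algorithm
#'
#' Temperature is smoothed with a centred moving average, then each
#' one-minute window is non-wear iff its mean temperature is `<= 26` degC
#' and either (primary) all three axes have SD `< 13` mg, or (secondary) the
#' window's mean temperature is lower than the previous window's mean.
#' Maximal runs of non-wear windows become intervals.
#'
#' @param rec a `RawRecording` of at least two minutes.
#' @param params a [zhou_params()] object.
#' @return an `AnnotationSet`; attribute `algorithm = "zhou"`.
#' @export
zhou_detect <- function(rec, params = zhou_params()) {
  stopifnot(inherits(rec, "RawRecording"))
  if (rec_duration(rec) < 2 * params$window_min * 60)
    stop("recording must cover at least two classification windows")
  w_s <- params$window_min * 60
  n_win <- floor(rec_duration(rec) / w_s)
  # centred moving-average smoothing of the temperature stream
  span <- max(1L, round(params$smooth_span_min * 60 * rec$fs_temp))
  ts <- as.numeric(stats::filter(rec$temp, rep(1 / span, span), sides = 2))
  ts[is.na(ts)] <- rec$temp[is.na(ts)]          # edges: fall back to raw
  spw_t <- round(w_s * rec$fs_temp)
  spw_a <- round(w_s * rec$fs_accel)
  mean_t <- vapply(seq_len(n_win), function(k)
    mean(ts[((k - 1L) * spw_t + 1L):(k * spw_t)]), 0)
  sd_ok <- rep(TRUE, n_win)
  for (j in 1:3) {
    x <- rec$accel[, j] - mean(rec$accel[, j])
    cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x * x))
    i0 <- (seq_len(n_win) - 1L) * spw_a + 1L
    i1 <- seq_len(n_win) * spw_a
    v <- pmax(0, (cs2[i1 + 1L] - cs2[i0]) / spw_a -
                ((cs[i1 + 1L] - cs[i0]) / spw_a)^2)
    sd_ok <- sd_ok & (sqrt(v) * 1000 < params$sd_thresh)
  }
  cold <- mean_t <= params$temp_thresh
  falling <- c(FALSE, mean_t[-1] < mean_t[-n_win])
  nonwear <- (cold & sd_ok) | (cold & falling)
  iv <- runs_to_intervals(nonwear, rec$start_time, w_s)
  out <- annotation_set(rep(rec$participant_id, length.out = nrow(iv)),
                        iv$start, iv$end, source = "algorithm")
  attr(out, "algorithm") <- "zhou"
  out
}
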