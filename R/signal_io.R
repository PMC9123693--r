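# Canonical data model for dual-rate wrist-device recordings (tri-axial
# acceleration + near-body temperature) and non-wear annotation sets, with
# EDF and plain-CSV serialization.

#' Construct a raw dual-rate device recording
#'
#' A `RawRecording` couples a tri-axial acceleration stream (gravity units,
#' nominally 75 Hz) with a near-body temperature stream (degrees Celsius,
#' nominally 0.25 Hz) under a single absolute start time.  The two streams
#' must describe the same span of time to within one temperature sample
#' period, and the acceleration sample rate must be an integer multiple of
#' the temperature sample rate.
#'
#' @param participant_id single string identifying the wearer.
#' @param start_time absolute start of the recording (coerced to UTC).
#' @param accel numeric matrix with three columns (x, y, z) in g.
#' @param temp numeric vector of temperatures in degrees Celsius.
#' @param fs_accel acceleration sampling rate in Hz (default 75).
#' @param fs_temp temperature sampling rate in Hz (default 0.25).
#' @param meta named list of free-form metadata.  `meta$dynamic_range_g`
#'   (default 8) declares the accelerometer's dynamic range; samples outside
#'   it are rejected.
#' @return an object of class `RawRecording`.
#' @export
raw_recording <- function(participant_id, start_time, accel, temp,
                          fs_accel = 75, fs_temp = 0.25, meta = list()) {
  if (!is.character(participant_id) || length(participant_id) != 1L)
    stop("`participant_id` must be a single string")
  start_time <- as_utc(start_time)
  accel <- as.matrix(accel)
  storage.mode(accel) <- "double"
  if (ncol(accel) != 3L)
    stop("`accel` must have three columns (x, y, z)")
  temp <- as.numeric(temp)
  if (!is.numeric(fs_accel) || fs_accel <= 0 || !is.numeric(fs_temp) || fs_temp <= 0)
    stop("sampling rates must be positive")
  ratio <- fs_accel / fs_temp
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("`fs_accel` must be an integer multiple of `fs_temp`")
  rng <- meta$dynamic_range_g %||% 8
  if (nrow(accel) > 0L && max(abs(accel)) > rng + 1e-9)
    stop(sprintf("acceleration exceeds the declared +/-%g g dynamic range", rng))
  dur_a <- nrow(accel) / fs_accel
  dur_t <- length(temp) / fs_temp
  if (abs(dur_a - dur_t) > 1 / fs_temp + 1e-9)
    stop(sprintf(
      "stream durations disagree beyond one temperature sample: accel %.2f s, temp %.2f s",
      dur_a, dur_t))
  structure(
    list(participant_id = participant_id, start_time = start_time,
         accel = accel, temp = temp, fs_accel = fs_accel, fs_temp = fs_temp,
         meta = meta),
    class = "RawRecording")
}

#' Recording duration in seconds
#'
#' The acceleration stream is the canonical clock; both streams agree with it
#' to within one temperature sample by construction.
#'
#' @param rec a `RawRecording`.
#' @return duration in seconds.
#' @export
rec_duration <- function(rec) {
  stopifnot(inherits(rec, "RawRecording"))
  nrow(rec$accel) / rec$fs_accel
}

#' @export
print.RawRecording <- function(x, ...) {
  cat(sprintf(
    "RawRecording '%s': %.1f h from %s\n  accel %d x 3 @ %g Hz, temp %d @ %g Hz\n",
    x$participant_id, rec_duration(x) / 3600, format_iso(x$start_time),
    nrow(x$accel), x$fs_accel, length(x$temp), x$fs_temp))
  invisible(x)
}

#' Truncate a recording at an absolute end time
#'
#' Both streams are cut at `end_time`; used to crop a recording to the end
#' of data collection (final device removal).
#'
#' @param rec a `RawRecording`.
#' @param end_time absolute timestamp, or a number of seconds from the
#'   recording start.  Must lie in `(start, recording end]`.
#' @return the cropped `RawRecording`.
#' @export
crop_recording <- function(rec, end_time) {
  stopifnot(inherits(rec, "RawRecording"))
  off <- if (is.numeric(end_time)) end_time else
    as.numeric(difftime(as_utc(end_time), rec$start_time, units = "secs"))
  dur <- rec_duration(rec)
  if (off <= 0 || off > dur + 1e-9)
    stop(sprintf("crop point %.1f s outside recording bounds (0, %.1f]", off, dur))
  n_a <- round(off * rec$fs_accel)
  n_t <- round(off * rec$fs_temp)
  raw_recording(rec$participant_id, rec$start_time,
                rec$accel[seq_len(min(n_a, nrow(rec$accel))), , drop = FALSE],
                rec$temp[seq_len(min(n_t, length(rec$temp)))],
                rec$fs_accel, rec$fs_temp, rec$meta)
}

#' Construct a validated non-wear annotation set
#'
#' Intervals are half-open `[start, end)`, must be sorted by start, strictly
#' positive in length and non-overlapping.  Touching intervals
#' (`end[i] == start[i+1]`) are legal and are never merged here; merging is
#' an explicit evaluation-layer choice.
#'
#' @param participant_id single string.
#' @param start,end POSIXct (or coercible) interval bounds.
#' @param source provenance: one of `"expert"`, `"synthetic_truth"`,
#'   `"algorithm"`.
#' @param extra optional data.frame of per-interval columns (e.g. detection
#'   pathway) carried along unchanged.
#' @return data.frame of class `AnnotationSet` with columns
#'   `participant_id`, `start`, `end` plus any extras; attribute `source`.
#' @export
annotation_set <- function(participant_id, start, end,
                           source = c("algorithm", "expert", "synthetic_truth"),
                           extra = NULL) {
  source <- match.arg(source)
  start <- as_utc(start); end <- as_utc(end)
  if (length(start) != length(end))
    stop("`start` and `end` must have equal length")
  if (!is.character(participant_id) ||
      !(length(participant_id) %in% c(1L, length(start))))
    stop("`participant_id` must be a single string (or one per interval)")
  if (any(end <= start))
    stop("every interval must satisfy start < end")
  if (is.unsorted(as.numeric(start), strictly = FALSE))
    stop("intervals must be sorted by start time")
  n <- length(start)
  if (n > 1L && any(as.numeric(start[-1]) < as.numeric(end[-n]) - 1e-9))
    stop("intervals must not overlap")
  out <- data.frame(participant_id = rep(participant_id, length.out = n),
                    start = start, end = end)
  if (!is.null(extra)) {
    stopifnot(nrow(extra) == n)
    out <- cbind(out, extra)
  }
  structure(out, source = source, class = c("AnnotationSet", "data.frame"))
}

#' Read / write annotation sets as CSV
#'
#' CSV columns: `participant_id`, `start`, `end` (ISO-8601 UTC), plus any
#' extra columns which are preserved verbatim.  Intervals are validated and
#' sorted on read; overlap or non-positive length is an error.
#'
#' @param path file path.
#' @param source provenance tag to attach on read.
#' @return `read_annotations` returns an `AnnotationSet` (possibly with zero
#'   rows); `write_annotations` returns `path` invisibly.
#' @export
read_annotations <- function(path, source = "algorithm") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "start", "end")
  if (!all(need %in% names(df)))
    stop("annotations CSV must have columns participant_id, start, end")
  if (nrow(df) == 0L)
    return(annotation_set(character(0), as_utc(character(0)),
                          as_utc(character(0)), source = source))
  df <- df[order(df$participant_id, df$start), , drop = FALSE]
  extra <- df[setdiff(names(df), need)]
  if (ncol(extra) == 0L) extra <- NULL
  # validate per participant, then bind
  pieces <- lapply(split(seq_len(nrow(df)), df$participant_id), function(i) {
    annotation_set(df$participant_id[i[1]], parse_iso(df$start[i]),
                   parse_iso(df$end[i]), source = source,
                   extra = if (is.null(extra)) NULL else extra[i, , drop = FALSE])
  })
  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  structure(out, source = source, class = c("AnnotationSet", "data.frame"))
}

#' @rdname read_annotations
#' @param set an `AnnotationSet`.
#' @export
write_annotations <- function(set, path) {
  df <- as.data.frame(set)
  df$start <- format_iso(df$start)
  df$end <- format_iso(df$end)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# EDF serialization.  Minimal implementation of the 16-bit European Data
# Format: 256-byte fixed header, 256 bytes per signal header, then data
# records of little-endian 16-bit integers.  One record spans the smallest
# whole number of seconds giving integer sample counts on both streams
# (4 s under the 75 Hz / 0.25 Hz defaults).

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  formatC(s, width = -width)
}

edf_record_seconds <- function(fs_accel, fs_temp) {
  for (d in 1:3600) {
    if (abs(fs_accel * d - round(fs_accel * d)) < 1e-9 &&
        abs(fs_temp * d - round(fs_temp * d)) < 1e-9 &&
        round(fs_temp * d) >= 1)
      return(d)
  }
  stop("no EDF record duration up to 1 h yields whole samples per record")
}

default_edf_labels <- function() {
  c(x = "Accelerometer X", y = "Accelerometer Y", z = "Accelerometer Z",
    temp = "Temperature")
}

write_edf_recording <- function(rec, path, label_map = default_edf_labels()) {
  d <- edf_record_seconds(rec$fs_accel, rec$fs_temp)
  spr_a <- round(rec$fs_accel * d)
  spr_t <- round(rec$fs_temp * d)
  n_rec <- nrow(rec$accel) / spr_a
  if (abs(n_rec - round(n_rec)) > 1e-9)
    stop(sprintf("recording length must be a whole number of %d s EDF records", d))
  n_rec <- round(n_rec)
  if (round(rec_duration(rec) * rec$fs_temp) != n_rec * spr_t)
    stop("temperature stream does not fill a whole number of EDF records")
  rng <- rec$meta$dynamic_range_g %||% 8
  t_min <- floor(min(rec$temp)) - 1
  t_max <- ceiling(max(rec$temp)) + 1
  p_min <- c(-rng, -rng, -rng, t_min)
  p_max <- c(rng, rng, rng, t_max)
  d_min <- -32768L; d_max <- 32767L
  to_dig <- function(x, lo, hi)
    as.integer(round((x - lo) / (hi - lo) * (d_max - d_min) + d_min))
  con <- file(path, "wb")
  on.exit(close(con))
  st <- as_utc(rec$start_time)
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(gsub("\\s+", "_", rec$participant_id), 80),
    edf_field(paste("Startdate", toupper(format(st, "%d-%b-%Y", tz = "UTC"))), 80),
    edf_field(format(st, "%d.%m.%y", tz = "UTC"), 8),
    edf_field(format(st, "%H.%M.%S", tz = "UTC"), 8),
    edf_field(256L * 5L, 8),
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_field(d, 8),
    edf_field(4L, 4))
  labels <- unname(label_map[c("x", "y", "z", "temp")])
  units <- c("g", "g", "g", "degC")
  spr <- c(spr_a, spr_a, spr_a, spr_t)
  sig <- paste0(
    paste(vapply(labels, edf_field, "", width = 16), collapse = ""),
    paste(rep(edf_field("", 80), 4), collapse = ""),
    paste(vapply(units, edf_field, "", width = 8), collapse = ""),
    paste(vapply(p_min, edf_field, "", width = 8), collapse = ""),
    paste(vapply(p_max, edf_field, "", width = 8), collapse = ""),
    paste(rep(edf_field(d_min, 8), 4), collapse = ""),
    paste(rep(edf_field(d_max, 8), 4), collapse = ""),
    paste(rep(edf_field("", 80), 4), collapse = ""),
    paste(vapply(spr, edf_field, "", width = 8), collapse = ""),
    paste(rep(edf_field("", 32), 4), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)
  blocks <- rbind(
    matrix(to_dig(rec$accel[, 1], -rng, rng), nrow = spr_a),
    matrix(to_dig(rec$accel[, 2], -rng, rng), nrow = spr_a),
    matrix(to_dig(rec$accel[, 3], -rng, rng), nrow = spr_a),
    matrix(to_dig(rec$temp, t_min, t_max), nrow = spr_t))
  writeBin(as.integer(as.vector(blocks)), con, size = 2L, endian = "little")
  invisible(path)
}

read_edf_recording <- function(path, label_map = default_edf_labels()) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  readChar(con, 8, useBytes = TRUE)              # version
  pid <- rd(80); rd(80)                          # patient, recording ids
  date <- rd(8); time <- rd(8)
  rd(8); rd(44)                                  # header bytes, reserved
  n_rec <- as.integer(rd(8))
  d <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) readChar(con, 16, useBytes = TRUE), ""))
  for (i in seq_len(ns)) readChar(con, 80, useBytes = TRUE)   # transducer
  for (i in seq_len(ns)) readChar(con, 8, useBytes = TRUE)    # units
  p_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  p_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  d_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  d_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) readChar(con, 80, useBytes = TRUE)   # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) readChar(con, 32, useBytes = TRUE)   # reserved
  idx <- match(tolower(label_map[c("x", "y", "z", "temp")]), tolower(labels))
  if (anyNA(idx))
    stop(sprintf(
      "EDF channels not identifiable; expected %s but file contains: %s",
      paste(label_map, collapse = ", "), paste(labels, collapse = ", ")))
  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2L,
                 endian = "little", signed = TRUE)
  if (length(raw) < n_rec * sum(spr))
    stop("EDF data section shorter than the header declares")
  big <- matrix(raw, nrow = sum(spr))
  offs <- c(0L, cumsum(spr))
  phys <- function(i) {
    dig <- as.vector(big[(offs[i] + 1L):offs[i + 1L], , drop = FALSE])
    (dig - d_min[i]) / (d_max[i] - d_min[i]) * (p_max[i] - p_min[i]) + p_min[i]
  }
  yy <- as.integer(substr(date, 7, 8))
  year <- if (!is.na(yy) && yy >= 85) 1900L + yy else 2000L + yy
  st <- as.POSIXct(sprintf("%04d-%s-%s %s", year, substr(date, 4, 5),
                           substr(date, 1, 2), gsub("\\.", ":", time)),
                   tz = "UTC")
  raw_recording(pid, st, cbind(phys(idx[1]), phys(idx[2]), phys(idx[3])),
                phys(idx[4]), fs_accel = spr[idx[1]] / d,
                fs_temp = spr[idx[4]] / d)
}

# ---------------------------------------------------------------------------
# Long-format CSV (timestamp, channel, value) for small, human-readable
# fixtures.  Sample rates are inferred from the channel timestamps.

write_csv_recording <- function(rec, path) {
  st <- as.numeric(rec$start_time)
  ts_a <- st + (seq_len(nrow(rec$accel)) - 1L) / rec$fs_accel
  ts_t <- st + (seq_len(length(rec$temp)) - 1L) / rec$fs_temp
  fmt <- function(t) format(as.POSIXct(t, tz = "UTC", origin = "1970-01-01"),
                            "%Y-%m-%dT%H:%M:%OS6Z", tz = "UTC")
  df <- data.frame(
    participant_id = rec$participant_id,
    timestamp = c(rep(fmt(ts_a), 3L), fmt(ts_t)),
    channel = rep(c("accel_x", "accel_y", "accel_z", "temperature"),
                  times = c(nrow(rec$accel), nrow(rec$accel), nrow(rec$accel),
                            length(rec$temp))),
    value = c(rec$accel[, 1], rec$accel[, 2], rec$accel[, 3], rec$temp))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_recording <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "channel", "value")
  if (!all(need %in% names(df)))
    stop("recording CSV must have columns timestamp, channel, value")
  pid <- if ("participant_id" %in% names(df)) as.character(df$participant_id[1]) else "unknown"
  t <- as.numeric(as.POSIXct(strptime(sub("Z$", "", df$timestamp),
                                      "%Y-%m-%dT%H:%M:%OS", tz = "UTC"), tz = "UTC"))
  chans <- split(data.frame(t = t, v = df$value), df$channel)
  need_ch <- c("accel_x", "accel_y", "accel_z", "temperature")
  if (!all(need_ch %in% names(chans)))
    stop(sprintf("recording CSV must contain channels %s; found: %s",
                 paste(need_ch, collapse = ", "),
                 paste(names(chans), collapse = ", ")))
  infer_fs <- function(ch) {
    if (nrow(ch) < 2L) stop("each channel needs at least two samples")
    fs <- (nrow(ch) - 1) / (max(ch$t) - min(ch$t))
    round(fs * 4) / 4   # snap to a quarter-Hz grid (covers 75 and 0.25 Hz)
  }
  ax <- chans$accel_x[order(chans$accel_x$t), ]
  ay <- chans$accel_y[order(chans$accel_y$t), ]
  az <- chans$accel_z[order(chans$accel_z$t), ]
  tt <- chans$temperature[order(chans$temperature$t), ]
  raw_recording(pid,
                as.POSIXct(min(t), tz = "UTC", origin = "1970-01-01"),
                cbind(ax$v, ay$v, az$v), tt$v,
                fs_accel = infer_fs(ax), fs_temp = infer_fs(tt))
}

#' Read / write a device recording
#'
#' EDF is the interchange format (16-bit quantization within each channel's
#' declared physical range); the long CSV format (`timestamp, channel,
#' value`) is intended for small test fixtures.
#'
#' @param path file path; format is inferred from the extension when
#'   `format = "auto"`.
#' @param format `"edf"`, `"csv"`, or `"auto"`.
#' @param label_map named character vector mapping `x`, `y`, `z`, `temp` to
#'   EDF channel labels (defaults match GENEActiv conventions).
#' @return `read_recording` returns a `RawRecording`; `write_recording`
#'   returns `path` invisibly.
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"),
                           label_map = default_edf_labels()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "edf"
  switch(format,
         edf = read_edf_recording(path, label_map),
         csv = read_csv_recording(path))
}

#' @rdname read_recording
#' @param rec a `RawRecording` with non-empty streams.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "csv"),
                            label_map = default_edf_labels()) {
  stopifnot(inherits(rec, "RawRecording"))
  format <- match.arg(format)
  if (nrow(rec$accel) == 0L || length(rec$temp) == 0L)
    stop("empty recordings are not serializable")
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "edf"
  switch(format,
         edf = write_edf_recording(rec, path, label_map),
         csv = write_csv_recording(rec, path))
}
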