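# Small shared helpers (internal).

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(x, tz = "UTC")
}

format_iso <- function(x) format(as_utc(x), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_iso <- function(x) {
  out <- as.POSIXct(strptime(sub("Z$", "", x), "%Y-%m-%dT%H:%M:%OS", tz = "UTC"),
                    tz = "UTC")
  if (anyNA(out) && !all(is.na(x)))
    stop("timestamps must be ISO-8601 (e.g. 2020-01-06T08:30:00Z)")
  out
}

#' Convert maximal runs of TRUE into half-open intervals
#'
#' @param labels logical vector sampled on a uniform grid.
#' @param start_time absolute time of the first grid point.
#' @param step_s grid period in seconds.
#' @return data.frame with POSIXct `start`, `end` columns (half-open
#'   `[start, end)`), zero rows when no run is present.
#' @keywords internal
runs_to_intervals <- function(labels, start_time, step_s) {
  labels[is.na(labels)] <- FALSE
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  start_time <- as_utc(start_time)
  data.frame(
    start = start_time + (starts[keep] - 1) * step_s,
    end = start_time + ends[keep] * step_s
  )
}

# Overlap (seconds) between one interval [s, e) and a set of intervals.
overlap_seconds <- function(s, e, starts, ends) {
  if (length(starts) == 0L) return(0)
  sum(pmax(0, pmin(as.numeric(ends), as.numeric(e)) -
             pmax(as.numeric(starts), as.numeric(s))))
}

# Forward rolling mean of length `w` over a numeric/logical vector; entry i
# averages x[i .. i + w - 1].  Entries whose window leaves the vector are NA
# unless `partial` is TRUE, in which case the available points are averaged.
roll_mean_forward <- function(x, w, partial = FALSE) {
  n <- length(x)
  cs <- cumsum(c(0, as.numeric(x)))
  hi <- pmin(seq_len(n) + w - 1L, n)
  out <- (cs[hi + 1L] - cs[seq_len(n)]) / (hi - seq_len(n) + 1L)
  if (!partial) out[seq_len(n) + w - 1L > n] <- NA_real_
  out
}
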