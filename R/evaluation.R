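# Second-resolution scoring of predicted against reference non-wear:
# per-second label vectors, duration-weighted confusion matrices, the four
# performance metrics, and per-participant aggregation with 95% CIs.

#' Per-second non-wear label vector
#'
#' The evaluation span is partitioned into whole seconds `[s, s + 1)`;
#' second `s` is labelled non-wear when at least half of it is covered by an
#' interval (detector output is snapped to whole seconds upstream, so the
#' majority rule only matters for sub-second reference annotations).
#' Intervals extending beyond the span are clipped with a warning.
#'
#' @param intervals an `AnnotationSet` or data.frame with `start`, `end`.
#' @param span recording bounds: a `RawRecording`, or `list(start=, end=)`
#'   of POSIXct.
#' @return logical vector of length `floor(span seconds)`.
#' @export
labels_per_second <- function(intervals, span) {
  if (inherits(span, "RawRecording"))
    span <- list(start = span$start_time,
                 end = span$start_time + rec_duration(span))
  t0 <- as.numeric(as_utc(span$start))
  t1 <- as.numeric(as_utc(span$end))
  n_sec <- floor(t1 - t0)
  cover <- numeric(n_sec)
  if (nrow(intervals) > 0L) {
    s <- as.numeric(as_utc(intervals$start)) - t0
    e <- as.numeric(as_utc(intervals$end)) - t0
    if (any(s < -1e-9 | e > n_sec + 1e-9))
      warning("intervals extend beyond the evaluation span; clipping")
    s <- pmax(s, 0)
    e <- pmin(e, n_sec)
    for (i in seq_along(s)) {
      if (e[i] <= s[i]) next
      lo <- floor(s[i]); hi <- ceiling(e[i]) - 1
      secs <- lo:hi
      cover[secs + 1L] <- cover[secs + 1L] +
        pmin(e[i], secs + 1) - pmax(s[i], secs)
    }
  }
  cover >= 0.5
}

#' Duration-weighted confusion matrix
#'
#' Positives are non-wear.  Durations are stored in seconds; use
#' [cm_minutes()] to report in minutes.
#'
#' @param pred,ref logical per-second label vectors of equal length.
#' @return list of class `ConfusionMatrix` with elements `tp`, `tn`, `fp`,
#'   `fn` (seconds).
#' @export
confusion <- function(pred, ref) {
  if (length(pred) != length(ref))
    stop("`pred` and `ref` must have equal length")
  structure(list(tp = sum(pred & ref), tn = sum(!pred & !ref),
                 fp = sum(pred & !ref), fn = sum(!pred & ref)),
            class = "ConfusionMatrix")
}

#' Build a confusion matrix directly from the four cell durations
#'
#' @param tp,tn,fp,fn non-negative durations (any consistent unit).
#' @return a `ConfusionMatrix`.
#' @export
confusion_from_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "ConfusionMatrix")
}

#' @export
print.ConfusionMatrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp) / 60, 2, 2, byrow = TRUE,
              dimnames = list(predicted = c("wear", "non-wear"),
                              reference = c("wear", "non-wear")))
  cat("Confusion matrix (minutes):\n")
  print(round(m, 1))
  invisible(x)
}

#' Confusion matrix in minutes
#'
#' @param cm a `ConfusionMatrix` whose cells are in seconds.
#' @return named numeric vector (minutes).
#' @export
cm_minutes <- function(cm) {
  c(tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn) / 60
}

#' Performance metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, F1 `2 PR/(P+R)`, and wear specificity `TN/(TN+FP)`.
#' A metric whose denominator is zero is reported as `NA` (absent), never
#' imputed as zero; F1 is absent when either component is absent or when
#' `P + R = 0`.
#'
#' @param cm a `ConfusionMatrix`.
#' @return named list `precision`, `recall`, `f1`, `accuracy`,
#'   `specificity`, each in `[0, 1]` or `NA`.
#' @export
nonwear_metrics <- function(cm) {
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  p <- safe(cm$tp, cm$tp + cm$fp)
  r <- safe(cm$tp, cm$tp + cm$fn)
  f1 <- if (is.na(p) || is.na(r) || p + r == 0) NA_real_ else
    2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1,
       accuracy = safe(cm$tp + cm$tn, cm$tp + cm$tn + cm$fp + cm$fn),
       specificity = safe(cm$tn, cm$tn + cm$fp))
}

#' Score one participant's detection against reference annotations
#'
#' @param pred,ref `AnnotationSet`s (or data.frames with `start`, `end`).
#' @param span evaluation span (see [labels_per_second()]).
#' @return list with the `ConfusionMatrix` and the metric list.
#' @export
evaluate_detection <- function(pred, ref, span) {
  cm <- confusion(labels_per_second(pred, span), labels_per_second(ref, span))
  list(confusion = cm, metrics = nonwear_metrics(cm))
}

#' Aggregate per-participant metrics
#'
#' Means with two-sided 95% confidence intervals from the t distribution
#' across participants, clipped to `[0, 1]`.  Participants whose metric is
#' absent (`NA`) are excluded from that metric's aggregation, with the count
#' reported.  With a single participant the mean is reported and the CI is
#' absent.
#'
#' @param per_participant data.frame with one row per participant and metric
#'   columns (any of `precision`, `recall`, `f1`, `accuracy`,
#'   `specificity`).
#' @param conf confidence level (default 0.95).
#' @return data.frame of class `MetricsReport`: one row per metric with
#'   `mean`, `ci_lo`, `ci_hi`, `n_used`, `n_excluded`.
#' @export
aggregate_metrics <- function(per_participant, conf = 0.95) {
  cols <- intersect(c("precision", "recall", "f1", "accuracy", "specificity"),
                    names(per_participant))
  if (length(cols) == 0L) stop("no metric columns found")
  rows <- lapply(cols, function(cl) {
    x <- per_participant[[cl]]
    n_ex <- sum(is.na(x))
    x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0L)
      return(data.frame(metric = cl, mean = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, n_used = 0L, n_excluded = n_ex))
    m <- mean(x)
    if (n >= 2L) {
      half <- stats::qt(1 - (1 - conf) / 2, df = n - 1L) *
        stats::sd(x) / sqrt(n)
      lo <- max(0, m - half); hi <- min(1, m + half)
    } else {
      lo <- NA_real_; hi <- NA_real_
    }
    data.frame(metric = cl, mean = m, ci_lo = lo, ci_hi = hi,
               n_used = n, n_excluded = n_ex)
  })
  structure(do.call(rbind, rows), class = c("MetricsReport", "data.frame"))
}

#' Pool per-participant confusion matrices
#'
#' @param cms list of `ConfusionMatrix` objects.
#' @return the cell-wise sum as a `ConfusionMatrix`.
#' @export
pool_confusions <- function(cms) {
  confusion_from_counts(sum(vapply(cms, `[[`, 0, "tp")),
                        sum(vapply(cms, `[[`, 0, "tn")),
                        sum(vapply(cms, `[[`, 0, "fp")),
                        sum(vapply(cms, `[[`, 0, "fn")))
}
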