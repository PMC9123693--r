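# Lazily-computed, cached battery results shared by the acceptance tests,
# so each synthetic battery is generated and scored exactly once per test
# run.  The master seed is fixed; recordings are processed one at a time to
# bound memory.

BATTERY_SEED <- 1L

.battery_cache <- new.env(parent = emptyenv())

battery_results <- function(name, algorithms = c("detach")) {
  key <- paste(name, paste(sort(algorithms), collapse = "+"))
  if (!is.null(.battery_cache[[key]])) return(.battery_cache[[key]])
  out <- lapply(scenario_configs(name, seed = BATTERY_SEED), function(cf) {
    g <- generate_recording(cf)
    ref <- labels_per_second(g$truth, g$recording)
    span <- list(start = g$recording$start_time,
                 end = g$recording$start_time + rec_duration(g$recording))
    res <- list(truth = g$truth, sleep_blocks = g$sleep_blocks,
                start_time = g$recording$start_time,
                duration_s = rec_duration(g$recording))
    for (alg in algorithms) {
      iv <- switch(alg,
                   detach = detect_nonwear(g$recording),
                   zhou = zhou_detect(g$recording),
                   vanhees = vanhees_detect(g$recording))
      cm <- confusion(labels_per_second(iv, span), ref)
      res[[alg]] <- list(intervals = iv, cm = cm,
                         metrics = nonwear_metrics(cm))
    }
    res
  })
  .battery_cache[[key]] <- out
  out
}
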