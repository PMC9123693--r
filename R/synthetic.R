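# Synthetic recording generator: produces RawRecordings with exact
# ground-truth non-wear annotations whose temperature and acceleration
# dynamics follow the cohort statistics the detector was built around
# (wear temperature ~29 +/- 2 degC, removal cooling edges ~ -0.4 degC/min,
# donning warming edges ~ +0.36 degC/min, removal durations log-normal with
# median 23 min and ~85% under an hour, sleep as quiet-but-warm epochs).

#' Synthetic recording configuration
#'
#' Temperature follows Newtonian relaxation toward a state-dependent target
#' (skin-coupled during wear, ambient during non-wear) plus AR(1)
#' measurement noise; acceleration is a gravity-oriented baseline (re-drawn
#' at bout boundaries during wear, frozen during non-wear) plus Gaussian
#' bout noise at per-axis SD targets.  Removal durations are log-normal
#' (median `exp(removal_meanlog)` minutes); each removal is flanked by
#' forced active bouts and preceded/followed by brief high-SD handling
#' bursts (taking the device off / putting it back on).  Sleep blocks are
#' quiet with a stable target of 30.5-32.5 degC, above the 30 degC absolute
#' gate of the start rules.  Motion artifacts (brief bumps) are placed in
#' the interior of sufficiently long removals.
#'
#' @param seed integer RNG seed; generation is bit-reproducible per seed.
#' @param participant_id identifier string.
#' @param start_time recording start (UTC).
#' @param duration_h recording length in hours.
#' @param ambient_c ambient temperature, degC.
#' @param skin_c_mean,skin_c_sd per-participant skin temperature draw, degC.
#' @param contact_offset_c device reads this much below skin during wear.
#' @param cool_rate_const per-minute Newtonian constant toward ambient
#'   during non-wear (0.045/min gives ~ -0.4 degC/min at a 9 degC gap).
#' @param warm_rate_const per-minute constant toward the wear target.
#' @param n_removals number of removals, or `NULL` to draw uniformly from
#'   `n_removals_range`.
#' @param n_removals_range inclusive range for the removal count draw.
#' @param removal_meanlog,removal_sdlog log-normal duration parameters
#'   (minutes); defaults give median 23 min and ~85.5% below 60 min.
#' @param removal_dur_range_min clamp for sampled durations, minutes.
#' @param removal_durations_min optional explicit durations (overrides the
#'   sampler).
#' @param sleep_blocks data.frame with `start_h`, `end_h` columns, or
#'   `NULL`; default one block over hours 0-8 for recordings of 10 h or
#'   more.
#' @param sleep_temp_range sleep target temperature range, degC.
#' @param activity_sd_mg named list of per-axis SD ranges (mg) for
#'   `sedentary`, `light`, `active`, `sleep` states.
#' @param bout_dur_range_min wake activity bout duration range, minutes.
#' @param bout_probs sampling weights for sedentary/light/active bouts; two
#'   sedentary bouts never occur back to back (the next state is re-drawn),
#'   so motionless wear runs stay bounded.
#' @param artifact_rate_per_h expected bumps per hour of non-wear.
#' @param artifact_dur_s,artifact_sd_mg bump duration (s) and SD (mg) ranges.
#' @param artifact_edge_gap_min bumps are kept this far from the removal
#'   start (and 2 min from its end).
#' @param artifact_min_removal_min bumps only occur in removals at least
#'   this long.
#' @param outdoor_n number of cold outdoor wear epochs (0 outside the
#'   cold-ambient scenario); during them the device cools toward
#'   `outdoor_temp_c` while the wearer keeps moving.
#' @param outdoor_dur_min,outdoor_temp_c outdoor epoch duration range and
#'   device temperature target.
#' @param temp_noise_sd,temp_ar1 stationary SD and lag-1 coefficient of the
#'   AR(1) temperature measurement noise.
#' @param accel_noise_floor_mg sensor noise during undisturbed non-wear.
#' @param handling_dur_s,handling_sd_mg removal/donning handling burst
#'   duration (s) and SD range (mg).
#' @param flank_active_min forced active-bout length before each removal,
#'   minutes, and the minimum forced-active length after it.
#' @param recovery_temp_c the wearer keeps moving after re-donning until the
#'   modeled device temperature clears this value (people re-don the device
#'   in the middle of the activity that prompted the removal); above it,
#'   normal bout sampling resumes.
#' @param post_flank_cap_min cap on the post-donning forced-active flank,
#'   minutes.
#' @param fs_accel,fs_temp stream sample rates, Hz.
#' @return a `SyntheticConfig` list.
#' @export
synthetic_config <- function(seed = 1L,
                             participant_id = "synth-01",
                             start_time = as.POSIXct("2020-01-06 00:00:00",
                                                     tz = "UTC"),
                             duration_h = 24,
                             ambient_c = 21,
                             skin_c_mean = 31, skin_c_sd = 1.5,
                             contact_offset_c = 2,
                             cool_rate_const = 0.045,
                             warm_rate_const = 0.04,
                             n_removals = NULL,
                             n_removals_range = c(2L, 6L),
                             removal_meanlog = log(23),
                             removal_sdlog = 0.906,
                             removal_dur_range_min = c(3, 240),
                             removal_durations_min = NULL,
                             sleep_blocks = NULL,
                             sleep_temp_range = c(30.5, 32.5),
                             activity_sd_mg = list(sedentary = c(2, 6),
                                                   light = c(10, 40),
                                                   active = c(50, 300),
                                                   sleep = c(1.5, 4)),
                             bout_dur_range_min = c(10, 45),
                             bout_probs = c(sedentary = 0.45, light = 0.35,
                                            active = 0.20),
                             artifact_rate_per_h = 0.5,
                             artifact_dur_s = c(10, 25),
                             artifact_sd_mg = c(15, 30),
                             artifact_edge_gap_min = 7,
                             artifact_min_removal_min = 30,
                             outdoor_n = 0,
                             outdoor_dur_min = c(20, 40),
                             outdoor_temp_c = 24,
                             temp_noise_sd = 0.1, temp_ar1 = 0.9,
                             accel_noise_floor_mg = 0.3,
                             handling_dur_s = 20,
                             handling_sd_mg = c(30, 80),
                             flank_active_min = 15,
                             recovery_temp_c = 26.5,
                             post_flank_cap_min = 35,
                             fs_accel = 75, fs_temp = 0.25) {
  stopifnot(duration_h > 0, cool_rate_const > 0, warm_rate_const > 0,
            temp_noise_sd >= 0, temp_ar1 >= 0, temp_ar1 < 1)
  if (is.null(sleep_blocks) && duration_h >= 10)
    sleep_blocks <- data.frame(start_h = 0, end_h = 8)
  cfg <- as.list(environment())
  structure(cfg, class = "SyntheticConfig")
}

#' Draw removal durations from the configured distribution
#'
#' Log-normal in minutes, clamped to `removal_dur_range_min`.
#'
#' @param n number of draws.
#' @param config a [synthetic_config()].
#' @return numeric vector of durations in minutes.
#' @export
draw_removal_durations <- function(n, config = synthetic_config()) {
  d <- stats::rlnorm(n, config$removal_meanlog, config$removal_sdlog)
  pmin(pmax(d, config$removal_dur_range_min[1]), config$removal_dur_range_min[2])
}

# --- schedule ---------------------------------------------------------------
# The schedule is a per-cell state vector on the 0.25 Hz grid (one cell =
# one temperature sample = 4 s at the defaults).

CELL_S <- function(config) 1 / config$fs_temp

build_schedule <- function(config, wear_c = config$skin_c_mean -
                             config$contact_offset_c) {
  cell_s <- CELL_S(config)
  n <- round(config$duration_h * 3600 / cell_s)
  cells_per_min <- round(60 / cell_s)
  state <- rep("wake", n)

  # Forced-active flank after a removal of `d` minutes: the wearer keeps
  # moving until the modeled device temperature recovers past
  # recovery_temp_c (Newtonian closed form), within [flank_active_min,
  # post_flank_cap_min].
  post_flank_cells <- function(d) {
    gap0 <- max(wear_c - config$ambient_c, 0.1)
    t_don <- config$ambient_c + gap0 * exp(-config$cool_rate_const * d)
    gap_don <- max(wear_c - t_don, 0.05)
    margin <- wear_c - config$recovery_temp_c
    rec_min <- if (margin <= 0.3) config$post_flank_cap_min else
      log(gap_don / margin) / config$warm_rate_const + 2
    round(min(config$post_flank_cap_min,
              max(config$flank_active_min, rec_min)) * cells_per_min)
  }

  sleep <- config$sleep_blocks
  if (!is.null(sleep) && nrow(sleep)) {
    for (b in seq_len(nrow(sleep))) {
      i0 <- round(sleep$start_h[b] * 3600 / cell_s) + 1L
      i1 <- min(round(sleep$end_h[b] * 3600 / cell_s), n)
      if (i0 <= i1) state[i0:i1] <- "sleep"
    }
  }

  # removal placement: each removal plus its active flanks must fit inside a
  # contiguous wake region, away from the recording edges
  n_rem <- if (!is.null(config$removal_durations_min))
    length(config$removal_durations_min)
  else if (!is.null(config$n_removals)) config$n_removals
  else sample(config$n_removals_range[1]:config$n_removals_range[2], 1L)
  durs <- config$removal_durations_min %||% draw_removal_durations(n_rem, config)
  flank <- round(config$flank_active_min * cells_per_min)
  edge <- 15L * cells_per_min
  placed <- data.frame(start = integer(0), end = integer(0))
  occupied <- state != "wake"
  occupied[seq_len(min(edge, n))] <- TRUE
  if (edge < n) occupied[(n - edge + 1L):n] <- TRUE
  for (d in durs) {
    len <- max(1L, round(d * cells_per_min))
    post <- post_flank_cells(d)
    ok <- FALSE
    for (try in 1:200) {
      s <- sample.int(n - len - flank - post, 1L) + flank
      span <- (s - flank):(s + len - 1L + post)
      if (max(span) > n) next
      if (!any(occupied[span])) { ok <- TRUE; break }
    }
    if (!ok) next   # could not place this removal; drop it
    placed <- rbind(placed, data.frame(start = s, end = s + len))  # half-open
    occupied[(max(1L, s - flank - 2L * cells_per_min)):
               min(n, s + len - 1L + post + 2L * cells_per_min)] <- TRUE
    state[s:(s + len - 1L)] <- "nonwear"
    state[(s - flank):(s - 1L)] <- "active"
    state[(s + len):(s + len - 1L + post)] <- "active"
  }
  placed <- placed[order(placed$start), , drop = FALSE]

  # outdoor cold epochs (cold-ambient scenario): wearer keeps moving
  if (config$outdoor_n > 0) {
    for (k in seq_len(config$outdoor_n)) {
      len <- round(stats::runif(1, config$outdoor_dur_min[1],
                                config$outdoor_dur_min[2]) * cells_per_min)
      for (try in 1:200) {
        s <- sample.int(max(1L, n - len - edge), 1L) + edge %/% 2L
        span <- s:(s + len - 1L)
        if (max(span) <= n && all(state[span] == "wake")) {
          state[span] <- "outdoor"
          break
        }
      }
    }
  }

  # partition remaining wake time into activity bouts; never two sedentary
  # bouts back to back, so motionless wear runs stay bounded
  kinds <- names(config$bout_probs)
  i <- 1L
  prev_kind <- ""
  while (i <= n) {
    if (state[i] != "wake") { i <- i + 1L; next }
    j <- i
    while (j < n && state[j + 1L] == "wake") j <- j + 1L
    k <- i
    while (k <= j) {
      len <- round(stats::runif(1, config$bout_dur_range_min[1],
                                config$bout_dur_range_min[2]) * cells_per_min)
      kind <- sample(kinds, 1L, prob = config$bout_probs)
      if (kind == "sedentary" && prev_kind == "sedentary")
        kind <- sample(c("light", "active"), 1L)
      state[k:min(j, k + len - 1L)] <- kind
      prev_kind <- kind
      k <- k + len
    }
    i <- j + 1L
  }

  # handling bursts: taking the device off just before a removal, putting it
  # back on just after
  hand <- max(1L, round(config$handling_dur_s / cell_s))
  for (r in seq_len(nrow(placed))) {
    s <- placed$start[r]; e <- placed$end[r]
    state[max(1L, s - hand):(s - 1L)] <- "handling"
    state[e:min(n, e + hand - 1L)] <- "handling"
  }

  # motion artifacts inside long removals
  art <- data.frame(start = integer(0), end = integer(0), sd = numeric(0))
  for (r in seq_len(nrow(placed))) {
    len_min <- (placed$end[r] - placed$start[r]) / cells_per_min
    if (len_min < config$artifact_min_removal_min) next
    n_art <- stats::rpois(1, config$artifact_rate_per_h * len_min / 60)
    if (n_art == 0L) next
    lo <- placed$start[r] + round(config$artifact_edge_gap_min * cells_per_min)
    hi <- placed$end[r] - 1L - 2L * cells_per_min
    for (a in seq_len(n_art)) {
      alen <- max(1L, round(stats::runif(1, config$artifact_dur_s[1],
                                         config$artifact_dur_s[2]) / cell_s))
      if (hi - alen <= lo) next
      pos <- lo:(hi - alen)
      s <- pos[sample.int(length(pos), 1L)]
      art <- rbind(art, data.frame(start = s, end = s + alen,
                                   sd = stats::runif(1, config$artifact_sd_mg[1],
                                                     config$artifact_sd_mg[2])))
    }
  }

  list(state = state, removals = placed, artifacts = art, n = n,
       cell_s = cell_s)
}

# --- signal synthesis -------------------------------------------------------

#' Simulate the near-body temperature stream for a schedule
#'
#' Newtonian relaxation per 0.25 Hz step toward a state-dependent target
#' (wear target = skin - contact offset; sleep target; ambient during
#' non-wear; `outdoor_temp_c` during outdoor epochs), continuous at every
#' transition, plus stationary AR(1) measurement noise.
#'
#' @param schedule result of the internal schedule builder (a list with a
#'   per-cell `state` vector), as produced inside [generate_recording()].
#' @param config a [synthetic_config()].
#' @param skin_c participant skin temperature, degC (drawn from the config's
#'   distribution when `NULL`).
#' @param sleep_c sleep target temperature, degC.
#' @return numeric temperature vector at `fs_temp`.
#' @export
simulate_temperature <- function(schedule, config, skin_c = NULL,
                                 sleep_c = NULL) {
  if (is.null(skin_c))
    skin_c <- stats::rnorm(1, config$skin_c_mean, config$skin_c_sd)
  if (is.null(sleep_c))
    sleep_c <- stats::runif(1, config$sleep_temp_range[1],
                            config$sleep_temp_range[2])
  wear_c <- skin_c - config$contact_offset_c
  st <- schedule$state
  n <- schedule$n
  dt_min <- schedule$cell_s / 60
  target <- ifelse(st == "nonwear", config$ambient_c,
            ifelse(st == "sleep", sleep_c,
            ifelse(st == "outdoor", config$outdoor_temp_c, wear_c)))
  k <- ifelse(st == "nonwear", config$cool_rate_const,
       ifelse(st == "sleep", config$warm_rate_const / 2,
       ifelse(st == "outdoor", 0.05, config$warm_rate_const)))
  # Waking is a slow thermal transition: after a sleep block the device
  # drifts back DOWN to the wear baseline at no more than ~0.045 degC/min,
  # so sleep-to-wake edges stay well below the non-wear cooling signature
  # (the discriminating feature of sleep in this model).  The cap applies
  # only while the device is above its target, so re-warming after a
  # removal is never slowed.
  gap_sleep <- sleep_c - wear_c
  slow_mask <- rep(FALSE, n)
  k_slow <- config$warm_rate_const
  if (gap_sleep > 1.1) {
    k_slow <- min(config$warm_rate_const, 0.045 / gap_sleep)
    span <- round(90 * 60 / schedule$cell_s)
    wakeish <- !(st %in% c("sleep", "nonwear"))
    after <- which(st == "sleep" & c(st[-1], "end") != "sleep")
    for (i0 in after) {
      idx <- seq(i0 + 1L, min(n, i0 + span))
      slow_mask[idx[wakeish[idx]]] <- TRUE
    }
  }
  step <- 1 - exp(-k * dt_min)
  step_slow <- 1 - exp(-k_slow * dt_min)
  temp <- numeric(n)
  temp[1] <- target[1]
  for (i in 2:n) {
    s_i <- if (slow_mask[i] && temp[i - 1] > target[i])
      min(step[i], step_slow) else step[i]
    temp[i] <- temp[i - 1] + (target[i] - temp[i - 1]) * s_i
  }
  if (config$temp_noise_sd > 0) {
    innov <- stats::rnorm(n, 0,
                          config$temp_noise_sd * sqrt(1 - config$temp_ar1^2))
    temp <- temp + as.numeric(stats::filter(innov, config$temp_ar1,
                                            method = "recursive"))
  }
  temp
}

#' Simulate the tri-axial acceleration stream for a schedule
#'
#' Gravity-oriented unit baseline, re-drawn at each wear bout boundary and
#' frozen throughout non-wear, plus zero-mean Gaussian noise at the per-axis
#' SD target of each cell's state (sensor noise floor during undisturbed
#' non-wear; scheduled artifact bumps override it).
#'
#' @inheritParams simulate_temperature
#' @return an N x 3 matrix in g at `fs_accel`, clipped to +/- 8 g.
#' @export
simulate_acceleration <- function(schedule, config) {
  st <- schedule$state
  n <- schedule$n
  spc <- round(config$fs_accel * schedule$cell_s)   # samples per cell

  # per-cell SD targets (mg), drawn once per contiguous same-state segment
  sd_cell <- matrix(config$accel_noise_floor_mg, n, 3L)
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rand_unit <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v * v))
  }
  base_cell <- matrix(0, n, 3L)
  orient <- rand_unit()
  for (s in seq_along(r$values)) {
    kind <- r$values[s]
    idx <- starts[s]:ends[s]
    if (kind != "nonwear") orient <- rand_unit()
    base_cell[idx, ] <- matrix(orient, length(idx), 3L, byrow = TRUE)
    rng <- switch(kind,
                  sedentary = config$activity_sd_mg$sedentary,
                  light = config$activity_sd_mg$light,
                  active = ,
                  outdoor = config$activity_sd_mg$active,
                  sleep = config$activity_sd_mg$sleep,
                  handling = config$handling_sd_mg,
                  NULL)
    if (!is.null(rng))
      sd_cell[idx, ] <- matrix(stats::runif(3, rng[1], rng[2]),
                               length(idx), 3L, byrow = TRUE)
  }
  if (nrow(schedule$artifacts)) {
    for (a in seq_len(nrow(schedule$artifacts))) {
      idx <- schedule$artifacts$start[a]:(schedule$artifacts$end[a] - 1L)
      sd_cell[idx, ] <- schedule$artifacts$sd[a]
    }
  }

  idx <- rep(seq_len(n), each = spc)
  N <- n * spc
  acc <- base_cell[idx, , drop = FALSE] +
    matrix(stats::rnorm(N * 3L), N, 3L) * sd_cell[idx, , drop = FALSE] / 1000
  acc[acc > 8] <- 8
  acc[acc < -8] <- -8
  acc
}

#' Generate a synthetic recording with exact ground truth
#'
#' Deterministic per `config$seed` (the caller's RNG state is preserved).
#'
#' @param config a [synthetic_config()].
#' @return list with elements `recording` (`RawRecording`), `truth`
#'   (`AnnotationSet`, source `synthetic_truth`), `schedule` (per-cell state
#'   vector with the cell length as attribute), and `sleep_blocks`.
#' @export
generate_recording <- function(config = synthetic_config()) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  skin_c <- stats::rnorm(1, config$skin_c_mean, config$skin_c_sd)
  sleep_c <- stats::runif(1, config$sleep_temp_range[1],
                          config$sleep_temp_range[2])
  sch <- build_schedule(config, wear_c = skin_c - config$contact_offset_c)
  temp <- simulate_temperature(sch, config, skin_c, sleep_c)
  accel <- simulate_acceleration(sch, config)

  rec <- raw_recording(config$participant_id, config$start_time, accel, temp,
                       config$fs_accel, config$fs_temp,
                       meta = list(synthetic = TRUE, skin_c = skin_c))
  t0 <- as_utc(config$start_time)
  truth <- annotation_set(
    rep(config$participant_id, length.out = nrow(sch$removals)),
    t0 + (sch$removals$start - 1L) * sch$cell_s,
    t0 + (sch$removals$end - 1L) * sch$cell_s,
    source = "synthetic_truth")
  list(recording = rec, truth = truth,
       schedule = structure(sch$state, cell_s = sch$cell_s),
       sleep_blocks = config$sleep_blocks)
}

#' Named scenario batteries
#'
#' `scenario_configs` returns the per-recording configurations (one RNG
#' stream per recording derived from the master seed and participant index);
#' `scenario_battery` generates them all.  Scenarios:
#' \describe{
#'   \item{standard}{defaults: 24 h, ambient 21 degC, 2-6 removals.}
#'   \item{cold_ambient}{ambient 8 degC with outdoor wear epochs in which
#'     the worn device cools below 26 degC while the wearer keeps moving.}
#'   \item{sleep_heavy}{ten quiet, warm sleep blocks per recording.}
#'   \item{short_removals}{4-6 removals, all 5-15 min.}
#'   \item{bumped_nonwear}{frequent motion artifacts during non-wear.}
#' }
#'
#' @param name scenario name.
#' @param seed master seed.
#' @param n_recordings recordings (participants) per battery.
#' @param duration_h recording length, hours.
#' @return `scenario_configs`: list of `SyntheticConfig`;
#'   `scenario_battery`: list of [generate_recording()] results.
#' @export
scenario_configs <- function(name = c("standard", "cold_ambient",
                                      "sleep_heavy", "short_removals",
                                      "bumped_nonwear"),
                             seed = 1L, n_recordings = 10L, duration_h = 24) {
  name <- match.arg(name)
  lapply(seq_len(n_recordings), function(i) {
    s <- as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483629)
    base <- list(seed = s, participant_id = sprintf("%s-%02d", name, i),
                 duration_h = duration_h)
    extra <- switch(name,
      standard = list(),
      cold_ambient = list(ambient_c = 8, outdoor_n = 4,
                          outdoor_dur_min = c(30, 60),
                          n_removals_range = c(1L, 2L)),
      sleep_heavy = list(
        sleep_blocks = data.frame(
          start_h = seq(0, by = duration_h / 10, length.out = 10),
          end_h = seq(0, by = duration_h / 10, length.out = 10) +
            duration_h / 20),
        n_removals = 2L),
      short_removals = list(
        n_removals_range = c(4L, 6L),
        removal_dur_range_min = c(5, 15),
        removal_meanlog = log(10), removal_sdlog = 0.35,
        bout_probs = c(sedentary = 0.2, light = 0.5, active = 0.3),
        bout_dur_range_min = c(10, 30)),
      bumped_nonwear = list(artifact_rate_per_h = 2,
                            artifact_min_removal_min = 10))
    do.call(synthetic_config, c(base, extra))
  })
}

#' @rdname scenario_configs
#' @export
scenario_battery <- function(name, seed = 1L, n_recordings = 10L,
                             duration_h = 24) {
  lapply(scenario_configs(name, seed, n_recordings, duration_h),
         generate_recording)
}
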