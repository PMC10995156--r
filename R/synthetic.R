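# Synthetic cohort generator.
#
# Emulates hip-worn triaxial recordings with known ground truth: a
# gravitational component of exactly unit norm following a circadian posture
# rhythm (longitudinal axis near-vertical during a configurable night block,
# 10-20 degrees off-horizontal by day), Gaussian activity fluctuations scaled
# by an hourly intensity profile, sporadic sleep movements so worn nights are
# distinguishable from non-wear, non-wear episodes (frozen orientation plus
# sensor noise only), per-axis offset/gain distortion, and 12-bit
# quantization with clipping at the dynamic-range edges.

# converts a nominal MAD intensity in mg into the per-axis SD (in g) of the
# dynamic component: for isotropic Gaussian fluctuation the vector-norm MAD
# is sd * sqrt(2/pi)
MAD_TO_SD <- sqrt(pi / 2) * 1e-3

#' Scenario configuration for the synthetic cohort
#'
#' Holds every knob of the generator. Defaults describe the emulated study
#' conditions: 8 recording days, a +/-6 g 12-bit device, activity following a
#' typical population diurnal profile, about one multi-hour non-wear episode
#' per three days, and a 3 mg sensor noise floor. The default desk-scale
#' sampling rate is 20 Hz; all downstream algorithms are rate-parameterised
#' and accept the devices' native 100 Hz.
#'
#' @param n_participants number of participants
#' @param days recording days per participant
#' @param sampling_rate Hz
#' @param dynamic_range device half-range in g, 6 or 8
#' @param quantization_bits ADC resolution
#' @param posture_axis which axis (1-3) is the body's longitudinal axis
#' @param activity_profile 24 per-hour mean movement intensities in mg
#'   (nominal epoch MAD); hours are local clock 0-23
#' @param nonwear_rate expected non-wear episodes per participant-day, used
#'   when `nonwear_episodes` is `NULL`
#' @param nonwear_episodes explicit episodes: a data.frame with columns
#'   `day` (1-based), `start_slot` (0-95) and `n_slots`, or a list of such
#'   data.frames (one per participant, named by participant id)
#' @param nonwear_duration_slots candidate episode lengths in 15-min slots
#' @param calib_offset per-axis additive distortion in g (applied before gain)
#' @param calib_gain per-axis multiplicative distortion (must be > 0)
#' @param noise_sd sensor noise SD in mg
#' @param night_start,night_end night block in local hours (reclined posture)
#' @param day_angle_range daytime longitudinal-axis elevation in degrees;
#'   each participant draws one value from this range
#' @param still_bouts_per_day short motionless bouts at random orientations
#'   per day (device handling at varied poses); these give the calibration
#'   sphere fit its orientation coverage
#' @param still_bout_min duration of each still bout in minutes
#' @param activity_bouts_per_day sustained higher-intensity bouts per day
#' @param bout_intensity added intensity during a bout in mg
#' @param bout_duration_min bout duration range in minutes
#' @param sleep_burst_every_min mean spacing of brief sleep movements
#' @param sleep_burst_sd intensity of sleep movements in mg
#' @param sleep_burst_sec duration of each sleep movement in seconds
#' @param start_date first recording day (a Monday by default)
#' @param seed cohort seed; per-participant substreams are derived by a
#'   stable hash of the participant id so generation order does not matter
#' @return object of class `scenario_config`
#' @export
scenario_config <- function(n_participants = 1L, days = 8L,
                            sampling_rate = 20, dynamic_range = 6,
                            quantization_bits = 12L, posture_axis = 3L,
                            activity_profile = NULL,
                            nonwear_rate = 0.3, nonwear_episodes = NULL,
                            nonwear_duration_slots = 6:16,
                            calib_offset = c(0, 0, 0),
                            calib_gain = c(1, 1, 1),
                            noise_sd = 3,
                            night_start = 23, night_end = 7,
                            day_angle_range = c(10, 20),
                            still_bouts_per_day = 6L, still_bout_min = 2,
                            activity_bouts_per_day = 2L,
                            bout_intensity = 120,
                            bout_duration_min = c(10, 30),
                            sleep_burst_every_min = 6,
                            sleep_burst_sd = 80, sleep_burst_sec = 15,
                            start_date = as.Date("2015-03-02"),
                            seed = 1L) {
  if (is.null(activity_profile))
    activity_profile <- c(1, 1, 1, 1, 1, 2, 12, 25, 28, 25, 22, 25,
                          30, 32, 35, 30, 25, 22, 18, 14, 8, 5, 2, 1)
  stopifnot(n_participants >= 1, days >= 1, sampling_rate > 0,
            dynamic_range %in% c(6, 8), quantization_bits >= 2,
            posture_axis %in% 1:3, length(activity_profile) == 24,
            all(activity_profile >= 0), nonwear_rate >= 0,
            length(calib_offset) == 3, length(calib_gain) == 3,
            all(calib_gain > 0), noise_sd >= 0,
            all(nonwear_duration_slots >= 1))
  structure(list(
    n_participants = as.integer(n_participants), days = as.integer(days),
    sampling_rate = sampling_rate, dynamic_range = dynamic_range,
    quantization_bits = as.integer(quantization_bits),
    posture_axis = as.integer(posture_axis),
    activity_profile = activity_profile,
    nonwear_rate = nonwear_rate, nonwear_episodes = nonwear_episodes,
    nonwear_duration_slots = as.integer(nonwear_duration_slots),
    calib_offset = calib_offset, calib_gain = calib_gain,
    noise_sd = noise_sd, night_start = night_start, night_end = night_end,
    day_angle_range = day_angle_range,
    still_bouts_per_day = as.integer(still_bouts_per_day),
    still_bout_min = still_bout_min,
    activity_bouts_per_day = as.integer(activity_bouts_per_day),
    bout_intensity = bout_intensity, bout_duration_min = bout_duration_min,
    sleep_burst_every_min = sleep_burst_every_min,
    sleep_burst_sd = sleep_burst_sd, sleep_burst_sec = sleep_burst_sec,
    start_date = as.Date(start_date), seed = as.integer(seed)),
    class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<scenario_config> %d participant(s), %d day(s) @ %g Hz, +/-%g g ",
    "(%d-bit), seed %d\n"),
    x$n_participants, x$days, x$sampling_rate, x$dynamic_range,
    x$quantization_bits, x$seed))
  invisible(x)
}

# truncated centered moving average over +/- w entries
moving_average <- function(v, w) {
  n <- length(v)
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  lo <- pmax(i - w - 1L, 0L)
  hi <- pmin(i + w, n)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# draws non-wear episodes for one participant; returns data.frame
# (day, start_slot, n_slots) with no overlaps
draw_nonwear_episodes <- function(config) {
  n_ep <- rpois(1, config$nonwear_rate * config$days)
  out <- data.frame(day = integer(), start_slot = integer(),
                    n_slots = integer())
  taken <- matrix(FALSE, config$days, SLOTS_PER_DAY)
  for (i in seq_len(n_ep)) {
    for (try in 1:25) {
      dur <- if (length(config$nonwear_duration_slots) == 1L)
        config$nonwear_duration_slots else sample(config$nonwear_duration_slots, 1)
      d <- sample.int(config$days, 1)
      s0 <- sample.int(SLOTS_PER_DAY - dur + 1L, 1) - 1L
      if (!any(taken[d, (s0 + 1L):(s0 + dur)])) {
        taken[d, (s0 + 1L):(s0 + dur)] <- TRUE
        out <- rbind(out, data.frame(day = d, start_slot = s0, n_slots = dur))
        break
      }
    }
  }
  out
}

#' Generate one synthetic recording with ground truth
#'
#' @param config a [scenario_config()]
#' @param participant_id identifier; selects the RNG substream
#' @return list with elements `recording` (a [raw_recording()], already
#'   quantized and clipped to the device grid) and `truth` (class
#'   `ground_truth`: the 15-min wear mask, injected offsets/gains, the true
#'   longitudinal axis, activity bout log, non-wear episodes, and the count
#'   of clipped samples)
#' @export
generate_recording <- function(config, participant_id = "P001") {
  stopifnot(inherits(config, "scenario_config"))
  seed_p <- (as.numeric(config$seed) * 10007 + stable_hash(participant_id)) %%
    2147483647
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed_p))

  days <- config$days
  rate <- config$sampling_rate
  ns <- days * 86400L
  sod <- (seq_len(ns) - 1L) %% 86400L
  day_ix <- (seq_len(ns) - 1L) %/% 86400L + 1L
  hour <- sod %/% 3600L
  night <- if (config$night_start > config$night_end)
    (sod >= config$night_start * 3600) | (sod < config$night_end * 3600)
  else (sod >= config$night_start * 3600) & (sod < config$night_end * 3600)

  ## --- non-wear episodes -------------------------------------------------
  episodes <- config$nonwear_episodes
  if (is.list(episodes) && !is.data.frame(episodes))
    episodes <- episodes[[participant_id]]
  if (is.null(episodes)) {
    episodes <- if (config$nonwear_rate > 0) draw_nonwear_episodes(config)
    else data.frame(day = integer(), start_slot = integer(),
                    n_slots = integer())
  }
  if (nrow(episodes) > 0 &&
      any(episodes$n_slots < 1 | episodes$start_slot < 0 |
          episodes$start_slot + episodes$n_slots > SLOTS_PER_DAY |
          episodes$day < 1 | episodes$day > days))
    stop("invalid non-wear episode specification")

  wear_mask <- rep(TRUE, days * SLOTS_PER_DAY)
  nonwear_sec <- rep(FALSE, ns)
  for (i in seq_len(nrow(episodes))) {
    d <- episodes$day[i]; s0 <- episodes$start_slot[i]; k <- episodes$n_slots[i]
    wear_mask[(d - 1L) * SLOTS_PER_DAY + s0 + seq_len(k)] <- FALSE
    a <- (d - 1L) * 86400L + s0 * SLOT_SEC
    nonwear_sec[(a + 1L):(a + k * SLOT_SEC)] <- TRUE
  }

  ## --- posture rhythm ----------------------------------------------------
  day_angle <- runif(1, config$day_angle_range[1], config$day_angle_range[2])
  night_sign <- sample(c(-1, 1), 1)
  theta_raw <- ifelse(night, night_sign * 90, day_angle)
  theta <- moving_average(theta_raw, 900L)  # 30-min smooth transition
  phi <- runif(1, 0, 2 * pi) + cumsum(rnorm(ns, 0, 0.003))

  ## --- postural micro-movement bursts during all worn time ---------------
  ## a device on a body is never still for a whole hour: brief adjustments
  ## every few minutes keep worn low-activity periods (sleep, quiet
  ## evenings) distinguishable from true non-wear
  every <- config$sleep_burst_every_min * 60
  phase <- runif(days, 0, every)
  in_burst <- !nonwear_sec &
    ((sod + phase[day_ix]) %% every) < config$sleep_burst_sec
  # posture shifts at burst onsets: azimuth jumps + night-angle jitter
  onset <- which(in_burst & !c(FALSE, in_burst[-ns]))
  if (length(onset)) {
    jump <- numeric(ns)
    jump[onset] <- rnorm(length(onset), 0, 0.5)
    phi <- phi + cumsum(jump)
    tjit <- numeric(ns)
    tjit[onset] <- rnorm(length(onset), 0, 6)
    theta <- theta - abs(cumsum(tjit) %% 20) * night * night_sign * 0.5
  }

  ## --- intensity profile -------------------------------------------------
  sigma <- ifelse(night, 0, config$activity_profile[hour + 1L])
  sigma[in_burst] <- pmax(sigma[in_burst], config$sleep_burst_sd)

  ## --- activity bouts ----------------------------------------------------
  bout_log <- data.frame(day = integer(), start_sec = integer(),
                         duration_sec = integer(), intensity_mg = numeric())
  day_lo <- config$night_end * 3600 + 3600
  day_hi <- config$night_start * 3600 - 3600
  for (d in seq_len(days)) {
    for (b in seq_len(config$activity_bouts_per_day)) {
      for (try in 1:20) {
        dur <- round(runif(1, config$bout_duration_min[1],
                           config$bout_duration_min[2]) * 60)
        s0 <- floor(runif(1, day_lo, day_hi - dur))
        idx <- (d - 1L) * 86400L + s0 + seq_len(dur)
        if (!any(nonwear_sec[idx])) {
          sigma[idx] <- sigma[idx] + config$bout_intensity
          bout_log <- rbind(bout_log, data.frame(
            day = d, start_sec = s0, duration_sec = dur,
            intensity_mg = config$bout_intensity))
          break
        }
      }
    }
  }

  ## --- still bouts at varied orientations --------------------------------
  still_orient <- list()
  still_rows <- list()
  for (d in seq_len(days)) {
    for (b in seq_len(config$still_bouts_per_day)) {
      for (try in 1:20) {
        dur <- round(config$still_bout_min * 60)
        s0 <- floor(runif(1, day_lo, day_hi - dur))
        idx <- (d - 1L) * 86400L + s0 + seq_len(dur)
        if (!any(nonwear_sec[idx]) && !any(sigma[idx] > config$bout_intensity)) {
          still_rows[[length(still_rows) + 1L]] <- idx
          still_orient[[length(still_orient) + 1L]] <- random_unit_vector()
          sigma[idx] <- 0
          break
        }
      }
    }
  }

  ## --- gravity assembly --------------------------------------------------
  th <- theta * pi / 180
  gl <- sin(th)
  m <- cos(th)
  other <- setdiff(1:3, config$posture_axis)
  G <- matrix(0, ns, 3)
  G[, config$posture_axis] <- gl
  G[, other[1]] <- m * cos(phi)
  G[, other[2]] <- m * sin(phi)
  for (i in seq_along(still_rows))
    G[still_rows[[i]], ] <- matrix(still_orient[[i]], length(still_rows[[i]]),
                                   3, byrow = TRUE)
  for (i in seq_len(nrow(episodes))) {
    d <- episodes$day[i]; s0 <- episodes$start_slot[i]; k <- episodes$n_slots[i]
    a <- (d - 1L) * 86400L + s0 * SLOT_SEC
    idx <- (a + 1L):(a + k * SLOT_SEC)
    sigma[idx] <- 0
    G[idx, ] <- matrix(random_unit_vector(), length(idx), 3, byrow = TRUE)
  }

  ## --- sample-level signal, distortion, quantization ---------------------
  if (rate != round(rate)) stop("sampling_rate must be an integer number of Hz")
  n <- ns * as.integer(rate)
  s_tot <- sqrt((sigma * MAD_TO_SD)^2 + (config$noise_sd * 1e-3)^2)
  step <- quantization_step(config$dynamic_range, config$quantization_bits)
  half <- 2^(config$quantization_bits - 1L)
  q <- .synth_quantize_cpp(G, s_tot, as.integer(rate),
                           config$calib_gain, config$calib_offset,
                           step, half)
  data <- q$data
  colnames(data) <- c("x", "y", "z")
  attr(data, "adc_counts") <- list(x = q$cx, y = q$cy, z = q$cz)
  n_clipped <- q$n_clipped
  rm(q)

  rec <- raw_recording(
    data, start = as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC"),
    rate = rate, dynamic_range = config$dynamic_range,
    bits = config$quantization_bits, participant_id = participant_id)

  truth <- structure(list(
    participant_id = participant_id,
    wear_mask = wear_mask,
    true_offsets = config$calib_offset,
    true_gains = config$calib_gain,
    true_longitudinal_axis = config$posture_axis,
    activity_bout_log = bout_log,
    nonwear_episodes = episodes,
    clipped_sample_count = n_clipped), class = "ground_truth")

  list(recording = rec, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %s: %d/%d wear slots, axis %d, %d clipped samples\n",
    x$participant_id, sum(x$wear_mask), length(x$wear_mask),
    x$true_longitudinal_axis, x$clipped_sample_count))
  invisible(x)
}

#' Generate a cohort: raw files, covariates and ground truth
#'
#' Writes one raw recording per participant (text dialect of
#' [write_recording()]), a covariate table (`covariates.csv`: age, sex,
#' height, weight, first wear date) and per-participant ground-truth
#' annotations (`truth/<id>.json`). Deterministic under the config seed:
#' covariates come from the cohort stream, each signal from a substream
#' hashed from the participant id.
#'
#' @param config a [scenario_config()]
#' @param dir output directory (created if needed)
#' @param overwrite overwrite existing recordings?
#' @return invisibly, a list with `dir`, `files`, `covariates`, `truth`
#' @export
generate_cohort <- function(config, dir, overwrite = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  ids <- sprintf("P%03d", seq_len(config$n_participants))
  files <- file.path(dir, paste0(ids, ".csv"))
  if (!overwrite && any(file.exists(files)))
    stop("output files already exist; pass overwrite = TRUE")

  covariates <- generate_covariates(config, ids)
  data.table::fwrite(covariates, file.path(dir, "covariates.csv"))

  truths <- vector("list", length(ids))
  names(truths) <- ids
  for (i in seq_along(ids)) {
    g <- generate_recording(config, ids[i])
    write_recording(g$recording, files[i])
    truths[[i]] <- g$truth
    jsonlite::write_json(
      list(participant_id = g$truth$participant_id,
           wear_mask = as.integer(g$truth$wear_mask),
           true_offsets = g$truth$true_offsets,
           true_gains = g$truth$true_gains,
           true_longitudinal_axis = g$truth$true_longitudinal_axis,
           activity_bout_log = g$truth$activity_bout_log,
           nonwear_episodes = g$truth$nonwear_episodes,
           clipped_sample_count = g$truth$clipped_sample_count),
      file.path(dir, "truth", paste0(ids[i], ".json")),
      auto_unbox = TRUE, digits = NA)
    rm(g)
  }
  invisible(list(dir = dir, files = files, covariates = covariates,
                 truth = truths))
}

# Age 19-74 at recruitment (with the follow-up allowance the cohort design
# implies, categories above 70 can occur); heights/weights give a plausible
# BMI spread around 26 kg/m^2.
generate_covariates <- function(config, ids) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  n <- length(ids)
  sex <- sample(c("man", "woman"), n, replace = TRUE)
  height <- round(ifelse(sex == "man", rnorm(n, 178, 7), rnorm(n, 165, 6.5)), 1)
  bmi <- pmin(pmax(rnorm(n, 26.4, 4.8), 16), 45)
  data.frame(
    participant_id = ids,
    age = sample(19:74, n, replace = TRUE),
    sex = sex,
    height = height,
    weight = round(bmi * (height / 100)^2, 1),
    first_wear_date = config$start_date,
    stringsAsFactors = FALSE)
}

#' Per-day summary panel for the reliability simulation
#'
#' Generates per-participant per-day mean activity metrics under a two-level
#' model: `value[i, j] = mean_level + b[i] + e[i, j]` with participant
#' effects `b ~ N(0, between_sd^2)` and day effects `e ~ N(0, within_sd^2)`.
#' Emulates a perfectly compliant panel (all days valid) so the ICC
#' missing-day simulation runs without any raw-signal processing. Days are
#' labelled Monday through Sunday, so a 7-day panel has 5 weekdays and 2
#' weekend days.
#'
#' @param n participants (>= 2)
#' @param days days per participant (7 for the canonical design)
#' @param between_sd between-participant SD in mg
#' @param within_sd within-participant day-to-day SD in mg
#' @param mean_level grand mean in mg
#' @param seed RNG seed
#' @return data.frame with columns `participant_id`, `day`, `weekday`,
#'   `is_weekend`, `value`
#' @export
generate_day_summary_panel <- function(n, days = 7L, between_sd = 4,
                                       within_sd = 2, mean_level = 12,
                                       seed = 1L) {
  stopifnot(n >= 2, days >= 1, between_sd >= 0, within_sd >= 0)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  b <- rnorm(n, 0, between_sd)
  wd <- rep_len(c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"), days)
  out <- data.frame(
    participant_id = rep(sprintf("P%05d", seq_len(n)), each = days),
    day = rep(seq_len(days), n),
    weekday = rep(wd, n),
    is_weekend = rep(wd %in% c("Sat", "Sun"), n),
    value = mean_level + rep(b, each = days) + rnorm(n * days, 0, within_sd),
    stringsAsFactors = FALSE)
  out
}
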