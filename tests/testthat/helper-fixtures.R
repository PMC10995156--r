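# Shared fixtures, memoized so expensive synthetic recordings are generated
# once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small clean recording: 3 days @ 5 Hz, no distortion
small_recording <- function() {
  cached("small_rec", {
    cfg <- scenario_config(days = 3, sampling_rate = 5, seed = 11,
                           nonwear_rate = 0)
    generate_recording(cfg, "P001")
  })
}

# 3 days @ 5 Hz with a known distortion and non-wear episodes
distorted_recording <- function() {
  cached("distorted_rec", {
    cfg <- scenario_config(
      days = 3, sampling_rate = 5, seed = 7,
      calib_offset = c(0.05, -0.03, 0.02), calib_gain = c(1.02, 0.98, 1.01),
      nonwear_episodes = data.frame(day = c(1, 2), start_slot = c(40, 10),
                                    n_slots = c(8, 12)),
      still_bouts_per_day = 10L)
    generate_recording(cfg, "P001")
  })
}

# epoch series of the calibrated small recording
small_epochs <- function() {
  cached("small_es", {
    g <- small_recording()
    compute_epoch_series(g$recording)
  })
}

# hand-built epoch series (for imputation / aggregation arithmetic): one
# epoch per 15-min slot, values supplied per (day, slot)
toy_epoch_series <- function(values_by_day, metric2 = NULL,
                             start_date = as.Date("2015-03-02")) {
  n_days <- length(values_by_day)
  rows <- do.call(rbind, lapply(seq_len(n_days), function(d) {
    v <- values_by_day[[d]]
    data.frame(
      epoch_start = as.POSIXct(paste(start_date + d - 1, "00:00:00"),
                               tz = "UTC") + (seq_along(v) - 1) * 900,
      enmo = v,
      mad = if (is.null(metric2)) v * 2 else metric2[[d]])
  }))
  structure(rows, epoch_length = 900, rate = 1, samples_per_epoch = 900L,
            dynamic_range = 6, participant_id = "TOY",
            enmo_truncation = "sample",
            class = c("epoch_series", "data.frame"))
}

# hand-built segment mask matching toy_epoch_series
toy_mask <- function(labels_by_day, start_date = as.Date("2015-03-02")) {
  n_days <- length(labels_by_day)
  rows <- do.call(rbind, lapply(seq_len(n_days), function(d) {
    lab <- labels_by_day[[d]]
    data.frame(date = start_date + d - 1, slot = seq_along(lab) - 1L,
               label = lab, imputed = FALSE, n_epochs = 1L,
               stringsAsFactors = FALSE)
  }))
  structure(rows, epoch_length = 900, participant_id = "TOY",
            class = c("segment_mask", "data.frame"))
}

# still recording with a fixed orientation (for rule-table non-wear cases):
# builds a raw_recording from explicit per-axis generators
manual_recording <- function(n_sec, rate, fn, start = "2015-03-02T00:00:00") {
  n <- n_sec * rate
  t <- (seq_len(n) - 1) / rate
  data <- cbind(x = fn$x(t), y = fn$y(t), z = fn$z(t))
  raw_recording(data, start, rate, 6, participant_id = "MAN")
}
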