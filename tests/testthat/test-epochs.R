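# Per-epoch signal features: ENMO, MAD, posture angles, epoch tiling.

test_that("ENMO matches its definition on canonical still inputs", {
  still_1g <- matrix(rep(c(0, 0, 1), each = 10), ncol = 3)
  expect_equal(epoch_enmo(still_1g), 0)
  over <- matrix(rep(c(0, 0, 1.1), each = 10), ncol = 3)
  expect_equal(epoch_enmo(over), 100, tolerance = 1e-12)
  # negative values are set to zero, not averaged in
  under <- matrix(rep(c(0, 0, 0.9), each = 10), ncol = 3)
  expect_equal(epoch_enmo(under), 0)
  expect_equal(epoch_enmo(under, truncation = "epoch"), 0)
})

test_that("MAD matches its definition on canonical inputs", {
  expect_equal(epoch_mad(matrix(rep(c(0.3, 0.4, 0), each = 7), ncol = 3)), 0)
  half_half <- rbind(
    matrix(rep(c(0, 0, 0.9), each = 5), ncol = 3),
    matrix(rep(c(0, 0, 1.1), each = 5), ncol = 3))
  expect_equal(epoch_mad(half_half), 100, tolerance = 1e-12)
})

test_that("random epochs match the brute-force oracles to 1e-9", {
  set.seed(401)
  for (i in 1:25) {
    s <- matrix(rnorm(3 * sample(5:200, 1), sd = 0.5) + c(0, 0, 1), ncol = 3)
    expect_equal(epoch_enmo(s), oracle_enmo(s), tolerance = 1e-9)
    expect_equal(epoch_mad(s), oracle_mad(s), tolerance = 1e-9)
  }
})

test_that("posture angles recover axis alignment and the closed form", {
  expect_equal(epoch_angles(matrix(rep(c(0, 0, 1), each = 5), ncol = 3)),
               c(0, 0, 90))
  expect_equal(epoch_angles(matrix(rep(c(1, 0, 0), each = 5), ncol = 3)),
               c(90, 0, 0))
  a <- epoch_angles(matrix(rep(c(0.6, 0, 0.8), each = 5), ncol = 3))
  expect_equal(a[3], atan(0.8 / 0.6) * 180 / pi, tolerance = 1e-12)
  expect_true(all(a >= -90 & a <= 90))
})

test_that("epoch series tiles the recording and matches the per-epoch ops", {
  g <- small_recording()
  es <- small_epochs()
  k <- attr(es, "samples_per_epoch")
  expect_identical(nrow(es), nrow(g$recording$data) %/% k)
  # spot-check epochs against the public single-epoch operations
  set.seed(42)
  for (e in sample(nrow(es), 20)) {
    idx <- ((e - 1) * k + 1):(e * k)
    expect_equal(es$enmo[e], epoch_enmo(g$recording$data[idx, ]),
                 tolerance = 1e-9)
    expect_equal(es$mad[e], epoch_mad(g$recording$data[idx, ]),
                 tolerance = 1e-9)
    expect_equal(c(es$angle_x[e], es$angle_y[e], es$angle_z[e]),
                 epoch_angles(g$recording$data[idx, ]), tolerance = 1e-9)
  }
})

test_that("a 10-s recording at 5-s epochs yields exactly 2 epochs", {
  rec <- manual_recording(10, 10, list(x = function(t) 0 * t,
                                       y = function(t) 0 * t,
                                       z = function(t) 0 * t + 1))
  expect_identical(nrow(compute_epoch_series(rec)), 2L)
})

test_that("still recordings have ENMO below the quantization bound", {
  cfg <- scenario_config(days = 1, sampling_rate = 5, seed = 3,
                         activity_profile = rep(0, 24), noise_sd = 0,
                         nonwear_rate = 0, still_bouts_per_day = 0L,
                         activity_bouts_per_day = 0L, sleep_burst_sd = 0)
  g <- generate_recording(cfg, "STILL")
  es <- compute_epoch_series(g$recording)
  step_mg <- 1000 * quantization_step(6, 12)
  expect_true(all(es$enmo <= step_mg))
  expect_true(all(es$mad <= step_mg))
})

test_that("chunked processing equals one pass", {
  g <- small_recording()
  rec <- g$recording
  es_full <- compute_epoch_series(rec)
  k <- attr(es_full, "samples_per_epoch")
  cut <- (nrow(rec$data) %/% (2 * k)) * k
  r1 <- raw_recording(rec$data[1:cut, , drop = FALSE], rec$start, rec$rate,
                      rec$dynamic_range, rec$bits, rec$participant_id)
  r2 <- raw_recording(rec$data[(cut + 1):nrow(rec$data), , drop = FALSE],
                      rec$start + cut / rec$rate, rec$rate,
                      rec$dynamic_range, rec$bits, rec$participant_id)
  es_chunks <- rbind(compute_epoch_series(r1), compute_epoch_series(r2))
  expect_equal(es_full$enmo, es_chunks$enmo, tolerance = 1e-12)
  expect_equal(es_full$mad, es_chunks$mad, tolerance = 1e-12)
  expect_equal(es_full$angle_z, es_chunks$angle_z, tolerance = 1e-12)
})

test_that("MAD is shift-invariant in the norm; ENMO is not", {
  set.seed(77)
  s <- matrix(rnorm(300, sd = 0.05) + c(0, 0, 1), ncol = 3)
  r <- sqrt(rowSums(s^2))
  shifted <- s * (r + 0.05) / r  # adds 0.05 g to every norm
  expect_equal(epoch_mad(shifted), epoch_mad(s), tolerance = 1e-9)
  expect_gt(epoch_enmo(shifted), epoch_enmo(s) + 25)
})

test_that("scaling dynamic deviations up does not decrease ENMO or MAD", {
  set.seed(78)
  for (i in 1:5) {
    dev <- matrix(rnorm(300, sd = 0.03), ncol = 3)
    base <- matrix(rep(c(0, 0, 1), each = 100), ncol = 3)
    s1 <- base + dev
    s2 <- base + 2 * dev
    expect_gte(epoch_enmo(s2), epoch_enmo(s1))
    expect_gte(epoch_mad(s2), epoch_mad(s1))
  }
})

test_that("on-the-fly calibration equals materialized calibration", {
  g <- distorted_recording()
  pts <- detect_still_points(g$recording)
  mod <- fit_calibration(pts)
  es_fused <- compute_epoch_series(g$recording, calibration = mod)
  es_mat <- compute_epoch_series(apply_calibration(g$recording, mod))
  expect_equal(es_fused$enmo, es_mat$enmo, tolerance = 1e-9)
  expect_equal(es_fused$mad, es_mat$mad, tolerance = 1e-9)
  expect_equal(es_fused$sd_x, es_mat$sd_x, tolerance = 1e-9)
  expect_equal(es_fused$angle_y, es_mat$angle_y, tolerance = 1e-9)
})

test_that("empty or degenerate epochs are rejected", {
  expect_error(epoch_enmo(matrix(numeric(0), ncol = 3)), "sample")
  expect_error(epoch_mad(matrix(numeric(0), ncol = 3)), "sample")
  rec <- manual_recording(2, 1, list(x = function(t) 0 * t,
                                     y = function(t) 0 * t,
                                     z = function(t) 0 * t + 1))
  expect_error(compute_epoch_series(rec, epoch_length = 5), "epoch")
})
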