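# Non-wear and clipping classification, imputation of invalid segments.

# 2-h recordings with controlled per-axis behaviour; detect_nonwear labels
# every covered 15-min slot from its enclosing 60-min window
flat <- function(t) 0 * t
noisy <- function(sd_mg, range_mg = NULL) {
  function(t) {
    v <- rnorm(length(t), sd = sd_mg / 1000)
    if (!is.null(range_mg)) {
      # rare single-sample spikes widen the range while barely moving the SD
      spikes <- seq(1, length(t), by = 3000)
      v[spikes] <- v[spikes] + rep_len(c(1, -1), length(spikes)) *
        (range_mg / 2000)
    }
    v
  }
}

test_that("all-still windows are non-wear, all-active windows are wear", {
  set.seed(70)
  still_rec <- manual_recording(7200, 5, list(
    x = noisy(1), y = noisy(1), z = function(t) 1 + noisy(1)(t)))
  m1 <- detect_nonwear(compute_epoch_series(still_rec))
  expect_true(all(m1$label == "nonwear"))

  active_rec <- manual_recording(7200, 5, list(
    x = noisy(40), y = noisy(35), z = function(t) 1 + noisy(45)(t)))
  m2 <- detect_nonwear(compute_epoch_series(active_rec))
  expect_true(all(m2$label == "wear"))
})

test_that("one active axis still gives non-wear under the 2-of-3 vote", {
  set.seed(71)
  rec <- manual_recording(7200, 5, list(
    x = noisy(50), y = noisy(1), z = function(t) 1 + noisy(1)(t)))
  m <- detect_nonwear(compute_epoch_series(rec))
  expect_true(all(m$label == "nonwear"))
  # requiring all three axes still flips the label
  m3 <- detect_nonwear(compute_epoch_series(rec), axes_required = 3L)
  expect_true(all(m3$label == "wear"))
})

test_that("the SD and range criteria combine as OR by default, AND on request", {
  set.seed(72)
  # small SD but large range on every axis: still under OR, not under AND
  rec <- manual_recording(7200, 5, list(
    x = noisy(5, 200), y = noisy(5, 200),
    z = function(t) 1 + noisy(5, 200)(t)))
  es <- compute_epoch_series(rec)
  expect_true(all(detect_nonwear(es)$label == "nonwear"))
  expect_true(all(detect_nonwear(es, combine = "and")$label == "wear"))
})

test_that("labelled non-wear episodes are recovered at segment level", {
  g <- distorted_recording()
  es <- compute_epoch_series(g$recording)  # distortion barely moves the SDs
  mask <- detect_nonwear(es)
  acc <- mean((mask$label == "wear") == g$truth$wear_mask)
  expect_gte(acc, 0.95)
})

test_that("clipping needs more than 80% of samples at the range edges", {
  pin <- function(frac) {
    n_sec <- 900
    manual_recording(n_sec, 4, list(
      x = function(t) ifelse(seq_along(t) <= frac * length(t), 6, 0),
      y = flat, z = function(t) ifelse(seq_along(t) <= frac * length(t), 0, 1)))
  }
  full <- detect_clipping(pin(1))
  expect_true(all(full$slots$clipped))
  expect_equal(full$score, 1)
  half <- detect_clipping(pin(0.5))
  expect_false(any(half$slots$clipped))
  expect_equal(half$score, 0)
  most <- detect_clipping(pin(0.9))
  expect_true(all(most$slots$clipped))
})

test_that("normal wear does not clip and both clipping routes agree", {
  g <- small_recording()
  a <- detect_clipping(g$recording)
  es <- compute_epoch_series(g$recording, angles = FALSE)
  b <- hipacc:::clipping_from_epochs(es)
  expect_equal(a$score, 0)
  expect_equal(b$score, 0)
  expect_identical(sum(a$slots$clipped), sum(b$slots$clipped))
})

test_that("clipped slots override the wear label in the mask", {
  mask <- toy_mask(list(rep("wear", 4)))
  clip <- list(slots = data.frame(date = as.Date("2015-03-02"), slot = 2L,
                                  clip_fraction = 0.9, clipped = TRUE),
               score = 0.25)
  m2 <- apply_clipping(mask, clip)
  expect_identical(m2$label, c("wear", "wear", "clipped", "wear"))
})

test_that("imputation replaces invalid slots with the valid-day slot mean", {
  es <- toy_epoch_series(list(c(10, 5), c(20, 5), c(99, 5)))
  mask <- toy_mask(list(c("wear", "wear"), c("wear", "wear"),
                        c("nonwear", "wear")))
  out <- impute_segments(es, mask)
  # slot 0 on day 3 imputed with mean(10, 20) = 15
  expect_equal(out$epochs$enmo[5], 15)
  expect_true(out$epochs$imputed[5])
  # valid slots untouched
  expect_equal(out$epochs$enmo[c(1, 3)], c(10, 20))
  expect_false(any(out$epochs$imputed[-5]))
  expect_identical(out$unimputable_slots, integer(0))
  expect_true(all(out$mask$imputed == c(FALSE, FALSE, FALSE, FALSE, TRUE,
                                        FALSE)))
})

test_that("slots invalid on every day are unimputable and flagged", {
  es <- toy_epoch_series(list(c(10, 5), c(20, 6)))
  mask <- toy_mask(list(c("nonwear", "wear"), c("nonwear", "wear")))
  out <- impute_segments(es, mask)
  expect_identical(out$unimputable_slots, 0L)
  expect_equal(out$epochs$enmo, c(10, 5, 20, 6))  # left untouched
  expect_false(any(out$mask$imputed))
})

test_that("imputation conserves the across-valid-day slot mean", {
  es <- toy_epoch_series(list(c(8, 1), c(12, 1), c(40, 1), c(16, 1)))
  mask <- toy_mask(list(c("wear", "wear"), c("wear", "wear"),
                        c("nonwear", "wear"), c("wear", "wear")))
  out <- impute_segments(es, mask)
  valid_mean <- mean(c(8, 12, 16))
  expect_equal(out$epochs$enmo[5], valid_mean)
  # the across-day mean over all four days now equals the valid-day mean
  expect_equal(mean(out$epochs$enmo[c(1, 3, 5, 7)]), valid_mean)
})

test_that("imputed slots never count toward wear hours", {
  mask <- toy_mask(list(rep(c("wear", "nonwear"), 2)))
  es <- toy_epoch_series(list(rep(5, 4)))
  out <- impute_segments(es, mask)
  wh <- wear_hours_per_day(out$mask)
  expect_equal(wh$wear_hours, 2 * 0.25)
})
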