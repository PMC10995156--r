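# Valid days, inclusion, four-level aggregation, bins, MVPA, winsorization,
# subgroup tables.

test_that("the 16-hour valid-day boundary is inclusive", {
  lab64 <- c(rep("wear", 64), rep("nonwear", 32))
  lab63 <- c(rep("wear", 63), rep("nonwear", 33))
  days <- classify_days(toy_mask(list(lab64, lab63)))
  expect_identical(days$valid, c(TRUE, FALSE))
  expect_equal(days$wear_hours, c(16, 15.75))
})

test_that("the threshold scales with civil day length on time-shift days", {
  # a 23-h spring-forward day has 92 slots; 62 wear slots = 15.5 h
  lab <- c(rep("wear", 62), rep("nonwear", 30))  # 92 slots = 23 h
  mask <- toy_mask(list(lab))
  days23 <- classify_days(mask, day_hours = c("2015-03-02" = 23))
  expect_equal(days23$threshold_hours, 16 / 24 * 23)
  expect_true(days23$valid)  # 15.5 >= 15.33
  expect_false(classify_days(mask)$valid)  # under the unscaled 16-h rule
})

test_that("weekends are Saturday and Sunday", {
  # 2015-03-02 is a Monday
  mask <- toy_mask(rep(list(rep("wear", 96)), 8))
  days <- classify_days(mask)
  expect_identical(days$is_weekend,
                   c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
})

test_that("inclusion needs 1 weekend day, 2 weekdays and a complete cycle", {
  wear_day <- rep("wear", 96)
  off_day <- rep("nonwear", 96)
  # Mon + Tue valid, Sat valid -> included
  mask <- toy_mask(list(wear_day, wear_day, off_day, off_day, off_day,
                        wear_day, off_day))
  days <- classify_days(mask)
  inc <- include_participant(days, mask)
  expect_true(inc$included)
  expect_true(is.na(inc$reason))

  # five valid weekdays but no weekend day -> excluded, reason weekend
  mask2 <- toy_mask(list(wear_day, wear_day, wear_day, wear_day, wear_day,
                         off_day, off_day))
  inc2 <- include_participant(classify_days(mask2), mask2)
  expect_false(inc2$included)
  expect_identical(inc2$reason, "weekend")

  # one valid weekday only -> reason weekday (weekend satisfied first)
  mask3 <- toy_mask(list(wear_day, off_day, off_day, off_day, off_day,
                         wear_day, wear_day))
  inc3 <- include_participant(classify_days(mask3), mask3)
  expect_identical(inc3$reason, "weekday")

  # slot 12 (03:00-03:15) invalid on all days -> reason cycle
  hole_day <- replace(wear_day, 13, "nonwear")
  mask4 <- toy_mask(rep(list(hole_day), 7))
  inc4 <- include_participant(classify_days(mask4), mask4)
  expect_false(inc4$included)
  expect_identical(inc4$reason, "cycle")
  expect_identical(inc4$incomplete_slots, 12L)
})

test_that("L1 is the mean of the L3 daily means, exactly", {
  es <- toy_epoch_series(list(rep(10, 96), rep(14, 96)))
  mask <- toy_mask(rep(list(rep("wear", 96)), 2))
  days <- classify_days(mask)
  ps <- aggregate_participant(es, days)
  expect_equal(ps$overall[["enmo"]], 12)
  expect_equal(ps$overall[["enmo"]], mean(ps$days$mean_enmo))
  expect_equal(ps$overall[["mad"]], mean(ps$days$mean_mad))
})

test_that("L4 slot means average back to L1 on complete days", {
  set.seed(81)
  es <- toy_epoch_series(list(runif(96, 0, 30), runif(96, 0, 30),
                              runif(96, 0, 30)))
  mask <- toy_mask(rep(list(rep("wear", 96)), 3))
  days <- classify_days(mask)
  ps <- aggregate_participant(es, days)
  expect_equal(mean(ps$slots$mean_enmo), ps$overall[["enmo"]],
               tolerance = 1e-12)
  expect_identical(nrow(ps$slots), 96L)
})

test_that("identical days collapse all aggregation levels", {
  day_vals <- runif(96, 0, 20)
  es <- toy_epoch_series(rep(list(day_vals), 8))
  mask <- toy_mask(rep(list(rep("wear", 96)), 8))
  days <- classify_days(mask)
  ps <- aggregate_participant(es, days)
  m <- mean(day_vals)
  expect_equal(ps$overall[["enmo"]], m)
  expect_equal(ps$weekday[["enmo"]], m)
  expect_equal(ps$weekend[["enmo"]], m)
  expect_true(all(abs(ps$days$mean_enmo - m) < 1e-12))
})

test_that("weekday and weekend L2 means partition the L3 days", {
  es <- toy_epoch_series(lapply(1:7, function(d) rep(d, 96)))
  mask <- toy_mask(rep(list(rep("wear", 96)), 7))
  days <- classify_days(mask)
  ps <- aggregate_participant(es, days)
  expect_equal(ps$weekday[["enmo"]], mean(1:5))
  expect_equal(ps$weekend[["enmo"]], mean(6:7))
  n_wd <- sum(!days$is_weekend); n_we <- sum(days$is_weekend)
  expect_equal((n_wd * ps$weekday[["enmo"]] + n_we * ps$weekend[["enmo"]]) /
                 7, ps$overall[["enmo"]])
})

test_that("intensity bins are half-open, complete days sum to 1440 min", {
  es <- toy_epoch_series(list(rep(5, 96)))
  mask <- toy_mask(list(rep("wear", 96)))
  days <- classify_days(mask)
  bins <- intensity_distribution(es, days)
  expect_equal(bins$enmo_minutes[1], 1440)
  expect_equal(sum(bins$enmo_minutes), 1440)
  # an epoch at exactly 10 mg goes to [10, 20)
  es2 <- toy_epoch_series(list(rep(10, 96)))
  bins2 <- intensity_distribution(es2, days)
  expect_equal(bins2$enmo_minutes[2], 1440)
  expect_equal(bins2$enmo_minutes[1], 0)
})

test_that("random series bin totals match a brute-force histogram", {
  set.seed(82)
  v <- c(runif(90, 0, 120), runif(6, 900, 1100))
  es <- toy_epoch_series(list(v))
  mask <- toy_mask(list(rep("wear", 96)))
  bins <- intensity_distribution(es, classify_days(mask))
  breaks <- c(seq(0, 1000, 10), Inf)
  for (b in seq_len(length(breaks) - 1)) {
    manual <- sum(v >= breaks[b] & v < breaks[b + 1]) * 15
    expect_equal(bins$enmo_minutes[b], manual)
  }
})

test_that("threshold minutes follow the worked example and monotonicity", {
  expect_equal(minutes_above(c(65, 75, 80, 60), 60, 70), 2)
  expect_equal(minutes_above(rep(10, 50), 60, 70), 0)
  expect_equal(minutes_above(rep(10, 50), 60, 70,
                             list(duration = 10, tolerance = 0.8)), 0)
  set.seed(83)
  v <- runif(200, 0, 150)
  thr <- seq(30, 150, 10)
  mins <- vapply(thr, function(th) minutes_above(v, 60, th), numeric(1))
  expect_true(all(diff(mins) <= 0))
  # bout minutes never exceed no-bout minutes at equal threshold
  for (th in c(50, 90)) {
    expect_lte(minutes_above(v, 60, th, list(duration = 10, tolerance = 0.8)),
               minutes_above(v, 60, th))
  }
})

test_that("bout minutes equal the exhaustive window enumeration", {
  set.seed(84)
  for (i in 1:60) {
    v <- ifelse(runif(36) < 0.5, 100, 10)
    got <- minutes_above(v, 60, 70, list(duration = 10, tolerance = 0.8))
    want <- oracle_bout_minutes(v >= 70, 10, 0.8, 1)
    expect_equal(got, want)
  }
  # full-tolerance bouts reduce to runs of consecutive exceedance
  for (i in 1:20) {
    v <- ifelse(runif(36) < 0.5, 100, 10)
    got <- minutes_above(v, 60, 70, list(duration = 5, tolerance = 1))
    want <- oracle_bout_minutes(v >= 70, 5, 1, 1)
    expect_equal(got, want)
  }
})

test_that("60-s MVPA epochs are block means of twelve 5-s epochs", {
  g <- small_recording()
  es <- small_epochs()
  mask <- detect_nonwear(es)
  days <- classify_days(mask)
  v60 <- mvpa_variant("enmo", 60, 40)
  v5 <- mvpa_variant("enmo", 5, 40)
  m60 <- mvpa_minutes(es, v60, days)
  m5 <- mvpa_minutes(es, v5, days)
  expect_gte(m5, 0)
  expect_gte(m60, 0)
  # manual check of the re-epoching on one day
  d0 <- as.numeric(days$date[days$valid][1])
  vals <- es$enmo[floor(as.numeric(es$epoch_start) / 86400) == d0]
  nb <- length(vals) %/% 12
  manual <- colMeans(matrix(vals[1:(nb * 12)], 12, nb))
  expect_equal(sum(manual >= 40),
               minutes_above(manual, 60, 40))
})

test_that("invalid MVPA variants are rejected", {
  expect_error(mvpa_variant("enmo", 60, 0), "threshold")
  expect_error(mvpa_variant("enmo", 60, 70,
                            list(duration = 0.5, tolerance = 0.8)),
               "bout duration")
  expect_error(mvpa_variant("enmo", 60, 70,
                            list(duration = 10, tolerance = 1.5)),
               "tolerance")
})

test_that("the default MVPA grid covers both metrics and the anchors", {
  grid <- mvpa_grid()
  labels <- names(grid)
  expect_true(any(grepl("enmo_60s_70mg_nobout", labels)))
  expect_true(any(grepl("mad_60s_90mg_nobout", labels)))
  expect_true(all(vapply(grid, inherits, TRUE, "mvpa_variant")))
})

test_that("winsorization caps only the stratum's extreme tail", {
  x <- as.numeric(1:1000)
  w <- winsorize_by_stratum(x, rep("a", 1000))
  cap <- quantile(x, 0.999, type = 7, names = FALSE)
  expect_equal(max(w), cap)
  expect_identical(sum(w != x), 1L)  # only the maximum is altered
  expect_true(all(w <= x))
  expect_lte(mean(w), mean(x))
  # near-idempotence: re-capping only moves the extreme by the
  # interpolation width between the two largest order statistics
  expect_equal(winsorize_by_stratum(w, rep("a", 1000)), w,
               tolerance = 1e-5)
  expect_equal(winsorize_by_stratum(rep(3, 10), rep("a", 10)), rep(3, 10))
  # strata are capped independently
  s <- rep(c("a", "b"), each = 1000)
  w2 <- winsorize_by_stratum(c(x, x * 10), s)
  expect_equal(max(w2[s == "b"]), 10 * cap)
  expect_error(winsorize_by_stratum(1:3, c("a", "a", "b")), "stratum")
})

test_that("covariate groupings follow the WHO and calendar conventions", {
  expect_identical(as.character(bmi_class(c(24.9, 25, 18.4, 18.5, 30))),
                   c("normal", "overweight", "underweight", "normal",
                     "obese"))
  expect_identical(as.character(season_of(as.Date(c(
    "2015-03-01", "2015-02-28", "2015-06-01", "2015-09-01", "2015-12-01")))),
    c("spring", "winter", "summer", "autumn", "winter"))
  expect_identical(as.character(age_band(c(29, 30, 69, 70))),
                   c("<30", "30-39", "60-69", "70+"))
})

test_that("subgroup report covers every grouping and a lone participant", {
  es <- toy_epoch_series(lapply(1:7, function(d) rep(10 + d, 96)))
  mask <- toy_mask(rep(list(rep("wear", 96)), 7))
  days <- classify_days(mask)
  ps <- aggregate_participant(es, days)
  cov <- data.frame(participant_id = "TOY", age = 44, sex = "woman",
                    height = 165, weight = 60,
                    first_wear_date = as.Date("2015-03-02"))
  rep_ <- subgroup_report(list(ps), cov, winsorize = FALSE)
  expect_setequal(unique(rep_$grouping),
                  c("age_band", "sex", "bmi_class", "season", "week_segment",
                    "time_of_day"))
  one <- rep_[rep_$grouping == "sex", ]
  expect_equal(one$mean_enmo, ps$overall[["enmo"]])
  # missing covariates are reported as an NA group, not dropped
  cov_na <- cov; cov_na$age <- NA
  rep_na <- subgroup_report(list(ps), cov_na, winsorize = FALSE)
  expect_true("NA" %in% rep_na$group[rep_na$grouping == "age_band"])
})
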