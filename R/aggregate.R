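# Valid-day and inclusion rules, multi-level aggregation, intensity bins,
# MVPA estimators, winsorization and subgroup summaries.
#
# A day is valid with at least 16 h of detected wear (2/3 of a 24-h wear
# protocol); on days with a civil-time shift the threshold scales with the
# actual day length. Participants need at least one valid weekend day, two
# valid weekdays, and a complete 24-h cycle (no 15-min clock slot invalid on
# every recording day). Metrics aggregate at four levels: overall across
# valid days (L1), per week segment (L2), per valid day (L3), and per 15-min
# clock slot across valid days (L4).

#' Classify days as valid or invalid
#'
#' @param mask a `segment_mask`
#' @param day_hours optional named numeric vector (names = dates as
#'   `"YYYY-MM-DD"`) giving the civil length in hours of specific days (23
#'   or 25 on daylight-saving transitions); defaults to 24
#' @param min_wear_hours wear-hour threshold for a 24-h day
#' @return data.frame with `date`, `weekday` (1 = Monday), `is_weekend`,
#'   `n_slots`, `wear_hours`, `threshold_hours`, `valid`
#' @export
classify_days <- function(mask, day_hours = NULL, min_wear_hours = 16) {
  wh <- wear_hours_per_day(mask)
  hours <- rep(24, nrow(wh))
  if (!is.null(day_hours)) {
    hit <- match(as.character(wh$date), names(day_hours))
    hours[!is.na(hit)] <- day_hours[hit[!is.na(hit)]]
  }
  threshold <- min_wear_hours / 24 * hours
  wd <- as.integer(format(wh$date, "%u"))
  data.frame(
    date = wh$date, weekday = wd, is_weekend = wd >= 6L,
    n_slots = wh$n_slots, wear_hours = wh$wear_hours,
    threshold_hours = threshold, valid = wh$wear_hours >= threshold)
}

#' Participant inclusion decision
#'
#' A participant is included with at least one valid weekend day, at least
#' two valid weekdays, and a complete 24-h cycle. The first failing
#' criterion (checked in the order weekend, weekday, cycle) is the recorded
#' exclusion reason.
#'
#' @param days result of [classify_days()]
#' @param mask the participant's `segment_mask`
#' @return list with `included`, `reason` (`NA`, `"weekend"`, `"weekday"`
#'   or `"cycle"`), valid-day counts and the incomplete clock slots
#' @export
include_participant <- function(days, mask) {
  n_weekend <- sum(days$valid & days$is_weekend)
  n_weekday <- sum(days$valid & !days$is_weekend)
  valid_by_slot <- tapply(mask$label == "wear", mask$slot, any)
  covered <- as.integer(names(valid_by_slot))[unlist(valid_by_slot)]
  incomplete <- setdiff(0:(SLOTS_PER_DAY - 1L), covered)
  reason <- if (n_weekend < 1) "weekend"
  else if (n_weekday < 2) "weekday"
  else if (length(incomplete) > 0) "cycle"
  else NA_character_
  list(included = is.na(reason), reason = reason,
       n_valid_weekend = n_weekend, n_valid_weekdays = n_weekday,
       incomplete_slots = incomplete)
}

#' Four-level aggregation of epoch metrics
#'
#' L1: overall mean over valid days of the daily means. L2: the same
#' restricted to weekdays and to weekend days. L3: per valid day. L4: per
#' 15-min clock slot, mean across valid days of the day-by-slot means.
#' Imputed epochs contribute; un-imputable epochs are the caller's concern
#' (included participants have none).
#'
#' @param es an (imputed) epoch series
#' @param days result of [classify_days()]
#' @param metrics metric columns to aggregate
#' @return object of class `participant_summary` with `overall`, `weekday`,
#'   `weekend` (named metric vectors), `days` (L3 data.frame) and `slots`
#'   (L4 data.frame, one row per clock slot)
#' @export
aggregate_participant <- function(es, days, metrics = c("enmo", "mad")) {
  stopifnot(inherits(es, "epoch_series"))
  t0 <- as.numeric(es$epoch_start)
  e_day <- floor(t0 / 86400)
  e_slot <- as.integer(floor((t0 %% 86400) / SLOT_SEC))
  valid_dates <- as.numeric(days$date[days$valid])
  keep <- e_day %in% valid_dates
  if (!any(keep)) stop("participant has no valid days to aggregate")

  kday <- e_day[keep]
  n_day <- rowsum(rep(1, length(kday)), kday)
  daily <- data.frame(date = as.Date(as.numeric(rownames(n_day)),
                                     origin = "1970-01-01"))
  for (m in metrics)
    daily[[paste0("mean_", m)]] <-
      as.numeric(rowsum(es[[m]][keep], kday) / n_day)
  ix <- match(as.numeric(daily$date), as.numeric(days$date))
  daily$weekday <- days$weekday[ix]
  daily$is_weekend <- days$is_weekend[ix]
  daily$wear_hours <- days$wear_hours[ix]

  l1 <- sapply(metrics, function(m) mean(daily[[paste0("mean_", m)]]))
  l2_wd <- sapply(metrics, function(m)
    mean(daily[[paste0("mean_", m)]][!daily$is_weekend]))
  l2_we <- sapply(metrics, function(m)
    mean(daily[[paste0("mean_", m)]][daily$is_weekend]))

  # L4: day-by-slot means, then the across-day mean per clock slot
  key <- e_day[keep] * SLOTS_PER_DAY + e_slot[keep]
  n_key <- rowsum(rep(1, length(key)), key)
  slot_of_key <- as.numeric(rownames(n_key)) %% SLOTS_PER_DAY
  slots <- data.frame(slot = sort(unique(as.integer(slot_of_key))))
  for (m in metrics) {
    ds <- rowsum(es[[m]][keep], key) / n_key
    sm <- tapply(as.numeric(ds), slot_of_key, mean)
    slots[[paste0("mean_", m)]] <- as.numeric(sm[as.character(slots$slot)])
  }

  structure(list(
    participant_id = attr(es, "participant_id"),
    overall = l1, weekday = l2_wd, weekend = l2_we,
    days = daily, slots = slots, metrics = metrics),
    class = "participant_summary")
}

#' @export
print.participant_summary <- function(x, ...) {
  cat(sprintf(
    "<participant_summary> %s: %d valid day(s); ENMO %.2f mg, MAD %.2f mg\n",
    x$participant_id, nrow(x$days),
    x$overall["enmo"], x$overall["mad"]))
  invisible(x)
}

#' Intensity distribution in 10-mg bins
#'
#' Minutes per day spent in acceleration bins `[0,10), [10,20), ...,
#' [990,1000), [1000,Inf)` mg, from epoch counts scaled by the epoch length
#' and averaged over valid days. For complete (imputed) days the bin
#' minutes per day sum to 1440.
#'
#' @param es an (imputed) epoch series
#' @param days result of [classify_days()]
#' @param bin_width bin width in mg
#' @param metrics metric columns
#' @return data.frame with `bin_lo`, `bin_hi` and `<metric>_minutes`
#'   columns (mean minutes per valid day)
#' @export
intensity_distribution <- function(es, days, bin_width = 10,
                                   metrics = c("enmo", "mad")) {
  stopifnot(inherits(es, "epoch_series"))
  t0 <- as.numeric(es$epoch_start)
  e_day <- floor(t0 / 86400)
  valid_dates <- as.numeric(days$date[days$valid])
  keep <- e_day %in% valid_dates
  n_days <- length(valid_dates)
  breaks <- c(seq(0, 1000, by = bin_width), Inf)
  out <- data.frame(bin_lo = head(breaks, -1), bin_hi = breaks[-1])
  scale <- attr(es, "epoch_length") / 60
  for (m in metrics) {
    cnt <- tabulate(findInterval(es[[m]][keep], breaks,
                                 rightmost.closed = FALSE),
                    nbins = length(breaks) - 1)
    out[[paste0(m, "_minutes")]] <- cnt * scale / n_days
  }
  out
}

#' MVPA estimator variant
#'
#' @param metric `"enmo"` or `"mad"`
#' @param epoch_length evaluation epoch in seconds (60-s epochs are built
#'   by averaging twelve 5-s epochs)
#' @param threshold cut-point in mg (> 0); literature anchors are 70 mg for
#'   ENMO and 90 mg for MAD
#' @param bout `NULL` for no bout criterion, or `list(duration, tolerance)`
#'   with the minimum bout duration in minutes and the fraction of epochs
#'   within the bout that must exceed the threshold
#' @return object of class `mvpa_variant`
#' @export
mvpa_variant <- function(metric = c("enmo", "mad"), epoch_length = 60,
                         threshold = 70, bout = NULL) {
  metric <- match.arg(metric)
  stopifnot(threshold > 0, epoch_length > 0)
  if (!is.null(bout)) {
    stopifnot(is.numeric(bout$duration), bout$duration > 0,
              bout$tolerance > 0, bout$tolerance <= 1)
    if (bout$duration * 60 < epoch_length)
      stop("bout duration shorter than the epoch length")
  }
  structure(list(metric = metric, epoch_length = epoch_length,
                 threshold = threshold, bout = bout),
            class = "mvpa_variant")
}

variant_label <- function(v) {
  sprintf("%s_%gs_%gmg_%s", v$metric, v$epoch_length, v$threshold,
          if (is.null(v$bout)) "nobout"
          else sprintf("bout%gmin%g", v$bout$duration, v$bout$tolerance * 100))
}

#' Default MVPA variant grid
#'
#' Metrics ENMO and MAD, epoch lengths 5 s and 60 s, thresholds 30-150 mg
#' in steps of 10 plus the literature anchors (70 mg ENMO, 90 mg MAD), and
#' bout rules none / 1 min / 10 min at 80%.
#'
#' @return list of [mvpa_variant()] objects
#' @export
mvpa_grid <- function() {
  out <- list()
  for (metric in c("enmo", "mad")) {
    thresholds <- sort(unique(c(seq(30, 150, by = 10),
                                if (metric == "enmo") 70 else 90)))
    for (ep in c(5, 60)) for (thr in thresholds)
      for (bout in list(NULL, list(duration = 1, tolerance = 1),
                        list(duration = 10, tolerance = 0.8))) {
        if (!is.null(bout) && bout$duration * 60 < ep) next
        v <- mvpa_variant(metric, ep, thr, bout)
        out[[variant_label(v)]] <- v
      }
  }
  out
}

#' Minutes above threshold in one epoch sequence
#'
#' Without a bout rule, the summed duration of epochs at or above the
#' threshold. With `bout = list(duration, tolerance)`, the time inside the
#' union of all windows of at least `duration` minutes whose first and last
#' epochs are above threshold and in which at least `tolerance` of the
#' epochs are above threshold.
#'
#' @param values metric values per epoch (mg), one contiguous sequence
#' @param epoch_length epoch length in seconds
#' @param threshold cut-point in mg
#' @param bout `NULL` or `list(duration, tolerance)` as in [mvpa_variant()]
#' @return minutes
#' @export
minutes_above <- function(values, epoch_length, threshold, bout = NULL) {
  above <- values >= threshold
  if (is.null(bout)) return(sum(above) * epoch_length / 60)
  w <- as.integer(round(bout$duration * 60 / epoch_length))
  if (w < 1) stop("bout duration shorter than the epoch length")
  tol <- bout$tolerance
  n <- length(above)
  if (n < w || !any(above)) return(0)

  # window [i, j] qualifies iff above[i], above[j], j - i + 1 >= w and
  # sum(above[i..j]) >= tol * (j - i + 1); with S the prefix sum and
  # A[j] = S[j] - tol * j this is A[j] >= A[i - 1]. For each i the union of
  # its qualifying windows is [i, jmax(i)] with jmax the largest qualifying
  # j, found through the non-increasing suffix maximum of A over "above"
  # positions.
  S <- cumsum(as.numeric(above))
  j_all <- seq_len(n)
  A <- S - tol * j_all
  A_use <- ifelse(above, A, -Inf)
  B <- rev(cummax(rev(A_use)))           # suffix max, non-increasing
  i_pos <- which(above)
  a_i <- c(0, S)[i_pos] - tol * (i_pos - 1)
  # count of positions with B >= a_i (a prefix, since B is non-increasing);
  # the 1e-9 slack keeps exact-tolerance windows (frac == tol) qualifying
  # despite floating-point rounding
  jmax <- findInterval(-(a_i - 1e-9), -B)
  ok <- jmax >= i_pos + w - 1L
  if (!any(ok)) return(0)
  starts <- i_pos[ok]; ends <- jmax[ok]
  prev_end <- c(0, head(cummax(ends), -1))
  covered <- sum(pmax(0, ends - pmax(starts - 1L, prev_end)))
  covered * epoch_length / 60
}

# re-epochs a day's 5-s metric values to the variant's epoch length by
# block-averaging full blocks
reepoch_values <- function(values, base_len, target_len) {
  if (target_len == base_len) return(values)
  ratio <- target_len / base_len
  if (ratio != round(ratio))
    stop("variant epoch length must be a multiple of the series epoch length")
  ratio <- as.integer(ratio)
  nb <- length(values) %/% ratio
  if (nb == 0) return(numeric(0))
  .colMeans(matrix(values[seq_len(nb * ratio)], ratio, nb), ratio, nb)
}

#' MVPA minutes per day for one variant
#'
#' Evaluates the variant day by day on valid days (each calendar day is one
#' contiguous sequence; 60-s epochs are block means of twelve 5-s epochs)
#' and returns the mean minutes per valid day.
#'
#' @param es an (imputed) epoch series
#' @param variant an [mvpa_variant()]
#' @param days result of [classify_days()]
#' @return mean minutes per valid day
#' @export
mvpa_minutes <- function(es, variant, days) {
  stopifnot(inherits(es, "epoch_series"), inherits(variant, "mvpa_variant"))
  base_len <- attr(es, "epoch_length")
  t0 <- as.numeric(es$epoch_start)
  e_day <- floor(t0 / 86400)
  valid_dates <- as.numeric(days$date[days$valid])
  per_day <- vapply(valid_dates, function(d) {
    v <- reepoch_values(es[[variant$metric]][e_day == d], base_len,
                        variant$epoch_length)
    minutes_above(v, variant$epoch_length, variant$threshold, variant$bout)
  }, numeric(1))
  mean(per_day)
}

#' Winsorize values within strata
#'
#' Caps values above their stratum's percentile (99.9th by default,
#' linear-interpolation "type 7" quantile) at that percentile.
#'
#' @param values numeric vector
#' @param strata stratum labels, same length as `values`
#' @param probs capping percentile
#' @return the capped vector, in the original order
#' @export
winsorize_by_stratum <- function(values, strata, probs = 0.999) {
  stopifnot(length(values) == length(strata))
  strata <- as.character(strata)
  tab <- table(strata)
  if (any(tab < 2)) stop("every stratum needs at least 2 members")
  out <- values
  for (s in names(tab)) {
    ix <- which(strata == s)
    cap <- as.numeric(quantile(values[ix], probs, type = 7, names = FALSE))
    out[ix] <- pmin(values[ix], cap)
  }
  out
}

#' Age band in 10-year increments
#' @param age age in years
#' @return factor with levels `<30` through `70+`
#' @export
age_band <- function(age) {
  cut(as.numeric(age), breaks = c(-Inf, 29, 39, 49, 59, 69, Inf),
      labels = c("<30", "30-39", "40-49", "50-59", "60-69", "70+"))
}

#' WHO BMI class
#' @param bmi body-mass index in kg/m^2
#' @return factor: underweight (< 18.5), normal (18.5-24.9), overweight
#'   (25.0-29.9), obese (>= 30)
#' @export
bmi_class <- function(bmi) {
  cut(as.numeric(bmi), breaks = c(-Inf, 18.5, 25, 30, Inf), right = FALSE,
      labels = c("underweight", "normal", "overweight", "obese"))
}

#' Season of a date (meteorological, spring starting 1 March)
#' @param date a `Date`
#' @return factor spring/summer/autumn/winter
#' @export
season_of <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  factor(c("winter", "winter", "spring", "spring", "spring", "summer",
           "summer", "summer", "autumn", "autumn", "autumn", "winter")[m],
         levels = c("spring", "summer", "autumn", "winter"))
}

# time-of-day block of a 15-min clock slot (0-95)
tod_block <- function(slot) {
  factor(c("00:00-05:59", "06:00-11:59", "12:00-17:59",
           "18:00-23:59")[slot %/% 24 + 1],
         levels = c("00:00-05:59", "06:00-11:59", "12:00-17:59",
                    "18:00-23:59"))
}

#' Subgroup summary tables
#'
#' Mean and SD of the overall ENMO and MAD by age band, sex, BMI class,
#' week segment, season of the first wear day, and time-of-day block (the
#' latter from the per-slot L4 means). Overall metric values are winsorized
#' at the age-and-sex-specific 99.9th percentile beforehand when every
#' stratum has at least two members. Participants with missing covariates
#' are reported under an `"NA"` group, not dropped.
#'
#' @param summaries list of [aggregate_participant()] results (included
#'   participants)
#' @param covariates covariate table with `participant_id`, `age`, `sex`,
#'   `height`, `weight`, `first_wear_date`
#' @param winsorize cap metric values before summarising?
#' @return data.frame with `grouping`, `group`, `n`, and mean/SD columns
#'   per metric
#' @export
subgroup_report <- function(summaries, covariates, winsorize = TRUE) {
  stopifnot(length(summaries) >= 1)
  ids <- vapply(summaries, `[[`, "", "participant_id")
  df <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (m in c("enmo", "mad")) {
    df[[m]] <- vapply(summaries, function(s) s$overall[[m]], numeric(1))
    df[[paste0(m, "_weekday")]] <-
      vapply(summaries, function(s) s$weekday[[m]], numeric(1))
    df[[paste0(m, "_weekend")]] <-
      vapply(summaries, function(s) s$weekend[[m]], numeric(1))
  }
  cov <- covariates[match(ids, covariates$participant_id), , drop = FALSE]
  df$age_band <- as.character(age_band(cov$age))
  df$sex <- as.character(cov$sex)
  df$bmi <- cov$weight / (cov$height / 100)^2
  df$bmi_class <- as.character(bmi_class(df$bmi))
  df$season <- as.character(season_of(cov$first_wear_date))

  if (winsorize) {
    stratum <- paste(df$age_band, df$sex)
    if (all(table(stratum) >= 2)) {
      df$enmo <- winsorize_by_stratum(df$enmo, stratum)
      df$mad <- winsorize_by_stratum(df$mad, stratum)
    } else {
      message("winsorization skipped: a stratum has fewer than 2 members")
    }
  }

  grp_stats <- function(grouping, value_df, labels) {
    labels[is.na(labels)] <- "NA"
    out <- NULL
    for (g in unique(labels)) {
      ix <- labels == g
      row <- data.frame(grouping = grouping, group = g, n = sum(ix))
      for (m in c("enmo", "mad")) {
        row[[paste0("mean_", m)]] <- mean(value_df[[m]][ix])
        row[[paste0("sd_", m)]] <- sd(value_df[[m]][ix])
      }
      out <- rbind(out, row)
    }
    out
  }

  by_cov <- rbind(
    grp_stats("age_band", df, df$age_band),
    grp_stats("sex", df, df$sex),
    grp_stats("bmi_class", df, df$bmi_class),
    grp_stats("season", df, df$season))

  # week segment: weekday vs weekend participant means
  seg <- NULL
  for (s in c("weekday", "weekend")) {
    row <- data.frame(grouping = "week_segment", group = s, n = nrow(df))
    for (m in c("enmo", "mad")) {
      v <- df[[paste0(m, "_", s)]]
      row[[paste0("mean_", m)]] <- mean(v, na.rm = TRUE)
      row[[paste0("sd_", m)]] <- sd(v, na.rm = TRUE)
    }
    seg <- rbind(seg, row)
  }

  # time-of-day blocks from L4 slot means
  tod <- NULL
  for (b in levels(tod_block(0))) {
    vals <- sapply(c("enmo", "mad"), function(m)
      vapply(summaries, function(s) {
        ix <- as.character(tod_block(s$slots$slot)) == b
        mean(s$slots[[paste0("mean_", m)]][ix])
      }, numeric(1)), simplify = FALSE)
    row <- data.frame(grouping = "time_of_day", group = b,
                      n = length(summaries))
    for (m in c("enmo", "mad")) {
      row[[paste0("mean_", m)]] <- mean(vals[[m]])
      row[[paste0("sd_", m)]] <- sd(vals[[m]])
    }
    tod <- rbind(tod, row)
  }

  out <- rbind(by_cov, seg, tod)
  rownames(out) <- NULL
  out
}
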