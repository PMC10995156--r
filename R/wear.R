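# Wear / non-wear / clipping classification on the 15-min segment grid.
#
# Segments are aligned to local midnight (96 slots per day). Non-wear is
# decided per slot from the enclosing 60-min window (centered, truncated at
# the recording edges): an axis is "still" when its SD is below 13 mg or its
# value range below 50 mg, and a slot is non-wear when at least two of the
# three axes are still. Clipping flags slots where more than 80% of samples
# sit at the dynamic-range edges. Invalid slots are imputed with the mean of
# the same clock slot over the days where it is valid.

#' Detect non-wear segments
#'
#' @param es an epoch series from [compute_epoch_series()]
#' @param sd_crit per-axis stillness SD criterion in mg
#' @param range_crit per-axis stillness range criterion in mg
#' @param axes_required number of still axes that makes a slot non-wear
#' @param combine how the SD and range criteria combine into "still":
#'   `"or"` (default, either suffices) or `"and"`
#' @param window_min evaluation window in minutes, centered on the slot
#' @return a `segment_mask`: data.frame with one row per covered 15-min
#'   slot (`date`, `slot` 0-95, `label` wear/nonwear, `imputed = FALSE`,
#'   `n_epochs`)
#' @export
detect_nonwear <- function(es, sd_crit = 13, range_crit = 50,
                           axes_required = 2L, combine = c("or", "and"),
                           window_min = 60) {
  stopifnot(inherits(es, "epoch_series"))
  combine <- match.arg(combine)
  k <- attr(es, "samples_per_epoch")
  t0 <- as.numeric(es$epoch_start)
  if ((t0[length(t0)] - t0[1]) < window_min * 60 - attr(es, "epoch_length"))
    stop("recording shorter than the non-wear evaluation window")

  slot_key <- floor(t0 / SLOT_SEC)
  slots <- unique(slot_key)  # epochs are time-ordered
  half <- window_min * 60 / 2

  # cumulative per-axis sums/sums-of-squares over epochs for pooled window SD
  ne <- nrow(es)
  cs <- css <- matrix(0, ne + 1L, 3)
  mins <- maxs <- vector("list", 3)
  axes <- c("x", "y", "z")
  for (a in 1:3) {
    mu <- es[[paste0("mean_", axes[a])]]
    sdv <- es[[paste0("sd_", axes[a])]]
    s_e <- k * mu
    ss_e <- (k - 1) * sdv^2 + k * mu^2
    cs[, a] <- c(0, cumsum(s_e))
    css[, a] <- c(0, cumsum(ss_e))
    mins[[a]] <- es[[paste0("min_", axes[a])]]
    maxs[[a]] <- es[[paste0("max_", axes[a])]]
  }

  n_slots <- length(slots)
  label <- character(n_slots)
  n_epochs <- integer(n_slots)
  mid <- slots * SLOT_SEC + SLOT_SEC / 2
  lo_i <- findInterval(mid - half, t0, left.open = TRUE) + 1L
  hi_i <- findInterval(mid + half, t0, left.open = TRUE)
  slot_of_epoch <- match(slot_key, slots)
  n_epochs <- tabulate(slot_of_epoch, n_slots)

  for (s in seq_len(n_slots)) {
    i1 <- lo_i[s]; i2 <- hi_i[s]
    n <- (i2 - i1 + 1L) * k
    still <- 0L
    for (a in 1:3) {
      S <- cs[i2 + 1L, a] - cs[i1, a]
      SS <- css[i2 + 1L, a] - css[i1, a]
      sdv <- sqrt(max(0, (SS - S^2 / n) / (n - 1)))
      rng <- max(maxs[[a]][i1:i2]) - min(mins[[a]][i1:i2])
      ok <- if (combine == "or") (sdv < sd_crit) || (rng < range_crit)
      else (sdv < sd_crit) && (rng < range_crit)
      still <- still + ok
    }
    label[s] <- if (still >= axes_required) "nonwear" else "wear"
  }

  out <- data.frame(
    date = as.Date(as.POSIXct(slots * SLOT_SEC, origin = "1970-01-01",
                              tz = "UTC")),
    slot = as.integer(slots %% SLOTS_PER_DAY),
    label = label, imputed = FALSE, n_epochs = n_epochs,
    stringsAsFactors = FALSE)
  structure(out, epoch_length = attr(es, "epoch_length"),
            participant_id = attr(es, "participant_id"),
            class = c("segment_mask", "data.frame"))
}

#' @export
print.segment_mask <- function(x, ...) {
  tab <- table(factor(x$label, levels = c("wear", "nonwear", "clipped")))
  cat(sprintf(
    "<segment_mask> %d slots over %d day(s): %d wear, %d nonwear, %d clipped, %d imputed\n",
    nrow(x), length(unique(x$date)), tab["wear"], tab["nonwear"],
    tab["clipped"], sum(x$imputed)))
  invisible(x)
}

#' Wear hours per calendar day
#'
#' Wear hours count un-imputed wear slots only (0.25 h per slot).
#'
#' @param mask a `segment_mask`
#' @return data.frame with `date`, `n_slots` (slots covered by the
#'   recording) and `wear_hours`
#' @export
wear_hours_per_day <- function(mask) {
  stopifnot(inherits(mask, "segment_mask"))
  agg <- aggregate(cbind(n = rep(1L, nrow(mask)),
                         wear = as.integer(mask$label == "wear")),
                   by = list(date = mask$date), FUN = sum)
  data.frame(date = agg$date, n_slots = agg$n, wear_hours = agg$wear * 0.25)
}

#' Detect clipped segments and the file-level clipping score
#'
#' A sample is clipped when its absolute value on any axis reaches
#' `edge_fraction` of the dynamic range; a slot is flagged when more than
#' `slot_fraction` of its samples are clipped. Operates on the uncorrected
#' recording, since the dynamic-range edges are a property of the device.
#'
#' @param rec a [raw_recording()]
#' @param edge_fraction "close to the edge" as a fraction of the range
#' @param slot_fraction fraction of clipped samples that invalidates a slot
#' @return list with `slots` (data.frame `date`, `slot`, `clip_fraction`,
#'   `clipped`) and `score` (fraction of flagged slots)
#' @export
detect_clipping <- function(rec, edge_fraction = 0.98, slot_fraction = 0.8) {
  stopifnot(inherits(rec, "raw_recording"))
  thr <- edge_fraction * rec$dynamic_range
  n <- nrow(rec$data)
  # slots are contiguous sample blocks; block boundaries from the clock
  t_start <- as.numeric(rec$start)
  t_end <- t_start + n / rec$rate
  keys <- seq(floor(t_start / SLOT_SEC), ceiling(t_end / SLOT_SEC) - 1L)
  bounds <- pmin(pmax(round((keys * SLOT_SEC - t_start) * rec$rate), 0), n)
  bounds <- c(bounds, n)
  bc <- .clip_block_counts_cpp(rec$data[, 1], rec$data[, 2], rec$data[, 3],
                               thr, bounds)
  keep <- bc$n_total > 0
  keys <- keys[keep]
  frac <- bc$n_clipped[keep] / bc$n_total[keep]
  flagged <- frac > slot_fraction
  list(
    slots = data.frame(
      date = as.Date(as.POSIXct(keys * SLOT_SEC, origin = "1970-01-01",
                                tz = "UTC")),
      slot = as.integer(keys %% SLOTS_PER_DAY),
      clip_fraction = frac, clipped = flagged),
    score = mean(flagged))
}

#' Merge clipping flags into a segment mask
#'
#' Clipped slots override the wear/non-wear label.
#'
#' @param mask a `segment_mask`
#' @param clipping result of [detect_clipping()]
#' @return the updated mask
#' @export
apply_clipping <- function(mask, clipping) {
  stopifnot(inherits(mask, "segment_mask"))
  key_m <- as.numeric(mask$date) * SLOTS_PER_DAY + mask$slot
  cl <- clipping$slots[clipping$slots$clipped, , drop = FALSE]
  key_c <- as.numeric(cl$date) * SLOTS_PER_DAY + cl$slot
  mask$label[key_m %in% key_c] <- "clipped"
  mask
}

#' Impute invalid segments from the same clock slot on valid days
#'
#' For every invalid (non-wear or clipped) slot, the metric values of its
#' epochs are replaced by the mean of the same 15-min clock slot over all
#' days where that slot is valid. A slot that is invalid on every recording
#' day cannot be imputed; it is left untouched and reported, and marks the
#' participant's 24-h cycle as incomplete. Not imputing would count
#' non-wear as zero movement; dropping the epochs would implicitly impute
#' with the rest of the recording.
#'
#' @param es an epoch series
#' @param mask a `segment_mask` for the same recording
#' @param metrics metric columns to impute
#' @return list with `epochs` (epoch series with imputed values and a
#'   logical `imputed` column), `mask` (with its `imputed` flags set) and
#'   `unimputable_slots` (clock slots 0-95 invalid on all days)
#' @export
impute_segments <- function(es, mask, metrics = c("enmo", "mad")) {
  stopifnot(inherits(es, "epoch_series"), inherits(mask, "segment_mask"))
  t0 <- as.numeric(es$epoch_start)
  e_date <- as.Date(as.POSIXct(floor(t0 / 86400) * 86400,
                               origin = "1970-01-01", tz = "UTC"))
  e_slot <- as.integer(floor((t0 %% 86400) / SLOT_SEC))
  key_e <- as.numeric(e_date) * SLOTS_PER_DAY + e_slot
  key_m <- as.numeric(mask$date) * SLOTS_PER_DAY + mask$slot
  row_m <- match(key_e, key_m)
  valid_m <- mask$label == "wear"

  # per (day, slot) metric means, then per-slot means over valid days
  es$imputed <- FALSE
  unimputable <- integer(0)
  per_slot_valid_days <- tapply(valid_m, mask$slot, sum)
  covered_slots <- as.integer(names(per_slot_valid_days))
  unimputable <- covered_slots[per_slot_valid_days == 0]

  invalid_rows <- which(!valid_m[row_m])
  if (length(invalid_rows)) {
    valid_rows <- valid_m[row_m]
    vkey <- key_e[valid_rows]
    for (metric in metrics) {
      # day-by-slot means on valid days, then the across-day mean per slot
      ds_sum <- rowsum(es[[metric]][valid_rows], vkey)
      ds_n <- rowsum(rep(1, length(vkey)), vkey)
      ds_mean <- ds_sum / ds_n
      ds_slot <- as.numeric(rownames(ds_sum)) %% SLOTS_PER_DAY
      slot_mean <- tapply(as.numeric(ds_mean), ds_slot, mean)
      repl <- slot_mean[as.character(e_slot[invalid_rows])]
      ok <- !is.na(repl)
      es[[metric]][invalid_rows[ok]] <- as.numeric(repl[ok])
    }
    imputable <- !(e_slot[invalid_rows] %in% unimputable)
    es$imputed[invalid_rows[imputable]] <- TRUE
  }
  mask$imputed <- !valid_m & !(mask$slot %in% unimputable)

  list(epochs = es, mask = mask, unimputable_slots = unimputable)
}

#' Write a segment mask as CSV
#'
#' @param mask a `segment_mask`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_segment_mask <- function(mask, path) {
  data.table::fwrite(data.table::data.table(
    date = as.character(mask$date), slot_index = mask$slot,
    label = mask$label, imputed = mask$imputed), path)
  invisible(path)
}

# Clipping report assembled from a pre-calibration epoch series (n_clip is
# counted against the dynamic-range edges in the epoch kernel); same return
# shape as detect_clipping().
clipping_from_epochs <- function(es, slot_fraction = 0.8) {
  k <- attr(es, "samples_per_epoch")
  t0 <- as.numeric(es$epoch_start)
  key <- floor(t0 / SLOT_SEC)
  keys <- unique(key)
  f <- factor(key, levels = keys)
  nclip <- as.numeric(tapply(es$n_clip, f, sum))
  ntot <- tabulate(f, length(keys)) * k
  frac <- nclip / ntot
  flagged <- frac > slot_fraction
  list(
    slots = data.frame(
      date = as.Date(as.POSIXct(keys * SLOT_SEC, origin = "1970-01-01",
                                tz = "UTC")),
      slot = as.integer(keys %% SLOTS_PER_DAY),
      clip_fraction = frac, clipped = flagged),
    score = mean(flagged))
}
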