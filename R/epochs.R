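# Epoch-level signal features.
#
# ENMO (Euclidean norm minus one, negatives truncated to zero) and MAD (mean
# amplitude deviation of the vector norm around its epoch mean) are computed
# per 5-s epoch directly from the unfiltered signal: no low-pass filter is
# applied, since high frequencies carry harmonics of genuine movement.

#' Per-epoch ENMO
#'
#' Mean over the epoch's samples of `max(||a|| - 1, 0)`, in mg. By default
#' the truncation at zero is applied per sample before averaging (the
#' convention of the established raw-processing toolchain); the alternative
#' truncates the epoch mean instead.
#'
#' @param samples n x 3 matrix of triaxial accelerations in g
#' @param truncation `"sample"` (default) or `"epoch"`
#' @return ENMO in mg (scalar)
#' @export
epoch_enmo <- function(samples, truncation = c("sample", "epoch")) {
  truncation <- match.arg(truncation)
  if (!is.matrix(samples) || ncol(samples) != 3 || nrow(samples) < 1)
    stop("need at least one triaxial sample")
  r <- sqrt(rowSums(samples^2))
  if (truncation == "sample") 1000 * mean(pmax(r - 1, 0))
  else 1000 * max(mean(r) - 1, 0)
}

#' Per-epoch MAD
#'
#' Mean absolute deviation of the sample vector norms around their epoch
#' mean, in mg. Invariant to a constant shift of all norms, which makes it
#' less sensitive to calibration error than ENMO.
#'
#' @inheritParams epoch_enmo
#' @return MAD in mg (scalar)
#' @export
epoch_mad <- function(samples) {
  if (!is.matrix(samples) || ncol(samples) != 3 || nrow(samples) < 1)
    stop("need at least one triaxial sample")
  r <- sqrt(rowSums(samples^2))
  1000 * mean(abs(r - mean(r)))
}

#' Per-epoch posture angles
#'
#' Elevation of each axis relative to the horizontal plane, from the
#' per-axis epoch medians `m`: `atan(m_i / sqrt(m_j^2 + m_k^2)) * 180 / pi`,
#' in `[-90, 90]` degrees. A zero denominator maps to +/-90 by the sign of
#' `m_i`. Medians over the 5-s epoch damp movement so the angle tracks the
#' gravity direction.
#'
#' @inheritParams epoch_enmo
#' @return numeric length-3 vector of angles in degrees
#' @export
epoch_angles <- function(samples) {
  if (!is.matrix(samples) || ncol(samples) != 3 || nrow(samples) < 1)
    stop("need at least one triaxial sample")
  m <- unname(apply(samples, 2, median))
  angles_from_medians(m[1], m[2], m[3])
}

# atan2 handles the degenerate zero-denominator cases: (m_i, 0) -> +/-90,
# (0, 0) -> 0
angles_from_medians <- function(mx, my, mz) {
  deg <- 180 / pi
  c(atan2(mx, sqrt(my^2 + mz^2)) * deg,
    atan2(my, sqrt(mx^2 + mz^2)) * deg,
    atan2(mz, sqrt(mx^2 + my^2)) * deg)
}

#' Compute the epoch series of a recording
#'
#' Tiles the recording with half-open epochs `[t, t + epoch_length)`
#' starting at the first full epoch boundary of the local clock after the
#' recording start; a trailing partial epoch is dropped. No frequency
#' filtering is applied. The recording should already be
#' calibration-corrected (see [apply_calibration()]); feature columns also
#' carry the per-axis statistics (SD, range, clipped-sample counts) that
#' non-wear and clipping detection consume.
#'
#' @param rec a [raw_recording()]
#' @param epoch_length epoch length in seconds (default 5)
#' @param enmo_truncation `"sample"` or `"epoch"`, see [epoch_enmo()]
#' @param clip_fraction samples at or beyond this fraction of the dynamic
#'   range count as clipped
#' @param angles compute per-axis posture angles? (skipping the per-epoch
#'   medians roughly halves the work when only ENMO/MAD/axis statistics are
#'   needed)
#' @param calibration optional [fit_calibration()] model applied on the fly
#'   (equivalent to [apply_calibration()] first, without copying the
#'   samples); an error if the recording is already corrected
#' @return an `epoch_series`: a data.frame with one row per epoch
#'   (`epoch_start`, `enmo`, `mad` in mg, `angle_x/y/z` in degrees, per-axis
#'   `sd_*`, `min_*`, `max_*` in mg, `n_clip`), with the recording metadata
#'   in attributes
#' @export
compute_epoch_series <- function(rec, epoch_length = 5,
                                 enmo_truncation = c("sample", "epoch"),
                                 clip_fraction = 0.98, angles = TRUE,
                                 calibration = NULL) {
  stopifnot(inherits(rec, "raw_recording"))
  enmo_truncation <- match.arg(enmo_truncation)
  gain <- c(1, 1, 1)
  offset <- c(0, 0, 0)
  if (!is.null(calibration)) {
    stopifnot(inherits(calibration, "calibration_model"))
    if (rec$calibrated)
      stop("recording is already calibration-corrected")
    gain <- calibration$gain
    offset <- calibration$offset
  }
  k <- epoch_length * rec$rate
  if (k != round(k) || k < 1)
    stop("epoch_length x rate must be a positive integer sample count")
  k <- as.integer(k)

  # align to the local clock's epoch grid
  sod <- as.numeric(rec$start) %% 86400
  boundary <- ceiling(sod / epoch_length) * epoch_length
  skip <- round((boundary - sod) * rec$rate)
  n_avail <- nrow(rec$data) - skip
  if (n_avail < k) stop("recording spans less than one epoch")
  ne <- n_avail %/% k

  idx <- (skip + 1L):(skip + ne * k)
  st <- .epoch_stats_cpp(rec$data[idx, 1], rec$data[idx, 2],
                         rec$data[idx, 3], k,
                         clip_fraction * rec$dynamic_range, angles,
                         gain, offset)

  enmo <- if (enmo_truncation == "sample") st$enmo else pmax(st$enmo_raw, 0)
  deg <- 180 / pi
  den_x <- sqrt(st$med_y^2 + st$med_z^2)
  den_y <- sqrt(st$med_x^2 + st$med_z^2)
  den_z <- sqrt(st$med_x^2 + st$med_y^2)

  out <- data.frame(
    epoch_start = rec$start + (boundary - sod) +
      (seq_len(ne) - 1L) * epoch_length,
    enmo = 1000 * enmo,
    mad = 1000 * st$mad,
    angle_x = if (angles) atan2(st$med_x, den_x) * deg else NA_real_,
    angle_y = if (angles) atan2(st$med_y, den_y) * deg else NA_real_,
    angle_z = if (angles) atan2(st$med_z, den_z) * deg else NA_real_,
    mean_x = 1000 * st$mean_x, mean_y = 1000 * st$mean_y,
    mean_z = 1000 * st$mean_z,
    sd_x = 1000 * st$sd_x, sd_y = 1000 * st$sd_y, sd_z = 1000 * st$sd_z,
    min_x = 1000 * st$min_x, min_y = 1000 * st$min_y, min_z = 1000 * st$min_z,
    max_x = 1000 * st$max_x, max_y = 1000 * st$max_y, max_z = 1000 * st$max_z,
    n_clip = st$n_clip)
  structure(out,
            epoch_length = epoch_length, rate = rec$rate,
            samples_per_epoch = k,
            dynamic_range = rec$dynamic_range,
            participant_id = rec$participant_id,
            enmo_truncation = enmo_truncation,
            class = c("epoch_series", "data.frame"))
}

#' Write an epoch series as CSV
#'
#' @param es an epoch series from [compute_epoch_series()]
#' @param path output path
#' @param valid optional logical vector marking epochs in valid (wear or
#'   imputed) segments
#' @return `path`, invisibly
#' @export
write_epoch_series <- function(es, path, valid = NULL) {
  out <- data.table::data.table(
    epoch_start = format(es$epoch_start, "%Y-%m-%dT%H:%M:%S"),
    enmo_mg = round(es$enmo, 4), mad_mg = round(es$mad, 4),
    angle_x = round(es$angle_x, 2), angle_y = round(es$angle_y, 2),
    angle_z = round(es$angle_z, 2),
    valid_flag = if (is.null(valid)) TRUE else valid)
  data.table::fwrite(out, path)
  invisible(path)
}

#' Identify the longitudinal axis from the posture-angle rhythm
#'
#' The body's longitudinal axis swings between an upright daytime posture
#' and a reclined night posture, so its angle series repeats with a strong
#' 24-h period. Each axis's angle series is aggregated to `agg_min`-minute
#' means and correlated (Pearson) with itself lagged exactly 24 h over the
#' overlapping span; the axis with the highest lag-24h autocorrelation is
#' the estimated longitudinal axis.
#'
#' @param es an epoch series
#' @param agg_min aggregation width in minutes (damps within-epoch noise)
#' @return an `axis_report`: list with `correlations` (length 3),
#'   `estimated_longitudinal_axis` (1-3, or `NA` when inconclusive) and
#'   `inconclusive` (recording shorter than 48 h, or an undefined
#'   correlation from a constant angle series)
#' @export
verify_longitudinal_axis <- function(es, agg_min = 5) {
  stopifnot(inherits(es, "epoch_series"))
  w <- agg_min * 60
  t0 <- as.numeric(es$epoch_start)
  bin <- floor(t0 / w)
  bins <- sort(unique(bin))
  series <- sapply(c("angle_x", "angle_y", "angle_z"), function(cn)
    tapply(es[[cn]], factor(bin, levels = bins), mean))
  lag <- as.integer(86400 / w)

  duration <- t0[length(t0)] - t0[1]
  cors <- rep(NA_real_, 3)
  inconclusive <- duration < 2 * 86400 - w
  if (!inconclusive) {
    # require contiguous bins for an exact 24-h lag
    L <- nrow(series)
    a <- series[1:(L - lag), , drop = FALSE]
    b <- series[(lag + 1):L, , drop = FALSE]
    for (j in 1:3) {
      if (sd(a[, j]) > 0 && sd(b[, j]) > 0)
        cors[j] <- cor(a[, j], b[, j])
    }
    if (anyNA(cors)) inconclusive <- TRUE
  }
  structure(list(
    correlations = stats::setNames(cors, c("x", "y", "z")),
    estimated_longitudinal_axis = if (inconclusive) NA_integer_
    else which.max(cors),
    inconclusive = inconclusive, agg_min = agg_min),
    class = "axis_report")
}

#' @export
print.axis_report <- function(x, ...) {
  if (x$inconclusive) cat("<axis_report> inconclusive\n")
  else cat(sprintf(
    "<axis_report> longitudinal axis: %d (lag-24h r = %.3f / %.3f / %.3f)\n",
    x$estimated_longitudinal_axis, x$correlations[1], x$correlations[2],
    x$correlations[3]))
  invisible(x)
}
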