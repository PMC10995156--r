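# Auto-calibration.
#
# Offset/gain drift of the sensor is estimated from non-movement periods:
# during stillness the device measures gravity only, so still-window mean
# vectors must lie on the unit sphere. An iteratively reweighted per-axis
# regression pulls the cloud of still points onto the sphere; the residual
# mean distance from unit norm is the calibration error, and recordings
# whose error stays above 0.02 g after correction are excluded. Hip wear
# limits orientation variability, so a fit is only attempted when the still
# points cover enough of the sphere.

#' Detect still points for calibration
#'
#' Cuts the recording into non-overlapping windows (10 s by default) and
#' returns the mean acceleration vector of every window whose per-axis SD
#' is below `sd_threshold` on all three axes.
#'
#' @param rec a [raw_recording()]
#' @param window window length in seconds
#' @param sd_threshold stillness criterion in mg (all three axes)
#' @return numeric matrix (one row per still window, columns x/y/z in g)
#'   with attribute `n_windows` (number of windows examined)
#' @export
detect_still_points <- function(rec, window = 10, sd_threshold = 13) {
  stopifnot(inherits(rec, "raw_recording"))
  k <- as.integer(window * rec$rate)
  if (k < 2) stop("window too short for an SD at this sampling rate")
  nw <- nrow(rec$data) %/% k
  if (nw < 1) return(structure(matrix(numeric(0), 0, 3), n_windows = 0L))
  n_use <- nw * k
  still <- rep(TRUE, nw)
  means <- matrix(0, nw, 3)
  for (ax in 1:3) {
    m <- matrix(rec$data[seq_len(n_use), ax], k, nw)
    mu <- .colMeans(m, k, nw)
    ss <- .colMeans(m * m, k, nw)
    sdev <- sqrt(pmax(0, (ss - mu^2) * k / (k - 1)))
    means[, ax] <- mu
    still <- still & (sdev < sd_threshold * MG)
  }
  structure(means[still, , drop = FALSE], n_windows = nw)
}

#' Fit an offset/gain calibration model to still points
#'
#' Iteratively reweighted least squares for the per-axis affine map
#' `a -> gain * a + offset` minimising the squared distance of the mapped
#' still points from the unit sphere. Because hip-worn recordings spend
#' most still time in very few postures, the raw point cloud is first
#' balanced: points are binned by orientation and each bin contributes its
#' mean vector once, so a dominant posture cannot trade offset against
#' gain and leave the sphere fit unidentified. Each iteration then
#' regresses, per axis, the closest unit-sphere point against the balanced
#' point, with weights `1 / max(|residual|, 1e-3)` refreshed from the
#' current fit (with the denominator floored at the mean residual so that
#' early, far-from-sphere iterations are effectively unweighted); only
#' error-non-increasing damped steps are accepted. When
#' fewer than `min_points` still points exist or their per-axis span is
#' below `min_span`, no fit is attempted and the identity model is
#' returned with `converged = FALSE`.
#'
#' @param points still-point matrix from [detect_still_points()]
#' @param min_points minimum number of sphere points
#' @param min_span minimum per-axis span of the points in g
#' @param tol stop when no parameter changes by more than this
#' @param max_iter iteration cap
#' @param error_gate usability threshold in g: recordings whose residual
#'   calibration error exceeds it are flagged unusable and excluded
#' @return object of class `calibration_model` with per-axis `offset` and
#'   `gain`, `error_before` / `error_after` (mean absolute deviation of the
#'   still-point norms from 1 g), `n_still_points`, `sphere_coverage`,
#'   `converged`, `usable`, `iterations`
#' @export
fit_calibration <- function(points, min_points = 72L, min_span = 0.3,
                            tol = 1e-9, max_iter = 1000L,
                            error_gate = 0.02) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  m <- nrow(points)
  span <- if (m > 0) apply(points, 2, function(v) diff(range(v))) else c(0, 0, 0)
  err0 <- if (m > 0) mean(abs(sqrt(rowSums(points^2)) - 1)) else NA_real_

  identity_model <- function() {
    structure(list(
      offset = c(0, 0, 0), gain = c(1, 1, 1),
      error_before = err0, error_after = err0,
      n_still_points = m, sphere_coverage = span,
      converged = FALSE, usable = isTRUE(err0 <= error_gate),
      iterations = 0L, error_gate = error_gate),
      class = "calibration_model")
  }
  if (m < min_points || any(span < min_span)) {
    mod <- identity_model()
    warning(sprintf(paste0(
      "insufficient still points (%d) or sphere coverage ",
      "(span %.2f/%.2f/%.2f g); falling back to identity calibration"),
      m, span[1], span[2], span[3]))
    return(mod)
  }

  raw_points <- points
  points <- balance_orientations(points)
  offset <- c(0, 0, 0)
  gain <- c(1, 1, 1)
  sphere_error <- function(off, g, p = points) {
    mapped <- sweep(p, 2, g, "*")
    mapped <- sweep(mapped, 2, off, "+")
    mean(abs(sqrt(rowSums(mapped^2)) - 1))
  }
  # the iteration minimises the balanced-cloud error; the reported
  # error_before/error_after are over all still windows
  best_err <- sphere_error(c(0, 0, 0), c(1, 1, 1))
  it <- 0L
  repeat {
    it <- it + 1L
    mapped <- sweep(sweep(points, 2, gain, "*"), 2, offset, "+")
    nr <- sqrt(rowSums(mapped^2))
    target <- mapped / nr
    # robust weights with a floor at the mean residual: early iterations
    # weight points near-uniformly (the fit is far from the sphere
    # everywhere), later ones downweight contaminated windows
    resid <- abs(nr - 1)
    w <- 1 / pmax(resid, max(1e-3, mean(resid)))
    new_off <- offset
    new_gain <- gain
    for (ax in 1:3) {
      p <- points[, ax]; tgt <- target[, ax]
      pw <- sum(w * p) / sum(w); tw <- sum(w * tgt) / sum(w)
      den <- sum(w * (p - pw)^2)
      b <- if (den > 0) sum(w * (p - pw) * (tgt - tw)) / den else gain[ax]
      if (b <= 0) b <- gain[ax]  # gains must stay positive
      new_gain[ax] <- b
      new_off[ax] <- tw - b * pw
    }
    # backtracking line search: accept the longest damped step that does
    # not increase the sphere residual, so every accepted iteration is
    # monotone
    accepted <- FALSE
    for (alpha in 2^-(0:5)) {
      cand_off <- offset + alpha * (new_off - offset)
      cand_gain <- gain + alpha * (new_gain - gain)
      cand_err <- sphere_error(cand_off, cand_gain)
      if (cand_err <= best_err) {
        delta <- max(abs(c(cand_off - offset, cand_gain - gain)))
        offset <- cand_off; gain <- cand_gain; best_err <- cand_err
        accepted <- TRUE
        break
      }
    }
    if (!accepted || delta < tol || it >= max_iter) break
  }

  err_after <- sphere_error(offset, gain, raw_points)
  if (err_after > err0) {  # guard: never leave the recording worse off
    offset <- c(0, 0, 0); gain <- c(1, 1, 1); err_after <- err0
  }

  structure(list(
    offset = offset, gain = gain,
    error_before = err0, error_after = err_after,
    n_still_points = m, sphere_coverage = span,
    converged = TRUE, usable = err_after <= error_gate,
    iterations = it, error_gate = error_gate),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    paste0("<calibration_model> offset (%.4f, %.4f, %.4f) g, ",
           "gain (%.4f, %.4f, %.4f)\n  error %.4f -> %.4f g over %d still ",
           "points; %s, %s\n"),
    x$offset[1], x$offset[2], x$offset[3],
    x$gain[1], x$gain[2], x$gain[3],
    x$error_before, x$error_after, x$n_still_points,
    if (x$converged) "converged" else "identity fallback",
    if (x$usable) "usable" else
      sprintf("NOT usable (error > %.2f g)", x$error_gate)))
  invisible(x)
}

#' @export
coef.calibration_model <- function(object, ...) {
  rbind(offset = object$offset, gain = object$gain)
}

#' Apply a calibration model to a recording
#'
#' Maps every sample through `gain * a + offset`. Applying a correction to
#' an already-corrected recording is an error, not a no-op.
#'
#' @param rec a [raw_recording()]
#' @param model a [fit_calibration()] result
#' @return the corrected recording, with the model attached as
#'   `rec$calibration`
#' @export
apply_calibration <- function(rec, model) {
  stopifnot(inherits(rec, "raw_recording"),
            inherits(model, "calibration_model"))
  if (rec$calibrated)
    stop("recording is already calibration-corrected")
  d <- rec$data
  attr(d, "adc_counts") <- NULL  # no longer on the ADC grid
  for (ax in 1:3)  # first assignment duplicates once, the rest are in place
    d[, ax] <- model$gain[ax] * d[, ax] + model$offset[ax]
  rec$data <- d
  rec$calibrated <- TRUE
  rec$calibration <- model
  rec
}

# Orientation balancing: bin points by their direction (unit vector rounded
# to a 0.2-wide grid) and keep one representative per bin, equalizing the
# influence of rare postures against the dominant one. The representative
# is the bin's mean direction rescaled to the members' mean norm -- a plain
# coordinate mean of points spread over an arc would sit inside the sphere
# (chord shrinkage) and bias the fit by a few mg.
balance_orientations <- function(points, grid = 0.2) {
  nr <- sqrt(rowSums(points^2))
  nr[nr == 0] <- 1
  u <- points / nr
  dirs <- round(u / grid)
  key <- paste(dirs[, 1], dirs[, 2], dirs[, 3])
  n <- as.vector(rowsum(rep(1, nrow(points)), key))
  dbar <- rowsum(u, key) / n
  dbar <- dbar / sqrt(rowSums(dbar^2))
  rbar <- as.vector(rowsum(nr, key)) / n
  dbar * rbar
}

# plain-list form for JSON serialization
calibration_to_list <- function(model) {
  model[c("offset", "gain", "error_before", "error_after",
          "n_still_points", "sphere_coverage", "converged", "usable",
          "iterations")]
}

# Still points assembled from a pre-calibration epoch series: consecutive
# epoch groups spanning `window` seconds, pooled per-axis SD below the
# threshold on all axes. Exact pooling of the per-epoch sums/sums-of-squares,
# so it agrees with detect_still_points() on clock-aligned recordings while
# reusing the single pass over the samples.
still_points_from_epochs <- function(es, window = 10, sd_threshold = 13) {
  el <- attr(es, "epoch_length")
  k <- attr(es, "samples_per_epoch")
  m <- window / el
  if (m != round(m) || m < 1)
    stop("still window must be a multiple of the epoch length")
  m <- as.integer(m)
  ne <- nrow(es)
  ng <- ne %/% m
  if (ng < 1) return(structure(matrix(numeric(0), 0, 3), n_windows = 0L))
  N <- m * k
  still <- rep(TRUE, ng)
  means <- matrix(0, ng, 3)
  for (a in 1:3) {
    mu <- es[[paste0("mean_", c("x", "y", "z")[a])]] * MG
    sdv <- es[[paste0("sd_", c("x", "y", "z")[a])]] * MG
    S <- .colMeans(matrix(k * mu[seq_len(ng * m)], m, ng), m, ng) * m
    SS <- .colMeans(matrix(((k - 1) * sdv^2 + k * mu^2)[seq_len(ng * m)],
                           m, ng), m, ng) * m
    pooled_sd <- sqrt(pmax(0, (SS - S^2 / N) / (N - 1)))
    means[, a] <- S / N
    still <- still & (pooled_sd < sd_threshold * MG)
  }
  structure(means[still, , drop = FALSE], n_windows = ng)
}
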