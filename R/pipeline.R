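# End-to-end orchestration: read -> calibrate -> epochs -> wear/clipping ->
# impute -> valid days -> inclusion -> aggregate, with a participant-flow
# ledger that telescopes: received = unprocessable + quality_excluded +
# validity_excluded + included.

#' Pipeline run configuration
#'
#' Gathers every tunable of the processing stages, with the study defaults:
#' 5-s epochs, per-sample ENMO truncation, 10-s still windows and a 0.02 g
#' calibration gate, the 13 mg / 50 mg non-wear criteria on centered 60-min
#' windows with a 2-of-3 axis vote, 98% range edges with the 80% per-slot
#' clipping rule and a 0.3 file-level clipping score gate, 16 valid wear
#' hours per valid day, and absolute-agreement ICC.
#'
#' @param epoch_length epoch length in seconds
#' @param enmo_truncation `"sample"` or `"epoch"`, see [epoch_enmo()]
#' @param still_window still-window length in seconds for calibration
#' @param still_sd still criterion in mg for calibration windows
#' @param calib_min_points,calib_min_span sphere-fit requirements
#' @param calib_error_gate exclusion gate on the calibration error in g
#' @param force_identity_calibration skip the sphere fit and apply the
#'   identity correction (for diagnostics)
#' @param nonwear_sd,nonwear_range per-axis stillness criteria in mg
#' @param nonwear_axes axes that must be still for a non-wear slot
#' @param nonwear_combine `"or"` or `"and"` of the SD/range criteria
#' @param nonwear_window window in minutes
#' @param clip_edge_fraction,clip_slot_fraction clipping rules
#' @param clip_score_gate file-level exclusion gate on the clipping score
#' @param min_wear_hours valid-day threshold in hours (for a 24-h day)
#' @param mvpa_variants list of [mvpa_variant()]s evaluated per participant
#' @param icc_type ICC form for reliability analyses
#' @param seed seed recorded with the run (synthetic-cohort generation and
#'   subset draws; processing itself is deterministic)
#' @return object of class `run_config`
#' @export
run_config <- function(epoch_length = 5,
                       enmo_truncation = "sample",
                       still_window = 10, still_sd = 13,
                       calib_min_points = 72L, calib_min_span = 0.3,
                       calib_error_gate = 0.02,
                       force_identity_calibration = FALSE,
                       nonwear_sd = 13, nonwear_range = 50,
                       nonwear_axes = 2L, nonwear_combine = "or",
                       nonwear_window = 60,
                       clip_edge_fraction = 0.98, clip_slot_fraction = 0.8,
                       clip_score_gate = 0.3,
                       min_wear_hours = 16,
                       mvpa_variants = list(
                         mvpa_variant("enmo", 60, 70),
                         mvpa_variant("mad", 60, 90)),
                       icc_type = "agreement",
                       seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<run_config> %g-s epochs (%s ENMO truncation), calibration gate ",
    "%.3g g,\n  non-wear SD<%g mg / range<%g mg (%s, %d axes, %g-min ",
    "window),\n  clipping %g%% edges / %g%% slot / score gate %g, valid ",
    "day >= %g h, %d MVPA variant(s)\n"),
    x$epoch_length, x$enmo_truncation, x$calib_error_gate,
    x$nonwear_sd, x$nonwear_range, x$nonwear_combine, x$nonwear_axes,
    x$nonwear_window, 100 * x$clip_edge_fraction,
    100 * x$clip_slot_fraction, x$clip_score_gate, x$min_wear_hours,
    length(x$mvpa_variants)))
  invisible(x)
}

config_to_json <- function(config, path) {
  ser <- unclass(config)
  ser$mvpa_variants <- lapply(config$mvpa_variants, function(v)
    list(metric = v$metric, epoch_length = v$epoch_length,
         threshold = v$threshold, bout = v$bout))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read back a serialized run configuration
#'
#' @param path JSON file written by [run_cohort()]
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path)
  raw$mvpa_variants <- lapply(raw$mvpa_variants, function(v)
    mvpa_variant(v$metric, v$epoch_length, v$threshold,
                 if (is.null(v$bout)) NULL else
                   list(duration = v$bout$duration,
                        tolerance = v$bout$tolerance)))
  raw$calib_min_points <- as.integer(raw$calib_min_points)
  raw$nonwear_axes <- as.integer(raw$nonwear_axes)
  raw$seed <- as.integer(raw$seed)
  structure(raw, class = "run_config")
}

rejection <- function(stage, reason, participant_id = NA_character_) {
  structure(list(stage = stage, reason = reason,
                 participant_id = participant_id),
            class = "hipacc_rejection")
}

#' @export
print.hipacc_rejection <- function(x, ...) {
  cat(sprintf("<rejection> %s: %s (%s)\n", x$participant_id, x$stage,
              x$reason))
  invisible(x)
}

#' Process one raw recording file
#'
#' Runs calibration, epoch features, non-wear/clipping classification,
#' imputation, day validity and aggregation for a single file. Every
#' rejection is a typed outcome, not an error: unreadable or too-small
#' files are `unprocessable`; a failed calibration gate or an excessive
#' clipping score is `quality_excluded`; inclusion-rule failures are
#' reported in the result and ledgered as `validity_excluded` by
#' [run_cohort()].
#'
#' @param path raw recording file
#' @param config a [run_config()]
#' @return on success, a list with `epochs` (imputed), `mask`,
#'   `calibration`, `clipping`, `days`, `inclusion`, `summary` (`NULL` for
#'   excluded participants), `axis_report`; otherwise a `hipacc_rejection`
#' @export
process_recording <- function(path, config = run_config()) {
  pid <- sub("\\.[^.]*$", "", basename(path))
  rec <- tryCatch(read_recording(path),
                  error = function(e) rejection("unprocessable",
                                                conditionMessage(e), pid))
  if (inherits(rec, "hipacc_rejection")) return(rec)
  if (nrow(rec$data) < rec$rate * config$nonwear_window * 60)
    return(rejection("unprocessable", "recording too short", pid))

  # one pre-calibration pass: clipping slots and calibration still points
  es_raw <- compute_epoch_series(rec, config$epoch_length,
                                 config$enmo_truncation,
                                 config$clip_edge_fraction, angles = FALSE)
  clipping <- clipping_from_epochs(es_raw, config$clip_slot_fraction)
  if (clipping$score > config$clip_score_gate)
    return(rejection("quality_excluded",
                     sprintf("clipping score %.2f", clipping$score), pid))

  calib <- if (config$force_identity_calibration) {
    structure(list(offset = c(0, 0, 0), gain = c(1, 1, 1),
                   error_before = NA_real_, error_after = NA_real_,
                   n_still_points = 0L, sphere_coverage = c(0, 0, 0),
                   converged = TRUE, usable = TRUE, iterations = 0L,
                   error_gate = config$calib_error_gate),
              class = "calibration_model")
  } else {
    pts <- still_points_from_epochs(es_raw, config$still_window,
                                    config$still_sd)
    suppressWarnings(fit_calibration(
      pts, config$calib_min_points, config$calib_min_span,
      error_gate = config$calib_error_gate))
  }
  rm(es_raw)
  if (!calib$usable)
    return(rejection("quality_excluded",
                     sprintf("calibration error %.4f g", calib$error_after),
                     pid))
  es <- compute_epoch_series(rec, config$epoch_length,
                             config$enmo_truncation,
                             config$clip_edge_fraction,
                             calibration = calib)
  axis_report <- tryCatch(verify_longitudinal_axis(es),
                          error = function(e) NULL)
  mask <- detect_nonwear(es, config$nonwear_sd, config$nonwear_range,
                         config$nonwear_axes, config$nonwear_combine,
                         config$nonwear_window)
  mask <- apply_clipping(mask, clipping)
  imp <- impute_segments(es, mask)
  days <- classify_days(imp$mask, min_wear_hours = config$min_wear_hours)
  inclusion <- include_participant(days, imp$mask)

  summary <- NULL
  mvpa <- NULL
  bins <- NULL
  if (inclusion$included) {
    summary <- aggregate_participant(imp$epochs, days)
    bins <- intensity_distribution(imp$epochs, days)
    mvpa <- vapply(config$mvpa_variants, function(v)
      mvpa_minutes(imp$epochs, v, days), numeric(1))
    names(mvpa) <- vapply(config$mvpa_variants, variant_label, "")
    summary$mvpa <- mvpa
    summary$bin_minutes <- bins
  }
  list(participant_id = pid, epochs = imp$epochs, mask = imp$mask,
       calibration = calib, clipping = clipping, days = days,
       inclusion = inclusion, summary = summary, axis_report = axis_report)
}

#' Process a cohort of raw recordings
#'
#' Applies [process_recording()] to every `*.csv` recording in `input_dir`,
#' maintains the participant-flow ledger, and writes the output artifacts:
#' per-participant segment masks and calibration models, a wide
#' participant-summary CSV, long day-level (L3) and slot-level (L4) CSVs,
#' the subgroup report, the flow ledger and the run configuration (JSON).
#' Partial failures do not abort the cohort. Re-running with the same
#' configuration and inputs reproduces the outputs byte for byte.
#'
#' @param input_dir directory of raw recordings (and `covariates.csv`,
#'   unless given separately)
#' @param covariates covariate data.frame or path to a CSV; missing
#'   covariate rows exclude a participant from the subgroup report only
#' @param config a [run_config()]
#' @param output_dir where to write artifacts
#' @param write_epochs also write the (large) per-participant epoch CSVs?
#' @return invisibly, a list with `ledger` (class `flow_ledger`),
#'   `summaries`, `subgroups`, `results` (per-participant outcomes)
#' @export
run_cohort <- function(input_dir, covariates = NULL,
                       config = run_config(), output_dir,
                       write_epochs = FALSE) {
  files <- sort(list.files(input_dir, pattern = "\\.csv$", full.names = TRUE))
  files <- files[basename(files) != "covariates.csv"]
  if (length(files) == 0) stop("no recordings found in ", input_dir)
  if (is.null(covariates)) {
    cpath <- file.path(input_dir, "covariates.csv")
    covariates <- if (file.exists(cpath))
      as.data.frame(data.table::fread(cpath)) else NULL
  } else if (is.character(covariates)) {
    covariates <- as.data.frame(data.table::fread(covariates))
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(output_dir, "masks"), showWarnings = FALSE)
  dir.create(file.path(output_dir, "calibration"), showWarnings = FALSE)
  if (write_epochs)
    dir.create(file.path(output_dir, "epochs"), showWarnings = FALSE)

  counts <- c(received = length(files), unprocessable = 0L,
              quality_excluded = 0L, validity_excluded = 0L, included = 0L)
  reasons <- c(weekend = 0L, weekday = 0L, cycle = 0L)
  results <- list()
  summaries <- list()
  log_rows <- list()

  for (f in files) {
    res <- process_recording(f, config)
    pid <- if (inherits(res, "hipacc_rejection")) res$participant_id
    else res$participant_id
    if (inherits(res, "hipacc_rejection")) {
      counts[res$stage] <- counts[res$stage] + 1L
      log_rows[[pid]] <- data.frame(participant_id = pid,
                                    outcome = res$stage,
                                    reason = res$reason)
    } else {
      write_segment_mask(res$mask,
                         file.path(output_dir, "masks",
                                   paste0(pid, "_mask.csv")))
      jsonlite::write_json(calibration_to_list(res$calibration),
                           file.path(output_dir, "calibration",
                                     paste0(pid, "_calibration.json")),
                           auto_unbox = TRUE, digits = NA)
      if (write_epochs)
        write_epoch_series(res$epochs,
                           file.path(output_dir, "epochs",
                                     paste0(pid, "_epochs.csv")))
      if (res$inclusion$included) {
        counts["included"] <- counts["included"] + 1L
        summaries[[pid]] <- res$summary
        log_rows[[pid]] <- data.frame(participant_id = pid,
                                      outcome = "included", reason = "")
      } else {
        counts["validity_excluded"] <- counts["validity_excluded"] + 1L
        reasons[res$inclusion$reason] <- reasons[res$inclusion$reason] + 1L
        log_rows[[pid]] <- data.frame(participant_id = pid,
                                      outcome = "validity_excluded",
                                      reason = res$inclusion$reason)
      }
      res$epochs <- NULL  # keep the result list small
    }
    results[[pid]] <- res
  }

  ledger <- structure(list(counts = counts, validity_reasons = reasons),
                      class = "flow_ledger")

  # wide per-participant summary
  if (length(summaries)) {
    wide <- do.call(rbind, lapply(summaries, function(s) {
      row <- data.frame(participant_id = s$participant_id,
                        n_valid_days = nrow(s$days),
                        enmo = s$overall["enmo"], mad = s$overall["mad"],
                        enmo_weekday = s$weekday["enmo"],
                        mad_weekday = s$weekday["mad"],
                        enmo_weekend = s$weekend["enmo"],
                        mad_weekend = s$weekend["mad"])
      for (v in names(s$mvpa)) row[[paste0("mvpa_", v)]] <- s$mvpa[[v]]
      row
    }))
    rownames(wide) <- NULL
    data.table::fwrite(signif_df(wide, 10),
                       file.path(output_dir, "participant_summary.csv"))
    l3 <- do.call(rbind, lapply(summaries, function(s)
      data.frame(participant_id = s$participant_id,
                 s$days[c("date", "weekday", "is_weekend", "wear_hours",
                          "mean_enmo", "mean_mad")])))
    data.table::fwrite(signif_df(l3, 10),
                       file.path(output_dir, "daily_summary.csv"))
    l4 <- do.call(rbind, lapply(summaries, function(s)
      data.frame(participant_id = s$participant_id, s$slots)))
    data.table::fwrite(signif_df(l4, 10),
                       file.path(output_dir, "slot_summary.csv"))
    subgroups <- if (!is.null(covariates))
      subgroup_report(summaries, covariates) else NULL
    if (!is.null(subgroups))
      data.table::fwrite(signif_df(subgroups, 10),
                         file.path(output_dir, "subgroup_report.csv"))
  } else {
    subgroups <- NULL
  }

  data.table::fwrite(do.call(rbind, log_rows[sort(names(log_rows))]),
                     file.path(output_dir, "processing_log.csv"))
  jsonlite::write_json(list(counts = as.list(counts),
                            validity_reasons = as.list(reasons)),
                       file.path(output_dir, "ledger.json"),
                       auto_unbox = TRUE)
  config_to_json(config, file.path(output_dir, "run_config.json"))

  invisible(list(ledger = ledger, summaries = summaries,
                 subgroups = subgroups, results = results))
}

# round numeric columns to a fixed number of significant digits so CSV
# output is byte-stable across runs and platforms
signif_df <- function(df, digits) {
  for (j in seq_along(df))
    if (is.double(df[[j]]) && is.null(attr(df[[j]], "class")))
      df[[j]] <- signif(df[[j]], digits)
  df
}

#' @export
print.flow_ledger <- function(x, ...) {
  c0 <- x$counts
  cat(sprintf(paste0(
    "<flow_ledger> received %d = unprocessable %d + quality_excluded %d + ",
    "validity_excluded %d + included %d\n"),
    c0["received"], c0["unprocessable"], c0["quality_excluded"],
    c0["validity_excluded"], c0["included"]))
  if (c0["validity_excluded"] > 0)
    cat(sprintf("  validity reasons: weekend %d, weekday %d, cycle %d\n",
                x$validity_reasons["weekend"], x$validity_reasons["weekday"],
                x$validity_reasons["cycle"]))
  invisible(x)
}

#' Check that a flow ledger telescopes
#'
#' @param ledger a `flow_ledger`
#' @return `TRUE` if received equals the sum of the outcome counts
#' @export
ledger_telescopes <- function(ledger) {
  c0 <- ledger$counts
  unname(c0["received"] ==
           c0["unprocessable"] + c0["quality_excluded"] +
           c0["validity_excluded"] + c0["included"])
}
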