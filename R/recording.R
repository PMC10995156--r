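#' Raw triaxial recording container
#'
#' Bundles a triaxial acceleration signal (in g) with the metadata every
#' processing stage needs: start time (local civil clock), sampling rate,
#' device dynamic range and converter resolution. All timestamps are treated
#' as local civil time; internally they are stored as UTC `POSIXct` so that
#' clock arithmetic is free of timezone rules (the synthetic device has no
#' daylight-saving shifts; see `classify_days()` for how real shifted days
#' are handled downstream).
#'
#' @param data numeric matrix with n rows and 3 columns (x, y, z) in g
#' @param start start of the recording, `POSIXct` or ISO-8601 string
#' @param rate sampling rate in Hz
#' @param dynamic_range device half-range in g (6 or 8)
#' @param bits ADC resolution
#' @param participant_id identifier string
#' @param calibrated has a calibration correction been applied already?
#' @return an object of class `raw_recording`
#' @export
raw_recording <- function(data, start, rate, dynamic_range, bits = 12L,
                          participant_id = "unknown", calibrated = FALSE) {
  if (!is.matrix(data) || ncol(data) != 3L)
    stop("`data` must be an n x 3 matrix (axes x, y, z)")
  if (!is.numeric(rate) || rate <= 0) stop("`rate` must be > 0")
  if (!dynamic_range %in% c(6, 8))
    stop("`dynamic_range` must be 6 or 8 g")
  if (is.character(start))
    start <- as.POSIXct(start, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  if (is.na(start)) stop("unparseable start time")
  structure(
    list(participant_id = participant_id, start = start, rate = rate,
         dynamic_range = dynamic_range, bits = as.integer(bits),
         data = data, calibrated = calibrated),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  dur <- nrow(x$data) / x$rate
  cat(sprintf(
    "<raw_recording> %s: %.2f h @ %g Hz, +/-%g g (%d-bit)%s\n",
    x$participant_id, dur / 3600, x$rate, x$dynamic_range, x$bits,
    if (x$calibrated) ", calibrated" else ""))
  invisible(x)
}

#' @export
summary.raw_recording <- function(object, ...) {
  r <- sqrt(rowSums(object$data^2))
  cat(sprintf("samples: %d  duration: %.2f h  mean |a|: %.4f g\n",
              nrow(object$data), nrow(object$data) / object$rate / 3600,
              mean(r)))
  invisible(object)
}

#' Write a recording in the package's raw text dialect
#'
#' Plain comma-separated text: a short header (format tag, start time as
#' ISO-8601 local clock, rate in Hz, dynamic range in g, ADC bits) followed
#' by one row per sample with the three axes as signed integer ADC counts
#' (`g = count * 2 * range / 2^bits`). Integer counts preserve the
#' quantization grid exactly and keep files compact.
#'
#' @param rec a [raw_recording()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_recording <- function(rec, path) {
  step <- quantization_step(rec$dynamic_range, rec$bits)
  counts <- attr(rec$data, "adc_counts")  # set by the generator
  if (is.null(counts))
    counts <- list(x = as.integer(round(rec$data[, 1] / step)),
                   y = as.integer(round(rec$data[, 2] / step)),
                   z = as.integer(round(rec$data[, 3] / step)))
  if (max(abs(range(counts$x)), abs(range(counts$y)),
          abs(range(counts$z))) > 2^(rec$bits - 1))
    stop("samples exceed the stated dynamic range")
  header <- c(
    "# hipacc-raw v1",
    sprintf("# start: %s", format(rec$start, "%Y-%m-%dT%H:%M:%S")),
    sprintf("# rate_hz: %g", rec$rate),
    sprintf("# range_g: %g", rec$dynamic_range),
    sprintf("# bits: %d", rec$bits))
  con <- file(path, "w")
  writeLines(header, con)
  close(con)
  data.table::fwrite(data.table::data.table(
    x = counts$x, y = counts$y, z = counts$z),
    path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path file path
#' @param participant_id identifier; defaults to the file name stem
#' @return a [raw_recording()] with samples converted back to g
#' @export
read_recording <- function(path, participant_id = NULL) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("empty or missing recording file: ", path)
  header <- readLines(path, n = 5L)
  if (length(header) < 5L || header[1] != "# hipacc-raw v1")
    stop("not a hipacc raw file: ", path)
  field <- function(i, key) {
    m <- regmatches(header[i], regexec(paste0("^# ", key, ": (.+)$"), header[i]))[[1]]
    if (length(m) < 2) stop("malformed header line ", i, " in ", path)
    m[2]
  }
  start <- field(2, "start")
  rate <- as.numeric(field(3, "rate_hz"))
  rng <- as.numeric(field(4, "range_g"))
  bits <- as.integer(field(5, "bits"))
  dt <- data.table::fread(path, skip = 5L, header = TRUE,
                          colClasses = "integer", showProgress = FALSE)
  if (nrow(dt) == 0) stop("recording has no samples: ", path)
  step <- quantization_step(rng, bits)
  data <- .counts_to_g_cpp(dt$x, dt$y, dt$z, step)
  colnames(data) <- c("x", "y", "z")
  if (is.null(participant_id))
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  raw_recording(data, start, rate, rng, bits, participant_id)
}
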