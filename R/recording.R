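#' Subject metadata
#'
#' Metadata attached to a tongue biopotential recording: subject identifier,
#' PROP taster label (psychophysical phenotype), TAS2R38 diplotype, and the
#' labeled-magnitude-scale (LMS) bitterness rating.
#'
#' @param subject_id Character scalar.
#' @param taster_label One of `"NT"`, `"MT"`, `"ST"`, `"unknown"`.
#' @param diplotype One of `"PAV/PAV"`, `"PAV/AVI"`, `"AVI/AVI"`, `"unknown"`.
#' @param lms_rating Optional bitterness rating on the 0-100 LMS scale.
#' @return A list of class `prop_subject`.
#' @export
subject_meta <- function(subject_id = "unknown",
                         taster_label = "unknown",
                         diplotype = "unknown",
                         lms_rating = NA_real_) {
  taster_label <- as.character(taster_label)
  diplotype <- as.character(diplotype)
  if (!taster_label %in% c("NT", "MT", "ST", "unknown")) {
    stop("taster_label must be one of NT, MT, ST, unknown; got '",
         taster_label, "'", call. = FALSE)
  }
  if (!diplotype %in% c("PAV/PAV", "PAV/AVI", "AVI/AVI", "unknown")) {
    stop("diplotype must be one of PAV/PAV, PAV/AVI, AVI/AVI, unknown; got '",
         diplotype, "'", call. = FALSE)
  }
  lms_rating <- as.numeric(lms_rating)
  if (!is.na(lms_rating) && (lms_rating < 0 || lms_rating > 100)) {
    stop("lms_rating must lie in [0, 100]", call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id),
                 taster_label = taster_label,
                 diplotype = diplotype,
                 lms_rating = lms_rating),
            class = "prop_subject")
}

#' Annotated biopotential recording
#'
#' A single-channel differential tongue biopotential trace in millivolt, with
#' the stimulus application/removal annotations needed by the processing
#' pipeline. The pre-stimulus baseline must be at least 5 s long because the
#' analysis window extends 5 s before the stimulus.
#'
#' @param samples Numeric vector of voltage samples (mV).
#' @param fs Sampling rate in Hz (default 2048).
#' @param t_stim_on Stimulus application time, seconds from recording start.
#' @param t_stim_off Stimulus removal time, seconds from recording start.
#' @param subject Optional [subject_meta()] object.
#' @return A list of class `prop_recording` with the fields above.
#' @export
recording <- function(samples, fs = 2048, t_stim_on, t_stim_off,
                      subject = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("samples must be non-empty", call. = FALSE)
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  duration <- length(samples) / fs
  if (!is.finite(t_stim_on) || !is.finite(t_stim_off)) {
    stop("stimulus annotations must be finite", call. = FALSE)
  }
  if (!(0 < t_stim_on && t_stim_on < t_stim_off && t_stim_off <= duration + 1 / fs)) {
    stop("annotations must satisfy 0 < t_stim_on < t_stim_off <= duration",
         call. = FALSE)
  }
  if (t_stim_on < 5) {
    stop("t_stim_on must be >= 5 s (a 5 s pre-stimulus baseline is required); got ",
         t_stim_on, " s", call. = FALSE)
  }
  if (!is.null(subject) && !inherits(subject, "prop_subject")) {
    subject <- do.call(subject_meta, as.list(subject))
  }
  structure(list(samples = samples, fs = fs,
                 t_stim_on = t_stim_on, t_stim_off = t_stim_off,
                 subject = subject),
            class = "prop_recording")
}

#' @export
print.prop_recording <- function(x, ...) {
  cat(sprintf("Tongue biopotential recording: %.1f s at %g Hz (%d samples)\n",
              length(x$samples) / x$fs, x$fs, length(x$samples)))
  cat(sprintf("  stimulus on at %.3f s, off at %.3f s\n",
              x$t_stim_on, x$t_stim_off))
  if (!is.null(x$subject)) {
    cat(sprintf("  subject %s: taster %s, diplotype %s\n",
                x$subject$subject_id, x$subject$taster_label,
                x$subject$diplotype))
  }
  invisible(x)
}

.header_keys <- c("fs_hz", "duration_s", "t_stim_on_s", "t_stim_off_s",
                  "subject_id", "taster_label", "diplotype", "lms_rating")
.required_keys <- c("fs_hz", "duration_s", "t_stim_on_s", "t_stim_off_s")

#' Write a recording to the text interchange format
#'
#' The interchange file is UTF-8 text: a `key: value` header (sampling rate,
#' duration, annotation times, subject fields), a blank line, then one voltage
#' sample per line in mV. Values are written with enough digits that a
#' round-trip through [read_recording()] loses less than 1e-9 mV.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "prop_recording"))
  sub <- rec$subject
  if (is.null(sub)) sub <- subject_meta()
  hdr <- c(
    sprintf("fs_hz: %.15g", rec$fs),
    sprintf("duration_s: %.15g", length(rec$samples) / rec$fs),
    sprintf("t_stim_on_s: %.15g", rec$t_stim_on),
    sprintf("t_stim_off_s: %.15g", rec$t_stim_off),
    sprintf("subject_id: %s", sub$subject_id),
    sprintf("taster_label: %s", sub$taster_label),
    sprintf("diplotype: %s", sub$diplotype)
  )
  if (!is.na(sub$lms_rating)) {
    hdr <- c(hdr, sprintf("lms_rating: %.15g", sub$lms_rating))
  }
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing: ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(c(hdr, ""), con)
  writeLines(sprintf("%.15g", rec$samples), con)
  invisible(path)
}

#' Read a recording from the text interchange format
#'
#' Parses the `key: value` header and the sample block written by
#' [write_recording()], validates the annotations against the recording
#' invariants (in particular `t_stim_on >= 5` s), and checks that the sample
#' count matches the declared duration within one sample.
#'
#' @param path File path.
#' @return A [recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  blank <- which(lines == "")[1]
  if (is.na(blank)) stop("format error in '", path,
                         "': missing blank line after header", call. = FALSE)
  hdr_lines <- lines[seq_len(blank - 1L)]
  m <- regmatches(hdr_lines, regexec("^([A-Za-z_]+):[ ]*(.*)$", hdr_lines))
  bad <- which(vapply(m, length, 1L) != 3L)
  if (length(bad)) stop("format error: unparseable header line '",
                        hdr_lines[bad[1]], "'", call. = FALSE)
  keys <- vapply(m, `[`, "", 2L)
  vals <- vapply(m, `[`, "", 3L)
  if (anyDuplicated(keys)) {
    stop("format error: duplicate header key '",
         keys[duplicated(keys)][1], "'", call. = FALSE)
  }
  unknown <- setdiff(keys, .header_keys)
  if (length(unknown)) {
    stop("format error: unknown header key '", unknown[1], "'", call. = FALSE)
  }
  missing <- setdiff(.required_keys, keys)
  if (length(missing)) {
    stop("format error: missing header key '", missing[1], "'", call. = FALSE)
  }
  h <- as.list(vals)
  names(h) <- keys
  fs <- as.numeric(h$fs_hz)
  duration <- as.numeric(h$duration_s)
  samples <- as.numeric(lines[(blank + 1L):length(lines)])
  if (anyNA(samples)) stop("format error: non-numeric sample line",
                           call. = FALSE)
  if (abs(length(samples) - duration * fs) > 1) {
    stop("format error: sample count ", length(samples),
         " does not match duration_s * fs_hz = ", duration * fs, call. = FALSE)
  }
  sub <- subject_meta(
    subject_id = if (is.null(h$subject_id)) "unknown" else h$subject_id,
    taster_label = if (is.null(h$taster_label)) "unknown" else h$taster_label,
    diplotype = if (is.null(h$diplotype)) "unknown" else h$diplotype,
    lms_rating = if (is.null(h$lms_rating)) NA_real_ else as.numeric(h$lms_rating)
  )
  recording(samples = samples, fs = fs,
            t_stim_on = as.numeric(h$t_stim_on_s),
            t_stim_off = as.numeric(h$t_stim_off_s),
            subject = sub)
}

#' Read a cohort metadata table
#'
#' @param path CSV with columns
#'   `subject_id,taster_label,diplotype,lms_rating,recording_path`.
#' @return A data frame with those columns.
#' @export
read_cohort_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "taster_label", "diplotype", "lms_rating",
            "recording_path")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("cohort metadata is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}
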