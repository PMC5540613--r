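#' Pipeline configuration
#'
#' Nested list of every tunable constant of the processing chain, with the
#' defaults of the automated system: 6 Hz / order-86 low-pass, 5 + 15 s
#' analysis window, decimation by 16, five-point central-difference
#' derivative, knee thresholds 2.1 mV/s and 0.8, post-trend slope threshold
#' 0.2 mV/s, end-flattening fraction 0.02, k = 10 neighbours and 20 x
#' 10-fold cross-validation.
#'
#' @param ... Named overrides, e.g. `knee = list(abs_threshold_mv_s = 3)`.
#'   Unknown keys are rejected.
#' @return Nested configuration list of class `prop_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    filter = list(order = 86, passband_hz = 6, stopband_hz = 50),
    segment = list(pre_s = 5, post_s = 15),
    decimation = list(factor = 16L),
    derivative = list(kernel = "central"),
    knee = list(abs_threshold_mv_s = 2.1, rel_fraction = 0.8,
                search_window_s = 6),
    trend = list(post_window_frac = 0.2, slope_threshold_mv_s = 0.2),
    fit = list(multistarts = 8, max_iter = 200, tol = 1e-12, seed = 1),
    end = list(theta = 0.02, variant = "flattening"),
    classification = list(knn_k = 10, svm_cost = 1, svm_gamma = 1,
                          svm_type = "C", nu = 0.5, folds = 10,
                          repeats = 20, standardize = TRUE),
    seed = 42,
    log_level = "info"
  )
  over <- list(...)
  structure(.merge_config(defaults, over, path = ""), class = "prop_config")
}

.merge_config <- function(base, over, path) {
  for (nm in names(over)) {
    full <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(base)) {
      stop("unknown configuration key '", full, "'", call. = FALSE)
    }
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], over[[nm]], full)
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file of overrides and merges it onto [pipeline_config()]'s
#' defaults; unknown keys are rejected with the offending key path.
#'
#' @param path YAML file.
#' @return A `prop_config`.
#' @export
read_pipeline_config <- function(path) {
  over <- yaml::read_yaml(path)
  if (is.null(over)) over <- list()
  do.call(pipeline_config, over)
}

#' Process one recording into a feature vector
#'
#' Filter, window, delineate and extract features for one recording; the
#' single-subject core of [run_pipeline()].
#'
#' @param rec A [recording()] (raw, unfiltered).
#' @param config A [pipeline_config()].
#' @return An [extract_features()] vector (with delineation attributes).
#' @export
process_recording <- function(rec, config = pipeline_config()) {
  taps <- design_lowpass(fs = rec$fs, order = config$filter$order,
                         passband_hz = config$filter$passband_hz,
                         stopband_hz = config$filter$stopband_hz)
  filt <- recording(lowpass_filter(rec$samples, fs = rec$fs, taps = taps),
                    fs = rec$fs, t_stim_on = rec$t_stim_on,
                    t_stim_off = rec$t_stim_off, subject = rec$subject)
  seg <- extract_segment(filt, pre_s = config$segment$pre_s,
                         post_s = config$segment$post_s)
  res <- delineate(seg, config)
  extract_features(res)
}

#' Run the full feature-extraction pipeline over a cohort
#'
#' Processes each recording (file path or in-memory [recording()]) through
#' filtering, delineation and feature extraction. A failure in any stage
#' skips that recording with a stage-labelled warning; the run continues and
#' errors only if no recording succeeds.
#'
#' @param recordings Character vector of interchange file paths, or a list
#'   of [recording()] objects.
#' @param config A [pipeline_config()].
#' @param metadata Optional metadata data frame (see
#'   [read_cohort_metadata()]); merged into the output.
#' @param out_csv Optional path: the feature table is also written as CSV.
#' @return Feature table data frame, one row per successful recording.
#' @export
run_pipeline <- function(recordings, config = pipeline_config(),
                         metadata = NULL, out_csv = NULL) {
  get_rec <- function(r) if (is.character(r)) read_recording(r) else r
  ids <- if (is.character(recordings)) {
    sub("\\.[^.]*$", "", basename(recordings))
  } else if (!is.null(names(recordings))) {
    names(recordings)
  } else {
    sprintf("rec%03d", seq_along(recordings))
  }
  out <- list()
  for (i in seq_along(recordings)) {
    fv <- tryCatch({
      rec <- get_rec(recordings[[i]])
      if (!is.null(rec$subject) && rec$subject$subject_id != "unknown") {
        ids[i] <- rec$subject$subject_id
      }
      process_recording(rec, config)
    }, error = function(e) {
      warning("recording '", ids[i], "' skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(fv)) out[[ids[i]]] <- fv
  }
  if (length(out) == 0) {
    stop("no recording could be processed", call. = FALSE)
  }
  tab <- feature_table(out, metadata = metadata)
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  tab
}
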