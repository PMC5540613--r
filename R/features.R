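#' Extract the seven waveform features
#'
#' Computes the seven morphological/dynamical features of the approximated
#' depolarization signal d-tilde and of the *feature signal* (the product of
#' the approximated signal with its first derivative), over the onset-end
#' interval:
#'
#' * `f1_area_dd` — area under the feature signal,
#'   `(d(t_end)^2 - d(t_onset)^2) / 2` in closed form (mV^2);
#' * `f2_delta_amp` — depolarization amplitude `d(t_onset) - d(t_end)` (mV);
#' * `f3_area_d` — area under the approximated signal, by the analytic
#'   antiderivative (mV s);
#' * `f4_dd_mean` — integral mean of the feature signal,
#'   `f1 / (t_end - t_onset)` (mV^2/s);
#' * `f5_delta_amp_2s` — amplitude 2 s after the onset,
#'   `d(t_onset) - d(t_onset + 2)` (mV; clipped to `t_end` and flagged if the
#'   depolarization ends sooner);
#' * `f6_max_dd` — maximum of the feature signal on the discrete 2048 Hz
#'   grid of the analytic signal (mV^2/s);
#' * `f7_t_half` — time from the onset at which the cumulative area of the
#'   feature signal reaches half its total, solved on the closed-form
#'   cumulative by [stats::uniroot()] to 1e-6 s.
#'
#' @param x A `prop_delineation` or a bare [fit_model()] (with its
#'   `t_onset`/`t_end` fiducials).
#' @param fs Grid rate for the discrete `f6` search (default 2048 Hz).
#' @return Named numeric vector of class `prop_features` with the seven
#'   features, and attributes `model_kind`, `t_onset`, `t_end`, `flags`.
#' @export
extract_features <- function(x, fs = 2048) {
  fit <- if (inherits(x, "prop_delineation")) x$fit else x
  stopifnot(inherits(fit, "prop_fitmodel"))
  t0 <- fit$t_onset
  t1 <- fit$t_end
  flags <- character(0)
  f_on <- eval_model(fit, t0)
  f_end <- eval_model(fit, t1)

  f1 <- (f_end^2 - f_on^2) / 2
  f2 <- f_on - f_end
  f3 <- eval_model_antideriv(fit, t1) - eval_model_antideriv(fit, t0)
  dt <- t1 - t0
  f4 <- if (dt > 0) f1 / dt else 0
  t5 <- t0 + 2
  if (t5 > t1) {
    t5 <- t1
    flags <- c(flags, "f5 evaluated at t_end (depolarization shorter than 2 s)")
  }
  f5 <- f_on - eval_model(fit, t5)
  if (dt > 0) {
    tt <- seq(t0, t1, by = 1 / fs)
    f6 <- max(eval_model(fit, tt) * eval_model_deriv(fit, tt))
  } else {
    f6 <- 0
  }
  # cumulative area of the feature signal is (f(t)^2 - f(t0)^2)/2
  if (dt > 0 && abs(f1) > 0) {
    g <- function(t) (eval_model(fit, t)^2 - f_on^2) / 2 - f1 / 2
    f7 <- tryCatch(stats::uniroot(g, lower = t0, upper = t1,
                                  tol = 1e-6)$root - t0,
                   error = function(e) {
                     flags <<- c(flags, "f7: cumulative not bracketed, set to t_end")
                     t1 - t0
                   })
  } else {
    f7 <- dt
    if (dt == 0) flags <- c(flags, "degenerate zero-width window")
  }
  structure(c(f1_area_dd = f1, f2_delta_amp = f2, f3_area_d = f3,
              f4_dd_mean = f4, f5_delta_amp_2s = f5, f6_max_dd = f6,
              f7_t_half = f7),
            model_kind = fit$kind, t_onset = t0, t_end = t1,
            rmse = fit$rmse, flags = flags,
            class = "prop_features")
}

#' @export
print.prop_features <- function(x, ...) {
  v <- unclass(x)
  attributes(v) <- list(names = names(unclass(x)))
  print(v)
  invisible(x)
}

#' The evaluated feature combinations
#'
#' Named list of feature-index subsets used in the classification tests:
#' Combo 1 = \{1,4\}, Combo 2 = \{1,2,4\}, Combo 3 = \{1,2,4,5\},
#' Combo 4 = \{1,4,5,6\}, Best 1 = \{1,2,3,4,5\}, Best 2 = \{1,2,4,5,6\},
#' All = \{1..7\}.
#'
#' @return Named list of integer vectors.
#' @export
feature_combos <- function() {
  list(combo1 = c(1L, 4L),
       combo2 = c(1L, 2L, 4L),
       combo3 = c(1L, 2L, 4L, 5L),
       combo4 = c(1L, 4L, 5L, 6L),
       best1 = 1:5,
       best2 = c(1L, 2L, 4L, 5L, 6L),
       all = 1:7)
}

.normalize_combo <- function(name) {
  key <- gsub("[ _]", "", tolower(name))
  combos <- feature_combos()
  if (!key %in% names(combos)) {
    stop("unknown feature combination '", name, "'; valid names: ",
         paste(names(combos), collapse = ", "), call. = FALSE)
  }
  combos[[key]]
}

#' Select a feature combination
#'
#' @param fv A [extract_features()] vector (or any numeric vector of the 7
#'   features in index order).
#' @param combo Combination name (`"combo1"` ... `"combo4"`, `"best1"`,
#'   `"best2"`, `"all"`; spaces/case ignored) or an integer vector of
#'   feature indices.
#' @return Numeric vector of the selected features in ascending index order.
#' @export
select_combo <- function(fv, combo) {
  idx <- if (is.character(combo)) .normalize_combo(combo) else
    sort(as.integer(combo))
  if (any(idx < 1 | idx > 7)) stop("feature indices must lie in 1..7",
                                   call. = FALSE)
  out <- unclass(fv)[idx]
  attributes(out) <- list(names = names(unclass(fv))[idx])
  out
}

#' Feature-vs-bitterness correlation table
#'
#' Plain linear (Pearson) correlation of each feature with the LMS
#' bitterness rating, with the two-sided p-value, as a reporting utility for
#' cohort feature tables.
#'
#' @param features Data frame with columns `f1_area_dd` ... `f7_t_half` and
#'   `lms_rating`.
#' @return Data frame: `feature`, `r`, `p_value`.
#' @export
feature_lms_correlation <- function(features) {
  fcols <- c("f1_area_dd", "f2_delta_amp", "f3_area_d", "f4_dd_mean",
             "f5_delta_amp_2s", "f6_max_dd", "f7_t_half")
  stopifnot(all(fcols %in% names(features)), "lms_rating" %in% names(features))
  res <- lapply(fcols, function(cn) {
    ct <- stats::cor.test(features[[cn]], features$lms_rating)
    data.frame(feature = cn, r = unname(ct$estimate),
               p_value = ct$p.value)
  })
  do.call(rbind, res)
}

#' Assemble a cohort feature table
#'
#' One row per subject: identifiers and labels, the seven features, the
#' selected model kind, the fiducials and the fit RMSE.
#'
#' @param feature_list Named list of [extract_features()] vectors (names =
#'   subject ids).
#' @param metadata Optional data frame with `subject_id`, `taster_label`,
#'   `diplotype`, `lms_rating` columns.
#' @return Data frame in the package's feature-table layout.
#' @export
feature_table <- function(feature_list, metadata = NULL) {
  rows <- lapply(names(feature_list), function(id) {
    fv <- feature_list[[id]]
    df <- as.data.frame(as.list(unclass(fv)))
    df$subject_id <- id
    df$model_kind <- attr(fv, "model_kind")
    df$t_onset <- attr(fv, "t_onset")
    df$t_end <- attr(fv, "t_end")
    df$rmse <- attr(fv, "rmse")
    df
  })
  tab <- do.call(rbind, rows)
  if (!is.null(metadata)) {
    tab <- merge(metadata[, intersect(names(metadata),
                                      c("subject_id", "taster_label",
                                        "diplotype", "lms_rating"))],
                 tab, by = "subject_id", sort = FALSE)
  }
  tab
}
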