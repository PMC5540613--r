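#' Baseline/post-depolarization trend estimation
#'
#' Ordinary least-squares lines over the pre-knee baseline and over the tail
#' of the post-stimulus window (the final `post_window_frac` of the segment,
#' standing in for the post-removal tract when only the 20 s analysis frame
#' is available). The detrending branch follows the slope rule: if the
#' baseline slope is non-positive and the post slope is below
#' `slope_threshold` (0.2 mV/s), only an offset correction is applied;
#' otherwise the baseline trend is subtracted from the entire segment.
#'
#' @param seg A [segment()] (128 Hz design point).
#' @param knee A `prop_knee` from [find_knee()].
#' @param post_window_frac Fraction of the segment used for the post trend
#'   (default 0.2, i.e. the final 3 s of the 15 s post window).
#' @param slope_threshold Post-slope threshold in mV/s (default 0.2).
#' @return A list of class `prop_trend`: `pre_slope`, `pre_intercept`,
#'   `post_slope`, `post_intercept` (time axis: seconds relative to
#'   stimulus), `branch`.
#' @export
estimate_trends <- function(seg, knee, post_window_frac = 0.2,
                            slope_threshold = 0.2) {
  stopifnot(inherits(seg, "prop_segment"))
  tt <- segment_time(seg)
  k <- knee$index
  if (k < 10) stop("insufficient baseline: knee at sample ", k,
                   " leaves fewer than 10 pre-knee samples", call. = FALSE)
  pre <- stats::lm.fit(cbind(1, tt[1:k]), seg$x[1:k])$coefficients
  n <- length(seg$x)
  j0 <- max(k + 1L, n - max(10L, round(post_window_frac * n)) + 1L)
  post <- stats::lm.fit(cbind(1, tt[j0:n]), seg$x[j0:n])$coefficients
  branch <- if (pre[2] <= 0 && post[2] < slope_threshold) {
    "offset_only"
  } else {
    "subtract_pre_trend"
  }
  structure(list(pre_slope = unname(pre[2]), pre_intercept = unname(pre[1]),
                 post_slope = unname(post[2]),
                 post_intercept = unname(post[1]), branch = branch),
            class = "prop_trend")
}

#' Detrend a segment at the knee
#'
#' `offset_only`: subtract the signal value at the knee, so 0 mV is achieved
#' at the knee point. `subtract_pre_trend`: subtract the fitted baseline line
#' from the entire segment.
#'
#' @param seg A [segment()].
#' @param trends A `prop_trend` from [estimate_trends()].
#' @param knee A `prop_knee`.
#' @return Numeric detrended signal `d` (mV), same length as the segment.
#' @export
detrend <- function(seg, trends, knee) {
  stopifnot(inherits(seg, "prop_segment"), inherits(trends, "prop_trend"))
  if (trends$branch == "offset_only") {
    seg$x - seg$x[knee$index]
  } else {
    tt <- segment_time(seg)
    seg$x - (trends$pre_intercept + trends$pre_slope * tt)
  }
}

#' Refine the knee on the upsampled grid
#'
#' After upsampling to 2048 Hz the baseline is replaced by a 0 mV line and
#' the onset is taken where the model curve crosses zero: the first sample at
#' which the analytic curve turns negative, scanning forward (one-sample
#' resolution, 0.488 ms). The continuous root of the model is also solved
#' (to 1e-10 s) and stored so that the analytic feature identities hold
#' exactly. If the curve never crosses zero the coarse knee is mapped to the
#' fine grid and flagged.
#'
#' @param fit A [fit_model()] in the local time coordinate (0 = coarse knee).
#' @param fs Fine rate in Hz (2048).
#' @param t_back How far before the coarse knee to extend the scan (s).
#' @param t_forward End of the scan, seconds after the coarse knee.
#' @return List: `t_onset` (continuous root, local time), `n_offset` (signed
#'   sample offset of the fiducial from the coarse knee at `fs`),
#'   `fallback` (logical).
#' @export
refine_knee <- function(fit, fs = 2048, t_back = 2, t_forward = 15) {
  tt <- seq(-t_back, t_forward, by = 1 / fs)
  v <- eval_model(fit, tt)
  neg <- v < 0
  cross <- which(!neg[-length(neg)] & neg[-1])   # sign change + to -
  if (length(cross) == 0) {
    if (all(neg)) {
      # already negative at scan start: no crossing from above
      return(list(t_onset = 0, n_offset = 0L, fallback = TRUE))
    }
    return(list(t_onset = 0, n_offset = 0L, fallback = TRUE))
  }
  i <- cross[1] + 1L                              # first negative sample
  root <- tryCatch(
    stats::uniroot(function(t) eval_model(fit, t),
                   lower = tt[i - 1L], upper = tt[i], tol = 1e-10)$root,
    error = function(e) tt[i])
  list(t_onset = root, n_offset = as.integer(round(tt[i] * fs)),
       fallback = FALSE)
}

#' Choose between the exponential-sum and rational fits
#'
#' Computes the RMSE of each candidate against the detrended signal from the
#' refined knee onward and returns the model with the smaller error; ties go
#' to the exponential sum.
#'
#' @param fit_e,fit_r Candidate [fit_model()]s (either may be flagged
#'   non-converged).
#' @param t Local times of the comparison samples (s).
#' @param d Detrended signal values at `t` (mV).
#' @return List: `fit` (winner, `rmse` updated), `alt_rmse` (loser's RMSE,
#'   NA if it failed), `kind`.
#' @export
select_model <- function(fit_e, fit_r, t, d) {
  ok_e <- !is.null(fit_e) && fit_e$converged
  ok_r <- !is.null(fit_r) && fit_r$converged
  if (!ok_e && !ok_r) stop("both regression models failed to converge",
                           call. = FALSE)
  rm_e <- if (ok_e) .rmse(d - eval_model(fit_e, t)) else Inf
  rm_r <- if (ok_r) .rmse(d - eval_model(fit_r, t)) else Inf
  if (rm_e <= rm_r) {
    fit_e$rmse <- rm_e
    list(fit = fit_e, alt_rmse = if (ok_r) rm_r else NA_real_,
         kind = "exp_sum")
  } else {
    fit_r$rmse <- rm_r
    list(fit = fit_r, alt_rmse = if (ok_e) rm_e else NA_real_,
         kind = "rational")
  }
}

#' Detect the depolarization end
#'
#' Evaluates the analytic derivative of the fitted model on the 2048 Hz grid
#' from the onset to `t_max`. The end is the first instant after the
#' derivative-magnitude peak at which the derivative has flattened to within
#' `theta * max|f'|` of zero (`f' >= -theta * max|f'|`); if that never
#' happens within the window (very slow depolarizations), the end falls back
#' to `t_max`, i.e. 15 s after the stimulus application. The `"printed"`
#' variant instead requires `f' >= +theta * max|f'|`.
#'
#' @param fit A [fit_model()].
#' @param theta Flattening fraction (default 0.02).
#' @param t_onset Onset time (local coordinate, s).
#' @param t_max Window end (local coordinate, s).
#' @param fs Evaluation rate (default 2048).
#' @param variant `"flattening"` (default) or `"printed"`.
#' @return List: `t_end` (s), `fallback` (logical, TRUE if the 15 s rule
#'   fired).
#' @export
detect_end <- function(fit, theta = 0.02, t_onset = fit$t_onset,
                       t_max = t_onset + 15, fs = 2048,
                       variant = c("flattening", "printed")) {
  variant <- match.arg(variant)
  tt <- seq(t_onset, t_max, by = 1 / fs)
  dv <- eval_model_deriv(fit, tt)
  m <- max(abs(dv))
  if (m == 0) return(list(t_end = t_max, fallback = TRUE))
  if (variant == "printed") {
    idx <- which(dv >= theta * m)
    if (length(idx) == 0) return(list(t_end = t_max, fallback = TRUE))
    return(list(t_end = tt[idx[1]], fallback = FALSE))
  }
  ipk <- which.max(abs(dv))
  rest <- dv[ipk:length(dv)]
  idx <- which(rest >= -theta * m)
  if (length(idx) == 0) return(list(t_end = t_max, fallback = TRUE))
  list(t_end = tt[ipk + idx[1] - 1L], fallback = FALSE)
}

#' Delineate a depolarization waveform
#'
#' Full automatic delineation of a filtered 2048 Hz analysis segment:
#' decimation to 128 Hz, knee detection on the derivative's moving SD,
#' trend estimation and detrending, coarse fits of the exponential-sum and
#' rational models between the knee and 15 s after the stimulus, upsampling
#' back to 2048 Hz, knee refinement at the model's zero crossing, model
#' selection by RMSE, end detection on the analytic derivative, and a final
#' refit of the selected model restricted to the depolarization interval
#' `[n_k, n_end]`.
#'
#' @param seg A [segment()] at 2048 Hz (already low-pass filtered), from
#'   [extract_segment()].
#' @param config A [pipeline_config()] (or any sub-list of overrides).
#' @return An object of class `prop_delineation`: the detrended upsampled
#'   signal `d`, selected `fit` (a [fit_model()] in local time, origin at the
#'   coarse knee), fine-grid fiducials `n_k` and `n_end` (1-based indices
#'   into the segment), `alt_rmse`, coarse `knee`, `trends`, `flags`.
#' @export
delineate <- function(seg, config = pipeline_config()) {
  stopifnot(inherits(seg, "prop_segment"))
  cfg <- config
  flags <- character(0)

  seg128 <- decimate16(seg, factor = cfg$decimation$factor)
  knee <- find_knee(seg128,
                    abs_thresh = cfg$knee$abs_threshold_mv_s,
                    rel_frac = cfg$knee$rel_fraction,
                    search_window_s = cfg$knee$search_window_s,
                    kernel = cfg$derivative$kernel)
  trends <- estimate_trends(seg128, knee,
                            post_window_frac = cfg$trend$post_window_frac,
                            slope_threshold = cfg$trend$slope_threshold_mv_s)
  d128 <- detrend(seg128, trends, knee)

  # coarse fit window: knee to 15 s after the stimulus application
  fs128 <- seg128$fs
  k <- knee$index
  n128 <- length(d128)
  tloc128 <- (seq_len(n128) - k) / fs128        # local time, 0 at coarse knee
  win <- k:min(n128, k + round(15 * fs128))     # knee to 15 s after the knee
  fit_e <- tryCatch(
    fit_exp_sum(tloc128[win], d128[win], multistarts = cfg$fit$multistarts,
                seed = cfg$fit$seed, max_iter = cfg$fit$max_iter,
                tol = cfg$fit$tol),
    error = function(e) { flags <<- c(flags, paste0("exp_sum: ",
                                                    conditionMessage(e))); NULL })
  fit_r <- tryCatch(
    fit_rational(tloc128[win], d128[win]),
    error = function(e) { flags <<- c(flags, paste0("rational: ",
                                                    conditionMessage(e))); NULL })
  if (is.null(fit_e) && is.null(fit_r)) {
    stop("delineation failed at stage 'coarse fit': ",
         paste(flags, collapse = "; "), call. = FALSE)
  }

  # upsample the detrended signal back to 2048 Hz
  d_up <- upsample16(d128, factor = cfg$decimation$factor)
  fs_up <- seg$fs
  k_up <- (k - 1L) * cfg$decimation$factor + 1L  # coarse knee on fine grid
  tloc_up <- (seq_along(d_up) - k_up) / fs_up

  # refine the knee using the better coarse candidate
  pick0 <- select_model(fit_e, fit_r, tloc128[win], d128[win])
  t_back <- min(2, (k_up - 1L) / fs_up)
  ref <- refine_knee(pick0$fit, fs = fs_up, t_back = t_back,
                     t_forward = max(tloc_up))
  if (ref$fallback) flags <- c(flags, "knee refinement fell back to the coarse knee")
  n_k <- k_up + ref$n_offset
  n_k <- max(1L, min(n_k, length(d_up) - 1L))

  # select by RMSE from n_k to the end of the coarse window
  sel_idx <- n_k:min(length(d_up), k_up + round(15 * fs_up))
  sel <- select_model(fit_e, fit_r, tloc_up[sel_idx], d_up[sel_idx])
  fit <- sel$fit
  fit$t_onset <- ref$t_onset

  # depolarization end on the analytic derivative
  t_stim_end <- max(tloc_up)                     # 15 s after stimulus
  end <- detect_end(fit, theta = cfg$end$theta, t_onset = ref$t_onset,
                    t_max = t_stim_end, fs = fs_up,
                    variant = cfg$end$variant)
  if (end$fallback) flags <- c(flags, "end detection fell back to the 15 s rule")
  n_end <- k_up + as.integer(round(end$t_end * fs_up))
  n_end <- max(n_k + 1L, min(n_end, length(d_up)))

  # finer refit restricted to [n_k, n_end]
  idx <- n_k:n_end
  coarse_rmse_win <- .rmse(d_up[idx] - eval_model(fit, tloc_up[idx]))
  refit <- tryCatch({
    if (fit$kind == "exp_sum") {
      f <- fit_exp_sum(tloc_up[idx], d_up[idx],
                       multistarts = max(2, cfg$fit$multistarts %/% 2),
                       seed = cfg$fit$seed, max_iter = cfg$fit$max_iter,
                       tol = cfg$fit$tol)
    } else {
      f <- fit_rational(tloc_up[idx], d_up[idx])
    }
    f
  }, error = function(e) NULL)
  if (!is.null(refit) && refit$converged &&
      .rmse(d_up[idx] - eval_model(refit, tloc_up[idx])) <= coarse_rmse_win) {
    fit <- refit
  }
  fit$rmse <- .rmse(d_up[idx] - eval_model(fit, tloc_up[idx]))

  # re-solve the onset root of the (possibly refitted) model near t = 0
  root <- tryCatch({
    lo <- ref$t_onset - 0.1; hi <- ref$t_onset + 0.1
    if (eval_model(fit, lo) > 0 && eval_model(fit, hi) < 0) {
      stats::uniroot(function(t) eval_model(fit, t), lower = lo, upper = hi,
                     tol = 1e-10)$root
    } else ref$t_onset
  }, error = function(e) ref$t_onset)
  fit$t_onset <- root
  fit$t_end <- min(end$t_end, root + 15)

  structure(list(segment = seg, d = d_up, fs = fs_up,
                 n_k = n_k, n_end = n_end, k_up = k_up,
                 knee_time = knee$time,
                 t_onset_segment = knee$time + root,
                 t_end_segment = knee$time + fit$t_end,
                 fit = fit, alt_rmse = sel$alt_rmse,
                 knee = knee, trends = trends, flags = flags),
            class = "prop_delineation")
}

#' @export
print.prop_delineation <- function(x, ...) {
  cat("Depolarization delineation\n")
  cat(sprintf("  model: %s (rmse %.4g mV; rejected model rmse %.4g mV)\n",
              x$fit$kind, x$fit$rmse, x$alt_rmse))
  cat(sprintf("  onset %.4f s, end %.4f s after stimulus (knee rule: %s)\n",
              x$t_onset_segment, x$t_end_segment, x$knee$rule_used))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.prop_delineation <- function(object, ...) {
  fv <- extract_features(object)
  out <- list(delineation = object, features = fv)
  class(out) <- "summary.prop_delineation"
  out
}

#' @export
print.summary.prop_delineation <- function(x, ...) {
  print(x$delineation)
  cat("  features:\n")
  fv <- unclass(x$features)
  for (nm in names(fv)) cat(sprintf("    %-14s %12.5g\n", nm, fv[[nm]]))
  invisible(x)
}

#' @export
coef.prop_delineation <- function(object, ...) object$fit$params

#' Approximated (baseline-replaced) signal of a delineation
#'
#' Evaluates the analytic approximated signal: 0 mV up to the onset, the
#' fitted model curve between onset and end, and the model's end value
#' afterwards (plateau).
#'
#' @param object A `prop_delineation`.
#' @param t Times in seconds relative to stimulus application; defaults to
#'   the segment's fine grid.
#' @param ... Unused.
#' @return Numeric vector of d-tilde values (mV).
#' @export
predict.prop_delineation <- function(object, t = NULL, ...) {
  if (is.null(t)) t <- segment_time(object$segment)
  tau <- t - object$knee_time                     # local model time
  out <- numeric(length(t))
  on <- object$fit$t_onset
  en <- object$fit$t_end
  mid <- tau >= on & tau <= en
  out[mid] <- eval_model(object$fit, tau[mid])
  out[tau > en] <- eval_model(object$fit, en)
  out
}

#' @export
fitted.prop_delineation <- function(object, ...) {
  predict(object, t = segment_time(object$segment))
}

#' @export
residuals.prop_delineation <- function(object, ...) {
  idx <- object$n_k:object$n_end
  tau <- (idx - object$k_up) / object$fs
  object$d[idx] - eval_model(object$fit, tau)
}

#' Plot a delineation
#'
#' Detrended signal with the fitted analytic curve and the onset/end
#' fiducials.
#'
#' @param x A `prop_delineation`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.prop_delineation <- function(x, ...) {
  tt <- segment_time(x$segment)
  graphics::plot(tt, x$d, type = "l", col = "grey60",
                 xlab = "time after stimulus (s)",
                 ylab = "detrended potential (mV)", ...)
  graphics::lines(tt, fitted(x), col = "red", lwd = 2)
  graphics::abline(v = c(x$t_onset_segment, x$t_end_segment),
                   lty = 2, col = "blue")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
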