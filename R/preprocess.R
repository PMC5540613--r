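#' Design the 6 Hz equiripple low-pass filter
#'
#' Linear-phase equiripple (Parks-McClellan) FIR low-pass of order 86
#' (87 taps) with a 6 Hz passband edge, used to remove mains interference and
#' other high-frequency noise from the slow depolarization waveform. The
#' stopband edge defaults to 50 Hz so the mains fundamental falls inside the
#' stopband. Taps are normalised to exact unit DC gain, so baseline offsets
#' in mV pass through unchanged.
#'
#' @param fs Sampling rate in Hz (default 2048; edges scale with `fs`).
#' @param order Filter order (taps = order + 1).
#' @param passband_hz Passband edge in Hz.
#' @param stopband_hz Stopband edge in Hz.
#' @return Numeric vector of `order + 1` filter coefficients.
#' @export
design_lowpass <- function(fs = 2048, order = 86, passband_hz = 6,
                           stopband_hz = 50) {
  nyq <- fs / 2
  if (!(passband_hz > 0 && passband_hz < stopband_hz && stopband_hz < nyq)) {
    stop("infeasible filter specification: need 0 < passband < stopband < fs/2",
         call. = FALSE)
  }
  h <- signal::remez(order, c(0, passband_hz / nyq, stopband_hz / nyq, 1),
                     c(1, 1, 0, 0))
  h / sum(h)
}

#' Zero-phase low-pass filtering
#'
#' Applies the FIR low-pass with group-delay compensation (the symmetric taps
#' are centred on each sample), so fiducial timings downstream are unbiased.
#' The signal is reflect-padded by one filter length at each end to suppress
#' start-up transients inside the 5 s baseline.
#'
#' @param x Numeric voltage vector (mV).
#' @param fs Sampling rate in Hz.
#' @param taps Optional filter coefficients; defaults to [design_lowpass()]
#'   at `fs`.
#' @return Filtered vector, same length as `x`.
#' @export
lowpass_filter <- function(x, fs = 2048, taps = NULL) {
  if (is.null(taps)) taps <- design_lowpass(fs = fs)
  L <- length(taps)
  n <- length(x)
  if (n <= 2 * L) {
    stop("input too short to filter: need more than ", 2 * L, " samples, got ",
         n, call. = FALSE)
  }
  xp <- c(x[(L + 1):2], x, x[(n - 1):(n - L)])
  yp <- stats::filter(xp, taps, method = "convolution", sides = 2)
  as.numeric(yp[(L + 1):(L + n)])
}

#' Analysis segment around the stimulus
#'
#' @param x Voltage samples (mV).
#' @param fs Rate in Hz.
#' @param t0 Time of the first sample relative to stimulus application (s).
#' @param stim_index 1-based index of the stimulus-application sample.
#' @return A list of class `prop_segment`.
#' @export
segment <- function(x, fs, t0, stim_index) {
  structure(list(x = as.numeric(x), fs = fs, t0 = t0,
                 stim_index = as.integer(stim_index)),
            class = "prop_segment")
}

#' Time axis of a segment
#'
#' @param seg A `prop_segment`.
#' @return Times of all samples, seconds relative to stimulus application.
#' @export
segment_time <- function(seg) {
  seg$t0 + (seq_along(seg$x) - 1) / seg$fs
}

#' @export
print.prop_segment <- function(x, ...) {
  cat(sprintf("Analysis segment: %d samples at %g Hz, t in [%.3f, %.3f] s (stimulus at 0)\n",
              length(x$x), x$fs, x$t0,
              x$t0 + (length(x$x) - 1) / x$fs))
  invisible(x)
}

#' Extract the 20 s analysis window
#'
#' Cuts the window from 5 s before to 15 s after the stimulus application
#' annotation (half-open, `pre_s + post_s` seconds total).
#'
#' @param rec A [recording()] (already low-pass filtered).
#' @param pre_s Seconds of baseline before the stimulus (default 5).
#' @param post_s Seconds after the stimulus (default 15).
#' @return A [segment()] whose `stim_index` sample sits at t = 0.
#' @export
extract_segment <- function(rec, pre_s = 5, post_s = 15) {
  stopifnot(inherits(rec, "prop_recording"))
  fs <- rec$fs
  i0 <- round((rec$t_stim_on - pre_s) * fs)     # 0-based start sample
  n <- round((pre_s + post_s) * fs)
  if (i0 < 0) stop("recording starts less than ", pre_s,
                   " s before the stimulus", call. = FALSE)
  if (i0 + n > length(rec$samples)) {
    stop("recording ends less than ", post_s,
         " s after the stimulus application", call. = FALSE)
  }
  segment(rec$samples[(i0 + 1):(i0 + n)], fs = fs, t0 = -pre_s,
          stim_index = round(pre_s * fs) + 1L)
}

#' Decimate a segment by 16 (2048 -> 128 Hz)
#'
#' Exact sample selection: every 16th sample is retained, with no
#' interpolation. The input must already be low-passed well below the new
#' Nyquist rate (the 6 Hz filter guarantees this), so no further anti-alias
#' filter is applied.
#'
#' @param seg A [segment()] at a rate divisible by 16.
#' @param factor Decimation factor (default 16).
#' @return A [segment()] at `fs / factor`.
#' @export
decimate16 <- function(seg, factor = 16L) {
  stopifnot(inherits(seg, "prop_segment"))
  factor <- as.integer(factor)
  if (seg$fs %% factor != 0) {
    stop("sampling rate ", seg$fs, " is not divisible by the decimation factor ",
         factor, call. = FALSE)
  }
  keep <- seq(1L, length(seg$x), by = factor)
  segment(seg$x[keep], fs = seg$fs / factor, t0 = seg$t0,
          stim_index = (seg$stim_index - 1L) %/% factor + 1L)
}

#' Upsample a sequence by 16 (128 -> 2048 Hz)
#'
#' Band-limited interpolation by zero-stuffing followed by a windowed-sinc
#' low-pass (Hamming window, 12 input samples half-width), reflect-padded at
#' the edges. Each polyphase branch is normalised to unit sum, so constant
#' signals are reproduced exactly and original samples are preserved.
#'
#' @param x Numeric vector at the low rate.
#' @param factor Upsampling factor (default 16).
#' @return Numeric vector of length `factor * length(x)`.
#' @export
upsample16 <- function(x, factor = 16L) {
  factor <- as.integer(factor)
  n <- length(x)
  if (n < 32) stop("input too short to upsample: need at least 32 samples, got ",
                   n, call. = FALSE)
  half <- 12L                       # kernel half-width in input samples
  tt <- seq(-half * factor, half * factor)
  h <- ifelse(tt == 0, 1, sin(pi * tt / factor) / (pi * tt / factor))
  h <- h * (0.54 + 0.46 * cos(pi * tt / (half * factor)))
  # normalise each polyphase branch so every output phase has unit DC gain
  ph <- ((tt %% factor) + factor) %% factor
  for (p in unique(ph)) h[ph == p] <- h[ph == p] / sum(h[ph == p])
  z <- numeric(n * factor)
  z[seq(1L, by = factor, length.out = n)] <- x
  # reflect-pad in the original (non-zero-stuffed) domain
  leftpad <- numeric(half * factor)
  leftpad[seq(1L, by = factor, length.out = half)] <- x[(half + 1):2]
  rightpad <- numeric(half * factor)
  rightpad[seq(1L, by = factor, length.out = half)] <- x[(n - 1):(n - half)]
  zp <- c(leftpad, z, rightpad)
  yp <- stats::filter(zp, h, method = "convolution", sides = 2)
  as.numeric(yp[(half * factor + 1):(half * factor + n * factor)])
}
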