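#' First derivative by five-point central differences
#'
#' Interior samples use the five-point central-difference kernel
#' `(x[n-2] - 8 x[n-1] + 8 x[n+1] - x[n+2]) * fs / 12` (exact on polynomials
#' up to degree 4). The first/last two samples fall back to one-sided or
#' two-point central differences and are excluded from `valid_range`, so the
#' knee search never relies on them. A `"printed"` kernel variant,
#' `fs/8 * (x[n-2] + x[n-1] + x[n+1] + x[n+2])`, is selectable for
#' comparison with the non-differencing transfer-function form.
#'
#' @param x Numeric vector (mV).
#' @param fs Sampling rate in Hz.
#' @param kernel `"central"` (default) or `"printed"`.
#' @return A list of class `prop_deriv`: `xdot` (mV/s, same length as `x`),
#'   `fs`, and `valid_range` (indices where the 5-point stencil is supported).
#' @export
derivative5 <- function(x, fs, kernel = c("central", "printed")) {
  kernel <- match.arg(kernel)
  n <- length(x)
  if (n < 5) stop("need at least 5 samples for the five-point stencil, got ",
                  n, call. = FALSE)
  i <- 3:(n - 2)
  xdot <- numeric(n)
  if (kernel == "central") {
    xdot[i] <- (x[i - 2] - 8 * x[i - 1] + 8 * x[i + 1] - x[i + 2]) * fs / 12
  } else {
    xdot[i] <- (x[i - 2] + x[i - 1] + x[i + 1] + x[i + 2]) * fs / 8
  }
  # one-sided / short central fills at the edges (flagged via valid_range)
  xdot[1] <- (x[2] - x[1]) * fs
  xdot[2] <- (x[3] - x[1]) * fs / 2
  xdot[n - 1] <- (x[n] - x[n - 2]) * fs / 2
  xdot[n] <- (x[n] - x[n - 1]) * fs
  structure(list(xdot = xdot, fs = fs, valid_range = c(3L, n - 2L)),
            class = "prop_deriv")
}

#' Moving standard deviation of the derivative
#'
#' Sliding sample standard deviation with a two-sample window:
#' `s[k] = sd(xdot[k], xdot[k+1]) = |xdot[k+1] - xdot[k]| / sqrt(2)`.
#' Applied to the first 6 s of the derivative it yields the detection
#' signal for the knee search.
#'
#' @param xdot Numeric vector (mV/s) or a `prop_deriv`.
#' @param window Window length in samples (>= 2; default 2 uses the exact
#'   closed form).
#' @return Numeric vector of length `length(xdot) - window + 1`.
#' @export
moving_sd <- function(xdot, window = 2L) {
  if (inherits(xdot, "prop_deriv")) xdot <- xdot$xdot
  window <- as.integer(window)
  if (window < 2) stop("window must be at least 2 samples", call. = FALSE)
  n <- length(xdot)
  if (n < window) stop("input shorter than the window", call. = FALSE)
  if (window == 2L) {
    abs(diff(xdot)) / sqrt(2)
  } else {
    vapply(seq_len(n - window + 1L),
           function(k) stats::sd(xdot[k:(k + window - 1L)]), numeric(1))
  }
}

#' Detect the depolarization knee point
#'
#' Scans the detection signal `s` (moving SD of the derivative over the first
#' 6 s) for the earliest index exceeding the absolute threshold (2.1 mV/s by
#' default). If no sample qualifies, the relative rule fires instead: the
#' earliest index with `s >= rel_frac * max(s)`. The thresholds are
#' empirical defaults and are exposed as arguments.
#'
#' @param s Numeric detection signal (mV/s).
#' @param abs_thresh Absolute threshold in mV/s (default 2.1).
#' @param rel_frac Fraction of the maximum for the fallback rule (default 0.8).
#' @return A list: `index` (1-based into `s`), `rule_used`
#'   (`"absolute_threshold"` or `"relative_threshold"`).
#' @export
detect_knee <- function(s, abs_thresh = 2.1, rel_frac = 0.8) {
  if (length(s) == 0 || all(is.na(s))) {
    stop("detection signal is empty or all-NA", call. = FALSE)
  }
  idx <- which(s > abs_thresh)
  if (length(idx)) {
    return(list(index = idx[1], rule_used = "absolute_threshold"))
  }
  idx <- which(s >= rel_frac * max(s, na.rm = TRUE))
  list(index = idx[1], rule_used = "relative_threshold")
}

#' Locate the knee on a 128 Hz segment
#'
#' Convenience wrapper: differentiates the segment, restricts to the first
#' `search_window_s` seconds, computes the two-point moving SD and applies
#' [detect_knee()]. The returned time is relative to stimulus application.
#'
#' @param seg A [segment()] at 128 Hz (any rate works; 128 Hz is the design
#'   point).
#' @param abs_thresh,rel_frac Thresholds passed to [detect_knee()].
#' @param search_window_s Search window from the start of the segment
#'   (default 6 s: the 5 s baseline plus the first second after stimulus).
#' @param kernel Derivative kernel, see [derivative5()].
#' @return A list of class `prop_knee`: `index` (1-based into the segment),
#'   `time` (s relative to stimulus), `rule_used`.
#' @export
find_knee <- function(seg, abs_thresh = 2.1, rel_frac = 0.8,
                      search_window_s = 6, kernel = "central") {
  stopifnot(inherits(seg, "prop_segment"))
  nwin <- min(length(seg$x), round(search_window_s * seg$fs))
  d <- derivative5(seg$x[seq_len(nwin)], seg$fs, kernel = kernel)
  s <- moving_sd(d$xdot)
  # exclude edge samples where the stencil is one-sided
  s[seq_len(min(2L, length(s)))] <- 0
  k <- detect_knee(s, abs_thresh = abs_thresh, rel_frac = rel_frac)
  structure(list(index = k$index,
                 time = seg$t0 + (k$index - 1) / seg$fs,
                 rule_used = k$rule_used),
            class = "prop_knee")
}
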