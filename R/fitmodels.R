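#' Analytic waveform model
#'
#' Container for a fitted depolarization model: either a sum of exponentials
#' `f(t) = a e^(b t) + c e^(d t)` or a rational function
#' `f(t) = (p1 t^2 + p2 t + p3) / (t + q1)`, together with the onset/end
#' fiducials of the depolarization (in the model's time coordinate, seconds)
#' and the fit RMSE.
#'
#' @param kind `"exp_sum"` or `"rational"`.
#' @param params Named numeric vector: `a, b, c, d` (mV, 1/s, mV, 1/s) or
#'   `p1, p2, p3, q1` (mV/s, mV, mV s, s).
#' @param t_onset,t_end Depolarization onset and end, seconds.
#' @param rmse Root-mean-square residual in mV (NA until evaluated).
#' @param converged Logical fit-status flag.
#' @return A list of class `prop_fitmodel`.
#' @export
fit_model <- function(kind = c("exp_sum", "rational"), params,
                      t_onset = 0, t_end = 15, rmse = NA_real_,
                      converged = TRUE) {
  kind <- match.arg(kind)
  need <- if (kind == "exp_sum") c("a", "b", "c", "d") else
    c("p1", "p2", "p3", "q1")
  if (!all(need %in% names(params))) {
    stop("params must contain ", paste(need, collapse = ", "), call. = FALSE)
  }
  params <- params[need]
  if (!(t_onset < t_end || isTRUE(all.equal(t_onset, t_end)))) {
    stop("t_onset must not exceed t_end", call. = FALSE)
  }
  if (t_end > t_onset + 15 + 1e-9) {
    stop("t_end must lie within 15 s of t_onset", call. = FALSE)
  }
  if (kind == "rational") {
    q1 <- params[["q1"]]
    if (-q1 >= t_onset && -q1 <= t_end) {
      stop("rational model pole at t = ", -q1,
           " lies inside [t_onset, t_end]", call. = FALSE)
    }
  }
  structure(list(kind = kind, params = params, t_onset = t_onset,
                 t_end = t_end, rmse = rmse, converged = converged),
            class = "prop_fitmodel")
}

#' @export
print.prop_fitmodel <- function(x, ...) {
  cat(sprintf("%s model: %s\n",
              if (x$kind == "exp_sum") "Sum-of-exponentials" else "Rational",
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", ")))
  cat(sprintf("  onset %.4f s, end %.4f s, rmse %.4g mV%s\n", x$t_onset,
              x$t_end, x$rmse, if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
coef.prop_fitmodel <- function(object, ...) object$params

#' Evaluate a waveform model
#'
#' @param fit A [fit_model()].
#' @param t Times (s) in the model's coordinate.
#' @return `f(t)` in mV.
#' @export
eval_model <- function(fit, t) {
  p <- fit$params
  if (fit$kind == "exp_sum") {
    p[["a"]] * exp(p[["b"]] * t) + p[["c"]] * exp(p[["d"]] * t)
  } else {
    (p[["p1"]] * t^2 + p[["p2"]] * t + p[["p3"]]) / (t + p[["q1"]])
  }
}

#' Analytic first derivative of a waveform model
#'
#' Closed forms: `a b e^(bt) + c d e^(dt)` for the exponential sum and
#' `(p1 t^2 + 2 p1 q1 t + p2 q1 - p3) / (t + q1)^2` for the rational model.
#'
#' @inheritParams eval_model
#' @return `f'(t)` in mV/s.
#' @export
eval_model_deriv <- function(fit, t) {
  p <- fit$params
  if (fit$kind == "exp_sum") {
    p[["a"]] * p[["b"]] * exp(p[["b"]] * t) +
      p[["c"]] * p[["d"]] * exp(p[["d"]] * t)
  } else {
    (p[["p1"]] * t^2 + 2 * p[["p1"]] * p[["q1"]] * t +
       p[["p2"]] * p[["q1"]] - p[["p3"]]) / (t + p[["q1"]])^2
  }
}

#' Antiderivative of a waveform model
#'
#' For the exponential sum, `a/b e^(bt) + c/d e^(dt)` with the `b = 0`
#' (or `d = 0`) limit `a t` (`c t`). For the rational model, polynomial
#' division gives
#' `p1 t^2/2 + (p2 - p1 q1) t + (p3 - p2 q1 + p1 q1^2) log|t + q1|`,
#' valid because the pole is excluded from the evaluation window.
#'
#' @inheritParams eval_model
#' @return Antiderivative values (mV s), defined up to a constant.
#' @export
eval_model_antideriv <- function(fit, t) {
  p <- fit$params
  if (fit$kind == "exp_sum") {
    term <- function(amp, rate) {
      if (abs(rate) < 1e-12) amp * t else (amp / rate) * exp(rate * t)
    }
    term(p[["a"]], p[["b"]]) + term(p[["c"]], p[["d"]])
  } else {
    p1 <- p[["p1"]]; p2 <- p[["p2"]]; p3 <- p[["p3"]]; q1 <- p[["q1"]]
    p1 * t^2 / 2 + (p2 - p1 * q1) * t +
      (p3 - p2 * q1 + p1 * q1^2) * log(abs(t + q1))
  }
}

.rmse <- function(resid) sqrt(mean(resid^2))

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Fit the sum-of-exponentials model
#'
#' Nonlinear least squares (Levenberg-Marquardt) for
#' `f(t) = a e^(b t) + c e^(d t)`. Initialisation uses a two-timescale
#' heuristic: the plateau and a log-linear fit of the residual give one
#' fast decaying pair plus a near-constant pair; a small number of seeded
#' random multi-starts around the heuristic guards against local minima.
#'
#' @param t Times (s), typically starting at the knee.
#' @param y Detrended voltages (mV).
#' @param multistarts Number of extra randomised starts (default 8).
#' @param seed Seed for the multi-start jitter (default 1).
#' @param max_iter,tol Optimiser control.
#' @return A [fit_model()] of kind `"exp_sum"`; `converged = FALSE` flags
#'   total failure (the model is then excluded from selection).
#' @export
fit_exp_sum <- function(t, y, multistarts = 8, seed = 1,
                        max_iter = 200, tol = 1e-12) {
  if (length(t) < 50) stop("need at least 50 samples to fit, got ",
                           length(t), call. = FALSE)
  if (max(abs(y)) < 1e-12) {       # degenerate all-zero input
    return(fit_model("exp_sum", c(a = 0, b = -1, c = 0, d = 0),
                     t_onset = min(t), t_end = max(t), rmse = 0))
  }
  resid_fun <- function(p) {
    r <- y - (p[1] * exp(pmin(p[2] * t, 50)) + p[3] * exp(pmin(p[4] * t, 50)))
    r[!is.finite(r)] <- 1e6
    r
  }
  # heuristic start: plateau + single decaying exponential toward it
  tail_n <- max(5L, round(length(y) * 0.1))
  plateau <- mean(y[(length(y) - tail_n + 1):length(y)])
  r0 <- y - plateau
  amp0 <- r0[1]
  span <- max(t) - min(t)
  pos <- which(abs(r0) > max(abs(r0)) * 0.05 & sign(r0) == sign(amp0))
  b0 <- -2 / span
  if (length(pos) > 5 && abs(amp0) > 1e-9) {
    lf <- stats::lm.fit(cbind(1, t[pos] - t[1]), log(abs(r0[pos])))
    if (is.finite(lf$coefficients[2])) b0 <- min(lf$coefficients[2], -1e-3)
  }
  starts <- list(c(amp0, b0, plateau, 0),
                 c(amp0, b0 * 4, plateau, -0.01),
                 c(amp0 / 2, b0, amp0 / 2 + plateau, b0 / 10))
  jitters <- .with_seed(seed, replicate(multistarts, {
    c(amp0 * stats::runif(1, 0.3, 2),
      b0 * exp(stats::runif(1, -1.5, 1.5)),
      plateau * stats::runif(1, 0.5, 1.5),
      -exp(stats::runif(1, log(1e-3), log(2))))
  }, simplify = FALSE))
  best <- NULL
  for (p0 in c(starts, jitters)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ftol = tol, ptol = tol)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(resid_fun(fit$par)^2)
    if (is.null(best) || sse < best$sse) best <- list(par = fit$par, sse = sse)
  }
  if (is.null(best)) {
    return(fit_model("exp_sum", c(a = NA_real_, b = NA_real_,
                                  c = NA_real_, d = NA_real_),
                     t_onset = min(t), t_end = max(t), converged = FALSE))
  }
  p <- best$par
  fit_model("exp_sum", c(a = p[1], b = p[2], c = p[3], d = p[4]),
            t_onset = min(t), t_end = max(t),
            rmse = sqrt(best$sse / length(y)))
}

#' Fit the rational model
#'
#' Least squares for `f(t) = (p1 t^2 + p2 t + p3) / (t + q1)` with the pole
#' `-q1` constrained outside the fitting window. For fixed `q1` the numerator
#' is linear in `(p1, p2, p3)`, so the profile SSE over `q1` is minimised by
#' a log-spaced grid scan over both admissible pole branches followed by
#' golden-section refinement (`stats::optimize`).
#'
#' @inheritParams fit_exp_sum
#' @param margin Minimum distance of the pole from the window (s).
#' @return A [fit_model()] of kind `"rational"`.
#' @export
fit_rational <- function(t, y, margin = 0.01) {
  if (length(t) < 50) stop("need at least 50 samples to fit, got ",
                           length(t), call. = FALSE)
  tmin <- min(t); tmax <- max(t)
  solve_q <- function(q1) {
    den <- t + q1
    X <- cbind(t^2, t, 1) / den
    f <- stats::lm.fit(X, y)
    list(sse = sum(f$residuals^2), p = f$coefficients)
  }
  sse_q <- function(q1) solve_q(q1)$sse
  # admissible q1: pole -q1 < tmin - margin  (q1 > -tmin + margin)
  #            or  pole -q1 > tmax + margin  (q1 < -tmax - margin)
  grid_pos <- (-tmin + margin) + 10^seq(-2, 3.5, length.out = 45)
  grid_neg <- (-tmax - margin) - 10^seq(-2, 3.5, length.out = 30)
  grid <- c(grid_pos, grid_neg)
  sse <- vapply(grid, sse_q, numeric(1))
  sse[!is.finite(sse)] <- Inf
  i <- which.min(sse)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
  opt <- stats::optimize(sse_q, lower = lo, upper = hi, tol = 1e-10)
  q1 <- if (opt$objective < sse[i]) opt$minimum else grid[i]
  s <- solve_q(q1)
  p <- s$p
  fit_model("rational", c(p1 = unname(p[1]), p2 = unname(p[2]),
                          p3 = unname(p[3]), q1 = q1),
            t_onset = tmin, t_end = tmax,
            rmse = sqrt(s$sse / length(y)))
}
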