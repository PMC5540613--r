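#' Parameters of a synthetic recording
#'
#' Describes one synthetic tongue-biopotential recording: the taster class
#' it emulates, the depolarization amplitude and time constants, the onset
#' delay after the stimulus annotation, baseline drift, measurement noise,
#' mains interference, and movement artefacts.
#'
#' When `tau_fast == tau_slow` (the default draw), the clean depolarization
#' is a single exponential relaxation to `-delta_amp`, which lies exactly in
#' the fitted sum-of-exponentials family and therefore provides exact ground
#' truth for the delineation stage. When `tau_fast < tau_slow` a
#' two-timescale mixture (70% fast) is generated instead.
#'
#' @param taster_class `"NT"`, `"MT"` or `"ST"`.
#' @param delta_amp Depolarization amplitude in mV (> 0; the signal drops to
#'   `-delta_amp`).
#' @param tau_fast,tau_slow Time constants in s (`tau_fast <= tau_slow`).
#' @param onset_delay Seconds between the stimulus annotation and the true
#'   depolarization onset.
#' @param baseline_slope Linear drift in mV/s.
#' @param noise_sd Additive white Gaussian noise SD in mV.
#' @param mains_amp Amplitude of the 50 Hz mains component in mV.
#' @param artifact_spec List of `c(time, height, width)` raised-cosine bumps
#'   (time in s from recording start, height mV, width s).
#' @param seed Integer seed making the recording reproducible.
#' @return A list of class `prop_synth_params`.
#' @export
synth_params <- function(taster_class = "ST", delta_amp = 80, tau_fast = 1.5,
                         tau_slow = tau_fast, onset_delay = 0.2,
                         baseline_slope = 0, noise_sd = 0, mains_amp = 0,
                         artifact_spec = list(), seed = 1) {
  if (!taster_class %in% c("NT", "MT", "ST")) {
    stop("taster_class must be NT, MT or ST", call. = FALSE)
  }
  if (!is.finite(delta_amp) || delta_amp <= 0) {
    stop("delta_amp must be positive", call. = FALSE)
  }
  if (tau_fast <= 0 || tau_fast > tau_slow) {
    stop("need 0 < tau_fast <= tau_slow", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(taster_class = taster_class, delta_amp = delta_amp,
                 tau_fast = tau_fast, tau_slow = tau_slow,
                 onset_delay = onset_delay, baseline_slope = baseline_slope,
                 noise_sd = noise_sd, mains_amp = mains_amp,
                 artifact_spec = artifact_spec, seed = as.integer(seed)),
            class = "prop_synth_params")
}

#' Generate a synthetic annotated recording
#'
#' Produces a 95 s recording at 2048 Hz with the stimulus annotated at 30 s
#' and its removal at 45 s: a drifting baseline, an abrupt-to-slow negative
#' exponential depolarization starting `onset_delay` after the stimulus,
#' optional Gaussian noise, fixed-phase 50 Hz mains interference, and
#' raised-cosine movement artefacts. The returned recording carries a
#' `truth` attribute with the construction ground truth: the onset time, the
#' clean model parameters (local time origin at the onset), the analytic end
#' time under the 2% flattening rule, and the analytic feature values.
#'
#' @param params A [synth_params()].
#' @param duration_s,fs,t_stim_on,t_stim_off Recording geometry (defaults
#'   95 s, 2048 Hz, stimulus on at 30 s, off at 45 s).
#' @param subject Optional [subject_meta()] attached to the recording.
#' @return A [recording()] with attribute `truth`.
#' @export
synth_recording <- function(params, duration_s = 95, fs = 2048,
                            t_stim_on = 30, t_stim_off = 45,
                            subject = NULL) {
  stopifnot(inherits(params, "prop_synth_params"))
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  t_onset <- t_stim_on + params$onset_delay
  tau_f <- params$tau_fast; tau_s <- params$tau_slow
  da <- params$delta_amp
  if (tau_f == tau_s) {
    model <- fit_model("exp_sum",
                       c(a = da, b = -1 / tau_f, c = -da, d = 0),
                       t_onset = 0,
                       t_end = min(15 - params$onset_delay,
                                   tau_f * log(50)))
  } else {
    model <- NULL                  # two-timescale mix: no exact model truth
  }
  depol <- function(tl) {          # clean depolarization, local time tl >= 0
    if (tau_f == tau_s) {
      da * exp(-tl / tau_f) - da
    } else {
      w <- 0.7
      da * (w * exp(-tl / tau_f) + (1 - w) * exp(-tl / tau_s)) - da
    }
  }
  clean <- params$baseline_slope * t
  after <- t >= t_onset
  clean[after] <- clean[after] + depol(t[after] - t_onset)
  x <- clean
  if (params$mains_amp > 0) x <- x + params$mains_amp * sin(2 * pi * 50 * t)
  for (a in params$artifact_spec) {
    tc <- a[1]; h <- a[2]; wdt <- a[3]
    inb <- abs(t - tc) < wdt / 2
    x[inb] <- x[inb] + h / 2 * (1 + cos(2 * pi * (t[inb] - tc) / wdt))
  }
  if (params$noise_sd > 0) {
    x <- x + .with_seed(params$seed, {
      # baseline noise: smooth low-frequency electrode/tissue drift (cubic
      # spline through ~2 Hz Gaussian control points, SD = noise_sd) plus a
      # fixed 20 uV wideband instrumental floor; surface-electrode baselines
      # are drift-dominated, with broadband amplifier noise at the uV level
      ct <- seq(-0.5, duration_s + 0.5, by = 0.5)
      drift <- stats::spline(ct, stats::rnorm(length(ct)), xout = t)$y
      drift <- drift / stats::sd(drift) * params$noise_sd
      drift + stats::rnorm(n, 0, 0.02)
    })
  }
  rec <- recording(x, fs = fs, t_stim_on = t_stim_on,
                   t_stim_off = t_stim_off, subject = subject)
  truth <- list(params = params,
                onset_time = params$onset_delay,   # s after stimulus
                model = model)
  if (!is.null(model)) truth$features <- extract_features(model)
  attr(rec, "truth") <- truth
  rec
}

#' Default per-class waveform profiles
#'
#' Uniform parameter ranges emulating the qualitative class contrast:
#' supertasters show large, fast depolarizations, non-tasters small, slow
#' ones, and medium tasters an intermediate range deliberately overlapping
#' both neighbours. These are calibration choices of the generator (no
#' waveform parameter tables exist for real cohorts); all ranges are
#' arguments and every draw is recorded in the cohort's truth table.
#'
#' @return Named list (`ST`, `MT`, `NT`) of lists with `delta_amp` and `tau`
#'   ranges, plus a `shared` element (onset delay, baseline slope ranges).
#' @export
class_profiles <- function() {
  list(ST = list(delta_amp = c(50, 110), tau = c(0.5, 3)),
       MT = list(delta_amp = c(25, 70), tau = c(2, 12)),
       NT = list(delta_amp = c(5, 45), tau = c(8, 30)),
       shared = list(onset_delay = c(0.1, 0.8),
                     baseline_slope = c(-0.1, 0.05)))
}

#' Generate a synthetic cohort
#'
#' Draws `n_per_class` subjects per taster class from the per-class profile,
#' generates their recordings, and assembles the metadata and ground-truth
#' tables. Diplotypes are assigned deterministically (ST to PAV/PAV, MT to
#' PAV/AVI, NT to AVI/AVI) and LMS bitterness ratings are drawn from
#' class-typical normal distributions (62 +/- 12 ST, 29 +/- 19 MT, 7 +/- 7
#' NT, clipped to 0-100).
#'
#' @param profile Profiles as returned by [class_profiles()].
#' @param n_per_class Subjects per class (default 13).
#' @param seed Cohort seed; every per-subject seed derives from it.
#' @param noise_sd,mains_amp Noise levels shared by all subjects. Defaults:
#'   0.3 mV baseline drift and a 0.05 mV (50 uV) residual 50 Hz component,
#'   the order of magnitude left by an isolated differential recording chain
#'   with a driven common ground.
#' @param stimulus_bump Height (mV) of a small stimulus-application bump
#'   added to every recording (0 disables; default 0).
#' @param out_dir Optional directory: writes the interchange recordings, a
#'   `cohort.csv` metadata table and a `truth.csv` table.
#' @return List: `recordings` (list of [recording()]s), `metadata` (data
#'   frame), `truth` (data frame of drawn parameters).
#' @export
synth_cohort <- function(profile = class_profiles(), n_per_class = 13,
                         seed = 42, noise_sd = 0.3, mains_amp = 0.05,
                         stimulus_bump = 0, out_dir = NULL) {
  stopifnot(n_per_class >= 1)
  classes <- c("NT", "MT", "ST")
  diplo <- c(NT = "AVI/AVI", MT = "PAV/AVI", ST = "PAV/PAV")
  lms_mu <- c(NT = 7, MT = 29, ST = 62)
  lms_sd <- c(NT = 7, MT = 19, ST = 12)
  draws <- .with_seed(seed, {
    rows <- list()
    for (cl in classes) {
      pr <- profile[[cl]]
      for (i in seq_len(n_per_class)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("%s%02d", cl, i),
          taster_label = cl,
          diplotype = diplo[[cl]],
          delta_amp = stats::runif(1, pr$delta_amp[1], pr$delta_amp[2]),
          tau = stats::runif(1, pr$tau[1], pr$tau[2]),
          onset_delay = stats::runif(1, profile$shared$onset_delay[1],
                                     profile$shared$onset_delay[2]),
          baseline_slope = stats::runif(1, profile$shared$baseline_slope[1],
                                        profile$shared$baseline_slope[2]),
          lms_rating = min(100, max(0, stats::rnorm(1, lms_mu[[cl]],
                                                    lms_sd[[cl]]))),
          rec_seed = sample.int(2^30, 1)
        )
      }
    }
    do.call(rbind, rows)
  })
  recs <- vector("list", nrow(draws))
  names(recs) <- draws$subject_id
  for (i in seq_len(nrow(draws))) {
    d <- draws[i, ]
    bumps <- if (stimulus_bump > 0) list(c(30.05, stimulus_bump, 0.3)) else
      list()
    p <- synth_params(taster_class = d$taster_label, delta_amp = d$delta_amp,
                      tau_fast = d$tau, tau_slow = d$tau,
                      onset_delay = d$onset_delay,
                      baseline_slope = d$baseline_slope,
                      noise_sd = noise_sd, mains_amp = mains_amp,
                      artifact_spec = bumps, seed = d$rec_seed)
    recs[[i]] <- synth_recording(
      p, subject = subject_meta(d$subject_id, d$taster_label, d$diplotype,
                                d$lms_rating))
  }
  metadata <- draws[, c("subject_id", "taster_label", "diplotype",
                        "lms_rating")]
  metadata$recording_path <- NA_character_
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(recs)) {
      pth <- file.path(out_dir, paste0(draws$subject_id[i], ".txt"))
      write_recording(recs[[i]], pth)
      metadata$recording_path[i] <- pth
    }
    utils::write.csv(metadata, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(draws, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  list(recordings = recs, metadata = metadata, truth = draws)
}
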