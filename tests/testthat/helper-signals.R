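# Shared fixtures: tiny recordings and model signals built in code.

# noiseless single-exponential recording with known onset
make_clean_recording <- function(delta_amp = 80, tau = 1.5,
                                 onset_delay = 0.2, noise_sd = 0,
                                 mains_amp = 0, seed = 1, subject = NULL,
                                 ...) {
  synth_recording(synth_params("ST", delta_amp = delta_amp, tau_fast = tau,
                               onset_delay = onset_delay, noise_sd = noise_sd,
                               mains_amp = mains_amp, seed = seed, ...),
                  subject = subject)
}

# filtered analysis segment for a recording
filtered_segment <- function(rec) {
  filt <- recording(lowpass_filter(rec$samples, rec$fs), rec$fs,
                    rec$t_stim_on, rec$t_stim_off, rec$subject)
  extract_segment(filt)
}

# reference single-exponential fit used by the analytic feature examples
example_exp_fit <- function() {
  fit_model("exp_sum", c(a = 30, b = -0.5, c = -30, d = 0),
            t_onset = 0, t_end = 15)
}

example_rational_fit <- function() {
  fit_model("rational", c(p1 = -1, p2 = -10, p3 = 0, q1 = 5),
            t_onset = 0, t_end = 15)
}

# trapezoidal quadrature oracle on a fine grid
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
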