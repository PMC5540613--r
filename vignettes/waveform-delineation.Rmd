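---
title: "Delineating PROP-evoked tongue biopotentials: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating PROP-evoked tongue biopotentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propsignal)
```

## The measurement and the problem

Applying a drop of 6-n-propylthiouracil (PROP) solution to the dorsal tongue
of a sensitive subject evokes a slow negative shift of the tongue surface
potential — a depolarization of the stimulated taste cells, recorded
differentially between a dorsal ring electrode and a ventral reference at
2048 Hz. Supertasters (ST) show fast depolarizations of many tens of mV;
non-tasters (NT) show slow, shallow ones; medium tasters (MT) lie in
between and overlap both. The goal of this package is a fully automatic,
observer-independent path from the raw annotated trace to (i) a smooth
analytic description of the waveform, (ii) seven morphological features,
and (iii) taster-status / TAS2R38-diplotype classification under repeated
stratified cross-validation.

The processing chain is:

1. **Low-pass filtering** (`design_lowpass()`, `lowpass_filter()`) — an
   order-86 equiripple FIR, passband edge 6 Hz. The depolarization carries
   essentially no energy above a few Hz, so this removes mains interference
   and wide-band noise without touching the waveform.
2. **Windowing** (`extract_segment()`) — 5 s before to 15 s after the
   stimulus-application annotation.
3. **Decimation** (`decimate16()`) — 2048 to 128 Hz by keeping 1 sample in
   16 (the 6 Hz filter already guarantees there is no aliasing that
   matters), which shortens the data and emphasises sample-to-sample
   amplitude differences for event detection.
4. **Knee detection** (`find_knee()`) — the onset of the depolarization,
   from the moving standard deviation of the first derivative.
5. **Delineation** (`delineate()`) — detrending, two candidate analytic
   models fitted, the onset refined at 2048 Hz, the depolarization end
   found on the analytic derivative, and the winning model refitted on the
   onset-to-end interval.
6. **Feature extraction** (`extract_features()`) and **classification**
   (`run_problem()`).

## Event detection

On the 128 Hz segment `x[n]`, the first derivative is the five-point
central difference

$$\dot x[n] = \frac{f_s}{12}\left(x[n-2] - 8x[n-1] + 8x[n+1] - x[n+2]\right),$$

exact on quartics. (The transfer-function form in which this filter is
sometimes printed, $\frac{f_s}{8}(z^{-2}+z^{-1}+z^{1}+z^{2})$, sums rather
than differences the samples; we read that as a typesetting loss of the
minus signs and implement the canonical differencing kernel, with the
summing variant selectable through `derivative$kernel = "printed"` for
comparison.) The two edge samples on either side use one-sided differences
and are excluded from the knee search.

The detection signal is the two-sample moving standard deviation
$s[n] = |\dot x[n+1]-\dot x[n]|/\sqrt 2$ over the first 6 s of the segment.
The knee is the earliest $n$ with $s[n] > 2.1$ mV/s; when no sample
qualifies (slow waveforms), the earliest $n$ with
$s[n] \ge 0.8\,\max s$ is used instead. Both thresholds are empirical
constants of the method and are exposed in the configuration; we keep the
published defaults. Note the degenerate case: an all-zero detection signal
returns index 1 under the relative rule (0 >= 0.8 x 0), which is the
documented behaviour rather than an error.

## Detrending

Two least-squares lines are estimated: over the pre-knee baseline and over
the tail of the window (the final 20% of the segment, standing in for the
post-removal tract when only the 20 s analysis frame exists; with longer
recordings a genuine post-removal window can be configured). If the
baseline slope is non-positive *and* the tail slope is below 0.2 mV/s, only
an offset is removed, anchored so the signal is 0 mV at the knee; otherwise
the baseline line is subtracted from the entire segment. The signed
comparisons are deliberate: a *rising* baseline is evidence of drift that
must be subtracted, while a falling baseline with a flat tail would, if
subtracted, manufacture a spurious post-depolarization rise that taste-cell
physiology does not produce.

## Waveform models

The detrended signal `d[n]` between the knee and 15 s later is fitted by
two candidate analytic models,

$$f_e(t) = a e^{bt} + c e^{dt}, \qquad
  f_r(t) = \frac{p_1 t^2 + p_2 t + p_3}{t + q_1},$$

with time measured from the (coarse) knee. Both families describe an
abrupt-to-slow monotone decay; the rational form often wins on waveforms
whose late tract is not exponential.

**Fitting.** $f_e$ is fitted by Levenberg–Marquardt least squares
(`minpack.lm`), initialised by a two-timescale heuristic — the tail mean
estimates a plateau, a log-linear fit of the residual estimates the fast
pair — plus eight seeded random multi-starts to guard against local
minima. $f_r$ is linear in $(p_1,p_2,p_3)$ once $q_1$ is fixed, so its
profile SSE is scanned on a log-spaced $q_1$ grid over both admissible pole
branches and polished with `optimize()` to 1e-10; the pole $-q_1$ is
constrained at least 0.01 s outside the fitting window, so the model is
finite everywhere it is ever evaluated. Both routes are deterministic given
the configuration seed. On noiseless data from either family the true
parameters are recovered to well below 0.1% relative error (the test suite
checks 100 random draws per family).

**Onset refinement.** The detrended signal is upsampled back to 2048 Hz
(polyphase windowed-sinc interpolation, reflect-padded, each polyphase
branch normalised to unit sum so constants — and the original samples —
pass through exactly). The baseline is replaced by a 0 mV line and the
onset $n_k$ is the first sample at which the model curve turns negative,
i.e. the zero crossing of the fit, at one-sample resolution (0.488 ms).
Alongside the discrete fiducial we store the *exact* root of the model
(solved to 1e-10 s): the feature definitions assume
$\tilde d(t_{onset}) = 0$, and evaluating them at the exact root is what
makes the analytic identities below hold to numerical precision rather
than to one sample of model slope. If the curve never crosses zero (flat
or degenerate records) the coarse knee is used and flagged.

**Selection and end detection.** The winner is the model with the smaller
RMSE against the detrended signal from $n_k$ onward; ties go to the
exponential sum. The depolarization end uses the analytic derivative
($f'_e(t) = ab\,e^{bt}+cd\,e^{dt}$;
$f'_r(t) = (p_1t^2+2p_1q_1t+p_2q_1-p_3)/(t+q_1)^2$): after the
derivative-magnitude peak, the end is the first instant at which the
derivative has flattened to within 2% of that peak
($\dot{\tilde d} \ge -0.02\max|\dot{\tilde d}|$), falling back to 15 s
after the stimulus for waveforms that never flatten (typical of NTs). As
printed elsewhere the rule requires a *positive* derivative
($\ge +0.02\max|\dot{\tilde d}|$), which a monotone decay never attains;
we treat that as a sign slip and implement the flattening reading, keeping
the literal variant behind `end$variant = "printed"`. Finally the selected
model is refitted on $[n_k, n_{end}]$ at 2048 Hz, keeping the refit only
if it does not degrade the windowed RMSE.

Because the end is a shallow threshold crossing, it is intrinsically the
most sensitive fiducial: for a single exponential $t_{end}=\tau\ln 50$, so
a 1% perturbation of $\tau$ moves $t_{end}$ by $\sim$4% of $\tau$. The
onset, anchored at a steep zero crossing, is robust at the few-ms level.

## Features

With $\tilde d$ the onset-zeroed approximated signal and
$\tilde d\,\dot{\tilde d}$ the *feature signal*, the seven features are

| # | name | definition | computation |
|---|------|------------|-------------|
| 1 | `f1_area_dd` | $\int_{t_{on}}^{t_{end}} \tilde d'\tilde d\,dt$ | closed form $[\tilde d^2]/2$ |
| 2 | `f2_delta_amp` | $\tilde d(t_{on}) - \tilde d(t_{end})$ | model evaluation |
| 3 | `f3_area_d` | $\int_{t_{on}}^{t_{end}} \tilde d\,dt$ | analytic antiderivative |
| 4 | `f4_dd_mean` | $f_1/(t_{end}-t_{on})$ | ratio |
| 5 | `f5_delta_amp_2s` | $\tilde d(t_{on}) - \tilde d(t_{on}+2)$ | model evaluation |
| 6 | `f6_max_dd` | $\max \tilde d\,\dot{\tilde d}$ | discrete 2048 Hz grid of the analytic signal |
| 7 | `f7_t_half` | time from $t_{on}$ to half of $f_1$ | root of the closed-form cumulative |

The rational antiderivative uses polynomial division,
$p_1t^2/2 + (p_2-p_1q_1)t + (p_3-p_2q_1+p_1q_1^2)\ln|t+q_1|$, valid because
the pole is excluded from the window. `f7` is solved with `uniroot()` on
the closed-form cumulative $(\tilde d(t)^2-\tilde d(t_{on})^2)/2$ to
1e-6 s. Two identities follow from $\tilde d(t_{on})=0$ and are used as
self-checks throughout the tests: $f_1 = f_2^2/2$ and
$|\tilde d(t_{on}+f_7)| = f_2/\sqrt 2$. The amplitude at 2 s (`f5`) is
anchored at the *onset* (the defining formula is $n_{onset}+2f_s$), not at
the stimulus annotation; when the depolarization ends within 2 s the value
is taken at $t_{end}$ and flagged. Sign conventions are kept exactly as
defined: `f2` is positive and `f3` negative for a decaying signal.

## Classification harness

Cohort feature tables feed four problems: NT vs ST (MT dropped), NT vs
Tasters (MT+ST merged), NT vs MT vs ST, and the diplotype problem
(PAV/PAV vs PAV/AVI vs AVI/AVI). Feature subsets follow the published
combinations (`feature_combos()`): Combo 1 = {1,4} up to All = {1..7}.

Classifiers are a k-nearest-neighbour rule (k = 10, cosine or cubic
distance; vote ties broken by the nearest neighbour among the tied
classes, a deterministic and distance-respecting rule) and an RBF-kernel
SVM. The SVM literature the method cites mixes the nu-SVM and C-SVM
vocabularies ("nu = 0.5, box constraint 1"); we default to a C-SVM with
C = 1 and unit kernel scale on standardized features and keep a nu-SVM
(nu = 0.5) behind `svm_type = "nu"`. Features are z-scored using
**training-fold statistics only** — the features span mV, mV^2 and
seconds, and cosine or RBF geometry on raw units would be dominated by
whichever feature has the largest magnitude; a configuration switch
disables it.

Evaluation is 20-times repeated stratified 10-fold cross-validation: 200
held-out fold accuracies from a single seeded RNG stream, summarised by
mean, SD, type-7 quartiles and the boxplot outlier rule (outside
$q_1 - 1.5\,\mathrm{IQR}$, $q_3 + 1.5\,\mathrm{IQR}$). Outlier folds are
flagged but never removed from the mean or SD. With 13 subjects per class,
every fold holds that class's proportion within one subject by
construction of the per-class cyclic assignment.

## The synthetic generator

No public recordings of this kind exist, so `synth_recording()` /
`synth_cohort()` generate the study conditions: 95 s at 2048 Hz, stimulus
annotated at 30 s and removed at 45 s, and a depolarization starting
0.1-0.8 s after the annotation that relaxes exponentially to
$-\Delta_{amp}$. With a single time constant (the default draw) the clean
waveform lies *exactly* in the $f_e$ family, so the generator provides
exact ground truth for delineation and features; a two-timescale mixture
(70% fast) is available for stress-testing model mismatch.

Class profiles are uniform ranges chosen to mirror the qualitative class
contrast: ST $\Delta_{amp}\sim U(50,110)$ mV, $\tau\sim U(0.5,3)$ s;
MT $U(25,70)$ mV, $U(2,12)$ s; NT $U(5,45)$ mV, $U(8,30)$ s. MT overlaps
both neighbours on purpose — that overlap, not the NT/ST contrast, is what
limits three-class accuracy. Diplotypes are assigned deterministically
(ST PAV/PAV, MT PAV/AVI, NT AVI/AVI) and LMS bitterness ratings are drawn
from class-typical distributions (62±12, 29±19, 7±7, clipped to 0-100).

**Noise model.** The baseline noise parameter is realised as smooth
low-frequency electrode/tissue drift — a cubic spline through Gaussian
control points every 0.5 s, rescaled to `noise_sd` — plus a fixed 20 uV
wide-band instrumental floor. This reflects the recording chain the method
presumes: a 22-bit digitiser (1.4 uV resolution) behind an isolated
medical amplifier leaves drift, not broadband noise, as the dominant
baseline disturbance; and the 2.1 mV/s knee threshold only makes sense on
baselines whose filtered derivative is quiet. For the same reason the
default residual mains amplitude is 50 uV: an isolated, optically coupled
differential measurement with a driven cheek ground does not leave
half-millivolt mains on the record. Both are plain parameters
(`noise_sd`, `mains_amp`) and can be set to harsher values. Movement and
stimulus-application artefacts are raised-cosine bumps
(`artifact_spec`), analytically known so paired clean/artefact tests are
possible.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real recordings: genuine receptor kinetics and
repolarization, non-stationary EMG bursts from tongue musculature,
electrode detachment, inter-subject electrode-impedance variation, or the
true joint distribution of amplitude and time constants within a class
(the profiles are calibrated inventions). Classification accuracies on
synthetic cohorts characterise the *harness*, not human performance; with
the default profiles NT and ST are separable by construction, so NT-vs-ST
accuracy near 1 is expected and only the problem ordering
(NT/ST > NT/Tasters > three-class) is a meaningful qualitative check.

## Numerical choices and degenerate inputs

* The equiripple taps are normalised to exact unit DC gain; an order-86
  design over a 6-50 Hz transition has ~0.13 dB of passband ripple at DC
  otherwise, which would bias every amplitude feature by ~1.5%. Filtering
  is causal FIR with the 43-sample group delay compensated and one filter
  length of reflect padding, so fiducial timing is unbiased and there are
  no start-up transients inside the baseline.
* Decimation is exact sample selection (no interpolation); upsampling is
  the polyphase windowed-sinc described above (half-width 12 input
  samples, Hamming window).
* All-zero fitting windows return the degenerate exponential fit
  $a=c=0$ with RMSE 0 rather than an error; downstream features evaluate
  to 0. Zero-width feature windows give zero areas and amplitudes.
* A knee that leaves fewer than 10 baseline samples aborts that
  recording's delineation ("insufficient baseline"); `run_pipeline()`
  converts per-recording failures into stage-labelled warnings and
  continues, failing only if nothing processes. Slow NT waveforms
  occasionally trip this when the relative knee rule locks onto baseline
  noise — physiologically, a record with no detectable onset.
* Fit non-convergence is flagged on the model object and the model is
  excluded from selection; if both models fail, delineation errors with
  the stage name.
* Problem sizes in the test suite are chosen to keep the full suite in the
  low minutes on one core: 100 recovery draws per family, 200 knee-timing
  recordings, one 39-subject cohort through the full pipeline, 50
  permutation seeds with 2x10-fold CV each.

## Known limitations

* The 20 s analysis frame means the "post-removal" trend is approximated
  by the window tail; supplying the full 75 s post-stimulus recording and
  configuring `trend$post_window_frac` accordingly is the faithful setup.
* The rational model can win on slow noisy waveforms while extrapolating
  differently from the exponential near the end fiducial; end-anchored
  features (`f2`, `f4`) inherit that sensitivity on NT-like records.
* Repolarization, multi-phase events and artifact *classification* are out
  of scope; artefacts are only absorbed by the smooth fit.
* KNN and SVM hyperparameters are deliberately fixed at the published
  defaults; there is no tuning loop, by design, to avoid overfitting the
  small cohorts this method targets.
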