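# propsignal

Automatic processing of PROP-evoked tongue biopotential recordings for
objective taster-status screening.

Applying a drop of 6-n-propylthiouracil (PROP) to the tongue of a
PROP-sensitive subject evokes a slow negative depolarization of the tongue
surface potential, recorded differentially at 2048 Hz. Supertasters show
fast depolarizations of tens of mV; non-tasters show slow, shallow ones.
`propsignal` turns such a raw annotated trace into an analytic waveform
description, seven morphological features, and a taster-status
classification — with no manual cursor placement anywhere.

The pipeline: a 6 Hz, order-86 equiripple FIR low-pass; a 5 + 15 s analysis
window around the stimulus annotation; decimation to 128 Hz; onset ("knee")
detection on the moving standard deviation of the five-point derivative
(thresholds 2.1 mV/s, else 0.8 of the maximum); detrending; least-squares
fits of two analytic models,

    f_e(t) = a e^(b t) + c e^(d t)        (sum of exponentials)
    f_r(t) = (p1 t^2 + p2 t + p3)/(t + q1) (rational)

selection by RMSE; onset refinement at the model's zero crossing on the
2048 Hz grid; end detection where the analytic derivative flattens to 2% of
its peak; and a final refit on the onset-to-end interval. Features (areas,
amplitudes, the feature-signal maximum and the half-area time) are computed
in closed form from the fitted model. A KNN/SVM harness evaluates the NT vs
ST, NT vs Tasters, NT vs MT vs ST and TAS2R38-diplotype problems under
20-times repeated stratified 10-fold cross-validation. Because no public
recordings of this kind exist, a seeded generator (`synth_cohort()`)
produces annotated cohorts with exact ground truth.

See `vignettes/waveform-delineation.Rmd` for the full model account.

## Worked example

```r
library(propsignal)

rec <- synth_recording(synth_params("ST", delta_amp = 80, tau_fast = 1.5,
                                    onset_delay = 0.2, noise_sd = 0.3,
                                    mains_amp = 0.05, seed = 11))
rec
#> Tongue biopotential recording: 95.0 s at 2048 Hz (194560 samples)
#>   stimulus on at 30.000 s, off at 45.000 s

filt <- recording(lowpass_filter(rec$samples, rec$fs), rec$fs,
                  rec$t_stim_on, rec$t_stim_off)
res <- delineate(extract_segment(filt))
summary(res)
#> Depolarization delineation
#>   model: exp_sum (rmse 0.3265 mV; rejected model rmse 0.9409 mV)
#>   onset 0.1956 s, end 6.1764 s after stimulus (knee rule: absolute_threshold)
#>   features:
#>     f1_area_dd           3155.6
#>     f2_delta_amp         79.443
#>     f3_area_d           -364.02
#>     f4_dd_mean           527.62
#>     f5_delta_amp_2s        59.41
#>     f6_max_dd            1084.5
#>     f7_t_half            1.7866
```

The generator planted an 80 mV depolarization with a 1.5 s time constant
starting 0.2 s after the stimulus, under 0.3 mV of baseline drift noise.
The pipeline recovers the onset at 0.196 s and an amplitude
(`f2_delta_amp`) of 79.4 mV — the 0.7% shortfall is the part of the decay
beyond the detected end point. `f7_t_half` says half of the feature-signal
area accrues within 1.79 s of onset: a fast, supertaster-like waveform.

A whole cohort and one classification problem:

```r
co  <- synth_cohort(n_per_class = 13, seed = 42)
tab <- run_pipeline(co$recordings, metadata = co$metadata)
run_problem(tab, "nt_vs_st", classifier = "knn_cubic", combo = "all",
            seed = 7)
#> Repeated stratified CV (20 x 10-fold): accuracy 0.994 +/- 0.041
#>   quartiles 1.000 / 1.000 / 1.000; 4 outlier fold(s)
```

A command-line front end over the same functions lives in
`inst/scripts/propsignal.R` (subcommands `synth`, `process`, `classify`).

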