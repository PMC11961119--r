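# photoavoid

Analysis of fiber-photometry recordings from mice performing cued
active-avoidance, reward-approach, and open-field tasks — the recording
paradigm in which a population calcium signal (e.g. GCaMP6f fluorescence
collected through an implanted fiber) is measured alongside tracked
locomotion while animals learn to cross a chamber within a 5 s tone window to
avoid a foot shock.

The package implements the full analysis chain for such experiments:

* **ΔF/F preprocessing** — isosbestic (405 nm) correction and photobleaching
  normalization:
  `ΔF/F = 100 · (F475 − fitted F405) / (a·e^(−bt) + c)`,
  with a deterministic variable-projection bleaching fit.
* **Event-kernel encoding model** — the calcium trace is modeled as a linear
  superposition of event-locked kernels `k_i(τ)` (action events: −1…+2 s;
  sensory events: 0…+2 s at 15 Hz), solved by least squares; the unique
  contribution of an event type is the loss of explanatory power
  `ΔR² = R²_full − mean R²_reduced` over models refit with that type's event
  times shuffled.
* **Cross-covariance** between ΔF/F and running speed at lags up to ±2 s,
  per inter-trial segment, and its trial-by-trial evolution across a session.
* **Behavioral detectors** — k-means movement threshold, peak-prominence
  movement epochs with 10%-of-peak initiation, frame-differencing freezing
  detection (silhouette pixels < 27/255, changed-pixel threshold 190), and
  trial scoring (avoid / escape / fail, approach / omission).
* **Group statistics** — peri-event alignment, pre/peri contrasts, trial
  amplitude correlations, optogenetic speed and crossing-probability
  analyses over alternating 6-trial stimulation blocks, and the paired /
  unpaired / repeated-measures test wrappers these feed.
* **A synthetic-session generator** with full ground truth (true kernels,
  bleaching constants, shared motion artifact, latent movement epochs and
  freezing bouts), used to validate every stage end-to-end.

Everything is tibble-in / tibble-out and pipe-friendly; fitted objects have
`tidy()` / `glance()` methods and `plot_*()` / `autoplot()` helpers.

## A worked example

Simulate one avoidance session, preprocess it, and fit the encoding model:

```r
library(photoavoid)

cfg <- session_config("avoidance", n_trials = 12)
s   <- simulate_session(cfg, seed = 42)
s
#> <pa_session> avoidance task | 14 trials | 49653 photometry samples | 12414 speed frames

dplyr::select(s$trials, trial_id, phase, outcome, latency, special)[3:8, ]
#>   trial_id phase     outcome latency special
#> 3        3 avoidance avoid      4.20 none
#> 4        4 avoidance avoid      4.64 extended
#> 5        5 avoidance avoid      3.27 none
#> 6        6 avoidance avoid      3.74 extended
#> 7        7 avoidance avoid      1.66 none
#> 8        8 avoidance escape     5.95 none

d <- compute_dff(s$photometry)
d$fit
#> <pa_reference_fit> 405->475: slope 1.323, intercept -2.163 | bleach: a 31.62, b 0.001468, c 98.4
```

The two Pavlovian conditioning trials precede the avoidance trials; the
fitted bleaching constants recover the generator's values (a = 30,
b = 1/600 ≈ 0.00167, c = 100) up to the session's noise. Fit the encoding
model and ask how much unique predictive power the spontaneous inter-trial
crossings carry:

```r
enc <- encode_session(s, delta_r2_types = "iti_cross", n_shuffles = 20, seed = 1)
enc$fit
#> <pa_encoding_fit> 12414 samples, 232 params, R2 = 0.5248 | types: iti_cross, tone_on, ...

glance(enc$delta[["iti_cross"]])
#>   event_type r2_full r2_reduced_mean delta_r2 n_shuffles
#> 1 iti_cross    0.525           0.294    0.231         20

ka <- extract_kernel(enc$fit, "avoid_cross")
max(ka$coefficient)        # 5.16  (%dF/F per avoidance crossing; truth: 5)
ka$tau[which.max(ka$coefficient)]   # -0.27 s: activity rises before the crossing
```

Shuffling the inter-trial crossing times costs the model 0.23 of its 0.52
R² — those events genuinely drive the signal. The recovered avoidance kernel
peaks at 5.16 %ΔF/F just before the crossing, against a generative peak of 5.
Segment-wise neural-locomotor coupling across the session:

```r
dff15 <- lowpass_resample(d$trace, s$speed$t)
evo <- xcov_evolution(dff15, s$speed, s$trials, s$events, cfg)
plot_xcov_evolution(evo)
```

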