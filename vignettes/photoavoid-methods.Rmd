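---
title: "Models and methods behind photoavoid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind photoavoid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoavoid)
```

photoavoid analyses fiber-photometry recordings collected while mice perform
cued active-avoidance, reward-approach, or open-field tasks. This vignette
explains the models the package implements, the tunable parameters and their
defaults, what the synthetic-session generator does and does not emulate, and
the numerical choices a careful user should know about.

## The dF/F model

Bulk fluorescence from the calcium-sensitive 475 nm channel mixes the neural
signal with photobleaching and motion artifacts. The calcium-independent
405 nm (isosbestic) channel shares the artifacts but not the signal.
`compute_dff()` implements the standard correction:

$$\Delta F/F(t) = 100\cdot
\frac{F_{475}(t) - \widehat{F}_{405}(t)}{a\,e^{-bt}+c}$$

where $\widehat{F}_{405}$ is the ordinary least-squares affine fit of the
reference channel to the signal channel (computed once over the whole
session), and $a e^{-bt}+c$ is an exponential fitted to the 475 nm channel to
capture photobleaching. The exponent carries the session time $t$; with $b=0$
the model degenerates to a constant baseline.

Numerical choices:

* The bleaching fit is computed by **variable projection**: for any candidate
  decay rate $b$ the amplitude/offset pair $(a, c)$ has a closed-form
  least-squares solution (computed in centered form, which stays
  well-conditioned even when $e^{-bt}$ is nearly constant), so only $b$ is
  searched, by golden-section on $[0, 50/T]$ followed by bisection on the
  analytic gradient of the profiled objective. This replaces the usual
  Levenberg–Marquardt iteration: the fit is deterministic, needs no starting
  values, and is exactly scale-equivariant, which in turn makes
  $\Delta F/F$ invariant to joint rescaling of the two channels to
  $\sim 10^{-13}$ — a property the tests assert at $10^{-9}$.
* On sessions much shorter than the bleaching time constant the decay rate is
  weakly identified and the fit may legitimately return a near-flat curve;
  downstream analyses are insensitive to this because the denominator remains
  a smooth positive baseline.
* If the 405 nm channel is constant the reference fit is degenerate;
  `compute_dff()` substitutes slope 0 and intercept `mean(f475)` with a
  warning.
* A consequence of normalizing by a *fitted* baseline: the baseline absorbs
  the mean of the event signal, so kernels recovered through the full
  preprocessing chain carry a multiplicative bias of order
  $\overline{s}/100$, where $\overline{s}$ is the session-mean event signal
  in percent (a fraction of a percent in realistic sessions). Encoding-model
  recovery is exact on the model's own signal; through preprocessing it is
  exact only up to this bias, which the test suite measures against its
  analytic bound.

Before event-level analyses the trace is lowpass filtered (zero-phase
Butterworth, half-power 7 Hz, order 2 per pass — forward–backward application
avoids phase lag that would shift event-locked responses) and linearly
interpolated onto the 15 frames/s video time base (`lowpass_resample()`).

## The event-kernel encoding model

`fit_kernels()` models the trace as a linear superposition of event-locked
kernels: action events (avoidance crossing, escape crossing, spontaneous
inter-trial crossing, movement) contribute kernels spanning $-1$ to $+2$ s
around the event (46 taps at 15 Hz); sensory events (tone onset, tone offset,
shock onset, lick) contribute kernels from $0$ to $+2$ s (31 taps). The
design matrix has one column per (event type, lag) pair plus an intercept;
events are snapped to the nearest sample with ties going to the earlier
sample. Kernel coefficients minimize the mean squared error.

The normal equations are solved by Cholesky factorization; when the design is
rank-deficient the SVD minimum-norm solution is returned with a warning.
Rank deficiency is not exotic here: in a session where every trial is
avoided, tone offsets coincide exactly with crossings (the tone terminates at
the crossing) and the overlapping kernel windows duplicate columns. The
minimum-norm solution then splits the response between the two kernels; group
averages over sessions with mixed outcomes resolve the ambiguity.

The unique predictive power of an event type is measured by
$\Delta R^2 = R^2_\text{full} - \overline{R^2}_\text{reduced}$
(`delta_r2()`), where each reduced model redraws that type's event times
uniformly over the session and refits *all* kernels. Twenty shuffles are
averaged by default; the number is configurable, and each shuffle's seed
derives from the caller's seed so results are reproducible.

## Cross-covariance between dF/F and speed

`segment_xcov()` computes the mean-removed cross-covariance at every lag up
to ±2 s on the 15 Hz grid,
$c(\ell) = \sum_i (x_i-\bar x)(y_{i-\ell}-\bar y)$, so a positive extremal
lag means the neural trace lags the speed trace. The value with the largest
absolute magnitude over the lag range summarizes a segment; on an exact tie
the earlier (more negative) lag is kept. Covariance is reported raw
(unnormalized) by default, matching the convention of session-level segment
analyses; `normalize = TRUE` rescales to a correlation. Segments are the
inter-trial intervals from 5 s after tone offset to 5 s before the next tone
onset, dropped below 61 samples; the pre-task habituation period is cut into
30 s segments and processed identically. Because raw covariance sums grow
with segment length, comparisons across session phases assume comparable
segment lengths — the generator's habituation segments are sized to match
typical inter-trial windows for exactly this reason.

## Behavioral detectors

**Movement threshold (open field).** Speeds are clustered into
nonmovement / low / high movement by k-means (k = 3, 10 restarts, seeded from
the config); the threshold is the lowest speed among members of the
middle-centroid cluster, which makes the result invariant to cluster label
permutation.

**Movement epochs.** Open-field epochs are speed peaks above the k-means
threshold with topographic prominence ≥ 5 cm/s; inter-trial epochs use an
absolute 10 cm/s height and 3 cm/s prominence on a trace smoothed with a
7-frame Gaussian-weighted moving average, and an epoch within 5 s after a
kept epoch is excluded (applied greedily in time order). Movement initiation
is the first sample within 2 s before the peak at which speed exceeds 10% of
the peak and does not fall back below it; open-field epochs additionally
require the second before initiation to stay below threshold. The Gaussian
window's standard deviation is window/5 samples — wide enough that a
single-frame tracking spike of ~30 cm/s is suppressed below the absolute
threshold, which is the purpose the smoothing serves.

**Freezing.** The animal silhouette is the set of pixels darker than 27/255;
the per-frame count of silhouette pixels that changed since the previous
frame is the movement signal. It is bandpass filtered (zero-phase Butterworth)
between 0.01 and 0.9 Hz corners — read as Hz because those timescales bracket
the freezing-bout durations the detector must resolve (seconds to tens of
seconds) — with the signal mean restored after filtering so the absolute
190-pixel threshold keeps its meaning (a pure bandpass would zero any
constant movement signal and label a continuously moving animal frozen).
Frames with fewer than 190 changed pixels are freezing; the first frame
inherits the second frame's label; maximal runs of freezing frames form
bouts. Both pixel constants are resolution-dependent and configurable.

**Trial scoring.** A crossing within 5 s of tone onset is an avoid
(approach); in the avoidance task a crossing between the end of the window
and the end of the 2 s shock is an escape; otherwise the trial fails.
Crossings come from the event stream when present, else from the chamber
x-position as a midline sign change with 1 cm hysteresis. In the approach
task a crossing followed by a lick within 2 s is a rewarded approach; a
crossing without one is an omission.

## Group analyses

Animals are the unit of analysis throughout: per-animal means are computed
first, and the cohort tests are paired t (within subject), pooled-variance
unpaired t (between subjects), one-sample t (correlations against zero), the
mixed two-factor ANOVA for opsin × stimulation, and one-way repeated-measures
ANOVA with Tukey-adjusted pairwise post-hocs (via emmeans when available).
The pre/peri contrast uses baseline $[-4, -2)$ s (half-open to avoid
double-counting a sample) and peri $[-1, +1]$ s around the crossing.
Crossing-latency histograms use 0.25 s bins over 0–7 s normalized by total
trial count; the stimulation-window ratio divides the summed crossing
probability inside 0.5–2.5 s after tone onset under illumination by the same
quantity without. Block-structure series section the 12 alternating
OFF/ON blocks into chunks (6 pre + 6 on; 6 on + 6 post over 5 chunks,
excluding the first OFF and last ON block; or 3 + 6 + 3 over 5 chunks) and
average latency at each relative trial position.

## The synthetic-session generator

`simulate_session()` draws a complete session with known ground truth:

* **Trials.** Habituation (default 120 s), then (avoidance) two Pavlovian
  tone+shock conditioning trials, then cued trials. Crossing latency follows
  a shifted log-normal (`0.3 + lognormal(meanlog 1.144, sdlog 0.6)`,
  ~75% success within the 5 s window, matching a trained animal); 5% of
  trials have no crossing at all. Inter-trial intervals are uniform on
  0.5–1.5 times the 40 s mean. Special trials (shortened/extended tones,
  reward omissions) are drawn at 10% each. Stimulation alternates OFF/ON in
  blocks of 6; the laser window is 0.5–2.5 s after tone onset.
* **Latent behavior.** Spontaneous inter-trial crossings (1 per ITI on
  average, and at the same per-second rate during habituation), movement
  epochs (1.5 per ITI; every ~20 s during habituation), and freezing bouts in
  post-shock ITIs. Latent events keep ≥ 6 s separation so detector rules can
  be tested unambiguously.
* **Speed and position.** 15 frames/s; Gaussian bumps (SD 0.4 s) at
  crossings (~18 cm/s) and movement epochs (log-normal peaks, 12–30 cm/s)
  over a small positive baseline; near-zero speed during freezing bouts; the
  chamber x-position flips sign at each crossing.
* **Photometry.** The event signal $s(t)$ is the design-matrix superposition
  of difference-of-exponentials kernels (rise 0.1 s, decay 0.6 s, GCaMP6f-like;
  action kernels begin rising 0.5 s before the event), with per-type peak
  amplitudes of a few percent dF/F. Then
  $F_{475} = (a e^{-bt}+c)(1 + s/100) + \text{artifact} + \varepsilon$ and
  $F_{405} = (a' e^{-b't}+c') + \text{artifact} + \varepsilon'$: channel-specific
  bleaching, a shared band-limited (0.5 Hz) motion artifact of 2% of baseline
  added equally to both channels so the reference subtraction can remove it,
  and white noise of 0.5% of baseline per channel.
* **Post-shock gain.** After the first shock, movement-locked kernels
  (movement, inter-trial crossing) are scaled by `post_shock_gain`
  (default 1), emulating an abrupt change in movement-related neural gain.
* **Video.** A dark blob (radius 10 px, well below the 27/255 silhouette
  threshold) on a light 80×80 background; static during freezing bouts,
  random-walking ≥ 6 px/frame otherwise, reflecting at walls so the full
  displacement is always realized.

What the generator does *not* emulate: drifting baselines beyond a single
exponential, hemodynamic or pH artifacts, sensor nonlinearity and saturation,
spike-timing structure within transients, tracking dropouts, occlusions or
lighting changes in video, and any learning dynamics within a session (the
latency distribution is stationary; the post-shock gain is a step). Passing
recovery tests on these sessions therefore demonstrates correctness of the
estimators under the stated generative model, not robustness to every
pathology of real recordings.

## Problem sizes used in validation

The test suite and the acceptance script exercise the pipeline at desk
scale, chosen to finish in minutes while leaving comfortable statistical
margins: 600 s sessions at 15 Hz for exact-recovery checks; 10–12 trial
sessions with 60 Hz photometry for ΔR², pre/peri and cross-covariance
cohorts of 8 animals; 72-trial, 13-animal (8 opsin + 5 control) cohorts for
the optogenetic analyses; 120 s, 15 fps videos for freezing. Shuffle counts
(20) and seed counts (10–50 per check) follow the same logic.

## Known limitations

* Exact collinearity between tone-offset and crossing kernels in all-avoid
  sessions is resolved by the minimum-norm convention, not by the data.
* Raw (unnormalized) segment covariance depends on segment length; compare
  phases only with comparable segment durations, or use `normalize = TRUE`.
* The bleaching decay rate is unidentifiable on sessions much shorter than
  its time constant; the fit degrades gracefully to a near-constant baseline.
* The freezing detector assumes a single dark animal on a lighter background;
  it is not a tracker and will miscount changed pixels if other dark objects
  move.
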