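---
title: "Estimating vertical ground reaction force characteristics from sacral acceleration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating vertical ground reaction force characteristics from sacral acceleration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vgrfstep)
```

## The problem

Vertical ground reaction force (vGRF) during running is a central quantity in
gait analysis and running-related-injury research, but it normally requires an
instrumented treadmill or force plates. A single accelerometer worn over the
sacrum, close to the body's centre of mass, carries much of the same
information: by Newton's second law the whole-body vertical acceleration is
proportional to the net vertical force. This package implements a complete
pipeline that learns to predict four per-step vGRF characteristics from 3-D
sacral acceleration:

* **active peak** — the larger vGRF maximum near mid-stance (≈ 2.4 BW),
* **impact peak** — a transient local maximum within the first 10 % of stance,
  present on a subset of steps (mainly rearfoot strikes),
* **stance impulse** — the time-integral of the normalized vGRF over ground
  contact (BW·s),
* **contact time** — the duration from initial contact (IC) to toe-off (TO).

Forces are expressed in multiples of body weight (BW), i.e. divided by
$m\,g$ with $g = 9.81\ \mathrm{m/s^2}$ exactly.

## Ground truth from the force plate

Force signals are low-pass filtered with a fifth-order Butterworth filter at
30 Hz (60 Hz for acceleration channels), applied forward and backward so the
filter is zero-phase and event timing is preserved. Because the filter runs
twice, the effective magnitude response is $|H(f)|^2$: exactly 1 at DC and
$1/2$ at the cutoff. We initialize each pass in steady state at the signal's
edge level and pad with odd reflection (3 × the filter order), which removes
start-up transients — a constant signal passes through unchanged to machine
precision.

Steps are detected on the filtered, *unnormalized* force as contiguous regions
above the absolute 50 N threshold; regions touching the record boundary are
discarded as incomplete. The four characteristics are then computed on the
BW-normalized stance window:

* active peak: the window maximum (the impact region is not excluded — the
  impact peak is by definition the smaller maximum, so the global maximum is
  the active peak);
* impact peak: the first local maximum (strict sign change of the first
  difference) within the first 10 % of the stance samples with prominence of
  at least 0.05 BW, where prominence is the drop to the lowest point before
  the curve next exceeds the peak; absent otherwise. Both the window fraction
  and the prominence are configurable;
* impulse: trapezoidal quadrature, which at 1200 Hz is accurate to well below
  0.5 % for these band-limited waveforms;
* contact time: the sample-index span of the stance over the sampling rate.

## Event detection on the acceleration signal

Acceleration is used in the gravity-subtracted convention: free flight reads
−1 g and quiet standing 0 g. Whether a deployed accelerometer is gravity
compensated varies between systems, so the simulator exposes the convention
as a flag; the detection thresholds below assume the gravity-subtracted form.

Initial contacts are upward crossings of **+0.18 g** that satisfy three
constraints (all configurable): the signal must rise to at least 0.5 g within
0.10 s after the crossing (the expected post-contact increase), must have
been at or below 0 g at some point within the 0.10 s before it (the expected
pre-contact decrease, approximated by a non-positivity condition), and must
be at least 0.2 s after the previous retained contact. Toe-off is the last
downward crossing of **−0.25 g** before the next contact; when no crossing
exists the threshold is relaxed in +0.05 g increments up to −0.05 g, after
which the step is dropped as unmatched.

Acceleration-detected steps are matched one-to-one to force-detected steps by
nearest IC time. With a smooth stance waveform, the +0.18 g crossing sits a
predictable 40–75 ms after the 50 N force crossing (the acceleration must
climb from −1 g through +0.18 g, i.e. the force from 0 through 1.18 BW), so
the matching tolerance defaults to 0.10 s: larger than this structural lag,
but well under half the shortest step period (~0.15 s), so pairings remain
unambiguous. Matched steps are then filtered: stance durations must lie in
[0.167 s, 0.4 s], the window must contain no missing samples, and the stance
peak must reach 1.2 BW (our operationalization of "signal falling away"
data corruption).

A consequence worth stating explicitly: a threshold detector estimates the
*threshold-crossing time*, not the biomechanical stance onset. The simulator
therefore reports both per step — the exact stance onset and the analytic
crossing times of the 50 N, +0.18 g and −0.25 g levels on the continuous
waveform — and recovery tests compare each detector against the crossing
times it is actually estimating.

## Features

Each retained step yields a feature vector with provenance categories:

* **subject** features: body mass (kg) and leg length (m);
* **domain** features: step frequency (1/step period), and the trapezoidal
  impulse of the vertical acceleration over the stance window and over the
  entire IC-to-next-IC step;
* **general** time-series features, computed per axis (vertical, AP, ML) on
  either the stance window or the entire step: mean, SD, min, max, median,
  skewness, kurtosis, RMS, absolute energy, number of mean-crossings,
  autocorrelation at lags 1/5/10, dominant DFT frequency and magnitude,
  linear-trend slope, and window duration. The catalogue is frozen and
  versioned ("v1"); it is a compact, closed-form-testable counterpart of the
  large automatic catalogues used in time-series feature libraries, and the
  window duration entry (those libraries' `length`) is the natural carrier of
  contact-time information. Spectral features are reported in Hz and the
  duration in seconds, so features are comparable across windows of different
  lengths without resampling;
* optionally the trial **speed** (m/s), giving the "with speed" model
  variants.

Feature cleaning removes columns with any missing value or zero variance and
one-hot encodes categorical columns. Numeric features are z-scored with the
*population* SD; scaler parameters are always estimated on training rows only
and re-estimated inside every cross-validation fold, so held-out subjects can
never influence the transform.

## Models and evaluation

The predictor is a Lasso, minimizing
$$\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i\beta)^2 + \lambda\|\beta\|_1$$
with an unpenalized intercept, fitted by cyclic coordinate descent in
covariance form (the inner loop in C++). Iteration stops when the largest
variance-scaled squared update $d_j(\Delta\beta_j)^2$ falls below $10^{-7}$.
The penalty grid is 20 log-spaced values on $[5\times10^{-6},\ 0.05]$; ties in
validation score break toward the stronger penalty for parsimony.

Data are split at the subject level (default test fraction 7/43, which gives
a 36/7 split on a 43-subject cohort). The penalty and the feature window
(stance vs entire step) are selected by leave-one-subject-out cross-validation
on the training subjects, scoring each penalty by the unweighted mean over
folds of the per-fold RMSE. The final model is refitted on all training rows.

Two literature-style baselines are implemented behind the same harness:

* an **acceleration plug-in** method: the vGRF is estimated as
  $\hat F(t) = m g (a(t) + 1)$, clipped at zero; the matched characteristic
  computed from this curve, together with body mass and speed, feeds an OLS
  regression per target (active peak, impulse, contact time);
* a **trunk-segment** method for the impact peak: the trunk CoM acceleration
  is interpolated between neck and L5 channels at the CoM fraction, the
  segment force curve $m_{trunk}\, g\,(a_{com}+1)$ (expressed in BW of total
  body weight) is formed, its impact peak extracted with the same operator as
  the ground truth, and OLS maps it to the true impact peak. Trunk mass
  fraction 0.4346 and CoM fraction 0.4486 follow standard anthropometric
  tables and are configurable. Steps without a detectable segment-curve
  impact peak are excluded; to keep every method on identical evaluation
  rows, the impact-peak task uses exactly the steps with a present true
  impact peak *and* an available segment estimate.

A mean regressor (constant training-mean prediction) anchors the comparisons.
Metrics are RMSE, MAPE in percent, and $R^2$ computed against the evaluation
split's own mean — so a constant predictor can score negative $R^2$ on a
shifted test distribution. Per-speed evaluation partitions the test steps by
trial speed; the step-weighted per-speed MSEs recombine exactly to the
overall MSE.

## The synthetic cohort generator

The study's measurement data are not redistributable, so the package ships a
generator that emulates their statistical structure with exact per-step
ground truth. The stance waveform, normalized to body weight, is a half-sine
active component plus an optional Gaussian impact bump:
$$F(t)/mg = A \sin(\pi t/T_c) + I\, e^{-(t - f T_c)^2 / 2w^2},
\qquad t \in [0, T_c],$$
the simplest form with the observed two-peak morphology that still admits
closed-form oracles: the peak location, the impulse
$2 A T_c/\pi + I w \sqrt{2\pi}\,[\Phi((T_c - fT_c)/w) - \Phi(-fT_c/w)]$, and
all threshold-crossing times are available analytically. Vertical
acceleration follows from the same curve as $F/(mg) - 1$, so force and
acceleration are exactly consistent by construction; AP/ML channels carry
noise only, and neck/L5 channels mirror the vertical channel with independent
noise. Sensor noise is additive i.i.d. Gaussian per channel (no drift model).

Default study conditions: 20 subjects × 4 belt speeds (2.22, 2.50, 2.78,
3.33 m/s), 30 s trials, force at 1200 Hz, acceleration at 240 Hz, noise SDs
0.05 g and 5 N, impact-bump probability 0.41 per step. Per-step parameters
vary around speed- and subject-dependent means: the active peak increases
with speed (mean $2.44 + 0.25\,(v - 2.9)$ BW, subject intercept SD 0.12,
step SD 0.06) and contact time decreases (mean $0.26 - 0.05\,(v - 2.9)$ s,
subject SD 0.012, step SD 0.006); flight time rises mildly with speed.
Subject mass (74 ± 11.9 kg) and leg length (0.92 ± 0.05 m) match a mixed
recreational cohort. Impact-bump geometry — amplitude scaling with the
carrier steepness $A/T_c$ (so bumps remain distinct shoulders at fast
speeds, where impact peaks are empirically larger), width
$\min(5.5\ \mathrm{ms},\ 0.026\,T_c)$, apex inside $[2.8 w,\ 0.078\,T_c]$ —
was chosen once so that a generated bump *is* a detectable impact peak by
construction: the apex stays inside the 10 % window after 30 Hz filtering,
and the waveform stays below 50 N at contact onset so the crossing structure
is preserved. One deliberate compromise: with a half-sine carrier the impulse
is tied to $2AT_c/\pi$, so matching the empirical active peak (2.44 BW) and
contact time (0.26 s) puts the simulated impulse mean near 0.40 BW·s, a
little above the ≈ 0.37 BW·s seen in measured cohorts, whose stance curves
are slightly sub-sinusoidal.

All randomness derives from one integer seed expanded into named sub-streams
per stage and per (subject, speed) trial, so cohorts are bitwise reproducible
and adding subjects never perturbs earlier subjects' draws.

### What the generator does not emulate

Real sacral acceleration contains soft-tissue resonance, axis cross-talk,
posture-dependent gravity leakage, drift, and asymmetries between left and
right steps; real vGRF curves are not exactly sinusoidal and their impact
transients vary in shape. Passing the recovery and ordering tests on this
generator therefore shows that the pipeline's machinery is correct and that
the learning stage extracts the information the signals contain — it does not
by itself certify accuracy on measured data.

## Numerical choices and degenerate inputs

* Windows shorter than 4 samples raise an error in feature extraction;
  stances touching record boundaries and trailing steps without a next IC are
  dropped rather than guessed.
* Zero-variance feature columns inside a CV fold are dropped with a warning
  (they cannot be z-scored); constant columns never survive cleaning on the
  full table.
* Coordinate descent warm-starts along the decreasing penalty path; with
  heavily collinear feature blocks the argmin at tiny penalties is nearly
  degenerate, which affects coefficients but not predictions.
* Problem sizes in the shipped tests — 1000 stances for extraction recovery,
  a 3 × 2 noiseless cohort for event recovery, a 20 × 4 cohort for the
  end-to-end ordering — were chosen as the smallest sizes at which the
  checked properties are stable.

## Known limitations

The event constraints ("expected increase after IC, decrease before IC and
TO") are operationalized with specific constants (0.5 g rise, non-positive
dip, 0.2 s refractory); other operationalizations exist, which is why all
three are exposed in the configuration. The general feature catalogue is a
compact stand-in for the much larger automatic catalogues of time-series
feature libraries; an adapter can supply an external catalogue where exact
reproduction of such a set is needed. Left/right foot attribution and
overground running are out of scope.
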