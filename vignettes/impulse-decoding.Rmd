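---
title: "Impulse-response decoding of working memory: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Impulse-response decoding of working memory: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, estimators and design choices behind
`impulsewm`: what each stage computes, which parameters matter, what the
synthetic generator does and does not emulate, and the numerical
conventions adopted where the method leaves room.

## The paradigm

A participant memorizes the orientation of a low-contrast grating and,
after a delay, judges whether a probe grating is rotated clockwise or
counter-clockwise relative to it. On half the trials ("long" trials) a
fixed, task-irrelevant, high-contrast impulse stimulus is flashed
mid-delay — at either 1170 ms ("early") or 1230 ms ("late") after the
memory item; the ±30 ms jitter exists so that time-locking of any decoding
effect to the impulse itself can be demonstrated. The working hypothesis
is that the memory content may be held in an "activity-silent" state that
ordinary delay-period decoding misses, but that patterns the impulse
evokes through the memory-configured network carry the content and can be
decoded.

## The decoding statistic

For each time point, trials are split into four 45° orientation bins, two
ways (scheme A anchored at 0°, scheme B shifted by 22.5°, half-open
intervals, wrap-around at 180°), and only orthogonal bins — 90° apart —
are compared. For a held-out trial `x` (one value per channel), the
statistic is the difference of squared Mahalanobis distances

    D = (m_orth − x)' pC⁺ (m_orth − x) − (m_same − x)' pC⁺ (m_same − x)

where `m_same`/`m_orth` are the training means of the trial's own and the
orthogonal bin, both computed with the test trial excluded, and `pC⁺` is
the pseudoinverse of the pooled, shrinkage-regularized error covariance of
the training trials. Every trial yields one estimate per bin scheme (two
in total); the reported time-course averages all estimates. Positive
values indicate decodable orientation information. The univariate control
applies the same leave-one-trial-out structure to the channel-averaged
voltage, `|m_orth − x̄| − |m_same − x̄|`, and is blind to amplitude-free
pattern differences by construction.

### Shrinkage covariance

No installed package provides the analytic shrinkage estimator, so it is
implemented in the engine (and documented here): residuals about each
bin's own mean are pooled; with `S` the n-denominator pooled scatter,
`m = tr(S)/p`, `d² = ‖S − mI‖²_F / p` and
`b² = min(d², (Σ_j ‖z_j‖⁴ − n‖S‖²_F)/(n² p))`, the shrinkage intensity is
`λ = b²/d²` and the estimate is `(1−λ)·S_unbiased + λ·(tr(S_unbiased)/p)·I`.
This is the standard analytic optimal shrinkage toward a scaled identity;
`λ ∈ [0, 1]`, it vanishes as trials grow, and it keeps the estimate
well-conditioned when trials are scarcer than channels. The pseudoinverse
zeroes eigenvalues below `max(eig) · 1e−12`. A fixed `shrinkage` can be
passed to any decoding function; `shrinkage = 0` reproduces the plain
inverse on well-conditioned data (tested against an independent oracle).

### Finite-sample behaviour

Because the same-bin training mean uses one fewer trial than the
orthogonal-bin mean, the statistic carries a small negative offset of
order `p/(n/2)²` under the null. At the trial counts of the emulated task
(hundreds per bin) this is negligible against any standard error; it is
visible only in aggressive null simulations with very few trials per bin,
and the test suite sizes its null checks accordingly.

## Cross-temporal machinery

The generalization matrix decouples training and test times: training
means and pooled precision at train time Y are applied to test vectors at
test time X. When train and test epochs hold the same trials — including
the memory-locked vs impulse-locked epochs of the same long trials — the
test trial is excluded from the training statistics at every train time.
The method itself does not say whether cross-epoch training sets should
exclude the test trial; exclusion is enforced here because the epochs
contain the same trials and anything else leaks information.

The shifted-training analysis extracts the cross-epoch entries along
`train = test − t₀ + shift`, with the nominal onset `t₀` an explicit
parameter (default 1200 ms, the mean of the two true onsets) rather than a
hard-coded constant. The lag-correlation analysis Pearson-correlates the
early-onset decoding time-course over 1370–2170 ms with the late-onset
time-course delayed by 0..120 ms in 4 ms steps (31 lags), Fisher-z
transforms each r (clamped to ±(1−1e−12) so degenerate fixtures stay
finite), averages z over participants, and reports the argmax lag (ties
toward the smaller lag).

Time-courses entering the lag correlation are computed at the
condition-best training shifts (determined by the group-mean
shifted-training scan). At zero shift the early and late time-courses
share the training-strength profile as a common factor and their
correlation no longer isolates the onset difference; the best-shift
time-courses are exact 60 ms translates of each other in expectation.

## Inference

Group-level inference uses two-sided sign-permutation tests: each
participant's time-course is randomly multiplied by ±1 (10,000 draws by
default), the per-time permutation distribution of the group mean gives
per-time p-values, and contiguous same-sign runs with p below the
cluster-forming threshold (0.01) form clusters. The cluster statistic is
the sum of group-mean values in the run — chosen to match the per-time
statistic being the mean discrimination value, and swappable in
`find_clusters`'s caller if a t-mass is preferred. The corrected p is the
fraction of permutations whose maximal absolute cluster mass reaches the
observed mass, floored at `1/n_perm`; the same draws serve the per-time
and cluster nulls (single pass, deterministic given the logged seed).
Default analysis windows are 0–1400 ms (memory-locked) and 0–800 ms
(impulse-locked); the post-impulse *increase* test first subtracts each
participant's mean discrimination over [−100, 0) ms before onset. The
family-wise error calibration is verified by simulation in the test suite
(500 null replicates, binomial tolerance).

## The behavioral model

The 2AFC mixture model attributes errors to two causes: pure guesses
(probability `g`, clockwise with probability 1/2) and Gaussian noise of SD
`σ` degrees on the remembered orientation, giving
`P(cw | Δ) = g/2 + (1 − g)·Φ(Δ/σ)`. The reference analyses fit this model
through an external toolbox whose exact 2AFC link is not printed; this
form is the package's own definition, used consistently for generation and
fitting, so self-consistency (parameter recovery) is the testable
contract. Whether the noise SD refers to one or both compared
representations only rescales σ by √2 and is fixed here as the
single-representation convention. Fitting maximizes the log-likelihood by
L-BFGS-B within `g ∈ [0, 1]`, `σ ∈ [0.1, 100]` degrees, from five
deterministic starts spanning the box; with all-guess data σ is
unidentified and the fit is flagged as a boundary case.

## The synthetic generator

`generate_epochs()` emulates exactly the statistical structure the
analyses assume:

- **Trial structure** — 800 short / 400 early / 400 late at full scale,
  conditions randomized across the session; orientations uniform on
  [0°, 180°); probe offsets uniform over ±{4,5,7,9,12,15,20,26,34,45}°;
  memory item at 0–200 ms; impulses at 1170/1230 ms; epochs −200..1400 ms
  (short) and −200..2800 ms (long) at 250 Hz.
- **Orientation tuning** — the signal lives in a two-dimensional tuning
  subspace: (cos 2θ, sin 2θ) projected onto two orthonormal channel
  patterns, so orthogonal orientations are maximally separated, matching
  the orthogonal-bin design.
- **Dynamics** — under `dynamics = "dynamic"` the pattern pair drifts
  smoothly through channel space as a Gaussian process in time since the
  driving stimulus (squared-exponential kernel,
  `pattern_drift_tau = 50` ms, orthonormalized per sample). The drift
  rate was chosen once to mirror how quickly real evoked topographies
  change (tens of milliseconds): it yields the diagonal-dominant
  generalization matrices of dynamic coding *and* gives decoders the
  temporal selectivity without which a ±30 ms training-shift optimum
  could not be resolved at all. A slowly rotating code was tried first
  and rejected for exactly that reason. `"static"` keeps patterns fixed
  and produces block-uniform generalization.
- **Envelopes** — encoding rises with a 30 ms time constant during the
  item, then decays exponentially (`encode_decay_tau = 300` ms, so
  decodability is near baseline by ~1 s, as observed); the impulse
  response is a gamma-like bump peaking 200 ms after onset.
- **Impulse code** — independent of the encoding code by default
  (`shared_code = FALSE`), reproducing the observed absence of
  cross-epoch generalization; `shared_code = TRUE` re-plays the encoding
  sequence impulse-locked, for testing the opposite regime. Note that in
  a p-channel space two independent random patterns overlap by ~1/√p, so
  the cross-epoch null holds across participants, not trial-by-trial
  within one.
- **Noise** — spatially correlated Gaussian noise (AR(1) across channels,
  neighbour correlation 0.5), white in time before the 8 ms smoothing.
  Amplitudes default to 1.0 µV (encoding) and 0.8 µV (impulse) against
  1.0 µV noise — the physiological amplitude of orientation information
  is not known a priori, so the default SNR is the free parameter of the
  generator, set once so that desk-scale runs reproduce the qualitative
  result pattern (clear encoding decodability, near-zero late delay,
  clear post-impulse re-emergence).

What the generator does **not** emulate: continuous (non-epoched) data,
realistic head-model topographies, 1/f and oscillatory background
spectra, eye movements and other artifacts, and amplitude non-stationarity
across a session. Passing tests therefore validate the estimators and
their contracts, not the claim that real EEG satisfies the generator's
assumptions.

## Numerical conventions

- **Sampling grid** — everything lives on the 4 ms (250 Hz) grid. The
  1170/1230 ms onsets fall exactly between samples; re-epoching aligns to
  the nearest sample with ties toward the *earlier* sample (1168/1228),
  preserving the 60 ms separation exactly. Consequence: with the nominal
  onset at 1200 ms, the continuous-time optimum of the early-trial
  training shift (≈ +30 ms) sits between the 28 and 32 ms grid points,
  and the recovered best shift and lag peak snap to a neighbouring grid
  value (28 rather than 30; 56 or 60 rather than 60). This is a property
  of the grid, not a bias of the estimator.
- **Baseline window** — half-open `[−200, 0)` ms, excluding the
  stimulus-onset sample.
- **Smoothing kernel** — truncated at ±4 SD and renormalized; edges by
  reflection, so constant traces are exact fixed points.
- **Half-open bins** — 45° belongs to `[45, 90)`; 157.5° wraps into
  scheme B's `[−22.5, 22.5)` bin. The bins tile the orientation circle.
- **Ties** — best-shift and peak-lag ties resolve toward the smaller
  value; `which.max` order makes this deterministic.
- **Seeds** — one root seed; per-participant and per-stage seeds are
  derived deterministically from it (`seed + i·100003 mod 2³¹−1`), so
  participant-level parallelism cannot change results.

## Problem sizes

The package's own validation runs at reduced desk scale, chosen as the
smallest sizes at which every qualitative contrast is unambiguous: the
impulse-latency analyses use 8 simulated participants with 200 early +
200 late trials each (acceptance script) or 4 participants with 96 + 96
(test suite); parameter recovery uses 20 replicates of 800 trials
(acceptance) or 12 (tests); the family-wise-error simulation uses 500
null replicates of 24 participants × 400 time points with 400
permutations per test; pipeline defaults use 6 participants with
200/100/100 trials. Full-scale designs (`wm_design()` defaults) are
supported throughout and only cost time.

## Known limitations

- The LOO statistic's small-sample offset (above) makes *absolute* values
  at very low trial counts slightly conservative; comparisons and
  inference are unaffected.
- The generalization matrix at the native grid is O(T²·n·p²) per
  comparison; use `stride` for exploratory runs.
- The mixture model's σ is weakly identified near the smallest probe
  offsets (±4–5°); per-fit σ has a standard deviation of ≈ 0.5° even at
  800 trials, which the recovery tolerances reflect.
- `fit_mixture()` treats trials as exchangeable; sequential effects and
  lapses other than uniform guessing are out of scope.
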