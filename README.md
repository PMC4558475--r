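# impulsewm

Decoding "activity-silent" visual working memory from EEG with an impulse
stimulus.

## The problem

During a working-memory delay, the content being remembered often cannot be
decoded from ongoing EEG: maintenance may be carried by hidden neural
variables (e.g. short-term synaptic changes) rather than persistent
activity. One way to read such hidden states out non-invasively is an
echolocation-like perturbation: flash a fixed, task-irrelevant high-contrast
stimulus (the *impulse*) in the middle of the delay and ask whether the
evoked response depends on the memorandum. If it does, the memory content
can be decoded from the impulse response even though the delay activity
itself is silent.

`impulsewm` implements the complete analysis chain for this paradigm, plus
a synthetic-data generator with the paradigm's trial and signal structure,
so that every stage can be exercised and validated without any recordings:

- **Synthesis** — `wm_design()`, `generate_epochs()`, `generate_behavior()`:
  orientation working-memory trials (1600 trials split 800 short /
  400 early-impulse / 400 late-impulse at full scale), 17 posterior
  channels at 250 Hz, orientation-tuned dynamic evoked patterns that decay
  through the delay, an impulse-evoked orientation-dependent pattern with
  an independent spatial code, and 2AFC responses from a mixture model.
- **Preprocessing** — `baseline_correct()`, `smooth_gaussian()` (SD 8 ms),
  `select_channels()`, `reepoch_impulse()` (re-locks long trials to the
  1170/1230 ms impulse onsets), `flag_artifacts()`.
- **Decoding** — `loo_discrimination()`: the core statistic. Trials are
  binned twice into four 45-degree orientation bins (schemes offset by
  22.5 degrees) and only orthogonal bins are compared. For a held-out
  trial `x` with same-bin training mean `m_same`, orthogonal-bin mean
  `m_orth` and pooled shrunk error-covariance pseudoinverse `pC+`, the
  statistic is the Mahalanobis distance difference

  ```
  D = (m_orth - x)' pC+ (m_orth - x) - (m_same - x)' pC+ (m_same - x)
  ```

  averaged over trials, bin schemes and time points; positive values mean
  decodable orientation information. `univariate_discrimination()` is the
  channel-averaged amplitude control.
- **Cross-temporal analysis** — `generalization_matrix()` (decoupled
  train/test times, within and across epochs),
  `shifted_training_timecourse()` / `shifted_training_scan()` (decoder
  trained impulse-locked, tested memory-locked at shifted training times),
  `lag_correlation()` (early- vs late-onset decoding time-courses,
  lags 0..120 ms).
- **Inference** — `sign_permutation_cluster()`: two-sided sign-permutation
  tests with cluster-based multiple-comparison correction (10,000
  permutations, cluster-forming p < 0.01), and `baseline_increase_test()`
  for the post-impulse increase in decodability.
- **Behavior** — `fit_mixture()`: maximum-likelihood fit of the
  two-parameter mixture model for 2AFC orientation judgments,
  `P(cw | delta) = g/2 + (1 - g) * pnorm(delta / sigma)`, with the usual
  `print`/`summary`/`coef`/`predict`/`simulate`/`plot` methods;
  `compare_conditions()` runs the paired short-vs-long t-tests.
- **Orchestration** — `pipeline_config()` + `run_pipeline()` run the whole
  simulated experiment end-to-end and write plain-text artifacts.

## A worked example

Simulate one participant at reduced scale, preprocess, and decode the
memory and impulse epochs:

```r
library(impulsewm)

design <- wm_design(n_short = 60, n_early = 30, n_late = 30, seed = 1)
sim <- generate_epochs(design)

long <- smooth_gaussian(baseline_correct(sim$long), sd_ms = 8)
tc_mem <- loo_discrimination(long, window = c(-200, 1100))
tc_mem
#> <discrim_tc> multivariate, 60 trials, 326 time points (-200..1100 ms)
#>   mean discrimination: peak 28.78 at 100 ms

imp <- reepoch_impulse(long)
tc_imp <- loo_discrimination(imp, window = c(-100, 600))
mean(tc_imp$mean[tc_imp$time_ms >= 100 & tc_imp$time_ms <= 400])
#> [1] 12.38751
```

Discrimination rises steeply during memory-item encoding, decays toward
zero through the delay, and re-emerges after the impulse — the qualitative
signature the paradigm predicts. The values are Mahalanobis distance
differences in arbitrary units; zero means no orientation information.

Fit the behavioral mixture model to simulated 2AFC responses:

```r
trials <- generate_behavior(sim$trials, g = 0.074, sigma = 4.272, seed = 2)
fit <- fit_mixture(data = trials)
fit
#> 2AFC mixture model fit
#>   g = 0.0696, sigma = 5.900 deg  (n = 120, logLik = -33.54)
```

(With only 120 trials the fit is noisy; the recovery tests in
`tests/testthat/` and the acceptance script use 800 trials per fit.)

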