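# Shared fixture builders. All randomness is seeded locally so fixtures are
# reproducible and independent of test order.

# minimal trial-count design for fast end-to-end runs
tiny_design <- function(...) {
  args <- list(...)
  defaults <- list(n_channels = 8L, n_short = 24L, n_early = 12L,
                   n_late = 12L, seed = 7L)
  do.call(wm_design, utils::modifyList(defaults, args))
}

# epoch_set with pure noise and a balanced set of orientations
noise_epochs <- function(n = 24, p = 8, t_ms = seq(-100, 300, 4), seed = 1,
                         sd = 1) {
  set.seed(seed)
  ori <- as.numeric(seq(0, 179, length.out = n) %% 180)
  epoch_set(array(rnorm(n * p * length(t_ms), sd = sd),
                  dim = c(n, p, length(t_ms))),
            t_ms, paste0("ch", seq_len(p)),
            data.frame(trial_id = seq_len(n), orientation_deg = ori))
}

# epoch_set carrying an orientation-tuned spatial pattern inside a time
# window; `pattern` is p x 2 (projections of cos2t / sin2t components);
# zero-channel-mean patterns let univariate controls stay silent
patterned_epochs <- function(n = 32, p = 8, t_ms = seq(-100, 500, 4),
                             window = c(100, 300), amp = 2, noise = 0.5,
                             pattern = NULL, seed = 2) {
  set.seed(seed)
  if (is.null(pattern)) {
    pattern <- matrix(rnorm(p * 2), p, 2)
    pattern <- sweep(pattern, 2, colMeans(pattern))  # zero channel mean
  }
  ori <- as.numeric(seq(0, 179, length.out = n) %% 180)
  tune <- cbind(cos(2 * ori * pi / 180), sin(2 * ori * pi / 180))
  env <- as.numeric(t_ms >= window[1] & t_ms <= window[2])
  arr <- array(rnorm(n * p * length(t_ms), sd = noise),
               dim = c(n, p, length(t_ms)))
  for (i in seq_len(n)) {
    sig <- amp * (pattern %*% tune[i, ]) %*% t(env)
    arr[i, , ] <- arr[i, , ] + sig
  }
  epoch_set(arr, t_ms, paste0("ch", seq_len(p)),
            data.frame(trial_id = seq_len(n), orientation_deg = ori))
}
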