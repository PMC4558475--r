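#' Design of a synthetic working-memory EEG experiment
#'
#' Bundles every tunable of the synthetic generator with the defaults of the
#' emulated task: 17 posterior channels at 250 Hz, 1600 trials split
#' 800 short / 400 early-impulse / 400 late-impulse, memory item at 0 ms for
#' 200 ms, impulse at 1170 ms (early) or 1230 ms (late), probe offsets drawn
#' from the fixed +/-{4,5,7,9,12,15,20,26,34,45} degree set.
#'
#' The orientation signal lives in a two-dimensional tuning subspace:
#' (cos 2 theta, sin 2 theta) projected onto two orthonormal channel
#' patterns, so orthogonal orientations map to maximally separated patterns.
#' With `dynamics = "dynamic"` the pair of patterns drifts smoothly through
#' channel space as a function of time since its driving stimulus (memory
#' item or impulse): each pattern is a Gaussian process over time with
#' squared-exponential correlation length `pattern_drift_tau` ms,
#' orthonormalized at every sample. This produces the diagonal-dominant
#' cross-temporal generalization and temporally selective decoders that
#' fast evoked dynamics produce in real recordings; `"static"` keeps the
#' patterns fixed. The impulse-evoked pattern sequence is independent of
#' the encoding sequence unless `shared_code = TRUE`, in which case the
#' impulse re-plays the encoding patterns time-locked to its own onset.
#'
#' @param n_channels number of channels (>= 8; default 17).
#' @param sample_rate sampling rate in Hz; only 250 is supported.
#' @param n_short,n_early,n_late trial counts per condition (all > 0).
#' @param memory_onset_ms,memory_duration_ms memory item timing (ms).
#' @param impulse_onsets_ms length-2 vector, early and late impulse onset in
#'   ms after memory onset.
#' @param encode_amplitude,impulse_amplitude peak microvolt scale of the
#'   orientation-tuned encoding and impulse-evoked patterns (>= 0).
#' @param encode_decay_tau exponential decay constant (ms) of the encoding
#'   pattern after memory item offset.
#' @param dynamics `"dynamic"` (drifting patterns) or `"static"`.
#' @param pattern_drift_tau correlation length in ms of the pattern drift
#'   under `dynamics = "dynamic"`; patterns separated by this much time
#'   share about 60 percent of their overlap.
#' @param shared_code if `TRUE` the impulse response reuses the late
#'   encoding pattern instead of an independent one (default `FALSE`).
#' @param noise_spatial_corr AR(1) correlation between neighbouring
#'   channels, in [0, 1).
#' @param noise_sd per-sample, per-channel noise SD in microvolts (> 0).
#' @param seed integer seed; all randomness of [generate_epochs()] flows
#'   from it.
#' @return An object of class `wm_design` (a validated list).
#' @export
wm_design <- function(n_channels = 17L, sample_rate = 250,
                      n_short = 800L, n_early = 400L, n_late = 400L,
                      memory_onset_ms = 0, memory_duration_ms = 200,
                      impulse_onsets_ms = c(1170, 1230),
                      encode_amplitude = 1.0, impulse_amplitude = 0.8,
                      encode_decay_tau = 300,
                      dynamics = c("dynamic", "static"),
                      pattern_drift_tau = 50,
                      shared_code = FALSE,
                      noise_spatial_corr = 0.5, noise_sd = 1.0,
                      seed = 0L) {
  dynamics <- match.arg(dynamics)
  if (n_channels < 8L)
    stop("n_channels must be >= 8 (the tuning subspace is 8-dimensional)",
         call. = FALSE)
  if (sample_rate != 250)
    stop("only the 250 Hz (4 ms) sampling grid is supported", call. = FALSE)
  counts <- c(n_short = n_short, n_early = n_early, n_late = n_late)
  if (any(counts <= 0))
    stop("trial counts must all be positive", call. = FALSE)
  if (encode_amplitude < 0 || impulse_amplitude < 0)
    stop("amplitudes must be non-negative", call. = FALSE)
  if (encode_decay_tau <= 0) stop("encode_decay_tau must be > 0", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (noise_spatial_corr < 0 || noise_spatial_corr >= 1)
    stop("noise_spatial_corr must be in [0, 1)", call. = FALSE)
  if (length(impulse_onsets_ms) != 2L || diff(impulse_onsets_ms) <= 0)
    stop("impulse_onsets_ms must be an increasing pair", call. = FALSE)
  if (any(impulse_onsets_ms %% 2 != 0))
    stop("impulse onsets must be whole multiples of 2 ms", call. = FALSE)
  if (pattern_drift_tau <= 0)
    stop("pattern_drift_tau must be > 0", call. = FALSE)
  structure(list(n_channels = as.integer(n_channels), sample_rate = 250,
                 n_short = as.integer(n_short), n_early = as.integer(n_early),
                 n_late = as.integer(n_late),
                 memory_onset_ms = memory_onset_ms,
                 memory_duration_ms = memory_duration_ms,
                 impulse_onsets_ms = impulse_onsets_ms,
                 encode_amplitude = encode_amplitude,
                 impulse_amplitude = impulse_amplitude,
                 encode_decay_tau = encode_decay_tau,
                 dynamics = dynamics,
                 pattern_drift_tau = pattern_drift_tau,
                 shared_code = isTRUE(shared_code),
                 noise_spatial_corr = noise_spatial_corr,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "wm_design")
}

#' @export
print.wm_design <- function(x, ...) {
  cat(sprintf(paste0("<wm_design> %d channels, %d short / %d early / %d late",
                     " trials, %s code, seed %d\n"),
              x$n_channels, x$n_short, x$n_early, x$n_late, x$dynamics,
              x$seed))
  invisible(x)
}

# The 20 probe offsets of the 2AFC task (degrees).
probe_deltas <- function() {
  d <- c(4, 5, 7, 9, 12, 15, 20, 26, 34, 45)
  c(-rev(d), d)
}

# run code under a local RNG state derived from `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# smooth encoding envelope: fast rise during presentation, exponential
# decay with tau after offset
encode_envelope <- function(t, dur, tau) {
  env <- numeric(length(t))
  on_item <- t >= 0 & t <= dur
  env[on_item] <- 1 - exp(-t[on_item] / 30)
  late <- t > dur
  env[late] <- (1 - exp(-dur / 30)) * exp(-(t[late] - dur) / tau)
  env
}

# impulse-evoked envelope: gamma-like bump peaking 200 ms after onset
impulse_envelope <- function(s) {
  env <- numeric(length(s))
  pos <- s > 0
  env[pos] <- (s[pos] / 200) * exp(1 - s[pos] / 200)
  env
}

# Smoothly drifting orthonormal pattern pair: two p-channel Gaussian
# processes over the grid `s_grid` (squared-exponential kernel, length
# `l_ms`), Gram-Schmidt orthonormalized at every sample.  Consumes RNG
# draws; call inside with_seed().
drifting_patterns <- function(p, s_grid, l_ms) {
  K <- exp(-outer(s_grid, s_grid, "-")^2 / (2 * l_ms^2))
  diag(K) <- diag(K) + 1e-6
  L <- chol(K)
  raw1 <- matrix(rnorm(p * length(s_grid)), p) %*% L
  raw2 <- matrix(rnorm(p * length(s_grid)), p) %*% L
  w1 <- raw1 / rep(sqrt(colSums(raw1^2)), each = p)
  b <- raw2 - w1 * rep(colSums(w1 * raw2), each = p)
  w2 <- b / rep(sqrt(colSums(b^2)), each = p)
  list(w1 = w1, w2 = w2, s_grid = s_grid)
}

# evaluate a pattern table at times `s` (exact grid matches required where
# `active`); returns p x length(s) matrices, zero columns where !active
eval_patterns <- function(tab, s, active) {
  p <- nrow(tab$w1)
  w1 <- matrix(0, p, length(s))
  w2 <- matrix(0, p, length(s))
  idx <- match(round(s[active], 6), tab$s_grid)
  if (anyNA(idx)) stop("pattern table does not cover requested times")
  w1[, active] <- tab$w1[, idx]
  w2[, active] <- tab$w2[, idx]
  list(w1 = w1, w2 = w2)
}

#' Generate synthetic EEG epochs and a trial table
#'
#' Simulates one participant's memory-item-locked epochs: short trials span
#' -200..1400 ms and long (impulse) trials -200..2800 ms. Each trial carries
#' an orientation-tuned low-rank pattern (rising during item presentation,
#' decaying in the delay with `encode_decay_tau`); long trials additionally
#' carry an impulse-evoked orientation-dependent pattern time-locked to that
#' trial's true impulse onset. Spatially correlated Gaussian noise (AR(1)
#' across channels) is added everywhere. The output is bit-reproducible
#' from `design$seed`.
#'
#' @param design a [wm_design()].
#' @return A list of class `wm_sim` with elements `short` and `long`
#'   (both [epoch_set()]s, memory-item-locked), `trials` (the full trial
#'   table) and `design`.
#' @export
generate_epochs <- function(design) {
  stopifnot(inherits(design, "wm_design"))
  p <- design$n_channels
  n_long <- design$n_early + design$n_late
  n_tot <- design$n_short + n_long
  t_short <- seq(-200, 1400, by = 4)
  t_long <- seq(-200, 2800, by = 4)

  with_seed(design$seed, {
    # trial conditions randomized across the session
    type <- sample(rep(c("short", "early", "late"),
                       c(design$n_short, design$n_early, design$n_late)))
    onset <- ifelse(type == "early", design$impulse_onsets_ms[1L],
                    ifelse(type == "late", design$impulse_onsets_ms[2L],
                           NA_real_))
    trials <- data.frame(
      trial_id = seq_len(n_tot),
      orientation_deg = runif(n_tot, 0, 180),
      trial_type = ifelse(type == "short", "short", "long"),
      impulse_onset_ms = onset,
      probe_delta_deg = sample(probe_deltas(), n_tot, replace = TRUE),
      response = NA_character_,
      stringsAsFactors = FALSE)

    theta2 <- 2 * trials$orientation_deg * pi / 180
    tune <- cbind(cos(theta2), sin(theta2))          # n_tot x 2
    dyn <- design$dynamics == "dynamic"
    drift <- design$pattern_drift_tau

    # pattern tables on a 2 ms grid of time-since-stimulus (the impulse
    # onsets sit 2 ms off the 4 ms sample grid): static codes are constant
    # orthonormal pairs; dynamic codes drift smoothly
    t_max <- 2800
    enc_grid <- seq(-200, t_max, by = 2)
    if (dyn) {
      enc_tab <- drifting_patterns(p, enc_grid, drift)
      imp_tab <- if (design$shared_code) enc_tab else
        drifting_patterns(p, enc_grid, drift)
    } else {
      basis <- qr.Q(qr(matrix(rnorm(p * 4L), p, 4L)))
      const_tab <- function(cols) list(
        w1 = matrix(basis[, cols[1L]], p, length(enc_grid)),
        w2 = matrix(basis[, cols[2L]], p, length(enc_grid)),
        s_grid = enc_grid)
      enc_tab <- const_tab(c(1L, 2L))
      imp_tab <- if (design$shared_code) enc_tab else const_tab(c(3L, 4L))
    }

    chol_R <- chol(design$noise_spatial_corr ^
                     abs(outer(seq_len(p), seq_len(p), "-")))

    make_block <- function(idx, t_axis) {
      n <- length(idx)
      arr <- array(0, dim = c(n, p, length(t_axis)))
      env_e <- encode_envelope(t_axis, design$memory_duration_ms,
                               design$encode_decay_tau)
      pat <- eval_patterns(enc_tab, t_axis, env_e > 0)
      w1e <- pat$w1 * rep(env_e, each = p)   # p x T, envelope applied
      w2e <- pat$w2 * rep(env_e, each = p)
      # impulse pattern-times-envelope, precomputed per distinct onset
      vlist <- list()
      for (on in unique(trials$impulse_onset_ms[idx])) {
        if (is.na(on)) next
        s <- t_axis - on
        env_i <- impulse_envelope(s)
        vpat <- eval_patterns(imp_tab, s, env_i > 0)
        vlist[[as.character(on)]] <- list(
          v1 = vpat$w1 * rep(env_i, each = p),
          v2 = vpat$w2 * rep(env_i, each = p))
      }
      # signal: amp * env(t) * (cos2t * w1(t) + sin2t * w2(t))
      for (k in seq_len(n)) {
        i <- idx[k]
        sig <- design$encode_amplitude *
          (w1e * tune[i, 1L] + w2e * tune[i, 2L])
        if (!is.na(trials$impulse_onset_ms[i])) {
          v <- vlist[[as.character(trials$impulse_onset_ms[i])]]
          sig <- sig + design$impulse_amplitude *
            (v$v1 * tune[i, 1L] + v$v2 * tune[i, 2L])
        }
        noise <- design$noise_sd *
          crossprod(chol_R, matrix(rnorm(p * length(t_axis)), p))
        arr[k, , ] <- sig + noise
      }
      arr
    }

    idx_short <- which(trials$trial_type == "short")
    idx_long <- which(trials$trial_type == "long")
    short_arr <- make_block(idx_short, t_short)
    long_arr <- make_block(idx_long, t_long)

    structure(list(
      short = epoch_set(short_arr, t_short, paste0("ch", seq_len(p)),
                        trials[idx_short, , drop = FALSE]),
      long = epoch_set(long_arr, t_long, paste0("ch", seq_len(p)),
                       trials[idx_long, , drop = FALSE]),
      trials = trials, design = design), class = "wm_sim")
  })
}

#' @export
print.wm_sim <- function(x, ...) {
  cat(sprintf("<wm_sim> %d short + %d long trials, %d channels, seed %d\n",
              n_trials(x$short), n_trials(x$long), x$design$n_channels,
              x$design$seed))
  invisible(x)
}

#' Simulate 2AFC responses from the mixture model
#'
#' Draws clockwise/counter-clockwise responses for each trial from the
#' two-parameter mixture model: with probability `g` the response is a pure
#' guess (cw with probability 1/2); otherwise the remembered orientation
#' carries Gaussian noise with SD `sigma`, so
#' `P(cw | delta) = g/2 + (1 - g) * pnorm(delta / sigma)`.
#'
#' @param trials a trial table with a `probe_delta_deg` column.
#' @param g guess rate between 0 and 1.
#' @param sigma memory SD in degrees (> 0).
#' @param seed integer seed.
#' @return `trials` with its `response` column filled with `"cw"`/`"ccw"`.
#' @export
generate_behavior <- function(trials, g, sigma, seed = 0L) {
  if (g < 0 || g > 1) stop("g must be in [0, 1]", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (!"probe_delta_deg" %in% names(trials))
    stop("trials must have a probe_delta_deg column", call. = FALSE)
  with_seed(seed, {
    p_cw <- g / 2 + (1 - g) * pnorm(trials$probe_delta_deg / sigma)
    trials$response <- ifelse(rbinom(nrow(trials), 1L, p_cw) == 1L,
                              "cw", "ccw")
    trials
  })
}
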