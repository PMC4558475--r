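#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean voltage over the baseline
#' window. The window is half-open (`[from, to)`), so the default
#' `c(-200, 0)` uses the 200 ms before memory item onset and excludes the
#' onset sample itself.
#'
#' @param epochs an [epoch_set()].
#' @param window length-2 numeric, baseline window in ms (half-open).
#' @return The baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- window_idx(epochs$time_ms, window[1L], window[2L])
  base <- apply(epochs$data[, , idx, drop = FALSE], c(1L, 2L), mean)
  epochs$data <- epochs$data - as.vector(base)  # recycles over time (dim 3)
  epochs
}

#' Gaussian temporal smoothing
#'
#' Convolves every channel trace with a unit-sum Gaussian kernel along the
#' time axis only. The kernel is truncated at +/- 4 SD and renormalized;
#' epoch edges are handled by reflection so constant traces pass through
#' unchanged everywhere.
#'
#' @param epochs an [epoch_set()].
#' @param sd_ms kernel standard deviation in ms (> 0); default 8 ms
#'   (2 samples at 250 Hz).
#' @return The smoothed `epoch_set`.
#' @export
smooth_gaussian <- function(epochs, sd_ms = 8) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (sd_ms <= 0) stop("sd_ms must be > 0", call. = FALSE)
  sd_samp <- sd_ms / 4
  h <- ceiling(4 * sd_samp)
  k <- exp(-0.5 * ((-h:h) / sd_samp)^2)
  k <- k / sum(k)

  d <- dim(epochs$data)
  n_t <- d[3L]
  if (n_t < h + 1L)
    stop("epoch too short for the requested kernel", call. = FALSE)
  flat <- matrix(epochs$data, nrow = d[1L] * d[2L], ncol = n_t)
  # reflection padding: sample indices h..1 | 1..T | T..T-h+1
  pad_idx <- c(rev(seq_len(h) + 1L), seq_len(n_t),
               n_t - seq_len(h))
  padded <- flat[, pad_idx, drop = FALSE]
  out <- matrix(0, nrow(flat), n_t)
  for (o in seq_along(k))
    out <- out + k[o] * padded[, (o - 1L) + seq_len(n_t), drop = FALSE]
  epochs$data <- array(out, dim = d)
  epochs
}

#' Re-epoch long trials to impulse-locked time
#'
#' Re-zeroes each long trial's time axis at that trial's impulse onset and
#' crops to `window`. Onsets that fall between samples of the 4 ms grid are
#' aligned to the nearest sample, ties resolved toward the earlier sample
#' (so the default 1170/1230 ms onsets align to the 1168/1228 ms samples,
#' preserving their 60 ms separation exactly).
#'
#' @param epochs a memory-item-locked [epoch_set()] of long trials (every
#'   trial must have a non-missing `impulse_onset_ms`).
#' @param window length-2 numeric, output epoch span in ms relative to
#'   impulse onset (default `c(-200, 1400)`, inclusive).
#' @return An impulse-locked `epoch_set`.
#' @export
reepoch_impulse <- function(epochs, window = c(-200, 1400)) {
  stopifnot(inherits(epochs, "epoch_set"))
  onsets <- epochs$trials$impulse_onset_ms
  if (any(is.na(onsets)))
    stop("all trials must be long trials with a known impulse onset",
         call. = FALSE)
  t_out <- seq(window[1L], window[2L], by = 4)
  rel_idx <- t_out / 4
  d <- dim(epochs$data)
  out <- array(0, dim = c(d[1L], d[2L], length(t_out)))
  for (i in seq_len(d[1L])) {
    i0 <- nearest_sample(epochs$time_ms, onsets[i])
    idx <- i0 + rel_idx
    if (idx[1L] < 1L || idx[length(idx)] > d[3L])
      stop(sprintf("trial %d: window outside the source epoch", i),
           call. = FALSE)
    out[i, , ] <- epochs$data[i, , idx]
  }
  epoch_set(out, t_out, epochs$channels, epochs$trials)
}

#' Select and reorder channels
#'
#' @param epochs an [epoch_set()].
#' @param names channel names to keep, in the requested output order;
#'   defaults to the 17-channel posterior set ([posterior_17]).
#' @return An `epoch_set` restricted to the requested channels.
#' @export
select_channels <- function(epochs, names = posterior_17) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!length(names)) stop("empty channel selection", call. = FALSE)
  pos <- match(names, epochs$channels)
  if (anyNA(pos))
    stop("unknown channel(s): ", paste(names[is.na(pos)], collapse = ", "),
         call. = FALSE)
  epoch_set(epochs$data[, pos, , drop = FALSE], epochs$time_ms,
            epochs$channels[pos], epochs$trials)
}

#' Flag high-amplitude trials
#'
#' Optional stand-in for manual artifact screening: flags trials whose
#' peak-to-peak amplitude on any channel exceeds a threshold. Flagged trials
#' are marked in the metadata (`artifact` column), never dropped.
#'
#' @param epochs an [epoch_set()].
#' @param threshold_uv peak-to-peak threshold in microvolts.
#' @return `epochs` with a logical `artifact` column added to its trial
#'   table.
#' @export
flag_artifacts <- function(epochs, threshold_uv = 150) {
  stopifnot(inherits(epochs, "epoch_set"))
  ptp <- apply(epochs$data, c(1L, 2L), function(v) max(v) - min(v))
  epochs$trials$artifact <- apply(ptp, 1L, max) > threshold_uv
  epochs
}

#' Crop an epoch set to a time window
#'
#' @param epochs an [epoch_set()].
#' @param window length-2 numeric in ms, inclusive.
#' @return The cropped `epoch_set`.
#' @export
crop_epochs <- function(epochs, window) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- which(epochs$time_ms >= window[1L] & epochs$time_ms <= window[2L])
  if (!length(idx)) stop("window outside epoch time range", call. = FALSE)
  epoch_set(epochs$data[, , idx, drop = FALSE], epochs$time_ms[idx],
            epochs$channels, epochs$trials)
}

#' Concatenate two epoch sets trial-wise
#'
#' Both inputs must share the channel set and time axis.
#'
#' @param a,b [epoch_set()]s.
#' @return The combined `epoch_set`.
#' @export
combine_epochs <- function(a, b) {
  stopifnot(inherits(a, "epoch_set"), inherits(b, "epoch_set"))
  if (!identical(a$channels, b$channels))
    stop("channel sets differ", call. = FALSE)
  if (!isTRUE(all.equal(a$time_ms, b$time_ms)))
    stop("time axes differ", call. = FALSE)
  da <- dim(a$data); db <- dim(b$data)
  out <- array(0, dim = c(da[1L] + db[1L], da[2L], da[3L]))
  out[seq_len(da[1L]), , ] <- a$data
  out[da[1L] + seq_len(db[1L]), , ] <- b$data
  common <- intersect(names(a$trials), names(b$trials))
  epoch_set(out, a$time_ms, a$channels,
            rbind(a$trials[common], b$trials[common]))
}
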