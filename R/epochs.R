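#' The 17 posterior channels used for orientation decoding
#'
#' Standard 10-20 labels of the posterior channel set the analyses are
#' restricted to (parietal, parieto-occipital and occipital rows).
#'
#' @format Character vector of length 17.
#' @export
posterior_17 <- c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
                  "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2")

#' Construct an epoched EEG data set
#'
#' An `epoch_set` is the universal currency of the pipeline: a numeric
#' trials x channels x time array in microvolts, a strictly increasing time
#' axis in milliseconds relative to the locking event (4 ms steps, 250 Hz),
#' channel names, and a per-trial metadata table.
#'
#' @param data numeric array, trials x channels x time (microvolts).
#' @param time_ms numeric vector of per-sample times in ms; must be strictly
#'   increasing with a constant 4 ms step.
#' @param channels character vector of channel names, one per channel.
#' @param trials data frame of trial metadata with one row per trial;
#'   expected columns include `trial_id`, `orientation_deg`, `trial_type`,
#'   `impulse_onset_ms`, `probe_delta_deg`, `response` (extra columns pass
#'   through untouched).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, time_ms, channels, trials) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a trials x channels x time array", call. = FALSE)
  d <- dim(data)
  if (length(channels) != d[2L])
    stop("length(channels) must match dim(data)[2]", call. = FALSE)
  if (length(time_ms) != d[3L])
    stop("length(time_ms) must match dim(data)[3]", call. = FALSE)
  steps <- diff(time_ms)
  if (length(steps) && (any(steps <= 0) || max(abs(steps - 4)) > 1e-9))
    stop("time axis must increase in 4 ms steps (250 Hz)", call. = FALSE)
  if (!is.data.frame(trials) || nrow(trials) != d[1L])
    stop("`trials` must be a data frame with one row per trial", call. = FALSE)
  structure(list(data = data, time_ms = as.numeric(time_ms),
                 channels = as.character(channels), trials = trials),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  time: %g..%g ms (4 ms steps)\n",
              x$time_ms[1L], x$time_ms[length(x$time_ms)]))
  cat("  channels:", paste(head(x$channels, 8L), collapse = ", "),
      if (length(x$channels) > 8L) "...", "\n")
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Number of trials in an epoch set
#' @param epochs an `epoch_set`.
#' @return Integer trial count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1L]

# internal: subset trials, keeping metadata aligned
subset_trials <- function(epochs, keep) {
  epoch_set(epochs$data[keep, , , drop = FALSE], epochs$time_ms,
            epochs$channels, epochs$trials[keep, , drop = FALSE])
}

# internal: index of the sample nearest to `ms` (ties toward the earlier
# sample, the package-wide rounding rule for off-grid event times)
nearest_sample <- function(time_ms, ms) {
  d <- abs(time_ms - ms)
  which(d == min(d))[1L]
}

# internal: indices of samples with from <= t < to (half-open window)
window_idx <- function(time_ms, from, to) {
  idx <- which(time_ms >= from & time_ms < to)
  if (!length(idx))
    stop(sprintf("window [%g, %g) outside epoch time range [%g, %g]",
                 from, to, time_ms[1L], time_ms[length(time_ms)]),
         call. = FALSE)
  idx
}

#' Write an epoch set as a plain-text directory
#'
#' Serializes an `epoch_set` to a directory of text files: `data.csv`
#' (trials x channels rows by time columns, row names `trial.channel`),
#' `time_ms.csv`, `channels.csv` and `trials.csv`. This layout is the
#' package's on-disk interchange format; [read_epochs()] inverts it.
#'
#' @param epochs an `epoch_set`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(2L, 1L, 3L)), nrow = d[1L] * d[2L])
  write.csv(flat, file.path(dir, "data.csv"), row.names = FALSE)
  write.csv(data.frame(time_ms = epochs$time_ms),
            file.path(dir, "time_ms.csv"), row.names = FALSE)
  write.csv(data.frame(channel = epochs$channels),
            file.path(dir, "channels.csv"), row.names = FALSE)
  write.csv(epochs$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param dir directory containing `data.csv`, `time_ms.csv`,
#'   `channels.csv` and `trials.csv`.
#' @return An `epoch_set`.
#' @export
read_epochs <- function(dir) {
  time_ms <- read.csv(file.path(dir, "time_ms.csv"))$time_ms
  channels <- read.csv(file.path(dir, "channels.csv"))$channel
  trials <- read.csv(file.path(dir, "trials.csv"))
  flat <- as.matrix(read.csv(file.path(dir, "data.csv")))
  n_ch <- length(channels)
  n_tr <- nrow(flat) / n_ch
  arr <- aperm(array(flat, dim = c(n_ch, n_tr, length(time_ms))),
               c(2L, 1L, 3L))
  epoch_set(arr, time_ms, channels, trials)
}
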