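#' Cross-temporal (and cross-epoch) generalization matrix
#'
#' Extends the leave-one-trial-out Mahalanobis analysis by decoupling the
#' training and testing time points: training means and pooled shrunk
#' precision computed at train time Y are applied to test vectors at test
#' time X, for every (Y, X) combination. When both epoch sets hold the same
#' trials (within-epoch analysis, or memory vs impulse epochs of the same
#' long trials) the test trial is excluded from the training statistics at
#' every train time; with disjoint trial sets no exclusion is needed.
#'
#' @param train,test [epoch_set()]s. Channel sets must match. If their
#'   trial tables share `trial_id`s in the same order, the leave-one-out
#'   path is used; if the trial sets are disjoint, the independent path.
#' @param train_window,test_window optional ms windows (inclusive)
#'   restricting the two time axes.
#' @param stride integer sub-sampling of both time grids (default 1 = the
#'   native 4 ms grid).
#' @param shrinkage optional fixed shrinkage intensity (default analytic).
#' @param tol pseudoinverse eigenvalue tolerance.
#' @return An object of class `gen_matrix`: list with `values`
#'   (train times x test times), `train_time_ms`, `test_time_ms`,
#'   `same_trials`, `n_trials`.
#' @export
generalization_matrix <- function(train, test = train,
                                  train_window = NULL, test_window = NULL,
                                  stride = 1L, shrinkage = NULL,
                                  tol = 1e-12) {
  stopifnot(inherits(train, "epoch_set"), inherits(test, "epoch_set"))
  if (length(train$channels) != length(test$channels))
    stop("channel sets differ between train and test", call. = FALSE)
  sel <- function(e, w) {
    idx <- if (is.null(w)) seq_along(e$time_ms) else
      which(e$time_ms >= w[1L] & e$time_ms <= w[2L])
    if (!length(idx)) stop("window outside epoch time range", call. = FALSE)
    idx[seq(1L, length(idx), by = stride)]
  }
  tr_idx <- sel(train, train_window)
  te_idx <- sel(test, test_window)

  same <- identical(train$trials$trial_id, test$trials$trial_id)
  if (!same && length(intersect(train$trials$trial_id,
                                test$trials$trial_id)))
    stop("trial sets must be identical (aligned) or disjoint", call. = FALSE)

  n_tr <- length(tr_idx); n_te <- length(te_idx)
  values <- matrix(0, n_tr, n_te)
  # chunk train times so the per-call result stays small
  chunk <- max(1L, floor(4e6 / max(1L, n_trials(test) * n_te)))
  starts <- seq(1L, n_tr, by = chunk)
  ori_train <- train$trials$orientation_deg

  for (s in starts) {
    rows <- s:min(s + chunk - 1L, n_tr)
    pairs <- cbind(rep(seq_along(rows), each = n_te), rep(seq_len(n_te), length(rows)))
    tr_cube <- as_cube(train, tr_idx[rows])
    te_cube <- as_cube(test, te_idx)
    if (same) {
      res <- run_comparisons(tr_cube, te_cube, ori_train, pairs, tol,
                             shrinkage)
      values[rows, ] <- matrix(res$mean, nrow = length(rows), byrow = TRUE)
    } else {
      values[rows, ] <- dd_independent(tr_cube, ori_train, te_cube,
                                       test$trials$orientation_deg, pairs,
                                       tol, shrinkage, length(rows), n_te)
    }
  }
  structure(list(values = values, train_time_ms = train$time_ms[tr_idx],
                 test_time_ms = test$time_ms[te_idx], same_trials = same,
                 n_trials = n_trials(test)),
            class = "gen_matrix")
}

# internal: independent-trials generalization over the four comparisons,
# averaged over test-trial estimates; returns train x test matrix
dd_independent <- function(tr_cube, ori_train, te_cube, ori_test, pairs,
                           tol, shrinkage, n_row, n_col) {
  comps_tr <- comparison_sets(ori_train)
  comps_te <- comparison_sets(ori_test)
  lam <- if (is.null(shrinkage)) -1 else shrinkage
  total <- numeric(nrow(pairs))
  count <- 0L
  for (k in seq_along(comps_tr)) {
    ctr <- comps_tr[[k]]; cte <- comps_te[[k]]
    if (min(tabulate(ctr$lab, 2L)) < 2L)
      stop("training comparison with fewer than 2 trials per bin",
           call. = FALSE)
    if (!length(cte$idx)) next
    dd <- cpp_dd_train_test(tr_cube[ctr$idx, , , drop = FALSE], ctr$lab,
                            te_cube[cte$idx, , , drop = FALSE], cte$lab,
                            pairs, tol, lam)
    total <- total + colSums(dd)
    count <- count + length(cte$idx)
  }
  matrix(total / count, nrow = n_row, byrow = TRUE)
}

#' @export
print.gen_matrix <- function(x, ...) {
  cat(sprintf(paste0("<gen_matrix> %d train x %d test time points, ",
                     "%s trials (%d)\n"),
              nrow(x$values), ncol(x$values),
              if (x$same_trials) "shared" else "independent", x$n_trials))
  invisible(x)
}

#' @export
plot.gen_matrix <- function(x, ...) {
  graphics::image(x$train_time_ms, x$test_time_ms, x$values,
                  xlab = "train time (ms)", ylab = "test time (ms)", ...)
  invisible(x)
}

# internal: common machinery for shifted-training evaluation. Returns
# list(time_ms, values = shifts x time matrix of mean dd over the evaluated
# subset).
shifted_training_eval <- function(train, test, shifts, nominal_onset_ms,
                                  test_window, subset_ids, shrinkage, tol) {
  stopifnot(inherits(train, "epoch_set"), inherits(test, "epoch_set"))
  if (any(shifts %% 4 != 0))
    stop("shifts must lie on the 4 ms sample grid", call. = FALSE)
  if (!all(test$trials$trial_id %in% train$trials$trial_id))
    stop("test trials must be a subset of the training trials",
         call. = FALSE)
  pos <- match(test$trials$trial_id, train$trials$trial_id)

  # full-size test cube aligned to training trials; non-evaluated rows 0
  n <- n_trials(train)
  te_full <- array(0, dim = c(n, length(test$channels),
                              length(test$time_ms)))
  te_full[pos, , ] <- test$data
  eval_ids <- if (is.null(subset_ids)) test$trials$trial_id else subset_ids
  eval_rows <- match(eval_ids, train$trials$trial_id)

  # test times usable for every requested shift
  t_all <- if (is.null(test_window)) test$time_ms else
    test$time_ms[test$time_ms >= test_window[1L] &
                   test$time_ms <= test_window[2L]]
  ok <- vapply(t_all, function(t)
    all((t - nominal_onset_ms + shifts) %in% train$time_ms), logical(1L))
  t_use <- t_all[ok]
  if (!length(t_use))
    stop("no test times map into the training epoch for these shifts",
         call. = FALSE)

  te_slices <- match(t_use, test$time_ms)
  n_t <- length(t_use)
  pairs <- do.call(rbind, lapply(shifts, function(s)
    cbind(match(t_use - nominal_onset_ms + s, train$time_ms), te_slices)))

  res <- run_comparisons(train$data, te_full,
                         train$trials$orientation_deg, pairs, tol,
                         shrinkage, eval_idx = eval_rows)
  list(time_ms = t_use,
       values = matrix(res$mean, nrow = length(shifts), byrow = TRUE))
}

#' Discrimination time-course with shifted training times
#'
#' Trains at impulse-locked time `t - nominal_onset_ms + shift_ms` and
#' tests at memory-item-locked time `t`, i.e. extracts the cross-epoch
#' generalization entries along a diagonal offset by `shift_ms` from the
#' nominal impulse onset. The training set holds all impulse-locked long
#' trials; evaluation can be restricted to a trial subset (e.g. the
#' early-onset trials), with the evaluated trial always excluded from its
#' training statistics.
#'
#' @param train impulse-locked [epoch_set()] (all long trials).
#' @param test memory-item-locked [epoch_set()]; its trials must be a
#'   subset of `train`'s (matched by `trial_id`).
#' @param shift_ms training-time shift in ms (multiple of 4).
#' @param nominal_onset_ms the nominal impulse onset (ms after memory item)
#'   used to anchor the two time axes; default 1200, the mean of the early
#'   and late onsets.
#' @param test_window optional ms window (inclusive) on the test axis.
#' @param subset_ids optional `trial_id`s to evaluate (default: all trials
#'   of `test`).
#' @param shrinkage,tol as in [loo_discrimination()].
#' @return A `discrim_tc` over the memory-item-locked test axis.
#' @export
shifted_training_timecourse <- function(train, test, shift_ms,
                                        nominal_onset_ms = 1200,
                                        test_window = NULL,
                                        subset_ids = NULL,
                                        shrinkage = NULL, tol = 1e-12) {
  res <- shifted_training_eval(train, test, shift_ms, nominal_onset_ms,
                               test_window, subset_ids, shrinkage, tol)
  n_eval <- if (is.null(subset_ids)) n_trials(test) else length(subset_ids)
  structure(list(time_ms = res$time_ms, mean = res$values[1L, ],
                 per_trial = NULL, n_trials = n_eval,
                 mode = "shifted-training"),
            class = "discrim_tc")
}

#' Scan training-time shifts
#'
#' Evaluates [shifted_training_timecourse()] on a grid of shifts in one
#' pass and summarizes each shift by its mean discrimination over a
#' summary window. Ties for the best shift resolve toward the smallest
#' (most negative) shift.
#'
#' @inheritParams shifted_training_timecourse
#' @param shifts numeric vector of shifts in ms (multiples of 4).
#' @param summary_window ms window (inclusive, on the test axis) over which
#'   each shift's mean discrimination is taken; default the whole evaluated
#'   axis.
#' @return An object of class `shift_scan`: list with `shifts`, `time_ms`,
#'   `values` (shifts x time), `summary` (mean per shift) and `best_shift`.
#' @export
shifted_training_scan <- function(train, test, shifts = seq(-60, 60, by = 4),
                                  nominal_onset_ms = 1200,
                                  test_window = NULL, summary_window = NULL,
                                  subset_ids = NULL, shrinkage = NULL,
                                  tol = 1e-12) {
  res <- shifted_training_eval(train, test, shifts, nominal_onset_ms,
                               test_window, subset_ids, shrinkage, tol)
  use <- if (is.null(summary_window)) rep(TRUE, length(res$time_ms)) else
    res$time_ms >= summary_window[1L] & res$time_ms <= summary_window[2L]
  if (!any(use)) stop("summary window is empty", call. = FALSE)
  summ <- rowMeans(res$values[, use, drop = FALSE])
  structure(list(shifts = shifts, time_ms = res$time_ms,
                 values = res$values, summary = summ,
                 best_shift = shifts[which.max(summ)]),
            class = "shift_scan")
}

#' @export
print.shift_scan <- function(x, ...) {
  cat(sprintf("<shift_scan> shifts %g..%g ms, best shift %g ms\n",
              min(x$shifts), max(x$shifts), x$best_shift))
  invisible(x)
}

#' Lag correlation between early- and late-onset decoding time-courses
#'
#' For each participant, Pearson-correlates the early-onset discrimination
#' time-course over a fixed window with equal-length windows of the
#' late-onset time-course delayed by each lag, Fisher-z transforms the
#' correlations (r clamped to +/-(1 - 1e-12) so z stays finite), and
#' reports the group-mean z per lag. The peak lag is the argmax of the mean
#' z, ties resolved toward the smaller lag.
#'
#' @param early,late numeric matrices (participants x time) of
#'   discrimination values on a common memory-item-locked time axis.
#' @param time_ms the shared time axis in ms.
#' @param window length-2 ms window (inclusive) of the early time-course;
#'   default `c(1370, 2170)`.
#' @param lags numeric vector of lags in ms; default 0..120 in 4 ms steps
#'   (31 lags).
#' @return An object of class `lag_correlation`: list with `lags`, `r`
#'   (participants x lags), `z`, `mean_z`, `peak_lag_ms`, `window`.
#' @export
lag_correlation <- function(early, late, time_ms, window = c(1370, 2170),
                            lags = seq(0, 120, by = 4)) {
  early <- rbind(early); late <- rbind(late)
  if (ncol(early) != length(time_ms) || ncol(late) != length(time_ms))
    stop("time axis does not match the time-course matrices", call. = FALSE)
  if (nrow(early) != nrow(late))
    stop("early and late must have the same participants", call. = FALSE)
  base_idx <- which(time_ms >= window[1L] & time_ms <= window[2L])
  if (!length(base_idx)) stop("window outside time axis", call. = FALSE)
  step <- time_ms[2L] - time_ms[1L]
  if (any(lags %% step != 0))
    stop("lags must be multiples of the sampling step", call. = FALSE)
  max_off <- max(lags) / step
  if (max(base_idx) + max_off > length(time_ms))
    stop("time axis too short for the requested lags", call. = FALSE)

  n_sub <- nrow(early)
  r <- matrix(NA_real_, n_sub, length(lags))
  for (j in seq_along(lags)) {
    idx <- base_idx + lags[j] / step
    for (s in seq_len(n_sub))
      r[s, j] <- cor(early[s, base_idx], late[s, idx])
  }
  z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  mean_z <- colMeans(z)
  structure(list(lags = lags, r = r, z = z, mean_z = mean_z,
                 peak_lag_ms = lags[which.max(mean_z)], window = window),
            class = "lag_correlation")
}

#' @export
print.lag_correlation <- function(x, ...) {
  cat(sprintf(paste0("<lag_correlation> %d participants, lags %g..%g ms, ",
                     "peak at %g ms (mean z = %.3f)\n"),
              nrow(x$r), min(x$lags), max(x$lags), x$peak_lag_ms,
              max(x$mean_z)))
  invisible(x)
}

#' @export
plot.lag_correlation <- function(x, ...) {
  graphics::plot(x$lags, x$mean_z, type = "b", xlab = "lag (ms)",
                 ylab = "mean Fisher z", ...)
  graphics::abline(v = x$peak_lag_ms, lty = 3)
  invisible(x)
}
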