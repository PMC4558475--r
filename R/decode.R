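#' Assign orientations to the two 4-bin schemes
#'
#' Orientations in `[0, 180)` degrees are partitioned twice into four
#' 45-degree bins: scheme A at `[0,45), [45,90), [90,135), [135,180)` and
#' scheme B offset by 22.5 degrees, i.e. `[-22.5, 22.5), [22.5, 67.5),
#' [67.5, 112.5), [112.5, 157.5)` modulo 180. All intervals are half-open;
#' an orientation of exactly 157.5 wraps into scheme B's first bin.
#'
#' @param orientation_deg numeric vector of orientations in `[0, 180)`.
#' @return A data frame with integer columns `binA` and `binB` (1..4).
#' @export
assign_bins <- function(orientation_deg) {
  if (any(orientation_deg < 0 | orientation_deg >= 180))
    stop("orientations must lie in [0, 180)", call. = FALSE)
  data.frame(
    binA = as.integer(floor(orientation_deg / 45) %% 4L) + 1L,
    binB = as.integer(floor(((orientation_deg + 22.5) %% 180) / 45)) + 1L)
}

# The four orthogonal-pair comparisons: within each scheme, bins 1 vs 3 and
# bins 2 vs 4 (90 degrees apart). Returns, per comparison, the trial
# indices involved and their within-comparison label (1 or 2).
comparison_sets <- function(orientation_deg) {
  b <- assign_bins(orientation_deg)
  out <- list()
  for (scheme in c("binA", "binB")) {
    for (pair in list(c(1L, 3L), c(2L, 4L))) {
      idx <- which(b[[scheme]] %in% pair)
      out[[length(out) + 1L]] <- list(
        scheme = sub("bin", "", scheme), bins = pair, idx = idx,
        lab = ifelse(b[[scheme]][idx] == pair[1L], 1L, 2L))
    }
  }
  out
}

#' Pooled, shrunk error covariance and its pseudoinverse
#'
#' Pools the residual covariance of two training bins (residuals about each
#' bin's own mean, unbiased degrees-of-freedom weighting) and shrinks it
#' toward a scaled identity with an analytic intensity computed on the
#' pooled residuals:
#' `lambda = min(1, b2 / d2)` with `d2 = ||S - m I||_F^2 / p`,
#' `m = tr(S)/p`, and `b2 = (sum_j ||z_j||^4 - n ||S||_F^2) / (n^2 p)`
#' (clipped to `[0, d2]`), where `S` is the n-denominator pooled scatter of
#' the residuals `z_j`. The pseudoinverse zeroes eigenvalues below
#' `tol * max(eigenvalue)`.
#'
#' @param x1,x2 numeric matrices (trials x channels), the training trials
#'   of the two bins (>= 2 rows each).
#' @param shrinkage optional fixed shrinkage intensity in `[0, 1]`;
#'   `NULL` (default) uses the analytic intensity.
#' @param tol relative eigenvalue tolerance of the pseudoinverse.
#' @return An object of class `pooled_precision`: list with `covariance`,
#'   `precision` (the pseudoinverse), `shrinkage` and `df`.
#' @export
pooled_precision <- function(x1, x2, shrinkage = NULL, tol = 1e-12) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  if (nrow(x1) < 2L || nrow(x2) < 2L)
    stop("each bin needs at least 2 trials", call. = FALSE)
  if (ncol(x1) != ncol(x2))
    stop("bins must share the channel set", call. = FALSE)
  lam <- if (is.null(shrinkage)) -1 else {
    stopifnot(shrinkage >= 0, shrinkage <= 1)
    shrinkage
  }
  res <- cpp_pooled_precision(x1, x2, tol, lam)
  structure(res, class = "pooled_precision")
}

#' @export
print.pooled_precision <- function(x, ...) {
  cat(sprintf("<pooled_precision> %d channels, shrinkage %.4f, df %g\n",
              ncol(x$covariance), x$shrinkage, x$df))
  invisible(x)
}

#' Mahalanobis distance difference for one test vector
#'
#' The core single-trial statistic: the squared Mahalanobis distance from
#' the test vector to the orthogonal bin's training mean minus the distance
#' to its own bin's mean,
#' `(m_orth - x)' P (m_orth - x) - (m_same - x)' P (m_same - x)`.
#' Positive values indicate that the trial carries its bin's pattern.
#'
#' @param x numeric test vector (one value per channel).
#' @param mean_same,mean_orth training means of the test trial's own and
#'   orthogonal bin.
#' @param precision precision matrix (`pooled_precision$precision`, or any
#'   conformable symmetric matrix).
#' @return Scalar distance difference (arbitrary units).
#' @export
distance_difference <- function(x, mean_same, mean_orth, precision) {
  if (inherits(precision, "pooled_precision"))
    precision <- precision$precision
  x <- as.numeric(x)
  if (length(mean_same) != length(x) || length(mean_orth) != length(x) ||
      any(dim(precision) != length(x)))
    stop("non-conformable arguments", call. = FALSE)
  ds <- mean_same - x
  do <- mean_orth - x
  as.numeric(do %*% precision %*% do - ds %*% precision %*% ds)
}

# internal: run the LOO engine over the four comparisons and accumulate the
# per-(pair) average over all trial estimates. `pairs` is an integer matrix
# (train_slice, test_slice). Returns list(mean = numeric(npairs),
# per_trial = n x npairs matrix of per-trial averages or NULL).
run_comparisons <- function(train_cube, test_cube, orientation, pairs,
                            tol, shrinkage, eval_idx = NULL,
                            keep_trials = FALSE) {
  n <- dim(train_cube)[1L]
  comps <- comparison_sets(orientation)
  lam <- if (is.null(shrinkage)) -1 else shrinkage
  total <- numeric(nrow(pairs))
  count <- 0L
  per_trial <- if (keep_trials) matrix(0, n, nrow(pairs)) else NULL
  per_count <- integer(n)
  for (cmp in comps) {
    idx <- cmp$idx
    if (length(idx) < 6L || min(tabulate(cmp$lab, 2L)) < 3L)
      stop(sprintf("comparison %s %d-%d: each bin needs >= 3 trials",
                   cmp$scheme, cmp$bins[1L], cmp$bins[2L]), call. = FALSE)
    mask <- if (is.null(eval_idx)) rep(1L, length(idx)) else
      as.integer(idx %in% eval_idx)
    if (!any(mask == 1L)) next
    dd <- cpp_loo_dd(train_cube[idx, , , drop = FALSE],
                     test_cube[idx, , , drop = FALSE],
                     cmp$lab, pairs, tol, lam, mask)
    keep <- mask == 1L
    total <- total + colSums(dd[keep, , drop = FALSE])
    count <- count + sum(keep)
    if (keep_trials) {
      per_trial[idx[keep], ] <- per_trial[idx[keep], , drop = FALSE] +
        dd[keep, , drop = FALSE]
      per_count[idx[keep]] <- per_count[idx[keep]] + 1L
    }
  }
  if (keep_trials) {
    rows <- per_count > 0L
    per_trial[rows, ] <- per_trial[rows, , drop = FALSE] / per_count[rows]
  }
  list(mean = total / count, per_trial = per_trial, n_estimates = count)
}

# internal: epoch_set data as an (n, p, T) cube restricted to time indices
as_cube <- function(epochs, t_idx = NULL) {
  if (is.null(t_idx)) epochs$data else epochs$data[, , t_idx, drop = FALSE]
}

#' Leave-one-trial-out Mahalanobis discrimination time-course
#'
#' For every time point and each of the four orthogonal-bin comparisons,
#' computes for every trial the Mahalanobis distance difference between the
#' trial and the two training-bin means, with the test trial excluded from
#' the means and from the pooled shrunk error covariance. Each trial yields
#' one estimate per bin scheme (two in total); the time-course is the
#' average over all estimates and trials.
#'
#' @param epochs an [epoch_set()] whose trial table has `orientation_deg`.
#' @param window optional length-2 ms window restricting the time axis
#'   (inclusive); default uses every sample.
#' @param shrinkage optional fixed shrinkage intensity (default analytic).
#' @param tol pseudoinverse eigenvalue tolerance.
#' @param keep_trials keep the per-trial estimate matrix (trials x time)?
#' @return An object of class `discrim_tc`: list with `time_ms`, `mean`,
#'   `n_trials`, `mode`, and optionally `per_trial`.
#' @export
loo_discrimination <- function(epochs, window = NULL, shrinkage = NULL,
                               tol = 1e-12, keep_trials = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  t_idx <- if (is.null(window)) seq_along(epochs$time_ms) else
    which(epochs$time_ms >= window[1L] & epochs$time_ms <= window[2L])
  if (!length(t_idx)) stop("window outside epoch time range", call. = FALSE)
  cube <- as_cube(epochs, t_idx)
  pairs <- cbind(seq_along(t_idx), seq_along(t_idx))
  res <- run_comparisons(cube, cube, epochs$trials$orientation_deg, pairs,
                         tol, shrinkage, keep_trials = keep_trials)
  structure(list(time_ms = epochs$time_ms[t_idx], mean = res$mean,
                 per_trial = res$per_trial, n_trials = n_trials(epochs),
                 mode = "multivariate"),
            class = "discrim_tc")
}

#' Univariate discrimination time-course
#'
#' The amplitude-only control for [loo_discrimination()]: the statistic is
#' computed on the voltage averaged across all channels, as the absolute
#' difference between the test trial and the orthogonal bin's mean minus
#' the absolute difference to its own bin's mean, under the same
#' leave-one-trial-out scheme.
#'
#' @inheritParams loo_discrimination
#' @return A `discrim_tc` with `mode = "univariate"`.
#' @export
univariate_discrimination <- function(epochs, window = NULL,
                                      keep_trials = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  t_idx <- if (is.null(window)) seq_along(epochs$time_ms) else
    which(epochs$time_ms >= window[1L] & epochs$time_ms <= window[2L])
  if (!length(t_idx)) stop("window outside epoch time range", call. = FALSE)
  cm <- apply(epochs$data[, , t_idx, drop = FALSE], c(1L, 3L), mean)
  n <- nrow(cm)
  comps <- comparison_sets(epochs$trials$orientation_deg)
  total <- numeric(ncol(cm))
  count <- 0L
  per_trial <- if (keep_trials) matrix(0, n, ncol(cm)) else NULL
  per_count <- integer(n)
  for (cmp in comps) {
    x <- cm[cmp$idx, , drop = FALSE]
    lab <- cmp$lab
    n1 <- sum(lab == 1L); n2 <- sum(lab == 2L)
    if (n1 < 3L || n2 < 3L)
      stop(sprintf("comparison %s %d-%d: each bin needs >= 3 trials",
                   cmp$scheme, cmp$bins[1L], cmp$bins[2L]), call. = FALSE)
    s1 <- colSums(x[lab == 1L, , drop = FALSE])
    s2 <- colSums(x[lab == 2L, , drop = FALSE])
    m_own <- matrix(0, nrow(x), ncol(x))
    m_oth <- m_own
    i1 <- lab == 1L
    m_own[i1, ] <- (rep(s1, each = n1) - x[i1, ]) / (n1 - 1)
    m_oth[i1, ] <- rep(s2 / n2, each = n1)
    m_own[!i1, ] <- (rep(s2, each = n2) - x[!i1, ]) / (n2 - 1)
    m_oth[!i1, ] <- rep(s1 / n1, each = n2)
    dd <- abs(m_oth - x) - abs(m_own - x)
    total <- total + colSums(dd)
    count <- count + nrow(dd)
    if (keep_trials) {
      per_trial[cmp$idx, ] <- per_trial[cmp$idx, , drop = FALSE] + dd
      per_count[cmp$idx] <- per_count[cmp$idx] + 1L
    }
  }
  if (keep_trials) per_trial <- per_trial / pmax(per_count, 1L)
  structure(list(time_ms = epochs$time_ms[t_idx], mean = total / count,
                 per_trial = per_trial, n_trials = n, mode = "univariate"),
            class = "discrim_tc")
}

#' @export
print.discrim_tc <- function(x, ...) {
  cat(sprintf("<discrim_tc> %s, %d trials, %d time points (%g..%g ms)\n",
              x$mode, x$n_trials, length(x$time_ms), x$time_ms[1L],
              x$time_ms[length(x$time_ms)]))
  cat(sprintf("  mean discrimination: peak %.4g at %g ms\n",
              max(x$mean), x$time_ms[which.max(x$mean)]))
  invisible(x)
}

#' @export
plot.discrim_tc <- function(x, ...,
                            xlab = "time (ms)",
                            ylab = "distance difference (a.u.)") {
  graphics::plot(x$time_ms, x$mean, type = "l", xlab = xlab, ylab = ylab,
                 ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
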