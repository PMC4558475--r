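# internal: maximal contiguous runs of suprathreshold same-sign samples.
# stat: per-time statistic; supra: logical. Returns data.frame with one row
# per cluster (start/end indices, mass = sum of stat in the run).
find_clusters <- function(stat, supra) {
  code <- ifelse(supra, sign(stat), 0)
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  if (!any(keep))
    return(data.frame(start = integer(), end = integer(),
                      sign = numeric(), mass = numeric()))
  data.frame(
    start = starts[keep], end = ends[keep], sign = r$values[keep],
    mass = vapply(which(keep),
                  function(k) sum(stat[starts[k]:ends[k]]), numeric(1L)))
}

#' Cluster-based sign-permutation test
#'
#' Group-level inference for a participants x time matrix of decoding
#' values. The null distribution is built by randomly multiplying each
#' participant's time-course by +1 or -1; per-time two-sided p-values come
#' from the permutation distribution of the group mean. Contiguous
#' same-sign runs of suprathreshold samples (permutation p below
#' `cluster_alpha`) form clusters whose mass is the sum of the group-mean
#' values in the run; the corrected cluster p is the fraction of
#' permutations whose maximal absolute cluster mass reaches the observed
#' mass. Reported p-values are floored at `1/n_perm`.
#'
#' @param data numeric matrix, participants x time (>= 2 rows).
#' @param time_ms time axis in ms (one entry per column).
#' @param window length-2 ms analysis window (inclusive); default the full
#'   axis.
#' @param n_perm number of sign permutations (default 10000; a value below
#'   100 triggers a warning).
#' @param cluster_alpha cluster-forming threshold on the per-time
#'   permutation p (default 0.01, two-sided).
#' @param alpha significance level for corrected cluster p (default 0.05).
#' @param seed integer seed for the permutation draws (required, logged in
#'   the result).
#' @return An object of class `cluster_test`: list with `time_ms`,
#'   `group_mean`, `p_time`, `clusters` (data frame: `start_ms`, `end_ms`,
#'   `sign`, `mass`, `p`, `significant`) and `settings`.
#' @export
sign_permutation_cluster <- function(data, time_ms, window = NULL,
                                     n_perm = 10000L, cluster_alpha = 0.01,
                                     alpha = 0.05, seed = 1L) {
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop("need at least 2 participants", call. = FALSE)
  if (ncol(data) != length(time_ms))
    stop("time axis does not match data columns", call. = FALSE)
  if (n_perm < 100L) warning("n_perm < 100: p-values will be very coarse")
  if (!is.null(window)) {
    idx <- which(time_ms >= window[1L] & time_ms <= window[2L])
    if (!length(idx)) stop("window outside time axis", call. = FALSE)
    data <- data[, idx, drop = FALSE]
    time_ms <- time_ms[idx]
  }
  n_sub <- nrow(data)
  n_t <- ncol(data)
  obs <- colMeans(data)

  with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n_sub, replace = TRUE),
                    n_perm, n_sub)
    perm_means <- (signs %*% data) / n_sub

    # per-time two-sided permutation p for the observed mean
    abs_perm <- abs(perm_means)
    p_time <- pmax(colMeans(abs_perm >= rep(abs(obs), each = n_perm)),
                   1 / n_perm)

    # cluster-forming threshold: k-th largest |permutation mean| per time
    k <- max(1L, floor(cluster_alpha * n_perm))
    crit <- apply(abs_perm, 2L, function(v) sort(v, decreasing = TRUE)[k])

    cl <- find_clusters(obs, abs(obs) > crit)

    # permutation null of the maximal absolute cluster mass
    supra_perm <- abs_perm > rep(crit, each = n_perm)
    null_max <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      if (!any(supra_perm[b, ])) next
      cb <- find_clusters(perm_means[b, ], supra_perm[b, ])
      if (nrow(cb)) null_max[b] <- max(abs(cb$mass))
    }

    clusters <- data.frame(
      start_ms = time_ms[cl$start], end_ms = time_ms[cl$end],
      sign = cl$sign, mass = cl$mass,
      p = vapply(cl$mass, function(m)
        max(mean(null_max >= abs(m)), 1 / n_perm), numeric(1L)))
    clusters$significant <- clusters$p < alpha

    structure(list(time_ms = time_ms, group_mean = obs, p_time = p_time,
                   clusters = clusters,
                   settings = list(n_perm = n_perm,
                                   cluster_alpha = cluster_alpha,
                                   alpha = alpha, sidedness = "two-sided",
                                   window = range(time_ms), seed = seed,
                                   n_participants = n_sub)),
              class = "cluster_test")
  })
}

#' @export
print.cluster_test <- function(x, ...) {
  s <- x$settings
  cat(sprintf(paste0("<cluster_test> %d participants, window %g..%g ms, ",
                     "%d permutations (cluster alpha %.3g)\n"),
              s$n_participants, s$window[1L], s$window[2L], s$n_perm,
              s$cluster_alpha))
  if (!nrow(x$clusters)) {
    cat("  no clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters))) {
      cl <- x$clusters[i, ]
      p_txt <- if (cl$p <= 1 / s$n_perm)
        sprintf("p < %.3g", 1 / s$n_perm) else sprintf("p = %.3g", cl$p)
      cat(sprintf("  %s cluster %g-%g ms, mass %.3g, %s%s\n",
                  if (cl$sign > 0) "positive" else "negative",
                  cl$start_ms, cl$end_ms, cl$mass, p_txt,
                  if (cl$significant) " *" else ""))
    }
  }
  invisible(x)
}

#' Post-impulse increase in discriminability
#'
#' Tests whether discrimination rises above its pre-impulse level: per
#' participant, the mean discrimination over the baseline window (default
#' the 100 ms before impulse onset, half-open `[-100, 0)`) is subtracted
#' from every value, and [sign_permutation_cluster()] is run on the
#' differences over the post-onset window.
#'
#' @param data numeric matrix, participants x time, impulse-locked.
#' @param time_ms time axis in ms.
#' @param baseline length-2 ms window (half-open) averaged per participant.
#' @param window post-onset analysis window (inclusive); default
#'   `c(0, 800)`.
#' @inheritParams sign_permutation_cluster
#' @return A `cluster_test` on the baseline-subtracted data.
#' @export
baseline_increase_test <- function(data, time_ms, baseline = c(-100, 0),
                                   window = c(0, 800), n_perm = 10000L,
                                   cluster_alpha = 0.01, alpha = 0.05,
                                   seed = 1L) {
  data <- as.matrix(data)
  base_idx <- which(time_ms >= baseline[1L] & time_ms < baseline[2L])
  if (!length(base_idx))
    stop("baseline window not covered by the time axis", call. = FALSE)
  shifted <- data - rowMeans(data[, base_idx, drop = FALSE])
  sign_permutation_cluster(shifted, time_ms, window = window,
                           n_perm = n_perm, cluster_alpha = cluster_alpha,
                           alpha = alpha, seed = seed)
}
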