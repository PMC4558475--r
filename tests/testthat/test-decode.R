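test_that("orientations fall in the stated bins of both schemes", {
  b <- assign_bins(c(10, 100, 45, 157.5, 0, 44.999, 135, 179.9))
  expect_equal(b$binA, c(1L, 3L, 2L, 4L, 1L, 1L, 4L, 4L))
  # scheme B is offset by 22.5 and wraps at 180
  expect_equal(b$binB, c(1L, 3L, 2L, 1L, 1L, 2L, 4L, 1L))
  expect_error(assign_bins(180), "\\[0, 180\\)")
  expect_error(assign_bins(-1), "\\[0, 180\\)")

  # orthogonal orientations land in paired bins in both schemes
  ori <- runif(200, 0, 180)
  b1 <- assign_bins(ori)
  b2 <- assign_bins((ori + 90) %% 180)
  expect_true(all(abs(b1$binA - b2$binA) == 2))
  expect_true(all(abs(b1$binB - b2$binB) == 2))
  # and the independent oracle agrees everywhere
  ob <- oracle_bins(ori)
  expect_equal(b1$binA, unname(ob[, "A"]))
  expect_equal(b1$binB, unname(ob[, "B"]))
})

test_that("every trial joins exactly one comparison per scheme", {
  ori <- runif(100, 0, 180)
  comps <- impulsewm:::comparison_sets(ori)
  expect_length(comps, 4L)
  counts <- integer(100)
  for (cmp in comps) counts[cmp$idx] <- counts[cmp$idx] + 1L
  expect_true(all(counts == 2L))
})

test_that("distance differences match hand computation and the oracle", {
  # identity precision: plain squared-Euclidean difference
  expect_equal(distance_difference(c(0, 0), c(0, 0), c(3, 4), diag(2)), 25)
  # equidistant test vector gives exactly zero
  expect_equal(distance_difference(c(1, 0), c(0, 1), c(2, -1), diag(2)), 0)

  set.seed(10)
  for (rep in 1:5) {
    p <- 17
    A <- matrix(rnorm(p * p), p)
    P <- crossprod(A) / p
    x <- rnorm(p); m1 <- rnorm(p); m2 <- rnorm(p)
    got <- distance_difference(x, m1, m2, P)
    want <- oracle_dd(x, m1, m2, P)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("pooled precision is shrunk, symmetric and matches the oracle", {
  set.seed(11)
  x1 <- matrix(rnorm(40 * 8), 40)
  x2 <- matrix(rnorm(35 * 8), 35)
  pp <- pooled_precision(x1, x2)
  expect_true(pp$shrinkage >= 0 && pp$shrinkage <= 1)
  expect_equal(pp$precision, t(pp$precision), tolerance = 1e-10)
  orc <- oracle_precision(x1, x2)
  expect_equal(pp$shrinkage, orc$lambda, tolerance = 1e-10)
  expect_equal(pp$precision, orc$P, tolerance = 1e-8)

  # forcing shrinkage to zero recovers the plain inverse of the pooled
  # sample covariance
  pp0 <- pooled_precision(x1, x2, shrinkage = 0)
  z <- rbind(sweep(x1, 2, colMeans(x1)), sweep(x2, 2, colMeans(x2)))
  s <- crossprod(z) / (nrow(x1) + nrow(x2) - 2)
  expect_equal(pp0$precision, solve(s), tolerance = 1e-8)

  # fewer trials than channels: still finite, symmetric, PSD
  y1 <- matrix(rnorm(5 * 12), 5)
  y2 <- matrix(rnorm(6 * 12), 6)
  pps <- pooled_precision(y1, y2)
  expect_true(all(is.finite(pps$precision)))
  ev <- eigen(pps$precision, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))

  expect_error(pooled_precision(x1[1, , drop = FALSE], x2), "2 trials")
})

test_that("white data with many trials gives a near-identity precision", {
  set.seed(12)
  p <- 6
  x1 <- matrix(rnorm(600 * p), 600)
  x2 <- matrix(rnorm(600 * p), 600)
  pp <- pooled_precision(x1, x2)
  expect_true(max(abs(pp$precision - diag(p))) < 0.15)
})

test_that("the LOO time-course equals the independent oracle", {
  set.seed(13)
  n <- 16; p <- 5; n_t <- 4
  ori <- seq(2, 178, length.out = n)
  arr <- array(rnorm(n * p * n_t), dim = c(n, p, n_t))
  # plant a weak pattern so values are not pure noise
  tune <- cos(2 * ori * pi / 180)
  for (i in seq_len(n)) arr[i, 1, ] <- arr[i, 1, ] + tune[i]
  e <- epoch_set(arr, seq(0, by = 4, length.out = n_t),
                 paste0("ch", 1:p),
                 data.frame(trial_id = 1:n, orientation_deg = ori))
  got <- loo_discrimination(e)
  want <- oracle_loo_tc(arr, ori)
  expect_equal(got$mean, want, tolerance = 1e-8)

  # same equality with shrinkage pinned, exercising that code path
  got0 <- loo_discrimination(e, shrinkage = 0.3)
  want0 <- oracle_loo_tc(arr, ori, shrinkage = 0.3)
  expect_equal(got0$mean, want0, tolerance = 1e-8)
})

test_that("leave-one-out hygiene: a trial's training-time data does not
           leak into its own estimate", {
  set.seed(14)
  n <- 16; p <- 4
  ori <- seq(3, 177, length.out = n)
  comps <- impulsewm:::comparison_sets(ori)
  cmp <- comps[[1]]
  train <- array(rnorm(length(cmp$idx) * p * 1),
                 dim = c(length(cmp$idx), p, 1))
  test <- array(rnorm(length(cmp$idx) * p * 1),
                dim = c(length(cmp$idx), p, 1))
  pairs <- cbind(1L, 1L)
  mask <- rep(1L, length(cmp$idx))
  base <- impulsewm:::cpp_loo_dd(train, test, cmp$lab, pairs, 1e-12, -1, mask)
  # corrupt trial 1's TRAINING data only: everyone else's estimate moves,
  # trial 1's own estimate must not
  train2 <- train
  train2[1, , 1] <- train2[1, , 1] + 100
  pert <- impulsewm:::cpp_loo_dd(train2, test, cmp$lab, pairs, 1e-12, -1, mask)
  expect_equal(pert[1, 1], base[1, 1], tolerance = 1e-10)
  expect_false(isTRUE(all.equal(pert[-1, 1], base[-1, 1])))
})

test_that("decoding is positive only where a pattern is planted", {
  e <- patterned_epochs(n = 32, amp = 2, noise = 0.6, seed = 21)
  tc <- loo_discrimination(e, keep_trials = TRUE)
  inside <- tc$time_ms >= 104 & tc$time_ms <= 296
  outside <- tc$time_ms < 60 | tc$time_ms > 340
  expect_gt(mean(tc$mean[inside]), 0)
  sem_out <- apply(tc$per_trial[, outside], 2, sd) / sqrt(tc$n_trials)
  expect_gte(mean(abs(tc$mean[outside]) <= 3 * sem_out), 0.9)
  expect_gt(mean(tc$mean[inside]), 10 * mean(abs(tc$mean[outside])))
})

test_that("scaling the data never flips the sign of estimates", {
  e <- patterned_epochs(n = 24, amp = 1.5, noise = 0.7, seed = 22)
  tc1 <- loo_discrimination(e)
  e$data <- e$data * 3.7
  tc2 <- loo_discrimination(e)
  expect_true(all(sign(tc1$mean) == sign(tc2$mean)))
})

test_that("univariate control sees amplitude but not zero-mean patterns", {
  # zero-channel-mean pattern: multivariate decodes, univariate stays flat
  e <- patterned_epochs(n = 32, amp = 2, noise = 0.5, seed = 23)
  mv <- loo_discrimination(e)
  uv <- univariate_discrimination(e, keep_trials = TRUE)
  inside <- mv$time_ms >= 104 & mv$time_ms <= 296
  expect_gt(mean(mv$mean[inside]), 1)
  sem <- apply(uv$per_trial, 2, sd) / sqrt(uv$n_trials)
  expect_gte(mean(abs(uv$mean[inside]) <= 3 * sem[inside]), 0.85)

  # a uniform amplitude offset between bins: univariate lights up
  p <- 8
  offset_pattern <- cbind(rep(0.8, p), rep(0, p))
  e2 <- patterned_epochs(n = 32, amp = 2, noise = 0.5, seed = 24,
                         pattern = offset_pattern)
  uv2 <- univariate_discrimination(e2)
  expect_gt(mean(uv2$mean[inside]), 0.2)

  # pure noise: univariate centred on zero
  e3 <- noise_epochs(n = 32, seed = 25)
  uv3 <- univariate_discrimination(e3, keep_trials = TRUE)
  sem3 <- apply(uv3$per_trial, 2, sd) / sqrt(uv3$n_trials)
  expect_gte(mean(abs(uv3$mean) <= 3 * sem3), 0.9)
})

test_that("undersized bins are reported by name", {
  e <- noise_epochs(n = 8)
  e$trials$orientation_deg <- c(10, 10, 10, 100, 100, 100, 100, 100)
  expect_error(loo_discrimination(e), ">= 3 trials")
})
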