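make_epochs <- function(arr, t_ms, onsets = NA) {
  n <- dim(arr)[1]
  epoch_set(arr, t_ms, paste0("ch", seq_len(dim(arr)[2])),
            data.frame(trial_id = seq_len(n),
                       orientation_deg = runif(n, 0, 180),
                       impulse_onset_ms = onsets))
}

test_that("baseline correction subtracts the pre-stimulus mean", {
  t_ms <- seq(-200, 400, 4)
  arr <- array(3, dim = c(2, 3, length(t_ms)))
  e <- make_epochs(arr, t_ms)
  out <- baseline_correct(e)
  expect_equal(max(abs(out$data)), 0)

  # traces that are already zero in the window pass through unchanged
  arr2 <- array(0, dim = c(2, 3, length(t_ms)))
  arr2[, , t_ms >= 0] <- 5
  e2 <- make_epochs(arr2, t_ms)
  expect_equal(baseline_correct(e2)$data, arr2)

  # idempotence
  set.seed(1)
  e3 <- make_epochs(array(rnorm(2 * 3 * length(t_ms)),
                          dim = c(2, 3, length(t_ms))), t_ms)
  once <- baseline_correct(e3)
  expect_equal(baseline_correct(once)$data, once$data, tolerance = 1e-12)

  expect_error(baseline_correct(e, window = c(2000, 2200)), "window")
})

test_that("Gaussian smoothing has unit gain and the stated kernel", {
  t_ms <- seq(-100, 300, 4)
  arr <- array(2.5, dim = c(1, 2, length(t_ms)))
  e <- make_epochs(arr, t_ms)
  expect_equal(smooth_gaussian(e, 8)$data, arr, tolerance = 1e-12)

  # a unit impulse becomes the (truncated, renormalized) Gaussian kernel
  arr2 <- array(0, dim = c(1, 1, length(t_ms)))
  i0 <- 50
  arr2[1, 1, i0] <- 1
  sm <- smooth_gaussian(make_epochs(arr2, t_ms), 8)$data[1, 1, ]
  sd_samp <- 2
  h <- ceiling(4 * sd_samp)
  k <- exp(-0.5 * ((-h:h) / sd_samp)^2)
  k <- k / sum(k)
  expect_equal(sm[(i0 - h):(i0 + h)], k, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)  # interior mass preserved

  expect_error(smooth_gaussian(e, 0), "sd_ms")
})

test_that("smoothing commutes with channel selection", {
  set.seed(4)
  t_ms <- seq(-100, 300, 4)
  e <- make_epochs(array(rnorm(3 * 4 * length(t_ms)),
                         dim = c(3, 4, length(t_ms))), t_ms)
  a <- select_channels(smooth_gaussian(e, 12), c("ch3", "ch1"))
  b <- smooth_gaussian(select_channels(e, c("ch3", "ch1")), 12)
  expect_equal(a$data, b$data, tolerance = 1e-12)
})

test_that("impulse re-epoching aligns t = 0 to the nearest onset sample", {
  t_ms <- seq(-200, 2800, 4)
  n <- 4
  arr <- array(0, dim = c(n, 2, length(t_ms)))
  # encode the absolute sample time into the data so alignment is checkable
  for (i in seq_len(n)) arr[i, 1, ] <- t_ms
  onsets <- c(1170, 1230, 1170, 1230)
  e <- make_epochs(arr, t_ms, onsets)
  out <- reepoch_impulse(e)
  expect_equal(out$time_ms, seq(-200, 1400, 4))
  at0 <- out$data[, 1, out$time_ms == 0]
  # ties between grid samples resolve toward the earlier sample
  expect_equal(at0, c(1168, 1228, 1168, 1228))
  # the 60 ms onset difference survives the rounding exactly
  expect_equal(at0[2] - at0[1], 60)

  e_short <- make_epochs(arr[1:2, , , drop = FALSE], t_ms, c(1170, NA))
  expect_error(reepoch_impulse(e_short), "long trials")
  expect_error(reepoch_impulse(e, window = c(-200, 2600)), "outside")
})

test_that("channel selection respects request order and validates names", {
  set.seed(5)
  t_ms <- seq(0, 100, 4)
  e <- make_epochs(array(rnorm(2 * 4 * length(t_ms)),
                         dim = c(2, 4, length(t_ms))), t_ms)
  out <- select_channels(e, c("ch4", "ch2"))
  expect_equal(out$channels, c("ch4", "ch2"))
  expect_equal(out$data[, 1, ], e$data[, 4, ])
  expect_equal(n_trials(out), n_trials(e))
  expect_error(select_channels(e, c("ch1", "nope")), "unknown")
  expect_error(select_channels(e, character()), "empty")
})

test_that("artifact flagging marks but never drops trials", {
  t_ms <- seq(0, 100, 4)
  arr <- array(0, dim = c(3, 2, length(t_ms)))
  arr[2, 1, 5] <- 300
  e <- make_epochs(arr, t_ms)
  out <- flag_artifacts(e, threshold_uv = 150)
  expect_equal(out$trials$artifact, c(FALSE, TRUE, FALSE))
  expect_equal(n_trials(out), 3)
})

test_that("epoch sets round-trip through the text serialization", {
  set.seed(6)
  t_ms <- seq(-20, 60, 4)
  e <- make_epochs(array(rnorm(3 * 2 * length(t_ms)),
                         dim = c(3, 2, length(t_ms))), t_ms)
  dir <- file.path(tempdir(), "epochs_rt")
  write_epochs(e, dir)
  back <- read_epochs(dir)
  expect_equal(back$data, e$data, tolerance = 1e-12)
  expect_equal(back$time_ms, e$time_ms)
  expect_equal(back$channels, e$channels)
  expect_equal(back$trials$orientation_deg, e$trials$orientation_deg)
  unlink(dir, recursive = TRUE)
})
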