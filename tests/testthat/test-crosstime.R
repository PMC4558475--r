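test_that("the within-epoch matrix diagonal equals the LOO time-course", {
  e <- patterned_epochs(n = 24, t_ms = seq(0, 100, 4), window = c(20, 60),
                        seed = 31)
  gm <- generalization_matrix(e)
  tc <- loo_discrimination(e)
  expect_equal(diag(gm$values), tc$mean, tolerance = 1e-12)
  expect_equal(gm$train_time_ms, tc$time_ms)
})

test_that("static codes generalize across time, dynamic codes stay near
           the diagonal", {
  d_static <- tiny_design(n_short = 48L, dynamics = "static", seed = 41L,
                          encode_decay_tau = 1e6, noise_sd = 0.7)
  d_dynamic <- tiny_design(n_short = 48L, dynamics = "dynamic", seed = 41L,
                           encode_decay_tau = 1e6, noise_sd = 0.7,
                           pattern_drift_tau = 50)
  win <- c(100, 600)
  ratio <- function(d) {
    sim <- generate_epochs(d)
    gm <- generalization_matrix(sim$short, train_window = win,
                                test_window = win, stride = 4L)
    n <- nrow(gm$values)
    off <- abs(outer(seq_len(n), seq_len(n), "-")) >= 10  # >= 160 ms apart
    mean(gm$values[off]) / mean(diag(gm$values))
  }
  r_static <- ratio(d_static)
  r_dynamic <- ratio(d_dynamic)
  expect_gt(r_static, 0.7)   # near-uniform block
  expect_lt(r_dynamic, 0.5)  # diagonal dominance
  expect_lt(r_dynamic, r_static)
})

test_that("memory and impulse codes do not cross-generalize unless shared", {
  run <- function(shared) {
    d <- tiny_design(n_short = 10L, n_early = 24L, n_late = 24L,
                     shared_code = shared, seed = 43L)
    sim <- generate_epochs(d)
    long <- smooth_gaussian(baseline_correct(sim$long), 8)
    imp <- reepoch_impulse(long)
    mem <- crop_epochs(long, c(-200, 1400))
    gm <- generalization_matrix(imp, mem, train_window = c(100, 400),
                                test_window = c(0, 400), stride = 4L)
    within <- loo_discrimination(imp, window = c(100, 400))
    c(cross = mean(gm$values), within = mean(within$mean))
  }
  indep <- run(FALSE)
  expect_gt(indep["within"], 0.5)
  expect_lt(abs(indep["cross"]), indep["within"] / 5)
  shared <- run(TRUE)
  expect_gt(shared["cross"], indep["within"] / 5)
})

test_that("a zero shift reproduces the cross-epoch matrix slice", {
  d <- tiny_design(n_short = 10L, n_early = 16L, n_late = 16L, seed = 44L)
  sim <- generate_epochs(d)
  long <- sim$long
  imp <- reepoch_impulse(long)
  tc <- shifted_training_timecourse(imp, long, shift_ms = 0,
                                    nominal_onset_ms = 1200,
                                    test_window = c(1300, 1500))
  gm <- generalization_matrix(imp, long,
                              train_window = c(100, 300),
                              test_window = c(1300, 1500))
  slice <- gm$values[cbind(match(tc$time_ms - 1200, gm$train_time_ms),
                           match(tc$time_ms, gm$test_time_ms))]
  expect_equal(tc$mean, slice, tolerance = 1e-10)
  expect_error(shifted_training_timecourse(imp, long, shift_ms = 2),
               "4 ms")
})

test_that("lag correlation recovers a planted delay exactly", {
  set.seed(45)
  t_ms <- seq(1200, 2400, 4)
  for (L in c(0, 24, 60, 100)) {
    x <- as.numeric(stats::filter(rnorm(length(t_ms) + 50), rep(1, 5),
                                  sides = 1))[-(1:50)]
    early <- rbind(x, x + rnorm(length(x), sd = 1e-6))
    late <- cbind(matrix(0, 2, L / 4),
                  early[, 1:(length(x) - L / 4), drop = FALSE])
    lc <- lag_correlation(early, late, t_ms, window = c(1370, 2170),
                          lags = seq(0, 120, 4))
    expect_equal(lc$peak_lag_ms, L)
    expect_gt(lc$r[1, lc$lags == L], 0.999)
  }
})

test_that("lag correlation of independent noise is centred on zero", {
  set.seed(46)
  t_ms <- seq(1200, 2400, 4)
  early <- matrix(rnorm(12 * length(t_ms)), 12)
  late <- matrix(rnorm(12 * length(t_ms)), 12)
  lc <- lag_correlation(early, late, t_ms)
  # per-lag z has sd ~ 1/sqrt(197); the 12-participant mean ~ 0.021
  expect_lt(max(abs(lc$mean_z)), 0.15)
  expect_lt(abs(mean(lc$mean_z)), 0.05)
})

test_that("perfect correlations stay finite through the Fisher transform", {
  t_ms <- seq(1200, 2400, 4)
  x <- sin(seq_along(t_ms) / 5)
  lc <- lag_correlation(rbind(x), rbind(x), t_ms, lags = 0)
  expect_true(is.finite(lc$z[1, 1]))
  expect_gt(lc$z[1, 1], 13)  # atanh(1 - 1e-12) / 2 ~ 13.9
})

test_that("coverage shorter than window plus lags is rejected", {
  t_ms <- seq(1300, 2200, 4)
  x <- matrix(rnorm(2 * length(t_ms)), 2)
  expect_error(lag_correlation(x, x, t_ms), "too short")
})
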