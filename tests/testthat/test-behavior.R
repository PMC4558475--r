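probe_grid <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(probe_delta_deg = sample(c(-45, -34, -26, -20, -15, -12, -9,
                                        -7, -5, -4, 4, 5, 7, 9, 12, 15,
                                        20, 26, 34, 45), n, replace = TRUE))
}

test_that("pure guessing drives the guess rate to its boundary", {
  tr <- generate_behavior(probe_grid(600), g = 1, sigma = 5, seed = 2)
  fit <- fit_mixture(data = tr)
  expect_gt(coef(fit)["g"], 0.85)
  expect_true(fit$boundary || coef(fit)["g"] > 0.99 ||
                coef(fit)["sigma"] >= 99)
})

test_that("deterministic responses drive g to zero and sigma to its
           lower bound", {
  tr <- probe_grid(400)
  tr$response <- ifelse(tr$probe_delta_deg > 0, "cw", "ccw")
  fit <- fit_mixture(data = tr)
  expect_lt(coef(fit)["g"], 0.02)
  expect_equal(unname(coef(fit)["sigma"]), 0.1, tolerance = 1e-6)
  expect_true(fit$boundary)
})

test_that("parameters near the study's short-trial values are recovered", {
  tr <- generate_behavior(probe_grid(800, seed = 3), g = 0.074,
                          sigma = 4.272, seed = 4)
  fit <- fit_mixture(data = tr)
  expect_lt(abs(coef(fit)["g"] - 0.074), 0.06)
  expect_lt(abs(coef(fit)["sigma"] - 4.272), 1.2)
  expect_true(fit$convergence)
  expect_false(fit$boundary)
})

test_that("the fit is invariant to trial order", {
  tr <- generate_behavior(probe_grid(300, seed = 5), g = 0.1, sigma = 6,
                          seed = 6)
  fit1 <- fit_mixture(data = tr)
  fit2 <- fit_mixture(data = tr[sample(nrow(tr)), ])
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-8)
})

test_that("the fitted likelihood is at least the generating likelihood", {
  wins <- 0
  for (r in 1:10) {
    tr <- generate_behavior(probe_grid(400, seed = r + 10), g = 0.1,
                            sigma = 5, seed = r + 50)
    fit <- fit_mixture(data = tr)
    ll_truth <- -impulsewm:::mixture_nll(
      c(0.1, 5), tr$probe_delta_deg,
      ifelse(tr$response == "cw", 1, -1))
    if (fit$logLik >= ll_truth - 1e-8) wins <- wins + 1
  }
  expect_gte(wins, 10)  # MLE can never fall below the truth's likelihood
})

test_that("estimation error shrinks with sample size", {
  err <- sapply(c(100, 1600), function(n) {
    g_err <- s_err <- numeric(8)
    for (r in 1:8) {
      tr <- generate_behavior(probe_grid(n, seed = 100 * n + r), g = 0.1,
                              sigma = 5, seed = 200 * n + r)
      co <- coef(fit_mixture(data = tr))
      g_err[r] <- (co["g"] - 0.1)^2
      s_err[r] <- (co["sigma"] - 5)^2
    }
    c(g = sqrt(mean(g_err)), sigma = sqrt(mean(s_err)))
  })
  expect_lt(err["g", 2], err["g", 1])
  expect_lt(err["sigma", 2], err["sigma", 1])
})

test_that("model methods are coherent", {
  tr <- generate_behavior(probe_grid(500, seed = 30), g = 0.1, sigma = 6,
                          seed = 31)
  fit <- fit_mixture(data = tr)
  expect_s3_class(fit, "mixture_fit")
  expect_named(coef(fit), c("g", "sigma"))
  expect_equal(attr(logLik(fit), "nobs"), 500)
  # predictions respect the mixture bounds and monotonicity
  pr <- predict(fit, seq(-45, 45, 5))
  expect_true(all(pr >= 0 & pr <= 1))
  expect_true(all(diff(pr) >= 0))
  # simulating from the fit and refitting recovers similar parameters
  sims <- simulate(fit, nsim = 1, seed = 32)
  refit <- fit_mixture(tr$probe_delta_deg, sims$sim_1)
  expect_lt(abs(coef(refit)["g"] - coef(fit)["g"]), 0.1)
  expect_lt(abs(coef(refit)["sigma"] - coef(fit)["sigma"]), 2)
  expect_error(fit_mixture(numeric(), character()), "no trials")
  expect_error(fit_mixture(c(4, 4, -4), c("cw", "cw", "ccw")), "distinct")
})

test_that("condition comparison pairs fits and detects shifts", {
  fits_a <- lapply(1:8, function(i) {
    tr <- generate_behavior(probe_grid(400, seed = i), g = 0.08,
                            sigma = 4.3, seed = i + 40)
    fit_mixture(data = tr)
  })
  same <- compare_conditions(fits_a, fits_a)
  expect_equal(same$t, c(0, 0))
  expect_equal(same$p, c(1, 1))

  # constant sigma offset with per-participant noise: positive t for sigma
  fits_b <- lapply(seq_along(fits_a), function(i) {
    f <- fits_a[[i]]
    f$coefficients["sigma"] <- f$coefficients["sigma"] - 1 +
      0.05 * sin(i)
    f
  })
  cmp <- compare_conditions(fits_a, fits_b)
  expect_gt(cmp$t[cmp$parameter == "sigma"], 0)
  expect_lt(cmp$p[cmp$parameter == "sigma"], 0.01)

  expect_error(compare_conditions(fits_a, fits_a[1:3]), "pair")
})
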