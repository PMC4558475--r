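# internal: coerce responses to +1 (cw) / -1 (ccw)
response_sign <- function(response) {
  if (is.logical(response)) return(ifelse(response, 1, -1))
  r <- tolower(as.character(response))
  if (!all(r %in% c("cw", "ccw")))
    stop('responses must be "cw"/"ccw" (or logical cw)', call. = FALSE)
  ifelse(r == "cw", 1, -1)
}

# internal: negative log-likelihood of the 2AFC mixture model
mixture_nll <- function(par, delta, s) {
  g <- par[1L]; sigma <- par[2L]
  p <- g / 2 + (1 - g) * pnorm(s * delta / sigma)
  -sum(log(pmax(p, 1e-300)))
}

#' Fit the two-parameter 2AFC mixture model
#'
#' Maximum-likelihood fit of the standard mixture model of visual working
#' memory adapted to the two-alternative forced-choice task. A response is
#' a pure guess with probability `g` (clockwise with probability 1/2);
#' otherwise the remembered orientation carries Gaussian noise with SD
#' `sigma` degrees, so the probability of a clockwise response at probe
#' offset `delta` is `g/2 + (1 - g) * pnorm(delta / sigma)`. The deviance
#' is minimized by bounded quasi-Newton (L-BFGS-B) from 5 deterministic
#' starting points; `g` is bounded to `[0, 1]` and `sigma` to
#' `[0.1, 100]` degrees.
#'
#' @param delta_deg numeric vector of probe - memory orientation
#'   differences in degrees (signed).
#' @param response per-trial responses, `"cw"`/`"ccw"` (or logical,
#'   `TRUE` = clockwise).
#' @param data optional data frame holding columns `probe_delta_deg` and
#'   `response`; when supplied, `delta_deg` and `response` are taken from
#'   it.
#' @return An object of class `mixture_fit` with components `coefficients`
#'   (`g`, `sigma`), `logLik`, `n`, `convergence` (TRUE if the best start
#'   converged), `boundary` (TRUE when `g` is at 1 and `sigma` is
#'   unidentified, or `sigma` sits on a bound), `data`.
#' @seealso [generate_behavior()] for the matching simulator,
#'   [compare_conditions()] for the paired condition contrast.
#' @export
fit_mixture <- function(delta_deg, response, data = NULL) {
  if (!is.null(data)) {
    delta_deg <- data$probe_delta_deg
    response <- data$response
  }
  if (!length(delta_deg)) stop("no trials to fit", call. = FALSE)
  if (length(unique(abs(delta_deg))) < 2L)
    stop("need at least 2 distinct |delta| values", call. = FALSE)
  s <- response_sign(response)
  delta <- as.numeric(delta_deg)

  lower <- c(0, 0.1); upper <- c(1, 100)
  starts <- list(c(0.05, 3), c(0.05, 10), c(0.3, 5), c(0.6, 20),
                 c(0.95, 40))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, mixture_nll, delta = delta, s = s, method = "L-BFGS-B",
            lower = lower, upper = upper),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)

  g <- best$par[1L]; sigma <- best$par[2L]
  boundary <- g > 0.99 || sigma <= lower[2L] + 1e-9 ||
    sigma >= upper[2L] - 1e-9
  structure(list(coefficients = c(g = g, sigma = sigma),
                 logLik = -best$value, n = length(delta),
                 convergence = best$convergence == 0L,
                 boundary = boundary,
                 data = data.frame(probe_delta_deg = delta,
                                   response = ifelse(s > 0, "cw", "ccw"),
                                   stringsAsFactors = FALSE)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("2AFC mixture model fit\n")
  cat(sprintf("  g = %.4f, sigma = %.3f deg  (n = %d, logLik = %.2f)\n",
              x$coefficients["g"], x$coefficients["sigma"], x$n, x$logLik))
  if (!x$convergence) cat("  warning: optimizer did not converge\n")
  if (x$boundary) cat("  note: estimate at parameter boundary\n")
  invisible(x)
}

#' @export
coef.mixture_fit <- function(object, ...) object$coefficients

#' @export
logLik.mixture_fit <- function(object, ...) {
  structure(object$logLik, df = 2L, nobs = object$n, class = "logLik")
}

#' @export
summary.mixture_fit <- function(object, ...) {
  p_hat <- predict(object)
  emp <- tapply(object$data$response == "cw", object$data$probe_delta_deg,
                mean)
  structure(list(fit = object,
                 curve = data.frame(
                   probe_delta_deg = as.numeric(names(emp)),
                   p_cw_observed = as.numeric(emp),
                   p_cw_fitted = predict(object,
                                         as.numeric(names(emp))))),
            class = "summary.mixture_fit")
}

#' @export
print.summary.mixture_fit <- function(x, ...) {
  print(x$fit)
  cat("\n  P(cw) by probe offset:\n")
  print(format(x$curve, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Predicted clockwise-response probability
#'
#' @param object a `mixture_fit`.
#' @param newdata optional numeric vector of probe offsets in degrees;
#'   default the fitted trials' offsets.
#' @param ... unused.
#' @return Numeric vector of P(clockwise).
#' @export
predict.mixture_fit <- function(object, newdata = NULL, ...) {
  delta <- if (is.null(newdata)) object$data$probe_delta_deg else
    as.numeric(newdata)
  g <- object$coefficients["g"]; sigma <- object$coefficients["sigma"]
  unname(g / 2 + (1 - g) * pnorm(delta / sigma))
}

#' @export
residuals.mixture_fit <- function(object, ...) {
  y <- as.numeric(object$data$response == "cw")
  p <- predict(object)
  (y - p) / sqrt(p * (1 - p))
}

#' Simulate responses from a fitted mixture model
#'
#' @param object a `mixture_fit`.
#' @param nsim number of simulated response sets.
#' @param seed integer seed.
#' @param ... unused.
#' @return A data frame with `nsim` columns of `"cw"`/`"ccw"` responses at
#'   the fitted trials' probe offsets.
#' @export
simulate.mixture_fit <- function(object, nsim = 1, seed = NULL, ...) {
  p <- predict(object)
  if (!is.null(seed)) {
    return(with_seed(seed, {
      as.data.frame(lapply(seq_len(nsim), function(k)
        ifelse(rbinom(length(p), 1L, p) == 1L, "cw", "ccw")),
        col.names = paste0("sim_", seq_len(nsim)))
    }))
  }
  as.data.frame(lapply(seq_len(nsim), function(k)
    ifelse(rbinom(length(p), 1L, p) == 1L, "cw", "ccw")),
    col.names = paste0("sim_", seq_len(nsim)))
}

#' @export
plot.mixture_fit <- function(x, ...) {
  emp <- tapply(x$data$response == "cw", x$data$probe_delta_deg, mean)
  d_obs <- as.numeric(names(emp))
  grid <- seq(min(d_obs), max(d_obs), length.out = 200L)
  graphics::plot(d_obs, emp, xlab = "probe - memory offset (deg)",
                 ylab = "P(clockwise)", ylim = c(0, 1), ...)
  graphics::lines(grid, predict(x, grid))
  graphics::abline(h = 0.5, v = 0, lty = 3)
  invisible(x)
}

#' Paired comparison of mixture fits between conditions
#'
#' Paired-samples t-tests on the guess rate and on the memory SD between
#' two conditions fitted per participant (e.g. short vs long trials).
#'
#' @param fits_a,fits_b lists of `mixture_fit` objects, one per
#'   participant, in the same participant order.
#' @return A data frame with one row per parameter: condition means,
#'   paired t statistic, df, two-sided p.
#' @export
compare_conditions <- function(fits_a, fits_b) {
  if (length(fits_a) != length(fits_b))
    stop("condition fit lists must pair up participant-wise", call. = FALSE)
  get <- function(fits, par)
    vapply(fits, function(f) coef(f)[[par]], numeric(1L))
  out <- lapply(c("g", "sigma"), function(par) {
    a <- get(fits_a, par); b <- get(fits_b, par)
    if (all(a == b)) {
      data.frame(parameter = par, mean_a = mean(a), mean_b = mean(b),
                 t = 0, df = length(a) - 1L, p = 1)
    } else {
      tt <- t.test(a, b, paired = TRUE)
      data.frame(parameter = par, mean_a = mean(a), mean_b = mean(b),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    }
  })
  do.call(rbind, out)
}
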