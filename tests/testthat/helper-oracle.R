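# Independent reference implementations, written from the definitions and
# kept deliberately naive (explicit loops, svd-based pseudoinverse) so they
# share no code with the package's computational path.

# shrunk pooled precision from two bins of training trials
oracle_precision <- function(x1, x2, lambda = NULL, tol = 1e-12) {
  m1 <- colMeans(x1)
  m2 <- colMeans(x2)
  z <- rbind(sweep(x1, 2, m1), sweep(x2, 2, m2))
  nz <- nrow(z)
  p <- ncol(z)
  s_n <- crossprod(z) / nz
  if (is.null(lambda)) {
    m <- sum(diag(s_n)) / p
    d2 <- sum((s_n - diag(m, p))^2) / p
    b2 <- (sum(rowSums(z^2)^2) - nz * sum(s_n^2)) / (nz^2 * p)
    lambda <- if (d2 > 0) min(1, max(0, b2 / d2)) else 0
  }
  df <- nrow(x1) + nrow(x2) - 2
  s_unb <- crossprod(z) / df
  sig <- (1 - lambda) * s_unb + lambda * (sum(diag(s_unb)) / p) * diag(p)
  sv <- svd(sig)
  pos <- sv$d > max(sv$d) * tol
  P <- sv$v[, pos, drop = FALSE] %*%
    diag(1 / sv$d[pos], sum(pos)) %*% t(sv$u[, pos, drop = FALSE])
  list(P = P, lambda = lambda)
}

# quadratic-form distance difference, element by element
oracle_dd <- function(x, m_same, m_orth, P) {
  quad <- function(d) {
    s <- 0
    for (a in seq_along(d))
      for (b in seq_along(d))
        s <- s + d[a] * P[a, b] * d[b]
    s
  }
  quad(m_orth - x) - quad(m_same - x)
}

# independent binning: scheme A anchored at 0, scheme B at -22.5 (mod 180)
oracle_bins <- function(ori) {
  binA <- findInterval(ori, c(0, 45, 90, 135, 180))
  binB <- findInterval((ori + 22.5) %% 180, c(0, 45, 90, 135, 180))
  cbind(A = binA, B = binB)
}

# full leave-one-trial-out discrimination time-course, from scratch
oracle_loo_tc <- function(data, ori, shrinkage = NULL) {
  n <- dim(data)[1]
  n_time <- dim(data)[3]
  bins <- oracle_bins(ori)
  out <- numeric(n_time)
  for (ti in seq_len(n_time)) {
    x_t <- data[, , ti, drop = FALSE]
    dim(x_t) <- dim(data)[1:2]
    acc <- 0
    cnt <- 0
    for (scheme in c("A", "B")) {
      for (pair in list(c(1, 3), c(2, 4))) {
        sel <- bins[, scheme] %in% pair
        for (i in which(sel)) {
          own <- bins[i, scheme]
          oth <- pair[pair != own]
          own_rows <- setdiff(which(bins[, scheme] == own), i)
          oth_rows <- which(bins[, scheme] == oth)
          pr <- oracle_precision(x_t[own_rows, , drop = FALSE],
                                 x_t[oth_rows, , drop = FALSE],
                                 lambda = shrinkage)
          acc <- acc + oracle_dd(x_t[i, ],
                                 colMeans(x_t[own_rows, , drop = FALSE]),
                                 colMeans(x_t[oth_rows, , drop = FALSE]),
                                 pr$P)
          cnt <- cnt + 1
        }
      }
    }
    out[ti] <- acc / cnt
  }
  out
}
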