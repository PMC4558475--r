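// Leave-one-trial-out Mahalanobis distance-difference engine.
//
// Data layout: epochs enter as cubes with dimensions (trial, channel, time).
// Each call works on ONE orthogonal-bin comparison: `lab` holds 1 or 2 for
// every trial (its angle bin within the comparison).  The returned statistic
// is always D_orth - D_same for the held-out trial, i.e. positive values mean
// the trial is closer (in Mahalanobis terms) to its own bin's mean than to
// the orthogonal bin's mean.
//
// The error covariance is pooled over the two bins (residuals about each
// bin's own mean, unbiased df weighting) and shrunk toward a scaled identity
// with the analytic (Ledoit-Wolf-type) intensity
//     lambda = min(1, b^2 / d^2),
//     d^2   = ||S_n - m I||_F^2 / p,          m = tr(S_n)/p,
//     b^2   = min(d^2, (sum_j ||z_j||^4 - n ||S_n||_F^2) / (n^2 p)),
// computed on the pooled residuals z_j (S_n is the n-denominator pooled
// scatter).  The precision is the eigenvalue pseudoinverse of the shrunk
// covariance with relative tolerance `tol` (eigenvalues below tol * max are
// treated as zero).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Shrunk pooled precision from residual rows Z with unbiased df.
// lambda_override < 0 means "use the analytic intensity".
static mat shrunk_precision(const mat& Z, double df, double tol,
                            double lambda_override, double* lambda_out) {
  const uword p = Z.n_cols;
  const double nz = static_cast<double>(Z.n_rows);
  mat G = Z.t() * Z;              // pooled scatter
  mat S_n = G / nz;
  double m_n = trace(S_n) / p;

  double lambda;
  if (lambda_override >= 0.0) {
    lambda = lambda_override;
  } else {
    mat D = S_n;
    D.diag() -= m_n;
    double d2 = accu(square(D)) / p;
    if (d2 <= 0.0) {
      lambda = 0.0;
    } else {
      double sum4 = 0.0;
      for (uword j = 0; j < Z.n_rows; ++j) {
        double q = dot(Z.row(j), Z.row(j));
        sum4 += q * q;
      }
      double b2 = (sum4 - nz * accu(square(S_n))) / (nz * nz * p);
      if (b2 < 0.0) b2 = 0.0;
      if (b2 > d2) b2 = d2;
      lambda = b2 / d2;
    }
  }
  if (lambda_out) *lambda_out = lambda;

  mat S_unb = G / df;
  double m_unb = trace(S_unb) / p;
  mat Sigma = (1.0 - lambda) * S_unb;
  Sigma.diag() += lambda * m_unb;

  vec eigval;
  mat eigvec;
  eig_sym(eigval, eigvec, symmatu(Sigma));
  double cut = eigval.max() * tol;
  vec inv_val(eigval.n_elem, fill::zeros);
  for (uword k = 0; k < eigval.n_elem; ++k)
    if (eigval(k) > cut && eigval(k) > 0.0) inv_val(k) = 1.0 / eigval(k);
  return eigvec * diagmat(inv_val) * eigvec.t();
}

static double quad(const rowvec& d, const mat& P) {
  return as_scalar(d * P * d.t());
}

// LOO path: train and test cubes hold the SAME trials (possibly different
// epochs/time axes); the held-out trial is excluded from means and
// covariance at every train time.  pairs is (npairs x 2), 1-based
// (train_slice, test_slice).  evalmask (0/1 per trial) limits which trials
// are evaluated as test trials (all trials always contribute to training,
// minus the held-out one).  Returns (n_trials x npairs); rows with
// evalmask == 0 are left at zero.
// [[Rcpp::export]]
arma::mat cpp_loo_dd(const arma::cube& train, const arma::cube& test,
                     const arma::ivec& lab, const arma::umat& pairs,
                     double tol, double lambda_override,
                     const arma::ivec& evalmask) {
  const uword n = train.n_rows;
  const uword npairs = pairs.n_rows;
  if (test.n_rows != n)
    Rcpp::stop("train and test must hold the same trials");
  if (test.n_cols != train.n_cols)
    Rcpp::stop("channel mismatch between train and test");
  if (evalmask.n_elem != n)
    Rcpp::stop("evalmask must have one entry per trial");

  uvec idx1 = find(lab == 1);
  uvec idx2 = find(lab == 2);
  if (idx1.n_elem < 3 || idx2.n_elem < 3)
    Rcpp::stop("each bin needs at least 3 trials for leave-one-out");

  mat out(n, npairs, fill::zeros);

  // group pair indices by train slice
  uvec tau_all = pairs.col(0);
  uvec tau_unique = unique(tau_all);

  for (uword u = 0; u < tau_unique.n_elem; ++u) {
    uword tau = tau_unique(u);
    uvec grp = find(tau_all == tau);
    mat X = train.slice(tau - 1);             // n x p
    rowvec sum1 = sum(X.rows(idx1), 0);
    rowvec sum2 = sum(X.rows(idx2), 0);
    const double n1 = static_cast<double>(idx1.n_elem);
    const double n2 = static_cast<double>(idx2.n_elem);

    for (uword i = 0; i < n; ++i) {
      if (evalmask(i) == 0) continue;
      const bool in1 = (lab(i) == 1);
      rowvec xi = X.row(i);
      rowvec m_own = in1 ? (sum1 - xi) / (n1 - 1.0) : (sum2 - xi) / (n2 - 1.0);
      rowvec m_oth = in1 ? sum2 / n2 : sum1 / n1;

      // pooled residuals excluding trial i
      const uword n_own = static_cast<uword>(in1 ? n1 : n2) - 1;
      const uword n_oth = static_cast<uword>(in1 ? n2 : n1);
      mat Z(n_own + n_oth, X.n_cols);
      uword r = 0;
      const uvec& own_idx = in1 ? idx1 : idx2;
      const uvec& oth_idx = in1 ? idx2 : idx1;
      for (uword k = 0; k < own_idx.n_elem; ++k) {
        if (own_idx(k) == i) continue;
        Z.row(r++) = X.row(own_idx(k)) - m_own;
      }
      for (uword k = 0; k < oth_idx.n_elem; ++k)
        Z.row(r++) = X.row(oth_idx(k)) - m_oth;

      double df = static_cast<double>(n_own - 1) + static_cast<double>(n_oth - 1);
      mat P = shrunk_precision(Z, df, tol, lambda_override, nullptr);

      for (uword g = 0; g < grp.n_elem; ++g) {
        uword t = pairs(grp(g), 1);
        rowvec xt = test.slice(t - 1).row(i);
        double d_same = quad(m_own - xt, P);
        double d_orth = quad(m_oth - xt, P);
        out(i, grp(g)) = d_orth - d_same;
      }
    }
  }
  return out;
}

// Independent-trials path: training stats use ALL training trials (no
// exclusion); test trials are a disjoint set with their own labels.
// Returns (n_test x npairs).
// [[Rcpp::export]]
arma::mat cpp_dd_train_test(const arma::cube& train, const arma::ivec& lab_train,
                            const arma::cube& test, const arma::ivec& lab_test,
                            const arma::umat& pairs, double tol,
                            double lambda_override) {
  const uword n_test = test.n_rows;
  const uword npairs = pairs.n_rows;
  if (test.n_cols != train.n_cols)
    Rcpp::stop("channel mismatch between train and test");

  uvec idx1 = find(lab_train == 1);
  uvec idx2 = find(lab_train == 2);
  if (idx1.n_elem < 2 || idx2.n_elem < 2)
    Rcpp::stop("each training bin needs at least 2 trials");

  mat out(n_test, npairs, fill::zeros);
  uvec tau_all = pairs.col(0);
  uvec tau_unique = unique(tau_all);

  for (uword u = 0; u < tau_unique.n_elem; ++u) {
    uword tau = tau_unique(u);
    uvec grp = find(tau_all == tau);
    mat X = train.slice(tau - 1);
    rowvec m1 = mean(X.rows(idx1), 0);
    rowvec m2 = mean(X.rows(idx2), 0);

    mat Z(idx1.n_elem + idx2.n_elem, X.n_cols);
    uword r = 0;
    for (uword k = 0; k < idx1.n_elem; ++k) Z.row(r++) = X.row(idx1(k)) - m1;
    for (uword k = 0; k < idx2.n_elem; ++k) Z.row(r++) = X.row(idx2(k)) - m2;
    double df = static_cast<double>(idx1.n_elem - 1) +
                static_cast<double>(idx2.n_elem - 1);
    mat P = shrunk_precision(Z, df, tol, lambda_override, nullptr);

    for (uword g = 0; g < grp.n_elem; ++g) {
      uword t = pairs(grp(g), 1);
      mat T = test.slice(t - 1);
      for (uword i = 0; i < n_test; ++i) {
        rowvec xt = T.row(i);
        rowvec m_own = (lab_test(i) == 1) ? m1 : m2;
        rowvec m_oth = (lab_test(i) == 1) ? m2 : m1;
        out(i, grp(g)) = quad(m_oth - xt, P) - quad(m_own - xt, P);
      }
    }
  }
  return out;
}

// Shrunk pooled precision for two training-bin matrices (exposed for the
// pooled_precision() R surface; X1/X2 are trials x channels).
// [[Rcpp::export]]
Rcpp::List cpp_pooled_precision(const arma::mat& X1, const arma::mat& X2,
                                double tol, double lambda_override) {
  if (X1.n_rows < 2 || X2.n_rows < 2)
    Rcpp::stop("each bin needs at least 2 trials");
  if (X1.n_cols != X2.n_cols) Rcpp::stop("channel mismatch between bins");
  rowvec m1 = mean(X1, 0), m2 = mean(X2, 0);
  mat Z(X1.n_rows + X2.n_rows, X1.n_cols);
  for (uword k = 0; k < X1.n_rows; ++k) Z.row(k) = X1.row(k) - m1;
  for (uword k = 0; k < X2.n_rows; ++k) Z.row(X1.n_rows + k) = X2.row(k) - m2;
  double df = static_cast<double>(X1.n_rows - 1) +
              static_cast<double>(X2.n_rows - 1);
  double lambda = 0.0;
  mat P = shrunk_precision(Z, df, tol, lambda_override, &lambda);

  mat G = Z.t() * Z;
  mat S_unb = G / df;
  double m_unb = trace(S_unb) / Z.n_cols;
  mat Sigma = (1.0 - lambda) * S_unb;
  Sigma.diag() += lambda * m_unb;

  return Rcpp::List::create(Rcpp::Named("covariance") = Sigma,
                            Rcpp::Named("precision") = P,
                            Rcpp::Named("shrinkage") = lambda,
                            Rcpp::Named("df") = df);
}
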