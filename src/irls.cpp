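#include <Rcpp.h>
using namespace Rcpp;

// Solve a small symmetric positive-definite system in place via Cholesky.
// Returns false when the factorization fails (singular/indefinite).
static bool chol_solve(std::vector<double>& A, std::vector<double>& b, int p) {
  // A is p x p column-major; factor A = L L'
  for (int j = 0; j < p; ++j) {
    double d = A[j + j * p];
    for (int k = 0; k < j; ++k) d -= A[j + k * p] * A[j + k * p];
    if (d <= 0.0) return false;
    d = std::sqrt(d);
    A[j + j * p] = d;
    for (int i = j + 1; i < p; ++i) {
      double s = A[i + j * p];
      for (int k = 0; k < j; ++k) s -= A[i + k * p] * A[j + k * p];
      A[i + j * p] = s / d;
    }
  }
  // forward substitution L y = b
  for (int i = 0; i < p; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= A[i + k * p] * b[k];
    b[i] = s / A[i + i * p];
  }
  // back substitution L' x = y
  for (int i = p - 1; i >= 0; --i) {
    double s = b[i];
    for (int k = i + 1; k < p; ++k) s -= A[k + i * p] * b[k];
    b[i] = s / A[i + i * p];
  }
  return true;
}

// Invert SPD matrix from its (already computed) Cholesky factor stored in A.
static void chol_inverse(std::vector<double>& A, std::vector<double>& inv, int p) {
  // columns of the inverse via repeated solves with unit vectors
  std::vector<double> e(p);
  for (int j = 0; j < p; ++j) {
    std::fill(e.begin(), e.end(), 0.0);
    e[j] = 1.0;
    for (int i = 0; i < p; ++i) {
      double s = e[i];
      for (int k = 0; k < i; ++k) s -= A[i + k * p] * e[k];
      e[i] = s / A[i + i * p];
    }
    for (int i = p - 1; i >= 0; --i) {
      double s = e[i];
      for (int k = i + 1; k < p; ++k) s -= A[k + i * p] * e[k];
      e[i] = s / A[i + i * p];
    }
    for (int i = 0; i < p; ++i) inv[i + j * p] = e[i];
  }
}

//' Logistic regression by iteratively reweighted least squares
//'
//' Minimal binomial-logit IRLS used for the per-window principal-component
//' regressions. An optional ridge penalty stabilizes separated fits.
//'
//' @param X design matrix (n x p), first column typically the intercept.
//' @param y 0/1 response vector of length n.
//' @param ridge L2 penalty added to the diagonal of the information matrix
//'   (0 for the unpenalized fit).
//' @param maxit maximum IRLS iterations.
//' @param tol convergence tolerance on the coefficient change.
//' @return list with `coef`, `se2` (diagonal of the inverse information),
//'   `converged`, and `separated` (fit drifted to infinite coefficients).
//' @keywords internal
// [[Rcpp::export]]
List irls_logit(NumericMatrix X, NumericVector y, double ridge = 0.0,
                int maxit = 30, double tol = 1e-8,
                Nullable<NumericVector> init = R_NilValue) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> beta(p, 0.0), beta_old(p), eta(n), mu(n), w(n);
  if (init.isNotNull()) {
    NumericVector b0(init);
    if ((int)b0.size() == p)
      for (int j = 0; j < p; ++j) beta[j] = b0[j];
  }
  std::vector<double> XtWX(p * p), Xtz(p), rhs(p);
  bool converged = false, separated = false;

  for (int it = 0; it < maxit; ++it) {
    for (int i = 0; i < n; ++i) {
      double e = 0.0;
      for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
      if (e > 30.0) e = 30.0; else if (e < -30.0) e = -30.0;
      eta[i] = e;
      mu[i] = 1.0 / (1.0 + std::exp(-e));
      w[i] = mu[i] * (1.0 - mu[i]);
      if (w[i] < 1e-10) w[i] = 1e-10;
    }
    std::fill(XtWX.begin(), XtWX.end(), 0.0);
    std::fill(Xtz.begin(), Xtz.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double zi = w[i] * eta[i] + (y[i] - mu[i]); // w * working response
      for (int j = 0; j < p; ++j) {
        double xij = X(i, j);
        Xtz[j] += xij * zi;
        for (int k = 0; k <= j; ++k) XtWX[j + k * p] += w[i] * xij * X(i, k);
      }
    }
    for (int j = 0; j < p; ++j) {
      for (int k = 0; k < j; ++k) XtWX[k + j * p] = XtWX[j + k * p];
      XtWX[j + j * p] += ridge;
    }
    std::vector<double> A(XtWX);
    rhs = Xtz;
    if (!chol_solve(A, rhs, p)) { separated = true; break; }
    beta_old = beta;
    beta = rhs;
    double delta = 0.0, scale = 0.0;
    for (int j = 0; j < p; ++j) {
      delta += std::fabs(beta[j] - beta_old[j]);
      scale += std::fabs(beta[j]);
      if (!R_finite(beta[j]) || std::fabs(beta[j]) > 1e6) separated = true;
    }
    if (separated) break;
    if (delta < tol * (1.0 + scale)) { converged = true; break; }
  }

  // diagonal of the inverse information at the final beta
  NumericVector se2(p, NA_REAL);
  if (!separated) {
    std::fill(XtWX.begin(), XtWX.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double e = 0.0;
      for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
      double m = 1.0 / (1.0 + std::exp(-e));
      double wi = std::max(m * (1.0 - m), 1e-10);
      for (int j = 0; j < p; ++j)
        for (int k = 0; k <= j; ++k) XtWX[j + k * p] += wi * X(i, j) * X(i, k);
    }
    for (int j = 0; j < p; ++j) {
      for (int k = 0; k < j; ++k) XtWX[k + j * p] = XtWX[j + k * p];
      XtWX[j + j * p] += ridge;
    }
    std::vector<double> A(XtWX), dummy(p, 0.0);
    // factor once, then invert
    bool ok = true;
    {
      std::vector<double> Af(A), bf(p, 0.0);
      ok = chol_solve(Af, bf, p); // factor check
      if (ok) {
        std::vector<double> inv(p * p);
        // refactor for inverse (chol_solve destroyed only copies)
        std::vector<double> L(A);
        std::vector<double> b0(p, 0.0);
        chol_solve(L, b0, p); // leaves factor in L
        chol_inverse(L, inv, p);
        for (int j = 0; j < p; ++j) se2[j] = inv[j + j * p];
      }
    }
  }
  return List::create(_["coef"] = NumericVector(beta.begin(), beta.end()),
                      _["se2"] = se2,
                      _["converged"] = converged,
                      _["separated"] = separated);
}
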