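// Active-set non-negative least squares on the normal equations
// (fast-NNLS of Bro & de Jong, 1997), plus batched drivers used by the
// deconvolution updates. All solvers operate on A'A / A'b so that the
// Gram matrix of a shared design is formed once per batch.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Solve the passive-set least-squares subproblem; falls back to a
// pseudo-inverse when the passive Gram block is singular (degenerate
// designs, e.g. duplicated cell types).
static vec solve_passive(const mat& AtA, const vec& Atb, const uvec& P) {
  mat App = AtA.submat(P, P);
  vec bp = Atb.elem(P);
  vec s;
  bool ok = solve(s, App, bp, solve_opts::no_approx);
  if (!ok || !s.is_finite()) {
    s = pinv(App) * bp;
  }
  return s;
}

// Core fast-NNLS: argmin_{x >= 0} 0.5 x'AtA x - Atb'x.
static vec fnnls_core(const mat& AtA, const vec& Atb) {
  const uword q = AtA.n_rows;
  vec x(q, fill::zeros);
  std::vector<bool> passive(q, false);
  vec w = Atb; // negative gradient at x = 0

  double tol = 10.0 * datum::eps * norm(AtA, 1) * static_cast<double>(q);
  if (!std::isfinite(tol) || tol <= 0.0) tol = 10.0 * datum::eps;

  const uword outer_max = 30 * q + 30;
  uword outer = 0;

  while (outer++ < outer_max) {
    // most violating KKT multiplier among free variables
    double wmax = -datum::inf;
    sword jmax = -1;
    for (uword j = 0; j < q; ++j) {
      if (!passive[j] && w(j) > wmax) { wmax = w(j); jmax = j; }
    }
    if (jmax < 0 || wmax <= tol) break;
    passive[(uword)jmax] = true;

    uword inner = 0;
    while (inner++ < outer_max) {
      std::vector<uword> pidx;
      for (uword j = 0; j < q; ++j) if (passive[j]) pidx.push_back(j);
      uvec P = conv_to<uvec>::from(pidx);
      if (P.n_elem == 0) { x.zeros(); break; }
      vec s = solve_passive(AtA, Atb, P);
      if (s.min() > 0.0) {
        x.zeros();
        x.elem(P) = s;
        break;
      }
      // step back along the segment x -> s to the first zero crossing
      double alpha = datum::inf;
      for (uword i = 0; i < P.n_elem; ++i) {
        if (s(i) <= 0.0) {
          double xi = x(P(i));
          double denom = xi - s(i);
          double a = (denom > 0.0) ? xi / denom : 0.0;
          if (a < alpha) alpha = a;
        }
      }
      if (!std::isfinite(alpha)) alpha = 0.0;
      for (uword i = 0; i < P.n_elem; ++i) {
        x(P(i)) += alpha * (s(i) - x(P(i)));
      }
      for (uword j = 0; j < q; ++j) {
        if (passive[j] && x(j) <= tol) { passive[j] = false; x(j) = 0.0; }
      }
    }
    w = Atb - AtA * x;
  }
  x.elem(find(x < 0.0)).zeros();
  return x;
}

// [[Rcpp::export]]
arma::vec cpp_nnls(const arma::mat& A, const arma::vec& b) {
  mat AtA = A.t() * A;
  vec Atb = A.t() * b;
  return fnnls_core(AtA, Atb);
}

// Solve min ||A x - B[,j]|| over x >= 0 for every column j of B.
// [[Rcpp::export]]
arma::mat cpp_nnls_multi(const arma::mat& A, const arma::mat& B) {
  mat AtA = A.t() * A;
  mat AtB = A.t() * B;
  mat X(A.n_cols, B.n_cols);
  for (uword j = 0; j < B.n_cols; ++j) {
    X.col(j) = fnnls_core(AtA, AtB.col(j));
  }
  return X;
}

// Coupled per-gene W update. For gene j the stacked design is
//   [ H1t        0   ]
//   [ 0          H2t ]
//   [ sqrt(lam) diag(sqrt(E_j))   -sqrt(lam) diag(sqrt(E_j)) ]
// with response (Y1t[,j], Y2t[,j], 0_k). Only the Gram matrix's diagonal
// coupling blocks change across genes, so the H Gram blocks are reused.
// [[Rcpp::export]]
arma::mat cpp_joint_w_update(const arma::mat& Y1t, const arma::mat& Y2t,
                             const arma::mat& H1t, const arma::mat& H2t,
                             const arma::mat& E, const double lam) {
  const uword k = H1t.n_cols;
  const uword m = Y1t.n_cols;
  mat G1 = H1t.t() * H1t;
  mat G2 = H2t.t() * H2t;
  mat A1tY = H1t.t() * Y1t;
  mat A2tY = H2t.t() * Y2t;

  mat X(2 * k, m);
  mat AtA(2 * k, 2 * k, fill::zeros);
  vec Atb(2 * k);
  for (uword j = 0; j < m; ++j) {
    vec d = lam * E.col(j);
    AtA.submat(0, 0, k - 1, k - 1) = G1 + diagmat(d);
    AtA.submat(k, k, 2 * k - 1, 2 * k - 1) = G2 + diagmat(d);
    AtA.submat(0, k, k - 1, 2 * k - 1) = -diagmat(d);
    AtA.submat(k, 0, 2 * k - 1, k - 1) = -diagmat(d);
    Atb.subvec(0, k - 1) = A1tY.col(j);
    Atb.subvec(k, 2 * k - 1) = A2tY.col(j);
    X.col(j) = fnnls_core(AtA, Atb);
  }
  return X;
}
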