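#include <Rcpp.h>
using namespace Rcpp;

// Graphical lasso by block coordinate descent (Friedman, Hastie &
// Tibshirani 2008).  Estimates a sparse precision matrix Theta maximising
//   log det(Theta) - tr(S Theta) - rho * ||Theta||_1(off-diagonal)
// for a symmetric positive-definite input S.  At rho = 0 the solution is
// the plain inverse of S.  Pure Rcpp: dimensions here are alignment
// lengths (a few hundred), so no external BLAS plumbing is needed beyond
// what the inner products below do.

// lasso sub-problem: minimise 0.5 b'Vb - s'b + rho|b|_1 by coordinate
// descent; V is (p-1)x(p-1) symmetric PD.
static void lasso_cd(const NumericMatrix& V, const NumericVector& s,
                     NumericVector& b, double rho, int maxit, double tol) {
  const int m = s.size();
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (int j = 0; j < m; ++j) {
      double g = s[j];
      for (int k = 0; k < m; ++k)
        if (k != j) g -= V(j, k) * b[k];
      double bj;
      if (g > rho) bj = (g - rho) / V(j, j);
      else if (g < -rho) bj = (g + rho) / V(j, j);
      else bj = 0.0;
      double d = std::fabs(bj - b[j]);
      if (d > dmax) dmax = d;
      b[j] = bj;
    }
    if (dmax < tol) break;
  }
}

// [[Rcpp::export(name = ".glasso_cpp")]]
List glasso_cpp(NumericMatrix S, double rho,
                int maxit = 100, double tol = 1e-8,
                int inner_maxit = 500, double inner_tol = 1e-10) {
  const int p = S.nrow();
  // working covariance estimate; diagonal unpenalized so the identity
  // maps to the identity at any rho and rho -> 0 gives the exact inverse
  NumericMatrix W(clone(S));
  NumericMatrix B(p, p);         // column regression coefficients

  double thr = 0.0;              // convergence scale: mean |off-diag S|
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) thr += std::fabs(S(i, j));
  thr = (p > 1) ? thr / (p * (p - 1.0)) : 1.0;
  if (thr <= 0) thr = 1.0;

  NumericMatrix V(p - 1, p - 1);
  NumericVector s12(p - 1), beta(p - 1);
  bool converged = (p == 1);

  for (int it = 0; it < maxit && !converged; ++it) {
    double shift = 0.0;
    for (int j = 0; j < p; ++j) {
      int a = 0;
      for (int r = 0; r < p; ++r) {
        if (r == j) continue;
        int b_ = 0;
        for (int c = 0; c < p; ++c) {
          if (c == j) continue;
          V(a, b_) = W(r, c);
          ++b_;
        }
        s12[a] = S(r, j);
        beta[a] = B(r, j);
        ++a;
      }
      lasso_cd(V, s12, beta, rho, inner_maxit, inner_tol);
      a = 0;
      for (int r = 0; r < p; ++r) {
        if (r == j) continue;
        double w = 0.0;
        for (int k = 0; k < p - 1; ++k) w += V(a, k) * beta[k];
        shift += std::fabs(W(r, j) - w);
        W(r, j) = w;
        W(j, r) = w;
        B(r, j) = beta[a];
        ++a;
      }
    }
    if (p > 1) shift /= p * (p - 1.0);
    if (shift < tol * thr) converged = true;
  }

  // back out Theta = W^{-1} from the final regressions
  NumericMatrix Theta(p, p);
  for (int j = 0; j < p; ++j) {
    double q = W(j, j);
    int a = 0;
    for (int r = 0; r < p; ++r) {
      if (r == j) continue;
      q -= W(r, j) * B(r, j);
      ++a;
    }
    double t22 = 1.0 / q;
    Theta(j, j) = t22;
    for (int r = 0; r < p; ++r)
      if (r != j) Theta(r, j) = -B(r, j) * t22;
  }
  // symmetrise (numerical)
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) {
      double v = 0.5 * (Theta(i, j) + Theta(j, i));
      Theta(i, j) = v;
      Theta(j, i) = v;
    }

  return List::create(_["theta"] = Theta, _["w"] = W,
                      _["converged"] = converged);
}
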