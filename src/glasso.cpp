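#include <Rcpp.h>
using namespace Rcpp;

// Graphical lasso by blockwise coordinate descent (Friedman-Hastie-Tibshirani).
// Solves max log det(Theta) - tr(S Theta) - lambda * ||Theta||_1 (off-diagonal
// penalty applied to all entries as in the reference algorithm; the diagonal
// of W is fixed at diag(S) + lambda).
//
// S: p x p empirical covariance/correlation. W, B are warm starts (estimated
// covariance and the p x p matrix of per-column regression coefficients,
// B(k, j) = beta_k for column j, B(j, j) unused). Both are modified copies.

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export]]
List glasso_cd(NumericMatrix S_, double lambda, NumericMatrix W_,
               NumericMatrix B_, double tol, int maxit) {
  NumericMatrix S(clone(S_)), W(clone(W_)), B(clone(B_));
  const int p = S.nrow();

  // convergence threshold scaled by average absolute off-diagonal of S
  double savg = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) savg += std::fabs(S(i, j));
  savg /= (double)(p * (p - 1));
  if (savg <= 0.0) savg = 1.0;
  const double thr = tol * savg;

  for (int j = 0; j < p; ++j) W(j, j) = S(j, j) + lambda;

  bool converged = false;
  int it = 0;
  std::vector<double> w12(p);
  for (it = 0; it < maxit; ++it) {
    double dw_max = 0.0;
    for (int j = 0; j < p; ++j) {
      // inner lasso: beta minimizes 0.5 b' W11 b - s12' b + lambda |b|_1
      for (int inner = 0; inner < 1000; ++inner) {
        double db_max = 0.0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          double grad = S(k, j);
          for (int l = 0; l < p; ++l) {
            if (l == j || l == k) continue;
            grad -= W(k, l) * B(l, j);
          }
          double bnew = soft(grad, lambda) / W(k, k);
          double d = std::fabs(bnew - B(k, j));
          if (d > db_max) db_max = d;
          B(k, j) = bnew;
        }
        if (db_max < thr * 0.1) break;
      }
      // w12 = W11 * beta
      for (int k = 0; k < p; ++k) {
        if (k == j) { w12[k] = W(j, j); continue; }
        double acc = 0.0;
        for (int l = 0; l < p; ++l) {
          if (l == j) continue;
          acc += W(k, l) * B(l, j);
        }
        w12[k] = acc;
      }
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        double d = std::fabs(w12[k] - W(k, j));
        if (d > dw_max) dw_max = d;
        W(k, j) = w12[k];
        W(j, k) = w12[k];
      }
    }
    if (dw_max < thr) { converged = true; ++it; break; }
  }

  // recover Theta: theta_jj = 1 / (w_jj - w12' beta); theta_.j = -beta * theta_jj
  NumericMatrix Theta(p, p);
  for (int j = 0; j < p; ++j) {
    double q = W(j, j);
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      q -= W(k, j) * B(k, j);
    }
    double tjj = 1.0 / q;
    Theta(j, j) = tjj;
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      Theta(k, j) = -B(k, j) * tjj;
    }
  }
  // symmetrize (numerically near-symmetric at convergence)
  for (int j = 0; j < p; ++j)
    for (int k = j + 1; k < p; ++k) {
      double v = 0.5 * (Theta(k, j) + Theta(j, k));
      Theta(k, j) = v;
      Theta(j, k) = v;
    }

  return List::create(_["W"] = W, _["B"] = B, _["Theta"] = Theta,
                      _["iterations"] = it, _["converged"] = converged);
}
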