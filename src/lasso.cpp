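#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for (1/(2n)) ||r - X g||^2 + lambda ||g||_1,
// warm-started down a decreasing penalty path. X should be centred.

// [[Rcpp::export]]
NumericMatrix lasso_path_cpp(NumericMatrix X, NumericVector r,
                             NumericVector lambdas, double tol,
                             int max_sweeps) {
  int n = X.nrow(), p = X.ncol(), nl = lambdas.size();
  std::vector<double> xtx(p), g(p, 0.0), res(r.begin(), r.end());
  for (int j = 0; j < p; ++j) {
    double s = 0; const double* xj = &X(0, j);
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xtx[j] = s / n;
  }
  NumericMatrix out(p, nl);
  for (int l = 0; l < nl; ++l) {
    double lam = lambdas[l];
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      double delta_max = 0;
      for (int j = 0; j < p; ++j) {
        if (xtx[j] <= 0) continue;
        const double* xj = &X(0, j);
        double z = 0;
        for (int i = 0; i < n; ++i) z += xj[i] * res[i];
        z = z / n + xtx[j] * g[j];
        double gn = 0.0;
        if (z > lam) gn = (z - lam) / xtx[j];
        else if (z < -lam) gn = (z + lam) / xtx[j];
        if (gn != g[j]) {
          double d = gn - g[j];
          for (int i = 0; i < n; ++i) res[i] -= xj[i] * d;
          double ch = std::fabs(d) * std::sqrt(xtx[j]);
          if (ch > delta_max) delta_max = ch;
          g[j] = gn;
        }
      }
      if (delta_max < tol) break;
    }
    for (int j = 0; j < p; ++j) out(j, l) = g[j];
  }
  return out;
}
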