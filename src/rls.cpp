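#include <Rcpp.h>
using namespace Rcpp;

// Exponentially weighted RLS estimation of time-varying AR coefficients.
//
// Model: x[n] = -sum_k a_k[n] x[n-k] + v[n], so the regressor is
// u[n] = (-x[n-1], ..., -x[n-M]) and the one-step prediction is u.a.
// Recursion (a-priori form), for n = M+1..N:
//   e[n]  = x[n] - u'a
//   k     = P u / (lambda + u'P u)
//   a    <- a + k e[n]
//   P    <- (P - k (P u)') / lambda, then symmetrized
// Rows 1..M of the coefficient matrix hold the initial value a = 0.
// [[Rcpp::export(name = ".rls_tvar")]]
List rls_tvar(NumericVector x, int M, double lambda, double delta) {
  const int n = x.size();
  if (n <= M) stop("signal must be longer than the model order");
  if (lambda <= 0.0 || lambda > 1.0) stop("lambda must be in (0, 1]");
  if (delta <= 0.0) stop("delta must be positive");

  NumericMatrix A(n, M);       // coefficient trajectories, zero-initialized
  NumericVector err(n);        // a-priori prediction errors (0 for n <= M)
  std::vector<double> a(M, 0.0), u(M), Pu(M), k(M);
  std::vector<double> P(M * M, 0.0);
  for (int i = 0; i < M; ++i) P[i * M + i] = 1.0 / delta;

  for (int t = M; t < n; ++t) {
    for (int i = 0; i < M; ++i) u[i] = -x[t - 1 - i];

    double pred = 0.0;
    for (int i = 0; i < M; ++i) pred += u[i] * a[i];
    const double e = x[t] - pred;

    double uPu = 0.0;
    for (int i = 0; i < M; ++i) {
      double s = 0.0;
      for (int j = 0; j < M; ++j) s += P[i * M + j] * u[j];
      Pu[i] = s;
      uPu += u[i] * s;
    }
    const double denom = lambda + uPu;
    for (int i = 0; i < M; ++i) k[i] = Pu[i] / denom;
    for (int i = 0; i < M; ++i) a[i] += k[i] * e;

    for (int i = 0; i < M; ++i)
      for (int j = 0; j < M; ++j)
        P[i * M + j] = (P[i * M + j] - k[i] * Pu[j]) / lambda;
    // enforce symmetry to suppress round-off drift
    for (int i = 0; i < M; ++i)
      for (int j = i + 1; j < M; ++j) {
        const double s = 0.5 * (P[i * M + j] + P[j * M + i]);
        P[i * M + j] = s;
        P[j * M + i] = s;
      }

    err[t] = e;
    for (int i = 0; i < M; ++i) A(t, i) = a[i];
  }

  return List::create(_["coeffs"] = A, _["errors"] = err);
}
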