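// Log-domain scaling iterations for entropy-regularized unbalanced
// optimal transport with KL marginal relaxation:
//
//   min_{pi >= 0}  <pi, M> + eps * sum(pi * (log pi - 1))
//                  + gamma * KL(pi 1 | a) + gamma * KL(pi' 1 | b)
//
// The scaling fixed point is u = (a / K v)^{gamma/(gamma+eps)},
// v = (b / K' u)^{gamma/(gamma+eps)} with K = exp(-M/eps); everything is
// iterated on log u, log v so that arbitrarily small eps stays stable.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double logsumexp_row(const std::vector<double>& x) {
  double m = R_NegInf;
  for (double v : x) if (v > m) m = v;
  if (!R_finite(m)) return R_NegInf;
  double s = 0.0;
  for (double v : x) s += std::exp(v - m);
  return m + std::log(s);
}

// [[Rcpp::export]]
List uot_sinkhorn_cpp(NumericVector a, NumericVector b, NumericMatrix M,
                      double eps, double gamma, int max_iter, double tol) {
  const int n = a.size(), m = b.size();
  std::vector<double> la(n), lb(m), lu(n, 0.0), lv(m, 0.0);
  for (int i = 0; i < n; ++i) la[i] = std::log(a[i]);
  for (int j = 0; j < m; ++j) lb[j] = std::log(b[j]);
  // C(i,j) = M(i,j)/eps, precomputed
  std::vector<double> C(static_cast<size_t>(n) * m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i)
      C[static_cast<size_t>(j) * n + i] = M(i, j) / eps;
  const double ratio = gamma / (gamma + eps);
  std::vector<double> tmp_m(m), tmp_n(n);
  int it = 0;
  bool converged = false;
  for (it = 1; it <= max_iter; ++it) {
    double delta = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < m; ++j)
        tmp_m[j] = lv[j] - C[static_cast<size_t>(j) * n + i];
      double lKv = logsumexp_row(tmp_m);
      double lu_new = ratio * (la[i] - lKv);
      double d = std::fabs(lu_new - lu[i]);
      if (d > delta) delta = d;
      lu[i] = lu_new;
    }
    for (int j = 0; j < m; ++j) {
      for (int i = 0; i < n; ++i)
        tmp_n[i] = lu[i] - C[static_cast<size_t>(j) * n + i];
      double lKu = logsumexp_row(tmp_n);
      double lv_new = ratio * (lb[j] - lKu);
      double d = std::fabs(lv_new - lv[j]);
      if (d > delta) delta = d;
      lv[j] = lv_new;
    }
    if (delta * eps < tol) { converged = true; break; }
  }
  // primal quantities from the converged potentials
  NumericVector m_row(n), m_col(m);
  double transport = 0.0;
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      double lp = lu[i] + lv[j] - C[static_cast<size_t>(j) * n + i];
      double p = std::exp(lp);
      m_row[i] += p;
      m_col[j] += p;
      transport += p * M(i, j);
    }
  }
  return List::create(
    _["lu"] = NumericVector(lu.begin(), lu.end()),
    _["lv"] = NumericVector(lv.begin(), lv.end()),
    _["m_row"] = m_row, _["m_col"] = m_col,
    _["transport"] = transport,
    _["iterations"] = it > max_iter ? max_iter : it,
    _["converged"] = converged);
}

// Coupled scaling iterations for the unbalanced entropic barycenter of S
// nonnegative mass vectors (columns of A) under the same ground cost:
// minimizes sum_s w_s W(a_s, b) over b.  The closed-form b-update is the
// power mean  b = ( sum_s w_s (K'u_s)^{eps/(gamma+eps)} )^{(gamma+eps)/eps}.
// [[Rcpp::export]]
List uot_barycenter_cpp(NumericMatrix A, NumericMatrix M, double eps,
                        double gamma, NumericVector w, int max_iter,
                        double tol) {
  const int n = A.nrow(), S = A.ncol();
  const double ratio = gamma / (gamma + eps);
  const double pw = eps / (gamma + eps);
  std::vector<double> C(static_cast<size_t>(n) * n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      C[static_cast<size_t>(j) * n + i] = M(i, j) / eps;
  std::vector<std::vector<double>> la(S, std::vector<double>(n)),
      lu(S, std::vector<double>(n, 0.0)), lv(S, std::vector<double>(n, 0.0)),
      lKu(S, std::vector<double>(n));
  std::vector<double> lw(S);
  for (int s = 0; s < S; ++s) {
    lw[s] = std::log(w[s]);
    for (int i = 0; i < n; ++i)
      la[s][i] = A(i, s) > 0 ? std::log(A(i, s)) : R_NegInf;
  }
  std::vector<double> lb(n, 0.0), tmp(n), lse_s(S);
  int it = 0;
  bool converged = false;
  for (it = 1; it <= max_iter; ++it) {
    for (int s = 0; s < S; ++s) {
      for (int i = 0; i < n; ++i) {
        for (int j = 0; j < n; ++j)
          tmp[j] = lv[s][j] - C[static_cast<size_t>(j) * n + i];
        double lKv = logsumexp_row(tmp);
        lu[s][i] = R_finite(la[s][i]) ? ratio * (la[s][i] - lKv) : R_NegInf;
      }
      for (int j = 0; j < n; ++j) {
        for (int i = 0; i < n; ++i)
          tmp[i] = lu[s][i] - C[static_cast<size_t>(j) * n + i];
        lKu[s][j] = logsumexp_row(tmp);
      }
    }
    double delta = 0.0;
    for (int j = 0; j < n; ++j) {
      for (int s = 0; s < S; ++s) lse_s[s] = lw[s] + pw * lKu[s][j];
      double lb_new = logsumexp_row(lse_s) / pw;
      double d = std::fabs(lb_new - lb[j]);
      if (R_finite(d) && d > delta) delta = d;
      lb[j] = lb_new;
    }
    for (int s = 0; s < S; ++s)
      for (int j = 0; j < n; ++j)
        lv[s][j] = R_finite(lb[j]) ? ratio * (lb[j] - lKu[s][j]) : R_NegInf;
    if (delta * eps < tol) { converged = true; break; }
  }
  NumericVector b(n);
  for (int j = 0; j < n; ++j)
    b[j] = R_finite(lb[j]) ? std::exp(lb[j]) : 0.0;
  return List::create(_["b"] = b,
                      _["iterations"] = it > max_iter ? max_iter : it,
                      _["converged"] = converged);
}
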