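#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Banded dynamic time warping of two scalar series under local cost
// |a_i - b_j|, symmetric unit-weight steps {(1,0),(0,1),(1,1)} and fixed
// endpoints. band <= 0 means unconstrained. Traceback tie-break: diagonal
// first, then the (i-1, j) predecessor (advance along a), then (i, j-1).
// [[Rcpp::export(name = ".dtw_core")]]
List dtw_core(NumericVector a, NumericVector b, int band) {
  const int n = a.size(), m = b.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> D((n + 1) * (m + 1), INF);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  D[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    int jlo = 1, jhi = m;
    if (band > 0) {
      jlo = std::max(1, i - band);
      jhi = std::min(m, i + band);
    }
    for (int j = jlo; j <= jhi; ++j) {
      double best = D[at(i - 1, j - 1)];
      if (D[at(i - 1, j)] < best) best = D[at(i - 1, j)];
      if (D[at(i, j - 1)] < best) best = D[at(i, j - 1)];
      if (best < INF) D[at(i, j)] = std::fabs(a[i - 1] - b[j - 1]) + best;
    }
  }
  double cost = D[at(n, m)];
  if (!R_finite(cost)) stop("no admissible warping path within the band");

  std::vector<int> pi, pj;
  int i = n, j = m;
  pi.push_back(i);
  pj.push_back(j);
  while (i > 1 || j > 1) {
    double diag = (i > 1 && j > 1) ? D[at(i - 1, j - 1)] : INF;
    double up = (i > 1) ? D[at(i - 1, j)] : INF;
    double left = (j > 1) ? D[at(i, j - 1)] : INF;
    double best = std::min(diag, std::min(up, left));
    if (diag == best) {
      --i;
      --j;
    } else if (up == best) {
      --i;
    } else {
      --j;
    }
    pi.push_back(i);
    pj.push_back(j);
  }
  const int L = pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = pi[L - 1 - k];
    path(k, 1) = pj[L - 1 - k];
  }
  return List::create(_["cost"] = cost, _["path"] = path);
}
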