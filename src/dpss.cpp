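// Discrete prolate spheroidal sequences (Slepian tapers) via the classic
// symmetric-tridiagonal formulation: the k-th DPSS of length N and
// half-bandwidth W is the eigenvector of the tridiagonal matrix with
//   diag[i] = ((N - 1 - 2i) / 2)^2 cos(2 pi W),  i = 0..N-1
//   off [i] = i (N - i) / 2,                     i = 1..N-1
// belonging to its (k+1)-th largest eigenvalue. Top-K eigenpairs are found
// by Sturm-sequence bisection plus inverse iteration, O(K N) per solve.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// number of eigenvalues of the tridiagonal (d, e) strictly less than x
int sturm_count(const std::vector<double> &d, const std::vector<double> &e,
                double x) {
  int n = (int)d.size(), cnt = 0;
  double q = d[0] - x;
  if (q < 0) ++cnt;
  for (int i = 1; i < n; ++i) {
    if (q == 0.0) q = 1e-300;
    q = (d[i] - x) - e[i] * e[i] / q;
    if (q < 0) ++cnt;
  }
  return cnt;
}

// solve (T - lam I) x = b by tridiagonal Gaussian elimination with partial
// pivoting (4-band storage)
void trisolve_shifted(const std::vector<double> &d, const std::vector<double> &e,
                      double lam, std::vector<double> &x) {
  int n = (int)d.size();
  std::vector<double> a(n), bdiag(n), c(n, 0.0), f(n, 0.0);
  for (int i = 0; i < n; ++i) {
    bdiag[i] = d[i] - lam;
    a[i] = (i > 0) ? e[i] : 0.0;       // subdiagonal entry coupling i-1,i
    c[i] = (i < n - 1) ? e[i + 1] : 0.0;  // superdiagonal
  }
  // forward elimination with row swaps
  for (int i = 0; i < n - 1; ++i) {
    double sub = a[i + 1];
    if (std::fabs(sub) > std::fabs(bdiag[i])) {
      std::swap(bdiag[i], sub);             // pivot rows i, i+1
      double tc = c[i]; c[i] = bdiag[i + 1]; bdiag[i + 1] = tc;
      if (i < n - 2) { f[i] = c[i + 1]; c[i + 1] = 0.0; }
      std::swap(x[i], x[i + 1]);
    }
    if (bdiag[i] == 0.0) bdiag[i] = 1e-300;
    double m = sub / bdiag[i];
    bdiag[i + 1] -= m * c[i];
    if (i < n - 2) c[i + 1] -= m * f[i];
    x[i + 1] -= m * x[i];
  }
  // back substitution
  if (bdiag[n - 1] == 0.0) bdiag[n - 1] = 1e-300;
  x[n - 1] /= bdiag[n - 1];
  if (n >= 2) x[n - 2] = (x[n - 2] - c[n - 2] * x[n - 1]) / bdiag[n - 2];
  for (int i = n - 3; i >= 0; --i)
    x[i] = (x[i] - c[i] * x[i + 1] - f[i] * x[i + 2]) / bdiag[i];
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix dpss_tapers(int n, double nw, int k) {
  if (n < 2) stop("taper length must be >= 2");
  if (k < 1 || k > n) stop("invalid taper count");
  double W = nw / n;
  if (W >= 0.5) stop("time-bandwidth too large for series length");
  std::vector<double> d(n), e(n, 0.0);
  double c2w = std::cos(2.0 * M_PI * W);
  for (int i = 0; i < n; ++i) {
    double h = (n - 1 - 2.0 * i) / 2.0;
    d[i] = h * h * c2w;
    if (i > 0) e[i] = i * (n - i) / 2.0;
  }
  // Gershgorin bounds
  double lo = d[0], hi = d[0];
  for (int i = 0; i < n; ++i) {
    double r = ((i > 0) ? std::fabs(e[i]) : 0.0) +
               ((i < n - 1) ? std::fabs(e[i + 1]) : 0.0);
    lo = std::min(lo, d[i] - r);
    hi = std::max(hi, d[i] + r);
  }

  NumericMatrix tapers(n, k);
  std::vector<std::vector<double>> found;

  for (int j = 0; j < k; ++j) {
    int target = n - 1 - j;  // eigenvalue index (ascending) of j-th largest
    double a = lo, b = hi;
    for (int it = 0; it < 120 && (b - a) > 1e-12 * std::max(1.0, std::fabs(b));
         ++it) {
      double mid = 0.5 * (a + b);
      if (sturm_count(d, e, mid) <= target) a = mid; else b = mid;
    }
    double lam = 0.5 * (a + b);

    // inverse iteration from a deterministic start
    std::vector<double> v(n);
    for (int i = 0; i < n; ++i)
      v[i] = std::sin((j + 1) * M_PI * (i + 1) / (n + 1.0)) + 1e-4 * (i % 7);
    for (int it = 0; it < 6; ++it) {
      // orthogonalise against previously found vectors
      for (const auto &u : found) {
        double dp = 0;
        for (int i = 0; i < n; ++i) dp += u[i] * v[i];
        for (int i = 0; i < n; ++i) v[i] -= dp * u[i];
      }
      trisolve_shifted(d, e, lam + 1e-10, v);
      double nrm = 0;
      for (int i = 0; i < n; ++i) nrm += v[i] * v[i];
      nrm = std::sqrt(nrm);
      for (int i = 0; i < n; ++i) v[i] /= nrm;
    }
    // sign convention: symmetric tapers positive mean, antisymmetric tapers
    // positive initial lobe
    double s = 0;
    for (int i = 0; i < n; ++i) s += v[i];
    if (std::fabs(s) > 1e-8) {
      if (s < 0) for (int i = 0; i < n; ++i) v[i] = -v[i];
    } else {
      double first = 0;
      for (int i = 0; i < n / 2; ++i) first += v[i];
      if (first < 0) for (int i = 0; i < n; ++i) v[i] = -v[i];
    }
    for (int i = 0; i < n; ++i) tapers(i, j) = v[i];
    found.push_back(v);
  }
  return tapers;
}
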