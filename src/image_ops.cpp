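#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 8-connected labelling of a binary matrix. Labels are assigned in
// column-major scan order of the first pixel met, so output is deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const IntegerMatrix &mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<int> q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) != 0 && lab(i, j) == 0) {
        lab(i, j) = ++next;
        q.push(i + j * nr);
        while (!q.empty()) {
          int p = q.front(); q.pop();
          int pi = p % nr, pj = p / nr;
          for (int dj = -1; dj <= 1; ++dj) {
            for (int di = -1; di <= 1; ++di) {
              int qi = pi + di, qj = pj + dj;
              if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
              if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
                lab(qi, qj) = next;
                q.push(qi + qj * nr);
              }
            }
          }
        }
      }
    }
  }
  return lab;
}

// Separable Gaussian blur with reflected boundary; kernel truncated at
// ceil(3*sigma).
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(const NumericMatrix &img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  const int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += k[d + r] * img(reflect(i + d, nr), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += k[d + r] * tmp(i, reflect(j + d, nc));
      out(i, j) = acc;
    }
  return out;
}
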