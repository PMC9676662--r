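#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// 3x3 spatial median per band with reflect (edge-replicating) padding.
// cube dims: lines x pixels x bands, column-major.
// [[Rcpp::export(name = ".median3x3_cpp")]]
NumericVector median3x3_cpp(NumericVector cube, IntegerVector dims) {
  const int L = dims[0], P = dims[1], B = dims[2];
  NumericVector out(cube.size());
  out.attr("dim") = dims;
  std::vector<double> win(9);
  for (int b = 0; b < B; ++b) {
    const double *src = &cube[(R_xlen_t)b * L * P];
    double *dst = &out[(R_xlen_t)b * L * P];
    for (int p = 0; p < P; ++p) {
      for (int l = 0; l < L; ++l) {
        int k = 0;
        for (int dp = -1; dp <= 1; ++dp) {
          int pp = p + dp;
          if (pp < 0) pp = 0; else if (pp >= P) pp = P - 1;
          for (int dl = -1; dl <= 1; ++dl) {
            int ll = l + dl;
            if (ll < 0) ll = 0; else if (ll >= L) ll = L - 1;
            win[k++] = src[ll + (R_xlen_t)pp * L];
          }
        }
        std::nth_element(win.begin(), win.begin() + 4, win.end());
        dst[l + (R_xlen_t)p * L] = win[4];
      }
    }
  }
  return out;
}

// 4-connected component labelling of a logical matrix (two-pass union-find).
// Labels are 1..n in first-encounter (column-major) order before relabelling;
// final labels are renumbered 1..n by scan order of the representative.
// [[Rcpp::export(name = ".label4_cpp")]]
IntegerMatrix label4_cpp(LogicalMatrix mask) {
  const int L = mask.nrow(), P = mask.ncol();
  IntegerMatrix lab(L, P);
  std::vector<int> parent(1, 0); // parent[0] unused

  auto find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };

  int next = 0;
  // pass over pixels in (line-major) scan order: line by line, pixel by pixel
  for (int l = 0; l < L; ++l) {
    for (int p = 0; p < P; ++p) {
      if (!mask(l, p)) continue;
      int up = (l > 0 && mask(l - 1, p)) ? lab(l - 1, p) : 0;
      int left = (p > 0 && mask(l, p - 1)) ? lab(l, p - 1) : 0;
      if (up == 0 && left == 0) {
        ++next;
        parent.push_back(next);
        lab(l, p) = next;
      } else if (up != 0 && left == 0) {
        lab(l, p) = up;
      } else if (up == 0) {
        lab(l, p) = left;
      } else {
        int ru = find(up), rl = find(left);
        int r = std::min(ru, rl);
        parent[ru] = r; parent[rl] = r;
        lab(l, p) = r;
      }
    }
  }
  // second pass: resolve + renumber compactly in scan order
  std::vector<int> newlab(next + 1, 0);
  int n = 0;
  for (int l = 0; l < L; ++l) {
    for (int p = 0; p < P; ++p) {
      if (!mask(l, p)) continue;
      int r = find(lab(l, p));
      if (newlab[r] == 0) newlab[r] = ++n;
      lab(l, p) = newlab[r];
    }
  }
  return lab;
}
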