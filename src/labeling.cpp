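#include <Rcpp.h>
#include <functional>
using namespace Rcpp;

// Two-pass union-find connected-component labeling with 8-connectivity.
// Labels are assigned in raster order (top-to-bottom, left-to-right) of each
// component's first pixel, so the result is deterministic.
//
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);

  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (a < b) parent[b] = a; else parent[a] = b;
  };

  int next = 1;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c)) continue;
      // previously visited 8-neighbours in raster order
      const int nb[4][2] = {{r - 1, c - 1}, {r - 1, c}, {r - 1, c + 1}, {r, c - 1}};
      int lmin = 0;
      for (int k = 0; k < 4; ++k) {
        int rr = nb[k][0], cc = nb[k][1];
        if (rr < 0 || cc < 0 || cc >= nc) continue;
        if (!mask(rr, cc)) continue;
        int l = lab(rr, cc);
        if (lmin == 0 || l < lmin) lmin = l;
      }
      if (lmin == 0) {
        lab(r, c) = next;
        parent.push_back(next);
        ++next;
      } else {
        lab(r, c) = lmin;
        for (int k = 0; k < 4; ++k) {
          int rr = nb[k][0], cc = nb[k][1];
          if (rr < 0 || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc)) unite(lab(rr, cc), lmin);
        }
      }
    }
  }

  // compact labels in raster order of first occurrence
  std::vector<int> newlab(next, 0);
  int k = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c)) continue;
      int root = find(lab(r, c));
      if (newlab[root] == 0) newlab[root] = ++k;
      lab(r, c) = newlab[root];
    }
  }
  lab.attr("n_objects") = k;
  return lab;
}
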