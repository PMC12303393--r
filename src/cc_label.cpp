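#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-pass union-find connected-component labelling on a logical matrix.
// connectivity: 4 (edge neighbours) or 8 (edge + diagonal neighbours).
// Labels are assigned in raster (column-major) order of first encounter,
// then compacted to 1..n.

static int find_root(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void unite(std::vector<int> &parent, int a, int b) {
  int ra = find_root(parent, a), rb = find_root(parent, b);
  if (ra < rb) parent[rb] = ra; else parent[ra] = rb;
}

// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(256);
  int next = 0;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      // previously visited neighbours in column-major raster order
      int best = -1;
      int nbr[4][2] = {{r - 1, c}, {r, c - 1}, {r - 1, c - 1}, {r + 1, c - 1}};
      int nn = (connectivity == 4) ? 2 : 4;
      for (int k = 0; k < nn; ++k) {
        int rr = nbr[k][0], cc = nbr[k][1];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (!mask(rr, cc)) continue;
        int l = lab(rr, cc) - 1;
        if (best < 0) best = l; else unite(parent, best, l);
      }
      if (best < 0) {
        parent.push_back(next);
        lab(r, c) = ++next;
      } else {
        lab(r, c) = find_root(parent, best) + 1;
      }
    }
  }

  // compact roots to consecutive ids
  std::vector<int> remap(next, 0);
  int nfinal = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) {
        int root = find_root(parent, lab(r, c) - 1);
        if (remap[root] == 0) remap[root] = ++nfinal;
        lab(r, c) = remap[root];
      }
  return lab;
}
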