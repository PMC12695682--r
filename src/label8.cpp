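#include <Rcpp.h>
using namespace Rcpp;

// Two-pass connected-component labelling with 8-connectivity and
// union-find label equivalence. Input is a logical matrix (NA treated as
// background); output an integer matrix with labels 1..k in raster order
// of first appearance after relabelling.

static int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void unite(std::vector<int>& parent, int a, int b) {
  int ra = find_root(parent, a), rb = find_root(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export(name = ".label8cpp")]]
IntegerMatrix label8cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // label 0 = background
  int next = 1;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == NA_LOGICAL || !mask(i, j)) { lab(i, j) = 0; continue; }
      // previously visited 8-neighbours in column-major raster order:
      // (i-1, j), (i-1, j-1), (i, j-1), (i+1, j-1)
      int neigh[4] = {0, 0, 0, 0};
      if (i > 0)               neigh[0] = lab(i - 1, j);
      if (i > 0 && j > 0)      neigh[1] = lab(i - 1, j - 1);
      if (j > 0)               neigh[2] = lab(i, j - 1);
      if (i < nr - 1 && j > 0) neigh[3] = lab(i + 1, j - 1);
      int lmin = 0;
      for (int k = 0; k < 4; ++k)
        if (neigh[k] > 0 && (lmin == 0 || neigh[k] < lmin)) lmin = neigh[k];
      if (lmin == 0) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else {
        lab(i, j) = lmin;
        for (int k = 0; k < 4; ++k)
          if (neigh[k] > 0) unite(parent, neigh[k], lmin);
      }
    }
  }

  // resolve equivalences and relabel densely
  std::vector<int> remap(next, 0);
  int out = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) {
        int r = find_root(parent, lab(i, j));
        if (remap[r] == 0) remap[r] = ++out;
        lab(i, j) = remap[r];
      }
  return lab;
}
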