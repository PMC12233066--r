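#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-pass connected-component labeling with union-find.
// Labels are relabeled to consecutive integers 1..K in raster-scan order
// of first appearance, so output is deterministic for a given mask.

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra < rb) parent[rb] = ra; else if (rb < ra) parent[ra] = rb;
}

// [[Rcpp::export]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(1024);
  parent.push_back(0); // dummy so labels are 1-based

  // raster order: column-major to match R storage; neighbor offsets are the
  // already-visited half of the 4- or 8-neighborhood
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int best = 0;
      int cand[4];
      int ncand = 0;
      if (i > 0 && mask(i - 1, j)) cand[ncand++] = lab(i - 1, j);
      if (j > 0 && mask(i, j - 1)) cand[ncand++] = lab(i, j - 1);
      if (connectivity == 8) {
        if (i > 0 && j > 0 && mask(i - 1, j - 1)) cand[ncand++] = lab(i - 1, j - 1);
        if (i < nr - 1 && j > 0 && mask(i + 1, j - 1)) cand[ncand++] = lab(i + 1, j - 1);
      }
      for (int k = 0; k < ncand; ++k) {
        int r = uf_find(parent, cand[k]);
        if (best == 0 || r < best) best = r;
      }
      if (best == 0) {
        int nl = (int)parent.size();
        parent.push_back(nl);
        lab(i, j) = nl;
      } else {
        lab(i, j) = best;
        for (int k = 0; k < ncand; ++k) uf_union(parent, best, cand[k]);
      }
    }
  }

  // second pass: resolve + relabel consecutively by first raster appearance
  std::vector<int> newlab(parent.size(), 0);
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = uf_find(parent, l);
      if (newlab[r] == 0) newlab[r] = ++next;
      lab(i, j) = newlab[r];
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// Binary dilation/erosion with an arbitrary structuring element given as
// offset vectors (dr, dc). `outside` sets the value assumed beyond the
// image: false for dilation; true for the erosion half of a closing, so
// closing never detaches frame-touching objects from the frame.
// [[Rcpp::export]]
LogicalMatrix bin_morph(LogicalMatrix mask, IntegerVector dr, IntegerVector dc,
                        bool dilate, bool outside) {
  const int nr = mask.nrow(), nc = mask.ncol(), m = dr.size();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      bool v = dilate ? false : true;
      for (int k = 0; k < m; ++k) {
        int ii = i + dr[k], jj = j + dc[k];
        bool px = (ii >= 0 && ii < nr && jj >= 0 && jj < nc) ? (bool)mask(ii, jj) : outside;
        if (dilate) { if (px) { v = true; break; } }
        else        { if (!px) { v = false; break; } }
      }
      out(i, j) = v;
    }
  }
  return out;
}
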