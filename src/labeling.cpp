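#include <Rcpp.h>
using namespace Rcpp;

// Two-pass connected-component labeling with union-find, 8-connectivity.
// Returns an integer matrix with components numbered 1..k in raster order
// of first appearance; background is 0.

static int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];  // path halving
    i = parent[i];
  }
  return i;
}

static void unite(std::vector<int>& parent, int a, int b) {
  int ra = find_root(parent, a);
  int rb = find_root(parent, b);
  if (ra < rb) parent[rb] = ra; else if (rb < ra) parent[ra] = rb;
}

// [[Rcpp::export]]
IntegerMatrix label_components_8(LogicalMatrix mask) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> parent;
  parent.push_back(0);  // dummy so provisional labels start at 1
  int next = 1;

  // first pass: scan column-major (R layout); neighbours already visited
  // relative to (r, c) are (r-1, c-1), (r, c-1), (r+1, c-1), (r-1, c)
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      const int dr[4] = {-1, 0, 1, -1};
      const int dc[4] = {-1, -1, -1, 0};
      int nb[4];
      int nnb = 0;
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= h || cc < 0 || cc >= w) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          nb[nnb++] = l;
          if (best == 0 || l < best) best = l;
        }
      }
      if (best == 0) {
        parent.push_back(next);
        lab(r, c) = next++;
      } else {
        lab(r, c) = best;
        for (int k = 0; k < nnb; ++k) unite(parent, best, nb[k]);
      }
    }
  }

  // second pass: resolve roots and renumber consecutively
  std::vector<int> renum(parent.size(), 0);
  int k = 0;
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = find_root(parent, l);
      if (renum[root] == 0) renum[root] = ++k;
      lab(r, c) = renum[root];
    }
  }
  return lab;
}
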