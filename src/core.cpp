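#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find with path halving
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// 8-connected component labeling of a binary raster.
// Returns an integer matrix with consecutive labels 1..n (0 = background).
// [[Rcpp::export]]
IntegerMatrix label8_cpp(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);  // parent[0] unused
  int next = 1;

  // first pass: column-major scan; predecessors are (r-1,c), (r,c-1),
  // (r-1,c-1), (r+1,c-1)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      int neigh[4][2] = {{r - 1, c}, {r, c - 1}, {r - 1, c - 1}, {r + 1, c - 1}};
      for (int k = 0; k < 4; ++k) {
        int rr = neigh[k][0], cc = neigh[k][1];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          if (best == 0) best = l;
          else uf_union(parent, best, l);
        }
      }
      if (best == 0) {
        parent.push_back(next);
        lab(r, c) = next++;
      } else {
        lab(r, c) = best;
      }
    }
  }

  // resolve to consecutive labels
  std::vector<int> remap(next, 0);
  int nlab = 0;
  for (int i = 1; i < next; ++i) {
    int root = uf_find(parent, i);
    if (remap[root] == 0) remap[root] = ++nlab;
    remap[i] = remap[root];
  }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) lab(r, c) = remap[lab(r, c)];
  return lab;
}

static inline int px(const IntegerMatrix& m, int r, int c) {
  if (r < 0 || r >= m.nrow() || c < 0 || c >= m.ncol()) return 0;
  return m(r, c) ? 1 : 0;
}

// Guo-Hall morphological thinning of a binary raster to a 1-px skeleton
// (cleaner diagonals than Zhang-Suen: no two-pixel staircase residue).
// [[Rcpp::export]]
IntegerMatrix thin_cpp(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img = clone(mask);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      img(r, c) = img(r, c) ? 1 : 0;

  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!img(r, c)) continue;
          // neighbours p2..p9 clockwise starting north
          int p2 = px(img, r - 1, c),     p3 = px(img, r - 1, c + 1);
          int p4 = px(img, r, c + 1),     p5 = px(img, r + 1, c + 1);
          int p6 = px(img, r + 1, c),     p7 = px(img, r + 1, c - 1);
          int p8 = px(img, r, c - 1),     p9 = px(img, r - 1, c - 1);
          int C = ((!p2 && (p3 || p4)) ? 1 : 0) +
                  ((!p4 && (p5 || p6)) ? 1 : 0) +
                  ((!p6 && (p7 || p8)) ? 1 : 0) +
                  ((!p8 && (p9 || p2)) ? 1 : 0);
          int N1 = ((p9 || p2) ? 1 : 0) + ((p3 || p4) ? 1 : 0) +
                   ((p5 || p6) ? 1 : 0) + ((p7 || p8) ? 1 : 0);
          int N2 = ((p2 || p3) ? 1 : 0) + ((p4 || p5) ? 1 : 0) +
                   ((p6 || p7) ? 1 : 0) + ((p8 || p9) ? 1 : 0);
          int N = N1 < N2 ? N1 : N2;
          int m = (step == 0) ? (((p6 || p7 || !p9) && p8) ? 1 : 0)
                              : (((p2 || p3 || !p5) && p4) ? 1 : 0);
          if (C == 1 && N >= 2 && N <= 3 && m == 0)
            kill.push_back(std::make_pair(r, c));
        }
      }
      for (size_t k = 0; k < kill.size(); ++k)
        img(kill[k].first, kill[k].second) = 0;
      if (!kill.empty()) changed = true;
    }
  }
  return img;
}
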