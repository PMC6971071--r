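#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// 8-connected component labeling of a logical matrix.
// Returns an integer matrix: 0 = background, components numbered 1..k
// in order of first appearance (column-major scan, matching R storage).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix &mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // dummy so labels are 1-based

  // First pass: provisional labels. Column-major scan; already-visited
  // 8-neighbors of (r, c) are (r-1, c), (r-1, c-1), (r, c-1), (r+1, c-1).
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int lmin = 0;
      int cand[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
      for (int k = 0; k < 4; ++k) {
        int rr = cand[k][0], cc = cand[k][1];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        int l = lab(rr, cc);
        if (l > 0) lmin = (lmin == 0) ? l : std::min(lmin, l);
      }
      if (lmin == 0) {
        parent.push_back((int)parent.size());
        lab(r, c) = (int)parent.size() - 1;
      } else {
        lab(r, c) = lmin;
        for (int k = 0; k < 4; ++k) {
          int rr = cand[k][0], cc = cand[k][1];
          if (rr < 0 || rr >= nr || cc < 0) continue;
          int l = lab(rr, cc);
          if (l > 0) uf_union(parent, l, lmin);
        }
      }
    }
  }

  // Second pass: flatten and renumber consecutively by first appearance.
  std::vector<int> newlab(parent.size(), 0);
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = uf_find(parent, l);
      if (newlab[root] == 0) newlab[root] = ++next;
      lab(r, c) = newlab[root];
    }
  }
  return lab;
}

static inline int px(const LogicalMatrix &m, int r, int c) {
  if (r < 0 || r >= m.nrow() || c < 0 || c >= m.ncol()) return 0;
  return m(r, c) ? 1 : 0;
}

// Zhang-Suen thinning to a 1-pixel-wide, topology-preserving skeleton.
// Out-of-image pixels count as background.
// [[Rcpp::export]]
LogicalMatrix thin_mask_cpp(const LogicalMatrix &mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix img(clone(mask));
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!img(r, c)) continue;
          // Neighbors in Zhang-Suen order P2..P9 (P2 = north, clockwise).
          int p2 = px(img, r - 1, c), p3 = px(img, r - 1, c + 1);
          int p4 = px(img, r, c + 1), p5 = px(img, r + 1, c + 1);
          int p6 = px(img, r + 1, c), p7 = px(img, r + 1, c - 1);
          int p8 = px(img, r, c - 1), p9 = px(img, r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (sub == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      for (size_t i = 0; i < kill.size(); ++i)
        img(kill[i].first, kill[i].second) = FALSE;
      if (!kill.empty()) changed = true;
    }
  }
  return img;
}
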