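#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <climits>
#include <cmath>

using namespace Rcpp;

// Row/col offsets for 4- and 8-neighborhoods. The 4-neighborhood order
// (up, down, left, right) is load-bearing for the breadth-first tracer:
// among equal-length paths the one found under this expansion order wins.
static const int DR4[4] = {-1, 1, 0, 0};
static const int DC4[4] = {0, 0, -1, 1};
static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Label connected components of pixels equal to `target` (0 or 1).
// Components are numbered 1..n in raster-scan order of their first pixel,
// which gives a deterministic labeling used for tie-breaking downstream.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerMatrix cc_label_cpp(IntegerMatrix mask, int connectivity, int target) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  const int *dr = (connectivity == 8) ? DR8 : DR4;
  const int *dc = (connectivity == 8) ? DC8 : DC4;
  int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  // raster scan: row-major (across columns first, top row first)
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (mask(r, c) != target || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r * W + c);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p / W, pc = p % W;
        for (int k = 0; k < nn; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
          if (mask(qr, qc) == target && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr * W + qc);
          }
        }
      }
    }
  }
  return lab;
}

// Pixel count and enclosed (hole) area per line component. The enclosed
// area is found by flood-filling the component's padded bounding box from
// the outside; anything unreachable and not part of the component is
// enclosed by it. "Filled area" (pixels + enclosure) ranks contours the
// way an outer-contour area would.
// [[Rcpp::export(name = ".component_areas_cpp")]]
List component_areas_cpp(IntegerMatrix lab, int ncomp) {
  int H = lab.nrow(), W = lab.ncol();
  IntegerVector size(ncomp), enclosed(ncomp);
  std::vector<int> rmin(ncomp, INT_MAX), rmax(ncomp, -1),
                   cmin(ncomp, INT_MAX), cmax(ncomp, -1);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      int id = lab(r, c);
      if (id > 0) {
        size[id - 1]++;
        rmin[id - 1] = std::min(rmin[id - 1], r);
        rmax[id - 1] = std::max(rmax[id - 1], r);
        cmin[id - 1] = std::min(cmin[id - 1], c);
        cmax[id - 1] = std::max(cmax[id - 1], c);
      }
    }
  for (int id = 1; id <= ncomp; ++id) {
    int r0 = rmin[id - 1] - 1, r1 = rmax[id - 1] + 1;
    int c0 = cmin[id - 1] - 1, c1 = cmax[id - 1] + 1;
    int bh = r1 - r0 + 1, bw = c1 - c0 + 1;
    std::vector<char> vis((size_t)bh * bw, 0);
    std::vector<int> stack;
    stack.push_back(0); // (r0, c0) is outside the image or not this component
    vis[0] = 1;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int pr = p / bw, pc = p % bw;
      for (int k = 0; k < 4; ++k) {
        int qr = pr + DR4[k], qc = pc + DC4[k];
        if (qr < 0 || qr >= bh || qc < 0 || qc >= bw) continue;
        size_t qi = (size_t)qr * bw + qc;
        if (vis[qi]) continue;
        int gr = r0 + qr, gc = c0 + qc;
        bool is_comp = gr >= 0 && gr < H && gc >= 0 && gc < W &&
                       lab(gr, gc) == id;
        if (!is_comp) {
          vis[qi] = 1;
          stack.push_back(qr * bw + qc);
        }
      }
    }
    int enc = 0;
    for (int pr = 0; pr < bh; ++pr)
      for (int pc = 0; pc < bw; ++pc) {
        int gr = r0 + pr, gc = c0 + pc;
        bool is_comp = gr >= 0 && gr < H && gc >= 0 && gc < W &&
                       lab(gr, gc) == id;
        if (!is_comp && !vis[(size_t)pr * bw + pc]) ++enc;
      }
    enclosed[id - 1] = enc;
  }
  return List::create(_["size"] = size, _["enclosed"] = enclosed);
}

// Topology-preserving thinning. Black (1) pixels are removed in order of
// their adjacency to white pixels (count of white 8-neighbors, descending;
// raster order among ties). A pixel is removed only when
//  (a) all of its white 4-neighbors belong to a single white region, so
//      removal neither creates nor merges white regions (the region
//      count is invariant; labels are maintained incrementally), and
//  (b) its black 8-neighbors form one contiguous run around the pixel,
//      so a one-pixel line is never broken locally (ring corners, line
//      interiors and junction pixels survive; blobs still erode).
// [[Rcpp::export(name = ".thin_cpp")]]
IntegerMatrix thin_cpp(IntegerMatrix mask_in) {
  int H = mask_in.nrow(), W = mask_in.ncol();
  IntegerMatrix mask = clone(mask_in);
  IntegerMatrix wl = cc_label_cpp(mask, 4, 0); // white region labels
  struct Cand { int adj; int idx; };
  std::vector<Cand> cands;
  bool changed = true;
  while (changed) {
    changed = false;
    cands.clear();
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c) {
        if (mask(r, c) != 1) continue;
        int adj = 0;
        for (int k = 0; k < 8; ++k) {
          int qr = r + DR8[k], qc = c + DC8[k];
          if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
          if (mask(qr, qc) == 0) ++adj;
        }
        if (adj > 0) cands.push_back({adj, r * W + c});
      }
    std::stable_sort(cands.begin(), cands.end(),
                     [](const Cand &a, const Cand &b) {
                       if (a.adj != b.adj) return a.adj > b.adj;
                       return a.idx < b.idx;
                     });
    // circular order of the 8 neighbors (consecutive entries are
    // 8-adjacent cells), for counting black runs around a pixel
    static const int CR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
    static const int CC[8] = {0, 1, 1, 1, 0, -1, -1, -1};
    for (size_t i = 0; i < cands.size(); ++i) {
      int r = cands[i].idx / W, c = cands[i].idx % W;
      if (mask(r, c) != 1) continue;
      int lab = 0;
      bool ok = true;
      for (int k = 0; k < 4; ++k) {
        int qr = r + DR4[k], qc = c + DC4[k];
        if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
        if (mask(qr, qc) == 0) {
          int l = wl(qr, qc);
          if (lab == 0) lab = l;
          else if (lab != l) { ok = false; break; }
        }
      }
      if (!ok || lab == 0) continue;
      int ring[8], nb = 0;
      for (int k = 0; k < 8; ++k) {
        int qr = r + CR[k], qc = c + CC[k];
        ring[k] = (qr >= 0 && qr < H && qc >= 0 && qc < W &&
                   mask(qr, qc) == 1) ? 1 : 0;
        nb += ring[k];
      }
      int runs = 0;
      for (int k = 0; k < 8; ++k)
        if (ring[k] == 1 && ring[(k + 7) % 8] == 0) ++runs;
      if (nb > 0 && runs != 1) continue; // would break a thin structure
      mask(r, c) = 0;
      wl(r, c) = lab;
      changed = true;
    }
  }
  return mask;
}

// Fewest-steps 4-connected path between two pixels of `passable` (1 =
// traversable). Breadth-first with neighbor order up, down, left, right;
// returns the k x 2 path (1-based row, col) or NULL when unreachable.
// [[Rcpp::export(name = ".bfs_path_cpp")]]
SEXP bfs_path_cpp(IntegerMatrix passable, int sr, int sc, int gr, int gc) {
  int H = passable.nrow(), W = passable.ncol();
  --sr; --sc; --gr; --gc; // to 0-based
  if (sr < 0 || sr >= H || sc < 0 || sc >= W ||
      gr < 0 || gr >= H || gc < 0 || gc >= W)
    stop("path endpoints outside the image");
  if (passable(sr, sc) != 1 || passable(gr, gc) != 1)
    stop("path endpoints are not on traversable pixels");
  std::vector<int> parent((size_t)H * W, -2); // -2 unvisited
  std::queue<int> q;
  int s = sr * W + sc, g = gr * W + gc;
  parent[s] = -1;
  q.push(s);
  while (!q.empty()) {
    int p = q.front(); q.pop();
    if (p == g) break;
    int pr = p / W, pc = p % W;
    for (int k = 0; k < 4; ++k) {
      int qr = pr + DR4[k], qc = pc + DC4[k];
      if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
      int qi = qr * W + qc;
      if (passable(qr, qc) == 1 && parent[qi] == -2) {
        parent[qi] = p;
        q.push(qi);
      }
    }
  }
  if (parent[g] == -2) return R_NilValue;
  std::vector<int> path;
  for (int p = g; p != -1; p = parent[p]) path.push_back(p);
  std::reverse(path.begin(), path.end());
  IntegerMatrix out(path.size(), 2);
  for (size_t i = 0; i < path.size(); ++i) {
    out(i, 0) = path[i] / W + 1;
    out(i, 1) = path[i] % W + 1;
  }
  return out;
}

// Exact anisotropic squared Euclidean distance maps, one per region label.
// st2 and sw2 are the squared data-unit lengths of one pixel step along
// rows (temperature) and columns (composition). The transform is exact:
// for each pixel the nearest source row is found per column, then columns
// are scanned outward with an early break, so the returned value is
// min over source pixels of st2*dr^2 + sw2*dc^2 with integer dr, dc --
// bit-identical to a brute-force scan of the same expression.
// [[Rcpp::export(name = ".phase_d2_maps_cpp")]]
List phase_d2_maps_cpp(IntegerMatrix lab, int nphase, double st2, double sw2) {
  int H = lab.nrow(), W = lab.ncol();
  List out(nphase);
  std::vector<int> drm((size_t)H * W); // nearest source row offset per column
  const int BIG = INT_MAX / 4;
  for (int ph = 1; ph <= nphase; ++ph) {
    // pass 1: per column, distance (in rows) to nearest source pixel
    std::vector<char> colHas(W, 0);
    for (int c = 0; c < W; ++c) {
      int last = -BIG;
      for (int r = 0; r < H; ++r) {
        if (lab(r, c) == ph) { last = r; colHas[c] = 1; }
        drm[(size_t)r * W + c] = (last == -BIG) ? BIG : r - last;
      }
      last = BIG;
      for (int r = H - 1; r >= 0; --r) {
        if (lab(r, c) == ph) last = r;
        if (last != BIG) {
          int d = last - r;
          size_t i = (size_t)r * W + c;
          if (d < drm[i]) drm[i] = d;
        }
      }
    }
    NumericMatrix d2(H, W);
    for (int r = 0; r < H; ++r) {
      for (int c = 0; c < W; ++c) {
        double best = R_PosInf;
        // scan columns outward from c; break once the column term alone
        // exceeds the current best
        for (int off = 0; off < W; ++off) {
          double colterm = sw2 * (double)(off * off);
          if (colterm >= best && off > 0) break;
          bool any = false;
          for (int s = 0; s < (off == 0 ? 1 : 2); ++s) {
            int cc = (s == 0) ? c - off : c + off;
            if (off == 0) cc = c;
            if (cc < 0 || cc >= W || !colHas[cc]) continue;
            any = true;
            int dr = drm[(size_t)r * W + cc];
            double v = st2 * (double)(dr * dr) + sw2 * (double)(off * off);
            if (v < best) best = v;
          }
          (void)any;
        }
        d2(r, c) = best;
      }
    }
    out[ph - 1] = d2;
  }
  return out;
}
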