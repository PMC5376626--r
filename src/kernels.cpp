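#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Stroke a set of segments (pixel coordinates, capsule model with round
// caps) into a logical mask of size nrow x ncol. x runs along columns,
// y along rows; pixel (r, c) has center (c + 0.5, r + 0.5).
// [[Rcpp::export]]
LogicalMatrix cpp_draw_segments(int nrow, int ncol,
                                NumericVector x0, NumericVector y0,
                                NumericVector x1, NumericVector y1,
                                NumericVector halfwidth) {
  LogicalMatrix img(nrow, ncol);
  int nseg = x0.size();
  for (int s = 0; s < nseg; s++) {
    double ax = x0[s], ay = y0[s], bx = x1[s], by = y1[s], hw = halfwidth[s];
    int cmin = std::max(0, (int)std::floor(std::min(ax, bx) - hw - 1.0));
    int cmax = std::min(ncol - 1, (int)std::ceil(std::max(ax, bx) + hw + 1.0));
    int rmin = std::max(0, (int)std::floor(std::min(ay, by) - hw - 1.0));
    int rmax = std::min(nrow - 1, (int)std::ceil(std::max(ay, by) + hw + 1.0));
    double dx = bx - ax, dy = by - ay;
    double len2 = dx * dx + dy * dy;
    double hw2 = hw * hw;
    for (int r = rmin; r <= rmax; r++) {
      double py = r + 0.5;
      for (int c = cmin; c <= cmax; c++) {
        if (img(r, c)) continue;
        double px = c + 0.5;
        double t = len2 > 0 ? ((px - ax) * dx + (py - ay) * dy) / len2 : 0.0;
        if (t < 0) t = 0; else if (t > 1) t = 1;
        double ex = ax + t * dx - px, ey = ay + t * dy - py;
        if (ex * ex + ey * ey <= hw2) img(r, c) = true;
      }
    }
  }
  return img;
}

// Zhang-Suen topology-preserving thinning of a binary mask. Only pixels
// on the current foreground boundary are examined each sweep (thick
// regions shrink from the outside in), which keeps dense images fast.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  int Wp = W + 2;
  std::vector<char> img((size_t)(H + 2) * Wp, 0);
  for (int r = 0; r < H; r++)
    for (int c = 0; c < W; c++)
      img[(size_t)(r + 1) * Wp + (c + 1)] = mask(r, c) ? 1 : 0;

  const int off[8] = {-Wp, -Wp + 1, 1, Wp + 1, Wp, Wp - 1, -1, -Wp - 1};
  std::vector<int> active;
  std::vector<char> queued(img.size(), 0);
  for (int r = 1; r <= H; r++)
    for (int c = 1; c <= W; c++) {
      int id = r * Wp + c;
      if (!img[id]) continue;
      for (int k = 0; k < 8; k++)
        if (!img[id + off[k]]) { active.push_back(id); queued[id] = 1; break; }
    }

  std::vector<int> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    // drop stale entries
    size_t w = 0;
    for (size_t k = 0; k < active.size(); k++)
      if (img[active[k]]) active[w++] = active[k];
      else queued[active[k]] = 0;
    active.resize(w);
    for (int pass = 0; pass < 2; pass++) {
      kill.clear();
      for (size_t k = 0; k < active.size(); k++) {
        int id = active[k];
        if (!img[id]) continue;
        int p2 = img[id - Wp],     p3 = img[id - Wp + 1];
        int p4 = img[id + 1],      p5 = img[id + Wp + 1];
        int p6 = img[id + Wp],     p7 = img[id + Wp - 1];
        int p8 = img[id - 1],      p9 = img[id - Wp - 1];
        int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
        if (B < 2 || B > 6) continue;
        int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
        if (A != 1) continue;
        bool cond;
        if (pass == 0)
          cond = (p2 * p4 * p6 == 0) && (p4 * p6 * p8 == 0);
        else
          cond = (p2 * p4 * p8 == 0) && (p2 * p6 * p8 == 0);
        if (cond) kill.push_back(id);
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); k++) {
        img[kill[k]] = 0;
        for (int q = 0; q < 8; q++) {
          int nb = kill[k] + off[q];
          if (img[nb] && !queued[nb]) { queued[nb] = 1; active.push_back(nb); }
        }
      }
    }
  }
  LogicalMatrix out(H, W);
  for (int r = 0; r < H; r++)
    for (int c = 0; c < W; c++)
      out(r, c) = img[(size_t)(r + 1) * Wp + (c + 1)] == 1;
  return out;
}

// Remove 8-connected foreground components smaller than min_size pixels.
// [[Rcpp::export]]
LogicalMatrix cpp_despeckle(LogicalMatrix mask, int min_size) {
  int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix out(H, W);
  std::vector<char> seen((size_t)H * W, 0);
  std::vector<int> stack, comp;
  for (int c0 = 0; c0 < W; c0++) {
    for (int r0 = 0; r0 < H; r0++) {
      size_t id0 = (size_t)c0 * H + r0;
      if (!mask[id0] || seen[id0]) continue;
      stack.clear(); comp.clear();
      stack.push_back((int)id0); seen[id0] = 1;
      while (!stack.empty()) {
        int id = stack.back(); stack.pop_back();
        comp.push_back(id);
        int r = id % H, c = id / H;
        for (int dr = -1; dr <= 1; dr++) {
          for (int dc = -1; dc <= 1; dc++) {
            if (!dr && !dc) continue;
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            int nid = cc * H + rr;
            if (mask[nid] && !seen[nid]) { seen[nid] = 1; stack.push_back(nid); }
          }
        }
      }
      if ((int)comp.size() >= min_size)
        for (size_t k = 0; k < comp.size(); k++) out[comp[k]] = true;
    }
  }
  return out;
}

static double seg_seg_dist(double ax, double ay, double bx, double by,
                           double cx, double cy, double dx, double dy) {
  // minimal distance between segments AB and CD
  double ux = bx - ax, uy = by - ay;
  double vx = dx - cx, vy = dy - cy;
  // proper intersection test via orientations
  double d1 = ux * (cy - ay) - uy * (cx - ax);
  double d2 = ux * (dy - ay) - uy * (dx - ax);
  double d3 = vx * (ay - cy) - vy * (ax - cx);
  double d4 = vx * (by - cy) - vy * (bx - cx);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
    return 0.0;
  // otherwise min over endpoint-to-segment distances
  double best = R_PosInf;
  double pts[4][6] = {
    {cx, cy, ax, ay, bx, by},
    {dx, dy, ax, ay, bx, by},
    {ax, ay, cx, cy, dx, dy},
    {bx, by, cx, cy, dx, dy}
  };
  for (int k = 0; k < 4; k++) {
    double px = pts[k][0], py = pts[k][1];
    double sx = pts[k][2], sy = pts[k][3];
    double ex = pts[k][4], ey = pts[k][5];
    double wx = ex - sx, wy = ey - sy;
    double L2 = wx * wx + wy * wy;
    double t = L2 > 0 ? ((px - sx) * wx + (py - sy) * wy) / L2 : 0.0;
    if (t < 0) t = 0; else if (t > 1) t = 1;
    double qx = sx + t * wx - px, qy = sy + t * wy - py;
    double d = std::sqrt(qx * qx + qy * qy);
    if (d < best) best = d;
  }
  return best;
}

// Flag segments whose stroked areas intersect another segment's stroke.
// Exclusions: adjacent edges of the same root (shared node) and a child
// root's first edge against the parent edges flanking its insertion point.
// root_id: 0-based root index per segment; edge_id: 0-based edge index
// within its root; parent_of / ins_edge: per-root parent root index
// (-1 for axes) and parent edge index containing the insertion point.
// [[Rcpp::export]]
LogicalVector cpp_segment_overlap(NumericVector x0, NumericVector y0,
                                  NumericVector x1, NumericVector y1,
                                  NumericVector radius,
                                  IntegerVector root_id, IntegerVector edge_id,
                                  IntegerVector parent_of, IntegerVector ins_edge) {
  int n = x0.size();
  LogicalVector hit(n);
  if (n == 0) return hit;
  double xmin = R_PosInf, ymin = R_PosInf, xmax = R_NegInf, ymax = R_NegInf;
  double rmax = 0, lmax = 0;
  for (int i = 0; i < n; i++) {
    xmin = std::min(xmin, std::min(x0[i], x1[i]));
    xmax = std::max(xmax, std::max(x0[i], x1[i]));
    ymin = std::min(ymin, std::min(y0[i], y1[i]));
    ymax = std::max(ymax, std::max(y0[i], y1[i]));
    rmax = std::max(rmax, radius[i]);
    double dx = x1[i] - x0[i], dy = y1[i] - y0[i];
    lmax = std::max(lmax, std::sqrt(dx * dx + dy * dy));
  }
  double cell = std::max(lmax + 2 * rmax, 1e-6);
  int nx = std::max(1, (int)std::floor((xmax - xmin) / cell) + 1);
  int ny = std::max(1, (int)std::floor((ymax - ymin) / cell) + 1);
  std::vector<std::vector<int> > grid((size_t)nx * ny);
  std::vector<int> cxlo(n), cxhi(n), cylo(n), cyhi(n);
  for (int i = 0; i < n; i++) {
    double sxmin = std::min(x0[i], x1[i]) - radius[i];
    double sxmax = std::max(x0[i], x1[i]) + radius[i];
    double symin = std::min(y0[i], y1[i]) - radius[i];
    double symax = std::max(y0[i], y1[i]) + radius[i];
    cxlo[i] = std::max(0, (int)((sxmin - xmin) / cell));
    cxhi[i] = std::min(nx - 1, (int)((sxmax - xmin) / cell));
    cylo[i] = std::max(0, (int)((symin - ymin) / cell));
    cyhi[i] = std::min(ny - 1, (int)((symax - ymin) / cell));
    for (int gx = cxlo[i]; gx <= cxhi[i]; gx++)
      for (int gy = cylo[i]; gy <= cyhi[i]; gy++)
        grid[(size_t)gx * ny + gy].push_back(i);
  }
  std::unordered_set<long long> seen;
  for (size_t g = 0; g < grid.size(); g++) {
    const std::vector<int> &v = grid[g];
    for (size_t a = 0; a + 1 < v.size(); a++) {
      for (size_t b = a + 1; b < v.size(); b++) {
        int i = v[a], j = v[b];
        if (i > j) std::swap(i, j);
        if (hit[i] && hit[j]) continue;
        // exclusions
        if (root_id[i] == root_id[j]) {
          if (std::abs(edge_id[i] - edge_id[j]) <= 1) continue;
        } else {
          int ri = root_id[i], rj = root_id[j];
          if (edge_id[i] == 0 && parent_of[ri] == rj &&
              std::abs(edge_id[j] - ins_edge[ri]) <= 1) continue;
          if (edge_id[j] == 0 && parent_of[rj] == ri &&
              std::abs(edge_id[i] - ins_edge[rj]) <= 1) continue;
        }
        long long key = (long long)i * n + j;
        if (!seen.insert(key).second) continue;
        double d = seg_seg_dist(x0[i], y0[i], x1[i], y1[i],
                                x0[j], y0[j], x1[j], y1[j]);
        if (d < radius[i] + radius[j]) {
          hit[i] = true;
          hit[j] = true;
        }
      }
    }
  }
  return hit;
}
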