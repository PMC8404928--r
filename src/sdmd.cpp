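#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double INF_ = 1e20;

// ---------------------------------------------------------------------------
// Exact Euclidean distance / feature transform (Felzenszwalb & Huttenlocher
// lower-envelope method), with argmin tracking so that every pixel also knows
// its nearest source pixel.  All grids are column-major (R layout),
// idx = y + x*h, y = row (downward), x = column (rightward).
// ---------------------------------------------------------------------------

static void dt1d(const double* f, int n, double* d, int* arg,
                 int* v, double* z) {
  int k = 0;
  v[0] = 0; z[0] = -INF_; z[1] = INF_;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INF_;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
    arg[q] = v[k];
  }
}

// squared distance to nearest source + coordinates of that source
static void ft2d(int h, int w, const std::vector<char>& issrc,
                 std::vector<double>& dist2,
                 std::vector<int>& sy, std::vector<int>& sx) {
  int m = std::max(h, w);
  std::vector<double> tmp((size_t)h * w);
  std::vector<int> besty((size_t)h * w);
  std::vector<double> f(m), d(m), z(m + 1);
  std::vector<int> arg(m), v(m);
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) f[y] = issrc[y + (size_t)x * h] ? 0.0 : INF_;
    dt1d(f.data(), h, d.data(), arg.data(), v.data(), z.data());
    for (int y = 0; y < h; ++y) {
      tmp[y + (size_t)x * h] = d[y];
      besty[y + (size_t)x * h] = arg[y];
    }
  }
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) f[x] = tmp[y + (size_t)x * h];
    dt1d(f.data(), w, d.data(), arg.data(), v.data(), z.data());
    for (int x = 0; x < w; ++x) {
      int bx = arg[x];
      dist2[y + (size_t)x * h] = d[x];
      sx[y + (size_t)x * h] = bx;
      sy[y + (size_t)x * h] = besty[y + (size_t)bx * h];
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix fg) {
  int h = fg.nrow(), w = fg.ncol();
  std::vector<char> issrc((size_t)h * w);
  bool any_src = false;
  for (size_t i = 0; i < issrc.size(); ++i) {
    issrc[i] = fg[i] ? 0 : 1;
    if (issrc[i]) any_src = true;
  }
  NumericMatrix out(h, w);
  if (!any_src) {
    std::fill(out.begin(), out.end(), R_PosInf);
    return out;
  }
  std::vector<double> d2((size_t)h * w);
  std::vector<int> sy((size_t)h * w), sx((size_t)h * w);
  ft2d(h, w, issrc, d2, sy, sx);
  for (size_t i = 0; i < d2.size(); ++i) out[i] = std::sqrt(d2[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (conn = 4 or 8), labels 1..k, background 0.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int conn) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::fill(lab.begin(), lab.end(), 0);
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy4[4] = {-1, 0, 0, 1};
  const int dx4[4] = {0, -1, 1, 0};
  const int* dy = (conn == 8) ? dy8 : dy4;
  const int* dx = (conn == 8) ? dx8 : dx4;
  int nd = (conn == 8) ? 8 : 4;
  std::vector<int> stack;
  int next = 0;
  for (int x = 0; x < w; ++x) for (int y = 0; y < h; ++y) {
    size_t i = y + (size_t)x * h;
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back((int)i);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int cy = cur % h, cx = cur / h;
      for (int k = 0; k < nd; ++k) {
        int ny = cy + dy[k], nx = cx + dx[k];
        if (ny < 0 || ny >= h || nx < 0 || nx >= w) continue;
        size_t j = ny + (size_t)nx * h;
        if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back((int)j); }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Moore contour tracing.  Assigns each contour pixel an arc-length parameter
// U (step index of first visit) and a contour id; returns total length per
// contour.  Outer contours of 8-connected foreground components and inner
// contours around 4-connected holes are traced.
// ---------------------------------------------------------------------------

// clockwise 8-neighbourhood, starting east
static const int cdy[8] = {0, 1, 1, 1, 0, -1, -1, -1};
static const int cdx[8] = {1, 1, 0, -1, -1, -1, 0, 1};

// trace one contour over pixels with labF == comp; start pixel (sy,sx),
// initial backtrack direction index bdir (direction from the start pixel to
// its backtrack/background neighbour).  Fills U/cid (first visit wins) and
// returns the closed-walk length (the contour's arc length in pixels).
static int trace_contour(int h, int w, const IntegerVector& labF, int comp,
                         int sy, int sx, int bdir,
                         std::vector<int>& U, std::vector<int>& cid,
                         int contour_id, std::vector<int>& state_step) {
  auto inside = [&](int y, int x) -> bool {
    if (y < 0 || y >= h || x < 0 || x >= w) return false;
    return labF[y + (size_t)x * h] == comp;
  };
  bool has_nbr = false;
  for (int k = 0; k < 8; ++k)
    if (inside(sy + cdy[k], sx + cdx[k])) { has_nbr = true; break; }
  size_t si = sy + (size_t)sx * h;
  if (!has_nbr) {
    if (cid[si] < 0) { cid[si] = contour_id; U[si] = 0; }
    return 1;
  }
  // Walk state: (current pixel, backtrack direction).  The walk is
  // deterministic, so it is eventually periodic; the period is the closed
  // contour length.  Terminate on the first repeated state.
  int cy = sy, cx = sx, bd = bdir;
  int steps = 0, period = 0;
  std::vector<size_t> touched;
  long cap = 8L * h * w + 64;
  while (cap-- > 0) {
    size_t ci = cy + (size_t)cx * h;
    size_t key = ci * 8 + bd;
    if (state_step[key] >= 0) { period = steps - state_step[key]; break; }
    state_step[key] = steps;
    touched.push_back(key);
    if (cid[ci] < 0) { cid[ci] = contour_id; U[ci] = steps; }
    // sweep clockwise starting just after the backtrack neighbour
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      int d = (bd + k) % 8;
      if (inside(cy + cdy[d], cx + cdx[d])) { found = k; break; }
    }
    if (found < 0) break;  // unreachable: has_nbr
    int fd = (bd + found) % 8;
    int pd = (bd + found - 1) % 8;           // background neighbour just before
    int by = cy + cdy[pd], bx = cx + cdx[pd]; // new backtrack pixel
    int ny = cy + cdy[fd], nx = cx + cdx[fd];
    ++steps;
    // direction from new current pixel to new backtrack pixel
    int ndy = by - ny, ndx = bx - nx, nbd = -1;
    for (int d = 0; d < 8; ++d)
      if (cdy[d] == ndy && cdx[d] == ndx) { nbd = d; break; }
    cy = ny; cx = nx; bd = nbd;
  }
  for (size_t k = 0; k < touched.size(); ++k) state_step[touched[k]] = -1;
  return std::max(period > 0 ? period : steps, 1);
}

// ---------------------------------------------------------------------------
// Guo-Hall thinning of a candidate mask (in place on std::vector<char>).
// ---------------------------------------------------------------------------
static void guo_hall(int h, int w, std::vector<char>& img) {
  auto at = [&](int y, int x) -> int {
    if (y < 0 || y >= h || x < 0 || x >= w) return 0;
    return img[y + (size_t)x * h] ? 1 : 0;
  };
  std::vector<size_t> del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      del.clear();
      for (int x = 0; x < w; ++x) for (int y = 0; y < h; ++y) {
        size_t i = y + (size_t)x * h;
        if (!img[i]) continue;
        int p2 = at(y - 1, x),     p3 = at(y - 1, x + 1);
        int p4 = at(y, x + 1),     p5 = at(y + 1, x + 1);
        int p6 = at(y + 1, x),     p7 = at(y + 1, x - 1);
        int p8 = at(y, x - 1),     p9 = at(y - 1, x - 1);
        int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
        int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
        int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
        int N = N1 < N2 ? N1 : N2;
        int m = (iter == 0) ? ((p6 | p7 | (!p9)) & p8)
                            : ((p2 | p3 | (!p5)) & p4);
        if (C == 1 && N >= 2 && N <= 3 && m == 0) del.push_back(i);
      }
      if (!del.empty()) changed = true;
      for (size_t k = 0; k < del.size(); ++k) img[del[k]] = 0;
    }
  }
}

// ---------------------------------------------------------------------------
// Full MAT pipeline for one binary layer:
//   exact EDT -> contour parameterisation -> feature transform ->
//   boundary-collapse importance rho -> candidate detection -> thinning.
// Returns list(skel = logical, dt = numeric, rho = numeric).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_mat(LogicalMatrix fg, bool complete) {
  int h = fg.nrow(), w = fg.ncol();
  size_t n = (size_t)h * w;

  // 1. exact EDT to background
  std::vector<char> isbg(n);
  bool any_bg = false;
  for (size_t i = 0; i < n; ++i) { isbg[i] = fg[i] ? 0 : 1; if (isbg[i]) any_bg = true; }
  if (!any_bg) stop("unbounded layer: no background pixels");
  std::vector<double> d2(n);
  std::vector<int> sy(n), sx(n);
  ft2d(h, w, isbg, d2, sy, sx);
  NumericMatrix dt(h, w);
  for (size_t i = 0; i < n; ++i) dt[i] = fg[i] ? std::sqrt(d2[i]) : 0.0;

  // 2. foreground components (8) and background components (4)
  IntegerMatrix labF = cpp_label(fg, 8);
  LogicalMatrix bgmask(h, w);
  for (size_t i = 0; i < n; ++i) bgmask[i] = !fg[i];
  IntegerMatrix labB = cpp_label(bgmask, 4);
  int ncompF = 0, ncompB = 0;
  for (size_t i = 0; i < n; ++i) {
    if (labF[i] > ncompF) ncompF = labF[i];
    if (labB[i] > ncompB) ncompB = labB[i];
  }
  // background components touching the frame border are "outside", not holes
  std::vector<char> bg_border(ncompB + 1, 0);
  for (int x = 0; x < w; ++x) {
    if (labB(0, x)) bg_border[labB(0, x)] = 1;
    if (labB(h - 1, x)) bg_border[labB(h - 1, x)] = 1;
  }
  for (int y = 0; y < h; ++y) {
    if (labB(y, 0)) bg_border[labB(y, 0)] = 1;
    if (labB(y, w - 1)) bg_border[labB(y, w - 1)] = 1;
  }

  // 3. contours
  std::vector<int> U(n, -1), cid(n, -1);
  std::vector<int> state_step(n * 8, -1);
  std::vector<int> P;           // contour lengths
  std::vector<int> comp_outer(ncompF + 1, -1);
  // outer contours: first pixel of each component in row-major scan
  std::vector<char> seen(ncompF + 1, 0);
  for (int y = 0; y < h; ++y) for (int x = 0; x < w; ++x) {
    int c = labF(y, x);
    if (!c || seen[c]) continue;
    seen[c] = 1;
    int id = (int)P.size();
    // backtrack is the pixel to the west (dir index 4)
    int len = trace_contour(h, w, labF, c, y, x, 4, U, cid, id, state_step);
    P.push_back(len);
    comp_outer[c] = id;
  }
  // inner contours around holes
  std::vector<char> hole_seen(ncompB + 1, 0);
  for (int y = 0; y < h; ++y) for (int x = 0; x < w; ++x) {
    int b = labB(y, x);
    if (!b || bg_border[b] || hole_seen[b]) continue;
    hole_seen[b] = 1;
    // pixel above the topmost-leftmost hole pixel is foreground
    int fy = y - 1, fx = x;
    if (fy < 0) continue;  // cannot happen for a hole
    int c = labF(fy, fx);
    if (!c) continue;
    int id = (int)P.size();
    // backtrack = the hole pixel itself (south of start, dir index 2)
    int len = trace_contour(h, w, labF, c, fy, fx, 2, U, cid, id, state_step);
    P.push_back(len);
  }

  // 4. feature transform to contour pixels
  std::vector<char> issrc(n, 0);
  for (size_t i = 0; i < n; ++i) if (cid[i] >= 0) issrc[i] = 1;
  std::vector<double> cd2(n);
  std::vector<int> cy(n), cx(n);
  ft2d(h, w, issrc, cd2, cy, cx);

  // 5. boundary-collapse importance rho (max circular arc-parameter jump to
  //    any 8-neighbour's feature point; different contours -> both lengths)
  //    and the feature-point separation used for skeleton detection: the
  //    Euclidean distance between the two nearest-boundary points.  Jumps up
  //    to 2*sqrt(2) occur spuriously along straight and staircase
  //    boundaries; genuine medial separation starts at 3 (a 3-px ribbon),
  //    so pixels with separation >= 2.9 are skeletal candidates.
  NumericMatrix rho(h, w);
  std::fill(rho.begin(), rho.end(), 0.0);
  std::vector<double> jump(n, 0.0);
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int x = 0; x < w; ++x) for (int y = 0; y < h; ++y) {
    size_t i = y + (size_t)x * h;
    if (!fg[i]) continue;
    size_t fi = cy[i] + (size_t)cx[i] * h;
    int myc = cid[fi], myU = U[fi];
    double r = 0.0, jmp = 0.0;
    for (int k = 0; k < 8; ++k) {
      int ny = y + dy8[k], nx = x + dx8[k];
      if (ny < 0 || ny >= h || nx < 0 || nx >= w) continue;
      size_t j = ny + (size_t)nx * h;
      if (!fg[j]) continue;
      size_t fj = cy[j] + (size_t)cx[j] * h;
      int nc = cid[fj], nU = U[fj];
      double arc, sep;
      double fdy = (double)cy[i] - cy[j], fdx = (double)cx[i] - cx[j];
      sep = std::sqrt(fdy * fdy + fdx * fdx);
      if (nc != myc) {
        arc = (double)P[myc] + (double)P[nc];
        sep = 1e9;              // separate boundary loops: always medial
      } else {
        int d = std::abs(myU - nU);
        int p = P[myc];
        arc = (double)std::min(d, p - d);
      }
      if (arc > r) r = arc;
      if (sep > jmp) jmp = sep;
    }
    rho[i] = r;
    jump[i] = jmp;
  }

  // 6. candidates: feature separation beyond both the spurious staircase
  //    bound (2*sqrt(2)) and the 60-degree feature-angle bound
  //    (2*dt*sin(30deg) = dt), so shallow same-side digitization corners do
  //    not masquerade as medial points
  std::vector<char> cand(n, 0);
  for (size_t i = 0; i < n; ++i)
    cand[i] = (fg[i] && jump[i] >= 2.9 && jump[i] + 1e-6 >= dt[i]) ? 1 : 0;

  // make sure each component contributes at least one MAT pixel
  std::vector<char> comp_has(ncompF + 1, 0);
  for (size_t i = 0; i < n; ++i) if (cand[i]) comp_has[labF[i]] = 1;
  std::vector<double> best_dt(ncompF + 1, -1.0);
  std::vector<size_t> best_ix(ncompF + 1, 0);
  for (size_t i = 0; i < n; ++i) {
    int c = labF[i];
    if (!c || comp_has[c]) continue;
    if (dt[i] > best_dt[c]) { best_dt[c] = dt[i]; best_ix[c] = i; }
  }
  for (int c = 1; c <= ncompF; ++c) {
    if (!comp_has[c] && best_dt[c] >= 0) {
      cand[best_ix[c]] = 1;
      rho[best_ix[c]] = (double)P[comp_outer[c]];
    }
  }

  // 7. thin to one-pixel width, preserving connectivity; the straddle line
  //    of a medial branch lies between pixels, so each surviving pixel
  //    inherits the collapsed-arc importance of thinning-removed neighbours
  std::vector<char> cand_pre(cand);
  guo_hall(h, w, cand);
  for (int x = 0; x < w; ++x) for (int y = 0; y < h; ++y) {
    size_t i = y + (size_t)x * h;
    if (!cand[i]) continue;
    double r = rho[i];
    for (int k = 0; k < 8; ++k) {
      int ny = y + dy8[k], nx = x + dx8[k];
      if (ny < 0 || ny >= h || nx < 0 || nx >= w) continue;
      size_t j = ny + (size_t)nx * h;
      if (cand_pre[j] && !cand[j] && rho[j] > r) r = rho[j];
    }
    rho[i] = r;
  }

  // 8. coverage completion: the ridge detector can miss weak maximal-disc
  //    centres (rim slivers); greedily add the deepest uncovered pixel --
  //    itself the centre of an inscribed disc -- until the open-disc union
  //    reproduces the layer exactly
  if (complete) {
    std::vector<char> covered(n, 0);
    auto stamp = [&](int py, int px) {
      double r = dt[py + (size_t)px * h];
      int x0 = std::max(0, (int)std::floor(px - r));
      int x1 = std::min(w - 1, (int)std::ceil(px + r));
      int y0 = std::max(0, (int)std::floor(py - r));
      int y1 = std::min(h - 1, (int)std::ceil(py + r));
      double r2 = r * r - 1e-9;
      for (int xx = x0; xx <= x1; ++xx)
        for (int yy = y0; yy <= y1; ++yy) {
          double ddx = xx - px, ddy = yy - py;
          if (ddx * ddx + ddy * ddy < r2) covered[yy + (size_t)xx * h] = 1;
        }
    };
    for (int x = 0; x < w; ++x) for (int y = 0; y < h; ++y)
      if (cand[y + (size_t)x * h]) stamp(y, x);
    std::vector<size_t> uncov;
    for (size_t i = 0; i < n; ++i) if (fg[i] && !covered[i]) uncov.push_back(i);
    std::sort(uncov.begin(), uncov.end(),
              [&](size_t a, size_t b) { return dt[a] > dt[b]; });
    for (size_t k = 0; k < uncov.size(); ++k) {
      size_t i = uncov[k];
      if (covered[i]) continue;
      cand[i] = 1;
      stamp((int)(i % h), (int)(i / h));
    }
  }

  LogicalMatrix skel(h, w);
  for (size_t i = 0; i < n; ++i) skel[i] = cand[i] ? 1 : 0;
  int n_traced = 0;
  for (size_t i = 0; i < n; ++i) if (cid[i] >= 0) ++n_traced;
  IntegerMatrix Um(h, w), Cm(h, w), FYm(h, w), FXm(h, w);
  for (size_t i = 0; i < n; ++i) {
    Um[i] = U[i]; Cm[i] = cid[i];
    FYm[i] = fg[i] ? cy[i] : -1; FXm[i] = fg[i] ? cx[i] : -1;
  }
  return List::create(_["skel"] = skel, _["dt"] = dt, _["rho"] = rho,
                      _["contour_lengths"] = wrap(P),
                      _["n_contour_px"] = n_traced,
                      _["U"] = Um, _["cid"] = Cm,
                      _["fy"] = FYm, _["fx"] = FXm);
}

// ---------------------------------------------------------------------------
// Disc stamping: union of discs centred at (x, y) (0-based pixel centres)
// with radii r, on a h x w canvas.  strict -> open discs (||p-c|| < r).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalMatrix cpp_stamp_discs(int h, int w, NumericVector x, NumericVector y,
                              NumericVector r, bool strict) {
  LogicalMatrix out(h, w);
  std::fill(out.begin(), out.end(), 0);
  double eps = 1e-9;
  for (int s = 0; s < x.size(); ++s) {
    double cx = x[s], cyy = y[s], rr = r[s];
    if (rr <= 0) {
      if (!strict) {
        int px = (int)std::lround(cx), py = (int)std::lround(cyy);
        if (px >= 0 && px < w && py >= 0 && py < h) out(py, px) = 1;
      }
      continue;
    }
    int x0 = std::max(0, (int)std::floor(cx - rr));
    int x1 = std::min(w - 1, (int)std::ceil(cx + rr));
    int y0 = std::max(0, (int)std::floor(cyy - rr));
    int y1 = std::min(h - 1, (int)std::ceil(cyy + rr));
    double r2 = rr * rr;
    for (int px = x0; px <= x1; ++px) {
      double ddx = px - cx;
      for (int py = y0; py <= y1; ++py) {
        double ddy = py - cyy;
        double d2 = ddx * ddx + ddy * ddy;
        bool in = strict ? (d2 < r2 - eps) : (d2 <= r2 + eps);
        if (in) out(py, px) = 1;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable 'valid' convolution with a 1-D kernel (used by the SSIM window).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_sepconv_valid(NumericMatrix img, NumericVector k) {
  int h = img.nrow(), w = img.ncol(), m = k.size();
  int oh = h - m + 1, ow = w - m + 1;
  if (oh < 1 || ow < 1) stop("kernel larger than image");
  NumericMatrix tmp(oh, w);
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < oh; ++y) {
      double s = 0;
      for (int j = 0; j < m; ++j) s += k[j] * img(y + j, x);
      tmp(y, x) = s;
    }
  NumericMatrix out(oh, ow);
  for (int x = 0; x < ow; ++x)
    for (int y = 0; y < oh; ++y) {
      double s = 0;
      for (int j = 0; j < m; ++j) s += k[j] * tmp(y, x + j);
      out(y, x) = s;
    }
  return out;
}
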