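#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
using namespace Rcpp;
#include <map>

// ---- CRC32 (PNG chunk checksums) ----------------------------------------

static uint32_t crc_table[256];
static bool crc_table_ready = false;

static void make_crc_table() {
  for (uint32_t n = 0; n < 256; n++) {
    uint32_t c = n;
    for (int k = 0; k < 8; k++)
      c = (c & 1) ? 0xedb88320L ^ (c >> 1) : c >> 1;
    crc_table[n] = c;
  }
  crc_table_ready = true;
}

// [[Rcpp::export]]
double cpp_crc32(RawVector data) {
  if (!crc_table_ready) make_crc_table();
  uint32_t c = 0xffffffffL;
  for (R_xlen_t i = 0; i < data.size(); i++)
    c = crc_table[(c ^ data[i]) & 0xff] ^ (c >> 8);
  return (double)(c ^ 0xffffffffL);
}

// ---- PNG scanline unfiltering (filters 0-4, 8-bit samples) ---------------

static inline int paeth(int a, int b, int c) {
  int p = a + b - c;
  int pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

// data: h*(1+w*ch) filtered bytes; returns h*w*ch unfiltered (scanline order)
// [[Rcpp::export]]
RawVector cpp_png_unfilter(RawVector data, int h, int w, int ch) {
  int stride = w * ch;
  if ((R_xlen_t)h * (stride + 1) != data.size())
    stop("corrupt PNG: scanline data has wrong length");
  RawVector out((R_xlen_t)h * stride);
  std::vector<unsigned char> prev(stride, 0), cur(stride, 0);
  R_xlen_t pos = 0;
  for (int y = 0; y < h; y++) {
    int f = data[pos++];
    for (int i = 0; i < stride; i++) cur[i] = data[pos++];
    switch (f) {
    case 0: break;
    case 1:
      for (int i = ch; i < stride; i++) cur[i] = (unsigned char)(cur[i] + cur[i - ch]);
      break;
    case 2:
      for (int i = 0; i < stride; i++) cur[i] = (unsigned char)(cur[i] + prev[i]);
      break;
    case 3:
      for (int i = 0; i < stride; i++) {
        int a = i >= ch ? cur[i - ch] : 0;
        cur[i] = (unsigned char)(cur[i] + ((a + prev[i]) >> 1));
      }
      break;
    case 4:
      for (int i = 0; i < stride; i++) {
        int a = i >= ch ? cur[i - ch] : 0;
        int c = i >= ch ? prev[i - ch] : 0;
        cur[i] = (unsigned char)(cur[i] + paeth(a, prev[i], c));
      }
      break;
    default: stop("unsupported PNG filter type %d", f);
    }
    for (int i = 0; i < stride; i++) out[(R_xlen_t)y * stride + i] = cur[i];
    std::swap(prev, cur);
  }
  return out;
}

// ---- separable convolution with reflected borders ------------------------

// [[Rcpp::export]]
NumericMatrix cpp_sepconv(NumericMatrix img, NumericVector k) {
  int h = img.nrow(), w = img.ncol(), m = k.size(), r = (m - 1) / 2;
  NumericMatrix tmp(h, w), out(h, w);
  const double *kp = REAL(k);
  // vertical pass (column-major: contiguous within a column)
  for (int c = 0; c < w; c++) {
    const double *col = &img(0, c);
    double *dst = &tmp(0, c);
    int lo = std::min(r, h), hi = std::max(h - r, lo);
    for (int i = 0; i < lo; i++) {
      double s = 0;
      for (int j = 0; j < m; j++) {
        int ii = i + j - r;
        if (ii < 0) ii = -ii - 1;
        if (ii >= h) ii = 2 * h - ii - 1;
        if (ii < 0) ii = 0;
        if (ii >= h) ii = h - 1;
        s += col[ii] * kp[j];
      }
      dst[i] = s;
    }
    for (int i = lo; i < hi; i++) {
      double s = 0;
      const double *p = col + i - r;
      for (int j = 0; j < m; j++) s += p[j] * kp[j];
      dst[i] = s;
    }
    for (int i = hi; i < h; i++) {
      double s = 0;
      for (int j = 0; j < m; j++) {
        int ii = i + j - r;
        if (ii < 0) ii = -ii - 1;
        if (ii >= h) ii = 2 * h - ii - 1;
        if (ii < 0) ii = 0;
        if (ii >= h) ii = h - 1;
        s += col[ii] * kp[j];
      }
      dst[i] = s;
    }
  }
  // horizontal pass: accumulate shifted columns (keeps accesses contiguous)
  std::fill(out.begin(), out.end(), 0.0);
  for (int j = 0; j < m; j++) {
    double kj = kp[j];
    for (int c = 0; c < w; c++) {
      int cc = c + j - r;
      if (cc < 0) cc = -cc - 1;
      if (cc >= w) cc = 2 * w - cc - 1;
      if (cc < 0) cc = 0;
      if (cc >= w) cc = w - 1;
      const double *src = &tmp(0, cc);
      double *dst = &out(0, c);
      for (int i = 0; i < h; i++) dst[i] += src[i] * kj;
    }
  }
  return out;
}

// ---- connected component labeling ----------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<std::pair<int,int> > nb;
  nb.push_back(std::make_pair(-1, 0)); nb.push_back(std::make_pair(1, 0));
  nb.push_back(std::make_pair(0, -1)); nb.push_back(std::make_pair(0, 1));
  if (connectivity == 8) {
    nb.push_back(std::make_pair(-1, -1)); nb.push_back(std::make_pair(-1, 1));
    nb.push_back(std::make_pair(1, -1)); nb.push_back(std::make_pair(1, 1));
  }
  int next = 0;
  std::vector<std::pair<int,int> > stack;
  for (int c = 0; c < w; c++) for (int i = 0; i < h; i++) {
    if (mask(i, c) == 0 || lab(i, c) != 0) continue;
    next++;
    lab(i, c) = next;
    stack.clear();
    stack.push_back(std::make_pair(i, c));
    while (!stack.empty()) {
      std::pair<int,int> p = stack.back(); stack.pop_back();
      for (size_t q = 0; q < nb.size(); q++) {
        int ni = p.first + nb[q].first, nc = p.second + nb[q].second;
        if (ni < 0 || nc < 0 || ni >= h || nc >= w) continue;
        if (mask(ni, nc) != 0 && lab(ni, nc) == 0) {
          lab(ni, nc) = next;
          stack.push_back(std::make_pair(ni, nc));
        }
      }
    }
  }
  return lab;
}

// ---- binary morphology with an arbitrary structuring element --------------

// offs: k x 2 matrix of (drow, dcol); outside-image treated as background
// [[Rcpp::export]]
IntegerMatrix cpp_binary_morph(IntegerMatrix mask, IntegerMatrix offs, bool dilate) {
  int h = mask.nrow(), w = mask.ncol(), k = offs.nrow();
  IntegerMatrix out(h, w);
  for (int c = 0; c < w; c++) for (int i = 0; i < h; i++) {
    bool hit = dilate ? false : true;
    for (int j = 0; j < k; j++) {
      int ni = i + offs(j, 0), nc = c + offs(j, 1);
      int v = (ni < 0 || nc < 0 || ni >= h || nc >= w) ? 0 : mask(ni, nc);
      if (dilate) { if (v != 0) { hit = true; break; } }
      else        { if (v == 0) { hit = false; break; } }
    }
    out(i, c) = hit ? 1 : 0;
  }
  return out;
}

// ---- polygon rasterization: even-odd scanline, center-on-edge => inside ---

// rings: list of Nx2 (x, y) matrices already in target-level pixel units;
// pixel (r, c) center is (c + 0.5, r + 0.5)
// [[Rcpp::export]]
IntegerMatrix cpp_rasterize_rings(List rings, int nrow, int ncol) {
  IntegerMatrix out(nrow, ncol);
  const double eps = 1e-9;
  std::vector<double> xs;
  for (int r = 0; r < nrow; r++) {
    double yc = r + 0.5;
    xs.clear();
    for (int g = 0; g < rings.size(); g++) {
      NumericMatrix ring = rings[g];
      int n = ring.nrow();
      for (int e = 0; e < n; e++) {
        double x1 = ring(e, 0), y1 = ring(e, 1);
        double x2 = ring((e + 1) % n, 0), y2 = ring((e + 1) % n, 1);
        if (std::fabs(y1 - y2) < eps) {
          // horizontal edge: centers lying on it are inside by convention
          if (std::fabs(y1 - yc) < eps) {
            double lo = std::min(x1, x2), hi = std::max(x1, x2);
            int c0 = (int)std::ceil(lo - 0.5 - eps), c1 = (int)std::floor(hi - 0.5 + eps);
            for (int c = std::max(0, c0); c <= std::min(ncol - 1, c1); c++)
              out(r, c) = 1;
          }
          continue;
        }
        // half-open crossing rule
        if ((y1 <= yc && y2 > yc) || (y2 <= yc && y1 > yc)) {
          double t = (yc - y1) / (y2 - y1);
          xs.push_back(x1 + t * (x2 - x1));
        }
      }
    }
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    for (int c = 0; c < ncol; c++) {
      double xc = c + 0.5;
      int cnt = 0; bool onedge = false;
      for (size_t q = 0; q < xs.size(); q++) {
        if (std::fabs(xs[q] - xc) < eps) { onedge = true; break; }
        if (xs[q] < xc) cnt++;
      }
      if (onedge || (cnt & 1)) out(r, c) = 1;
    }
  }
  return out;
}

// ---- triangle rasterization (barycentric, boundary inclusive) -------------

// pts: Nx2 (x, y); tris: Tx3 one-based vertex indices
// [[Rcpp::export]]
IntegerMatrix cpp_fill_triangles(NumericMatrix pts, IntegerMatrix tris,
                                 int nrow, int ncol) {
  IntegerMatrix out(nrow, ncol);
  const double eps = 1e-9;
  for (int t = 0; t < tris.nrow(); t++) {
    double ax = pts(tris(t, 0) - 1, 0), ay = pts(tris(t, 0) - 1, 1);
    double bx = pts(tris(t, 1) - 1, 0), by = pts(tris(t, 1) - 1, 1);
    double cx = pts(tris(t, 2) - 1, 0), cy = pts(tris(t, 2) - 1, 1);
    double det = (bx - ax) * (cy - ay) - (cx - ax) * (by - ay);
    if (std::fabs(det) < eps) continue;
    int r0 = std::max(0, (int)std::floor(std::min(ay, std::min(by, cy)) - 0.5));
    int r1 = std::min(nrow - 1, (int)std::ceil(std::max(ay, std::max(by, cy)) - 0.5));
    int c0 = std::max(0, (int)std::floor(std::min(ax, std::min(bx, cx)) - 0.5));
    int c1 = std::min(ncol - 1, (int)std::ceil(std::max(ax, std::max(bx, cx)) - 0.5));
    for (int r = r0; r <= r1; r++) {
      double py = r + 0.5;
      for (int c = c0; c <= c1; c++) {
        double px = c + 0.5;
        double l1 = ((bx - px) * (cy - py) - (cx - px) * (by - py)) / det;
        double l2 = ((cx - px) * (ay - py) - (ax - px) * (cy - py)) / det;
        double l3 = 1.0 - l1 - l2;
        if (l1 >= -eps && l2 >= -eps && l3 >= -eps) out(r, c) = 1;
      }
    }
  }
  return out;
}

// ---- Bowyer-Watson Delaunay triangulation ---------------------------------

struct Tri { int a, b, c; bool alive; };

static inline double orient2d(double ax, double ay, double bx, double by,
                              double cx, double cy) {
  return (bx - ax) * (cy - ay) - (cx - ax) * (by - ay);
}

// incircle: > 0 iff d strictly inside circumcircle of CCW triangle abc
static inline double incircle(double ax, double ay, double bx, double by,
                              double cx, double cy, double dx, double dy) {
  double adx = ax - dx, ady = ay - dy;
  double bdx = bx - dx, bdy = by - dy;
  double cdx = cx - dx, cdy = cy - dy;
  double ad = adx * adx + ady * ady;
  double bd = bdx * bdx + bdy * bdy;
  double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy)
       - ady * (bdx * cd - bd * cdx)
       + ad  * (bdx * cdy - bdy * cdx);
}

// pts: Nx2 (x, y), assumed deduplicated; returns Tx3 one-based indices
// [[Rcpp::export]]
IntegerMatrix cpp_delaunay(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 3) return IntegerMatrix(0, 3);
  std::vector<double> px(n + 3), py(n + 3);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; i++) {
    px[i] = pts(i, 0); py[i] = pts(i, 1);
    xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
    ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
  }
  double dmax = std::max(xmax - xmin, ymax - ymin);
  if (dmax <= 0) dmax = 1.0;
  double cx = (xmin + xmax) / 2, cy = (ymin + ymax) / 2;
  // normalize to a unit box so the incircle determinants keep precision
  for (int i = 0; i < n; i++) {
    px[i] = (px[i] - cx) / dmax;
    py[i] = (py[i] - cy) / dmax;
  }
  // super-triangle vertices (indices n, n+1, n+2)
  px[n] = -20; py[n] = -10;
  px[n + 1] = 20; py[n + 1] = -10;
  px[n + 2] = 0; py[n + 2] = 20;

  std::vector<Tri> tris;
  Tri t0 = {n, n + 1, n + 2, true};
  tris.push_back(t0);

  std::vector<int> bad;
  std::vector<std::pair<int,int> > edges;
  for (int ip = 0; ip < n; ip++) {
    double x = px[ip], y = py[ip];
    bad.clear();
    for (size_t t = 0; t < tris.size(); t++) {
      if (!tris[t].alive) continue;
      int a = tris[t].a, b = tris[t].b, c = tris[t].c;
      double o = orient2d(px[a], py[a], px[b], py[b], px[c], py[c]);
      double ic;
      if (o > 0)
        ic = incircle(px[a], py[a], px[b], py[b], px[c], py[c], x, y);
      else
        ic = incircle(px[a], py[a], px[c], py[c], px[b], py[b], x, y);
      if (ic > 0) bad.push_back((int)t);
    }
    // boundary of the cavity: edges appearing exactly once among bad triangles
    edges.clear();
    for (size_t q = 0; q < bad.size(); q++) {
      Tri &t = tris[bad[q]];
      int vv[3] = {t.a, t.b, t.c};
      for (int e = 0; e < 3; e++) {
        int u = vv[e], v = vv[(e + 1) % 3];
        bool dup = false;
        for (size_t w = 0; w < edges.size(); w++) {
          if ((edges[w].first == u && edges[w].second == v) ||
              (edges[w].first == v && edges[w].second == u)) {
            edges.erase(edges.begin() + w);
            dup = true;
            break;
          }
        }
        if (!dup) edges.push_back(std::make_pair(u, v));
      }
      t.alive = false;
    }
    for (size_t w = 0; w < edges.size(); w++) {
      Tri nt = {edges[w].first, edges[w].second, ip, true};
      tris.push_back(nt);
    }
  }
  std::vector<std::array<int,3> > keep;
  for (size_t t = 0; t < tris.size(); t++) {
    if (!tris[t].alive) continue;
    if (tris[t].a >= n || tris[t].b >= n || tris[t].c >= n) continue;
    // orient CCW so downstream boundary walking is consistent
    int a = tris[t].a, b = tris[t].b, c = tris[t].c;
    if (orient2d(px[a], py[a], px[b], py[b], px[c], py[c]) < 0) std::swap(b, c);
    std::array<int,3> tr = {{a, b, c}};
    keep.push_back(tr);
  }
  // Convexify the boundary: floating-point misses near collinear hull
  // points can leave sliver pockets; a true Delaunay boundary is convex,
  // so fill any reflex pocket with its sliver triangle.
  for (int pass = 0; pass < 64; pass++) {
    // directed boundary edges (those whose reverse is absent)
    std::map<std::pair<int,int>, int> dir;
    for (size_t t = 0; t < keep.size(); t++)
      for (int e = 0; e < 3; e++) {
        int u = keep[t][e], v = keep[t][(e + 1) % 3];
        dir[std::make_pair(u, v)]++;
      }
    std::map<int,int> nxt;
    for (std::map<std::pair<int,int>, int>::iterator it = dir.begin();
         it != dir.end(); ++it) {
      if (it->second == 1 &&
          dir.find(std::make_pair(it->first.second, it->first.first)) == dir.end())
        nxt[it->first.first] = it->first.second;
    }
    bool fixed_any = false;
    for (std::map<int,int>::iterator it = nxt.begin(); it != nxt.end(); ++it) {
      int u = it->first, v = it->second;
      std::map<int,int>::iterator jw = nxt.find(v);
      if (jw == nxt.end()) continue;
      int w = jw->second;
      if (w == u) continue;
      double o = orient2d(px[u], py[u], px[v], py[v], px[w], py[w]);
      if (o < -1e-15) {  // reflex pocket: fill with CCW sliver (u, w, v)
        std::array<int,3> tr = {{u, w, v}};
        keep.push_back(tr);
        fixed_any = true;
        break;  // boundary changed; recompute
      }
    }
    if (!fixed_any) break;
  }
  IntegerMatrix out((int)keep.size(), 3);
  for (size_t t = 0; t < keep.size(); t++) {
    out((int)t, 0) = keep[t][0] + 1;
    out((int)t, 1) = keep[t][1] + 1;
    out((int)t, 2) = keep[t][2] + 1;
  }
  return out;
}

// ---- block-mean downsampling by an integer factor -------------------------

// [[Rcpp::export]]
NumericMatrix cpp_block_mean(NumericMatrix m, int f) {
  int h = m.nrow() / f, w = m.ncol() / f;
  NumericMatrix out(h, w);
  for (int c = 0; c < w; c++) for (int i = 0; i < h; i++) {
    double s = 0;
    for (int dc = 0; dc < f; dc++) for (int di = 0; di < f; di++)
      s += m(i * f + di, c * f + dc);
    out(i, c) = s / (f * f);
  }
  return out;
}
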