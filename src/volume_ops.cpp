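// 3-D volume primitives shared by the segmentation, parcellation and
// skeletonization stages. All volumes are R arrays with dim = (nz, ny, nx),
// i.e. z is the fastest-varying index; linear index = z + nz*(y + ny*x).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Dims {
  int nz, ny, nx;
  long n() const { return (long)nz * ny * nx; }
};

inline Dims get_dims(const IntegerVector &dims) {
  if (dims.size() != 3) stop("expected a 3-D volume");
  Dims d;
  d.nz = dims[0]; d.ny = dims[1]; d.nx = dims[2];
  return d;
}

inline long lin(const Dims &d, int z, int y, int x) {
  return (long)z + (long)d.nz * ((long)y + (long)d.ny * x);
}

// neighbour offsets for a given connectivity (6 or 26)
void neighbour_offsets(int connectivity, std::vector<int> &dz,
                       std::vector<int> &dy, std::vector<int> &dx) {
  dz.clear(); dy.clear(); dx.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh > 1) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
}

} // namespace

// Connected-component labelling, BFS, labels 1..ncomp in order of first
// encountered voxel (deterministic).
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
  Dims d = get_dims(dims);
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  std::vector<int> dz, dy, dx;
  neighbour_offsets(connectivity, dz, dy, dx);
  long n = d.n();
  IntegerVector lab(n, 0);
  std::vector<long> stack;
  int next = 0;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      long p = stack.back(); stack.pop_back();
      int z = (int)(p % d.nz);
      long r = p / d.nz;
      int y = (int)(r % d.ny);
      int x = (int)(r / d.ny);
      for (size_t k = 0; k < dz.size(); ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny ||
            xx < 0 || xx >= d.nx) continue;
        long q = lin(d, zz, yy, xx);
        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Fill enclosed cavities: background voxels not 6-connected to the volume
// border become foreground. Foreground voxels are never removed.
// [[Rcpp::export]]
LogicalVector fill_holes_cpp(LogicalVector mask, IntegerVector dims) {
  Dims d = get_dims(dims);
  long n = d.n();
  std::vector<char> outside(n, 0);
  std::vector<long> stack;
  // seed from every border background voxel
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        if (z != 0 && z != d.nz - 1 && y != 0 && y != d.ny - 1 &&
            x != 0 && x != d.nx - 1) continue;
        long p = lin(d, z, y, x);
        if (!mask[p] && !outside[p]) { outside[p] = 1; stack.push_back(p); }
      }
  static const int oz[6] = {-1, 1, 0, 0, 0, 0};
  static const int oy[6] = {0, 0, -1, 1, 0, 0};
  static const int ox[6] = {0, 0, 0, 0, -1, 1};
  while (!stack.empty()) {
    long p = stack.back(); stack.pop_back();
    int z = (int)(p % d.nz);
    long r = p / d.nz;
    int y = (int)(r % d.ny);
    int x = (int)(r / d.ny);
    for (int k = 0; k < 6; ++k) {
      int zz = z + oz[k], yy = y + oy[k], xx = x + ox[k];
      if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny ||
          xx < 0 || xx >= d.nx) continue;
      long q = lin(d, zz, yy, xx);
      if (!mask[q] && !outside[q]) { outside[q] = 1; stack.push_back(q); }
    }
  }
  LogicalVector out(n);
  for (long p = 0; p < n; ++p) out[p] = mask[p] || !outside[p];
  out.attr("dim") = dims;
  return out;
}

// 3x3x3 median filter with symmetric (reflect) boundary handling.
// [[Rcpp::export]]
NumericVector median_filter3_cpp(NumericVector vol, IntegerVector dims) {
  Dims d = get_dims(dims);
  long n = d.n();
  NumericVector out(n);
  double buf[27];
  auto reflect = [](int i, int m) {
    if (m == 1) return 0;
    if (i < 0) return -i - 1;
    if (i >= m) return 2 * m - i - 1;
    return i;
  };
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        int m = 0;
        for (int a = -1; a <= 1; ++a)
          for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
              int zz = reflect(z + a, d.nz);
              int yy = reflect(y + b, d.ny);
              int xx = reflect(x + c, d.nx);
              buf[m++] = vol[lin(d, zz, yy, xx)];
            }
        std::nth_element(buf, buf + 13, buf + 27);
        out[lin(d, z, y, x)] = buf[13];
      }
  out.attr("dim") = dims;
  return out;
}

// Morphological reconstruction by erosion (26-connectivity): returns the
// largest J <= marker with J >= mask that is stable under
// J = max(mask, erode(J)). marker must dominate mask pointwise.
// Hybrid algorithm: forward/backward raster sweeps + FIFO propagation.
// [[Rcpp::export]]
NumericVector reconstruct_erode_cpp(NumericVector marker, NumericVector mask,
                                    IntegerVector dims) {
  Dims d = get_dims(dims);
  long n = d.n();
  if (marker.size() != n || mask.size() != n) stop("size mismatch");
  for (long p = 0; p < n; ++p)
    if (marker[p] < mask[p]) stop("marker must be >= mask everywhere");
  std::vector<double> J(marker.begin(), marker.end());
  std::vector<int> dz, dy, dx;
  neighbour_offsets(26, dz, dy, dx);
  // split neighbours by raster (linear-index) order
  std::vector<size_t> before, after;
  for (size_t k = 0; k < dz.size(); ++k) {
    long off = lin(d, 1, 1, 1) * 0; // silence unused warn path
    off = (long)dz[k] + (long)d.nz * ((long)dy[k] + (long)d.ny * dx[k]);
    if (off < 0) before.push_back(k); else after.push_back(k);
  }
  auto scan = [&](bool forward) {
    const std::vector<size_t> &nb = forward ? before : after;
    for (long i = 0; i < n; ++i) {
      long p = forward ? i : (n - 1 - i);
      int z = (int)(p % d.nz);
      long r = p / d.nz;
      int y = (int)(r % d.ny);
      int x = (int)(r / d.ny);
      double v = J[p];
      for (size_t t = 0; t < nb.size(); ++t) {
        size_t k = nb[t];
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny ||
            xx < 0 || xx >= d.nx) continue;
        double w = J[lin(d, zz, yy, xx)];
        if (w < v) v = w;
      }
      if (v < mask[p]) v = mask[p];
      J[p] = v;
    }
  };
  scan(true);
  scan(false);
  // queue phase
  std::queue<long> fifo;
  for (long p = 0; p < n; ++p) {
    int z = (int)(p % d.nz);
    long r = p / d.nz;
    int y = (int)(r % d.ny);
    int x = (int)(r / d.ny);
    for (size_t k = 0; k < dz.size(); ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny ||
          xx < 0 || xx >= d.nx) continue;
      long q = lin(d, zz, yy, xx);
      if (J[q] > J[p] && J[q] > mask[q]) { fifo.push(p); break; }
    }
  }
  while (!fifo.empty()) {
    long p = fifo.front(); fifo.pop();
    int z = (int)(p % d.nz);
    long r = p / d.nz;
    int y = (int)(r % d.ny);
    int x = (int)(r / d.ny);
    for (size_t k = 0; k < dz.size(); ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny ||
          xx < 0 || xx >= d.nx) continue;
      long q = lin(d, zz, yy, xx);
      double cand = std::max(J[p], (double)mask[q]);
      if (J[q] > cand) { J[q] = cand; fifo.push(q); }
    }
  }
  NumericVector out(J.begin(), J.end());
  out.attr("dim") = dims;
  return out;
}

// Marker-controlled watershed by priority flooding (26-connectivity).
// seeds: 0 = unlabelled, >0 = basin label. Floods the WHOLE volume; every
// voxel ends up in exactly one basin. Ties resolved by flooding order
// (first-come), matching "assigned to the basin of the lowest-priority
// flooding neighbour".
// [[Rcpp::export]]
IntegerVector watershed_flood_cpp(NumericVector vol, IntegerVector seeds,
                                  IntegerVector dims) {
  Dims d = get_dims(dims);
  long n = d.n();
  if (seeds.size() != n || vol.size() != n) stop("size mismatch");
  std::vector<int> dz, dy, dx;
  neighbour_offsets(26, dz, dy, dx);
  IntegerVector lab(clone(seeds));
  typedef std::tuple<double, long, long> Item; // (priority, order, index)
  std::priority_queue<Item, std::vector<Item>, std::greater<Item> > pq;
  long order = 0;
  for (long p = 0; p < n; ++p)
    if (lab[p] > 0) pq.push(Item(vol[p], order++, p));
  while (!pq.empty()) {
    Item it = pq.top(); pq.pop();
    long p = std::get<2>(it);
    int z = (int)(p % d.nz);
    long r = p / d.nz;
    int y = (int)(r % d.ny);
    int x = (int)(r / d.ny);
    for (size_t k = 0; k < dz.size(); ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny ||
          xx < 0 || xx >= d.nx) continue;
      long q = lin(d, zz, yy, xx);
      if (lab[q] == 0) {
        lab[q] = lab[p];
        pq.push(Item(vol[q], order++, q));
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---- 3-D thinning -----------------------------------------------------

namespace {

// cube positions: c = (dz+1) + 3*(dy+1) + 9*(dx+1), centre = 13
inline int cube_pos(int a, int b, int c) {
  return (a + 1) + 3 * (b + 1) + 9 * (c + 1);
}

// Simple-point test (Bertrand & Malandain): p is simple iff
//  (a) foreground restricted to the 26 neighbours has exactly one
//      26-connected component, and
//  (b) background restricted to the 18-neighbourhood has exactly one
//      6-connected component that is 6-adjacent to the centre.
bool is_simple_point(const bool nb[27]) {
  // (a) 26-connectivity on foreground neighbours
  int comp[27];
  for (int i = 0; i < 27; ++i) comp[i] = -1;
  int ncomp_fg = 0;
  int stack[27], top;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || comp[s] >= 0) continue;
    comp[s] = ncomp_fg;
    top = 0; stack[top++] = s;
    while (top) {
      int p = stack[--top];
      int pz = p % 3, py = (p / 3) % 3, px = p / 9;
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          for (int c = -1; c <= 1; ++c) {
            int zz = pz + a, yy = py + b, xx = px + c;
            if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2)
              continue;
            int q = zz + 3 * yy + 9 * xx;
            if (q == 13 || !nb[q] || comp[q] >= 0) continue;
            comp[q] = ncomp_fg;
            stack[top++] = q;
          }
    }
    ++ncomp_fg;
  }
  if (ncomp_fg != 1) return false;
  // (b) 6-connectivity on background within the 18-neighbourhood
  bool in18[27];
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int q = cube_pos(a, b, c);
        in18[q] = (std::abs(a) + std::abs(b) + std::abs(c)) <= 2 && q != 13;
      }
  for (int i = 0; i < 27; ++i) comp[i] = -1;
  int ncomp_bg_adj = 0;
  for (int s = 0; s < 27; ++s) {
    if (!in18[s] || nb[s] || comp[s] >= 0) continue;
    // BFS this background component, note 6-adjacency to centre
    bool touches_centre = false;
    top = 0; stack[top++] = s; comp[s] = 1;
    while (top) {
      int p = stack[--top];
      int pz = p % 3, py = (p / 3) % 3, px = p / 9;
      if (std::abs(pz - 1) + std::abs(py - 1) + std::abs(px - 1) == 1)
        touches_centre = true;
      static const int oz[6] = {-1, 1, 0, 0, 0, 0};
      static const int oy[6] = {0, 0, -1, 1, 0, 0};
      static const int ox[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int zz = pz + oz[k], yy = py + oy[k], xx = px + ox[k];
        if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2)
          continue;
        int q = zz + 3 * yy + 9 * xx;
        if (!in18[q] || nb[q] || comp[q] >= 0) continue;
        comp[q] = 1;
        stack[top++] = q;
      }
    }
    if (touches_centre) ++ncomp_bg_adj;
  }
  return ncomp_bg_adj == 1;
}

} // namespace

// Topology-preserving curve thinning: 6 directional sub-iterations per
// cycle, sequential deletion of simple non-endpoint border points, until
// stable. Endpoints (<= 1 foreground 26-neighbour) are preserved so curve
// geometry survives.
// [[Rcpp::export]]
LogicalVector thin3d_cpp(LogicalVector mask, IntegerVector dims) {
  Dims d = get_dims(dims);
  long n = d.n();
  std::vector<char> m(n);
  for (long p = 0; p < n; ++p) m[p] = mask[p] ? 1 : 0;
  static const int dirz[6] = {-1, 1, 0, 0, 0, 0};
  static const int diry[6] = {0, 0, -1, 1, 0, 0};
  static const int dirx[6] = {0, 0, 0, 0, -1, 1};
  auto gather = [&](long p, bool nb[27], int &fgcount) {
    int z = (int)(p % d.nz);
    long r = p / d.nz;
    int y = (int)(r % d.ny);
    int x = (int)(r / d.ny);
    fgcount = 0;
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          int q = cube_pos(a, b, c);
          int zz = z + a, yy = y + b, xx = x + c;
          bool v = false;
          if (zz >= 0 && zz < d.nz && yy >= 0 && yy < d.ny &&
              xx >= 0 && xx < d.nx)
            v = m[lin(d, zz, yy, xx)] != 0;
          nb[q] = v;
          if (q != 13 && v) ++fgcount;
        }
  };
  bool changed = true;
  std::vector<long> cand;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      cand.clear();
      for (long p = 0; p < n; ++p) {
        if (!m[p]) continue;
        int z = (int)(p % d.nz);
        long r = p / d.nz;
        int y = (int)(r % d.ny);
        int x = (int)(r / d.ny);
        int zz = z + dirz[dir], yy = y + diry[dir], xx = x + dirx[dir];
        bool bg = true;
        if (zz >= 0 && zz < d.nz && yy >= 0 && yy < d.ny &&
            xx >= 0 && xx < d.nx)
          bg = m[lin(d, zz, yy, xx)] == 0;
        if (bg) cand.push_back(p);
      }
      for (size_t i = 0; i < cand.size(); ++i) {
        long p = cand[i];
        if (!m[p]) continue;
        bool nb[27];
        int fgcount;
        gather(p, nb, fgcount);
        if (fgcount <= 1) continue; // endpoint, keep
        if (is_simple_point(nb)) { m[p] = 0; changed = true; }
      }
    }
  }
  LogicalVector out(n);
  for (long p = 0; p < n; ++p) out[p] = m[p] != 0;
  out.attr("dim") = dims;
  return out;
}

// ---- anisotropic Euclidean distance transform -------------------------

namespace {

// Felzenszwalb-Huttenlocher 1-D squared distance transform with sample
// spacing w (positions i*w).
void dt1d(std::vector<double> &f, std::vector<double> &out, int n, double w,
          std::vector<int> &v, std::vector<double> &zbp) {
  int k = 0;
  v[0] = 0;
  zbp[0] = -INFINITY;
  zbp[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double xq = q * w, xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= zbp[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zbp[k] = s;
    zbp[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (zbp[k + 1] < xq) ++k;
    double dxv = xq - v[k] * w;
    out[q] = dxv * dxv + f[v[k]];
  }
}

} // namespace

// Distance (physical units, spacing = (dz, dy, dx)) from each foreground
// voxel to the nearest background voxel; 0 on background.
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  Dims d = get_dims(dims);
  if (spacing.size() != 3) stop("spacing must have length 3");
  long n = d.n();
  const double INF = 1e30;
  std::vector<double> D(n);
  for (long p = 0; p < n; ++p) D[p] = mask[p] ? INF : 0.0;
  int maxdim = std::max(d.nz, std::max(d.ny, d.nx));
  std::vector<double> f(maxdim), g(maxdim), zbp(maxdim + 1);
  std::vector<int> v(maxdim);
  // z pass
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y) {
      for (int z = 0; z < d.nz; ++z) f[z] = D[lin(d, z, y, x)];
      dt1d(f, g, d.nz, spacing[0], v, zbp);
      for (int z = 0; z < d.nz; ++z) D[lin(d, z, y, x)] = g[z];
    }
  // y pass
  for (int x = 0; x < d.nx; ++x)
    for (int z = 0; z < d.nz; ++z) {
      for (int y = 0; y < d.ny; ++y) f[y] = D[lin(d, z, y, x)];
      dt1d(f, g, d.ny, spacing[1], v, zbp);
      for (int y = 0; y < d.ny; ++y) D[lin(d, z, y, x)] = g[y];
    }
  // x pass
  for (int z = 0; z < d.nz; ++z)
    for (int y = 0; y < d.ny; ++y) {
      for (int x = 0; x < d.nx; ++x) f[x] = D[lin(d, z, y, x)];
      dt1d(f, g, d.nx, spacing[2], v, zbp);
      for (int x = 0; x < d.nx; ++x) D[lin(d, z, y, x)] = g[x];
    }
  NumericVector out(n);
  for (long p = 0; p < n; ++p) out[p] = std::sqrt(D[p]);
  out.attr("dim") = dims;
  return out;
}

// Separable Gaussian convolution, per-axis sigma in voxels (0 skips the
// axis), symmetric (reflect) boundary, kernel radius = ceil(4*sigma).
// [[Rcpp::export]]
NumericVector gaussian_smooth_cpp(NumericVector vol, IntegerVector dims,
                                  NumericVector sigma) {
  Dims d = get_dims(dims);
  if (sigma.size() != 3) stop("sigma must have length 3");
  long n = d.n();
  std::vector<double> cur(vol.begin(), vol.end()), nxt(n);
  auto reflect = [](int i, int m) {
    while (i < 0 || i >= m) {
      if (i < 0) i = -i - 1;
      if (i >= m) i = 2 * m - i - 1;
    }
    return i;
  };
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int rad = (int)std::ceil(4.0 * s);
    std::vector<double> ker(2 * rad + 1);
    double sum = 0;
    for (int i = -rad; i <= rad; ++i) {
      ker[i + rad] = std::exp(-0.5 * i * i / (s * s));
      sum += ker[i + rad];
    }
    for (double &k : ker) k /= sum;
    int len = axis == 0 ? d.nz : (axis == 1 ? d.ny : d.nx);
    for (int x = 0; x < d.nx; ++x)
      for (int y = 0; y < d.ny; ++y)
        for (int z = 0; z < d.nz; ++z) {
          double acc = 0;
          for (int i = -rad; i <= rad; ++i) {
            int zz = z, yy = y, xx = x;
            if (axis == 0) zz = reflect(z + i, len);
            else if (axis == 1) yy = reflect(y + i, len);
            else xx = reflect(x + i, len);
            acc += ker[i + rad] * cur[lin(d, zz, yy, xx)];
          }
          nxt[lin(d, z, y, x)] = acc;
        }
    std::swap(cur, nxt);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dims;
  return out;
}
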