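#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Volumes are R arrays with dim = (nz, ny, nx), column-major:
// linear index = z + nz * (y + ny * x), all 0-based here.

// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector arr, IntegerVector dim,
                            NumericVector kernel, int axis) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = arr.size();
  const int nk = kernel.size();
  const int c = (nk - 1) / 2; // kernel center (odd length assumed)
  NumericVector out(n);

  int len, stride;
  if (axis == 1) { len = nz; stride = 1; }
  else if (axis == 2) { len = ny; stride = nz; }
  else { len = nx; stride = nz * ny; }

  const int nlines = (int)(n / len);
  std::vector<double> line(len);
  const double *k = kernel.begin();

  for (int l = 0; l < nlines; ++l) {
    // base offset of this line
    R_xlen_t base;
    if (axis == 1) {
      base = (R_xlen_t)l * nz;
    } else if (axis == 2) {
      int z = l % nz, x = l / nz;
      base = z + (R_xlen_t)nz * ny * x;
    } else {
      base = l; // l = z + nz*y
    }
    for (int i = 0; i < len; ++i) line[i] = arr[base + (R_xlen_t)i * stride];
    for (int i = 0; i < len; ++i) {
      double s = 0.0;
      for (int j = 0; j < nk; ++j) {
        int p = i + j - c; // replicate (edge-clamp) padding
        if (p < 0) p = 0; else if (p >= len) p = len - 1;
        s += k[j] * line[p];
      }
      out[base + (R_xlen_t)i * stride] = s;
    }
  }
  return out;
}

// Strict 26-neighbourhood local maxima with value > min_value.
// Neighbours outside the volume are ignored. Returns 1-based linear indices.
// [[Rcpp::export]]
IntegerVector local_maxima_cpp(NumericVector arr, IntegerVector dim,
                               double min_value) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> hits;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        double v = arr[i];
        if (!(v > min_value)) continue;
        bool ismax = true;
        for (int dx = -1; dx <= 1 && ismax; ++dx) {
          int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          for (int dy = -1; dy <= 1 && ismax; ++dy) {
            int yy = y + dy; if (yy < 0 || yy >= ny) continue;
            for (int dz = -1; dz <= 1; ++dz) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int zz = z + dz; if (zz < 0 || zz >= nz) continue;
              if (arr[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)] >= v) {
                ismax = false; break;
              }
            }
          }
        }
        if (ismax) hits.push_back((int)i + 1);
      }
    }
  }
  return wrap(hits);
}

// Greedy non-maximum suppression on physical coordinates (n x 3, already
// ordered by priority: highest first). A point is kept when no previously
// kept point lies within min_sep (Euclidean). Grid-hash accelerated.
// [[Rcpp::export]]
LogicalVector suppress_cpp(NumericMatrix coords, double min_sep) {
  const int n = coords.nrow();
  LogicalVector keep(n);
  if (n == 0) return keep;
  const double cell = min_sep;
  const double r2 = min_sep * min_sep;
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve((size_t)n * 2);
  auto key = [cell](double a, double b, double c2) {
    long long ka = (long long)std::floor(a / cell);
    long long kb = (long long)std::floor(b / cell);
    long long kc = (long long)std::floor(c2 / cell);
    return ((ka * 73856093LL) ^ (kb * 19349663LL) ^ (kc * 83492791LL));
  };
  for (int i = 0; i < n; ++i) {
    double a = coords(i, 0), b = coords(i, 1), c2 = coords(i, 2);
    bool ok = true;
    for (int da = -1; da <= 1 && ok; ++da)
      for (int db = -1; db <= 1 && ok; ++db)
        for (int dc = -1; dc <= 1 && ok; ++dc) {
          long long k = key(a + da * cell, b + db * cell, c2 + dc * cell);
          auto it = grid.find(k);
          if (it == grid.end()) continue;
          for (int j : it->second) {
            double dz = a - coords(j, 0), dy = b - coords(j, 1),
                   dx = c2 - coords(j, 2);
            if (dz * dz + dy * dy + dx * dx < r2) { ok = false; break; }
          }
        }
    if (ok) {
      keep[i] = true;
      grid[key(a, b, c2)].push_back(i);
    }
  }
  return keep;
}

// --- Exact anisotropic Euclidean distance/feature transform -----------------
// Felzenszwalb & Huttenlocher lower-envelope method, one pass per axis,
// propagating the label of the nearest site.

static void dt1d(const std::vector<double> &f, const std::vector<int> &lab,
                 int n, double s2, std::vector<double> &d,
                 std::vector<int> &dl, std::vector<int> &v,
                 std::vector<double> &zb) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; zb[0] = -INF; zb[1] = INF;
      continue;
    }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (s <= zb[k]) { --k; if (k < 0) break; } else break;
    }
    ++k;
    v[k] = q; zb[k] = s; zb[k + 1] = INF;
  }
  if (k < 0) { // no finite parabola in this line
    for (int q = 0; q < n; ++q) { d[q] = INF; dl[q] = 0; }
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[j + 1] < q) ++j;
    int p = v[j];
    d[q] = s2 * (q - p) * (q - p) + f[p];
    dl[q] = lab[p];
  }
}

// dist2 holds 0 at sites, +Inf elsewhere; labels holds the site labels.
// spacing is (z, y, x) in physical units. Returns squared distances and
// the label of the nearest site.
// [[Rcpp::export]]
List edt_feature_cpp(NumericVector dist2, IntegerVector labels,
                     IntegerVector dim, NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = dist2.size();
  std::vector<double> d(dist2.begin(), dist2.end());
  std::vector<int> lab(labels.begin(), labels.end());

  const int maxlen = std::max(nz, std::max(ny, nx));
  std::vector<double> fline(maxlen), dout(maxlen), zb(maxlen + 1);
  std::vector<int> lline(maxlen), lout(maxlen), v(maxlen);

  for (int axis = 0; axis < 3; ++axis) {
    int len, stride;
    if (axis == 0) { len = nz; stride = 1; }
    else if (axis == 1) { len = ny; stride = nz; }
    else { len = nx; stride = nz * ny; }
    double s2 = spacing[axis] * spacing[axis];
    const int nlines = (int)(n / len);
    for (int l = 0; l < nlines; ++l) {
      R_xlen_t base;
      if (axis == 0) base = (R_xlen_t)l * nz;
      else if (axis == 1) {
        int z = l % nz, x = l / nz;
        base = z + (R_xlen_t)nz * ny * x;
      } else base = l;
      for (int i = 0; i < len; ++i) {
        fline[i] = d[base + (R_xlen_t)i * stride];
        lline[i] = lab[base + (R_xlen_t)i * stride];
      }
      dt1d(fline, lline, len, s2, dout, lout, v, zb);
      for (int i = 0; i < len; ++i) {
        d[base + (R_xlen_t)i * stride] = dout[i];
        lab[base + (R_xlen_t)i * stride] = lout[i];
      }
    }
  }
  return List::create(_["dist2"] = wrap(d), _["label"] = wrap(lab));
}

// Connected components of mask != 0 (6- or 26-connectivity), labelled 1..N
// in raster-scan order of each component's first voxel (deterministic).
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = mask.size();
  IntegerVector out(n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  std::vector<int> off;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && man != 1) continue;
        off.push_back(dz); off.push_back(dy); off.push_back(dx);
      }
  const int noff = (int)off.size() / 3;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] == 0 || out[i] != 0) continue;
    ++next;
    out[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int z = (int)(cur % nz);
      int y = (int)((cur / nz) % ny);
      int x = (int)(cur / ((R_xlen_t)nz * ny));
      for (int o = 0; o < noff; ++o) {
        int zz = z + off[3 * o], yy = y + off[3 * o + 1], xx = x + off[3 * o + 2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[j] != 0 && out[j] == 0) { out[j] = next; stack.push_back(j); }
      }
    }
  }
  return out;
}

// Marker-controlled watershed (Meyer flooding) restricted to mask.
// Voxels are flooded in increasing order of `priority`; ties broken by
// insertion order, so the result is deterministic.
// [[Rcpp::export]]
IntegerVector watershed_cpp(NumericVector priority, IntegerVector seeds,
                            IntegerVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = priority.size();
  IntegerVector out(n);
  struct Node {
    double p; long long ord; R_xlen_t idx; int lab;
  };
  struct Cmp {
    bool operator()(const Node &a, const Node &b) const {
      if (a.p != b.p) return a.p > b.p;
      return a.ord > b.ord;
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  long long ord = 0;
  const int dz6[6] = { -1, 1, 0, 0, 0, 0 };
  const int dy6[6] = { 0, 0, -1, 1, 0, 0 };
  const int dx6[6] = { 0, 0, 0, 0, -1, 1 };

  for (R_xlen_t i = 0; i < n; ++i) {
    if (seeds[i] > 0) out[i] = seeds[i];
  }
  for (R_xlen_t i = 0; i < n; ++i) {
    if (out[i] == 0) continue;
    int z = (int)(i % nz), y = (int)((i / nz) % ny),
        x = (int)(i / ((R_xlen_t)nz * ny));
    for (int o = 0; o < 6; ++o) {
      int zz = z + dz6[o], yy = y + dy6[o], xx = x + dx6[o];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (mask[j] != 0 && out[j] == 0)
        pq.push({ priority[j], ord++, j, out[i] });
    }
  }
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    if (out[nd.idx] != 0) continue;
    out[nd.idx] = nd.lab;
    int z = (int)(nd.idx % nz), y = (int)((nd.idx / nz) % ny),
        x = (int)(nd.idx / ((R_xlen_t)nz * ny));
    for (int o = 0; o < 6; ++o) {
      int zz = z + dz6[o], yy = y + dy6[o], xx = x + dx6[o];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (mask[j] != 0 && out[j] == 0)
        pq.push({ priority[j], ord++, j, nd.lab });
    }
  }
  return out;
}
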