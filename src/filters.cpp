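#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Median over a discrete disk neighbourhood (centre distance <= radius),
// edge handling by replication. Operates in doubles so faint structures are
// not quantized away.
// [[Rcpp::export]]
NumericMatrix disk_median_cpp(const NumericMatrix& img, const int radius) {
  if (radius < 1) stop("radius must be >= 1");
  const int ny = img.nrow(), nx = img.ncol();
  std::vector<int> offy, offx;
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx)
      if (dy * dy + dx * dx <= radius * radius) {
        offy.push_back(dy);
        offx.push_back(dx);
      }
  const int K = (int)offy.size();
  std::vector<double> buf(K);
  NumericMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int k = 0; k < K; ++k) {
        int yy = y + offy[k];
        int xx = x + offx[k];
        if (yy < 0) yy = 0; else if (yy >= ny) yy = ny - 1;
        if (xx < 0) xx = 0; else if (xx >= nx) xx = nx - 1;
        buf[k] = img(yy, xx);
      }
      std::nth_element(buf.begin(), buf.begin() + K / 2, buf.end());
      double m = buf[K / 2];
      if (K % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + K / 2 - 1,
                         buf.begin() + K / 2);
        m = 0.5 * (m + buf[K / 2 - 1]);
      }
      out(y, x) = m;
    }
  }
  return out;
}

namespace {

int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

}  // namespace

// Regional maxima of a 2-D image filtered by topographic prominence.
//
// Prominence of a maximum is its height above the highest saddle that
// connects it to a strictly higher maximum; the highest maxima of a
// connected component are assigned height above the image minimum.  Computed
// by a watershed-by-flooding union-find over pixels in decreasing order of
// intensity (8-connectivity).  A flat plateau of tied maxima is marked at a
// single pixel, the plateau member closest to the plateau centroid.
//
// Returns an integer matrix with 1 at marked maxima, 0 elsewhere.  A maximum
// is marked when prominence > prom_thresh and intensity > min_intensity
// (both strict, so an all-zero image yields an empty result with the default
// thresholds of 0).
// [[Rcpp::export]]
IntegerMatrix prominent_maxima_cpp(const NumericMatrix& img,
                                   const double prom_thresh,
                                   const double min_intensity) {
  const int ny = img.nrow(), nx = img.ncol();
  const int n = ny * nx;
  IntegerMatrix out(ny, nx);
  if (n == 0) return out;

  const double* v = img.begin();  // column-major: idx = y + ny * x
  double vmin = v[0];
  for (int i = 1; i < n; ++i) if (v[i] < vmin) vmin = v[i];

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    if (v[a] != v[b]) return v[a] > v[b];
    return a < b;
  });

  std::vector<int> parent(n, -1);
  std::vector<double> peak_val(n, 0.0);
  // Peaks (plateau representatives) whose prominence is still undetermined,
  // stored at the component root.
  std::vector<std::vector<int> > pending(n);
  std::vector<double> prom(n, -1.0);

  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  for (int oi = 0; oi < n; ++oi) {
    const int p = order[oi];
    const int py = p % ny, px = p / ny;
    const double level = v[p];
    parent[p] = p;
    peak_val[p] = level;
    pending[p].push_back(p);
    for (int k = 0; k < 8; ++k) {
      const int qy = py + dy8[k], qx = px + dx8[k];
      if (qy < 0 || qy >= ny || qx < 0 || qx >= nx) continue;
      const int q = qy + ny * qx;
      if (parent[q] < 0) continue;  // not yet flooded
      int rp = uf_find(parent, p);
      int rq = uf_find(parent, q);
      if (rp == rq) continue;
      int hi = rp, lo = rq;
      if (peak_val[rq] > peak_val[rp]) { hi = rq; lo = rp; }
      if (peak_val[hi] > peak_val[lo]) {
        // saddle at the current flood level settles the lower peaks
        for (size_t t = 0; t < pending[lo].size(); ++t) {
          const int id = pending[lo][t];
          prom[id] = v[id] - level;
        }
        pending[lo].clear();
      } else {
        // tied maxima: stay pending together (only a strictly higher
        // maximum can settle their prominence)
        if (pending[lo].size() > pending[hi].size())
          pending[hi].swap(pending[lo]);
        pending[hi].insert(pending[hi].end(), pending[lo].begin(),
                           pending[lo].end());
        pending[lo].clear();
      }
      parent[lo] = hi;
    }
  }
  // survivors: highest maxima of their connected component
  for (int i = 0; i < n; ++i) {
    if (parent[i] == i || uf_find(parent, i) == i) {
      for (size_t t = 0; t < pending[i].size(); ++t) {
        const int id = pending[i][t];
        prom[id] = v[id] - vmin;
      }
      pending[i].clear();
    }
  }

  // Mark accepted maxima, one pixel per equal-valued plateau.
  std::vector<char> visited(n, 0);
  for (int oi = 0; oi < n; ++oi) {
    const int p = order[oi];
    if (visited[p]) continue;
    if (!(prom[p] > prom_thresh) || !(v[p] > min_intensity)) continue;
    // collect the 8-connected plateau of value v[p] containing p
    const double pv = v[p];
    std::vector<int> plateau;
    std::queue<int> bfs;
    bfs.push(p);
    visited[p] = 1;
    while (!bfs.empty()) {
      const int c = bfs.front();
      bfs.pop();
      plateau.push_back(c);
      const int cy = c % ny, cx = c / ny;
      for (int k = 0; k < 8; ++k) {
        const int qy = cy + dy8[k], qx = cx + dx8[k];
        if (qy < 0 || qy >= ny || qx < 0 || qx >= nx) continue;
        const int q = qy + ny * qx;
        if (!visited[q] && v[q] == pv) {
          visited[q] = 1;
          bfs.push(q);
        }
      }
    }
    double my = 0.0, mx = 0.0;
    for (size_t t = 0; t < plateau.size(); ++t) {
      my += plateau[t] % ny;
      mx += plateau[t] / ny;
    }
    my /= plateau.size();
    mx /= plateau.size();
    int best = plateau[0];
    double bestd = 1e300;
    for (size_t t = 0; t < plateau.size(); ++t) {
      const double dy = plateau[t] % ny - my, dx = plateau[t] / ny - mx;
      const double d = dy * dy + dx * dx;
      if (d < bestd || (d == bestd && plateau[t] < best)) {
        bestd = d;
        best = plateau[t];
      }
    }
    out[best] = 1;
  }
  return out;
}
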