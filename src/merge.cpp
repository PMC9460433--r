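// Bottom-up region-merging engine for multi-resolution segmentation.
//
// Merging is deterministic global greedy: while the minimum fusion cost over
// all adjacent segment pairs is below the threshold (scale^2), merge that
// pair. The global minimum-cost pair is in particular a mutually-best pair,
// so every executed merge satisfies local mutual best fitting. Ties are
// broken by the smaller (min id, max id) pair; the surviving segment keeps
// the smaller id. Pixel ids are row-major.

#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Ent {
  double cost;
  int a, b;    // a < b, root ids at push time
  int va, vb;  // version stamps
};

struct EntCmp {
  bool operator()(const Ent& x, const Ent& y) const {
    if (x.cost != y.cost) return x.cost > y.cost;  // min-heap on cost
    if (x.a != y.a) return x.a > y.a;
    return x.b > y.b;
  }
};

struct Engine {
  int npix, nlay;
  double w_color, w_shape, w_smooth, w_compact;
  const double* lw;      // per-layer weights
  const double* lay;     // npix x nlay, column-major (pixel-major per layer)

  std::vector<char> alive;
  std::vector<int> ver;
  std::vector<double> n, perim;
  std::vector<int> rmin, rmax, cmin, cmax;
  std::vector<double> sum, sumsq;  // npix * nlay
  std::vector<std::unordered_map<int, int>> adj;  // root -> (root -> shared edges)

  double seg_sd(int s, int k) const {
    double ns = n[s];
    double m = sum[(size_t)k * npix + s] / ns;
    double v = sumsq[(size_t)k * npix + s] / ns - m * m;
    if (v < 0) v = 0;
    return std::sqrt(v);
  }

  double fusion_cost(int a, int b, int shared) const {
    double na = n[a], nb = n[b], nm = na + nb;
    double dcolor = 0.0;
    for (int k = 0; k < nlay; ++k) {
      double sm = sum[(size_t)k * npix + a] + sum[(size_t)k * npix + b];
      double sq = sumsq[(size_t)k * npix + a] + sumsq[(size_t)k * npix + b];
      double mm = sm / nm;
      double vv = sq / nm - mm * mm;
      if (vv < 0) vv = 0;
      double sdm = std::sqrt(vv);
      dcolor += lw[k] * (nm * sdm - (na * seg_sd(a, k) + nb * seg_sd(b, k)));
    }
    double lm = perim[a] + perim[b] - 2.0 * shared;
    double h = (double)(std::max(rmax[a], rmax[b]) - std::min(rmin[a], rmin[b]) + 1);
    double w = (double)(std::max(cmax[a], cmax[b]) - std::min(cmin[a], cmin[b]) + 1);
    double bm = h < w ? h : w;
    double ba = (double)std::min(rmax[a] - rmin[a] + 1, cmax[a] - cmin[a] + 1);
    double bb = (double)std::min(rmax[b] - rmin[b] + 1, cmax[b] - cmin[b] + 1);
    double dsmooth = nm * lm / bm - (na * perim[a] / ba + nb * perim[b] / bb);
    double dcompact = nm * lm / std::sqrt(nm) -
      (na * perim[a] / std::sqrt(na) + nb * perim[b] / std::sqrt(nb));
    return w_color * dcolor + w_shape * (w_smooth * dsmooth + w_compact * dcompact);
  }
};

}  // namespace

// [[Rcpp::export(name = ".merge_engine")]]
IntegerVector merge_engine(NumericMatrix layers, int nrow, int ncol,
                           NumericVector layer_weights, double w_color,
                           double w_shape, double w_smooth, double w_compact,
                           double threshold, LogicalVector valid) {
  const int npix = nrow * ncol;
  if (layers.nrow() != npix) stop("layers must have nrow*ncol rows");
  const int nlay = layers.ncol();
  if (nlay < 1) stop("at least one layer is required");
  if (layer_weights.size() != nlay) stop("one weight per layer required");

  Engine e;
  e.npix = npix; e.nlay = nlay;
  e.w_color = w_color; e.w_shape = w_shape;
  e.w_smooth = w_smooth; e.w_compact = w_compact;
  e.lw = REAL(layer_weights);
  e.lay = REAL(layers);

  e.alive.assign(npix, 0);
  e.ver.assign(npix, 0);
  e.n.assign(npix, 0.0);
  e.perim.assign(npix, 0.0);
  e.rmin.assign(npix, 0); e.rmax.assign(npix, 0);
  e.cmin.assign(npix, 0); e.cmax.assign(npix, 0);
  e.sum.assign((size_t)npix * nlay, 0.0);
  e.sumsq.assign((size_t)npix * nlay, 0.0);
  e.adj.assign(npix, std::unordered_map<int, int>());

  // pixel id p = r*ncol + c (row-major, 0-based)
  for (int p = 0; p < npix; ++p) {
    if (!valid[p]) continue;
    e.alive[p] = 1;
    e.n[p] = 1.0;
    e.perim[p] = 4.0;
    int r = p / ncol, c = p % ncol;
    e.rmin[p] = e.rmax[p] = r;
    e.cmin[p] = e.cmax[p] = c;
    for (int k = 0; k < nlay; ++k) {
      double v = e.lay[(size_t)k * npix + p];
      e.sum[(size_t)k * npix + p] = v;
      e.sumsq[(size_t)k * npix + p] = v * v;
    }
  }

  std::priority_queue<Ent, std::vector<Ent>, EntCmp> pq;
  for (int p = 0; p < npix; ++p) {
    if (!e.alive[p]) continue;
    int r = p / ncol, c = p % ncol;
    if (c + 1 < ncol && e.alive[p + 1]) {
      e.adj[p][p + 1] = 1; e.adj[p + 1][p] = 1;
      pq.push({e.fusion_cost(p, p + 1, 1), p, p + 1, 0, 0});
    }
    if (r + 1 < nrow && e.alive[p + ncol]) {
      e.adj[p][p + ncol] = 1; e.adj[p + ncol][p] = 1;
      pq.push({e.fusion_cost(p, p + ncol, 1), p, p + ncol, 0, 0});
    }
  }

  std::vector<int> parent(npix);
  for (int p = 0; p < npix; ++p) parent[p] = p;

  while (!pq.empty()) {
    Ent t = pq.top(); pq.pop();
    int a = t.a, b = t.b;
    if (!e.alive[a] || !e.alive[b]) continue;
    if (e.ver[a] != t.va || e.ver[b] != t.vb) continue;
    if (!(t.cost < threshold)) break;  // global minimum not admissible: done

    int shared = e.adj[a][b];
    // fold b into a (a < b always: surviving id is the smaller)
    parent[b] = a;
    e.alive[b] = 0;
    e.ver[a] += 1;
    e.perim[a] = e.perim[a] + e.perim[b] - 2.0 * shared;
    e.n[a] += e.n[b];
    if (e.rmin[b] < e.rmin[a]) e.rmin[a] = e.rmin[b];
    if (e.rmax[b] > e.rmax[a]) e.rmax[a] = e.rmax[b];
    if (e.cmin[b] < e.cmin[a]) e.cmin[a] = e.cmin[b];
    if (e.cmax[b] > e.cmax[a]) e.cmax[a] = e.cmax[b];
    for (int k = 0; k < nlay; ++k) {
      e.sum[(size_t)k * npix + a] += e.sum[(size_t)k * npix + b];
      e.sumsq[(size_t)k * npix + a] += e.sumsq[(size_t)k * npix + b];
    }
    e.adj[a].erase(b);
    for (auto& kv : e.adj[b]) {
      int nb = kv.first;
      if (nb == a) continue;
      e.adj[a][nb] += kv.second;
      e.adj[nb].erase(b);
      e.adj[nb][a] = e.adj[a][nb];
    }
    e.adj[b].clear();
    for (auto& kv : e.adj[a]) {
      int nb = kv.first;
      int lo = a < nb ? a : nb, hi = a < nb ? nb : a;
      pq.push({e.fusion_cost(lo, hi, kv.second), lo, hi, e.ver[lo], e.ver[hi]});
    }
  }

  IntegerVector out(npix);
  for (int p = 0; p < npix; ++p) {
    if (!valid[p]) { out[p] = NA_INTEGER; continue; }
    int r = p;
    while (parent[r] != r) r = parent[r];
    // path compression for the output pass
    int q = p;
    while (parent[q] != r) { int nx = parent[q]; parent[q] = r; q = nx; }
    out[p] = r + 1;  // 1-based root pixel id
  }
  return out;
}
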