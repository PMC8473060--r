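#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Union-find with path halving; union by smaller root index so that the
// representative of every component is its lowest-indexed member.
static int uf_find(std::vector<int> &p, int i) {
  while (p[i] != i) { p[i] = p[p[i]]; i = p[i]; }
  return i;
}
static void uf_union(std::vector<int> &p, int a, int b) {
  a = uf_find(p, a); b = uf_find(p, b);
  if (a == b) return;
  if (a < b) p[b] = a; else p[a] = b;
}

static inline double sqdist(const double *x, int n, int d, int i, int j) {
  double s = 0.0;
  for (int k = 0; k < d; ++k) {
    double diff = x[i + (size_t)k * n] - x[j + (size_t)k * n];
    s += diff * diff;
  }
  return s;
}

// Deterministic DBSCAN labels. Semantics:
//   * a point is core iff it has >= min_pts neighbors within eps (inclusive,
//     counting itself);
//   * clusters are connected components of core points under eps-adjacency,
//     numbered 1..k by ascending lowest core index;
//   * a non-core point with at least one core neighbor within eps joins the
//     cluster of its lowest-indexed core neighbor (border point);
//   * everything else is noise, label 0.
// The construction never depends on traversal order, so the labeling is
// reproducible across platforms.
// [[Rcpp::export]]
IntegerVector dbscan_labels_cpp(NumericMatrix pts, double eps, int min_pts) {
  const int n = pts.nrow(), d = pts.ncol();
  IntegerVector out(n);
  if (n == 0) return out;
  const double eps2 = eps * eps;
  const double *x = REAL(pts);

  std::vector<int> ncount(n, 1); // self counts
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (sqdist(x, n, d, i, j) <= eps2) { ++ncount[i]; ++ncount[j]; }

  std::vector<char> core(n, 0);
  for (int i = 0; i < n; ++i) core[i] = (ncount[i] >= min_pts);

  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  for (int i = 0; i < n; ++i) {
    if (!core[i]) continue;
    for (int j = i + 1; j < n; ++j)
      if (core[j] && sqdist(x, n, d, i, j) <= eps2) uf_union(parent, i, j);
  }

  // cluster ids by ascending root (== lowest core index in the component)
  std::vector<int> cl(n, 0);
  int next_id = 0;
  std::vector<int> root_id(n, 0);
  for (int i = 0; i < n; ++i) {
    if (!core[i]) continue;
    int r = uf_find(parent, i);
    if (r == i) root_id[r] = ++next_id;
    cl[i] = root_id[r];
  }
  // border points: lowest-indexed core neighbor decides
  for (int i = 0; i < n; ++i) {
    if (core[i]) continue;
    for (int j = 0; j < n; ++j) {
      if (!core[j]) continue;
      if (sqdist(x, n, d, i, j) <= eps2) { cl[i] = cl[j]; break; }
    }
  }
  for (int i = 0; i < n; ++i) out[i] = cl[i];
  return out;
}

// Inverse-distance-weighted interpolation of src_z at query_xy using the k
// nearest of src_xy. An exact hit (distance < 1e-9 m) returns that source z.
// [[Rcpp::export]]
NumericVector idw_interp_cpp(NumericMatrix src_xy, NumericVector src_z,
                             NumericMatrix query_xy, int k, double power) {
  const int n = src_xy.nrow(), m = query_xy.nrow();
  NumericVector out(m);
  if (n == 0) { std::fill(out.begin(), out.end(), NA_REAL); return out; }
  const int kk = std::min(k, n);
  std::vector<std::pair<double, int> > dist(n);
  for (int q = 0; q < m; ++q) {
    const double qx = query_xy(q, 0), qy = query_xy(q, 1);
    for (int i = 0; i < n; ++i) {
      const double dx = src_xy(i, 0) - qx, dy = src_xy(i, 1) - qy;
      dist[i] = std::make_pair(dx * dx + dy * dy, i);
    }
    std::partial_sort(dist.begin(), dist.begin() + kk, dist.end());
    if (dist[0].first < 1e-18) { out[q] = src_z[dist[0].second]; continue; }
    double wsum = 0.0, zsum = 0.0;
    for (int j = 0; j < kk; ++j) {
      const double w = 1.0 / std::pow(std::sqrt(dist[j].first), power);
      wsum += w; zsum += w * src_z[dist[j].second];
    }
    out[q] = zsum / wsum;
  }
  return out;
}

// For each row of a, the Euclidean distance to the nearest row of b
// (both matrices share the same number of columns, 2 or 3).
// [[Rcpp::export]]
NumericVector nn_dist_cpp(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow(), d = a.ncol();
  NumericVector out(na);
  if (nb == 0) { std::fill(out.begin(), out.end(), R_PosInf); return out; }
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = a(i, k) - b(j, k);
        s += diff * diff;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
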