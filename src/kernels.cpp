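#include <Rcpp.h>
#include <algorithm>
#include <functional>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact dense linear assignment (Jonker-Volgenant shortest augmenting path).
// Returns, for every row, the assigned column (1-based).  Ties are resolved
// toward the lowest column index, so the result is deterministic.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_lap_solve(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<double> u(n, 0.0), v(n, 0.0);
  std::vector<int> col4row(n, -1), row4col(n, -1);
  std::vector<double> shortest(n);
  std::vector<int> path(n);
  std::vector<char> SR(n), SC(n);
  std::vector<int> remaining(n);

  for (int cur_row = 0; cur_row < n; ++cur_row) {
    std::fill(shortest.begin(), shortest.end(), INF);
    std::fill(path.begin(), path.end(), -1);
    std::fill(SR.begin(), SR.end(), 0);
    std::fill(SC.begin(), SC.end(), 0);
    int num_remaining = n;
    for (int j = 0; j < n; ++j) remaining[j] = j;

    double min_val = 0.0;
    int sink = -1;
    int i = cur_row;

    while (sink == -1) {
      SR[i] = 1;
      int index = -1;
      double lowest = INF;
      for (int it = 0; it < num_remaining; ++it) {
        const int j = remaining[it];
        const double r = min_val + cost(i, j) - u[i] - v[j];
        if (r < shortest[j]) {
          path[j] = i;
          shortest[j] = r;
        }
        // prefer unassigned columns, then lowest column index
        if (shortest[j] < lowest ||
            (shortest[j] == lowest && row4col[j] == -1 &&
             (index == -1 || row4col[remaining[index]] != -1))) {
          lowest = shortest[j];
          index = it;
        }
      }
      min_val = lowest;
      if (!(min_val < INF)) stop("assignment problem is infeasible");
      const int j = remaining[index];
      if (row4col[j] == -1) sink = j; else i = row4col[j];
      SC[j] = 1;
      remaining[index] = remaining[--num_remaining];
    }

    u[cur_row] += min_val;
    for (int k = 0; k < n; ++k) {
      if (SR[k] && k != cur_row) u[k] += min_val - shortest[col4row[k]];
      if (SC[k]) v[k] -= min_val - shortest[k];
    }

    int j = sink;
    while (true) {
      const int ii = path[j];
      row4col[j] = ii;
      std::swap(col4row[ii], j);
      if (ii == cur_row) break;
    }
  }

  IntegerVector out(n);
  for (int r = 0; r < n; ++r) out[r] = col4row[r] + 1;
  return out;
}

// ---------------------------------------------------------------------------
// Spatial hash grid over 3D points (columns x, y, z).
// ---------------------------------------------------------------------------

struct Grid3 {
  double cell;
  std::unordered_map<long long, std::vector<int> > bins;

  static long long key(long long cx, long long cy, long long cz) {
    // coordinates here stay far below 2^20 cells
    return ((cx + 1048576LL) << 42) | ((cy + 1048576LL) << 21) | (cz + 1048576LL);
  }

  void build(const NumericMatrix& pts, double cell_size) {
    cell = cell_size;
    bins.clear();
    for (int i = 0; i < pts.nrow(); ++i) {
      long long cx = (long long)std::floor(pts(i, 0) / cell);
      long long cy = (long long)std::floor(pts(i, 1) / cell);
      long long cz = (long long)std::floor(pts(i, 2) / cell);
      bins[key(cx, cy, cz)].push_back(i);
    }
  }

  template <typename F>
  void visit_near(double x, double y, double z, F f) const {
    long long cx = (long long)std::floor(x / cell);
    long long cy = (long long)std::floor(y / cell);
    long long cz = (long long)std::floor(z / cell);
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          auto it = bins.find(key(cx + dx, cy + dy, cz + dz));
          if (it == bins.end()) continue;
          for (int idx : it->second) f(idx);
        }
  }
};

static inline double sqdist(const NumericMatrix& a, int i,
                            const NumericMatrix& b, int j) {
  const double dx = a(i, 0) - b(j, 0);
  const double dy = a(i, 1) - b(j, 1);
  const double dz = a(i, 2) - b(j, 2);
  return dx * dx + dy * dy + dz * dz;
}

// Number of OTHER points within distance <= radius of each point
// (hard-cutoff local density).
// [[Rcpp::export]]
IntegerVector cpp_radius_count(NumericMatrix pts, double radius) {
  const int n = pts.nrow();
  Grid3 grid;
  grid.build(pts, radius > 0 ? radius : 1.0);
  const double r2 = radius * radius;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int cnt = 0;
    grid.visit_near(pts(i, 0), pts(i, 1), pts(i, 2), [&](int j) {
      if (j != i && sqdist(pts, i, pts, j) <= r2) ++cnt;
    });
    out[i] = cnt;
  }
  return out;
}

// Greedy exclusion-radius cover: visit points in `order` (1-based indices);
// a visited point becomes a seed unless within <= radius of a chosen seed.
// [[Rcpp::export]]
LogicalVector cpp_greedy_seeds(NumericMatrix pts, IntegerVector order,
                               double radius) {
  const int n = pts.nrow();
  LogicalVector seed(n, false);
  const double r2 = radius * radius;
  std::vector<int> chosen;
  Grid3 grid;
  grid.cell = radius > 0 ? radius : 1.0;
  for (int k = 0; k < order.size(); ++k) {
    const int i = order[k] - 1;
    bool blocked = false;
    grid.visit_near(pts(i, 0), pts(i, 1), pts(i, 2), [&](int j) {
      if (!blocked && sqdist(pts, i, pts, j) <= r2) blocked = true;
    });
    if (!blocked) {
      seed[i] = true;
      long long cx = (long long)std::floor(pts(i, 0) / grid.cell);
      long long cy = (long long)std::floor(pts(i, 1) / grid.cell);
      long long cz = (long long)std::floor(pts(i, 2) / grid.cell);
      grid.bins[Grid3::key(cx, cy, cz)].push_back(i);
    }
  }
  return seed;
}

// For each row of `query`, nearest point in `ref` within `cap`:
// returns dist (Inf if none) and 1-based index (0 if none).
// [[Rcpp::export]]
List cpp_nn_within(NumericMatrix query, NumericMatrix ref, double cap) {
  const int n = query.nrow();
  NumericVector dist(n, R_PosInf);
  IntegerVector idx(n, 0);
  if (ref.nrow() == 0) return List::create(_["dist"] = dist, _["index"] = idx);
  Grid3 grid;
  grid.build(ref, cap > 0 ? cap : 1.0);
  const double cap2 = cap * cap;
  for (int i = 0; i < n; ++i) {
    double best = cap2;
    int bj = -1;
    grid.visit_near(query(i, 0), query(i, 1), query(i, 2), [&](int j) {
      const double d2 = sqdist(query, i, ref, j);
      if (d2 < best || (d2 == best && (bj == -1 || j < bj))) {
        best = d2;
        bj = j;
      }
    });
    if (bj >= 0) {
      dist[i] = std::sqrt(best);
      idx[i] = bj + 1;
    }
  }
  return List::create(_["dist"] = dist, _["index"] = idx);
}

// ---------------------------------------------------------------------------
// One fused E/M accumulation pass of the Gaussian mixture.
// prec: K x 9 row-major inverse covariances; logdet: log det of covariances.
// Returns soft counts, first and second moment accumulators, the hard
// assignment (argmax responsibility, lowest index on ties) and log-likelihood.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_gmm_pass(NumericMatrix X, NumericVector logpi, NumericMatrix mu,
                  NumericMatrix prec, NumericVector logdet,
                  Nullable<NumericVector> reach = R_NilValue) {
  const int n = X.nrow();
  const int K = mu.nrow();
  const double LOG2PI = std::log(2.0 * M_PI);
  NumericVector Nk(K);
  NumericMatrix Sx(K, 3), Sxx(K, 6);
  IntegerVector assign(n);
  double loglik = 0.0;
  std::vector<double> lp(K);
  std::vector<int> cand(K);

  // optional spatial truncation: cluster k only competes for points within
  // reach[k] of its mean (a generous multiple of its largest s.d., supplied
  // by the caller); the log-sum-exp then runs over the local candidates only
  const bool truncated = reach.isNotNull() &&
    NumericVector(reach.get()).size() == K && K > 1;
  NumericVector rch = truncated ? NumericVector(reach.get()) : NumericVector(0);
  Grid3 grid;
  double maxreach = 0.0;
  if (truncated) {
    for (int k = 0; k < K; ++k) maxreach = std::max(maxreach, rch[k]);
    grid.build(mu, maxreach > 0 ? maxreach : 1.0);
  }

  for (int i = 0; i < n; ++i) {
    const double x0 = X(i, 0), x1 = X(i, 1), x2 = X(i, 2);
    int nc = 0;
    if (truncated) {
      grid.visit_near(x0, x1, x2, [&](int k) {
        const double d0 = x0 - mu(k, 0), d1 = x1 - mu(k, 1),
                     d2 = x2 - mu(k, 2);
        if (d0 * d0 + d1 * d1 + d2 * d2 <= rch[k] * rch[k]) cand[nc++] = k;
      });
      std::sort(cand.begin(), cand.begin() + nc);
    }
    if (nc == 0) {
      for (int k = 0; k < K; ++k) cand[k] = k;
      nc = K;
    }
    double best = -std::numeric_limits<double>::infinity();
    int bk = cand[0];
    for (int c = 0; c < nc; ++c) {
      const int k = cand[c];
      const double d0 = x0 - mu(k, 0), d1 = x1 - mu(k, 1), d2 = x2 - mu(k, 2);
      const double q =
        d0 * (prec(k, 0) * d0 + prec(k, 1) * d1 + prec(k, 2) * d2) +
        d1 * (prec(k, 3) * d0 + prec(k, 4) * d1 + prec(k, 5) * d2) +
        d2 * (prec(k, 6) * d0 + prec(k, 7) * d1 + prec(k, 8) * d2);
      const double v = logpi[k] - 0.5 * (q + logdet[k] + 3.0 * LOG2PI);
      lp[c] = v;
      if (v > best) { best = v; bk = k; }
    }
    double sum = 0.0;
    for (int c = 0; c < nc; ++c) {
      const double e = lp[c] - best;
      lp[c] = (e > -36.0) ? std::exp(e) : 0.0;
      sum += lp[c];
    }
    loglik += best + std::log(sum);
    const double inv = 1.0 / sum;
    for (int c = 0; c < nc; ++c) {
      const double w = lp[c] * inv;
      if (w <= 0.0) continue;
      const int k = cand[c];
      Nk[k] += w;
      Sx(k, 0) += w * x0; Sx(k, 1) += w * x1; Sx(k, 2) += w * x2;
      Sxx(k, 0) += w * x0 * x0; Sxx(k, 1) += w * x1 * x1;
      Sxx(k, 2) += w * x2 * x2; Sxx(k, 3) += w * x0 * x1;
      Sxx(k, 4) += w * x0 * x2; Sxx(k, 5) += w * x1 * x2;
    }
    assign[i] = bk + 1;
  }
  return List::create(_["Nk"] = Nk, _["Sx"] = Sx, _["Sxx"] = Sxx,
                      _["assign"] = assign, _["loglik"] = loglik);
}

// ---------------------------------------------------------------------------
// 26-connectivity component labelling of integer voxel coordinates.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components26(IntegerMatrix pts) {
  const int n = pts.nrow();
  std::unordered_map<long long, int> vox;
  vox.reserve(2 * n);
  for (int i = 0; i < n; ++i)
    vox[Grid3::key(pts(i, 0), pts(i, 1), pts(i, 2))] = i;

  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };

  for (int i = 0; i < n; ++i) {
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          auto it = vox.find(Grid3::key(pts(i, 0) + dx, pts(i, 1) + dy,
                                        pts(i, 2) + dz));
          if (it == vox.end()) continue;
          const int a = find(i), b = find(it->second);
          if (a != b) parent[std::max(a, b)] = std::min(a, b);
        }
  }

  IntegerVector lab(n);
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    const int r = find(i);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = ++next; lab[i] = next; }
    else lab[i] = it->second;
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Distance field: for a volume of dims (nz, ny, nx), the Euclidean distance
// of each voxel (integer lattice positions) to the nearest of `pts`
// ((x, y, z) local 0-based coordinates, possibly fractional), capped at
// max_radius (voxels farther than that hold Inf).  Linear indexing matches an
// R array of dim c(nz, ny, nx).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_dist_field(IntegerVector dims, NumericMatrix pts,
                             double max_radius) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t total = (R_xlen_t)nz * ny * nx;
  NumericVector out(total, R_PosInf);
  const double r2 = max_radius * max_radius;
  const int m = pts.nrow();
  for (int p = 0; p < m; ++p) {
    const double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    const int x0 = std::max(0, (int)std::ceil(px - max_radius));
    const int x1 = std::min(nx - 1, (int)std::floor(px + max_radius));
    const int y0 = std::max(0, (int)std::ceil(py - max_radius));
    const int y1 = std::min(ny - 1, (int)std::floor(py + max_radius));
    const int z0 = std::max(0, (int)std::ceil(pz - max_radius));
    const int z1 = std::min(nz - 1, (int)std::floor(pz + max_radius));
    for (int x = x0; x <= x1; ++x) {
      const double ddx = (x - px) * (x - px);
      if (ddx > r2) continue;
      for (int y = y0; y <= y1; ++y) {
        const double ddxy = ddx + (y - py) * (y - py);
        if (ddxy > r2) continue;
        const R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        for (int z = z0; z <= z1; ++z) {
          const double d2 = ddxy + (z - pz) * (z - pz);
          if (d2 > r2) continue;
          const R_xlen_t idx = base + z;
          const double d = std::sqrt(d2);
          if (d < out[idx]) out[idx] = d;
        }
      }
    }
  }
  return out;
}
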