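#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Grid cells are addressed by R's column-major linear index (0-based here).
// Deterministic tie-breaks use row-major (row, col) order throughout.

static inline int rowmajor(int idx, int nr, int nc) {
  int r = idx % nr, c = idx / nr;
  return r * nc + c;
}

struct QNode {
  double d;
  int tie;   // row-major index, breaks ties deterministically
  int idx;   // column-major linear index
};
struct QNodeCmp {
  bool operator()(const QNode& a, const QNode& b) const {
    if (a.d != b.d) return a.d > b.d;
    return a.tie > b.tie;
  }
};

// Multi-source Dijkstra on the 8-connected grid graph.
// Edge cost between adjacent cells i,j: (R_i + R_j)/2 * cell_size * (sqrt(2) if diagonal).
// NA resistance = impassable. Returns cumulative cost-weighted distance (Inf where
// unreachable) and the predecessor cell (0-based column-major index, -1 at sources /
// unreached cells).
// [[Rcpp::export]]
List cpp_cost_distance(NumericMatrix resist, IntegerVector sources, double cell_size) {
  const int nr = resist.nrow(), nc = resist.ncol(), n = nr * nc;
  const double SQ2 = std::sqrt(2.0);
  std::vector<double> dist(n, std::numeric_limits<double>::infinity());
  std::vector<int> back(n, -1);
  std::priority_queue<QNode, std::vector<QNode>, QNodeCmp> pq;
  for (int k = 0; k < sources.size(); ++k) {
    int s = sources[k];
    if (s < 0 || s >= n) stop("source index out of range");
    if (NumericMatrix::is_na(resist[s])) continue;
    if (dist[s] > 0.0) {
      dist[s] = 0.0;
      pq.push({0.0, rowmajor(s, nr, nc), s});
    }
  }
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!pq.empty()) {
    QNode top = pq.top(); pq.pop();
    int u = top.idx;
    if (top.d > dist[u]) continue;
    int ur = u % nr, uc = u / nr;
    double Ru = resist[u];
    for (int k = 0; k < 8; ++k) {
      int vr = ur + dr[k], vc = uc + dc[k];
      if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
      int v = vr + vc * nr;
      if (NumericMatrix::is_na(resist[v])) continue;
      double mult = (dr[k] != 0 && dc[k] != 0) ? SQ2 : 1.0;
      double w = 0.5 * (Ru + resist[v]) * cell_size * mult;
      double nd = top.d + w;
      if (nd < dist[v]) {
        dist[v] = nd;
        back[v] = u;
        pq.push({nd, rowmajor(v, nr, nc), v});
      }
    }
  }
  NumericMatrix cwd(nr, nc);
  IntegerMatrix bk(nr, nc);
  for (int i = 0; i < n; ++i) { cwd[i] = dist[i]; bk[i] = back[i]; }
  return List::create(_["cwd"] = cwd, _["back"] = bk);
}

// Point-to-point least-cost distance with an optional set of cells whose
// resistance is overridden (barrier-restoration re-solve). Early exit once
// every target has been settled or the cheapest target is final.
// [[Rcpp::export]]
double cpp_cost_between(NumericMatrix resist, IntegerVector sources,
                        IntegerVector targets, IntegerVector override_cells,
                        double override_value, double cell_size) {
  const int nr = resist.nrow(), nc = resist.ncol(), n = nr * nc;
  const double SQ2 = std::sqrt(2.0);
  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = resist[i];
  for (int k = 0; k < override_cells.size(); ++k) {
    int i = override_cells[k];
    if (i < 0 || i >= n) stop("override index out of range");
    R[i] = override_value;
  }
  std::vector<bool> is_target(n, false);
  for (int k = 0; k < targets.size(); ++k) is_target[targets[k]] = true;
  std::vector<double> dist(n, std::numeric_limits<double>::infinity());
  std::priority_queue<QNode, std::vector<QNode>, QNodeCmp> pq;
  for (int k = 0; k < sources.size(); ++k) {
    int s = sources[k];
    if (std::isnan(R[s])) continue;
    if (dist[s] > 0.0) { dist[s] = 0.0; pq.push({0.0, rowmajor(s, nr, nc), s}); }
  }
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!pq.empty()) {
    QNode top = pq.top(); pq.pop();
    int u = top.idx;
    if (top.d > dist[u]) continue;
    if (is_target[u]) return top.d;  // first settled target is the cheapest
    int ur = u % nr, uc = u / nr;
    for (int k = 0; k < 8; ++k) {
      int vr = ur + dr[k], vc = uc + dc[k];
      if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
      int v = vr + vc * nr;
      if (std::isnan(R[v])) continue;
      double mult = (dr[k] != 0 && dc[k] != 0) ? SQ2 : 1.0;
      double nd = top.d + 0.5 * (R[u] + R[v]) * cell_size * mult;
      if (nd < dist[v]) { dist[v] = nd; pq.push({nd, rowmajor(v, nr, nc), v}); }
    }
  }
  return R_PosInf;
}

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// in cell units; separable 1-D lower-envelope passes over columns then rows.
static void edt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                  std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double BIG = 1e20;
  NumericMatrix g(nr, nc);
  int nmax = std::max(nr, nc);
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? 0.0 : BIG;
    edt1d(f, d, nr, v, z);
    for (int r = 0; r < nr; ++r) g(r, c) = d[r];
  }
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = g(r, c);
    edt1d(f, d, nc, v, z);
    for (int c = 0; c < nc; ++c) g(r, c) = d[c];
  }
  return g;
}

// 8-connected component labelling; labels assigned in row-major scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int u = stack.back(); stack.pop_back();
        int ur = u % nr, uc = u / nr;
        for (int k = 0; k < 8; ++k) {
          int vr = ur + dr[k], vc = uc + dc[k];
          if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
          if (mask(vr, vc) && lab(vr, vc) == 0) {
            lab(vr, vc) = next;
            stack.push_back(vr + vc * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Exact Fisher-Jenks optimal 1-D classification by dynamic programming:
// minimises total within-class sum of squared deviations. Input must be
// sorted ascending. Returns 1-based start index of each of the k classes.
// Ties broken toward the earliest split (lowest breaks).
// [[Rcpp::export]]
IntegerVector cpp_jenks_starts(NumericVector x, int k) {
  const int n = x.size();
  if (k < 1 || k > n) stop("k out of range");
  std::vector<double> S(n + 1, 0.0), S2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    S[i + 1] = S[i] + x[i];
    S2[i + 1] = S2[i] + x[i] * x[i];
  }
  auto sse = [&](int a, int b) {  // cells a..b inclusive, 0-based
    double s = S[b + 1] - S[a], s2 = S2[b + 1] - S2[a];
    double m = b - a + 1;
    return s2 - s * s / m;
  };
  const double INF = std::numeric_limits<double>::infinity();
  // cost[c][i]: minimal SSE of x[0..i] split into c+1 classes
  std::vector<std::vector<double>> cost(k, std::vector<double>(n, INF));
  std::vector<std::vector<int>> split(k, std::vector<int>(n, 0));
  for (int i = 0; i < n; ++i) cost[0][i] = sse(0, i);
  for (int c = 1; c < k; ++c) {
    for (int i = c; i < n; ++i) {
      double best = INF; int bj = c;
      for (int j = c; j <= i; ++j) {  // class c starts at j
        double val = cost[c - 1][j - 1] + sse(j, i);
        if (val < best) { best = val; bj = j; }
      }
      cost[c][i] = best;
      split[c][i] = bj;
    }
  }
  IntegerVector starts(k);
  int i = n - 1;
  for (int c = k - 1; c >= 1; --c) {
    int j = split[c][i];
    starts[c] = j + 1;  // 1-based
    i = j - 1;
  }
  starts[0] = 1;
  return starts;
}

// [[Rcpp::export]]
double cpp_jenks_objective(NumericVector x, IntegerVector starts) {
  const int n = x.size(), k = starts.size();
  double total = 0.0;
  for (int c = 0; c < k; ++c) {
    int a = starts[c] - 1;
    int b = (c + 1 < k ? starts[c + 1] - 2 : n - 1);
    double s = 0.0, s2 = 0.0, m = b - a + 1;
    for (int i = a; i <= b; ++i) { s += x[i]; s2 += x[i] * x[i]; }
    total += s2 - s * s / m;
  }
  return total;
}

// Even-odd rule point-in-polygon for one ring (closed or open coords).
// [[Rcpp::export]]
LogicalVector cpp_points_in_ring(NumericVector px, NumericVector py,
                                 NumericVector rx, NumericVector ry) {
  const int np = px.size(), nv = rx.size();
  LogicalVector out(np);
  for (int i = 0; i < np; ++i) {
    bool inside = false;
    double x = px[i], y = py[i];
    for (int a = 0, b = nv - 1; a < nv; b = a++) {
      if (((ry[a] > y) != (ry[b] > y)) &&
          (x < (rx[b] - rx[a]) * (y - ry[a]) / (ry[b] - ry[a]) + rx[a]))
        inside = !inside;
    }
    out[i] = inside;
  }
  return out;
}
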