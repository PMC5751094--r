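#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 8-connected component labeling by breadth-first flood fill.
// Returns an integer matrix with 0 = background, 1..k = component id.
// [[Rcpp::export]]
IntegerMatrix label_components8(LogicalMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  int cur = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++cur;
      lab(i, j) = cur;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            if (di == 0 && dj == 0) continue;
            int ni = p.first + di, nj = p.second + dj;
            if (ni < 0 || nj < 0 || ni >= h || nj >= w) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = cur;
              q.push(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  return lab;
}

static inline bool segment_inside(double r1, double c1, double r2, double c2,
                                  const LogicalMatrix &mask) {
  double len = std::sqrt((r2 - r1) * (r2 - r1) + (c2 - c1) * (c2 - c1));
  int nstep = (int)std::ceil(len / 0.35) + 1;
  int h = mask.nrow(), w = mask.ncol();
  for (int s = 0; s <= nstep; ++s) {
    double t = (double)s / nstep;
    int ri = (int)std::lround(r1 + t * (r2 - r1)) - 1;
    int ci = (int)std::lround(c1 + t * (c2 - c1)) - 1;
    if (ri < 0 || ci < 0 || ri >= h || ci >= w) return false;
    if (!mask(ri, ci)) return false;
  }
  return true;
}

// Inner distances between boundary sample points: build the visibility graph
// of the points (edge when the straight segment stays inside the mask), then
// complete by Floyd-Warshall shortest paths. Consecutive contour samples are
// always connected (they are adjacent along the boundary walk).
// pts: n x 2 matrix of (row, col) 1-based coordinates, ordered along the contour.
// Returns D (n x n inner distances) and `nxt` (1-based index of the first node
// after i on the shortest path i -> j; 0 on the diagonal or if unreachable).
// [[Rcpp::export]]
List inner_distance_graph(NumericMatrix pts, LogicalMatrix mask) {
  int n = pts.nrow();
  NumericMatrix D(n, n);
  IntegerMatrix nxt(n, n);
  double inf = R_PosInf;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) D(i, j) = (i == j) ? 0.0 : inf;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = std::sqrt(std::pow(pts(i, 0) - pts(j, 0), 2) +
                           std::pow(pts(i, 1) - pts(j, 1), 2));
      bool adjacent = (j == i + 1) || (i == 0 && j == n - 1);
      if (adjacent ||
          segment_inside(pts(i, 0), pts(i, 1), pts(j, 0), pts(j, 1), mask)) {
        D(i, j) = d;
        D(j, i) = d;
        nxt(i, j) = j + 1;
        nxt(j, i) = i + 1;
      }
    }
  }
  for (int k = 0; k < n; ++k) {
    for (int i = 0; i < n; ++i) {
      if (D(i, k) == inf) continue;
      for (int j = 0; j < n; ++j) {
        double alt = D(i, k) + D(k, j);
        if (alt < D(i, j)) {
          D(i, j) = alt;
          nxt(i, j) = nxt(i, k);
        }
      }
    }
  }
  return List::create(Named("distance") = D, Named("nxt") = nxt);
}

// Chi-squared / 2 matching cost between every row-histogram of Ha and Hb.
// Bins with zero combined mass contribute nothing.
// [[Rcpp::export]]
NumericMatrix chi2_cost_matrix(NumericMatrix Ha, NumericMatrix Hb) {
  int na = Ha.nrow(), nb = Hb.nrow(), K = Ha.ncol();
  if (Hb.ncol() != K) stop("histogram sets have different bin counts");
  NumericMatrix C(na, nb);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double acc = 0.0;
      for (int k = 0; k < K; ++k) {
        double s = Ha(i, k) + Hb(j, k);
        if (s > 0) {
          double d = Ha(i, k) - Hb(j, k);
          acc += d * d / s;
        }
      }
      C(i, j) = 0.5 * acc;
    }
  }
  return C;
}

// Order-preserving circular matching by dynamic programming with a fixed
// per-skip occlusion penalty, minimized over all circular start offsets of
// the second shape. C is the point-to-point matching cost matrix (n x m).
// [[Rcpp::export]]
double dp_match_cost(NumericMatrix C, double penalty) {
  int n = C.nrow(), m = C.ncol();
  std::vector<double> prev(m + 1), cur(m + 1);
  double best = R_PosInf;
  for (int s = 0; s < m; ++s) {
    for (int j = 0; j <= m; ++j) prev[j] = j * penalty;
    for (int i = 1; i <= n; ++i) {
      cur[0] = i * penalty;
      for (int j = 1; j <= m; ++j) {
        int jj = (j - 1 + s) % m;  // column of C for the j-th point after shift
        double v = prev[j - 1] + C(i - 1, jj);
        double vskip1 = prev[j] + penalty;
        double vskip2 = cur[j - 1] + penalty;
        if (vskip1 < v) v = vskip1;
        if (vskip2 < v) v = vskip2;
        cur[j] = v;
      }
      std::swap(prev, cur);
    }
    if (prev[m] < best) best = prev[m];
  }
  return best;
}
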