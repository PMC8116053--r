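// Inner loops of the spatial module: translation-corrected Ripley K over a
// convex polygon window, the set-covariance overlap it needs, and DBSCAN.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Poly {
  std::vector<double> x, y;
  size_t size() const { return x.size(); }
};

double signedArea(const Poly& p) {
  const size_t n = p.size();
  double a = 0.0;
  for (size_t i = 0, j = n - 1; i < n; j = i++) {
    a += p.x[j] * p.y[i] - p.x[i] * p.y[j];
  }
  return a / 2.0;
}

// Sutherland-Hodgman: clip subject polygon by the half-plane left of a->b.
// Valid when the clip polygon (traversed counterclockwise) is convex.
void clipHalfPlane(const Poly& in, Poly& out,
                   double ax, double ay, double bx, double by) {
  out.x.clear();
  out.y.clear();
  const size_t n = in.size();
  if (n == 0) return;
  const double ex = bx - ax, ey = by - ay;
  for (size_t i = 0, j = n - 1; i < n; j = i++) {
    const double sj = ex * (in.y[j] - ay) - ey * (in.x[j] - ax);
    const double si = ex * (in.y[i] - ay) - ey * (in.x[i] - ax);
    const bool inj = sj >= 0.0, ini = si >= 0.0;
    if (inj != ini) {
      const double t = sj / (sj - si);
      out.x.push_back(in.x[j] + t * (in.x[i] - in.x[j]));
      out.y.push_back(in.y[j] + t * (in.y[i] - in.y[j]));
    }
    if (ini) {
      out.x.push_back(in.x[i]);
      out.y.push_back(in.y[i]);
    }
  }
}

// |W  intersect  (W + v)| for a convex, counterclockwise window W.
double overlapArea(const Poly& w, double dx, double dy) {
  Poly cur = w, nxt;
  const size_t n = w.size();
  for (size_t i = 0, j = n - 1; i < n; j = i++) {
    clipHalfPlane(cur, nxt,
                  w.x[j] + dx, w.y[j] + dy, w.x[i] + dx, w.y[i] + dy);
    std::swap(cur, nxt);
    if (cur.size() < 3) return 0.0;
  }
  return std::fabs(signedArea(cur));
}

Poly asPoly(const NumericMatrix& verts) {
  Poly p;
  const int n = verts.nrow();
  p.x.resize(n);
  p.y.resize(n);
  for (int i = 0; i < n; ++i) {
    p.x[i] = verts(i, 0);
    p.y[i] = verts(i, 1);
  }
  if (signedArea(p) < 0) {  // enforce counterclockwise
    std::reverse(p.x.begin(), p.x.end());
    std::reverse(p.y.begin(), p.y.end());
  }
  return p;
}

}  // namespace

// [[Rcpp::export]]
double cpp_overlap_area(NumericMatrix verts, double dx, double dy) {
  return overlapArea(asPoly(verts), dx, dy);
}

// Translation-corrected (Goreaud-Pelissier) Ripley K at each radius:
//   K(r) = |W| / (n (n-1)) * sum_{i != j, d_ij <= r} |W| / |W ^ W_{v_ij}|
// [[Rcpp::export]]
NumericVector cpp_ripley_k(NumericVector x, NumericVector y,
                           NumericMatrix verts, NumericVector radii) {
  const int n = x.size();
  const int nr = radii.size();
  NumericVector K(nr);
  if (n < 2) return K;
  Poly w = asPoly(verts);
  const double area = std::fabs(signedArea(w));
  const double rmax = radii[nr - 1];
  std::vector<double> acc(nr, 0.0);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      const double d = std::sqrt(dx * dx + dy * dy);
      if (d > rmax) continue;
      const double ov = overlapArea(w, dx, dy);
      if (ov <= 0.0) continue;  // translation weight undefined; skip pair
      const double wt = 2.0 * area / ov;  // both ordered pairs
      // first radius index with radii[k] >= d
      int k = int(std::lower_bound(radii.begin(), radii.end(), d) -
                  radii.begin());
      if (k < nr) acc[k] += wt;
    }
  }
  double cum = 0.0;
  const double norm = area / (double(n) * double(n - 1));
  for (int k = 0; k < nr; ++k) {
    cum += acc[k];
    K[k] = norm * cum;
  }
  return K;
}

// Classic DBSCAN with the neighborhood count INCLUDING the focal point
// (MinPts = 2 means "at least one neighbor within eps"). Points are scanned
// in input order; border points join the first-discovered core cluster.
// Returns per-point labels: 0 = noise, 1..n_clusters otherwise.
// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericVector x, NumericVector y,
                         double eps, int min_pts) {
  const int n = x.size();
  IntegerVector labels(n, 0);
  if (n == 0) return labels;
  const double eps2 = eps * eps;
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) nb[i].push_back(i);  // self-inclusive count
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      if (dx * dx + dy * dy <= eps2) {
        nb[i].push_back(j);
        nb[j].push_back(i);
      }
    }
  }
  for (int i = 0; i < n; ++i) std::sort(nb[i].begin(), nb[i].end());
  std::vector<bool> visited(n, false);
  int cluster = 0;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = true;
    if (int(nb[i].size()) < min_pts) continue;  // noise unless claimed later
    ++cluster;
    labels[i] = cluster;
    std::queue<int> q;
    for (size_t k = 0; k < nb[i].size(); ++k) q.push(nb[i][k]);
    while (!q.empty()) {
      const int j = q.front();
      q.pop();
      if (!visited[j]) {
        visited[j] = true;
        labels[j] = cluster;
        if (int(nb[j].size()) >= min_pts) {
          for (size_t k = 0; k < nb[j].size(); ++k) q.push(nb[j][k]);
        }
      } else if (labels[j] == 0) {
        labels[j] = cluster;  // border point claimed by first core cluster
      }
    }
  }
  return labels;
}
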