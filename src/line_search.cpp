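#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Exhaustive search for the linear separator of labeled planar points
// maximizing the F-measure. The line is parameterized in normal form as
//   p1 * sin(alpha) - p2 * cos(alpha) - q > 0  =>  predicted positive,
// with alpha restricted to (0, pi/2) so that more positive-neighbour mass
// always pushes towards a positive call.
//
// Candidate angles: for every pair of distinct points the angle at which the
// two projected scores coincide (tan(alpha) = dp2/dp1, kept when it falls in
// (0, pi/2)), a uniform fallback grid of 64 angles, and +/-1e-6 perturbations
// of every candidate (a candidate that passes exactly through two points
// leaves them tied; the perturbations realize both ways of breaking the tie).
// For each fixed alpha the offset q is swept exactly: the projected scores
// are sorted and q is taken at midpoints between consecutive distinct values
// plus sentinels beyond both extremes.
//
// With k points predicted positive of which tp are true positives,
// F = 2*tp / (2*tp + fp + fn) = 2*tp / (k + P) where P is the number of
// positive points. Ties are broken by max F, then max tp, then min alpha,
// then min q (within one angle equal (F, tp) forces an equal cut, so the
// first three rules suffice for determinism).

// [[Rcpp::export]]
List cpp_best_line(NumericVector p1, NumericVector p2, IntegerVector y) {
  const int n = p1.size();
  int P = 0;
  for (int i = 0; i < n; ++i) P += y[i];
  if (P < 1) stop("at least one positive point is required");

  // unique points for candidate-angle generation
  std::vector<std::pair<double, double> > pts(n);
  for (int i = 0; i < n; ++i) pts[i] = std::make_pair(p1[i], p2[i]);
  std::sort(pts.begin(), pts.end());
  pts.erase(std::unique(pts.begin(), pts.end()), pts.end());
  const int m = pts.size();

  const double half_pi = M_PI / 2.0;
  const double eps = 1e-6;
  std::vector<double> base;
  base.reserve((size_t)m * (m - 1) / 2 + 64);
  for (int a = 0; a < m; ++a) {
    for (int b = a + 1; b < m; ++b) {
      double dp1 = pts[a].first - pts[b].first;
      double dp2 = pts[a].second - pts[b].second;
      if (dp1 == 0.0) continue;
      double ratio = dp2 / dp1;
      if (ratio <= 0.0) continue;
      base.push_back(std::atan(ratio));
    }
  }
  for (int g = 1; g <= 64; ++g) base.push_back(half_pi * g / 65.0);

  std::vector<double> angles;
  angles.reserve(base.size() * 3);
  for (size_t t = 0; t < base.size(); ++t) {
    double a = base[t];
    if (a > 0.0 && a < half_pi) angles.push_back(a);
    if (a - eps > 0.0 && a - eps < half_pi) angles.push_back(a - eps);
    if (a + eps > 0.0 && a + eps < half_pi) angles.push_back(a + eps);
  }
  std::sort(angles.begin(), angles.end());
  angles.erase(std::unique(angles.begin(), angles.end()), angles.end());

  double bestF = -1.0, bestAlpha = NA_REAL, bestQ = NA_REAL;
  int bestTp = -1, bestK = 0;

  std::vector<std::pair<double, int> > zy(n);
  for (size_t t = 0; t < angles.size(); ++t) {
    const double alpha = angles[t];
    const double s = std::sin(alpha), c = std::cos(alpha);
    for (int i = 0; i < n; ++i)
      zy[i] = std::make_pair(p1[i] * s - p2[i] * c, y[i]);
    // descending by projected score
    std::sort(zy.begin(), zy.end(),
              [](const std::pair<double, int>& a,
                 const std::pair<double, int>& b) { return a.first > b.first; });
    int cumPos = 0;
    for (int k = 1; k <= n; ++k) {
      cumPos += zy[k - 1].second;
      // only cut between distinct score values (strict rule z > q)
      if (k < n && zy[k].first == zy[k - 1].first) continue;
      double F = 2.0 * cumPos / (double)(k + P);
      if (F > bestF || (F == bestF && cumPos > bestTp)) {
        bestF = F;
        bestTp = cumPos;
        bestK = k;
        bestAlpha = alpha;
        bestQ = (k < n) ? 0.5 * (zy[k - 1].first + zy[k].first)
                        : zy[n - 1].first - 1.0;
      }
    }
  }

  int tp = bestTp;
  int fp = bestK - bestTp;
  int fn = P - bestTp;
  int tn = (n - P) - fp;
  return List::create(_["alpha"] = bestAlpha, _["q"] = bestQ,
                      _["tp"] = tp, _["fp"] = fp, _["fn"] = fn, _["tn"] = tn,
                      _["f"] = bestF);
}
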