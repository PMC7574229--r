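#include <Rcpp.h>
using namespace Rcpp;

// First exit times of a 2-D trajectory from circles centred at each fix.
//
// For fix i and radius r the exit time is the elapsed time until the path
// first reaches distance r from p_i, scanning forward (dir = +1) or backward
// (dir = -1), with linear interpolation between the last fix inside and the
// first fix at or beyond the radius. Fixes whose circle is never exited
// within the segment are censored (NA). Radii must be sorted increasing; a
// single monotone sweep over the running maximum distance serves all radii.
//
// [[Rcpp::export]]
NumericMatrix fpt_exit_times(NumericVector x, NumericVector y, NumericVector t,
                             NumericVector radii, int dir) {
  const int n = x.size();
  const int R = radii.size();
  NumericMatrix out(n, R);
  std::fill(out.begin(), out.end(), NA_REAL);
  if (dir != 1 && dir != -1) stop("dir must be +1 or -1");
  for (int i = 0; i < n; ++i) {
    double cmax = 0.0;
    int r_idx = 0;
    double dprev = 0.0, tprev = t[i];
    for (int j = i + dir; j >= 0 && j < n; j += dir) {
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      const double d = std::sqrt(dx * dx + dy * dy);
      if (d > cmax) {
        while (r_idx < R && d >= radii[r_idx]) {
          const double r = radii[r_idx];
          double tc;
          if (d == dprev) tc = t[j];
          else tc = tprev + (r - dprev) / (d - dprev) * (t[j] - tprev);
          out(i, r_idx) = std::fabs(tc - t[i]);
          ++r_idx;
        }
        cmax = d;
        if (r_idx >= R) break;
      }
      dprev = d;
      tprev = t[j];
    }
  }
  return out;
}
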