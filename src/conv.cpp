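#include <Rcpp.h>
using namespace Rcpp;

// Exact convolution of exp(-beta * t) with a piecewise-linear signal u(t)
// sampled at (possibly non-uniform) grid times t. Returns
//   y(t_n) = \int_0^{t_n} u(s) exp(-beta (t_n - s)) ds
// computed segment-by-segment with closed-form increments, so the only
// approximation is the piecewise-linear representation of u itself.
// Small beta*dt is handled via expm1 to keep the increment well conditioned.
// [[Rcpp::export]]
NumericVector conv_exp_lin(NumericVector t, NumericVector u, double beta) {
  int n = t.size();
  NumericVector y(n);
  if (n == 0) return y;
  y[0] = 0.0;
  for (int i = 1; i < n; ++i) {
    double dt = t[i] - t[i - 1];
    double u0 = u[i - 1], u1 = u[i];
    double inc;
    if (beta * dt < 1e-8) {
      // beta ~ 0: plain trapezoid of the segment
      inc = 0.5 * (u0 + u1) * dt;
      y[i] = y[i - 1] * std::exp(-beta * dt) + inc;
    } else {
      double em = -std::expm1(-beta * dt);       // 1 - exp(-beta dt)
      double slope = (u1 - u0) / dt;
      inc = u0 * em / beta + slope * (dt - em / beta) / beta;
      y[i] = y[i - 1] * (1.0 - em) + inc;
    }
  }
  return y;
}

// Logan slope per voxel for a matrix of tissue curves (rows = voxels,
// columns = frame midpoints). x-axis numerator intcp (integral of the
// plasma input at each midpoint) is shared across voxels; the tissue
// integral is the anchored trapezoid over midpoints per voxel.
// Returns slope (VT), intercept and r^2 per voxel; voxels with any
// non-positive tissue value at or after the first included point, or with
// fewer than 3 usable points, yield NaN.
// [[Rcpp::export]]
NumericMatrix logan_slopes(NumericMatrix ct, NumericVector mids,
                           NumericVector intcp, LogicalVector keep) {
  int nv = ct.nrow(), nf = ct.ncol();
  NumericMatrix out(nv, 3);
  std::vector<double> intct(nf), x, y;
  for (int v = 0; v < nv; ++v) {
    // anchored trapezoid of the voxel TAC over (0, mids)
    double acc = 0.0, prev_t = 0.0, prev_c = 0.0;
    for (int j = 0; j < nf; ++j) {
      double c = ct(v, j);
      acc += 0.5 * (prev_c + c) * (mids[j] - prev_t);
      intct[j] = acc;
      prev_t = mids[j];
      prev_c = c;
    }
    x.clear(); y.clear();
    bool bad = false;
    for (int j = 0; j < nf; ++j) {
      if (!keep[j]) continue;
      double c = ct(v, j);
      if (!(c > 0.0) || !R_finite(c)) { bad = true; continue; }
      x.push_back(intcp[j] / c);
      y.push_back(intct[j] / c);
    }
    int m = x.size();
    if (bad || m < 3) {
      out(v, 0) = NA_REAL; out(v, 1) = NA_REAL; out(v, 2) = NA_REAL;
      continue;
    }
    double sx = 0, sy = 0;
    for (int j = 0; j < m; ++j) { sx += x[j]; sy += y[j]; }
    double mx = sx / m, my = sy / m, sxx = 0, sxy = 0, syy = 0;
    for (int j = 0; j < m; ++j) {
      double dx = x[j] - mx, dy = y[j] - my;
      sxx += dx * dx; sxy += dx * dy; syy += dy * dy;
    }
    if (sxx <= 0.0) {
      out(v, 0) = NA_REAL; out(v, 1) = NA_REAL; out(v, 2) = NA_REAL;
      continue;
    }
    double b = sxy / sxx;
    out(v, 0) = b;
    out(v, 1) = my - b * mx;
    out(v, 2) = syy > 0 ? (sxy * sxy) / (sxx * syy) : 1.0;
  }
  return out;
}
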