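#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Fraction of the circle of radius r centred at (px, py) lying inside the
// rectangle [0,W] x [0,H], by the closed-form arc construction for a
// rectangular window. Valid for r <= min(W, H) / 2 (enforced by callers):
// at most one corner region can then overlap per pair of adjacent edges.
static double interior_fraction(double px, double py, double r,
                                double W, double H) {
  if (r <= 0.0) return 1.0;
  double dl = px, dr = W - px, db = py, dt = H - py;
  double ext = 0.0;
  if (dl < r) ext += 2.0 * std::acos(dl / r);
  if (dr < r) ext += 2.0 * std::acos(dr / r);
  if (db < r) ext += 2.0 * std::acos(db / r);
  if (dt < r) ext += 2.0 * std::acos(dt / r);
  const double corners[4][2] = {{dl, db}, {dl, dt}, {dr, db}, {dr, dt}};
  for (int c = 0; c < 4; ++c) {
    double e1 = corners[c][0], e2 = corners[c][1];
    if (e1 < r && e2 < r && e1 * e1 + e2 * e2 < r * r) {
      // the two edge arcs overlap beyond this corner; remove the
      // double-counted exterior wedge
      ext -= std::acos(e1 / r) + std::acos(e2 / r) - M_PI / 2.0;
    }
  }
  double frac = 1.0 - ext / (2.0 * M_PI);
  if (frac < 1e-12) frac = 1e-12;
  return frac;
}

// [[Rcpp::export]]
double interior_fraction_cpp(double px, double py, double r,
                             double W, double H) {
  return interior_fraction(px, py, r, W, H);
}

static double wrap_torus(double v, double lim) {
  v -= std::floor(v / lim) * lim;
  if (v >= lim) v -= lim;
  if (v < 0.0) v += lim;
  return v;
}

// All intertype pairs with d_ij <= max_d. wa is the Ripley weight centred
// on the point of pattern a (the focal point of the i-in-a direction),
// wb the weight centred on the b point. With ripley = false both are 1.
// [[Rcpp::export]]
List cross_pairs_cpp(NumericVector xa, NumericVector ya,
                     NumericVector xb, NumericVector yb,
                     double W, double H, double max_d, bool ripley) {
  int na = xa.size(), nb = xb.size();
  std::vector<double> d, wa, wb;
  std::vector<int> ii, jj;
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double dx = xa[i] - xb[j], dy = ya[i] - yb[j];
      double dij = std::sqrt(dx * dx + dy * dy);
      if (dij <= max_d) {
        d.push_back(dij);
        if (ripley) {
          wa.push_back(1.0 / interior_fraction(xa[i], ya[i], dij, W, H));
          wb.push_back(1.0 / interior_fraction(xb[j], yb[j], dij, W, H));
        } else {
          wa.push_back(1.0);
          wb.push_back(1.0);
        }
        ii.push_back(i + 1);
        jj.push_back(j + 1);
      }
    }
  }
  return List::create(_["d"] = wrap(d), _["wa"] = wrap(wa),
                      _["wb"] = wrap(wb), _["i"] = wrap(ii),
                      _["j"] = wrap(jj));
}

// Per-lag cumulative directional weight sums Sa(d), Sb(d) over pairs with
// d_ij <= lag (closed ball). lags must be strictly increasing.
static void directional_sums(const NumericVector& xa, const NumericVector& ya,
                             const NumericVector& xb, const NumericVector& yb,
                             double W, double H, const NumericVector& lags,
                             bool ripley, std::vector<double>& sa,
                             std::vector<double>& sb) {
  int na = xa.size(), nb = xb.size(), nl = lags.size();
  double max_d = lags[nl - 1];
  std::fill(sa.begin(), sa.end(), 0.0);
  std::fill(sb.begin(), sb.end(), 0.0);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double dx = xa[i] - xb[j], dy = ya[i] - yb[j];
      double dij = std::sqrt(dx * dx + dy * dy);
      if (dij > max_d) continue;
      int bin = std::lower_bound(lags.begin(), lags.end(), dij) - lags.begin();
      if (ripley) {
        sa[bin] += 1.0 / interior_fraction(xa[i], ya[i], dij, W, H);
        sb[bin] += 1.0 / interior_fraction(xb[j], yb[j], dij, W, H);
      } else {
        sa[bin] += 1.0;
        sb[bin] += 1.0;
      }
    }
  }
  for (int k = 1; k < nl; ++k) {
    sa[k] += sa[k - 1];
    sb[k] += sb[k - 1];
  }
}

// [[Rcpp::export]]
NumericVector lrs_curve_cpp(NumericVector xa, NumericVector ya,
                            NumericVector xb, NumericVector yb,
                            double W, double H, NumericVector lags,
                            bool ripley) {
  int na = xa.size(), nb = xb.size(), nl = lags.size();
  std::vector<double> sa(nl), sb(nl);
  directional_sums(xa, ya, xb, yb, W, H, lags, ripley, sa, sb);
  double A = W * H, N = na + nb;
  double pref = A / (N * N * M_PI);
  NumericVector out(nl);
  for (int k = 0; k < nl; ++k)
    out[k] = pref * (sa[k] / na + sb[k] / nb);
  return out;
}

// Null-model curves for the toroidal-shift model: pattern b is rigidly
// translated by (dx[k], dy[k]) on the torus for simulation k.
// [[Rcpp::export]]
NumericMatrix lrs_toroidal_sims_cpp(NumericVector xa, NumericVector ya,
                                    NumericVector xb, NumericVector yb,
                                    double W, double H, NumericVector lags,
                                    bool ripley, NumericVector dx,
                                    NumericVector dy) {
  int na = xa.size(), nb = xb.size(), nl = lags.size(), ns = dx.size();
  double A = W * H, N = na + nb;
  double pref = A / (N * N * M_PI);
  NumericMatrix out(ns, nl);
  std::vector<double> sa(nl), sb(nl);
  NumericVector xs(nb), ys(nb);
  for (int k = 0; k < ns; ++k) {
    for (int j = 0; j < nb; ++j) {
      xs[j] = wrap_torus(xb[j] + dx[k], W);
      ys[j] = wrap_torus(yb[j] + dy[k], H);
    }
    directional_sums(xa, ya, xs, ys, W, H, lags, ripley, sa, sb);
    for (int l = 0; l < nl; ++l)
      out(k, l) = pref * (sa[l] / na + sb[l] / nb);
  }
  return out;
}

// Pair table for the intertype mark correlation: per intertype pair the
// lag bin (1-based index of the first lag >= d_ij; 0 if beyond the grid)
// and the summed bidirectional weight wa + wb.
// [[Rcpp::export]]
List kmm_pairs_cpp(NumericVector xa, NumericVector ya,
                   NumericVector xb, NumericVector yb,
                   double W, double H, NumericVector lags, bool ripley) {
  int na = xa.size(), nb = xb.size(), nl = lags.size();
  double max_d = lags[nl - 1];
  std::vector<int> bin, ii, jj;
  std::vector<double> w;
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double dx = xa[i] - xb[j], dy = ya[i] - yb[j];
      double dij = std::sqrt(dx * dx + dy * dy);
      if (dij > max_d) continue;
      int b = std::lower_bound(lags.begin(), lags.end(), dij) - lags.begin();
      double wij = 2.0;
      if (ripley)
        wij = 1.0 / interior_fraction(xa[i], ya[i], dij, W, H) +
              1.0 / interior_fraction(xb[j], yb[j], dij, W, H);
      bin.push_back(b + 1);
      w.push_back(wij);
      ii.push_back(i + 1);
      jj.push_back(j + 1);
    }
  }
  return List::create(_["bin"] = wrap(bin), _["w"] = wrap(w),
                      _["i"] = wrap(ii), _["j"] = wrap(jj));
}

// Mark-correlation curves for a set of mark assignments (columns of
// za/zb hold per-point standardised marks; column k is one realisation).
// Lags with zero cumulative pair weight are NA.
// [[Rcpp::export]]
NumericMatrix kmm_curves_cpp(IntegerVector bin, NumericVector w,
                             IntegerVector i, IntegerVector j,
                             NumericMatrix za, NumericMatrix zb, int n_lags) {
  int np = bin.size(), ns = za.ncol();
  std::vector<double> den(n_lags, 0.0);
  for (int p = 0; p < np; ++p) den[bin[p] - 1] += w[p];
  for (int l = 1; l < n_lags; ++l) den[l] += den[l - 1];
  NumericMatrix out(ns, n_lags);
  std::vector<double> num(n_lags);
  for (int k = 0; k < ns; ++k) {
    std::fill(num.begin(), num.end(), 0.0);
    for (int p = 0; p < np; ++p)
      num[bin[p] - 1] += w[p] * za(i[p] - 1, k) * zb(j[p] - 1, k);
    double acc = 0.0;
    for (int l = 0; l < n_lags; ++l) {
      acc += num[l];
      out(k, l) = den[l] > 0.0 ? acc / den[l] : NA_REAL;
    }
  }
  return out;
}
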