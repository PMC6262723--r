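// Bivariate Ripley K estimation on a rectangular window.
//
// K12_hat(r) = A/(n1*n2) * sum_i sum_j w_ij * 1[d_ij <= r]
// translation correction: w_ij = (W*H) / ((W - |dx|) * (H - |dy|))
// isotropic correction:   w_ij = 1 / (fraction of the circle of radius
//                         d_ij centred on point i lying inside the window)

#include <Rcpp.h>
using namespace Rcpp;

static double iso_weight(double x, double y, double d, double W, double H) {
  // exterior arc angle of the circle of radius d centred at (x, y)
  double dist[4] = {x, W - x, y, H - y};  // left, right, bottom, top
  double outside = 0.0;
  for (int e = 0; e < 4; ++e)
    if (dist[e] < d) outside += 2.0 * std::acos(dist[e] / d);
  // corner overlap: when the circle covers a corner, the two edge caps
  // intersect and the overlap was counted twice
  double cx[4] = {x, W - x, x, W - x};
  double cy[4] = {y, y, H - y, H - y};
  for (int c = 0; c < 4; ++c) {
    double dc = std::sqrt(cx[c] * cx[c] + cy[c] * cy[c]);
    if (dc < d)
      outside -= (M_PI / 2.0 - std::asin(cx[c] / d) - std::asin(cy[c] / d));
  }
  double frac = 1.0 - outside / (2.0 * M_PI);
  return 1.0 / frac;
}

static void k_accumulate(const NumericVector& x1, const NumericVector& y1,
                         const NumericVector& x2, const NumericVector& y2,
                         double W, double H, const NumericVector& r,
                         bool isotropic, double* acc) {
  int n1 = x1.size(), n2 = x2.size(), nr = r.size();
  double rmax = 0.0;
  for (int k = 0; k < nr; ++k) rmax = std::max(rmax, r[k]);
  for (int i = 0; i < n1; ++i) {
    for (int j = 0; j < n2; ++j) {
      double dx = x1[i] - x2[j], dy = y1[i] - y2[j];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d > rmax || d == 0.0) continue;
      double w;
      if (isotropic)
        w = iso_weight(x1[i], y1[i], d, W, H);
      else
        w = (W * H) / ((W - std::fabs(dx)) * (H - std::fabs(dy)));
      for (int k = 0; k < nr; ++k)
        if (d <= r[k]) acc[k] += w;
    }
  }
}

// [[Rcpp::export(name = ".k12_cpp")]]
NumericVector k12_cpp(NumericVector x1, NumericVector y1,
                      NumericVector x2, NumericVector y2,
                      double W, double H, NumericVector r,
                      bool isotropic = false) {
  int nr = r.size();
  NumericVector K(nr);
  std::vector<double> acc(nr, 0.0);
  k_accumulate(x1, y1, x2, y2, W, H, r, isotropic, acc.data());
  double A = W * H;
  double n1 = x1.size(), n2 = x2.size();
  for (int k = 0; k < nr; ++k) K[k] = A / (n1 * n2) * acc[k];
  return K;
}

// K12 for each torus shift of pattern 1 (pattern 2 fixed): returns an
// n_shift x n_r matrix. Shift vectors are drawn in R for seed control.
// [[Rcpp::export(name = ".k12_shift_cpp")]]
NumericMatrix k12_shift_cpp(NumericVector x1, NumericVector y1,
                            NumericVector x2, NumericVector y2,
                            double W, double H, NumericVector r,
                            NumericVector dx, NumericVector dy,
                            bool isotropic = false) {
  int ns = dx.size(), nr = r.size(), n1 = x1.size();
  NumericMatrix K(ns, nr);
  NumericVector sx(n1), sy(n1);
  double A = W * H;
  double nn = (double)n1 * x2.size();
  for (int s = 0; s < ns; ++s) {
    for (int i = 0; i < n1; ++i) {
      sx[i] = std::fmod(x1[i] + dx[s], W);
      sy[i] = std::fmod(y1[i] + dy[s], H);
    }
    std::vector<double> acc(nr, 0.0);
    k_accumulate(sx, sy, x2, y2, W, H, r, isotropic, acc.data());
    for (int k = 0; k < nr; ++k) K(s, k) = A / nn * acc[k];
  }
  return K;
}
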