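#include <Rcpp.h>
#include <vector>
#include <cmath>

// Generalized Lotka-Volterra dynamics for a bacteria/phage community sharing
// one resource:
//   dB_i/dt = k_i B_i (1 - sum_j B_j) - alpha B_i - B_i sum_k eta_ki P_k
//   dP_k/dt = P_k beta_k sum_m eta_km B_m - delta P_k
// eta is phage-major (M x N, column-major storage from R). Competition
// coefficients between bacteria are identically 1 (fully shared resource).

namespace {

struct GlvSystem {
  int n, m;
  const double *k, *eta, *beta;  // eta: column-major M x N
  double alpha, delta;

  void rhs(const double* B, const double* P, double* dB, double* dP) const {
    double tot = 0.0;
    for (int i = 0; i < n; ++i) tot += B[i];
    for (int i = 0; i < n; ++i) {
      double press = 0.0;
      const double* col = eta + (size_t)i * m;
      for (int l = 0; l < m; ++l) press += col[l] * P[l];
      dB[i] = B[i] * (k[i] * (1.0 - tot) - alpha - press);
    }
    for (int l = 0; l < m; ++l) {
      double prey = 0.0;
      for (int i = 0; i < n; ++i) prey += eta[(size_t)i * m + l] * B[i];
      dP[l] = P[l] * (beta[l] * prey - delta);
    }
  }
};

// one classical RK4 step of size h from y (length d) into out
void rk4_step(const GlvSystem& sys, const std::vector<double>& y, double h,
              std::vector<double>& out, std::vector<double>& k1,
              std::vector<double>& k2, std::vector<double>& k3,
              std::vector<double>& k4, std::vector<double>& tmp) {
  const int n = sys.n;
  const int d = n + sys.m;
  sys.rhs(y.data(), y.data() + n, k1.data(), k1.data() + n);
  for (int i = 0; i < d; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
  sys.rhs(tmp.data(), tmp.data() + n, k2.data(), k2.data() + n);
  for (int i = 0; i < d; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
  sys.rhs(tmp.data(), tmp.data() + n, k3.data(), k3.data() + n);
  for (int i = 0; i < d; ++i) tmp[i] = y[i] + h * k3[i];
  sys.rhs(tmp.data(), tmp.data() + n, k4.data(), k4.data() + n);
  for (int i = 0; i < d; ++i)
    out[i] = y[i] + (h / 6.0) * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

}  // namespace

// Integrate with classical RK4 under step-doubling error control until one
// strain's density first falls below `threshold`. A trial step is rejected
// (and h halved) when the step-doubling error estimate exceeds tolerance or
// a density would drop below -1e-12; tiny negatives are clipped to zero
// (absorbing). If several strains cross threshold within one accepted step,
// the one with the smallest density is reported.
// [[Rcpp::export(name = ".rk4_until_extinction_cpp")]]
Rcpp::List rk4_until_extinction_cpp(Rcpp::NumericVector k, double alpha,
                                    Rcpp::NumericMatrix eta,
                                    Rcpp::NumericVector beta, double delta,
                                    Rcpp::NumericVector B0,
                                    Rcpp::NumericVector P0, double threshold,
                                    double h0, double t_max) {
  const int n = B0.size(), m = P0.size();
  const int d = n + m;
  GlvSystem sys{n, m, k.begin(), eta.begin(), beta.begin(), alpha, delta};

  const double rtol = 1e-8, atol = 1e-30;
  const double neg_tol = 1e-12;
  const double h_min = 1e-8, h_max = 10.0;

  std::vector<double> y(d), y_big(d), y_half(d), y_small(d);
  std::vector<double> k1(d), k2(d), k3(d), k4(d), tmp(d);
  for (int i = 0; i < n; ++i) y[i] = B0[i];
  for (int i = 0; i < m; ++i) y[n + i] = P0[i];

  double t = 0.0;
  double h = (h0 > 0) ? h0 : 0.01;
  unsigned long iter = 0;

  while (t < t_max) {
    if (h > t_max - t) h = t_max - t;
    if (h < h_min) h = h_min;

    rk4_step(sys, y, h, y_big, k1, k2, k3, k4, tmp);
    rk4_step(sys, y, 0.5 * h, y_half, k1, k2, k3, k4, tmp);
    rk4_step(sys, y_half, 0.5 * h, y_small, k1, k2, k3, k4, tmp);

    double err = 0.0;
    bool neg = false;
    for (int i = 0; i < d; ++i) {
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y_small[i]));
      double e = std::fabs(y_small[i] - y_big[i]) / sc;
      if (e > err) err = e;
      if (y_small[i] < -neg_tol || y_big[i] < -neg_tol) neg = true;
    }

    if ((err > 1.0 || neg) && h > h_min) {
      h *= 0.5;  // reject: retry with a smaller step
    } else {
      t += h;
      for (int i = 0; i < d; ++i) y[i] = (y_small[i] < 0.0) ? 0.0 : y_small[i];
      // step-size growth, capped
      double fac = (err > 0.0) ? 0.9 * std::pow(err, -0.2) : 4.0;
      if (fac > 4.0) fac = 4.0;
      if (fac < 0.2) fac = 0.2;
      h = std::min(h * fac, h_max);

      double worst = threshold;
      int worst_idx = -1;
      for (int i = 0; i < d; ++i) {
        if (y[i] < worst) { worst = y[i]; worst_idx = i; }
      }
      if (worst_idx >= 0) {
        const bool is_bact = worst_idx < n;
        Rcpp::NumericVector Bout(n), Pout(m);
        for (int i = 0; i < n; ++i) Bout[i] = y[i];
        for (int i = 0; i < m; ++i) Pout[i] = y[n + i];
        return Rcpp::List::create(
            Rcpp::Named("converged") = true,
            Rcpp::Named("extinct_is_bacterium") = is_bact,
            Rcpp::Named("extinct_index") = (is_bact ? worst_idx : worst_idx - n) + 1,
            Rcpp::Named("t") = t, Rcpp::Named("B") = Bout,
            Rcpp::Named("P") = Pout);
      }
    }
    if (++iter % 100000UL == 0UL) Rcpp::checkUserInterrupt();
  }

  Rcpp::NumericVector Bout(n), Pout(m);
  for (int i = 0; i < n; ++i) Bout[i] = y[i];
  for (int i = 0; i < m; ++i) Pout[i] = y[n + i];
  return Rcpp::List::create(Rcpp::Named("converged") = false,
                            Rcpp::Named("extinct_is_bacterium") = NA_LOGICAL,
                            Rcpp::Named("extinct_index") = NA_INTEGER,
                            Rcpp::Named("t") = t, Rcpp::Named("B") = Bout,
                            Rcpp::Named("P") = Pout);
}

// [[Rcpp::export(name = ".glv_rhs_cpp")]]
Rcpp::List glv_rhs_cpp(Rcpp::NumericVector k, double alpha,
                       Rcpp::NumericMatrix eta, Rcpp::NumericVector beta,
                       double delta, Rcpp::NumericVector B,
                       Rcpp::NumericVector P) {
  const int n = B.size(), m = P.size();
  GlvSystem sys{n, m, k.begin(), eta.begin(), beta.begin(), alpha, delta};
  Rcpp::NumericVector dB(n), dP(m);
  std::vector<double> db(n), dp(m);
  sys.rhs(B.begin(), P.begin(), db.data(), dp.data());
  for (int i = 0; i < n; ++i) dB[i] = db[i];
  for (int i = 0; i < m; ++i) dP[i] = dp[i];
  return Rcpp::List::create(Rcpp::Named("dB") = dB, Rcpp::Named("dP") = dP);
}
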