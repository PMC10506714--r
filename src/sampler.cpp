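// Model-tailored MCMC for the hierarchical decomposition/link model.
//
// Structure: conditional on the phases (t0), AR1 autocorrelations (rho) and the
// scale parameters (sigmas), every remaining parameter -- window means and
// amplitudes, WT window extrema, the extrema-regression coefficients, the daily
// link gains delta/gamma, and all latent missing values -- has an exactly
// Gaussian full conditional. Those are sampled by exact Gibbs; scalar sites use
// a quadratic fit to their local conditional log-density (exact for Gaussian
// conditionals, three evaluations), regression blocks use small conjugate
// multivariate-normal draws. The non-Gaussian scalars use adaptive random-walk
// Metropolis, with scales tuned toward 44% acceptance during burn-in and frozen
// afterwards.
//
// Under M2, latent missing WT days are likelihood leaves: parameter
// conditionals use observed WT days only and the latent days are redrawn as
// posterior-predictive leaves each sweep (partially collapsed Gibbs). Under M1
// the WT AR1 chain couples latent days, so they take part in the conditionals.

#include <Rcpp.h>
#include <functional>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

static const double TWOPI = 6.283185307179586476925286766559;

struct Priors {
  double theta_mean, theta_sd;
  double dg_mean, dg_sd;
  double rho_lo, rho_hi;
  double t0_lo, t0_hi;
  std::vector<double> alpha_at_mean; double alpha_at_sd, beta_at_sd;
  std::vector<double> alpha_q_mean;  double alpha_q_sd,  beta_q_sd;
  double sig_at_sd, sig_q_sd, sig_z_sd, sig_max_sd, sig_min_sd, sig_wt_sd;
};

struct Model {
  // data
  int T, W;
  std::vector<int> win;            // 0-based window per day
  std::vector<int> winlo, winhi;   // 0-based inclusive day range per window
  std::vector<double> doy, nyr;
  std::vector<double> wt, at, q;   // current values (latent filled in)
  std::vector<int> obs_wt, obs_at, obs_q;
  std::vector<int> mis_wt, mis_at, mis_q;   // indices of missing days
  bool useq, m1, shared;

  // parameters
  std::vector<double> aAT, bAT, aQ, bQ, maxWT, minWT;
  double t0AT, rhoAT, sigAT, t0Q, rhoQ, sigQ, t0WT;
  double th0, th1, th2, th0p, th1p, th2p, sigMax, sigMin;
  double delta, gamma, sigZ, rhoWT, sigWT;

  // caches
  std::vector<double> sinAT, sAT, epsAT, sinQ, sQ, epsQ, sinWT, modQ, sWT;
  std::vector<double> sind, cosd;   // sin/cos of omega_t * doy_t, fixed data
  std::vector<double> meanSind, meanCosd, omegaW;  // per-window averages of the above

  Priors pr;

  double omega(int t) const { return TWOPI / nyr[t]; }

  void init_trig() {
    sind.resize(T); cosd.resize(T);
    for (int t = 0; t < T; ++t) {
      sind[t] = std::sin(omega(t) * doy[t]);
      cosd[t] = std::cos(omega(t) * doy[t]);
    }
    meanSind.assign(W, 0.0); meanCosd.assign(W, 0.0); omegaW.assign(W, 0.0);
    for (int w = 0; w < W; ++w) {
      for (int t = winlo[w]; t <= winhi[w]; ++t) {
        meanSind[w] += sind[t]; meanCosd[w] += cosd[t];
      }
      int n = winhi[w] - winlo[w] + 1;
      meanSind[w] /= n; meanCosd[w] /= n;
      omegaW[w] = omega(winlo[w]);   // windows never straddle a year boundary
    }
  }

  // window average of sin(omega * (doy - t0))
  double win_avg_sin(int w, double t0) const {
    return meanSind[w] * std::cos(omegaW[w] * t0) - meanCosd[w] * std::sin(omegaW[w] * t0);
  }

  // sin(omega_t * (doy_t - t0)) for all t via the angle-addition identity:
  // only two distinct omega values occur (365- and 366-day years)
  void sin_for_t0(double t0, std::vector<double>& out) const {
    double c365 = std::cos(TWOPI / 365.0 * t0), s365 = std::sin(TWOPI / 365.0 * t0);
    double c366 = std::cos(TWOPI / 366.0 * t0), s366 = std::sin(TWOPI / 366.0 * t0);
    for (int t = 0; t < T; ++t) {
      bool leap = nyr[t] > 365.5;
      double c = leap ? c366 : c365, sn = leap ? s366 : s365;
      out[t] = sind[t] * c - cosd[t] * sn;
    }
  }

  void recompute_at() {
    sin_for_t0(t0AT, sinAT);
    for (int t = 0; t < T; ++t) {
      sAT[t] = aAT[win[t]] + bAT[win[t]] * sinAT[t];
      epsAT[t] = at[t] - sAT[t];
    }
  }
  void recompute_q() {
    if (!useq) return;
    sin_for_t0(t0Q, sinQ);
    for (int t = 0; t < T; ++t) {
      sQ[t] = aQ[win[t]] + bQ[win[t]] * sinQ[t];
      epsQ[t] = q[t] - sQ[t];
    }
  }
  void recompute_wt_geom() {
    sin_for_t0(t0WT, sinWT);
    for (int t = 0; t < T; ++t) {
      // sin(x + pi) == -sin(x): the flow modifier antiphases the seasonal sine
      modQ[t] = -sinWT[t];
      sWT[t] = 0.5 * (1.0 + sinWT[t]) * maxWT[win[t]] + 0.5 * (1.0 - sinWT[t]) * minWT[win[t]];
    }
  }
  void recompute_swt() {  // t0WT unchanged, extrema changed
    for (int t = 0; t < T; ++t)
      sWT[t] = 0.5 * (1.0 + sinWT[t]) * maxWT[win[t]] + 0.5 * (1.0 - sinWT[t]) * minWT[win[t]];
  }

  double mu_wt(int t) const {  // M2 daily mean
    double m = sWT[t] + delta * epsAT[t];
    if (useq) m += gamma * epsQ[t] * modQ[t];
    return m;
  }

  // ---- log-density pieces -------------------------------------------------
  static double ldnorm(double x, double m, double sd) {
    double z = (x - m) / sd;
    return -0.918938533204672742 - std::log(sd) - 0.5 * z * z;
  }

  // AR1 over a residual vector held in a cache; stationary first point.
  // log(sd) is factored out of the daily loop.
  double ll_ar1(const std::vector<double>& eps, double rho, double sig) const {
    double isig = 1.0 / sig;
    double q0 = eps[0] * isig;
    double ss = q0 * q0 * (1.0 - rho * rho);
    for (int t = 1; t < T; ++t) {
      double z = (eps[t] - rho * eps[t - 1]) * isig;
      ss += z * z;
    }
    return -T * (0.918938533204672742 + std::log(sig)) +
           0.5 * std::log(1.0 - rho * rho) - 0.5 * ss;
  }

  // AR1 terms whose residual index lies in [lo, hi] (0-based, inclusive)
  double ll_ar1_range(const std::vector<double>& eps, double rho, double sig,
                      int lo, int hi) const {
    double isig = 1.0 / sig, ss = 0.0, extra = 0.0;
    for (int t = lo; t <= hi; ++t) {
      if (t == 0) {
        double z = eps[0] * isig;
        ss += z * z * (1.0 - rho * rho);
        extra += 0.5 * std::log(1.0 - rho * rho);
      } else {
        double z = (eps[t] - rho * eps[t - 1]) * isig;
        ss += z * z;
      }
    }
    int cnt = hi - lo + 1;
    return -cnt * (0.918938533204672742 + std::log(sig)) + extra - 0.5 * ss;
  }

  // M2 daily WT likelihood over observed days (optionally restricted);
  // log(sd) factored out of the loop
  double ll_wt_m2(int lo, int hi) const {
    double isig = 1.0 / sigZ, ss = 0.0;
    int cnt = 0;
    for (int t = lo; t <= hi; ++t) {
      if (!obs_wt[t]) continue;
      double z = (wt[t] - mu_wt(t)) * isig;
      ss += z * z; ++cnt;
    }
    return -cnt * (0.918938533204672742 + std::log(sigZ)) - 0.5 * ss;
  }

  // M1: AR1 on WT residuals (all days, latent included)
  double ll_wt_m1_range(int lo, int hi) const {
    double isig = 1.0 / sigWT, ss = 0.0, extra = 0.0;
    int cnt = 0;
    for (int t = lo; t <= hi; ++t) {
      double e = wt[t] - sWT[t];
      if (t == 0) {
        double z = e * isig;
        ss += z * z * (1.0 - rhoWT * rhoWT);
        extra += 0.5 * std::log(1.0 - rhoWT * rhoWT);
      } else {
        double z = (e - rhoWT * (wt[t - 1] - sWT[t - 1])) * isig;
        ss += z * z;
      }
      ++cnt;
    }
    return -cnt * (0.918938533204672742 + std::log(sigWT)) + extra - 0.5 * ss;
  }

  double ll_wt(int lo, int hi) const {
    return m1 ? ll_wt_m1_range(lo, hi) : ll_wt_m2(lo, hi);
  }

  double eq2_mu_max(int w) const {
    double m = th0 + th1 * (aAT[w] + bAT[w]);
    if (useq) m += th2 * (aQ[w] - bQ[w]);
    return m;
  }
  double eq2_mu_min(int w) const {
    double m = (shared ? th0 : th0p) + th1p * (aAT[w] - bAT[w]);
    if (useq) m += th2p * (aQ[w] + bQ[w]);
    return m;
  }
  double ll_eq2_row(int w) const {
    return ldnorm(maxWT[w], eq2_mu_max(w), sigMax) +
           ldnorm(minWT[w], eq2_mu_min(w), sigMin);
  }
  double ll_eq2() const {
    double ll = 0.0;
    for (int w = 0; w < W; ++w) ll += ll_eq2_row(w);
    return ll;
  }
};

// ---------------------------------------------------------------------------
// samplers

static double rtnorm_lower(double mean, double sd, double lo) {
  double a = (lo - mean) / sd;
  if (a < 5.0) {
    double pa = R::pnorm(a, 0.0, 1.0, 1, 0);
    double u = R::runif(pa, 1.0);
    if (u >= 1.0) u = 1.0 - 1e-16;
    double z = R::qnorm(u, 0.0, 1.0, 1, 0);
    return mean + sd * z;
  }
  // deep tail: Robert's translated-exponential rejection
  double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (int it = 0; it < 1000; ++it) {
    double z = a + R::rexp(1.0) / alpha;
    double rho = std::exp(-0.5 * (z - alpha) * (z - alpha));
    if (R::runif(0.0, 1.0) <= rho) return mean + sd * z;
  }
  return mean + sd * a;  // unreachable in practice
}

// Exact Gibbs for a scalar site whose conditional log-density f is quadratic.
// f is evaluated at x0 - h, x0, x0 + h; draws N(mu, 1/P), optionally truncated
// below at `lo` (use -inf for none).
template <class F>
static double quad_gibbs(F f, double x0, double h, double lo) {
  double f1 = f(x0 - h), f2 = f(x0), f3 = f(x0 + h);
  double curv = 2.0 * f2 - f1 - f3;          // = P * h^2
  double P = curv / (h * h);
  if (!(P > 0.0)) return x0;                 // numerically flat: keep value
  double mu = x0 + h * (f3 - f1) / (2.0 * curv);
  double sd = 1.0 / std::sqrt(P);
  if (lo == R_NegInf) return R::rnorm(mu, sd);
  return rtnorm_lower(mu, sd, lo);
}

// Small conjugate Bayesian linear regression draw: posterior of coef c with
// prior N(m0, sd0^2 I), rows (y_i, x_i, prec tau_i). K <= 6.
static void conj_reg_draw(int K, const std::vector<double>& X,  // n x K row-major
                          const std::vector<double>& y,
                          const std::vector<double>& tau,
                          double m0, double sd0, double* out) {
  double A[36] = {0}, b[6] = {0};
  int n = (int)y.size();
  double p0 = 1.0 / (sd0 * sd0);
  for (int k = 0; k < K; ++k) { A[k * K + k] = p0; b[k] = p0 * m0; }
  for (int i = 0; i < n; ++i) {
    const double* xi = &X[i * K];
    for (int k = 0; k < K; ++k) {
      b[k] += tau[i] * xi[k] * y[i];
      for (int l = 0; l <= k; ++l) A[k * K + l] += tau[i] * xi[k] * xi[l];
    }
  }
  for (int k = 0; k < K; ++k)
    for (int l = k + 1; l < K; ++l) A[k * K + l] = A[l * K + k];
  // Cholesky A = L L'
  double L[36] = {0};
  for (int k = 0; k < K; ++k) {
    double s = A[k * K + k];
    for (int l = 0; l < k; ++l) s -= L[k * K + l] * L[k * K + l];
    L[k * K + k] = std::sqrt(s);
    for (int i = k + 1; i < K; ++i) {
      double t = A[i * K + k];
      for (int l = 0; l < k; ++l) t -= L[i * K + l] * L[k * K + l];
      L[i * K + k] = t / L[k * K + k];
    }
  }
  // mean: solve L L' m = b
  double z[6], m[6];
  for (int k = 0; k < K; ++k) {
    double s = b[k];
    for (int l = 0; l < k; ++l) s -= L[k * K + l] * z[l];
    z[k] = s / L[k * K + k];
  }
  for (int k = K - 1; k >= 0; --k) {
    double s = z[k];
    for (int l = k + 1; l < K; ++l) s -= L[l * K + k] * m[l];
    m[k] = s / L[k * K + k];
  }
  // draw: m + L'^{-1} eps
  double e[6];
  for (int k = 0; k < K; ++k) e[k] = R::norm_rand();
  for (int k = K - 1; k >= 0; --k) {
    double s = e[k];
    for (int l = k + 1; l < K; ++l) s -= L[l * K + k] * e[l];
    e[k] = s / L[k * K + k];
  }
  for (int k = 0; k < K; ++k) out[k] = m[k] + e[k];
}

struct RWSite { double scale; int acc = 0, tries = 0; };

static bool mh_accept(double lp_new, double lp_old) {
  if (!std::isfinite(lp_new)) return false;
  return std::log(R::unif_rand()) < lp_new - lp_old;
}

// ---------------------------------------------------------------------------

class Sampler {
public:
  Model m;
  RWSite rw_slide{2.0};
  RWSite rw_t0AT{2.0}, rw_rhoAT{0.1}, rw_sigAT{0.1},
         rw_t0Q{2.0},  rw_rhoQ{0.1},  rw_sigQ{0.1},
         rw_t0WT{2.0}, rw_sigZ{0.05}, rw_sigMax{0.2}, rw_sigMin{0.2},
         rw_rhoWT{0.1}, rw_sigWT{0.05};
  bool adapting = true;

  // ---- latent values ------------------------------------------------------
  void update_latent_at() {
    for (int idx : m.mis_at) {
      int t = idx;
      double x0 = m.at[t];
      auto f = [&](double x) {
        double e = x - m.sAT[t];
        double ll;
        if (t == 0) ll = Model::ldnorm(e, 0.0, m.sigAT / std::sqrt(1 - m.rhoAT * m.rhoAT));
        else ll = Model::ldnorm(e, m.rhoAT * m.epsAT[t - 1], m.sigAT);
        if (t + 1 < m.T) ll += Model::ldnorm(m.epsAT[t + 1], m.rhoAT * e, m.sigAT);
        if (!m.m1 && m.obs_wt[t]) {
          double mu = m.sWT[t] + m.delta * e;
          if (m.useq) mu += m.gamma * m.epsQ[t] * m.modQ[t];
          ll += Model::ldnorm(m.wt[t], mu, m.sigZ);
        }
        return ll;
      };
      double x = quad_gibbs(f, x0, 1.0, R_NegInf);
      m.at[t] = x; m.epsAT[t] = x - m.sAT[t];
    }
  }

  void update_latent_q() {
    if (!m.useq) return;
    for (int idx : m.mis_q) {
      int t = idx;
      auto f = [&](double x) {
        double e = x - m.sQ[t];
        double ll;
        if (t == 0) ll = Model::ldnorm(e, 0.0, m.sigQ / std::sqrt(1 - m.rhoQ * m.rhoQ));
        else ll = Model::ldnorm(e, m.rhoQ * m.epsQ[t - 1], m.sigQ);
        if (t + 1 < m.T) ll += Model::ldnorm(m.epsQ[t + 1], m.rhoQ * e, m.sigQ);
        if (!m.m1 && m.obs_wt[t]) {
          double mu = m.sWT[t] + m.delta * m.epsAT[t] + m.gamma * e * m.modQ[t];
          ll += Model::ldnorm(m.wt[t], mu, m.sigZ);
        }
        return ll;
      };
      double x = quad_gibbs(f, m.q[t], 1.0, R_NegInf);
      m.q[t] = x; m.epsQ[t] = x - m.sQ[t];
    }
  }

  void update_latent_wt() {
    if (!m.m1) {
      for (int t : m.mis_wt) m.wt[t] = R::rnorm(m.mu_wt(t), m.sigZ);  // leaf draw
      return;
    }
    for (int t : m.mis_wt) {
      auto f = [&](double x) {
        double e = x - m.sWT[t];
        double ll;
        if (t == 0) ll = Model::ldnorm(e, 0.0, m.sigWT / std::sqrt(1 - m.rhoWT * m.rhoWT));
        else ll = Model::ldnorm(e, m.rhoWT * (m.wt[t - 1] - m.sWT[t - 1]), m.sigWT);
        if (t + 1 < m.T)
          ll += Model::ldnorm(m.wt[t + 1] - m.sWT[t + 1], m.rhoWT * e, m.sigWT);
        return ll;
      };
      m.wt[t] = quad_gibbs(f, m.wt[t], 1.0, R_NegInf);
    }
  }

  // ---- window means / amplitudes of a covariate series --------------------
  // Local conditional of aX[w] or bX[w]: AR1 terms with residual index in
  // [lo, min(hi+1, T-1)], the WT daily terms in [lo, hi] (delta/gamma paths,
  // M2 only), the Eq 2 row of window w, and the prior.
  void update_cov_windows(bool is_q) {
    std::vector<double>& a = is_q ? m.aQ : m.aAT;
    std::vector<double>& b = is_q ? m.bQ : m.bAT;
    std::vector<double>& s = is_q ? m.sQ : m.sAT;
    std::vector<double>& sn = is_q ? m.sinQ : m.sinAT;
    std::vector<double>& eps = is_q ? m.epsQ : m.epsAT;
    std::vector<double>& val = is_q ? m.q : m.at;
    double rho = is_q ? m.rhoQ : m.rhoAT;
    double sig = is_q ? m.sigQ : m.sigAT;
    const std::vector<double>& amean = is_q ? m.pr.alpha_q_mean : m.pr.alpha_at_mean;
    double asd = is_q ? m.pr.alpha_q_sd : m.pr.alpha_at_sd;
    double bsd = is_q ? m.pr.beta_q_sd : m.pr.beta_at_sd;

    for (int w = 0; w < m.W; ++w) {
      int lo = m.winlo[w], hi = m.winhi[w];
      int hi1 = std::min(hi + 1, m.T - 1);
      for (int which = 0; which < 2; ++which) {   // 0 = alpha, 1 = beta
        double x0 = which == 0 ? a[w] : b[w];
        auto f = [&](double x) {
          double save = which == 0 ? a[w] : b[w];
          if (which == 0) a[w] = x; else b[w] = x;
          for (int t = lo; t <= hi; ++t) {
            s[t] = a[w] + b[w] * sn[t];
            eps[t] = val[t] - s[t];
          }
          double ll = ll_ar1_local(eps, rho, sig, lo, hi1);
          if (!m.m1) ll += m.ll_wt_m2(lo, hi);
          ll += m.ll_eq2_row(w);
          ll += which == 0 ? Model::ldnorm(x, amean[w], asd)
                           : Model::ldnorm(x, 0.0, bsd);
          if (which == 0) a[w] = save; else b[w] = save;
          return ll;
        };
        double lobnd = which == 0 ? R_NegInf : 0.0;
        double x = quad_gibbs(f, x0, 0.5, lobnd);
        if (which == 0) a[w] = x; else b[w] = x;
        for (int t = lo; t <= hi; ++t) {
          s[t] = a[w] + b[w] * sn[t];
          eps[t] = val[t] - s[t];
        }
      }
    }
  }

  double ll_ar1_local(const std::vector<double>& eps, double rho, double sig,
                      int lo, int hi) const {
    return m.ll_ar1_range(eps, rho, sig, lo, hi);
  }

  // ---- WT window extrema --------------------------------------------------
  void update_wt_extrema() {
    for (int w = 0; w < m.W; ++w) {
      int lo = m.winlo[w], hi = m.winhi[w];
      int hi1 = std::min(hi + 1, m.T - 1);
      for (int which = 0; which < 2; ++which) {   // 0 = max, 1 = min
        double x0 = which == 0 ? m.maxWT[w] : m.minWT[w];
        auto f = [&](double x) {
          double save = which == 0 ? m.maxWT[w] : m.minWT[w];
          if (which == 0) m.maxWT[w] = x; else m.minWT[w] = x;
          for (int t = lo; t <= hi; ++t)
            m.sWT[t] = 0.5 * (1 + m.sinWT[t]) * m.maxWT[w] + 0.5 * (1 - m.sinWT[t]) * m.minWT[w];
          double ll = m.ll_eq2_row(w);
          ll += m.m1 ? m.ll_wt_m1_range(lo, hi1) : m.ll_wt_m2(lo, hi);
          if (which == 0) m.maxWT[w] = save; else m.minWT[w] = save;
          return ll;
        };
        double x = quad_gibbs(f, x0, 0.5, R_NegInf);
        if (which == 0) m.maxWT[w] = x; else m.minWT[w] = x;
        for (int t = lo; t <= hi; ++t)
          m.sWT[t] = 0.5 * (1 + m.sinWT[t]) * m.maxWT[w] + 0.5 * (1 - m.sinWT[t]) * m.minWT[w];
      }
    }
  }

  // ---- theta regression block (conjugate MVN) -----------------------------
  void update_theta() {
    // coefficient layout: [th0, th1, (th2), (th0p), th1p, (th2p)]
    int K = 2 + (m.useq ? 1 : 0) + (m.shared ? 0 : 1) + 1 + (m.useq ? 1 : 0);
    std::vector<double> X(2 * m.W * K, 0.0), y(2 * m.W), tau(2 * m.W);
    for (int w = 0; w < m.W; ++w) {
      int rmax = 2 * w, rmin = 2 * w + 1, k = 0;
      // max row
      X[rmax * K + 0] = 1.0;                       // th0
      X[rmax * K + 1] = m.aAT[w] + m.bAT[w];       // th1
      k = 2;
      if (m.useq) { X[rmax * K + k] = m.aQ[w] - m.bQ[w]; k++; }  // th2
      int k0p = k;
      if (m.shared) { X[rmin * K + 0] = 1.0; } else { X[rmin * K + k0p] = 1.0; k++; }
      int k1p = k;
      X[rmin * K + k1p] = m.aAT[w] - m.bAT[w]; k++;              // th1p
      if (m.useq) X[rmin * K + k] = m.aQ[w] + m.bQ[w];           // th2p
      y[rmax] = m.maxWT[w]; y[rmin] = m.minWT[w];
      tau[rmax] = 1.0 / (m.sigMax * m.sigMax);
      tau[rmin] = 1.0 / (m.sigMin * m.sigMin);
    }
    double c[6];
    conj_reg_draw(K, X, y, tau, m.pr.theta_mean, m.pr.theta_sd, c);
    int k = 0;
    m.th0 = c[k++]; m.th1 = c[k++];
    m.th2 = m.useq ? c[k++] : 0.0;
    m.th0p = m.shared ? m.th0 : c[k++];
    m.th1p = c[k++];
    m.th2p = m.useq ? c[k++] : 0.0;
  }

  // ---- delta / gamma (conjugate, M2 only) ---------------------------------
  void update_delta_gamma() {
    if (m.m1) return;
    int K = m.useq ? 2 : 1;
    std::vector<double> X, y, tau;
    double tz = 1.0 / (m.sigZ * m.sigZ);
    for (int t = 0; t < m.T; ++t) {
      if (!m.obs_wt[t]) continue;
      X.push_back(m.epsAT[t]);
      if (m.useq) X.push_back(m.epsQ[t] * m.modQ[t]);
      y.push_back(m.wt[t] - m.sWT[t]);
      tau.push_back(tz);
    }
    double c[6];
    conj_reg_draw(K, X, y, tau, m.pr.dg_mean, m.pr.dg_sd, c);
    m.delta = c[0];
    if (m.useq) m.gamma = c[1];
  }

  // ---- random-walk sites --------------------------------------------------
  void rw_step(RWSite& s, double& par, double lo, double hi, bool circular,
               std::function<double(double)> logdens, std::function<void()> on_accept) {
    double cur = par;
    double prop = cur + R::norm_rand() * s.scale;
    if (circular) {
      double span = hi - lo;
      double u = (prop - lo) / span;
      prop = lo + span * (u - std::floor(u));
      if (prop >= hi) prop = lo;   // guard the half-open interval
    } else if (prop <= lo || prop >= hi) {
      s.tries++; return;  // symmetric proposal rejected out of bounds
    }
    double lp_old = logdens(cur), lp_new = logdens(prop);
    s.tries++;
    if (mh_accept(lp_new, lp_old)) { par = prop; s.acc++; on_accept(); }
  }

  void adapt(RWSite& s) {
    if (!adapting || s.tries < 50) return;
    double rate = (double)s.acc / s.tries;
    s.scale *= std::exp(rate > 0.44 ? 0.15 : -0.15);
    s.acc = 0; s.tries = 0;
  }

  // covariate-series scalar sites
  void update_cov_scalars(bool is_q) {
    std::vector<double>& eps = is_q ? m.epsQ : m.epsAT;
    double& t0 = is_q ? m.t0Q : m.t0AT;
    double& rho = is_q ? m.rhoQ : m.rhoAT;
    double& sig = is_q ? m.sigQ : m.sigAT;
    RWSite& st0 = is_q ? rw_t0Q : rw_t0AT;
    RWSite& srho = is_q ? rw_rhoQ : rw_rhoAT;
    RWSite& ssig = is_q ? rw_sigQ : rw_sigAT;
    double sig_pr = is_q ? m.pr.sig_q_sd : m.pr.sig_at_sd;

    // t0: epsilon vector changes everywhere; scratch evaluation
    std::vector<double> scratch(m.T);
    std::vector<double> snbuf(m.T);
    auto ll_t0 = [&](double t0x) {
      const std::vector<double>& val = is_q ? m.q : m.at;
      const std::vector<double>& a = is_q ? m.aQ : m.aAT;
      const std::vector<double>& b = is_q ? m.bQ : m.bAT;
      m.sin_for_t0(t0x, snbuf);
      for (int t = 0; t < m.T; ++t) {
        scratch[t] = val[t] - (a[m.win[t]] + b[m.win[t]] * snbuf[t]);
      }
      double ll = m.ll_ar1(scratch, rho, sig);
      if (!m.m1) {   // delta/gamma path sees the residuals
        double isig = 1.0 / m.sigZ, ss = 0.0;
        int cnt = 0;
        for (int t = 0; t < m.T; ++t) {
          if (!m.obs_wt[t]) continue;
          double mu = m.sWT[t] + (is_q ? m.delta * m.epsAT[t] + m.gamma * scratch[t] * m.modQ[t]
                                       : m.delta * scratch[t] +
                                         (m.useq ? m.gamma * m.epsQ[t] * m.modQ[t] : 0.0));
          double z = (m.wt[t] - mu) * isig;
          ss += z * z; ++cnt;
        }
        ll += -cnt * (0.918938533204672742 + std::log(m.sigZ)) - 0.5 * ss;
      }
      return ll;
    };
    rw_step(st0, t0, m.pr.t0_lo, m.pr.t0_hi, true, ll_t0, [&]() {
      if (is_q) m.recompute_q(); else m.recompute_at();
    });
    adapt(st0);

    auto ll_rho = [&](double r) { return m.ll_ar1(eps, r, sig); };
    rw_step(srho, rho, m.pr.rho_lo, m.pr.rho_hi, false, ll_rho, []() {});
    adapt(srho);

    // sigma: random walk on log scale with Jacobian, half-normal prior
    double lsig = std::log(sig);
    auto ll_lsig = [&](double lx) {
      double sx = std::exp(lx);
      return m.ll_ar1(eps, rho, sx) - 0.5 * sx * sx / (sig_pr * sig_pr) + lx;
    };
    rw_step(ssig, lsig, R_NegInf, R_PosInf, false, ll_lsig, []() {});
    sig = std::exp(lsig);
    adapt(ssig);
  }

  // Joint "phase slide": shift every series' phase by one common amount and
  // shear every window mean (and both WT extrema) by the exact change in the
  // window-averaged sinusoid, so the windowwise mean signal is preserved. The
  // individual phases, window means and extrema ride a narrow joint ridge;
  // this move walks along it. The shear map has unit Jacobian (the location
  // shifts depend only on the amplitudes and phases), so plain Metropolis
  // with the joint density ratio is valid.
  void update_phase_slide() {
    double d = R::norm_rand() * rw_slide.scale;
    double span = m.pr.t0_hi - m.pr.t0_lo;
    auto wrap = [&](double x) {
      double u = (x - m.pr.t0_lo) / span;
      double r = m.pr.t0_lo + span * (u - std::floor(u));
      return r >= m.pr.t0_hi ? m.pr.t0_lo : r;
    };
    double t0a = wrap(m.t0AT + d), t0q = wrap(m.t0Q + d), t0w = wrap(m.t0WT + d);

    // proposed sheared locations
    std::vector<double> aAT2(m.W), aQ2(m.W), maxWT2(m.W), minWT2(m.W);
    for (int w = 0; w < m.W; ++w) {
      aAT2[w] = m.aAT[w] - m.bAT[w] * (m.win_avg_sin(w, t0a) - m.win_avg_sin(w, m.t0AT));
      if (m.useq)
        aQ2[w] = m.aQ[w] - m.bQ[w] * (m.win_avg_sin(w, t0q) - m.win_avg_sin(w, m.t0Q));
      double bWT = 0.5 * (m.maxWT[w] - m.minWT[w]);
      double dA = bWT * (m.win_avg_sin(w, t0w) - m.win_avg_sin(w, m.t0WT));
      maxWT2[w] = m.maxWT[w] - dA;
      minWT2[w] = m.minWT[w] - dA;
    }

    std::vector<double> snAT(m.T), snQ(m.T), snW(m.T);
    auto joint_ll = [&](double ta, double tq, double tw,
                        const std::vector<double>& aA, const std::vector<double>& aQv,
                        const std::vector<double>& mx, const std::vector<double>& mn) {
      double ll = 0.0;
      m.sin_for_t0(ta, snAT);
      if (m.useq) m.sin_for_t0(tq, snQ);
      m.sin_for_t0(tw, snW);
      {
        double isig = 1.0 / m.sigAT, ss = 0.0, prev = 0.0;
        for (int t = 0; t < m.T; ++t) {
          double e = m.at[t] - (aA[m.win[t]] + m.bAT[m.win[t]] * snAT[t]);
          if (t == 0) ss += e * e * isig * isig * (1 - m.rhoAT * m.rhoAT);
          else { double z = (e - m.rhoAT * prev) * isig; ss += z * z; }
          prev = e;
        }
        ll += -0.5 * ss;
      }
      if (m.useq) {
        double isig = 1.0 / m.sigQ, ss = 0.0, prev = 0.0;
        for (int t = 0; t < m.T; ++t) {
          double e = m.q[t] - (aQv[m.win[t]] + m.bQ[m.win[t]] * snQ[t]);
          if (t == 0) ss += e * e * isig * isig * (1 - m.rhoQ * m.rhoQ);
          else { double z = (e - m.rhoQ * prev) * isig; ss += z * z; }
          prev = e;
        }
        ll += -0.5 * ss;
      }
      if (m.m1) {
        double isig = 1.0 / m.sigWT, ss = 0.0, prev = 0.0;
        for (int t = 0; t < m.T; ++t) {
          double sw = 0.5 * (1 + snW[t]) * mx[m.win[t]] + 0.5 * (1 - snW[t]) * mn[m.win[t]];
          double e = m.wt[t] - sw;
          if (t == 0) ss += e * e * isig * isig * (1 - m.rhoWT * m.rhoWT);
          else { double z = (e - m.rhoWT * prev) * isig; ss += z * z; }
          prev = e;
        }
        ll += -0.5 * ss;
      } else {
        double isig = 1.0 / m.sigZ, ss = 0.0;
        for (int t = 0; t < m.T; ++t) {
          if (!m.obs_wt[t]) continue;
          double sw = 0.5 * (1 + snW[t]) * mx[m.win[t]] + 0.5 * (1 - snW[t]) * mn[m.win[t]];
          double eA = m.at[t] - (aA[m.win[t]] + m.bAT[m.win[t]] * snAT[t]);
          double mu = sw + m.delta * eA;
          if (m.useq) {
            double eQ = m.q[t] - (aQv[m.win[t]] + m.bQ[m.win[t]] * snQ[t]);
            mu += m.gamma * eQ * (-snW[t]);
          }
          double z = (m.wt[t] - mu) * isig;
          ss += z * z;
        }
        ll += -0.5 * ss;
      }
      // extrema regression rows and window-mean priors move with the shear
      double tmax = 1.0 / (m.sigMax * m.sigMax), tmin = 1.0 / (m.sigMin * m.sigMin);
      for (int w = 0; w < m.W; ++w) {
        double mxAT = aA[w] + m.bAT[w], mnAT = aA[w] - m.bAT[w];
        double mumax = m.th0 + m.th1 * mxAT;
        double mumin = (m.shared ? m.th0 : m.th0p) + m.th1p * mnAT;
        if (m.useq) {
          mumax += m.th2 * (aQv[w] - m.bQ[w]);
          mumin += m.th2p * (aQv[w] + m.bQ[w]);
        }
        double zx = mx[w] - mumax, zn = mn[w] - mumin;
        ll += -0.5 * (zx * zx * tmax + zn * zn * tmin);
        double za = (aA[w] - m.pr.alpha_at_mean[w]) / m.pr.alpha_at_sd;
        ll += -0.5 * za * za;
        if (m.useq) {
          double zq = (aQv[w] - m.pr.alpha_q_mean[w]) / m.pr.alpha_q_sd;
          ll += -0.5 * zq * zq;
        }
      }
      return ll;
    };
    double lp_old = joint_ll(m.t0AT, m.t0Q, m.t0WT, m.aAT, m.aQ, m.maxWT, m.minWT);
    double lp_new = joint_ll(t0a, t0q, t0w, aAT2, m.useq ? aQ2 : m.aQ, maxWT2, minWT2);
    rw_slide.tries++;
    if (mh_accept(lp_new, lp_old)) {
      m.t0AT = t0a; if (m.useq) { m.t0Q = t0q; m.aQ = aQ2; }
      m.t0WT = t0w; m.aAT = aAT2; m.maxWT = maxWT2; m.minWT = minWT2;
      m.recompute_at(); m.recompute_q(); m.recompute_wt_geom();
      rw_slide.acc++;
    }
    adapt(rw_slide);
  }

  void update_wt_scalars() {
    // t0WT: changes sinWT, modQ, sWT
    std::vector<double> snw(m.T), sw(m.T);
    auto ll_t0wt = [&](double t0x) {
      m.sin_for_t0(t0x, snw);
      for (int t = 0; t < m.T; ++t) {
        sw[t] = 0.5 * (1 + snw[t]) * m.maxWT[m.win[t]] + 0.5 * (1 - snw[t]) * m.minWT[m.win[t]];
      }
      if (m.m1) {
        double isig = 1.0 / m.sigWT, ss = 0.0;
        double z0 = (m.wt[0] - sw[0]) * isig;
        ss += z0 * z0 * (1 - m.rhoWT * m.rhoWT);
        for (int t = 1; t < m.T; ++t) {
          double z = ((m.wt[t] - sw[t]) - m.rhoWT * (m.wt[t - 1] - sw[t - 1])) * isig;
          ss += z * z;
        }
        return -m.T * (0.918938533204672742 + std::log(m.sigWT)) +
               0.5 * std::log(1 - m.rhoWT * m.rhoWT) - 0.5 * ss;
      }
      double isig = 1.0 / m.sigZ, ss = 0.0;
      int cnt = 0;
      for (int t = 0; t < m.T; ++t) {
        if (!m.obs_wt[t]) continue;
        double mu = sw[t] + m.delta * m.epsAT[t];
        if (m.useq) mu += m.gamma * m.epsQ[t] * (-snw[t]);
        double z = (m.wt[t] - mu) * isig;
        ss += z * z; ++cnt;
      }
      return -cnt * (0.918938533204672742 + std::log(m.sigZ)) - 0.5 * ss;
    };
    rw_step(rw_t0WT, m.t0WT, m.pr.t0_lo, m.pr.t0_hi, true, ll_t0wt,
            [&]() { m.recompute_wt_geom(); });
    adapt(rw_t0WT);

    if (m.m1) {
      auto ll_rho = [&](double r) {
        double sv = m.rhoWT; m.rhoWT = r;
        double ll = m.ll_wt_m1_range(0, m.T - 1);
        m.rhoWT = sv;
        return ll;
      };
      rw_step(rw_rhoWT, m.rhoWT, m.pr.rho_lo, m.pr.rho_hi, false, ll_rho, []() {});
      adapt(rw_rhoWT);
      double lsig = std::log(m.sigWT);
      auto ll_lsig = [&](double lx) {
        double sv = m.sigWT; m.sigWT = std::exp(lx);
        double ll = m.ll_wt_m1_range(0, m.T - 1);
        m.sigWT = sv;
        double sx = std::exp(lx);
        return ll - 0.5 * sx * sx / (m.pr.sig_wt_sd * m.pr.sig_wt_sd) + lx;
      };
      rw_step(rw_sigWT, lsig, R_NegInf, R_PosInf, false, ll_lsig, []() {});
      m.sigWT = std::exp(lsig);
      adapt(rw_sigWT);
    } else {
      double lsig = std::log(m.sigZ);
      auto ll_lsig = [&](double lx) {
        double sv = m.sigZ; m.sigZ = std::exp(lx);
        double ll = m.ll_wt_m2(0, m.T - 1);
        m.sigZ = sv;
        double sx = std::exp(lx);
        return ll - 0.5 * sx * sx / (m.pr.sig_z_sd * m.pr.sig_z_sd) + lx;
      };
      rw_step(rw_sigZ, lsig, R_NegInf, R_PosInf, false, ll_lsig, []() {});
      m.sigZ = std::exp(lsig);
      adapt(rw_sigZ);
    }

    // sigma_max / sigma_min
    double lsx = std::log(m.sigMax);
    auto ll_lsx = [&](double lx) {
      double sx = std::exp(lx), ll = 0.0;
      for (int w = 0; w < m.W; ++w) ll += Model::ldnorm(m.maxWT[w], m.eq2_mu_max(w), sx);
      return ll - 0.5 * sx * sx / (m.pr.sig_max_sd * m.pr.sig_max_sd) + lx;
    };
    rw_step(rw_sigMax, lsx, R_NegInf, R_PosInf, false, ll_lsx, []() {});
    m.sigMax = std::exp(lsx);
    adapt(rw_sigMax);

    double lsn = std::log(m.sigMin);
    auto ll_lsn = [&](double lx) {
      double sx = std::exp(lx), ll = 0.0;
      for (int w = 0; w < m.W; ++w) ll += Model::ldnorm(m.minWT[w], m.eq2_mu_min(w), sx);
      return ll - 0.5 * sx * sx / (m.pr.sig_min_sd * m.pr.sig_min_sd) + lx;
    };
    rw_step(rw_sigMin, lsn, R_NegInf, R_PosInf, false, ll_lsn, []() {});
    m.sigMin = std::exp(lsn);
    adapt(rw_sigMin);
  }

  void sweep() {
    update_latent_at();
    update_latent_q();
    update_cov_windows(false);
    if (m.useq) update_cov_windows(true);
    update_wt_extrema();
    update_theta();
    update_delta_gamma();
    // the phase/scale scalars are the slowest movers; several cheap
    // Metropolis passes per sweep improve their mixing substantially
    for (int r = 0; r < 5; ++r) {
      update_cov_scalars(false);
      if (m.useq) update_cov_scalars(true);
      update_phase_slide();
      update_phase_slide();
      update_phase_slide();
      update_wt_scalars();
      update_wt_extrema();
    }
    update_latent_wt();
  }
};

// ---------------------------------------------------------------------------

static std::vector<double> as_vec(NumericVector v) {
  return std::vector<double>(v.begin(), v.end());
}
static std::vector<int> as_ivec(IntegerVector v) {
  return std::vector<int>(v.begin(), v.end());
}

// [[Rcpp::export(name = ".stm_run_chain")]]
List stm_run_chain(List data, List state, List priors, List config,
                   int n_burn, int n_keep, int thin) {
  Sampler S;
  Model& m = S.m;
  m.T = as<int>(data["T"]); m.W = as<int>(data["W"]);
  m.win = as_ivec(data["win"]);      // 1-based from R
  for (int& w : m.win) w -= 1;
  m.winlo = as_ivec(data["winlo"]); for (int& v : m.winlo) v -= 1;
  m.winhi = as_ivec(data["winhi"]); for (int& v : m.winhi) v -= 1;
  m.doy = as_vec(data["doy"]); m.nyr = as_vec(data["nyr"]);
  m.wt = as_vec(data["wt"]); m.at = as_vec(data["at"]);
  m.obs_wt = as_ivec(data["obs_wt"]); m.obs_at = as_ivec(data["obs_at"]);
  m.useq = as<bool>(config["use_discharge"]);
  m.m1 = as<bool>(config["m1"]);
  m.shared = as<bool>(config["shared_intercept"]);
  if (m.useq) { m.q = as_vec(data["q"]); m.obs_q = as_ivec(data["obs_q"]); }
  else { m.q.assign(m.T, 0.0); m.obs_q.assign(m.T, 1); }
  for (int t = 0; t < m.T; ++t) {
    if (!m.obs_wt[t]) m.mis_wt.push_back(t);
    if (!m.obs_at[t]) m.mis_at.push_back(t);
    if (m.useq && !m.obs_q[t]) m.mis_q.push_back(t);
  }

  // initial state (latent values already filled into wt/at/q by the caller)
  m.aAT = as_vec(state["alpha_at"]); m.bAT = as_vec(state["beta_at"]);
  m.t0AT = as<double>(state["t0_at"]); m.rhoAT = as<double>(state["rho_at"]);
  m.sigAT = as<double>(state["sigma_at"]);
  if (m.useq) {
    m.aQ = as_vec(state["alpha_q"]); m.bQ = as_vec(state["beta_q"]);
    m.t0Q = as<double>(state["t0_q"]); m.rhoQ = as<double>(state["rho_q"]);
    m.sigQ = as<double>(state["sigma_q"]);
  } else { m.aQ.assign(m.W, 0.0); m.bQ.assign(m.W, 0.0); m.t0Q = 0; m.rhoQ = 0; m.sigQ = 1; }
  m.maxWT = as_vec(state["max_wt"]); m.minWT = as_vec(state["min_wt"]);
  m.t0WT = as<double>(state["t0_wt"]);
  m.th0 = as<double>(state["theta0"]); m.th1 = as<double>(state["theta1"]);
  m.th2 = as<double>(state["theta2"]);
  m.th0p = as<double>(state["theta0p"]); m.th1p = as<double>(state["theta1p"]);
  m.th2p = as<double>(state["theta2p"]);
  m.sigMax = as<double>(state["sigma_max"]); m.sigMin = as<double>(state["sigma_min"]);
  if (m.m1) {
    m.rhoWT = as<double>(state["rho_wt"]); m.sigWT = as<double>(state["sigma_wt"]);
    m.delta = 0; m.gamma = 0; m.sigZ = 1;
  } else {
    m.delta = as<double>(state["delta"]);
    m.gamma = m.useq ? as<double>(state["gamma"]) : 0.0;
    m.sigZ = as<double>(state["sigma_zeta"]);
    m.rhoWT = 0; m.sigWT = 1;
  }

  Priors& pr = m.pr;
  pr.theta_mean = as<double>(priors["theta_mean"]); pr.theta_sd = as<double>(priors["theta_sd"]);
  pr.dg_mean = as<double>(priors["dg_mean"]); pr.dg_sd = as<double>(priors["dg_sd"]);
  pr.rho_lo = as<double>(priors["rho_lo"]); pr.rho_hi = as<double>(priors["rho_hi"]);
  pr.t0_lo = as<double>(priors["t0_lo"]); pr.t0_hi = as<double>(priors["t0_hi"]);
  pr.alpha_at_mean = as_vec(priors["alpha_at_mean"]);
  pr.alpha_at_sd = as<double>(priors["alpha_at_sd"]);
  pr.beta_at_sd = as<double>(priors["beta_at_sd"]);
  pr.alpha_q_mean = m.useq ? as_vec(priors["alpha_q_mean"]) : std::vector<double>(m.W, 0.0);
  pr.alpha_q_sd = m.useq ? as<double>(priors["alpha_q_sd"]) : 1.0;
  pr.beta_q_sd = m.useq ? as<double>(priors["beta_q_sd"]) : 1.0;
  pr.sig_at_sd = as<double>(priors["sigma_at_sd"]);
  pr.sig_q_sd = m.useq ? as<double>(priors["sigma_q_sd"]) : 1.0;
  pr.sig_z_sd = as<double>(priors["sigma_zeta_sd"]);
  pr.sig_max_sd = as<double>(priors["sigma_max_sd"]);
  pr.sig_min_sd = as<double>(priors["sigma_min_sd"]);
  pr.sig_wt_sd = as<double>(priors["sigma_wt_sd"]);

  m.sinAT.resize(m.T); m.sAT.resize(m.T); m.epsAT.resize(m.T);
  m.sinQ.resize(m.T); m.sQ.resize(m.T); m.epsQ.assign(m.T, 0.0);
  m.sinWT.resize(m.T); m.modQ.resize(m.T); m.sWT.resize(m.T);
  m.init_trig();
  m.recompute_at(); m.recompute_q(); m.recompute_wt_geom();

  // column layout must match layout_par_names() on the R side
  int P = 2 * m.W + 3 + (m.useq ? 2 * m.W + 3 : 0) + 2 * m.W + 1 +
          2 + (m.useq ? 1 : 0) + (m.shared ? 0 : 1) + 1 + (m.useq ? 1 : 0) + 2 +
          (m.m1 ? 2 : (m.useq ? 3 : 2));
  NumericMatrix draws(n_keep, P);
  NumericMatrix lat_wt(n_keep, (int)m.mis_wt.size());
  NumericMatrix lat_at(n_keep, (int)m.mis_at.size());
  NumericMatrix lat_q(n_keep, (int)m.mis_q.size());

  GetRNGstate();
  S.adapting = true;
  for (int it = 0; it < n_burn; ++it) S.sweep();
  S.adapting = false;
  for (int k = 0; k < n_keep; ++k) {
    for (int j = 0; j < thin; ++j) S.sweep();
    int c = 0;
    for (int w = 0; w < m.W; ++w) draws(k, c++) = m.aAT[w];
    for (int w = 0; w < m.W; ++w) draws(k, c++) = m.bAT[w];
    draws(k, c++) = m.t0AT; draws(k, c++) = m.rhoAT; draws(k, c++) = m.sigAT;
    if (m.useq) {
      for (int w = 0; w < m.W; ++w) draws(k, c++) = m.aQ[w];
      for (int w = 0; w < m.W; ++w) draws(k, c++) = m.bQ[w];
      draws(k, c++) = m.t0Q; draws(k, c++) = m.rhoQ; draws(k, c++) = m.sigQ;
    }
    for (int w = 0; w < m.W; ++w) draws(k, c++) = m.maxWT[w];
    for (int w = 0; w < m.W; ++w) draws(k, c++) = m.minWT[w];
    draws(k, c++) = m.t0WT;
    draws(k, c++) = m.th0; draws(k, c++) = m.th1;
    if (m.useq) draws(k, c++) = m.th2;
    if (!m.shared) draws(k, c++) = m.th0p;
    draws(k, c++) = m.th1p;
    if (m.useq) draws(k, c++) = m.th2p;
    draws(k, c++) = m.sigMax; draws(k, c++) = m.sigMin;
    if (m.m1) { draws(k, c++) = m.rhoWT; draws(k, c++) = m.sigWT; }
    else {
      draws(k, c++) = m.delta;
      if (m.useq) draws(k, c++) = m.gamma;
      draws(k, c++) = m.sigZ;
    }
    for (size_t j = 0; j < m.mis_wt.size(); ++j) lat_wt(k, j) = m.wt[m.mis_wt[j]];
    for (size_t j = 0; j < m.mis_at.size(); ++j) lat_at(k, j) = m.at[m.mis_at[j]];
    for (size_t j = 0; j < m.mis_q.size(); ++j) lat_q(k, j) = m.q[m.mis_q[j]];
  }
  PutRNGstate();

  return List::create(
    _["draws"] = draws, _["lat_wt"] = lat_wt, _["lat_at"] = lat_at, _["lat_q"] = lat_q,
    _["mis_wt"] = wrap(m.mis_wt), _["mis_at"] = wrap(m.mis_at), _["mis_q"] = wrap(m.mis_q));
}
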