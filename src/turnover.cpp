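// Turn-over (indirect response) model of MAP and HR under propofol /
// remifentanil drive and transient noxious-stimulus input.
//
// State:   dMAP/dt = kin_MAP * (1 - f(Cp_propo)) * (1 - gMAP(Cp_remi)) *
//                    p(HR) * h(Stim) - kout_MAP * MAP
//          dHR/dt  = kin_HR  * (1 - gHR(Cp_remi)) * q(MAP) - kout_HR * HR
// with kin_i = kout_i * baseline_i, p(HR) = (HR/HR0)^FB_HR,
// q(MAP) = (MAP/MAP0)^(-FB_MAP), h(Stim) = prod_e (1 + theta * exp(-k (t - t_e)))
// for t > t_e (1 otherwise).  The final model has gMAP = 0, FB_MAP = 0,
// gamma_propo = 1; neutral parameter values take literally the same code
// path as the final-model preset so the reduction is bit-for-bit exact.
//
// Parameter vector layout (shared with R/turnover.R):
//  0 map0  1 hr0  2 kout_map  3 kout_hr
//  4 c50p  5 emaxp  6 gammap
//  7 c50r_hr  8 emaxr_hr  9 gammar_hr
// 10 c50r_map 11 emaxr_map 12 gammar_map
// 13 fb_hr 14 fb_map 15 theta_stim 16 k_stim

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double hill(double c, double emax, double c50, double gamma) {
  if (c <= 0.0 || emax == 0.0) return 0.0;
  if (gamma == 1.0) return emax * c / (c + c50);
  double cg = std::pow(c, gamma), kg = std::pow(c50, gamma);
  return emax * cg / (cg + kg);
}

static inline double stim_factor(double t, const arma::vec& onsets,
                                 double theta, double k) {
  double h = 1.0;
  for (arma::uword i = 0; i < onsets.n_elem; ++i) {
    // the factor peaks at 1 + theta at the onset itself
    if (t >= onsets[i]) h *= 1.0 + theta * std::exp(-k * (t - onsets[i]));
  }
  return h;
}

struct TOPars {
  double map0, hr0, kout_map, kout_hr;
  double c50p, emaxp, gammap;
  double c50r_hr, emaxr_hr, gammar_hr;
  double c50r_map, emaxr_map, gammar_map;
  double fb_hr, fb_map, theta_stim, k_stim;
  double kin_map, kin_hr;
  void load(const double* p) {
    map0 = p[0]; hr0 = p[1]; kout_map = p[2]; kout_hr = p[3];
    c50p = p[4]; emaxp = p[5]; gammap = p[6];
    c50r_hr = p[7]; emaxr_hr = p[8]; gammar_hr = p[9];
    c50r_map = p[10]; emaxr_map = p[11]; gammar_map = p[12];
    fb_hr = p[13]; fb_map = p[14]; theta_stim = p[15]; k_stim = p[16];
    kin_map = kout_map * map0;
    kin_hr  = kout_hr * hr0;
  }
};

// RK4 with nsub substeps per grid interval; concentrations interpolated
// linearly between grid nodes; stimulus factor evaluated analytically.
// [[Rcpp::export]]
arma::mat sim_turnover_rk4(const arma::vec& times, const arma::vec& cp_propo,
                           const arma::vec& cp_remi, const arma::vec& stim_onsets,
                           const arma::vec& pars, int nsub = 4) {
  const arma::uword n = times.n_elem;
  TOPars P; P.load(pars.memptr());
  arma::mat out(n, 2);
  double MAP = P.map0, HR = P.hr0;
  out(0, 0) = MAP; out(0, 1) = HR;

  // Stimulus activity is decided at the start of each (sub)step so the
  // onset discontinuity coincides with a step boundary and each RK4 step
  // integrates a smooth right-hand side.
  auto deriv = [&](double t, double t_anchor, double cp, double cr,
                   double MAPv, double HRv, double& dMAP, double& dHR) {
    double f  = hill(cp, P.emaxp, P.c50p, P.gammap);
    double gh = hill(cr, P.emaxr_hr, P.c50r_hr, P.gammar_hr);
    double gm = (P.emaxr_map == 0.0) ? 0.0
                : hill(cr, P.emaxr_map, P.c50r_map, P.gammar_map);
    double p  = (P.fb_hr == 0.0) ? 1.0 : std::pow(HRv / P.hr0, P.fb_hr);
    double q  = (P.fb_map == 0.0) ? 1.0 : std::pow(MAPv / P.map0, -P.fb_map);
    double h = 1.0;
    if (P.theta_stim != 0.0) {
      for (arma::uword e = 0; e < stim_onsets.n_elem; ++e) {
        if (stim_onsets[e] <= t_anchor + 1e-12)
          h *= 1.0 + P.theta_stim *
               std::exp(-P.k_stim * (t - stim_onsets[e]));
      }
    }
    dMAP = P.kin_map * (1.0 - f) * (1.0 - gm) * p * h - P.kout_map * MAPv;
    dHR  = P.kin_hr * (1.0 - gh) * q - P.kout_hr * HRv;
  };

  for (arma::uword i = 0; i + 1 < n; ++i) {
    double t0 = times[i], t1 = times[i + 1];
    double hstep = (t1 - t0) / nsub;
    double c0p = cp_propo[i], c1p = cp_propo[i + 1];
    double c0r = cp_remi[i],  c1r = cp_remi[i + 1];
    for (int s = 0; s < nsub; ++s) {
      double ta = t0 + s * hstep;
      double frac_a = (ta - t0) / (t1 - t0);
      double frac_m = (ta + hstep / 2.0 - t0) / (t1 - t0);
      double frac_b = (ta + hstep - t0) / (t1 - t0);
      double cpa = c0p + frac_a * (c1p - c0p), cra = c0r + frac_a * (c1r - c0r);
      double cpm = c0p + frac_m * (c1p - c0p), crm = c0r + frac_m * (c1r - c0r);
      double cpb = c0p + frac_b * (c1p - c0p), crb = c0r + frac_b * (c1r - c0r);
      double k1m, k1h, k2m, k2h, k3m, k3h, k4m, k4h;
      deriv(ta, ta, cpa, cra, MAP, HR, k1m, k1h);
      deriv(ta + hstep / 2.0, ta, cpm, crm, MAP + hstep / 2.0 * k1m,
            HR + hstep / 2.0 * k1h, k2m, k2h);
      deriv(ta + hstep / 2.0, ta, cpm, crm, MAP + hstep / 2.0 * k2m,
            HR + hstep / 2.0 * k2h, k3m, k3h);
      deriv(ta + hstep, ta, cpb, crb, MAP + hstep * k3m, HR + hstep * k3h,
            k4m, k4h);
      MAP += hstep / 6.0 * (k1m + 2.0 * k2m + 2.0 * k3m + k4m);
      HR  += hstep / 6.0 * (k1h + 2.0 * k2h + 2.0 * k3h + k4h);
    }
    if (!std::isfinite(MAP) || !std::isfinite(HR))
      stop("integration failure: non-finite state at t = %f", t1);
    out(i + 1, 0) = MAP; out(i + 1, 1) = HR;
  }
  return out;
}

// Fast final-model path: with FB_MAP = 0 the HR equation is autonomous and
// both equations are linear first-order ODEs driven by a source that is
// evaluated at the grid nodes and treated as piecewise linear.  Exact
// exponential-integrator step:
//   X(t0+h) = X e^{-k h} + s0 (1-e^{-kh})/k + m (h - (1-e^{-kh})/k)/k
// where s(t) = s0 + m (t - t0).  Used inside the estimation core.
// [[Rcpp::export]]
arma::mat sim_turnover_final(const arma::vec& times, const arma::vec& cp_propo,
                             const arma::vec& cp_remi, const arma::vec& stim_onsets,
                             const arma::vec& pars) {
  const arma::uword n = times.n_elem;
  TOPars P; P.load(pars.memptr());
  const double h = times[1] - times[0];

  // HR first: source kin_hr * (1 - gHR(Cr))
  arma::vec sHR(n), HR(n);
  for (arma::uword i = 0; i < n; ++i)
    sHR[i] = P.kin_hr * (1.0 - hill(cp_remi[i], P.emaxr_hr, P.c50r_hr, P.gammar_hr));
  {
    const double k = P.kout_hr;
    const double E = std::exp(-k * h), A = (1.0 - E) / k;
    HR[0] = P.hr0;
    for (arma::uword i = 0; i + 1 < n; ++i) {
      double m = (sHR[i + 1] - sHR[i]) / h;
      HR[i + 1] = HR[i] * E + sHR[i] * A + m * (h - A) / k;
    }
  }
  // MAP: source kin_map * (1 - f(Cp)) * p(HR) * h(Stim); the stimulus
  // activity is anchored at the interval start (as in the RK4 path) so
  // the onset jump falls on a step boundary instead of being smeared.
  arma::vec sMAP(n), MAP(n);
  for (arma::uword i = 0; i < n; ++i) {
    double f = hill(cp_propo[i], P.emaxp, P.c50p, P.gammap);
    double gm = (P.emaxr_map == 0.0) ? 0.0
                : hill(cp_remi[i], P.emaxr_map, P.c50r_map, P.gammar_map);
    double p = (P.fb_hr == 0.0) ? 1.0 : std::pow(HR[i] / P.hr0, P.fb_hr);
    sMAP[i] = P.kin_map * (1.0 - f) * (1.0 - gm) * p;
  }
  auto stimf = [&](double t, double anchor) {
    double hh = 1.0;
    if (P.theta_stim != 0.0) {
      for (arma::uword e = 0; e < stim_onsets.n_elem; ++e)
        if (stim_onsets[e] <= anchor + 1e-12)
          hh *= 1.0 + P.theta_stim * std::exp(-P.k_stim * (t - stim_onsets[e]));
    }
    return hh;
  };
  {
    const double k = P.kout_map;
    const double E = std::exp(-k * h), A = (1.0 - E) / k;
    MAP[0] = P.map0;
    for (arma::uword i = 0; i + 1 < n; ++i) {
      double sL = sMAP[i] * stimf(times[i], times[i]);
      double sR = sMAP[i + 1] * stimf(times[i + 1], times[i]);
      double m = (sR - sL) / h;
      MAP[i + 1] = MAP[i] * E + sL * A + m * (h - A) / k;
    }
  }
  arma::mat out(n, 2);
  out.col(0) = MAP; out.col(1) = HR;
  return out;
}
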