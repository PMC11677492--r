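// Estimation core: per-subject penalized (MAP-Bayes) fits of the random
// effects by Gauss-Newton with a finite-difference Jacobian, and the
// Laplace approximation to the population marginal -2 log-likelihood
// evaluated at the per-subject mode with a Gauss-Newton Hessian.
//
// Random-effect vector eta (length 7), all multiplicative log-normal:
//  0 C50_propo  1 C50_remi  2 MAP0  3 HR0  4 kout_MAP  5 kout_HR  6 k_stim

#include <RcppArmadillo.h>
using namespace Rcpp;

arma::mat sim_turnover_final(const arma::vec& times, const arma::vec& cp_propo,
                             const arma::vec& cp_remi, const arma::vec& stim_onsets,
                             const arma::vec& pars);

struct Subj {
  arma::vec times, cpp, cpr, stim;
  arma::uvec i_map, i_hr;
  arma::vec y_map, y_hr;
};

static Subj parse_subj(const List& s) {
  Subj d;
  d.times = as<arma::vec>(s["times"]);
  d.cpp   = as<arma::vec>(s["cp_propo"]);
  d.cpr   = as<arma::vec>(s["cp_remi"]);
  d.stim  = as<arma::vec>(s["stim"]);
  d.i_map = as<arma::uvec>(s["i_map"]);
  d.y_map = as<arma::vec>(s["y_map"]);
  d.i_hr  = as<arma::uvec>(s["i_hr"]);
  d.y_hr  = as<arma::vec>(s["y_hr"]);
  return d;
}

static arma::vec apply_eta(const arma::vec& typ, const arma::vec& eta) {
  arma::vec p = typ;
  p[4]  *= std::exp(eta[0]);   // c50p
  p[7]  *= std::exp(eta[1]);   // c50r_hr
  p[0]  *= std::exp(eta[2]);   // map0
  p[1]  *= std::exp(eta[3]);   // hr0
  p[2]  *= std::exp(eta[4]);   // kout_map
  p[3]  *= std::exp(eta[5]);   // kout_hr
  p[16] *= std::exp(eta[6]);   // k_stim
  return p;
}

static arma::vec wres(const Subj& d, const arma::vec& typ, const arma::vec& eta,
                      double sig_map, double sig_hr) {
  arma::vec p = apply_eta(typ, eta);
  arma::mat tr = sim_turnover_final(d.times, d.cpp, d.cpr, d.stim, p);
  arma::vec r(d.i_map.n_elem + d.i_hr.n_elem);
  for (arma::uword j = 0; j < d.i_map.n_elem; ++j)
    r[j] = (d.y_map[j] - tr(d.i_map[j], 0)) / sig_map;
  for (arma::uword j = 0; j < d.i_hr.n_elem; ++j)
    r[d.i_map.n_elem + j] = (d.y_hr[j] - tr(d.i_hr[j], 1)) / sig_hr;
  return r;
}

// Penalized Gauss-Newton on eta.  Returns the mode, the objective
// F = r'r + eta' Oi eta at the mode, and log|J'J + Oi| for the Laplace term.
static void gn_fit(const Subj& d, const arma::vec& typ, const arma::mat& Oi,
                   double sig_map, double sig_hr, arma::vec& eta,
                   double& Fout, double& logdetH, int maxit, double tol) {
  const int q = 7;
  const double fd = 1e-4;
  arma::vec r = wres(d, typ, eta, sig_map, sig_hr);
  double F = arma::dot(r, r) + arma::as_scalar(eta.t() * Oi * eta);
  arma::mat J(r.n_elem, q);
  for (int it = 0; it < maxit; ++it) {
    for (int k = 0; k < q; ++k) {
      arma::vec e2 = eta; e2[k] += fd;
      J.col(k) = (wres(d, typ, e2, sig_map, sig_hr) - r) / fd;
    }
    arma::mat H = J.t() * J + Oi;
    arma::vec g = J.t() * r + Oi * eta;   // gradient of F/2 wrt eta (J = d r/d eta; r = y-pred scaled => grad uses -J'r; signs handled below)
    // r = (y - pred)/sigma, J = d r / d eta, so dF/2 = J'r + Oi eta
    arma::vec delta;
    bool ok = arma::solve(delta, H, -g, arma::solve_opts::likely_sympd);
    if (!ok) break;
    double step = 1.0, Fnew = F;
    arma::vec eta_new = eta, r_new = r;
    bool improved = false;
    for (int ls = 0; ls < 10; ++ls) {
      eta_new = eta + step * delta;
      r_new = wres(d, typ, eta_new, sig_map, sig_hr);
      Fnew = arma::dot(r_new, r_new) +
             arma::as_scalar(eta_new.t() * Oi * eta_new);
      if (std::isfinite(Fnew) && Fnew <= F) { improved = true; break; }
      step *= 0.5;
    }
    if (!improved) break;
    double dF = F - Fnew;
    eta = eta_new; r = r_new; F = Fnew;
    if (dF < tol * (std::abs(F) + 1.0) && arma::norm(step * delta, "inf") < 1e-5)
      break;
  }
  // final Jacobian at the mode for the Laplace Hessian
  for (int k = 0; k < q; ++k) {
    arma::vec e2 = eta; e2[k] += fd;
    J.col(k) = (wres(d, typ, e2, sig_map, sig_hr) - r) / fd;
  }
  arma::mat H = J.t() * J + Oi;
  double sign;
  arma::log_det(logdetH, sign, H);
  Fout = F;
}

// [[Rcpp::export]]
List gn_fit_eta_cpp(const List& subj, const arma::vec& typ, const arma::mat& Oi,
                    double sig_map, double sig_hr, const arma::vec& eta0,
                    int maxit = 40, double tol = 1e-10) {
  Subj d = parse_subj(subj);
  arma::vec eta = eta0;
  double F = NA_REAL, logdetH = NA_REAL;
  gn_fit(d, typ, Oi, sig_map, sig_hr, eta, F, logdetH, maxit, tol);
  return List::create(_["eta"] = eta, _["objective"] = F,
                      _["logdetH"] = logdetH);
}

// Population Laplace -2LL.  eta_warm (7 x nsubj) provides warm starts and is
// returned updated so the outer optimizer can reuse the modes.
// [[Rcpp::export]]
List pop_nll2_cpp(const arma::vec& typ, const arma::mat& Omega,
                  double sig_map, double sig_hr, const List& subjects,
                  const arma::mat& eta_warm, int maxit = 25) {
  const int q = 7;
  const int nsub = subjects.size();
  arma::mat Oi;
  bool ok = arma::inv_sympd(Oi, Omega);
  if (!ok) return List::create(_["nll2"] = 1e10, _["eta"] = eta_warm);
  double ldO, sgn;
  arma::log_det(ldO, sgn, Omega);

  arma::mat eta_out(q, nsub);
  const double l2pi = std::log(2.0 * M_PI);
  double total = 0.0;
  for (int i = 0; i < nsub; ++i) {
    Subj d = parse_subj(subjects[i]);
    arma::vec eta = eta_warm.col(i);
    double F, logdetH;
    gn_fit(d, typ, Oi, sig_map, sig_hr, eta, F, logdetH, maxit, 1e-10);
    if (!std::isfinite(F) || !std::isfinite(logdetH))
      return List::create(_["nll2"] = 1e10, _["eta"] = eta_warm);
    double nmap = (double)d.i_map.n_elem, nhr = (double)d.i_hr.n_elem;
    total += nmap * (l2pi + 2.0 * std::log(sig_map)) +
             nhr * (l2pi + 2.0 * std::log(sig_hr)) +
             F + ldO + logdetH;
    eta_out.col(i) = eta;
  }
  return List::create(_["nll2"] = total, _["eta"] = eta_out);
}
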