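// Closed-form infusion kinetics and the FOCE-I marginal-likelihood
// approximation. Micro-constant convention: k10 = CL/Vc, k12 = Q/Vc,
// k21 = Q/Vp; hybrid rate constants alpha/beta are the roots of
// l^2 - (k10+k12+k21) l + k10*k21 = 0.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Central-compartment concentration at time t (h) for a never-ending
// zero-order infusion at unit rate (1 mg/h) started at t = 0.
// A finite infusion of duration D is cin(t) - cin(t - D) by superposition.
static inline double cin(const double t, const double vc, const double k10,
                         const double k12, const double k21) {
  if (t <= 0.0) return 0.0;
  if (k12 <= 0.0 || k21 <= 0.0) {
    // one-compartment limit (Q = 0)
    return (1.0 - std::exp(-k10 * t)) / (vc * k10);
  }
  const double s = k10 + k12 + k21;
  const double disc = s * s - 4.0 * k10 * k21;  // >= 0 for positive rates
  const double sq = std::sqrt(disc > 0.0 ? disc : 0.0);
  const double a = 0.5 * (s + sq);
  const double b = 0.5 * (s - sq);
  if (a - b < 1e-9 * a) {
    // repeated-root limit: unit-bolus disposition (1/Vc)(1+(l-k21)t)e^{-lt}
    const double l = 0.5 * s;
    const double e = std::exp(-l * t);
    return ((1.0 - e) / l +
            (l - k21) * (1.0 - (1.0 + l * t) * e) / (l * l)) / vc;
  }
  const double A = (a - k21) / (vc * (a - b));
  const double B = (k21 - b) / (vc * (a - b));
  return A / a * (1.0 - std::exp(-a * t)) + B / b * (1.0 - std::exp(-b * t));
}

static void conc_events(const arma::vec& t, const arma::vec& dt,
                        const arma::vec& damt, const arma::vec& ddur,
                        const double cl, const double vc, const double q,
                        const double vp, arma::vec& out) {
  const double k10 = cl / vc;
  const double k12 = q > 0.0 ? q / vc : 0.0;
  const double k21 = (q > 0.0 && vp > 0.0) ? q / vp : 0.0;
  out.zeros();
  for (arma::uword j = 0; j < t.n_elem; ++j) {
    double c = 0.0;
    for (arma::uword e = 0; e < dt.n_elem; ++e) {
      const double rel = t[j] - dt[e];
      if (rel <= 0.0) continue;
      const double rate = damt[e] / ddur[e];
      c += rate * (cin(rel, vc, k10, k12, k21) -
                   cin(rel - ddur[e], vc, k10, k12, k21));
    }
    out[j] = c;
  }
}

// [[Rcpp::export]]
NumericVector cpp_conc(NumericVector times, NumericVector dose_time,
                       NumericVector dose_amt, NumericVector dose_dur,
                       double cl, double vc, double q, double vp) {
  arma::vec t(times.begin(), times.size(), false);
  arma::vec dt(dose_time.begin(), dose_time.size(), false);
  arma::vec da(dose_amt.begin(), dose_amt.size(), false);
  arma::vec dd(dose_dur.begin(), dose_dur.size(), false);
  arma::vec out(t.n_elem);
  conc_events(t, dt, da, dd, cl, vc, q, vp, out);
  return NumericVector(out.begin(), out.end());
}

// ---------------------------------------------------------------------------
// FOCE-I machinery

struct SubjData {
  arma::vec ot, y, dt, da, dd;  // observation times / values, dose history
  double clt, vct, q, vp;       // typical (covariate-resolved) parameters
};

static const double LOG2PI = 1.8378770664093454836;

// conditional -log joint density (up to the eta-prior normalising constant,
// which cancels in mode finding; added back in the OFV formula)
static double h_eta(const SubjData& s, const double e1, const double e2,
                    const double w1, const double w2, const double sig2,
                    arma::vec& f) {
  const double cl = s.clt * std::exp(e1);
  const double vc = s.vct * std::exp(e2);
  conc_events(s.ot, s.dt, s.da, s.dd, cl, vc, s.q, s.vp, f);
  double h = 0.0;
  for (arma::uword j = 0; j < f.n_elem; ++j) {
    const double fj = f[j] > 1e-10 ? f[j] : 1e-10;
    const double r = s.y[j] - fj;
    h += 0.5 * (std::log(sig2 * fj * fj) + LOG2PI + r * r / (sig2 * fj * fj));
  }
  if (w1 > 0.0) h += 0.5 * e1 * e1 / w1;
  if (w2 > 0.0) h += 0.5 * e2 * e2 / w2;
  return h;
}

// Newton minimisation of h over the active etas with finite-difference
// derivatives and backtracking line search; stateless start at eta = 0.
static void inner_mode(const SubjData& s, const double w1, const double w2,
                       const double sig2, double& e1, double& e2,
                       bool& ok) {
  const bool a1 = w1 > 0.0, a2 = w2 > 0.0;
  e1 = 0.0; e2 = 0.0; ok = true;
  if (!a1 && !a2) return;
  const double del = 1e-4;
  arma::vec f(s.y.n_elem);
  double h0 = h_eta(s, e1, e2, w1, w2, sig2, f);
  for (int iter = 0; iter < 60; ++iter) {
    double g1 = 0.0, g2 = 0.0, H11 = 1.0, H22 = 1.0, H12 = 0.0;
    if (a1) {
      const double hp = h_eta(s, e1 + del, e2, w1, w2, sig2, f);
      const double hm = h_eta(s, e1 - del, e2, w1, w2, sig2, f);
      g1 = (hp - hm) / (2.0 * del);
      H11 = (hp - 2.0 * h0 + hm) / (del * del);
    }
    if (a2) {
      const double hp = h_eta(s, e1, e2 + del, w1, w2, sig2, f);
      const double hm = h_eta(s, e1, e2 - del, w1, w2, sig2, f);
      g2 = (hp - hm) / (2.0 * del);
      H22 = (hp - 2.0 * h0 + hm) / (del * del);
    }
    if (a1 && a2) {
      const double hpp = h_eta(s, e1 + del, e2 + del, w1, w2, sig2, f);
      const double hpm = h_eta(s, e1 + del, e2 - del, w1, w2, sig2, f);
      const double hmp = h_eta(s, e1 - del, e2 + del, w1, w2, sig2, f);
      const double hmm = h_eta(s, e1 - del, e2 - del, w1, w2, sig2, f);
      H12 = (hpp - hpm - hmp + hmm) / (4.0 * del * del);
    }
    const double gnorm = std::max(std::fabs(g1), std::fabs(g2));
    if (gnorm < 1e-7) return;
    // regularise to positive definite
    double ridge = 0.0;
    double d1 = 0.0, d2 = 0.0;
    for (int k = 0; k < 8; ++k) {
      const double A11 = H11 + ridge, A22 = H22 + ridge;
      const double det = A11 * A22 - H12 * H12;
      if (A11 > 1e-10 && det > 1e-12) {
        if (a1 && a2) {
          d1 = -(A22 * g1 - H12 * g2) / det;
          d2 = -(A11 * g2 - H12 * g1) / det;
        } else if (a1) { d1 = -g1 / A11; }
        else { d2 = -g2 / A22; }
        break;
      }
      ridge = ridge == 0.0 ? 1.0 : ridge * 10.0;
      if (k == 7) { d1 = -g1; d2 = -g2; }  // steepest descent fallback
    }
    if (g1 * d1 + g2 * d2 >= 0.0) { d1 = -g1; d2 = -g2; }
    // backtracking line search
    double tstep = 1.0;
    bool moved = false;
    for (int ls = 0; ls < 40; ++ls) {
      const double htry = h_eta(s, e1 + tstep * d1, e2 + tstep * d2,
                                w1, w2, sig2, f);
      if (htry < h0 - 1e-13) {
        e1 += tstep * d1; e2 += tstep * d2; h0 = htry; moved = true;
        break;
      }
      tstep *= 0.5;
    }
    if (!moved) return;  // at numerical resolution of the line search
    if (std::fabs(tstep * d1) < 1e-10 && std::fabs(tstep * d2) < 1e-10)
      return;
  }
  ok = false;  // iteration cap; eta kept at best point found
}

// FOCE-I objective and (optionally) per-observation diagnostics.
// obs_ptr/dose_ptr are 0-based CSR offsets of length n_subjects + 1.
// [[Rcpp::export]]
List cpp_foce(NumericVector obs_time, NumericVector obs_y,
              IntegerVector obs_ptr, NumericVector dose_time,
              NumericVector dose_amt, NumericVector dose_dur,
              IntegerVector dose_ptr, NumericVector cl_typ,
              NumericVector vc_typ, NumericVector q_typ,
              NumericVector vp_typ, double omega2_cl, double omega2_vc,
              double sigma2, bool want_diag = false) {
  const int nsub = cl_typ.size();
  const int nobs_all = obs_time.size();
  const double w1 = omega2_cl, w2 = omega2_vc;
  double ofv = 0.0;
  int n_inner_fail = 0;
  arma::mat eta(nsub, 2, arma::fill::zeros);
  arma::vec pred, ipred, cwres;
  if (want_diag) {
    pred.set_size(nobs_all); ipred.set_size(nobs_all);
    cwres.set_size(nobs_all);
  }
  for (int i = 0; i < nsub; ++i) {
    const int o0 = obs_ptr[i], o1 = obs_ptr[i + 1];
    const int d0 = dose_ptr[i], d1 = dose_ptr[i + 1];
    const int n = o1 - o0;
    if (n == 0) continue;
    SubjData s;
    s.ot = arma::vec(&obs_time[o0], n);
    s.y = arma::vec(&obs_y[o0], n);
    s.dt = arma::vec(&dose_time[d0], d1 - d0);
    s.da = arma::vec(&dose_amt[d0], d1 - d0);
    s.dd = arma::vec(&dose_dur[d0], d1 - d0);
    s.clt = cl_typ[i]; s.vct = vc_typ[i]; s.q = q_typ[i]; s.vp = vp_typ[i];

    double e1, e2; bool ok;
    inner_mode(s, w1, w2, sigma2, e1, e2, ok);
    if (!ok) ++n_inner_fail;
    eta(i, 0) = e1; eta(i, 1) = e2;

    arma::vec fhat(n), ftmp(n);
    const double cl = s.clt * std::exp(e1), vc = s.vct * std::exp(e2);
    conc_events(s.ot, s.dt, s.da, s.dd, cl, vc, s.q, s.vp, fhat);
    for (arma::uword j = 0; j < fhat.n_elem; ++j)
      if (fhat[j] < 1e-10) fhat[j] = 1e-10;

    // linearize prediction in eta around the conditional mode
    const double del = 1e-4;
    arma::mat F(n, 2, arma::fill::zeros);
    if (w1 > 0.0) {
      conc_events(s.ot, s.dt, s.da, s.dd, s.clt * std::exp(e1 + del), vc,
                  s.q, s.vp, ftmp);
      arma::vec fp = ftmp;
      conc_events(s.ot, s.dt, s.da, s.dd, s.clt * std::exp(e1 - del), vc,
                  s.q, s.vp, ftmp);
      F.col(0) = (fp - ftmp) / (2.0 * del);
    }
    if (w2 > 0.0) {
      conc_events(s.ot, s.dt, s.da, s.dd, cl, s.vct * std::exp(e2 + del),
                  s.q, s.vp, ftmp);
      arma::vec fp = ftmp;
      conc_events(s.ot, s.dt, s.da, s.dd, cl, s.vct * std::exp(e2 - del),
                  s.q, s.vp, ftmp);
      F.col(1) = (fp - ftmp) / (2.0 * del);
    }
    arma::mat W(2, 2, arma::fill::zeros);
    W(0, 0) = w1; W(1, 1) = w2;
    arma::mat V = F * W * F.t();
    V.diag() += sigma2 * arma::square(fhat);  // interaction: R at eta-hat
    arma::vec evec(2); evec[0] = e1; evec[1] = e2;
    const arma::vec r = s.y - fhat + F * evec;
    arma::mat L;
    if (!arma::chol(L, V, "lower")) {
      V.diag() += 1e-8 * arma::max(V.diag());
      arma::chol(L, V, "lower");
    }
    const arma::vec z = arma::solve(arma::trimatl(L), r);
    ofv += 2.0 * arma::sum(arma::log(L.diag())) + arma::dot(z, z) +
           n * LOG2PI;
    if (want_diag) {
      arma::vec p0(n);
      conc_events(s.ot, s.dt, s.da, s.dd, s.clt, s.vct, s.q, s.vp, p0);
      for (int j = 0; j < n; ++j) {
        pred[o0 + j] = p0[j];
        ipred[o0 + j] = fhat[j];
        cwres[o0 + j] = z[j];
      }
    }
  }
  List out = List::create(_["ofv"] = ofv,
                          _["eta"] = wrap(eta),
                          _["n_inner_fail"] = n_inner_fail);
  if (want_diag) {
    out["pred"] = NumericVector(pred.begin(), pred.end());
    out["ipred"] = NumericVector(ipred.begin(), ipred.end());
    out["cwres"] = NumericVector(cwres.begin(), cwres.end());
  }
  return out;
}
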