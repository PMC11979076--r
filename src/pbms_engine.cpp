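// Laplace-approximate marginal -2 log-likelihood for sum-of-exponential
// population models with log-normal random effects.  Inner per-patient
// optimisation of eta uses damped Gauss-Newton steps; the Laplace
// log-determinant uses a finite-difference Hessian of the joint negative
// log density at the mode (full, not Gauss-Newton), so the objective is
// checkable against adaptive Gauss-Hermite quadrature.
#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double TWO_PI = 6.28318530717958647692;
// 131-I physical decay constant, ln(2)/T_half with T_half = 8.022 d, in 1/h.
// Single source of truth: R re-exports this value.
static const double LPHYS = 0.69314718055994530942 / (8.022 * 24.0);

// model codes: 0 a3a, 1 a3b, 2 a4a, 3 a4b, 4 a4c, 5 a5a, 6 a5b, 7 a6a, 8 a6b
// parameter order (natural scale):
//   a3a: a1, l1, l2            a3b: l1, l2, l3
//   a4a: a1, a2, l1, l2        a4b: a1, a2, l1, l2
//   a4c: a1, l1, l2, l3
//   a5a: a1, a2, l1, l2, l3    a5b: a1, a2, l1, l2, l3
//   a6a: a1, a2, a3, l1, l2, l3
//   a6b: a1, a2, a3, l1, l2, l3

inline double clamp_den(double d, int* flag) {
  if (std::fabs(d) < 1e-10) {
    if (flag) (*flag)++;
    return (d >= 0.0) ? 1e-10 : -1e-10;
  }
  return d;
}

static void soef_eval_core(int m, const double* p, const double* t, int n,
                           double* out, int* flag) {
  const double lp = LPHYS;
  switch (m) {
  case 0: // a3a
    for (int i = 0; i < n; ++i)
      out[i] = p[0] * std::exp(-(p[1] + lp) * t[i]) -
               p[0] * std::exp(-(p[2] + lp) * t[i]);
    break;
  case 1: { // a3b (EANM SOP bi-exponential)
    double A = p[0] / clamp_den(p[1] + p[0] - p[2], flag);
    for (int i = 0; i < n; ++i)
      out[i] = A * (std::exp(-(p[2] + lp) * t[i]) -
                    std::exp(-(p[0] + p[1] + lp) * t[i]));
    break;
  }
  case 2: // a4a
    for (int i = 0; i < n; ++i)
      out[i] = p[0] * std::exp(-(p[2] + lp) * t[i]) +
               p[1] * std::exp(-lp * t[i]) -
               (p[0] + p[1]) * std::exp(-(p[3] + lp) * t[i]);
    break;
  case 3: // a4b
    for (int i = 0; i < n; ++i)
      out[i] = (p[0] + p[1]) * std::exp(-lp * t[i]) -
               p[0] * std::exp(-(p[2] + lp) * t[i]) -
               p[1] * std::exp(-(p[3] + lp) * t[i]);
    break;
  case 4: { // a4c (SOP bi-exponential plus blood-pool amplitude a1)
    double A = p[1] / clamp_den(p[2] + p[1] - p[3], flag);
    for (int i = 0; i < n; ++i)
      out[i] = A * (std::exp(-(p[3] + lp) * t[i]) -
                    std::exp(-(p[1] + p[2] + lp) * t[i])) +
               p[0] * std::exp(-(p[1] + p[2] + lp) * t[i]);
    break;
  }
  case 5: // a5a
    for (int i = 0; i < n; ++i)
      out[i] = p[0] * std::exp(-(p[2] + lp) * t[i]) +
               p[1] * std::exp(-(p[3] + lp) * t[i]) -
               (p[0] + p[1]) * std::exp(-(p[4] + lp) * t[i]);
    break;
  case 6: // a5b
    for (int i = 0; i < n; ++i)
      out[i] = (p[0] + p[1]) * std::exp(-(p[2] + lp) * t[i]) -
               p[0] * std::exp(-(p[3] + lp) * t[i]) -
               p[1] * std::exp(-(p[4] + lp) * t[i]);
    break;
  case 7: // a6a
    for (int i = 0; i < n; ++i)
      out[i] = p[0] * std::exp(-(p[3] + lp) * t[i]) +
               p[1] * std::exp(-(p[4] + lp) * t[i]) +
               p[2] * std::exp(-lp * t[i]) -
               (p[0] + p[1] + p[2]) * std::exp(-(p[5] + lp) * t[i]);
    break;
  case 8: // a6b
    for (int i = 0; i < n; ++i)
      out[i] = p[0] * std::exp(-(p[3] + lp) * t[i]) +
               p[1] * std::exp(-lp * t[i]) -
               p[2] * std::exp(-(p[4] + lp) * t[i]) -
               (p[0] + p[1] - p[2]) * std::exp(-(p[5] + lp) * t[i]);
    break;
  default:
    stop("unknown model code");
  }
}

// [[Rcpp::export]]
double cpp_lambda_phys() { return LPHYS; }

// [[Rcpp::export]]
NumericVector cpp_soef_eval(int model, NumericVector params, NumericVector times) {
  int n = times.size();
  NumericVector out(n);
  int flag = 0;
  soef_eval_core(model, params.begin(), times.begin(), n, out.begin(), &flag);
  out.attr("singular") = (flag > 0);
  return out;
}

struct ErrSpec {
  int type;        // 0 additive, 1 proportional, 2 combined, 3 exponential
  double sa2, sp2; // additive / proportional variance components
  double s2;       // variance for the exponential (log-additive) model
};

inline double obs_nll(double y, double f, const ErrSpec& e) {
  if (e.type == 3) {
    double ff = (f > 1e-12) ? f : 1e-12;
    double r = std::log(y) - std::log(ff);
    return 0.5 * (std::log(TWO_PI * e.s2) + r * r / e.s2);
  }
  double v = e.sa2 + e.sp2 * f * f;
  if (v < 1e-300) v = 1e-300;
  double r = y - f;
  return 0.5 * (std::log(TWO_PI * v) + r * r / v);
}

inline double obs_dnll(double y, double f, const ErrSpec& e) {
  if (e.type == 3) {
    double ff = (f > 1e-12) ? f : 1e-12;
    double r = std::log(y) - std::log(ff);
    return -r / (ff * e.s2);
  }
  double v = e.sa2 + e.sp2 * f * f;
  if (v < 1e-300) v = 1e-300;
  double r = y - f;
  double dv = 2.0 * e.sp2 * f;
  return 0.5 * dv / v - r / v - 0.5 * r * r * dv / (v * v);
}

inline double obs_d2nll(double y, double f, const ErrSpec& e) {
  double h = 1e-6 * std::max(std::fabs(f), 1e-3);
  return (obs_dnll(y, f + h, e) - obs_dnll(y, f - h, e)) / (2.0 * h);
}

// Per-patient workspace: evaluates the joint negative log density g(eta)
// (observation terms plus the N(0, diag(w2)) prior on the free components,
// all normalisation constants included).
struct Patient {
  int m, p, q;                 // model, n structural params, n free etas
  const double* t;
  const double* y;
  int n;
  arma::vec tvp, w2;           // length p
  arma::uvec free_idx;         // indices of free (w2 > 0) etas
  ErrSpec err;
  int* flag;

  arma::vec eval_f(const arma::vec& eta_full) const {
    arma::vec P = tvp % arma::exp(eta_full);
    arma::vec f(n);
    soef_eval_core(m, P.memptr(), t, n, f.memptr(), flag);
    return f;
  }

  double g(const arma::vec& eta_free) const {
    arma::vec eta_full(p, arma::fill::zeros);
    for (int k = 0; k < q; ++k) eta_full(free_idx(k)) = eta_free(k);
    arma::vec f = eval_f(eta_full);
    double val = 0.0;
    for (int j = 0; j < n; ++j) {
      if (!std::isfinite(f(j))) return 1e10;
      val += obs_nll(y[j], f(j), err);
    }
    for (int k = 0; k < q; ++k) {
      double w = w2(free_idx(k));
      val += 0.5 * (eta_free(k) * eta_free(k) / w + std::log(TWO_PI * w));
    }
    return std::isfinite(val) ? val : 1e10;
  }

  // analytic-in-f gradient with finite-difference Jacobian of f wrt eta
  arma::vec grad(const arma::vec& eta_free, arma::mat* J_out = nullptr,
                 arma::vec* d1_out = nullptr, arma::vec* d2_out = nullptr) const {
    arma::vec eta_full(p, arma::fill::zeros);
    for (int k = 0; k < q; ++k) eta_full(free_idx(k)) = eta_free(k);
    arma::vec f0 = eval_f(eta_full);
    if (!f0.is_finite()) return arma::vec(q, arma::fill::zeros);
    arma::vec d1(n), d2(n);
    for (int j = 0; j < n; ++j) {
      d1(j) = obs_dnll(y[j], f0(j), err);
      d2(j) = obs_d2nll(y[j], f0(j), err);
      if (!std::isfinite(d1(j))) d1(j) = 0.0;
      if (!std::isfinite(d2(j))) d2(j) = 0.0;
    }
    const double h = 1e-6;
    arma::mat J(n, q);
    for (int k = 0; k < q; ++k) {
      arma::vec ep = eta_full;
      ep(free_idx(k)) += h;
      arma::vec fk = eval_f(ep);
      arma::vec col = (fk - f0) / h;
      if (!col.is_finite()) col.zeros();
      J.col(k) = col;
    }
    arma::vec gr(q);
    for (int k = 0; k < q; ++k)
      gr(k) = arma::dot(J.col(k), d1) + eta_free(k) / w2(free_idx(k));
    if (J_out) *J_out = J;
    if (d1_out) *d1_out = d1;
    if (d2_out) *d2_out = d2;
    return gr;
  }
};

// Damped Gauss-Newton minimisation of g over the free etas.
static bool inner_newton(const Patient& pat, arma::vec& eta, int max_iter,
                         double gtol) {
  int q = pat.q;
  double g0 = pat.g(eta);
  if (g0 >= 1e9) { eta.zeros(); g0 = pat.g(eta); }
  for (int it = 0; it < max_iter; ++it) {
    arma::mat J;
    arma::vec d1, d2;
    arma::vec gr = pat.grad(eta, &J, &d1, &d2);
    if (arma::norm(gr, "inf") < gtol) return true;
    arma::vec d2f = arma::clamp(d2, 0.0, arma::datum::inf);
    arma::mat H = J.t() * (J.each_col() % d2f);
    for (int k = 0; k < q; ++k) H(k, k) += 1.0 / pat.w2(pat.free_idx(k));
    double tau = 0.0;
    bool moved = false;
    for (int damp = 0; damp < 8 && !moved; ++damp) {
      arma::mat Hd = H;
      if (tau > 0) Hd.diag() += tau;
      arma::vec step;
      bool ok = arma::solve(step, Hd, -gr, arma::solve_opts::no_approx);
      if (ok && step.is_finite()) {
        double alpha = 1.0;
        for (int ls = 0; ls < 12; ++ls) {
          arma::vec cand = eta + alpha * step;
          double gc = pat.g(cand);
          if (gc < g0) { eta = cand; g0 = gc; moved = true; break; }
          alpha *= 0.5;
        }
      }
      tau = (tau == 0.0) ? 1e-4 : tau * 10.0;
    }
    if (!moved) return true; // cannot improve further: treat as converged
  }
  return true;
}

// Full finite-difference Hessian of g at the mode (one-sided differences
// of the analytic-in-f gradient, symmetrised; the mode gradient is
// reused).
static arma::mat full_hessian(const Patient& pat, const arma::vec& eta,
                              const arma::vec& grad0) {
  int q = pat.q;
  const double h = 1e-4;
  arma::mat H(q, q);
  for (int k = 0; k < q; ++k) {
    arma::vec ep = eta;
    ep(k) += h;
    H.col(k) = (pat.grad(ep) - grad0) / h;
  }
  return 0.5 * (H + H.t());
}

// theta layout: log(tvp) [p] , log(w2) [p] , log(sigma-pars) [1 or 2]
// error_model: 0 additive, 1 proportional, 2 combined (sa2 then sp2),
//              3 exponential
// [[Rcpp::export]]
List cpp_laplace_nll(int model, arma::vec theta, int n_struct,
                     arma::vec time, arma::vec y,
                     arma::uvec pat_start, arma::uvec pat_len,
                     int error_model, arma::mat eta_warm,
                     int inner_iter = 60, double inner_gtol = 1e-6) {
  int p = n_struct;
  int npat = pat_start.n_elem;
  arma::vec tvp = arma::exp(theta.subvec(0, p - 1));
  arma::vec w2 = arma::exp(theta.subvec(p, 2 * p - 1));
  ErrSpec err;
  err.type = error_model;
  err.sa2 = err.sp2 = err.s2 = 0.0;
  if (error_model == 0) err.sa2 = std::exp(theta(2 * p));
  else if (error_model == 1) err.sp2 = std::exp(theta(2 * p));
  else if (error_model == 2) {
    err.sa2 = std::exp(theta(2 * p));
    err.sp2 = std::exp(theta(2 * p + 1));
  } else err.s2 = std::exp(theta(2 * p));

  arma::uvec free_idx = arma::find(w2 > 1e-12);
  int q = free_idx.n_elem;

  int flag = 0;
  double total = 0.0;
  arma::vec per_pat(npat, arma::fill::zeros);
  arma::mat eta_out(p, npat, arma::fill::zeros);
  bool ok = true;

  for (int i = 0; i < npat; ++i) {
    Patient pat;
    pat.m = model;
    pat.p = p;
    pat.q = q;
    pat.t = time.memptr() + pat_start(i);
    pat.y = y.memptr() + pat_start(i);
    pat.n = pat_len(i);
    pat.tvp = tvp;
    pat.w2 = w2;
    pat.free_idx = free_idx;
    pat.err = err;
    pat.flag = &flag;

    double contrib;
    if (q == 0) {
      arma::vec e0;
      contrib = 2.0 * pat.g(e0);
    } else {
      arma::vec eta(q);
      for (int k = 0; k < q; ++k) eta(k) = eta_warm(free_idx(k), i);
      if (!eta.is_finite()) eta.zeros();
      inner_newton(pat, eta, inner_iter, inner_gtol);
      double gmode = pat.g(eta);
      arma::mat H = full_hessian(pat, eta, pat.grad(eta));
      // log-determinant, ridged to positive definiteness if needed
      double ld = 0.0;
      arma::mat L;
      double ridge = 0.0;
      if (!H.is_finite()) { ok = false; H.eye(q, q); }
      for (int tries = 0; tries < 8; ++tries) {
        arma::mat Hr = H;
        if (ridge > 0) Hr.diag() += ridge;
        if (arma::chol(L, Hr)) {
          ld = 2.0 * arma::accu(arma::log(L.diag()));
          break;
        }
        ridge = (ridge == 0.0) ? 1e-8 : ridge * 100.0;
        if (tries == 7) { ok = false; ld = 0.0; }
      }
      contrib = 2.0 * gmode + ld - q * std::log(TWO_PI);
      for (int k = 0; k < q; ++k) eta_out(free_idx(k), i) = eta(k);
    }
    if (!std::isfinite(contrib)) { contrib = 1e10; ok = false; }
    per_pat(i) = contrib;
    total += contrib;
  }

  return List::create(_["value"] = total, _["per_patient"] = per_pat,
                      _["eta"] = eta_out, _["n_singular"] = flag,
                      _["ok"] = ok);
}
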