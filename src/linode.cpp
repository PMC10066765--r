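// Exact propagation of linear compartmental systems x' = A x + u(t), where
// u(t) is piecewise constant (zero-order infusions) with instantaneous bolus
// jumps.  Compartmental matrices here have real spectra, but propagation is
// done in complex arithmetic via the eigendecomposition of A so no structural
// assumption is needed; a Pade expm fallback covers (near-)defective A.
// This is the hot path of the marginal-likelihood evaluation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Propagator {
  bool use_eig;
  cx_vec lam;
  cx_mat P;
  cx_mat Pinv;
  mat A;

  explicit Propagator(const mat& A_) : A(A_) {
    use_eig = false;
    cx_mat V;
    cx_vec l;
    if (eig_gen(l, V, A_)) {
      double rc = rcond(V);
      if (std::isfinite(rc) && rc > 1e-9) {
        lam = l;
        P = V;
        Pinv = inv(V);
        use_eig = true;
      }
    }
  }

  // x(dt) = e^{A dt} x0 + phi(dt) u,  phi = int_0^dt e^{A s} ds
  vec step(const vec& x0, const vec& u, double dt) const {
    const uword n = A.n_rows;
    if (dt <= 0.0) return x0;
    if (use_eig) {
      cx_vec el(n), il(n);
      for (uword i = 0; i < n; ++i) {
        cx_double z = lam(i) * dt;
        cx_double e = std::exp(z);
        el(i) = e;
        // (e^{lam dt} - 1)/lam, with series guard near lam = 0
        if (std::abs(lam(i)) * dt < 1e-8) {
          il(i) = dt * (1.0 + z / 2.0 + z * z / 6.0);
        } else {
          il(i) = (e - 1.0) / lam(i);
        }
      }
      cx_vec y = P * (el % (Pinv * cx_vec(x0, vec(n, fill::zeros))));
      if (any(u != 0.0)) {
        y += P * (il % (Pinv * cx_vec(u, vec(n, fill::zeros))));
      }
      return real(y);
    }
    // fallback: augmented-matrix expm gives both e^{A dt} and the integral term
    mat Aug(n + 1, n + 1, fill::zeros);
    Aug.submat(0, 0, n - 1, n - 1) = A * dt;
    Aug.submat(0, n, n - 1, n) = u * dt;
    mat E = expmat(Aug);
    return E.submat(0, 0, n - 1, n - 1) * x0 + E.submat(0, n, n - 1, n);
  }
};

}  // namespace

// Solve the system on a grid.  Doses: vectors of time, amount, duration
// (0 = bolus) and target compartment (1-based).  Returns n_state x n_obs
// matrix of states at obs_times (sorted, >= 0).  State starts at `init` at
// t = 0; obs exactly at a bolus time see the post-dose state.
// [[Rcpp::export(name = ".linode_solve")]]
arma::mat linode_solve(const arma::mat& A,
                       const arma::vec& init,
                       const arma::vec& dose_time,
                       const arma::vec& dose_amt,
                       const arma::vec& dose_dur,
                       const arma::ivec& dose_cmt,
                       const arma::vec& obs_times) {
  const uword n = A.n_rows;
  const uword nd = dose_time.n_elem;
  Propagator prop(A);

  // change points: every dose start and infusion end
  std::vector<double> brk;
  for (uword i = 0; i < nd; ++i) {
    brk.push_back(dose_time(i));
    if (dose_dur(i) > 0.0) brk.push_back(dose_time(i) + dose_dur(i));
  }
  std::sort(brk.begin(), brk.end());
  brk.erase(std::unique(brk.begin(), brk.end(),
                        [](double a, double b) { return std::abs(a - b) < 1e-12; }),
            brk.end());

  auto input_at = [&](double t) {
    vec u(n, fill::zeros);
    for (uword i = 0; i < nd; ++i) {
      if (dose_dur(i) > 0.0 && t >= dose_time(i) - 1e-12 &&
          t < dose_time(i) + dose_dur(i) - 1e-12) {
        u(dose_cmt(i) - 1) += dose_amt(i) / dose_dur(i);
      }
    }
    return u;
  };

  mat out(n, obs_times.n_elem);
  vec x = init;
  double t = 0.0;
  uword iobs = 0, ibrk = 0;

  // skip change points at/before t = 0 after applying t = 0 boluses
  for (uword i = 0; i < nd; ++i) {
    if (dose_dur(i) == 0.0 && std::abs(dose_time(i)) < 1e-12) {
      x(dose_cmt(i) - 1) += dose_amt(i);
    }
  }
  while (ibrk < brk.size() && brk[ibrk] <= 1e-12) ++ibrk;

  while (iobs < obs_times.n_elem) {
    double t_next_brk = (ibrk < brk.size()) ? brk[ibrk] : datum::inf;
    double t_obs = obs_times(iobs);
    vec u = input_at(t);
    if (t_obs <= t_next_brk + 1e-12) {
      x = prop.step(x, u, t_obs - t);
      t = t_obs;
      // flush all observations at this time (and apply a coincident bolus
      // first if the obs sits exactly on a dose: dose-then-observe)
      if (std::abs(t - t_next_brk) <= 1e-12) {
        for (uword i = 0; i < nd; ++i) {
          if (dose_dur(i) == 0.0 && std::abs(dose_time(i) - t) <= 1e-12) {
            x(dose_cmt(i) - 1) += dose_amt(i);
          }
        }
        ++ibrk;
      }
      while (iobs < obs_times.n_elem &&
             std::abs(obs_times(iobs) - t) <= 1e-12) {
        out.col(iobs) = x;
        ++iobs;
      }
    } else {
      x = prop.step(x, u, t_next_brk - t);
      t = t_next_brk;
      for (uword i = 0; i < nd; ++i) {
        if (dose_dur(i) == 0.0 && std::abs(dose_time(i) - t) <= 1e-12) {
          x(dose_cmt(i) - 1) += dose_amt(i);
        }
      }
      ++ibrk;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Compiled marginal likelihood for one subject: conditional log-likelihood
// (proportional error + M3 censoring) evaluated through the exact propagator,
// with the scalar CL32 random effect marginalised by Laplace or adaptive
// Gauss-Hermite quadrature around a safeguarded-Newton empirical-Bayes mode.
// ---------------------------------------------------------------------------

namespace {

struct SubjectModel {
  double k12, k23, k32_base, k20;
  bool need_pd;
  double ke0, ksyn, kdeg, kq, p_baseline;
  vec crow;
  vec dose_time, dose_amt, dose_dur;
  vec obs_time;
  ivec pred_code;  // 0 = mrna, 1 = pcc, >= 2 -> biomarker row (code - 2)
  mat bio;         // columns: e0, base, ic50, imax, gamma
  vec dv, lloq, sigma;
  uvec blq;

  double cond_loglik(double eta) const {
    double k32 = k32_base * std::exp(eta);
    uword n = need_pd ? 6 : 3;
    mat A(n, n, fill::zeros);
    A(0, 0) = -k12;
    A(1, 0) = k12; A(1, 1) = -(k23 + k20); A(1, 2) = k32;
    A(2, 1) = k23; A(2, 2) = -k32;
    vec init(n, fill::zeros);
    if (need_pd) {
      A(3, 0) = ke0 * crow(0); A(3, 1) = ke0 * crow(1);
      A(3, 2) = ke0 * crow(2); A(3, 3) = -ke0;
      A(4, 3) = ksyn; A(4, 4) = -(kdeg + kq); A(4, 5) = kq;
      A(5, 4) = kq; A(5, 5) = -kq;
      init(4) = p_baseline / 2.0;
      init(5) = p_baseline / 2.0;
    }
    ivec cmt(dose_time.n_elem, fill::ones);
    mat st = linode_solve(A, init, dose_time, dose_amt, dose_dur, cmt,
                          obs_time);
    double ll = 0.0;
    for (uword i = 0; i < obs_time.n_elem; ++i) {
      double f;
      int code = pred_code(i);
      if (code == 0) {
        f = crow(0) * st(0, i) + crow(2) * st(2, i);
      } else {
        double p = st(4, i) + st(5, i);
        if (code == 1) {
          f = p;
        } else {
          const double e0 = bio(code - 2, 0), base = bio(code - 2, 1),
                       ic50 = bio(code - 2, 2), imax = bio(code - 2, 3),
                       gam = bio(code - 2, 4);
          double pg = std::pow(p, gam);
          f = e0 + base * (1.0 - imax * pg / (std::pow(ic50, gam) + pg));
        }
      }
      double s = std::sqrt(sigma(i) * sigma(i) * f * f + 1e-10);
      double term;
      if (blq(i)) {
        term = R::pnorm(lloq(i), f, s, 1, 1);
      } else {
        term = R::dnorm(dv(i), f, s, 1);
      }
      if (!std::isfinite(term)) return -1e10;
      ll += term;
    }
    return std::isfinite(ll) ? ll : -1e10;
  }
};

}  // namespace

// [[Rcpp::export(name = ".marginal_loglik_cpp")]]
Rcpp::List marginal_loglik_cpp(
    double k12, double k23, double k32_base, double k20, bool need_pd,
    double ke0, double ksyn, double kdeg, double kq, double p_baseline,
    const arma::vec& crow, const arma::vec& dose_time,
    const arma::vec& dose_amt, const arma::vec& dose_dur,
    const arma::vec& obs_time, const arma::ivec& pred_code,
    const arma::mat& bio, const arma::vec& dv, const arma::vec& lloq,
    const arma::vec& sigma, const arma::uvec& blq, double omega, int method,
    const arma::vec& gh_x, const arma::vec& gh_w, double eta_start) {
  SubjectModel m{k12, k23, k32_base, k20, need_pd, ke0, ksyn, kdeg, kq,
                 p_baseline, crow, dose_time, dose_amt, dose_dur, obs_time,
                 pred_code, bio, dv, lloq, sigma, blq};
  if (omega < 1e-10) {
    return Rcpp::List::create(Rcpp::Named("loglik") = m.cond_loglik(0.0),
                              Rcpp::Named("eta_mode") = 0.0);
  }
  const double log_om = std::log(omega);
  auto h = [&](double eta) {
    double prior = -0.918938533204672742 - log_om -
                   0.5 * eta * eta / (omega * omega);
    return m.cond_loglik(eta) + prior;
  };
  // safeguarded Newton with fallback to golden-section on a wide bracket
  double mode = eta_start, hm = h(mode);
  const double step = std::max(1e-4, 0.01 * omega);
  bool ok = false;
  for (int it = 0; it < 12; ++it) {
    double hp = h(mode + step), hn = h(mode - step);
    double g = (hp - hn) / (2 * step);
    double d2 = (hp - 2 * hm + hn) / (step * step);
    if (!std::isfinite(g) || !std::isfinite(d2) || d2 >= 0) break;
    double delta = g / d2;
    if (std::abs(delta) > 1.5) delta = (delta > 0 ? 1.5 : -1.5);
    double cand = mode - delta;
    double hc = h(cand);
    if (!std::isfinite(hc)) break;
    if (hc < hm - 1e-8) {
      cand = 0.5 * (mode + cand);
      hc = h(cand);
      if (hc < hm) break;
    }
    bool conv = std::abs(cand - mode) < 1e-5;
    mode = cand;
    hm = hc;
    if (conv) { ok = true; break; }
  }
  if (!ok) {
    const double phi = 0.6180339887498949;
    double a = -5.0 * omega - 1.0, b = 5.0 * omega + 1.0;
    double x1 = b - phi * (b - a), x2 = a + phi * (b - a);
    double f1 = h(x1), f2 = h(x2);
    for (int it = 0; it < 60 && (b - a) > 1e-5; ++it) {
      if (f1 < f2) {
        a = x1; x1 = x2; f1 = f2;
        x2 = a + phi * (b - a); f2 = h(x2);
      } else {
        b = x2; x2 = x1; f2 = f1;
        x1 = b - phi * (b - a); f1 = h(x1);
      }
    }
    mode = 0.5 * (a + b);
    hm = h(mode);
  }
  double d2 = (h(mode + step) - 2 * hm + h(mode - step)) / (step * step);
  double sd_star = (std::isfinite(d2) && d2 < 0) ? 1.0 / std::sqrt(-d2) : omega;
  double out;
  if (method == 0) {  // laplace
    out = hm + 0.5 * std::log(2.0 * M_PI * sd_star * sd_star);
  } else {  // adaptive Gauss-Hermite
    uword q = gh_x.n_elem;
    vec lt(q);
    for (uword i = 0; i < q; ++i) {
      double e = mode + std::sqrt(2.0) * sd_star * gh_x(i);
      lt(i) = std::log(gh_w(i)) + h(e) + gh_x(i) * gh_x(i);
    }
    double mx = lt.max();
    out = std::log(std::sqrt(2.0) * sd_star) + mx +
          std::log(accu(exp(lt - mx)));
  }
  return Rcpp::List::create(Rcpp::Named("loglik") = out,
                            Rcpp::Named("eta_mode") = mode);
}
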