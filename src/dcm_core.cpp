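// Bilinear three-region DCM forward model with balloon-Windkessel
// haemodynamics, integrated by fixed-step Euler at TR/16. Compiled because
// variational-Laplace inversion evaluates it O(10^3) times per subject.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

// Fixed haemodynamic constants (per-region transit time is the only
// estimated haemodynamic parameter, as a log deviation from tau0).
constexpr double kappa = 0.64;  // signal decay (1/s)
constexpr double gamma_ = 0.32; // autoregulation (1/s)
constexpr double tau0 = 2.0;    // transit time (s)
constexpr double alpha_g = 0.32; // Grubb's exponent
constexpr double E0 = 0.4;      // resting oxygen extraction
constexpr double V0 = 4.0;      // resting venous volume (percent signal units)
const double k1 = 7.0 * E0;
const double k2 = 2.0;
const double k3 = 2.0 * E0 - 0.2;

struct DCMTheta {
  mat A;        // 3x3 with -0.5*exp(self) on diagonal
  cube B;       // 3x3x4, one slice per modulatory input (outcome channels 1-4)
  mat C;        // 3x8 input weights
  vec tau;      // per-region transit times
};

// theta layout (60): A offdiag 6 (column-major, skipping diag), self log 3,
// B 36 (4 slices x 9 column-major), C 12 (outc1-4 -> VIS, cue1-2 -> VIS,
// resp-choice -> 3 regions, resp-nochoice -> 3 regions), hemo log-transit 3.
DCMTheta unpack(const vec& th) {
  DCMTheta p;
  p.A.zeros(3, 3);
  int k = 0;
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i)
      if (i != j) p.A(i, j) = th[k++];
  for (int i = 0; i < 3; ++i) p.A(i, i) = -0.5 * std::exp(th[6 + i]);
  p.B.zeros(3, 3, 4);
  k = 9;
  for (int s = 0; s < 4; ++s)
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i) p.B(i, j, s) = th[k++];
  p.C.zeros(3, 8);
  for (int j = 0; j < 4; ++j) p.C(0, j) = th[45 + j]; // outcomes -> VIS
  p.C(0, 4) = th[49]; p.C(0, 5) = th[50];             // cues -> VIS
  for (int i = 0; i < 3; ++i) p.C(i, 6) = th[51 + i]; // response (choice)
  for (int i = 0; i < 3; ++i) p.C(i, 7) = th[54 + i]; // response (no-choice)
  p.tau = vec(3);
  for (int i = 0; i < 3; ++i) p.tau[i] = tau0 * std::exp(th[57 + i]);
  return p;
}

} // namespace

// Integrate the generative model. U: Tmicro x 8 (mean-centred stimulus
// functions at microtime dt = tr / microtime_per_tr). Returns n_scans x 3
// predicted BOLD sampled at scan onsets, plus a stability flag.
// [[Rcpp::export(name = ".dcm_forward_cpp")]]
Rcpp::List dcm_forward_cpp(const arma::vec& theta, const arma::mat& U,
                           int n_scans, double tr, int microtime_per_tr) {
  const DCMTheta p = unpack(theta);
  const double dt = tr / microtime_per_tr;
  const int Tm = U.n_rows;
  if (Tm < n_scans * microtime_per_tr)
    Rcpp::stop("input length shorter than the scan session");

  // Haemodynamic states f, v, q are integrated in log space (lf, lv, lq),
  // which enforces their positivity exactly; the dynamics are the standard
  // balloon-Windkessel equations transformed by the chain rule. The scheme
  // is second-order midpoint (RK2) with inputs held constant over each
  // microtime bin.
  vec state(15, fill::zeros);  // x(3), s(3), lf(3), lv(3), lq(3)
  mat y(n_scans, 3, fill::zeros);
  bool ok = true;
  int scan = 0;

  auto deriv = [&p](const vec& st, const vec& u) {
    vec d(15);
    const vec x = st.subvec(0, 2);
    mat J = p.A;
    for (int sl = 0; sl < 4; ++sl) J += u[sl] * p.B.slice(sl);
    d.subvec(0, 2) = J * x + p.C * u;
    for (int i = 0; i < 3; ++i) {
      const double s = st[3 + i];
      const double f = std::exp(st[6 + i]), v = std::exp(st[9 + i]),
                   q = std::exp(st[12 + i]);
      const double Ef = 1.0 - std::pow(1.0 - E0, 1.0 / f);
      const double fv = std::pow(v, 1.0 / alpha_g);
      d[3 + i] = x[i] - kappa * s - gamma_ * (f - 1.0);
      d[6 + i] = s / f;
      d[9 + i] = (f - fv) / (p.tau[i] * v);
      d[12 + i] = (f * Ef / E0 - fv * q / v) / (p.tau[i] * q);
    }
    return d;
  };

  for (int t = 0; t < Tm && scan < n_scans; ++t) {
    if (t == scan * microtime_per_tr) {
      for (int i = 0; i < 3; ++i) {
        const double v = std::exp(state[9 + i]), q = std::exp(state[12 + i]);
        y(scan, i) = V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) +
                           k3 * (1.0 - v));
      }
      ++scan;
    }
    const vec u = U.row(t).t();
    const vec k1s = deriv(state, u);
    const vec mid = state + 0.5 * dt * k1s;
    if (std::abs(mid.max()) > 1e6 || std::abs(mid.min()) > 1e6) {
      ok = false; break;
    }
    state += dt * deriv(mid, u);
    if (arma::abs(state.subvec(0, 2)).max() > 1e6 ||
        arma::abs(state.subvec(6, 14)).max() > 20) {
      ok = false; break;
    }
  }
  return Rcpp::List::create(Rcpp::_["bold"] = y, Rcpp::_["ok"] = ok);
}

// Forward-difference Jacobian of the vectorised prediction wrt theta,
// restricted to the free-parameter indices `free_idx` (1-based).
// [[Rcpp::export(name = ".dcm_jacobian_cpp")]]
Rcpp::List dcm_jacobian_cpp(const arma::vec& theta, const arma::mat& U,
                            int n_scans, double tr, int microtime_per_tr,
                            const arma::uvec& free_idx, double h) {
  Rcpp::List base = dcm_forward_cpp(theta, U, n_scans, tr, microtime_per_tr);
  mat y0 = Rcpp::as<mat>(base["bold"]);
  bool ok = Rcpp::as<bool>(base["ok"]);
  vec g0 = vectorise(y0);
  mat Jac(g0.n_elem, free_idx.n_elem, fill::zeros);
  for (uword k = 0; k < free_idx.n_elem && ok; ++k) {
    vec th = theta;
    th[free_idx[k] - 1] += h;
    Rcpp::List pert = dcm_forward_cpp(th, U, n_scans, tr, microtime_per_tr);
    if (!Rcpp::as<bool>(pert["ok"])) { ok = false; break; }
    vec gk = vectorise(Rcpp::as<mat>(pert["bold"]));
    Jac.col(k) = (gk - g0) / h;
  }
  return Rcpp::List::create(Rcpp::_["g0"] = g0, Rcpp::_["J"] = Jac,
                            Rcpp::_["ok"] = ok);
}
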