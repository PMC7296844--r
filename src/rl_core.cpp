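// Sequential Rescorla-Wagner replay for the five task models.
// Hot loop for MAP fitting and iBIC Monte Carlo, hence compiled.
#include <Rcpp.h>
using namespace Rcpp;

namespace {

inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Map unconstrained theta to native parameters for a model id.
// alpha in (0,1) via logit^-1, rho > 0 via exp. Shared parameters aliased.
void map_params(const NumericVector& theta, int model_id,
                double& a_c, double& a_nc, double& r_c, double& r_nc,
                int& ia_c, int& ia_nc, int& ir_c, int& ir_nc) {
  switch (model_id) {
  case 1:
    a_c = sigmoid(theta[0]); a_nc = 0.0;
    r_c = std::exp(theta[1]); r_nc = r_c;
    ia_c = 0; ia_nc = -1; ir_c = 1; ir_nc = 1;
    break;
  case 2:
    a_c = sigmoid(theta[0]); a_nc = a_c;
    r_c = std::exp(theta[1]); r_nc = r_c;
    ia_c = 0; ia_nc = 0; ir_c = 1; ir_nc = 1;
    break;
  case 3:
    a_c = sigmoid(theta[0]); a_nc = sigmoid(theta[1]);
    r_c = std::exp(theta[2]); r_nc = r_c;
    ia_c = 0; ia_nc = 1; ir_c = 2; ir_nc = 2;
    break;
  case 4:
    a_c = sigmoid(theta[0]); a_nc = a_c;
    r_c = std::exp(theta[1]); r_nc = std::exp(theta[2]);
    ia_c = 0; ia_nc = 0; ir_c = 1; ir_nc = 2;
    break;
  case 5:
    a_c = sigmoid(theta[0]); a_nc = sigmoid(theta[1]);
    r_c = std::exp(theta[2]); r_nc = std::exp(theta[3]);
    ia_c = 0; ia_nc = 1; ir_c = 2; ir_nc = 3;
    break;
  default:
    stop("unknown model id");
  }
}

} // namespace

// Replay one session. condition: 1 choice / 0 no-choice; action: 1 high / 0 low;
// outcome in {0,1} (ignored on missed trials); missed: 0/1.
// Returns NLL over choice trials, optionally its gradient in theta, the
// per-outcome RPE series and the per-trial P(high) under the running policy.
// [[Rcpp::export(name = ".rl_replay_cpp")]]
List rl_replay_cpp(NumericVector theta, int model_id,
                   IntegerVector condition, IntegerVector action,
                   IntegerVector outcome, IntegerVector missed,
                   bool want_grad, bool want_series,
                   bool rpe_on_nochoice) {
  const int n = condition.size();
  const int d = theta.size();
  double a_c, a_nc, r_c, r_nc;
  int ia_c, ia_nc, ir_c, ir_nc;
  map_params(theta, model_id, a_c, a_nc, r_c, r_nc, ia_c, ia_nc, ir_c, ir_nc);

  double q[2] = {0.0, 0.0};
  std::vector<double> dq0(d, 0.0), dq1(d, 0.0);
  double nll = 0.0;
  NumericVector grad(d);
  NumericVector rpe(want_series ? n : 0, NA_REAL);
  NumericVector phigh(want_series ? n : 0, NA_REAL);
  NumericMatrix qtraj(want_series ? n : 0, 2);

  for (int t = 0; t < n; ++t) {
    if (missed[t]) continue;
    const bool is_choice = condition[t] == 1;
    const double diff = q[1] - q[0];
    const double p1 = sigmoid(diff);
    if (want_series) phigh[t] = p1;

    if (is_choice) {
      const int a = action[t];
      const double pa = (a == 1) ? p1 : 1.0 - p1;
      nll -= std::log(std::max(pa, 1e-300));
      if (want_grad) {
        const double s = (a == 1) ? 1.0 : -1.0;
        const double w = -(1.0 - pa) * s;
        for (int k = 0; k < d; ++k) grad[k] += w * (dq1[k] - dq0[k]);
      }
    }

    // learning update
    const int a = action[t];
    const double r = static_cast<double>(outcome[t]);
    const bool learns = is_choice || model_id != 1;
    const double alpha = is_choice ? a_c : a_nc;
    const double rho = is_choice ? r_c : r_nc;
    const double pe = rho * r - q[a];
    if (want_series) {
      if (is_choice || model_id != 1 || rpe_on_nochoice) rpe[t] = pe;
      else rpe[t] = NA_REAL;
    }
    if (learns) {
      if (want_grad) {
        const int ia = is_choice ? ia_c : ia_nc;
        const int ir = is_choice ? ir_c : ir_nc;
        std::vector<double>& dqa = (a == 1) ? dq1 : dq0;
        for (int k = 0; k < d; ++k) {
          double dpe = -dqa[k];
          if (k == ir) dpe += rho * r; // drho/dtheta_ir = rho
          double dalpha = (k == ia) ? alpha * (1.0 - alpha) : 0.0;
          dqa[k] += dalpha * pe + alpha * dpe;
        }
      }
      q[a] += alpha * pe;
    }
    if (want_series) { qtraj(t, 0) = q[0]; qtraj(t, 1) = q[1]; }
  }

  List out = List::create(_["nll"] = nll);
  if (want_grad) out["grad"] = grad;
  if (want_series) {
    out["rpe"] = rpe;
    out["p_high"] = phigh;
    out["q"] = qtraj;
  }
  return out;
}

namespace {

// Likelihood-only replay used by the Monte-Carlo marginal likelihood.
double replay_nll(const double* theta, int d, int model_id,
                  const IntegerVector& condition, const IntegerVector& action,
                  const IntegerVector& outcome, const IntegerVector& missed) {
  NumericVector th(theta, theta + d);
  double a_c, a_nc, r_c, r_nc;
  int ia_c, ia_nc, ir_c, ir_nc;
  map_params(th, model_id, a_c, a_nc, r_c, r_nc, ia_c, ia_nc, ir_c, ir_nc);
  double q[2] = {0.0, 0.0};
  double nll = 0.0;
  const int n = condition.size();
  for (int t = 0; t < n; ++t) {
    if (missed[t]) continue;
    const bool is_choice = condition[t] == 1;
    if (is_choice) {
      const double p1 = sigmoid(q[1] - q[0]);
      const double pa = (action[t] == 1) ? p1 : 1.0 - p1;
      nll -= std::log(std::max(pa, 1e-300));
    }
    if (is_choice || model_id != 1) {
      const double alpha = is_choice ? a_c : a_nc;
      const double rho = is_choice ? r_c : r_nc;
      const int a = action[t];
      q[a] += alpha * (rho * outcome[t] - q[a]);
    }
  }
  return nll;
}

} // namespace

// Monte-Carlo log marginal likelihood of one subject's choices under a
// Gaussian prior in unconstrained space: log (1/K) sum_k exp(-NLL(theta_k)).
// Sampling the K x d draws here keeps the iBIC inner loop off the R heap.
// [[Rcpp::export(name = ".rl_log_marglik_cpp")]]
double rl_log_marglik_cpp(NumericMatrix theta_draws, int model_id,
                          IntegerVector condition, IntegerVector action,
                          IntegerVector outcome, IntegerVector missed) {
  const int K = theta_draws.nrow();
  const int d = theta_draws.ncol();
  std::vector<double> ll(K), th(d);
  double m = -std::numeric_limits<double>::infinity();
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < d; ++j) th[j] = theta_draws(k, j);
    ll[k] = -replay_nll(th.data(), d, model_id, condition, action, outcome,
                        missed);
    if (ll[k] > m) m = ll[k];
  }
  double s = 0.0;
  for (int k = 0; k < K; ++k) s += std::exp(ll[k] - m);
  return m + std::log(s / K);
}
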