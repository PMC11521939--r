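#include "cs.h"
using namespace Rcpp;

// Odorant transduction cascade for one OSN (receptor r, N = 1) and a mixture
// of O components.
//   u:       n_steps x O matrix of concentration samples (ppm)
//   b, d:    per-component binding / dissociation rates for this receptor
//   otp:     list(tau_h, gamma, alpha2, beta2, kappa, alpha3, beta3,
//                 rho, c, i_max, current_steady)
//   cs:      Connor-Stevens parameter list; sigma: OSN noise scale
// Peri-receptor filter h(t) = (1/tau_h) exp(-t/tau_h) is applied as a
// first-order low-pass; the derivative path uses the identity
// (h * du) = (u - h*u)/tau_h.
// [[Rcpp::export]]
List cpp_otp_run(NumericMatrix u, NumericVector b, NumericVector d,
                 List otp, List cs, double sigma, double dt, int trace_stride) {
  const int n = u.nrow(), O = u.ncol();
  if (b.size() != O || d.size() != O)
    stop("b/d length must match the number of mixture components");
  const double tau_h = as<double>(otp["tau_h"]);
  const double gamma = as<double>(otp["gamma"]);
  const double a2 = as<double>(otp["alpha2"]), b2 = as<double>(otp["beta2"]);
  const double kap = as<double>(otp["kappa"]);
  const double a3 = as<double>(otp["alpha3"]), b3 = as<double>(otp["beta3"]);
  const double rho = as<double>(otp["rho"]), cc = as<double>(otp["c"]);
  const double imax = as<double>(otp["i_max"]);
  const bool steady = as<bool>(otp["current_steady"]);
  CSParams p = cs_params_from_list(cs);
  CSState s; cs_init_rest(s);
  const double dt_ms = dt * 1000.0;
  const double noise_sd = sigma * std::sqrt(dt_ms);
  const double crho = std::pow(cc, rho);

  std::vector<double> y(O, 0.0), x1(O, 0.0);
  double x2 = 0.0, x3 = 0.0, cur = 0.0;
  std::vector<double> spikes;
  const int n_tr = trace_stride > 0 ? (n + trace_stride - 1) / trace_stride : 0;
  NumericMatrix v_tr(n_tr, O), x1_tr(n_tr, O);
  NumericVector x2_tr(n_tr), x3_tr(n_tr), i_tr(n_tr);

  std::vector<double> vloc(O);
  for (int k = 0; k < n; ++k) {
    // competitive binding, one backward-Euler step of the coupled system:
    // x1' = (x1 + dt b v (1 - S')) / (1 + dt d) summed over components gives
    // S' in closed form; unconditionally stable and keeps 0 <= S <= 1.
    double A = 0.0, B = 0.0;
    for (int o = 0; o < O; ++o) {
      double uk = u(k, o);
      double v = y[o] + gamma * (uk - y[o]) / tau_h;   // h*u + gamma * h*du
      if (v < 0.0) v = 0.0;
      vloc[o] = v;
      y[o] += dt * (uk - y[o]) / tau_h;
      double e = 1.0 / (1.0 + dt * d[o]);
      A += e * x1[o];
      B += e * dt * b[o] * v;
    }
    double s_new = (A + B) / (1.0 + B);
    double sx1_new = 0.0;
    for (int o = 0; o < O; ++o) {
      double e = 1.0 / (1.0 + dt * d[o]);
      x1[o] = e * x1[o] + e * dt * b[o] * vloc[o] * (1.0 - s_new);
      sx1_new += x1[o];
      if (trace_stride > 0 && k % trace_stride == 0) {
        v_tr(k / trace_stride, o) = vloc[o];
        x1_tr(k / trace_stride, o) = x1[o];
      }
    }
    if (sx1_new > 1.0 + 1e-9)
      stop("bound-receptor invariant violated: sum(x1)=%g at t=%g s", sx1_new, k * dt);
    double x2n = x2 + dt * (a2 * sx1_new * (1.0 - x2) - b2 * x2
                            - kap * std::pow(x2, 2.0 / 3.0) * std::pow(x3, 2.0 / 3.0));
    double x3n = x3 + dt * (a3 * x2 - b3 * x3);
    x2 = x2n < 0.0 ? 0.0 : (x2n > 1.0 ? 1.0 : x2n);
    x3 = x3n < 0.0 ? 0.0 : (x3n > 1.0 ? 1.0 : x3n);
    double x2r = std::pow(x2, rho);
    if (steady) {
      cur = x2r / (x2r + crho) * imax;
    } else {
      cur += dt * (x2r * (imax - cur) - crho * cur);
    }
    double noise = (sigma > 0.0) ? noise_sd * norm_rand() : 0.0;
    bool sp = cs_step_inline(s, cur, dt_ms, p, noise, k * dt_ms);
    if (sp) spikes.push_back((k + 1) * dt);
    if (trace_stride > 0 && k % trace_stride == 0) {
      int kk = k / trace_stride;
      x2_tr[kk] = x2; x3_tr[kk] = x3; i_tr[kk] = cur;
    }
  }
  return List::create(
    _["spike_times"] = wrap(spikes),
    _["v"] = v_tr, _["x1"] = x1_tr, _["x2"] = x2_tr, _["x3"] = x3_tr,
    _["i"] = i_tr);
}
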