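#ifndef OEMSIM_CS_H
#define OEMSIM_CS_H

#include <Rcpp.h>
#include <cmath>

// Connor-Stevens point neuron (standard constants: Na, K, transient A-current,
// leak; Cm = 1 uF/cm^2).  Internal units: mV, ms, uA/cm^2, mS/cm^2.
struct CSParams {
  double gna, ena;
  double gk, ek;
  double ga, eaa;
  double gl, el;
  double cm;
  double v_spike;      // spike-detection threshold (mV)
  double t_refrac_ms;  // detection lockout after a spike (ms)
};

struct CSState {
  double v, m, h, n, a, b;
  double t_last_spike_ms;  // -inf if none
};

inline CSParams cs_params_from_list(const Rcpp::List& p) {
  CSParams q;
  q.gna = Rcpp::as<double>(p["g_na"]);   q.ena = Rcpp::as<double>(p["e_na"]);
  q.gk  = Rcpp::as<double>(p["g_k"]);    q.ek  = Rcpp::as<double>(p["e_k"]);
  q.ga  = Rcpp::as<double>(p["g_a"]);    q.eaa = Rcpp::as<double>(p["e_a"]);
  q.gl  = Rcpp::as<double>(p["g_l"]);    q.el  = Rcpp::as<double>(p["e_l"]);
  q.cm  = Rcpp::as<double>(p["c_m"]);
  q.v_spike = Rcpp::as<double>(p["v_spike"]);
  q.t_refrac_ms = Rcpp::as<double>(p["t_refrac"]) * 1000.0;
  return q;
}

inline double cs_alpha_m(double v) {
  double x = v + 29.7;
  if (std::fabs(x) < 1e-7) return 3.8;  // limit of 0.38*x/(1-exp(-x/10))
  return 0.38 * x / (1.0 - std::exp(-x / 10.0));
}
inline double cs_beta_m(double v)  { return 15.2 * std::exp(-0.0556 * (v + 54.7)); }
inline double cs_alpha_h(double v) { return 0.266 * std::exp(-0.05 * (v + 48.0)); }
inline double cs_beta_h(double v)  { return 3.8 / (1.0 + std::exp(-0.1 * (v + 18.0))); }
inline double cs_alpha_n(double v) {
  double x = v + 45.7;
  if (std::fabs(x) < 1e-7) return 0.2;
  return 0.02 * x / (1.0 - std::exp(-x / 10.0));
}
inline double cs_beta_n(double v) { return 0.25 * std::exp(-0.0125 * (v + 55.7)); }
inline double cs_a_inf(double v) {
  double num = 0.0761 * std::exp(0.0314 * (v + 94.22));
  double den = 1.0 + std::exp(0.0346 * (v + 1.17));
  return std::cbrt(num / den);
}
inline double cs_tau_a(double v) { return 0.3632 + 1.158 / (1.0 + std::exp(0.0497 * (v + 55.96))); }
inline double cs_b_inf(double v) {
  double s = 1.0 / (1.0 + std::exp(0.0688 * (v + 53.3)));
  return s * s * s * s;
}
inline double cs_tau_b(double v) { return 1.24 + 2.678 / (1.0 + std::exp(0.0624 * (v + 50.0))); }

inline void cs_init_rest(CSState& s) {
  // steady state at the numerically determined resting potential
  double v = -67.97;
  s.v = v;
  s.m = cs_alpha_m(v) / (cs_alpha_m(v) + cs_beta_m(v));
  s.h = cs_alpha_h(v) / (cs_alpha_h(v) + cs_beta_h(v));
  s.n = cs_alpha_n(v) / (cs_alpha_n(v) + cs_beta_n(v));
  s.a = cs_a_inf(v);
  s.b = cs_b_inf(v);
  s.t_last_spike_ms = -1e18;
}

// One Euler(-Maruyama) step of dt_ms; i_ext in uA/cm^2 (inward positive),
// noise_term = sigma * sqrt(dt_ms) * Z, pre-drawn (0 if deterministic).
// Returns true if an upward crossing of v_spike occurred (refractory-guarded).
inline bool cs_step_inline(CSState& s, double i_ext, double dt_ms,
                           const CSParams& p, double noise_term, double t_ms) {
  double v = s.v;
  double i_ion = p.gna * s.m * s.m * s.m * s.h * (v - p.ena)
               + p.gk  * s.n * s.n * s.n * s.n * (v - p.ek)
               + p.ga  * s.a * s.a * s.a * s.b * (v - p.eaa)
               + p.gl  * (v - p.el);
  double v_new = v + dt_ms * (i_ext - i_ion) / p.cm + noise_term / p.cm;
  s.m += dt_ms * (cs_alpha_m(v) * (1.0 - s.m) - cs_beta_m(v) * s.m);
  s.h += dt_ms * (cs_alpha_h(v) * (1.0 - s.h) - cs_beta_h(v) * s.h);
  s.n += dt_ms * (cs_alpha_n(v) * (1.0 - s.n) - cs_beta_n(v) * s.n);
  s.a += dt_ms * (cs_a_inf(v) - s.a) / cs_tau_a(v);
  s.b += dt_ms * (cs_b_inf(v) - s.b) / cs_tau_b(v);
  bool spike = false;
  if (v < p.v_spike && v_new >= p.v_spike &&
      (t_ms - s.t_last_spike_ms) >= p.t_refrac_ms) {
    spike = true;
    s.t_last_spike_ms = t_ms;
  }
  s.v = v_new;
  return spike;
}

#endif
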