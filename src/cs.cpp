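#include "cs.h"
using namespace Rcpp;

// Simulate one Connor-Stevens neuron driven by a per-step external current.
// i_ext: length n_steps (uA/cm^2); dt in seconds; sigma: noise scale
// (uA/cm^2 * sqrt(ms)); trace_stride: keep every k-th voltage sample (0 = none).
// Uses R's RNG, so seeding is controlled from R.
// [[Rcpp::export]]
List cpp_cs_run(NumericVector i_ext, double dt, List params, double sigma,
                Nullable<NumericVector> init, int trace_stride) {
  CSParams p = cs_params_from_list(params);
  CSState s;
  if (init.isNotNull()) {
    NumericVector v(init);
    s.v = v[0]; s.m = v[1]; s.h = v[2]; s.n = v[3]; s.a = v[4]; s.b = v[5];
    s.t_last_spike_ms = -1e18;
  } else {
    cs_init_rest(s);
  }
  const int n = i_ext.size();
  const double dt_ms = dt * 1000.0;
  const double noise_sd = sigma * std::sqrt(dt_ms);
  std::vector<double> spikes;
  std::vector<double> vtr;
  if (trace_stride > 0) vtr.reserve(n / trace_stride + 1);
  for (int k = 0; k < n; ++k) {
    double t_ms = k * dt_ms;
    double noise = (sigma > 0.0) ? noise_sd * norm_rand() : 0.0;
    bool sp = cs_step_inline(s, i_ext[k], dt_ms, p, noise, t_ms);
    if (sp) spikes.push_back((k + 1) * dt);
    if (!std::isfinite(s.v))
      stop("Connor-Stevens integration failure: V became non-finite at t=%g s",
           k * dt);
    if (trace_stride > 0 && k % trace_stride == 0) vtr.push_back(s.v);
  }
  return List::create(
    _["spike_times"] = wrap(spikes),
    _["v"] = wrap(vtr),
    _["state"] = NumericVector::create(s.v, s.m, s.h, s.n, s.a, s.b));
}

// One integration step; state = (V, m, h, n, a, b), t_ms = current time,
// t_last_spike_ms for the refractory guard.  Returns updated state + spike flag.
// [[Rcpp::export]]
List cpp_cs_step(NumericVector state, double i_ext, double dt, List params,
                 double noise_term, double t_ms, double t_last_spike_ms) {
  CSParams p = cs_params_from_list(params);
  CSState s;
  s.v = state[0]; s.m = state[1]; s.h = state[2]; s.n = state[3];
  s.a = state[4]; s.b = state[5];
  s.t_last_spike_ms = t_last_spike_ms;
  bool sp = cs_step_inline(s, i_ext, dt * 1000.0, p, noise_term, t_ms);
  const char* vars[6] = {"V", "m", "h", "n", "a", "b"};
  double vals[6] = {s.v, s.m, s.h, s.n, s.a, s.b};
  for (int i = 0; i < 6; ++i)
    if (!std::isfinite(vals[i]))
      stop("Connor-Stevens integration failure: variable %s became non-finite",
           vars[i]);
  return List::create(
    _["state"] = NumericVector::create(s.v, s.m, s.h, s.n, s.a, s.b),
    _["spike"] = sp,
    _["t_last_spike_ms"] = s.t_last_spike_ms);
}

// Resting-state gating values at voltage v (mV) - used for initialization.
// [[Rcpp::export]]
NumericVector cpp_cs_rest_state() {
  CSState s;
  cs_init_rest(s);
  return NumericVector::create(s.v, s.m, s.h, s.n, s.a, s.b);
}
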