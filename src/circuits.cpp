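#include "cs.h"
using namespace Rcpp;

// Bin sorted spike times onto the dt grid: count per step.
static std::vector<int> bin_spikes(const NumericVector& times, int n, double dt) {
  std::vector<int> cnt(n, 0);
  for (int i = 0; i < times.size(); ++i) {
    int k = (int)std::floor(times[i] / dt - 1e-9);
    if (k < 0) k = 0;
    if (k >= n) k = n - 1;
    cnt[k]++;
  }
  return cnt;
}

// n_up impulsive increments x <- x + alpha (1 - x), applied n times exactly.
static inline double jump_up(double x, double alpha, int n_up) {
  if (n_up == 1) return x + alpha * (1.0 - x);
  return 1.0 - (1.0 - x) * std::pow(1.0 - alpha, n_up);
}

// Kinetic divisive-normalization state driven by spike events:
//   up event:   x <- x + alpha (1 - x)
//   down event: x <- x - kappa x
//   between:    dx/dt = -beta x
// Returns the full decimated trace and the mean over [t_from, T].
// [[Rcpp::export]]
List cpp_dnp_run(NumericVector up_times, NumericVector down_times,
                 double alpha, double beta, double kappa,
                 double T, double dt, double t_from, int trace_stride) {
  const int n = (int)std::round(T / dt);
  std::vector<int> up = bin_spikes(up_times, n, dt);
  std::vector<int> dn = bin_spikes(down_times, n, dt);
  double x = 0.0, acc = 0.0;
  int n_acc = 0;
  std::vector<double> tr;
  for (int k = 0; k < n; ++k) {
    x *= std::exp(-beta * dt);                    // exact decay between events
    if (up[k] > 0) x = jump_up(x, alpha, up[k]);
    if (dn[k] > 0) x *= std::pow(1.0 - kappa, dn[k]);
    if (k * dt >= t_from) { acc += x; n_acc++; }
    if (trace_stride > 0 && k % trace_stride == 0) tr.push_back(x);
  }
  return List::create(_["mean"] = n_acc ? acc / n_acc : NA_REAL,
                      _["x"] = wrap(tr));
}

// Antennal-lobe circuit: R channels, each with an OSN axon-terminal feedback
// DNP (normalized by the global Pre-LN), onset/offset post-synaptic local
// neurons, and a projection neuron.  osn_spikes: list of R sorted time vectors.
// [[Rcpp::export]]
List cpp_al_run(List osn_spikes, int n_steps, double dt, List al, List cs,
                int trace_stride) {
  const int R = osn_spikes.size();
  const double axt_a = as<double>(al["axt_alpha"]);
  const double axt_b = as<double>(al["axt_beta"]);
  const double axt_k = as<double>(al["axt_kappa"]);
  const double nt_max = as<double>(al["nt_max"]);
  const double a_ol = as<double>(al["ol_alpha"]), b_ol = as<double>(al["ol_beta"]);
  const double g_ol = as<double>(al["ol_gmax"]), e_ol = as<double>(al["ol_e"]);
  const double a_op = as<double>(al["op_alpha"]), b_op = as<double>(al["op_beta"]);
  const double g_op = as<double>(al["op_gmax"]), e_op = as<double>(al["op_e"]);
  const double tau_fast = as<double>(al["ln_tau_fast"]);
  const double tau_slow = as<double>(al["ln_tau_slow"]);
  const double k_eln = as<double>(al["eln_gain"]), k_iln = as<double>(al["iln_gain"]);
  const double a_lp = as<double>(al["lp_alpha"]), b_lp = as<double>(al["lp_beta"]);
  const double g_elp = as<double>(al["elp_gmax"]), e_elp = as<double>(al["elp_e"]);
  const double g_ilp = as<double>(al["ilp_gmax"]), e_ilp = as<double>(al["ilp_e"]);
  const double sig_l = as<double>(al["sigma_l"]), sig_p = as<double>(al["sigma_p"]);
  const double sig_ln = as<double>(al["sigma_ln"]);
  const double pn_bias = as<double>(al["pn_bias"]);
  CSParams p = cs_params_from_list(cs);
  const double dt_ms = dt * 1000.0;
  const double nsd_l = sig_l * std::sqrt(dt_ms);
  const double nsd_p = sig_p * std::sqrt(dt_ms);
  const double nsd_ln = sig_ln * std::sqrt(dt_ms);
  const double dec = std::exp(-axt_b * dt);

  std::vector<std::vector<int> > osn(R);
  for (int r = 0; r < R; ++r)
    osn[r] = bin_spikes(as<NumericVector>(osn_spikes[r]), n_steps, dt);

  std::vector<double> x_axt(R, 0.0), x_ol(R, 0.0), x_op(R, 0.0);
  std::vector<double> s_fast(R, 0.0), s_slow(R, 0.0);
  std::vector<double> x_elp(R, 0.0), x_ilp(R, 0.0);
  CSState preln; cs_init_rest(preln);
  std::vector<CSState> pn(R), eln(R), iln(R);
  for (int r = 0; r < R; ++r) { cs_init_rest(pn[r]); cs_init_rest(eln[r]); cs_init_rest(iln[r]); }

  std::vector<std::vector<double> > pn_sp(R), eln_sp(R), iln_sp(R);
  std::vector<double> preln_sp;
  bool preln_fired_prev = false;
  const int n_tr = trace_stride > 0 ? (n_steps + trace_stride - 1) / trace_stride : 0;
  NumericMatrix axt_tr(n_tr, R);

  for (int k = 0; k < n_steps; ++k) {
    double t_ms = k * dt_ms;
    double i_preln = 0.0;
    for (int r = 0; r < R; ++r) {
      // axon-terminal feedback DNP
      x_axt[r] *= dec;
      if (osn[r][k] > 0) x_axt[r] = jump_up(x_axt[r], axt_a, osn[r][k]);
      if (preln_fired_prev) x_axt[r] -= axt_k * x_axt[r];
      double nt = nt_max * x_axt[r];
      // OSN axon terminal -> Pre-LN synapse (graded, NT-driven)
      x_ol[r] += dt * (a_ol * nt * (1.0 - x_ol[r]) - b_ol * x_ol[r]);
      i_preln += g_ol * x_ol[r] * (e_ol - preln.v);
      // OSN axon terminal -> PN synapse
      x_op[r] += dt * (a_op * nt * (1.0 - x_op[r]) - b_op * x_op[r]);
      // post-LN rate filters (Hz); onset = fast - slow rectified
      s_fast[r] += osn[r][k] / tau_fast - dt * s_fast[r] / tau_fast;
      s_slow[r] += osn[r][k] / tau_slow - dt * s_slow[r] / tau_slow;
      if (trace_stride > 0 && k % trace_stride == 0)
        axt_tr(k / trace_stride, r) = x_axt[r];
    }
    // global Pre-LN
    double nl = (sig_l > 0.0) ? nsd_l * norm_rand() : 0.0;
    preln_fired_prev = cs_step_inline(preln, i_preln, dt_ms, p, nl, t_ms);
    if (preln_fired_prev) preln_sp.push_back((k + 1) * dt);
    for (int r = 0; r < R; ++r) {
      double onset = s_fast[r] - s_slow[r];
      double offset = -onset;
      if (onset < 0.0) onset = 0.0;
      if (offset < 0.0) offset = 0.0;
      double ne = (sig_ln > 0.0) ? nsd_ln * norm_rand() : 0.0;
      double ni = (sig_ln > 0.0) ? nsd_ln * norm_rand() : 0.0;
      bool sp_e = cs_step_inline(eln[r], k_eln * onset, dt_ms, p, ne, t_ms);
      bool sp_i = cs_step_inline(iln[r], k_iln * offset, dt_ms, p, ni, t_ms);
      if (sp_e) eln_sp[r].push_back((k + 1) * dt);
      if (sp_i) iln_sp[r].push_back((k + 1) * dt);
      // LN -> PN spike-driven synapses
      x_elp[r] -= dt * b_lp * x_elp[r];
      if (sp_e) x_elp[r] += a_lp * (1.0 - x_elp[r]);
      x_ilp[r] -= dt * b_lp * x_ilp[r];
      if (sp_i) x_ilp[r] += a_lp * (1.0 - x_ilp[r]);
      double i_pn = pn_bias
                  + g_op * x_op[r] * (e_op - pn[r].v)
                  + g_elp * x_elp[r] * (e_elp - pn[r].v)
                  + g_ilp * x_ilp[r] * (e_ilp - pn[r].v);
      double np = (sig_p > 0.0) ? nsd_p * norm_rand() : 0.0;
      if (cs_step_inline(pn[r], i_pn, dt_ms, p, np, t_ms))
        pn_sp[r].push_back((k + 1) * dt);
    }
  }
  List pn_out(R), eln_out(R), iln_out(R);
  for (int r = 0; r < R; ++r) {
    pn_out[r] = wrap(pn_sp[r]);
    eln_out[r] = wrap(eln_sp[r]);
    iln_out[r] = wrap(iln_sp[r]);
  }
  return List::create(
    _["pn_spikes"] = pn_out, _["preln_spikes"] = wrap(preln_sp),
    _["eln_spikes"] = eln_out, _["iln_spikes"] = iln_out,
    _["x_axt"] = axt_tr);
}

// Mushroom-body calyx: M Kenyon cells, each sampling Q projection neurons
// (graph: M x Q, 1-based PN indices), with APL feedback onto every KC
// dendrite.  pn_spikes: list of R sorted time vectors.  With bsg = false the
// KC spike generators are skipped (dendrite-only run; only meaningful when
// the APL loop is open, kcd_kappa = 0).
// [[Rcpp::export]]
List cpp_calyx_run(List pn_spikes, IntegerMatrix graph, int n_steps, double dt,
                   List cal, List cs, int trace_stride, bool bsg) {
  const int R = pn_spikes.size();
  const int M = graph.nrow(), Q = graph.ncol();
  const double a_kcd = as<double>(cal["kcd_alpha"]);
  const double b_kcd = as<double>(cal["kcd_beta"]);
  const double k_kcd = as<double>(cal["kcd_kappa"]);
  const double i_max = as<double>(cal["i_max_kc"]);
  const double a_apl = as<double>(cal["apl_alpha"]);
  const double b_apl = as<double>(cal["apl_beta"]);
  const double sig_k = as<double>(cal["sigma_k"]);
  const double v_jit = as<double>(cal["v_init_jitter"]);
  CSParams p = cs_params_from_list(cs);
  const double dt_ms = dt * 1000.0;
  const double nsd_k = sig_k * std::sqrt(dt_ms);

  std::vector<std::vector<int> > pn(R);
  for (int r = 0; r < R; ++r) {
    NumericVector v = pn_spikes[r];
    pn[r] = bin_spikes(v, n_steps, dt);
  }
  for (int m = 0; m < M; ++m)
    for (int q = 0; q < Q; ++q)
      if (graph(m, q) < 1 || graph(m, q) > R)
        stop("graph references PN %d outside 1..%d", graph(m, q), R);

  std::vector<double> x_kcd(M, 0.0);
  double x_apl = 0.0;
  // small random initial-voltage offsets desynchronize otherwise identical
  // KCs (drawn from R's RNG, hence seed-reproducible)
  std::vector<CSState> kc(M);
  for (int m = 0; m < M; ++m) {
    cs_init_rest(kc[m]);
    if (v_jit > 0.0) kc[m].v += v_jit * (2.0 * unif_rand() - 1.0);
  }
  std::vector<std::vector<double> > kc_sp(M);
  const int n_tr = trace_stride > 0 ? (n_steps + trace_stride - 1) / trace_stride : 0;
  NumericMatrix kcd_tr(n_tr, M);
  NumericVector apl_tr(n_tr);

  for (int k = 0; k < n_steps; ++k) {
    double t_ms = k * dt_ms;
    int kc_spikes_now = 0;
    double decay = std::exp(-(b_kcd + k_kcd * x_apl) * dt);
    bool rec = trace_stride > 0 && k % trace_stride == 0;
    for (int m = 0; m < M; ++m) {
      double x = x_kcd[m] * decay;
      int n_in = 0;
      for (int q = 0; q < Q; ++q) n_in += pn[graph(m, q) - 1][k];
      if (n_in > 0) x = jump_up(x, a_kcd, n_in);
      x_kcd[m] = x;
      if (bsg) {
        double noise = (sig_k > 0.0) ? nsd_k * norm_rand() : 0.0;
        if (cs_step_inline(kc[m], i_max * x, dt_ms, p, noise, t_ms)) {
          kc_sp[m].push_back((k + 1) * dt);
          kc_spikes_now++;
        }
      }
      if (rec) kcd_tr(k / trace_stride, m) = x;
    }
    x_apl *= std::exp(-b_apl * dt);
    if (kc_spikes_now > 0) x_apl = jump_up(x_apl, a_apl, kc_spikes_now);
    if (rec) apl_tr[k / trace_stride] = x_apl;
  }
  List kc_out(M);
  for (int m = 0; m < M; ++m) kc_out[m] = wrap(kc_sp[m]);
  return List::create(_["kc_spikes"] = kc_out, _["x_kcd"] = kcd_tr,
                      _["x_apl"] = apl_tr);
}
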