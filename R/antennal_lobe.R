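#' Antennal lobe circuit parameters
#'
#' Each of the `R` glomerular channels contains an OSN axon-terminal feedback
#' divisive-normalization processor (DNP) whose vesicle state is incremented
#' by OSN spikes, decays at `axt_beta`, and is divisively suppressed by
#' spikes of the global presynaptic local neuron (Pre-LN); its output is the
#' neurotransmitter level `NT = nt_max * x`.  Graded synapses driven by `NT`
#' excite the Pre-LN (`ol_*`) and the channel's projection neuron (`op_*`).
#' Onset/offset postsynaptic local neurons (Post-eLN / Post-iLN) are driven by
#' the rectified difference of a fast and a slow low-passed OSN rate estimate
#' and contact the PN through excitatory / inhibitory spike-driven synapses
#' (`lp_*`, `elp_*`, `ilp_*`).  Synaptic currents follow the conductance
#' convention `I = g x (E - V_post)` (inward positive).
#'
#' @param axt_alpha per-OSN-spike increment of the axon-terminal state.
#' @param axt_beta axon-terminal decay rate (1/s).
#' @param axt_kappa fractional divisive decrement per Pre-LN spike.
#' @param nt_max maximal neurotransmitter concentration (a.u.).
#' @param ol_alpha,ol_beta,ol_gmax,ol_e axon terminal to Pre-LN synapse
#'   (rates 1/(a.u. s) and 1/s; conductance mS/cm^2; reversal mV).
#' @param op_alpha,op_beta,op_gmax,op_e axon terminal to PN synapse.
#' @param ln_tau_fast,ln_tau_slow onset/offset rate-filter time constants (s).
#' @param eln_gain,iln_gain drive current per Hz of rectified rate change
#'   (uA/cm^2 / Hz).
#' @param lp_alpha,lp_beta LN-to-PN synaptic gate jump per spike and decay
#'   (1/s).
#' @param elp_gmax,elp_e,ilp_gmax,ilp_e Post-eLN / Post-iLN to PN synapses.
#' @param pn_bias constant depolarizing current into each PN (uA/cm^2),
#'   modeling the high intrinsic excitability of projection neurons; set just
#'   below rheobase so weak OSN inputs modulate PN firing smoothly instead of
#'   being clipped by the spiking threshold.
#' @param sigma_l,sigma_p,sigma_ln noise scales of the Pre-LN, PN and
#'   Post-LN spike generators.
#' @return list of class `al_params`.
#' @export
al_params <- function(axt_alpha = 0.02, axt_beta = 10, axt_kappa = 0.02,
                      nt_max = 1,
                      ol_alpha = 200, ol_beta = 20, ol_gmax = 0.15, ol_e = 0,
                      op_alpha = 10, op_beta = 20, op_gmax = 1.2, op_e = 0,
                      ln_tau_fast = 0.05, ln_tau_slow = 0.25,
                      eln_gain = 0.15, iln_gain = 0.15,
                      lp_alpha = 0.2, lp_beta = 20,
                      elp_gmax = 0.1, elp_e = 0, ilp_gmax = 0.1, ilp_e = -80,
                      pn_bias = 7, sigma_l = 0, sigma_p = 0, sigma_ln = 0) {
  p <- list(axt_alpha = axt_alpha, axt_beta = axt_beta, axt_kappa = axt_kappa,
            nt_max = nt_max, ol_alpha = ol_alpha, ol_beta = ol_beta,
            ol_gmax = ol_gmax, ol_e = ol_e, op_alpha = op_alpha,
            op_beta = op_beta, op_gmax = op_gmax, op_e = op_e,
            ln_tau_fast = ln_tau_fast, ln_tau_slow = ln_tau_slow,
            eln_gain = eln_gain, iln_gain = iln_gain, lp_alpha = lp_alpha,
            lp_beta = lp_beta, elp_gmax = elp_gmax, elp_e = elp_e,
            ilp_gmax = ilp_gmax, ilp_e = ilp_e, pn_bias = pn_bias,
            sigma_l = sigma_l, sigma_p = sigma_p, sigma_ln = sigma_ln)
  stopifnot(all(vapply(p[c("axt_alpha", "axt_beta", "axt_kappa", "nt_max",
                           "ol_alpha", "ol_beta", "ol_gmax", "op_alpha",
                           "op_beta", "op_gmax", "lp_alpha", "lp_beta",
                           "elp_gmax", "ilp_gmax")], function(v) v >= 0, TRUE)),
            axt_kappa <= 1, lp_alpha <= 1)
  structure(p, class = "al_params")
}

#' One event step of the axon-terminal feedback DNP
#'
#' Between spikes the state decays exponentially at `axt_beta`; an OSN spike
#' applies `x <- x + axt_alpha (1 - x)` and a Pre-LN spike applies
#' `x <- x - axt_kappa x`.  Under Poisson input at rate `lambda` and feedback
#' at rate `mu` the long-run mean is the divisive fixed point
#' `alpha lambda / (alpha lambda + beta + kappa mu)`.
#'
#' @param x state in `[0, 1]`.
#' @param osn_spikes,preln_spikes number of spikes of each kind in this step.
#' @param params `al_params`.
#' @param dt step (s).
#' @return updated state.
#' @export
axon_terminal_step <- function(x, osn_spikes, preln_spikes,
                               params = al_params(), dt) {
  stopifnot(x >= 0, x <= 1)
  x <- x * exp(-params$axt_beta * dt)
  if (osn_spikes > 0)
    x <- 1 - (1 - x) * (1 - params$axt_alpha)^osn_spikes
  if (preln_spikes > 0)
    x <- x * (1 - params$axt_kappa)^preln_spikes
  if (x < -1e-9 || x > 1 + 1e-9)
    stop("axon-terminal state left [0,1]")
  x
}

#' One Euler step of a graded conductance synapse
#'
#' `dx/dt = alpha drive (1 - x) - beta x`; the synaptic current reported
#' follows the sign convention `I = gmax x (v_post - e)` (positive outward
#' when the postsynaptic potential is above the reversal).
#'
#' @param x gating state in `[0, 1]`.
#' @param drive presynaptic drive (neurotransmitter level, a.u.).
#' @param v_post postsynaptic membrane voltage (mV).
#' @param alpha,beta,gmax,e synapse constants.
#' @param dt step (s).
#' @return list with updated `x` and current `i`.
#' @export
synapse_step <- function(x, drive, v_post, alpha, beta, gmax, e, dt) {
  stopifnot(x >= 0, x <= 1)
  x <- x + dt * (alpha * drive * (1 - x) - beta * x)
  list(x = x, i = gmax * x * (v_post - e))
}

#' Onset/offset local-neuron response to an OSN spike train
#'
#' Estimates the instantaneous OSN rate with a fast and a slow exponential
#' filter; the Post-eLN is driven by the rectified positive rate change
#' (`fast - slow`), the Post-iLN by the rectified negative change, each
#' through its own Connor-Stevens spike generator.
#'
#' @param spike_times OSN spike times (s).
#' @param kind `"onset"` (Post-eLN) or `"offset"` (Post-iLN).
#' @param params `al_params`.
#' @param cs `cs_params`.
#' @param t_total horizon (s).
#' @param dt step (s).
#' @return list with `drive` (rectified rate change, Hz, per step) and
#'   `ln_spikes` (s).
#' @export
run_post_ln <- function(spike_times, kind = c("onset", "offset"),
                        params = al_params(), cs = cs_params(), t_total,
                        dt = 1e-5) {
  kind <- match.arg(kind)
  n <- round(t_total / dt)
  cnt <- tabulate(pmin(pmax(floor(spike_times / dt - 1e-9), 0) + 1, n), n)
  lp <- function(tau) {
    as.numeric(filter(cnt / tau, 1 - dt / tau, method = "recursive"))
  }
  s_fast <- lp(params$ln_tau_fast)
  s_slow <- lp(params$ln_tau_slow)
  drive <- if (kind == "onset") pmax(s_fast - s_slow, 0)
           else pmax(s_slow - s_fast, 0)
  gain <- if (kind == "onset") params$eln_gain else params$iln_gain
  res <- cpp_cs_run(gain * drive, dt, cs, params$sigma_ln, NULL, 0L)
  list(drive = drive, ln_spikes = res$spike_times)
}

#' Simulate the antennal-lobe circuit
#'
#' Runs the `R`-channel AL on the OSN spike trains: per-channel axon-terminal
#' DNPs divisively normalized by the global Pre-LN, onset/offset local
#' neurons, and one projection neuron per channel.
#'
#' @param osn_spikes a `spike_train_set` over receptors (one train per
#'   channel).
#' @param params `al_params`.
#' @param cs `cs_params` shared by all AL spike generators.
#' @param t_total horizon (s); defaults to the horizon of `osn_spikes`.
#' @param dt step (s).
#' @param seed RNG seed (noise only).
#' @param trace_stride decimation of the `x_axt` trace.
#' @return list with `pn` (a `spike_train_set`), `preln_spikes`, `eln`/`iln`
#'   spike train sets, and the decimated `x_axt` matrix (time x channel).
#' @export
run_al <- function(osn_spikes, params = al_params(), cs = cs_params(),
                   t_total = NULL, dt = 1e-5, seed = NULL,
                   trace_stride = 20L) {
  stopifnot(inherits(osn_spikes, "spike_train_set"))
  t_total <- t_total %||% attr(osn_spikes, "t_end")
  n <- round(t_total / dt)
  res <- with_seed(seed,
                   cpp_al_run(unclass(osn_spikes), as.integer(n), dt, params,
                              cs, as.integer(trace_stride)))
  list(pn = spike_train_set(res$pn_spikes, "pn", t_total),
       preln_spikes = res$preln_spikes,
       eln = spike_train_set(res$eln_spikes, "eln", t_total),
       iln = spike_train_set(res$iln_spikes, "iln", t_total),
       x_axt = res$x_axt)
}
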