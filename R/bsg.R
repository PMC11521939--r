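#' Connor-Stevens neuron parameters
#'
#' Parameters of the Noisy Connor-Stevens point neuron used by every spiking
#' population (OSNs, local neurons, PNs, KCs).  Conductances in mS/cm^2,
#' potentials in mV, capacitance in uF/cm^2.  `noise_sd` scales additive white
#' current noise integrated with the Euler-Maruyama scheme; with
#' `noise_sd = 0` the neuron is deterministic.  Spikes are detected as upward
#' crossings of `v_spike` with a `t_refrac` lockout.
#'
#' @param g_na,e_na sodium conductance / reversal.
#' @param g_k,e_k delayed-rectifier potassium conductance / reversal.
#' @param g_a,e_a transient A-current conductance / reversal.
#' @param g_l,e_l leak conductance / reversal.
#' @param c_m membrane capacitance.
#' @param v_spike spike-detection threshold (mV).
#' @param t_refrac detection lockout (s).
#' @param noise_sd current-noise scale (uA/cm^2 sqrt(ms)).
#' @return list of class `cs_params`.
#' @export
cs_params <- function(g_na = 120, e_na = 55, g_k = 20, e_k = -72,
                      g_a = 47.7, e_a = -75, g_l = 0.3, e_l = -17,
                      c_m = 1, v_spike = 0, t_refrac = 0.002, noise_sd = 0) {
  stopifnot(g_na >= 0, g_k >= 0, g_a >= 0, g_l >= 0, c_m > 0, noise_sd >= 0)
  structure(list(g_na = g_na, e_na = e_na, g_k = g_k, e_k = e_k,
                 g_a = g_a, e_a = e_a, g_l = g_l, e_l = e_l, c_m = c_m,
                 v_spike = v_spike, t_refrac = t_refrac, noise_sd = noise_sd),
            class = "cs_params")
}

#' Rheobase current of the deterministic Connor-Stevens neuron
#'
#' Minimal constant current (uA/cm^2) eliciting repetitive firing, determined
#' by bisection on a `t_sim`-second simulation.  The default dendritic drive
#' scale of the Kenyon cells is calibrated against this value.
#'
#' @param params `cs_params`.
#' @param dt integration step (s).
#' @param t_sim probe duration (s).
#' @param tol bisection tolerance (uA/cm^2).
#' @export
cs_rheobase <- function(params = cs_params(), dt = 1e-5, t_sim = 2,
                        tol = 0.01) {
  n <- round(t_sim / dt)
  fires <- function(i) {
    length(cpp_cs_run(rep(i, n), dt, params, 0, NULL, 0L)$spike_times) > 1
  }
  lo <- 0; hi <- 20
  while (!fires(hi)) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' One integration step of the Connor-Stevens neuron
#'
#' Advances the state `(V, m, h, n, a, b)` by one Euler(-Maruyama) step and
#' reports whether a spike (upward crossing of the detection threshold,
#' refractory-guarded) occurred.  With `noise_sd = 0` the step is
#' deterministic.
#'
#' @param state numeric(6) `(V, m, h, n, a, b)`, or `NULL` for the resting
#'   state.
#' @param i_input external current (uA/cm^2, inward positive).
#' @param dt time step (s); must be `<= 2e-5` for stability.
#' @param params `cs_params`.
#' @param t_ms current time (ms), used by the refractory guard.
#' @param t_last_spike_ms time of the previous spike (ms), `-Inf` if none.
#' @return list with `state`, logical `spike`, and `t_last_spike_ms`.
#' @export
cs_step <- function(state, i_input, dt, params = cs_params(), t_ms = 0,
                    t_last_spike_ms = -1e18) {
  if (dt > 2e-5 + 1e-12) stop("dt must be <= 2e-5 s for stable integration")
  if (!is.finite(i_input)) stop("input current must be finite")
  if (is.null(state)) state <- cpp_cs_rest_state()
  noise <- if (params$noise_sd > 0)
    params$noise_sd * sqrt(dt * 1000) * stats::rnorm(1) else 0
  cpp_cs_step(state, i_input, dt, params, noise, t_ms, t_last_spike_ms)
}

#' Simulate a Connor-Stevens neuron on a current waveform
#'
#' @param i_ext numeric vector of per-step currents (uA/cm^2).
#' @param dt time step (s).
#' @param params `cs_params`.
#' @param seed optional RNG seed for the noise stream.
#' @param trace_stride keep every k-th voltage sample (0 = discard).
#' @return list with `spike_times` (s), decimated `v` trace, final `state`.
#' @export
cs_run <- function(i_ext, dt, params = cs_params(), seed = NULL,
                   trace_stride = 0L) {
  with_seed(seed,
            cpp_cs_run(as.numeric(i_ext), dt, params, params$noise_sd, NULL,
                       as.integer(trace_stride)))
}

#' Frequency-current curve
#'
#' Firing rate (spike count / duration) of the Connor-Stevens neuron at each
#' constant current level; with noise, averaged over trials.  The noise
#' variance smooths the curve around the rheobase, which is how the model's
#' f-I response is tuned.
#'
#' @param i_values currents (uA/cm^2); an empty vector yields an empty result.
#' @param t_sim duration per level (s), at least 1 s.
#' @param params `cs_params`.
#' @param dt time step (s).
#' @param n_trials trials to average when `noise_sd > 0`.
#' @param seed RNG seed.
#' @return numeric vector of rates (Hz).
#' @export
fi_curve <- function(i_values, t_sim = 1, params = cs_params(), dt = 2e-5,
                     n_trials = 3, seed = NULL) {
  if (length(i_values) == 0) return(numeric(0))
  stopifnot(t_sim >= 1)
  n <- round(t_sim / dt)
  trials <- if (params$noise_sd > 0) n_trials else 1
  with_seed(seed, vapply(i_values, function(i) {
    mean(vapply(seq_len(trials), function(tr) {
      length(cpp_cs_run(rep(i, n), dt, params, params$noise_sd, NULL,
                        0L)$spike_times) / t_sim
    }, 1))
  }, 1))
}
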