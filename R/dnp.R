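#' Event-driven simulation of a kinetic divisive-normalization state
#'
#' Simulates a single DNP state driven by spike events: each "up" event
#' applies `x <- x + alpha (1 - x)`, each "down" event applies
#' `x <- x - kappa x`, and the state decays exactly at rate `beta` between
#' events on a `dt` grid.  Under Poisson event rates `lambda` (up) and `mu`
#' (down) the long-run mean is the divisive fixed point
#' `alpha lambda / (alpha lambda + beta + kappa mu)` — the building block of
#' the OSN axon terminal, KC dendrite and APL stages.
#'
#' @param up_times,down_times sorted event times (s).
#' @param alpha per-up-event increment in `[0, 1]`.
#' @param beta decay rate (1/s).
#' @param kappa fractional decrement per down event in `[0, 1]`.
#' @param t_total horizon (s).
#' @param dt grid step (s).
#' @param t_from average the state from this time on (s) for the reported
#'   mean.
#' @param trace_stride decimation of the returned state trace (0 = none).
#' @return list with `mean` (long-run average over `[t_from, t_total]`) and
#'   the decimated trace `x`.
#' @export
dnp_run <- function(up_times, down_times = numeric(0), alpha, beta,
                    kappa = 0, t_total, dt = 1e-4, t_from = 0,
                    trace_stride = 0L) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, kappa >= 0, kappa <= 1,
            t_total > 0, dt > 0)
  cpp_dnp_run(as.numeric(up_times), as.numeric(down_times), alpha, beta,
              kappa, t_total, dt, t_from, as.integer(trace_stride))
}

#' Low-level odorant-transduction run on raw concentration samples
#'
#' Runs the full transduction cascade of one OSN (peri-receptor filter,
#' competitive binding, co-receptor channel, transduction current,
#' Connor-Stevens spiking) on an explicit matrix of concentration samples —
#' one column per mixture component.  [run_osn()] is the higher-level entry
#' point for `odorant_set` objects; this function is useful for fuzzing and
#' for custom waveforms.
#'
#' @param u `n_steps x O` matrix of concentrations (ppm).
#' @param b,d per-component binding/dissociation rates for this receptor.
#' @param params `otp_params`.
#' @param cs `cs_params`.
#' @param dt step (s).
#' @param seed RNG seed (noise only).
#' @param trace_stride decimation of the state traces.
#' @return list with `spike_times` and decimated traces `v`, `x1` (per
#'   component), `x2`, `x3`, `i`.
#' @export
otp_transduce <- function(u, b, d, params = otp_params(), cs = cs_params(),
                          dt = 1e-5, seed = NULL, trace_stride = 20L) {
  u <- as.matrix(u)
  with_seed(seed, cpp_otp_run(u, as.numeric(b), as.numeric(d), params, cs,
                              params$sigma, dt, as.integer(trace_stride)))
}
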