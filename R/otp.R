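#' Odorant transduction parameters
#'
#' Constants of the transduction cascade in each OSN: the peri-receptor
#' low-pass filter (`tau_h`, unit DC gain, with derivative gain `gamma`), the
#' co-receptor channel with calcium feedback (`alpha2, beta2, kappa, alpha3,
#' beta3`), and the transduction current with Hill exponent `rho`,
#' half-constant `c` and maximal amplitude `i_max` (uA/cm^2).  `i_max` is an
#' operating-point constant determined by parameter sweeping so that the
#' 50-200 ppm range spans non-saturated OSN rates.
#'
#' @param tau_h peri-receptor filter time constant (s).
#' @param gamma peri-receptor derivative gain (s).
#' @param alpha2,beta2 co-receptor activation/deactivation rates (1/s).
#' @param kappa calcium feedback constant (1/s).
#' @param alpha3,beta3 calcium gating rates (1/s).
#' @param rho,c current Hill exponent and half-constant (dimensionless).
#' @param i_max maximal transduction current (uA/cm^2).
#' @param current_steady use the steady-state current (Hill form) instead of
#'   integrating the current ODE.
#' @param sigma OSN spike-generator noise scale.
#' @return list of class `otp_params`.
#' @export
otp_params <- function(tau_h = 0.01, gamma = 0.1, alpha2 = 5, beta2 = 2,
                       kappa = 10, alpha3 = 2.5, beta3 = 1, rho = 1, c = 0.5,
                       i_max = 60, current_steady = TRUE, sigma = 0) {
  stopifnot(tau_h > 0, alpha2 >= 0, beta2 >= 0, kappa >= 0, alpha3 >= 0,
            beta3 >= 0, rho > 0, c > 0, i_max >= 0, sigma >= 0)
  structure(list(tau_h = tau_h, gamma = gamma, alpha2 = alpha2, beta2 = beta2,
                 kappa = kappa, alpha3 = alpha3, beta3 = beta3, rho = rho,
                 c = c, i_max = i_max, current_steady = current_steady,
                 sigma = sigma),
            class = "otp_params")
}

#' Peri-receptor filtering of a concentration waveform
#'
#' Applies `v = Re[(h * u) + gamma (h * du)]` with
#' `h(t) = (1/tau_h) exp(-t/tau_h)` (unit DC gain) and `Re = max(., 0)`,
#' sampled causally on the simulation grid.  The derivative path uses the
#' identity `h * du = (u - h * u) / tau_h`.
#'
#' @param u non-negative concentration samples (ppm) on the grid.
#' @param dt grid step (s).
#' @param params `otp_params`.
#' @return filtered concentration `v` (ppm), same length as `u`.
#' @export
peri_receptor <- function(u, dt, params = otp_params()) {
  stopifnot(all(u >= 0))
  n <- length(u)
  a <- dt / params$tau_h
  z <- as.numeric(filter(a * u, 1 - a, method = "recursive"))
  y <- c(0, z[-n])                       # state before each step
  pmax(y + params$gamma * (u - y) / params$tau_h, 0)
}

#' One integration step of competitive (syntopic) receptor binding
#'
#' Integrates `dx1_o/dt = b_o v_o (1 - sum_p x1_p) - d_o x1_o` for all mixture
#' components `o` sharing one receptor's free-receptor pool, using one
#' backward-Euler step of the coupled linear system (the total bound fraction
#' has a closed form, so the implicit step is exact and unconditionally
#' stable, and `0 <= sum(x1) <= 1` is preserved for any `dt`).  With a single
#' component this is exactly the mono-molecular binding equation.
#'
#' @param x1 current bound-receptor ratios (one per component).
#' @param v filtered concentrations at the receptor (ppm).
#' @param b,d binding / dissociation rates.
#' @param dt step (s).
#' @return updated `x1`.
#' @export
bound_receptor_step <- function(x1, v, b, d, dt) {
  stopifnot(dt > 0, length(x1) == length(v), length(v) == length(b),
            length(b) == length(d))
  e <- 1 / (1 + dt * d)
  bv <- dt * b * v
  s_new <- (sum(e * x1) + sum(e * bv)) / (1 + sum(e * bv))
  x1n <- e * x1 + e * bv * (1 - s_new)
  if (any(x1n < -1e-9) || sum(x1n) > 1 + 1e-9)
    stop("bound-receptor integration error: state left [0,1] ",
         "(sum = ", sum(x1n), ")")
  pmax(x1n, 0)
}

#' Steady state of competitive receptor binding
#'
#' Closed form `x1_o* = a_o v_o / (sum_p a_p v_p + 1)`; the total bound
#' fraction is `sum a v / (sum a v + 1)`.
#'
#' @param a affinities (1/ppm).
#' @param v constant filtered concentrations (ppm).
#' @return list with `x1` (per component) and `total`.
#' @export
bound_receptor_steady_state <- function(a, v) {
  if (any(a < 0) || any(v < 0)) stop("affinities and concentrations must be >= 0")
  s <- sum(a * v)
  list(x1 = a * v / (s + 1), total = s / (s + 1))
}

#' Effective affinity of a mixture
#'
#' Concentration-weighted mean affinity
#' `a_eff = sum_o a_o v_o / sum_o v_o`: a mixture at fixed component ratio
#' binds, in total steady state, exactly like a pure odorant of affinity
#' `a_eff` at the summed concentration.
#'
#' @param a per-component affinities (1/ppm).
#' @param v per-component concentrations (ppm); their sum must be positive.
#' @return scalar effective affinity (1/ppm).
#' @export
effective_affinity <- function(a, v) {
  stopifnot(length(a) == length(v))
  if (any(a < 0) || any(v < 0)) stop("affinities and concentrations must be >= 0")
  if (sum(v) <= 0) stop("effective affinity undefined: total concentration is 0")
  sum(a * v) / sum(v)
}

#' One Euler step of the co-receptor channel with calcium feedback
#'
#' `dx2/dt = alpha2 X (1 - x2) - beta2 x2 - kappa x2^(2/3) x3^(2/3)` and
#' `dx3/dt = alpha3 x2 - beta3 x3`, where `X` is the total bound-receptor
#' ratio.
#'
#' @param x2,x3 gating states in `[0, 1]`.
#' @param sum_x1 total bound-receptor ratio `X`.
#' @param params `otp_params`.
#' @param dt step (s).
#' @return list with updated `x2`, `x3`.
#' @note The calcium equation has no intrinsic saturation term, so for large
#'   sustained `x2` (possible when `kappa = 0`) its equilibrium
#'   `alpha3 x2 / beta3` can exceed 1; `x3` is treated as a saturating pool
#'   and capped at 1.  `x2` leaving `[0, 1]` beyond tolerance is an
#'   integration error.
#' @export
coreceptor_step <- function(x2, x3, sum_x1, params = otp_params(), dt) {
  stopifnot(x2 >= 0, x2 <= 1, x3 >= 0, x3 <= 1)
  x2n <- x2 + dt * (params$alpha2 * sum_x1 * (1 - x2) - params$beta2 * x2 -
                      params$kappa * x2^(2 / 3) * x3^(2 / 3))
  x3n <- x3 + dt * (params$alpha3 * x2 - params$beta3 * x3)
  if (x2n < -1e-9 || x2n > 1 + 1e-9 || x3n < -1e-9)
    stop("co-receptor integration error: gating state left [0,1]")
  list(x2 = min(max(x2n, 0), 1), x3 = min(max(x3n, 0), 1))
}

#' Transduction current through the co-receptor channel
#'
#' In `"steady"` mode returns the Hill form
#' `I = x2^rho / (x2^rho + c^rho) * i_max` (vectorized over `x2`).  In
#' `"dynamic"` mode `x2` is a time series on the `dt` grid and the current ODE
#' `dI/dt = x2^rho (i_max - I) - c^rho I` is integrated from `i0`.
#'
#' @param x2 gating value(s) in `[0, 1]`.
#' @param params `otp_params`.
#' @param mode `"steady"` or `"dynamic"`.
#' @param dt step (s), dynamic mode only.
#' @param i0 initial current, dynamic mode only.
#' @return current (uA/cm^2); a vector in dynamic mode.
#' @export
transduction_current <- function(x2, params = otp_params(),
                                 mode = c("steady", "dynamic"), dt = NULL,
                                 i0 = 0) {
  mode <- match.arg(mode)
  stopifnot(all(x2 >= 0), all(x2 <= 1))
  crho <- params$c^params$rho
  if (mode == "steady")
    return(x2^params$rho / (x2^params$rho + crho) * params$i_max)
  stopifnot(!is.null(dt))
  out <- numeric(length(x2))
  cur <- i0
  for (k in seq_along(x2)) {
    cur <- cur + dt * (x2[k]^params$rho * (params$i_max - cur) - crho * cur)
    out[k] <- cur
  }
  out
}

# Build the n_steps x O concentration matrix of an odorant_set.
odorant_u_matrix <- function(odorants, n_steps, dt) {
  stopifnot(inherits(odorants, "odorant_set"))
  vapply(odorants$waveforms, sample_waveform, numeric(n_steps),
         n_steps = n_steps, dt = dt)
}

#' Simulate one OSN's transduction cascade and spike output
#'
#' Full cascade for the OSN expressing receptor `receptor`: peri-receptor
#' filtering, competitive binding of all mixture components, co-receptor
#' channel, transduction current, Connor-Stevens spiking.
#'
#' @param odorants an `odorant_set`.
#' @param receptor receptor index (1-based).
#' @param params `otp_params`.
#' @param cs `cs_params` for the OSN spike generator.
#' @param t_total simulation horizon (s).
#' @param dt step (s).
#' @param seed RNG seed (noise only; with `sigma = 0` the run is
#'   deterministic).
#' @param osn OSN index within the receptor type.
#' @param trace_stride decimation of state traces (samples kept every
#'   `trace_stride` steps; 0 disables traces).
#' @return list with `spikes` (a `spike_train_set` of one neuron) and traces
#'   `v`, `x1` (per component), `x2`, `x3`, `i`.
#' @export
run_osn <- function(odorants, receptor, params = otp_params(),
                    cs = cs_params(), t_total, dt = 1e-5, seed = NULL,
                    osn = 1, trace_stride = 20L) {
  n <- round(t_total / dt)
  u <- odorant_u_matrix(odorants, n, dt)
  b <- odorants$tensor$b[, receptor, osn]
  d <- odorants$tensor$d[, receptor, osn]
  res <- with_seed(seed,
                   cpp_otp_run(u, b, d, params, cs, params$sigma, dt,
                               as.integer(trace_stride)))
  res$spikes <- spike_train_set(list(res$spike_times), "osn", t_total)
  res$spike_times <- NULL
  res
}

#' Simulate the whole antenna (all receptor types)
#'
#' Runs [run_osn()] for every receptor and collects the OSN spike trains.
#'
#' @inheritParams run_osn
#' @return list with `spikes` (a `spike_train_set` over receptors) and
#'   per-receptor trace lists in `traces`.
#' @export
run_antenna <- function(odorants, params = otp_params(), cs = cs_params(),
                        t_total, dt = 1e-5, seed = NULL, trace_stride = 20L) {
  n_rec <- dim(odorants$tensor$b)[2]
  traces <- vector("list", n_rec)
  times <- vector("list", n_rec)
  n <- round(t_total / dt)
  u <- odorant_u_matrix(odorants, n, dt)
  with_seed(seed, {
    for (r in seq_len(n_rec)) {
      res <- cpp_otp_run(u, odorants$tensor$b[, r, 1], odorants$tensor$d[, r, 1],
                         params, cs, params$sigma, dt, as.integer(trace_stride))
      times[[r]] <- res$spike_times
      res$spike_times <- NULL
      traces[[r]] <- res
    }
  })
  list(spikes = spike_train_set(times, "osn", t_total), traces = traces)
}
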