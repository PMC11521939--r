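#' Mushroom-body calyx parameters
#'
#' Each Kenyon cell (KC) dendrite is a feedback DNP: projection-neuron spikes
#' increment its state (`kcd_alpha` per spike), the state decays at
#' `kcd_beta`, and the anterior paired lateral (APL) neuron's activity
#' divisively suppresses it through `kcd_kappa * x * x_apl`.  The dendritic
#' current `i_max_kc * x` drives the KC spike generator; `i_max_kc` is
#' calibrated against the Connor-Stevens rheobase (about 8.1 uA/cm^2) so
#' that spiking starts at `x` slightly above the 0.5 dendritic activity
#' threshold — every KC reported active is then reliably spiking, and the
#' APL loop, which pins the marginal KC class at the firing onset, holds
#' that class above threshold at every concentration.  The APL state
#' is incremented by every KC spike (`apl_alpha`) and decays at `apl_beta`.
#' PN-KC and KC-APL synaptic dynamics are omitted: spikes act directly on the
#' kinetic states.
#'
#' @param kcd_alpha per-PN-spike increment of the dendritic state.
#' @param kcd_beta dendritic decay rate (1/s).
#' @param kcd_kappa APL feedback rate (1/s, per unit `x_apl`); set 0 to
#'   disable APL feedback.
#' @param i_max_kc maximal dendritic current (uA/cm^2).
#' @param apl_alpha per-KC-spike increment of the APL state.
#' @param apl_beta APL decay rate (1/s).
#' @param sigma_k KC spike-generator noise scale (0 in all characterizations).
#' @param v_init_jitter half-width (mV) of the uniform random offset applied
#'   to each KC's initial membrane voltage.  KCs wired to the same responding
#'   PNs receive identical drive; the seeded jitter desynchronizes them (as
#'   heterogeneous initial conditions do in vivo) without adding ongoing
#'   noise, so runs remain reproducible for a fixed seed.
#' @return list of class `calyx_params`.
#' @export
calyx_params <- function(kcd_alpha = 0.1, kcd_beta = 4, kcd_kappa = 120,
                         i_max_kc = 14, apl_alpha = 5e-4, apl_beta = 10,
                         sigma_k = 0, v_init_jitter = 2) {
  stopifnot(kcd_alpha >= 0, kcd_alpha <= 1, kcd_beta >= 0, kcd_kappa >= 0,
            i_max_kc >= 0, apl_alpha >= 0, apl_alpha <= 1, apl_beta >= 0,
            sigma_k >= 0, v_init_jitter >= 0)
  structure(list(kcd_alpha = kcd_alpha, kcd_beta = kcd_beta,
                 kcd_kappa = kcd_kappa, i_max_kc = i_max_kc,
                 apl_alpha = apl_alpha, apl_beta = apl_beta,
                 sigma_k = sigma_k, v_init_jitter = v_init_jitter),
            class = "calyx_params")
}

#' Sample a random PN-to-KC bipartite graph
#'
#' Every KC receives exactly `q` distinct PN inputs drawn uniformly without
#' replacement, independently across KCs (the "claw" wiring, random and
#' fly-specific).
#'
#' @param n_pn number of projection neurons `R`.
#' @param n_kc number of Kenyon cells `M`.
#' @param q PN inputs (claws) per KC, `1 <= q <= R`.
#' @param seed integer seed; the same arguments always yield the same graph.
#' @return An object of class `pn_kc_graph`: an `M x Q` integer matrix of
#'   1-based PN indices with attributes `n_pn`, `q`, `seed`.
#' @export
sample_pn_kc_graph <- function(n_pn, n_kc, q, seed = 1) {
  stopifnot(n_kc >= 1, n_pn >= 1)
  if (q < 1 || q > n_pn)
    stop("invalid Q: need 1 <= Q <= R (got Q=", q, ", R=", n_pn, ")")
  g <- with_seed(seed, t(vapply(seq_len(n_kc), function(m)
    sort(sample.int(n_pn, q)), integer(q))))
  if (q == 1) g <- matrix(g, ncol = 1)
  structure(g, class = c("pn_kc_graph", "matrix"),
            n_pn = n_pn, q = q, seed = seed)
}

#' @export
print.pn_kc_graph <- function(x, ...) {
  cat("<pn_kc_graph>", nrow(x), "KCs x", attr(x, "q"), "claws |",
      attr(x, "n_pn"), "PNs | seed", attr(x, "seed"), "\n")
  invisible(x)
}

#' Write / read a PN-KC graph as an edge-list CSV
#'
#' @param g a `pn_kc_graph`.
#' @param path CSV file (columns `kc_id`, `pn_id`).
#' @export
write_graph_csv <- function(g, path) {
  df <- data.frame(kc_id = rep(seq_len(nrow(g)), each = ncol(g)),
                   pn_id = as.vector(t(unclass(g))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' One event step of a KC dendrite
#'
#' PN spikes apply `x <- x + kcd_alpha (1 - x)` each; between events the
#' state decays at rate `kcd_beta + kcd_kappa * x_apl`.
#'
#' @param x dendritic state in `[0, 1]`.
#' @param pn_spikes number of PN spikes arriving in this step.
#' @param x_apl current APL state.
#' @param params `calyx_params`.
#' @param dt step (s).
#' @return updated state.
#' @export
kc_dendrite_step <- function(x, pn_spikes, x_apl, params = calyx_params(),
                             dt) {
  stopifnot(x >= 0, x <= 1, x_apl >= 0, x_apl <= 1)
  x <- x * exp(-(params$kcd_beta + params$kcd_kappa * x_apl) * dt)
  if (pn_spikes > 0)
    x <- 1 - (1 - x) * (1 - params$kcd_alpha)^pn_spikes
  if (x < -1e-9 || x > 1 + 1e-9) stop("KC dendrite state left [0,1]")
  x
}

#' One event step of the APL feedback state
#'
#' Every KC spike applies `x <- x + apl_alpha (1 - x)`; the state decays at
#' `apl_beta` between events.
#'
#' @param x APL state in `[0, 1]`.
#' @param kc_spikes total number of KC spikes in this step.
#' @param params `calyx_params`.
#' @param dt step (s).
#' @return updated state.
#' @export
apl_step <- function(x, kc_spikes, params = calyx_params(), dt) {
  stopifnot(x >= 0, x <= 1)
  x <- x * exp(-params$apl_beta * dt)
  if (kc_spikes > 0)
    x <- 1 - (1 - x) * (1 - params$apl_alpha)^kc_spikes
  x
}

#' Simulate the calyx circuit
#'
#' Closed loop of KC dendrites, KC spike generators and the APL feedback
#' neuron on the PN spike trains.
#'
#' @param pn_spikes a `spike_train_set` of PN outputs (one per channel).
#' @param graph a `pn_kc_graph` whose `n_pn` matches `pn_spikes`.
#' @param params `calyx_params`.
#' @param cs `cs_params` of the KC spike generators.
#' @param t_total horizon (s); defaults to the horizon of `pn_spikes`.
#' @param dt step (s).
#' @param seed RNG seed (noise only; the default `sigma_k = 0` run is
#'   deterministic).
#' @param steady_window `c(from, to)` (s) over which the steady-state
#'   dendritic output is averaged; defaults to the last 40% of the horizon.
#' @param trace_stride decimation of the `x_kcd` and `x_apl` traces.
#' @param bsg simulate the KC spike generators (default).  `FALSE` runs the
#'   dendrites only — valid when the APL loop is open (`kcd_kappa = 0`),
#'   where the dendritic states do not depend on KC spiking.
#' @return list with `kc` (a `spike_train_set` of `M` neurons), decimated
#'   `x_kcd` (time x KC) and `x_apl` traces, and `x_kcd_steady` (per-KC mean
#'   over `steady_window`).
#' @export
run_calyx <- function(pn_spikes, graph, params = calyx_params(),
                      cs = cs_params(), t_total = NULL, dt = 1e-5,
                      seed = NULL, steady_window = NULL, trace_stride = 20L,
                      bsg = TRUE) {
  stopifnot(inherits(pn_spikes, "spike_train_set"),
            inherits(graph, "pn_kc_graph"))
  if (!bsg && params$kcd_kappa != 0)
    stop("bsg = FALSE requires kcd_kappa = 0 (open APL loop)")
  if (attr(graph, "n_pn") != length(pn_spikes))
    stop("graph wires ", attr(graph, "n_pn"), " PNs but ", length(pn_spikes),
         " PN trains were supplied")
  t_total <- t_total %||% attr(pn_spikes, "t_end")
  n <- round(t_total / dt)
  trace_stride <- max(as.integer(trace_stride), 1L)
  res <- with_seed(seed,
                   cpp_calyx_run(unclass(pn_spikes),
                                 matrix(as.integer(unclass(graph)), nrow(graph)),
                                 as.integer(n), dt, params, cs,
                                 as.integer(trace_stride), bsg))
  if (is.null(steady_window)) steady_window <- c(0.6 * t_total, t_total)
  tr_t <- (seq_len(nrow(res$x_kcd)) - 1) * trace_stride * dt
  sel <- tr_t >= steady_window[1] & tr_t < steady_window[2]
  list(kc = spike_train_set(res$kc_spikes, "kc", t_total),
       x_kcd = res$x_kcd, x_apl = res$x_apl,
       x_kcd_steady = colMeans(res$x_kcd[sel, , drop = FALSE]),
       trace_times = tr_t)
}
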