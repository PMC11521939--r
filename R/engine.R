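#' Simulation configuration
#'
#' Assembles and validates the full configuration of an end-to-end run:
#' circuit sizes, clock, stimulus protocol, odorant declarations and all
#' module parameter blocks.  Defaults follow the reference protocol: 0.3 s
#' silence, a 1.0 s odor step, 0.2 s offset tail, `dt = 1e-5` s, `R = 23`
#' receptors, `M = 500` KCs with `Q = 6` claws.
#'
#' @param n_receptors number of receptor types / AL channels `R`.
#' @param n_kc number of Kenyon cells `M`.
#' @param q PN inputs per KC.
#' @param dt integration step (s), shared by kinetics and spike generators.
#' @param t_total simulation horizon (s); must exceed the stimulus offset.
#' @param stimulus list with `t_on`, `t_off` (s).
#' @param odorants list of mixture components; each component is a list with
#'   either `profile` (`"sparse"`/`"broad"`), `k`, `seed` for a synthetic
#'   affinity profile, or an explicit `tensor` (`affinity_tensor`), plus
#'   `amplitude` (ppm).
#' @param threshold KC activity threshold on the steady dendritic output.
#' @param seeds list with independent `graph` (wiring) and `noise` streams.
#' @param otp,al,calyx,cs module parameter blocks.
#' @param trace_stride decimation of stored state traces.
#' @return list of class `oem_config`.
#' @export
oem_config <- function(n_receptors = 23, n_kc = 500, q = 6, dt = 1e-5,
                       t_total = 1.5,
                       stimulus = list(t_on = 0.3, t_off = 1.3),
                       odorants = list(list(profile = "sparse", k = 1,
                                            seed = 7, amplitude = 100)),
                       threshold = 0.5,
                       seeds = list(graph = 1, noise = 1),
                       otp = otp_params(), al = al_params(),
                       calyx = calyx_params(), cs = cs_params(),
                       trace_stride = 20L) {
  cfg <- structure(list(n_receptors = n_receptors, n_kc = n_kc, q = q,
                        dt = dt, t_total = t_total, stimulus = stimulus,
                        odorants = odorants, threshold = threshold,
                        seeds = seeds, otp = otp, al = al, calyx = calyx,
                        cs = cs, trace_stride = as.integer(trace_stride)),
                   class = "oem_config")
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks field by field, raising errors that name the offending field path.
#'
#' @param cfg an `oem_config` (or plain list with the same fields).
#' @return the configuration, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  fail <- function(path, msg) stop("config error at ", path, ": ", msg,
                                   call. = FALSE)
  if (!is.numeric(cfg$dt) || cfg$dt <= 0) fail("dt", "must be > 0")
  if (cfg$dt > 2e-5 + 1e-12) fail("dt", "must be <= 2e-5 s for stability")
  if (cfg$n_receptors < 1) fail("n_receptors", "must be >= 1")
  if (cfg$n_kc < 1) fail("n_kc", "must be >= 1")
  if (cfg$q < 1 || cfg$q > cfg$n_receptors)
    fail("q", paste0("need 1 <= Q <= R (Q=", cfg$q, ", R=", cfg$n_receptors, ")"))
  st <- cfg$stimulus
  if (is.null(st$t_on) || is.null(st$t_off) || st$t_on >= st$t_off)
    fail("stimulus", "needs t_on < t_off")
  if (cfg$t_total <= st$t_off)
    fail("t_total", "must exceed stimulus$t_off")
  if (length(cfg$odorants) < 1) fail("odorants", "at least one component")
  for (i in seq_along(cfg$odorants)) {
    od <- cfg$odorants[[i]]
    path <- paste0("odorants[[", i, "]]")
    if (is.null(od$tensor) && is.null(od$profile))
      fail(path, "needs a synthetic `profile` or an explicit `tensor`")
    if (!is.null(od$profile) && !grepl("^(sparse(-[0-9]+)?|broad)$", od$profile))
      fail(paste0(path, "$profile"), "must be 'sparse', 'sparse-k' or 'broad'")
    if (is.null(od$amplitude) || od$amplitude < 0)
      fail(paste0(path, "$amplitude"), "needs a non-negative ppm amplitude")
  }
  if (cfg$threshold <= 0 || cfg$threshold >= 1)
    fail("threshold", "must lie in (0, 1)")
  if (is.null(cfg$seeds$graph) || is.null(cfg$seeds$noise))
    fail("seeds", "needs both `graph` and `noise`")
  invisible(cfg)
}

#' Read a configuration from YAML
#'
#' Scalar fields override the defaults of [oem_config()]; parameter blocks
#' (`otp`, `al`, `calyx`, `cs`) are merged entry-wise into the default
#' blocks.
#'
#' @param path YAML file.
#' @return validated `oem_config`.
#' @export
read_oem_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (f in c("n_receptors", "n_kc", "q", "dt", "t_total", "threshold",
              "trace_stride"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  if (!is.null(y$stimulus)) args$stimulus <- y$stimulus
  if (!is.null(y$odorants)) args$odorants <- y$odorants
  if (!is.null(y$seeds)) args$seeds <- y$seeds
  for (blk in c("otp", "al", "calyx", "cs")) {
    if (!is.null(y[[blk]])) {
      ctor <- switch(blk, otp = otp_params, al = al_params,
                     calyx = calyx_params, cs = cs_params)
      args[[blk]] <- do.call(ctor, y[[blk]])
    }
  }
  do.call(oem_config, args)
}

# Hash of the configuration for provenance stamping.
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f)
  unname(tools::md5sum(f))
}

# Materialize the odorant_set declared by a config; amplitude overrides allow
# the sweep experiments to rescale components without rebuilding profiles.
config_odorant_set <- function(cfg, amplitudes = NULL) {
  comps <- lapply(cfg$odorants, function(od) {
    if (!is.null(od$tensor)) od$tensor
    else synth_affinity_profile(cfg$n_receptors, od$profile,
                                k = od$k %||% 1L, seed = od$seed %||% 1L)
  })
  amps <- amplitudes %||% vapply(cfg$odorants, function(od) od$amplitude, 1)
  make_mixture(comps, amps, t_on = cfg$stimulus$t_on,
               t_off = cfg$stimulus$t_off)
}

# Steady-state sampling window: the trailing part of the odor step (up to the
# last 0.5 s, never more than half of the step).
steady_window <- function(cfg) {
  dur <- cfg$stimulus$t_off - cfg$stimulus$t_on
  c(cfg$stimulus$t_off - min(0.5, dur / 2), cfg$stimulus$t_off)
}

#' Run the full odorant-encoding cascade
#'
#' Antenna (transduction + OSN spiking) -> antennal lobe -> calyx ->
#' readouts, on one shared clock, deterministic when all noise scales are 0.
#'
#' @param cfg an `oem_config`.
#' @param graph optional `pn_kc_graph` to reuse across runs; defaults to a
#'   graph drawn with `cfg$seeds$graph`.
#' @param odorants optional `odorant_set` overriding the config declaration.
#' @return An object of class `oem_result`: spike trains of every population,
#'   steady OSN/PN rates, steady dendritic outputs `x_kcd_steady`, per-KC
#'   aggregate PN input `kc_input`, rank curves, the active set, the
#'   first-spike sequence with its cumulative ISI curve, and provenance
#'   (config hash, seeds, package version).
#' @export
run_oem <- function(cfg, graph = NULL, odorants = NULL) {
  validate_config(cfg)
  odorants <- odorants %||% config_odorant_set(cfg)
  graph <- graph %||% sample_pn_kc_graph(cfg$n_receptors, cfg$n_kc, cfg$q,
                                         seed = cfg$seeds$graph)
  win <- steady_window(cfg)
  ant <- run_antenna(odorants, cfg$otp, cfg$cs, t_total = cfg$t_total,
                     dt = cfg$dt, seed = cfg$seeds$noise,
                     trace_stride = cfg$trace_stride)
  al <- run_al(ant$spikes, cfg$al, cfg$cs, t_total = cfg$t_total,
               dt = cfg$dt, seed = cfg$seeds$noise + 1L,
               trace_stride = cfg$trace_stride)
  cal <- run_calyx(al$pn, graph, cfg$calyx, cfg$cs, t_total = cfg$t_total,
                   dt = cfg$dt, seed = cfg$seeds$noise + 2L,
                   steady_window = win, trace_stride = cfg$trace_stride)
  osn_rates <- firing_rates(ant$spikes, win)
  pn_rates <- firing_rates(al$pn, win)
  kc_input <- as.numeric(matrix(pn_rates[unclass(graph)], nrow(graph)) %*%
                           rep(1, ncol(graph)))
  active <- active_set(cal$x_kcd_steady, cfg$threshold)
  seq <- suppressWarnings(
    first_spike_sequence(cal$kc, active, t0 = cfg$stimulus$t_on))
  structure(list(
    osn = ant$spikes, pn = al$pn, kc = cal$kc,
    preln_spikes = al$preln_spikes, eln = al$eln, iln = al$iln,
    osn_rates = osn_rates, pn_rates = pn_rates,
    kc_input = kc_input, x_kcd_steady = cal$x_kcd_steady,
    x_apl = cal$x_apl, x_axt = al$x_axt,
    input_rank = rank_curve(kc_input),
    output_rank = rank_curve(cal$x_kcd_steady),
    active = active, sequence = seq,
    cumulative_isi = if (nrow(seq)) cumulative_isi(seq) else numeric(0),
    graph = graph, steady_window = win,
    provenance = list(config_hash = config_hash(cfg), seeds = cfg$seeds,
                      version = as.character(utils::packageVersion("oemsim")))),
    class = "oem_result")
}

#' @export
print.oem_result <- function(x, ...) {
  cat("<oem_result>\n",
      " OSN channels:", length(x$osn), "| mean steady rate",
      signif(mean(x$osn_rates), 3), "Hz\n",
      " PN  channels:", length(x$pn), "| mean steady rate",
      signif(mean(x$pn_rates), 3), "Hz\n",
      " KCs:", length(x$kc), "| active:", length(x$active),
      sprintf("(%.1f%%)", 100 * length(x$active) / length(x$kc)), "\n",
      " first-spike sequence length:", nrow(x$sequence), "\n",
      " config:", x$provenance$config_hash, "\n")
  invisible(x)
}

#' Concentration sweep of a pure or mixture odorant
#'
#' Re-runs the cascade at each concentration level (component amplitudes are
#' scaled proportionally so the mixture ratio is preserved) and summarizes
#' the concentration dependence at every stage, including an APL-off control
#' (`kcd_kappa = 0`) on the same wiring.
#'
#' @param cfg an `oem_config`.
#' @param levels concentration levels (ppm) applied to the first component.
#' @param apl_off_control also run the calyx with APL feedback disabled.
#' @return list of class `concentration_sweep`: per-level `oem_result`s
#'   (`runs`), the APL-off steady outputs (`x_kcd_off`), and a `summary`
#'   with per-stage coefficients of variation across levels
#'   (`cv_osn`, `cv_pn`, `cv_kcd_on`, `cv_kcd_off`).
#' @export
experiment_concentration_sweep <- function(cfg, levels = c(50, 100, 150, 200),
                                           apl_off_control = TRUE) {
  stopifnot(length(levels) >= 2)
  base_amp <- vapply(cfg$odorants, function(od) od$amplitude, 1)
  graph <- sample_pn_kc_graph(cfg$n_receptors, cfg$n_kc, cfg$q,
                              seed = cfg$seeds$graph)
  runs <- list()
  x_off <- list()
  cfg_off <- cfg
  cfg_off$calyx$kcd_kappa <- 0
  for (lv in levels) {
    amps <- base_amp / base_amp[1] * lv
    ods <- config_odorant_set(cfg, amplitudes = amps)
    res <- run_oem(cfg, graph = graph, odorants = ods)
    runs[[as.character(lv)]] <- res
    if (apl_off_control) {
      off <- run_calyx(res$pn, graph, cfg_off$calyx, cfg$cs,
                       t_total = cfg$t_total, dt = cfg$dt,
                       steady_window = steady_window(cfg),
                       trace_stride = cfg$trace_stride, bsg = FALSE)
      x_off[[as.character(lv)]] <- off$x_kcd_steady
    }
  }
  structure(list(levels = levels, runs = runs, x_kcd_off = x_off,
                 summary = sweep_cv_summary(runs, x_off, cfg$threshold)),
            class = "concentration_sweep")
}

# Coefficient of variation across concentration levels, per unit.  OSN and
# PN CVs are compared over the same channel set (channels whose OSN response
# exceeds rate_floor at every level, i.e. the odorant's responding channels);
# the dendritic CVs over KCs supra-threshold at every level with APL on.
sweep_cv_summary <- function(runs, x_off, threshold, rate_floor = 5) {
  cv <- function(m) {
    mu <- rowMeans(m)
    sdv <- apply(m, 1, stats::sd)
    list(mu = mu, cv = ifelse(mu > 0, sdv / mu, NA_real_))
  }
  osn_m <- vapply(runs, function(r) r$osn_rates, runs[[1]]$osn_rates)
  pn_m <- vapply(runs, function(r) r$pn_rates, runs[[1]]$pn_rates)
  resp <- rowSums(osn_m > rate_floor) == ncol(osn_m)
  kcd_on <- vapply(runs, function(r) r$x_kcd_steady, runs[[1]]$x_kcd_steady)
  supra <- rowSums(kcd_on > threshold) == ncol(kcd_on)
  out <- list(cv_osn = mean(cv(osn_m[resp, , drop = FALSE])$cv),
              cv_pn = mean(cv(pn_m[resp, , drop = FALSE])$cv),
              n_responsive = sum(resp), n_supra = sum(supra))
  if (any(supra)) {
    on_cv <- cv(kcd_on[supra, , drop = FALSE])$cv
    out$cv_kcd_on <- mean(on_cv)
    if (length(x_off)) {
      kcd_off <- vapply(x_off, identity, x_off[[1]])
      out$cv_kcd_off <- mean(cv(kcd_off[supra, , drop = FALSE])$cv)
    }
  }
  out
}

#' Claw-count (Q) sweep
#'
#' Re-runs the calyx with different numbers of PN inputs per KC on the same
#' antenna/AL responses, reporting the dendritic-input rank curve per Q and
#' the empirical fraction of KCs wired to the dominant PN (expected Q/R for
#' uniform sampling without replacement).
#'
#' @param cfg an `oem_config`.
#' @param q_values claw counts to test (all `<= n_receptors`).
#' @return list of class `q_sweep` with per-Q entries: `input_rank`,
#'   `x_kcd_steady`, `active_fraction`, `dominant_fraction`.
#' @export
experiment_q_sweep <- function(cfg, q_values = c(3, 6, 9)) {
  stopifnot(all(q_values >= 1), all(q_values <= cfg$n_receptors))
  ods <- config_odorant_set(cfg)
  ant <- run_antenna(ods, cfg$otp, cfg$cs, t_total = cfg$t_total,
                     dt = cfg$dt, seed = cfg$seeds$noise,
                     trace_stride = cfg$trace_stride)
  al <- run_al(ant$spikes, cfg$al, cfg$cs, t_total = cfg$t_total, dt = cfg$dt,
               seed = cfg$seeds$noise + 1L, trace_stride = cfg$trace_stride)
  win <- steady_window(cfg)
  pn_rates <- firing_rates(al$pn, win)
  dominant <- which.max(pn_rates)
  out <- list()
  for (q in q_values) {
    graph <- sample_pn_kc_graph(cfg$n_receptors, cfg$n_kc, q,
                                seed = cfg$seeds$graph)
    cal <- run_calyx(al$pn, graph, cfg$calyx, cfg$cs, t_total = cfg$t_total,
                     dt = cfg$dt, steady_window = win,
                     trace_stride = cfg$trace_stride)
    kc_input <- as.numeric(matrix(pn_rates[unclass(graph)], nrow(graph)) %*%
                             rep(1, q))
    out[[as.character(q)]] <- list(
      q = q, input_rank = rank_curve(kc_input),
      x_kcd_steady = cal$x_kcd_steady,
      active_fraction = length(active_set(cal$x_kcd_steady,
                                          cfg$threshold)) / cfg$n_kc,
      dominant_fraction = mean(apply(unclass(graph) == dominant, 1, any)))
  }
  structure(list(q_values = q_values, dominant_pn = dominant, results = out),
            class = "q_sweep")
}

#' Mixture-ratio sweep
#'
#' For a two-component mixture, sweeps the component ratio and, per ratio,
#' the total concentration, recording effective affinities, rates, rank
#' curves and first-spike sequences, and an invariance report grouped by
#' ratio (sequences should cluster by ratio, not by concentration).
#'
#' @param cfg an `oem_config` declaring exactly two components.
#' @param ratios first:second amplitude ratios (e.g. `c(4, 2, 1, 0.5, 0.25)`).
#' @param levels amplitudes of the first component (ppm).
#' @return list of class `mixture_sweep` with per-(ratio, level) summaries
#'   and the grouped `invariance_report`.
#' @export
experiment_mixture_sweep <- function(cfg, ratios = c(4, 2, 1, 0.5, 0.25),
                                     levels = c(50, 100, 150, 200)) {
  if (length(cfg$odorants) != 2)
    stop("mixture sweep needs a two-component mixture in the config")
  graph <- sample_pn_kc_graph(cfg$n_receptors, cfg$n_kc, cfg$q,
                              seed = cfg$seeds$graph)
  cells <- list()
  seq_runs <- list()
  for (rt in ratios) {
    for (lv in levels) {
      amps <- c(lv, lv / rt)
      ods <- config_odorant_set(cfg, amplitudes = amps)
      a <- affinity(ods$tensor)
      a_eff <- vapply(seq_len(dim(a)[2]), function(r)
        effective_affinity(a[, r, 1], amps), 1)
      res <- run_oem(cfg, graph = graph, odorants = ods)
      key <- paste0(rt, "@", lv)
      cells[[key]] <- list(ratio = rt, level = lv, amplitudes = amps,
                           effective_affinity = a_eff,
                           osn_rates = res$osn_rates, pn_rates = res$pn_rates,
                           input_rank = res$input_rank,
                           output_rank = res$output_rank,
                           sequence = res$sequence)
      seq_runs[[key]] <- list(label = as.character(rt), concentration = lv,
                              seq = res$sequence)
    }
  }
  structure(list(ratios = ratios, levels = levels, cells = cells,
                 invariance = invariance_report(seq_runs)),
            class = "mixture_sweep")
}
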