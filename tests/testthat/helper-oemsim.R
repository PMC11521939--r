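# Shared helpers: small configurations and synthetic spike trains.

# Short stimulus protocol used throughout the tests: 0.1 s silence, 0.6 s
# odor step, 0.1 s tail, dt = 2e-5 s.
quick_cfg <- function(odorants, n_kc = 500, q = 6, graph_seed = 1,
                      noise_seed = 1, threshold = 0.5) {
  oem_config(n_receptors = 23, n_kc = n_kc, q = q, dt = 2e-5, t_total = 0.8,
             stimulus = list(t_on = 0.1, t_off = 0.7), odorants = odorants,
             threshold = threshold,
             seeds = list(graph = graph_seed, noise = noise_seed))
}

synthetic_odorant <- function(profile, k, seed, amplitude = 100) {
  list(list(profile = profile, k = k, seed = seed, amplitude = amplitude))
}

# Homogeneous Poisson spike train on [0, t_total].
poisson_train <- function(rate, t_total, seed) {
  with_seed(seed, sort(runif(rpois(1, rate * t_total), 0, t_total)))
}

# Regular (evenly spaced) spike train at the given rate with a phase offset.
regular_train <- function(rate, t_total, phase = 0) {
  s <- seq(phase + 1 / rate / 2, t_total, by = 1 / rate)
  s[s > 0 & s <= t_total]
}

# Mean coefficient of variation across the columns of a matrix (rows = units,
# columns = conditions).
mean_cv <- function(m) {
  mean(apply(m, 1, stats::sd) / rowMeans(m))
}

# Spearman correlation between aggregate drive and steady output, computed on
# drive-class representatives: KCs sharing a drive value must share the same
# output (else the value is ambiguous and dropped), and representatives whose
# drives are closer than min_sep (relative) are excluded, since sub-resolution
# timing differences are not ranked by the drive.
class_spearman <- function(drive, x, min_sep = 0.02, tol = 1e-9) {
  vals <- sort(unique(drive))
  rep_x <- vapply(vals, function(v) {
    xs <- x[abs(drive - v) < tol]
    if (max(xs) - min(xs) > tol) NA_real_ else xs[1]
  }, 1)
  keep <- !is.na(rep_x)
  vals <- vals[keep]; rep_x <- rep_x[keep]
  sep <- c(TRUE, diff(vals) / pmax(vals[-1], 1e-12) >= min_sep) &
    c(diff(vals) / pmax(vals[-1], 1e-12) >= min_sep, TRUE)
  stats::cor(vals[sep], rep_x[sep], method = "spearman")
}

with_seed <- oemsim:::with_seed
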