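#' Odorant affinity tensors
#'
#' An odorant is identified (its *semantics*) by per-receptor binding and
#' dissociation rates; its concentration waveform (*syntax*) is carried
#' separately.  `affinity_tensor` stores binding rates `b[o, r, n]`
#' (1/(ppm s)) and dissociation rates `d[o, r, n]` (1/s) for `O` odorants,
#' `R` receptor types and `N` sensory neurons per type.  The affinity is
#' `a = b / d` (1/ppm).
#'
#' @param b,d numeric arrays of identical dimension `c(O, R, N)` (matrices and
#'   vectors are promoted: a vector is one odorant over `R` receptors, `N = 1`).
#' @return An object of class `affinity_tensor` (list with `b` and `d`).
#' @export
affinity_tensor <- function(b, d) {
  promote <- function(x) {
    if (is.null(dim(x))) x <- array(x, dim = c(1, length(x), 1))
    if (length(dim(x)) == 2) x <- array(x, dim = c(dim(x), 1))
    x
  }
  b <- promote(b); d <- promote(d)
  if (!identical(dim(b), dim(d)))
    stop("binding and dissociation tensors must have identical dimensions")
  if (!all(is.finite(b)) || !all(is.finite(d)))
    stop("affinity tensors must be finite")
  if (any(b < 0) || any(d < 0))
    stop("rates must be non-negative")
  if (any(b > 0 & d == 0))
    stop("dissociation rate must be positive wherever binding rate is positive")
  structure(list(b = b, d = d), class = "affinity_tensor")
}

#' @export
print.affinity_tensor <- function(x, ...) {
  dm <- dim(x$b)
  cat("<affinity_tensor>", dm[1], "odorant(s) x", dm[2], "receptor(s) x",
      dm[3], "OSN(s)/type\n")
  invisible(x)
}

#' Affinity a = b / d of an affinity tensor
#'
#' Entries with zero binding rate have affinity 0 regardless of `d`.
#'
#' @param x an `affinity_tensor`.
#' @return numeric array `O x R x N` of affinities (1/ppm).
#' @export
affinity <- function(x) {
  stopifnot(inherits(x, "affinity_tensor"))
  a <- x$b / x$d
  a[x$b == 0] <- 0
  a
}

#' Display-normalized affinity vector
#'
#' Divides each receptor's affinity by the sum across receptors so the
#' normalized profile sums to one (the convention used for affinity rank
#' plots).
#'
#' @param x an `affinity_tensor` with a single odorant.
#' @param osn OSN index (default 1).
#' @return numeric vector over receptors summing to 1.
#' @export
normalized_affinity <- function(x, osn = 1) {
  a <- affinity(x)
  stopifnot(dim(a)[1] == 1)
  v <- a[1, , osn]
  v / sum(v)
}

#' Generate a synthetic per-receptor affinity profile
#'
#' Emulates the two tuning regimes observed across real odorants: a single (or
#' a few) dominant receptor(s) ("sparse", like acetone with one strongly
#' responding channel) versus broad tuning across many receptors (like ethyl
#' butyrate).  For sparse profiles, `k` randomly chosen receptors receive
#' comparable dominant affinities drawn log-uniform in `[0.007, 0.016]` per
#' ppm; the remaining receptors form a geometrically decaying, jittered
#' "shoulder" (as in measured affinity rank profiles), rescaled downward if
#' needed so the dominant receptors jointly carry 85% of the summed affinity
#' (hence exactly `k` receptors carry at least 80%).  Broad profiles draw
#' every receptor log-uniform in `[1e-4, 1e-2]`.  The magnitudes place the
#' responsive receptors' `a * u` around the half-saturation of the binding
#' equilibrium over the 50-200 ppm range, where concentration sensitivity is
#' maximal.
#'
#' @param n_receptors number of receptor types `R`.
#' @param profile `"sparse"` (uses `k`) or `"broad"`.  The strings
#'   `"sparse-1"`, `"sparse-3"`, ... are accepted as shorthand for
#'   `profile = "sparse"` with the trailing integer as `k`.
#' @param k number of dominant receptors for sparse profiles (`1 <= k <= R`).
#' @param seed integer seed; the same `(R, profile, k, seed)` always yields
#'   the same tensor.
#' @param d_rate dissociation rate applied to every entry (1/s).
#' @return An `affinity_tensor` with one odorant and one OSN per type.
#' @export
synth_affinity_profile <- function(n_receptors, profile = c("sparse", "broad"),
                                   k = 1, seed = 1, d_rate = 10) {
  stopifnot(n_receptors >= 1)
  if (grepl("^sparse-[0-9]+$", profile[1])) {
    k <- as.integer(sub("^sparse-", "", profile[1]))
    profile <- "sparse"
  }
  profile <- match.arg(profile)
  if (profile == "sparse" && (k < 1 || k > n_receptors))
    stop("invalid profile: k must satisfy 1 <= k <= R (got k=", k,
         ", R=", n_receptors, ")")
  a <- with_seed(seed, {
    if (profile == "broad") {
      # broad tuning: many receptors bind appreciably
      10^runif(n_receptors, -4, -2)
    } else {
      # k comparable dominant receptors over a geometrically decaying,
      # jittered shoulder, as in measured descending affinity rank profiles
      dom <- sample.int(n_receptors, k)
      a <- numeric(n_receptors)
      a[dom] <- 10^runif(k, -2.15, -1.8)
      n_tail <- n_receptors - k
      if (n_tail > 0) {
        tail_a <- 0.15 * mean(a[dom]) * 0.4^(seq_len(n_tail) - 1) *
          10^rnorm(n_tail, 0, 0.15)
        a[-dom] <- sample(tail_a)
        frac <- sum(a[dom]) / sum(a)
        if (frac < 0.85)
          a[-dom] <- a[-dom] * (sum(a[dom]) * 0.15 / 0.85) / sum(a[-dom])
      }
      a
    }
  })
  affinity_tensor(b = a * d_rate, d = rep(d_rate, n_receptors))
}

#' Rectangular concentration waveform
#'
#' `u(t) = amplitude` on `[t_on, t_off)` and 0 elsewhere.
#'
#' @param amplitude concentration in ppm (must be >= 0).
#' @param t_on,t_off onset/offset times in seconds, `t_on < t_off`.
#' @return An object of class `conc_waveform`.
#' @export
step_waveform <- function(amplitude, t_on, t_off) {
  if (amplitude < 0) stop("amplitude must be non-negative (ppm)")
  if (!(t_on < t_off)) stop("t_on must be earlier than t_off")
  structure(list(segments = data.frame(t_on = t_on, t_off = t_off,
                                       amplitude = amplitude)),
            class = "conc_waveform")
}

#' Evaluate a concentration waveform
#'
#' @param w a `conc_waveform`.
#' @param t numeric vector of times (s).
#' @return concentrations in ppm.
#' @export
eval_waveform <- function(w, t) {
  stopifnot(inherits(w, "conc_waveform"))
  out <- numeric(length(t))
  for (i in seq_len(nrow(w$segments))) {
    seg <- w$segments[i, ]
    out <- out + ifelse(t >= seg$t_on & t < seg$t_off, seg$amplitude, 0)
  }
  out
}

# Sample a waveform on the simulation grid (n steps of dt, left endpoints).
sample_waveform <- function(w, n_steps, dt) {
  eval_waveform(w, (seq_len(n_steps) - 1) * dt)
}

#' Assemble an odorant set (pure odorant or mixture)
#'
#' Combines single-odorant affinity tensors and per-component step amplitudes
#' into one odorant set with a shared stimulus window.  A single component is
#' the pure-odorant case.
#'
#' @param components list of `affinity_tensor`s, each with one odorant, all
#'   with the same number of receptors.
#' @param amplitudes numeric vector of step amplitudes (ppm), one per
#'   component.
#' @param t_on,t_off stimulus window (s).
#' @return An object of class `odorant_set` holding the combined
#'   `affinity_tensor`, the per-component waveforms, and a ratio label such
#'   as `"4:1"`.
#' @export
make_mixture <- function(components, amplitudes, t_on = 0.3, t_off = 1.3) {
  stopifnot(length(components) >= 1, length(amplitudes) == length(components))
  dims <- lapply(components, function(x) dim(x$b))
  if (!all(vapply(dims, function(d) identical(d[2:3], dims[[1]][2:3]), TRUE)))
    stop("all components must share the same receptor/OSN dimensions")
  if (!all(vapply(dims, function(d) d[1] == 1L, TRUE)))
    stop("each component must be a single odorant")
  nr <- dims[[1]][2]; nn <- dims[[1]][3]
  O <- length(components)
  b <- array(0, c(O, nr, nn)); d <- array(0, c(O, nr, nn))
  for (o in seq_len(O)) {
    b[o, , ] <- components[[o]]$b[1, , ]
    d[o, , ] <- components[[o]]$d[1, , ]
  }
  waveforms <- lapply(amplitudes, step_waveform, t_on = t_on, t_off = t_off)
  ratio <- if (any(amplitudes > 0))
    paste(round(amplitudes / min(amplitudes[amplitudes > 0]), 3),
          collapse = ":")
  else paste(rep("0", length(amplitudes)), collapse = ":")
  structure(list(tensor = affinity_tensor(b, d), waveforms = waveforms,
                 amplitudes = amplitudes, t_on = t_on, t_off = t_off,
                 ratio = ratio),
            class = "odorant_set")
}

#' @export
print.odorant_set <- function(x, ...) {
  dm <- dim(x$tensor$b)
  cat("<odorant_set>", dm[1], "component(s),", dm[2], "receptors | amplitudes:",
      paste(x$amplitudes, collapse = ", "), "ppm | window: [", x$t_on, ",",
      x$t_off, ") s\n")
  invisible(x)
}

#' Write / read affinity tensors as CSV
#'
#' Long format with columns `odorant_id, receptor_id, osn_id, b, d`.
#'
#' @param x an `affinity_tensor`.
#' @param path CSV file path.
#' @export
write_affinity_csv <- function(x, path) {
  stopifnot(inherits(x, "affinity_tensor"))
  dm <- dim(x$b)
  idx <- expand.grid(odorant_id = seq_len(dm[1]), receptor_id = seq_len(dm[2]),
                     osn_id = seq_len(dm[3]))
  idx$b <- as.vector(x$b); idx$d <- as.vector(x$d)
  write.csv(idx, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_affinity_csv
#' @export
read_affinity_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("odorant_id", "receptor_id", "osn_id", "b", "d") %in% names(df)))
  O <- max(df$odorant_id); R <- max(df$receptor_id); N <- max(df$osn_id)
  b <- array(0, c(O, R, N)); d <- array(0, c(O, R, N))
  b[cbind(df$odorant_id, df$receptor_id, df$osn_id)] <- df$b
  d[cbind(df$odorant_id, df$receptor_id, df$osn_id)] <- df$d
  affinity_tensor(b, d)
}
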