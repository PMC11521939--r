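#' Spike train containers
#'
#' A `spike_train_set` holds the spike times of all neurons of one population
#' on a common clock: a list with one sorted numeric vector of spike times
#' (seconds) per neuron, tagged with the population name and the simulation
#' horizon.
#'
#' @param times list of numeric vectors, one per neuron, each sorted strictly
#'   increasing, all within `[0, t_end]`.
#' @param population character tag (e.g. `"osn"`, `"pn"`, `"kc"`).
#' @param t_end simulation horizon in seconds.
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(times, population, t_end) {
  stopifnot(is.list(times), is.character(population), t_end > 0)
  for (i in seq_along(times)) {
    tt <- times[[i]]
    if (length(tt)) {
      if (is.unsorted(tt, strictly = TRUE))
        stop("spike times of neuron ", i, " must be strictly increasing")
      if (min(tt) < 0 || max(tt) > t_end + 1e-12)
        stop("spike times of neuron ", i, " outside [0, t_end]")
    }
    times[[i]] <- as.numeric(tt)
  }
  structure(times, class = "spike_train_set",
            population = population, t_end = t_end)
}

#' @export
print.spike_train_set <- function(x, ...) {
  n_sp <- vapply(x, length, 1L)
  cat("<spike_train_set> population:", attr(x, "population"),
      "| neurons:", length(x),
      "| spikes:", sum(n_sp),
      "| T:", attr(x, "t_end"), "s\n")
  invisible(x)
}

#' @export
as.data.frame.spike_train_set <- function(x, ...) {
  n_sp <- vapply(x, length, 1L)
  data.frame(
    population = rep(attr(x, "population"), sum(n_sp)),
    neuron_id = rep(seq_along(x), n_sp),
    spike_time_s = unlist(x, use.names = FALSE)
  )
}

#' Mean firing rates of a spike-train set over a time window
#'
#' @param x a `spike_train_set`.
#' @param window numeric length-2, `c(from, to)` in seconds; defaults to the
#'   whole horizon.
#' @return numeric vector of rates (Hz), one per neuron.
#' @export
firing_rates <- function(x, window = NULL) {
  stopifnot(inherits(x, "spike_train_set"))
  if (is.null(window)) window <- c(0, attr(x, "t_end"))
  stopifnot(length(window) == 2, window[2] > window[1])
  vapply(x, function(tt) sum(tt >= window[1] & tt < window[2]), 1) /
    (window[2] - window[1])
}

#' Write spike trains to CSV (population, neuron_id, spike_time_s)
#'
#' @param x a `spike_train_set` or a list of them.
#' @param path output file.
#' @export
write_spikes_csv <- function(x, path) {
  if (inherits(x, "spike_train_set")) x <- list(x)
  df <- do.call(rbind, lapply(x, as.data.frame))
  df <- df[order(df$population, df$neuron_id, df$spike_time_s), ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read spike trains written by [write_spikes_csv()]
#'
#' @param path CSV file.
#' @param t_end simulation horizon (seconds) to stamp on the result.
#' @return named list of `spike_train_set`, one per population.
#' @export
read_spikes_csv <- function(path, t_end) {
  df <- read.csv(path)
  stopifnot(all(c("population", "neuron_id", "spike_time_s") %in% names(df)))
  out <- lapply(split(df, df$population), function(d) {
    n <- max(d$neuron_id)
    tt <- lapply(seq_len(n), function(i) sort(d$spike_time_s[d$neuron_id == i]))
    spike_train_set(tt, population = d$population[1], t_end = t_end)
  })
  out
}
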