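#' Rank curve of a response vector
#'
#' Stable descending sort, ties broken by ascending original index — the
#' standard presentation of KC dendritic inputs/outputs "in ranking order".
#'
#' @param values finite numeric vector.
#' @return An object of class `rank_curve`: list with `values` (descending)
#'   and `index` (original 1-based position of each rank).
#' @export
rank_curve <- function(values) {
  stopifnot(all(is.finite(values)))
  if (length(values) == 0)
    return(structure(list(values = numeric(0), index = integer(0)),
                     class = "rank_curve"))
  ord <- order(-values, seq_along(values))
  structure(list(values = values[ord], index = ord), class = "rank_curve")
}

#' @export
print.rank_curve <- function(x, ...) {
  cat("<rank_curve>", length(x$values), "entries; top:",
      paste(head(signif(x$values, 3), 5), collapse = ", "), "\n")
  invisible(x)
}

#' Relative gap statistic of a rank curve
#'
#' Sparse affinity profiles produce a visible cliff in the KC dendritic-input
#' rank curve (the jump between KCs wired to the dominant channel and the
#' rest), while broad profiles decay smoothly.  The statistic is the largest
#' adjacent-rank drop divided by the curve's total range: close to 1 when a
#' single cliff carries most of the range, small when the decline is spread
#' over many comparable steps.  It is well defined for curves with tied
#' values (tie plateaus contribute zero-size steps).
#'
#' @param rc a `rank_curve` (or numeric vector).
#' @return scalar in `[0, 1]` (`NA` for curves of fewer than 2 points or
#'   zero range).
#' @export
rank_gap_ratio <- function(rc) {
  v <- if (inherits(rc, "rank_curve")) rc$values else rank_curve(rc)$values
  d <- -diff(v)
  if (length(d) == 0 || max(v) == min(v)) return(NA_real_)
  max(d) / (max(v) - min(v))
}

#' Active Kenyon cells by dendritic-output threshold
#'
#' @param x_kcd steady-state dendritic outputs (one per KC).
#' @param threshold activity threshold in `(0, 1)`; 0.5 coincides with the
#'   KC spiking threshold under the default current calibration.
#' @return integer vector of active KC ids.
#' @export
active_set <- function(x_kcd, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  which(x_kcd > threshold)
}

#' First-spike sequence of the active KC population
#'
#' Takes the first spike (after `t0`) of each active KC and joins them, in
#' order of occurrence, into a single population sequence — the
#' concentration-invariant identity code read out downstream.  Active KCs
#' that never spike are dropped with a warning.
#'
#' @param kc_spikes a `spike_train_set` of KC outputs.
#' @param active integer ids of active KCs (see [active_set()]).
#' @param t0 alignment time (s), typically the stimulus onset; spikes before
#'   `t0` are ignored and reported times are relative to `t0`.
#' @return An object of class `first_spike_sequence`: data.frame with
#'   columns `kc` and `t` (s), sorted by `t`, ties broken by `kc`.
#' @export
first_spike_sequence <- function(kc_spikes, active, t0 = 0) {
  stopifnot(inherits(kc_spikes, "spike_train_set"))
  first <- vapply(active, function(m) {
    tt <- kc_spikes[[m]]
    tt <- tt[tt >= t0]
    if (length(tt)) tt[1] - t0 else NA_real_
  }, 1)
  silent <- is.na(first)
  if (any(silent))
    warning(sum(silent), " active KC(s) produced no spike and were dropped")
  df <- data.frame(kc = active[!silent], t = first[!silent])
  df <- df[order(df$t, df$kc), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("first_spike_sequence", "data.frame"))
}

#' @export
print.first_spike_sequence <- function(x, ...) {
  cat("<first_spike_sequence>", nrow(x), "active KCs")
  if (nrow(x)) cat("; span", signif(max(x$t) - min(x$t), 3), "s")
  cat("\n")
  print.data.frame(head(x, 10))
  invisible(x)
}

#' Cumulative interspike-interval curve of a first-spike sequence
#'
#' `curve[k] = t_k - t_1`: elapsed time from the first spike of the sequence
#' to each subsequent one.  These curves are largely concentration invariant.
#'
#' @param seq a `first_spike_sequence` with at least one entry.
#' @return non-decreasing numeric vector starting at 0.
#' @export
cumulative_isi <- function(seq) {
  stopifnot(inherits(seq, "first_spike_sequence"))
  if (nrow(seq) == 0) stop("cumulative ISI curve undefined for an empty sequence")
  seq$t - seq$t[1]
}

# Normalized Kendall-tau distance between two rankings (smaller rank =
# earlier spike; simultaneous first spikes share an average rank): distance
# = (1 - tau) / 2, which is the fraction of discordant pairs when both
# rankings are tie-free.
kendall_distance <- function(ra, rb) {
  if (length(ra) < 2) return(0)
  if (stats::var(ra) == 0 || stats::var(rb) == 0)
    return(if (stats::var(ra) == 0 && stats::var(rb) == 0) 0 else 0.5)
  (1 - cor(ra, rb, method = "kendall")) / 2
}

#' Distance between two first-spike sequences
#'
#' `set_overlap` is the Jaccard index of the two active-KC sets;
#' `order_distance` is the normalized Kendall-tau distance of the firing
#' orders restricted to the shared KCs (0 if fewer than 2 are shared).
#' Identical sequences give `(0, 1)`; a fully reversed order gives
#' `(1, 1)`.
#'
#' @param seq_a,seq_b `first_spike_sequence` objects.
#' @return list with `order_distance` and `set_overlap`, both in `[0, 1]`.
#' @export
sequence_distance <- function(seq_a, seq_b) {
  stopifnot(inherits(seq_a, "first_spike_sequence"),
            inherits(seq_b, "first_spike_sequence"))
  shared <- intersect(seq_a$kc, seq_b$kc)
  uni <- union(seq_a$kc, seq_b$kc)
  overlap <- if (length(uni) == 0) 1 else length(shared) / length(uni)
  if (length(shared) < 2)
    return(list(order_distance = 0, set_overlap = overlap))
  ra <- rank(seq_a$t[match(shared, seq_a$kc)])
  rb <- rank(seq_b$t[match(shared, seq_b$kc)])
  list(order_distance = kendall_distance(ra, rb), set_overlap = overlap)
}

#' Concentration-invariance summary of first-spike sequences
#'
#' Compares sequences recorded for several odorants at several
#' concentrations: mean pairwise order distance and set overlap *within* an
#' odorant (across concentrations) versus *between* odorants.  The identity
#' code is concentration invariant when the within-odorant order distance is
#' smaller than the between-odorant one.
#'
#' @param runs list of entries `list(label =, concentration =, seq =)`, at
#'   least 2 concentrations per label.
#' @return list of class `invariance_report` with `within`, `between`
#'   (data.frames of order distance and overlap) and logical `invariant`
#'   (`NA` if fewer than 2 odorants).
#' @export
invariance_report <- function(runs) {
  labels <- unname(vapply(runs, function(r) as.character(r$label), ""))
  if (any(table(labels) < 2))
    stop("need at least 2 concentrations per odorant label")
  pairs <- utils::combn(length(runs), 2)
  d <- apply(pairs, 2, function(ij) {
    sd <- sequence_distance(runs[[ij[1]]]$seq, runs[[ij[2]]]$seq)
    c(order = sd$order_distance, overlap = sd$set_overlap,
      within = labels[ij[1]] == labels[ij[2]])
  })
  within <- d[, d["within", ] == 1, drop = FALSE]
  between <- d[, d["within", ] == 0, drop = FALSE]
  summ <- function(m) if (ncol(m) == 0) NULL else
    data.frame(mean_order_distance = mean(m["order", ]),
               mean_set_overlap = mean(m["overlap", ]),
               n_pairs = ncol(m))
  res <- list(within = summ(within), between = summ(between))
  res$invariant <- if (is.null(res$between)) NA else
    res$within$mean_order_distance < res$between$mean_order_distance
  structure(res, class = "invariance_report")
}

#' @export
print.invariance_report <- function(x, ...) {
  cat("<invariance_report>\n  within-odorant : order",
      signif(x$within$mean_order_distance, 3), "| overlap",
      signif(x$within$mean_set_overlap, 3), "\n")
  if (!is.null(x$between))
    cat("  between-odorant: order", signif(x$between$mean_order_distance, 3),
        "| overlap", signif(x$between$mean_set_overlap, 3), "\n")
  else cat("  between-odorant: not available (single odorant)\n")
  cat("  concentration-invariant:", x$invariant, "\n")
  invisible(x)
}

#' Serialize a first-spike sequence to JSON
#'
#' Format: `[{"kc": id, "t": seconds}, ...]`.
#'
#' @param seq a `first_spike_sequence`.
#' @param path output file.
#' @export
write_sequence_json <- function(seq, path) {
  jsonlite::write_json(as.data.frame(unclass(seq)), path, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_sequence_json
#' @export
read_sequence_json <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  df <- df[order(df$t, df$kc), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("first_spike_sequence", "data.frame"))
}
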