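test_that("rank curves sort stably with index bookkeeping", {
  rc <- rank_curve(c(0.2, 0.9, 0.5))
  expect_equal(rc$values, c(0.9, 0.5, 0.2))
  expect_equal(rc$index, c(2L, 3L, 1L))

  const <- rank_curve(rep(1, 5))
  expect_equal(const$index, 1:5)   # stable tie-break by original index

  set.seed(3)
  v <- runif(100)
  expect_equal(rank_curve(v)$values, sort(v, decreasing = TRUE))

  empty <- rank_curve(numeric(0))
  expect_length(empty$values, 0)
})

test_that("the relative gap statistic flags single-cliff curves", {
  cliff <- c(rep(10, 5), rep(1, 20))
  smooth <- seq(10, 1, length.out = 25)
  expect_gt(rank_gap_ratio(cliff), 0.9)
  expect_lt(rank_gap_ratio(smooth), 0.1)
  expect_true(is.na(rank_gap_ratio(rep(2, 4))))
})

test_that("active sets respect the threshold and shrink as it rises", {
  expect_equal(active_set(c(0.6, 0.4), 0.5), 1L)
  expect_length(active_set(c(0.1, 0.2), 0.5), 0)
  x <- runif(200)
  sizes <- vapply(seq(0.05, 0.95, by = 0.1),
                  function(th) length(active_set(x, th)), 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("first-spike sequences order active KCs by spike latency", {
  # three deterministic neurons at decreasing drive: latency increases
  drives <- c(30, 15, 9.5)
  spikes <- lapply(drives, function(i)
    cs_run(rep(i, 2e4), dt = 2e-5)$spike_times)
  kc <- spike_train_set(spikes, "kc", 0.4)
  seq <- first_spike_sequence(kc, active = 1:3)
  expect_equal(seq$kc, c(1L, 2L, 3L))
  expect_true(all(diff(seq$t) > 0))

  expect_equal(nrow(first_spike_sequence(kc, integer(0))), 0L)
  expect_equal(nrow(first_spike_sequence(kc, 2L)), 1L)

  # an active KC without spikes is dropped with a warning
  kc2 <- spike_train_set(c(spikes, list(numeric(0))), "kc", 0.4)
  expect_warning(s2 <- first_spike_sequence(kc2, 1:4), "dropped")
  expect_equal(s2$kc, 1:3)

  # alignment at t0 subtracts the onset; earlier spikes are ignored
  s3 <- first_spike_sequence(kc, 1:3, t0 = 0.001)
  expect_equal(s3$t, seq$t - 0.001)
  s4 <- first_spike_sequence(kc, 3L, t0 = seq$t[3] + 0.001)
  expect_gt(s4$t[1], 0)
})

test_that("cumulative interspike curves are anchored differences", {
  seq <- structure(data.frame(kc = 1:3, t = c(0.10, 0.12, 0.15)),
                   class = c("first_spike_sequence", "data.frame"))
  expect_equal(cumulative_isi(seq), c(0, 0.02, 0.05))
  single <- structure(data.frame(kc = 1L, t = 0.2),
                      class = c("first_spike_sequence", "data.frame"))
  expect_equal(cumulative_isi(single), 0)
  empty <- structure(data.frame(kc = integer(0), t = numeric(0)),
                     class = c("first_spike_sequence", "data.frame"))
  expect_error(cumulative_isi(empty), "empty")
})

mk_seq <- function(kc, t) {
  df <- data.frame(kc = kc, t = t)
  df <- df[order(df$t, df$kc), ]
  rownames(df) <- NULL
  structure(df, class = c("first_spike_sequence", "data.frame"))
}

test_that("sequence distance hits its extremes and the pair-count oracle", {
  a <- mk_seq(1:5, seq(0.1, 0.5, by = 0.1))
  expect_equal(sequence_distance(a, a), list(order_distance = 0,
                                             set_overlap = 1))
  rev_b <- mk_seq(1:5, seq(0.5, 0.1, by = -0.1))
  d <- sequence_distance(a, rev_b)
  expect_equal(d$order_distance, 1)
  expect_equal(d$set_overlap, 1)

  # brute-force discordant-pair oracle on random tie-free permutations
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    ta <- sample(seq_len(n)) / 100
    tb <- sample(seq_len(n)) / 100
    sa <- mk_seq(1:n, ta)
    sb <- mk_seq(1:n, tb)
    disc <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      disc <- disc + ((ta[i] - ta[j]) * (tb[i] - tb[j]) < 0)
    oracle <- disc / (n * (n - 1) / 2)
    expect_equal(sequence_distance(sa, sb)$order_distance, oracle,
                 tolerance = 1e-12)
    # symmetry
    expect_equal(sequence_distance(sb, sa)$order_distance, oracle,
                 tolerance = 1e-12)
  }
})

test_that("sequence distance handles disjoint and tiny shared sets", {
  a <- mk_seq(1:3, c(.1, .2, .3))
  b <- mk_seq(4:6, c(.1, .2, .3))
  d <- sequence_distance(a, b)
  expect_equal(d$set_overlap, 0)
  expect_equal(d$order_distance, 0)   # < 2 shared KCs
  c1 <- mk_seq(c(1, 9), c(.1, .2))
  expect_equal(sequence_distance(a, c1)$set_overlap, 1 / 4)
})

test_that("invariance reports compare within- and between-odorant spread", {
  runs <- list(
    list(label = "a", concentration = 1, seq = mk_seq(1:4, c(.1, .2, .3, .4))),
    list(label = "a", concentration = 2, seq = mk_seq(1:4, c(.1, .2, .3, .45))),
    list(label = "b", concentration = 1, seq = mk_seq(c(2, 5, 6, 1), c(.1, .2, .3, .4))),
    list(label = "b", concentration = 2, seq = mk_seq(c(5, 2, 6, 1), c(.1, .2, .3, .4))))
  rep <- invariance_report(runs)
  expect_equal(rep$within$mean_order_distance, (0 + 1 / 6) / 2)
  expect_true(rep$between$mean_set_overlap < 1)
  expect_error(invariance_report(runs[c(1, 3, 4)]), "at least 2")

  # single odorant: between stats reported as missing
  solo <- invariance_report(runs[1:2])
  expect_null(solo$between)
  expect_true(is.na(solo$invariant))
})

test_that("first-spike sequences round-trip through JSON", {
  s <- mk_seq(c(3L, 1L, 7L), c(0.12, 0.05, 0.3))
  f <- tempfile(fileext = ".json")
  write_sequence_json(s, f)
  back <- read_sequence_json(f)
  expect_equal(back$kc, s$kc)
  expect_equal(back$t, s$t)
  unlink(f)
})
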