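test_that("the PN-KC graph is Q-regular, deterministic and validated", {
  g <- sample_pn_kc_graph(23, 500, 6, seed = 1)
  expect_equal(dim(unclass(g)), c(500L, 6L))
  expect_true(all(apply(unclass(g), 1, function(r) length(unique(r)) == 6)))
  expect_true(all(g >= 1 & g <= 23))

  expect_identical(unclass(sample_pn_kc_graph(23, 500, 6, seed = 1)),
                   unclass(g))
  expect_false(identical(unclass(sample_pn_kc_graph(23, 500, 6, seed = 2)),
                         unclass(g)))
  expect_error(sample_pn_kc_graph(23, 10, 24), "invalid Q")

  full <- sample_pn_kc_graph(5, 20, 5, seed = 1)
  expect_true(all(apply(unclass(full), 1, function(r) all(sort(r) == 1:5))))
})

test_that("dominant-PN wiring fraction matches the hypergeometric Q/R", {
  for (q in c(3, 6, 9)) {
    frac <- mean(vapply(1:10, function(s) {
      g <- sample_pn_kc_graph(23, 400, q, seed = s)
      mean(apply(unclass(g) == 5, 1, any))   # PN 5 stands in for the dominant
    }, 1))
    # binomial error over 4000 KCs
    expect_lt(abs(frac - q / 23), 3 * sqrt((q / 23) * (1 - q / 23) / 4000))
  }
})

test_that("KC dendrite and APL states honor their event kinetics", {
  p <- calyx_params()
  x <- 0.7
  for (k in 1:20000) x <- kc_dendrite_step(x, 0, 0, p, dt = 1e-4)
  expect_lt(x, 1e-3)

  y <- 0.5
  for (k in 1:40000) y <- apl_step(y, 0, p, dt = 1e-4)
  expect_lt(y, 1e-3)
})

test_that("dendrite and APL long-run means match divisive fixed points", {
  p <- calyx_params()
  # dendrite at fixed APL level y: decay beta + kappa y
  y <- 0.02
  for (lam in c(100, 300)) {
    sim <- cpp_dnp_run(poisson_train(lam, 40, seed = 50 + lam), numeric(0),
                       p$kcd_alpha, p$kcd_beta + p$kcd_kappa * y, 0,
                       40, 1e-4, t_from = 5, trace_stride = 0L)
    pred <- p$kcd_alpha * lam /
      (p$kcd_alpha * lam + p$kcd_beta + p$kcd_kappa * y)
    expect_lt(abs(sim$mean - pred) / pred, 0.05)
  }
  # opening the loop (kappa = 0) raises the mean
  open <- cpp_dnp_run(poisson_train(100, 40, seed = 150), numeric(0),
                      p$kcd_alpha, p$kcd_beta, 0, 40, 1e-4, 5, 0L)
  closed <- cpp_dnp_run(poisson_train(100, 40, seed = 150), numeric(0),
                        p$kcd_alpha, p$kcd_beta + p$kcd_kappa * 0.05, 0,
                        40, 1e-4, 5, 0L)
  expect_gt(open$mean, closed$mean)

  # APL driven by aggregate KC spiking: alpha S / (alpha S + beta), sublinear
  means <- vapply(c(1000, 2000, 4000), function(s_rate) {
    sim <- cpp_dnp_run(poisson_train(s_rate, 20, seed = s_rate), numeric(0),
                       p$apl_alpha, p$apl_beta, 0, 20, 1e-4, 2, 0L)
    pred <- p$apl_alpha * s_rate / (p$apl_alpha * s_rate + p$apl_beta)
    expect_lt(abs(sim$mean - pred) / pred, 0.05)
    sim$mean
  }, 1)
  expect_true(all(diff(means) > 0))
  expect_lt(means[2] / means[1], 2)          # saturating growth
})

test_that("silent PNs leave the calyx silent", {
  pn <- spike_train_set(rep(list(numeric(0)), 10), "pn", 0.3)
  g <- sample_pn_kc_graph(10, 50, 4, seed = 1)
  out <- run_calyx(pn, g, t_total = 0.3, dt = 2e-5, seed = 1)
  expect_equal(sum(lengths(out$kc)), 0)
  expect_true(all(out$x_apl == 0))
  expect_true(all(out$x_kcd_steady == 0))
})

test_that("graph/input dimension mismatches are rejected", {
  pn <- spike_train_set(rep(list(numeric(0)), 10), "pn", 0.3)
  g <- sample_pn_kc_graph(12, 50, 4, seed = 1)
  expect_error(run_calyx(pn, g, t_total = 0.3, dt = 2e-5), "wires 12 PNs")
})

test_that("KCs wired to the dominant PN receive markedly higher input", {
  # one strong PN (index 3), the rest weak
  rates <- c(10, 10, 150, rep(10, 7))
  pn <- spike_train_set(lapply(seq_along(rates), function(r)
    poisson_train(rates[r], 0.8, seed = 60 + r)), "pn", 0.8)
  g <- sample_pn_kc_graph(10, 200, 4, seed = 3)
  out <- run_calyx(pn, g, t_total = 0.8, dt = 2e-5, seed = 1,
                   steady_window = c(0.4, 0.8))
  has_dom <- apply(unclass(g) == 3, 1, any)
  expect_gt(min(out$x_kcd_steady[has_dom]), max(out$x_kcd_steady[!has_dom]))
})

test_that("steady dendritic outputs preserve the ranking of aggregate drive", {
  # regular trains: the steady mapping drive -> x is the monotone sigmoid;
  # Poisson burst structure would add pattern-dependent (non-rate) spread
  rates <- c(5, 20, 40, 70, 100, 130, 10, 55, 85, 115)
  pn <- spike_train_set(lapply(seq_along(rates), function(r)
    regular_train(rates[r], 0.8, phase = 0.001 * r)), "pn", 0.8)
  g <- sample_pn_kc_graph(10, 150, 4, seed = 5)
  out <- run_calyx(pn, g, t_total = 0.8, dt = 2e-5, seed = 1,
                   steady_window = c(0.4, 0.8))
  drive <- vapply(seq_len(nrow(g)), function(m)
    sum(firing_rates(pn, c(0.4, 0.8))[unclass(g)[m, ]]), 1)
  expect_equal(class_spearman(drive, out$x_kcd_steady), 1)
})

test_that("the dendrite-only fast path equals the full open-loop run", {
  rates <- rep(c(30, 90), 5)
  pn <- spike_train_set(lapply(seq_along(rates), function(r)
    poisson_train(rates[r], 0.5, seed = 80 + r)), "pn", 0.5)
  g <- sample_pn_kc_graph(10, 80, 4, seed = 2)
  p0 <- calyx_params(kcd_kappa = 0)
  full <- run_calyx(pn, g, p0, t_total = 0.5, dt = 2e-5, seed = 1)
  fast <- run_calyx(pn, g, p0, t_total = 0.5, dt = 2e-5, seed = 1,
                    bsg = FALSE)
  expect_equal(fast$x_kcd_steady, full$x_kcd_steady, tolerance = 1e-12)
  expect_error(run_calyx(pn, g, t_total = 0.5, dt = 2e-5, bsg = FALSE),
               "kcd_kappa")
})
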