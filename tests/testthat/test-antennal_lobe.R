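test_that("the axon-terminal state decays to zero without input", {
  p <- al_params()
  x <- 0.8
  for (k in 1:10000) x <- axon_terminal_step(x, 0, 0, p, dt = 1e-4)
  expect_lt(x, 1e-3)
})

test_that("axon-terminal long-run mean matches the divisive fixed point", {
  # event-driven simulation vs alpha lambda / (alpha lambda + beta + kappa mu)
  p <- al_params()
  t_tot <- 60
  i <- 0
  for (lam in c(50, 100, 200)) {
    for (mu in c(0, 50, 150)) {
      i <- i + 1
      up <- poisson_train(lam, t_tot, seed = 100 + i)
      dn <- poisson_train(mu, t_tot, seed = 200 + i)
      sim <- cpp_dnp_run(up, dn, p$axt_alpha, p$axt_beta, p$axt_kappa,
                         t_tot, 1e-4, t_from = 5, trace_stride = 0L)
      pred <- p$axt_alpha * lam /
        (p$axt_alpha * lam + p$axt_beta + p$axt_kappa * mu)
      expect_lt(abs(sim$mean - pred) / pred, 0.05)
    }
  }
})

test_that("stronger feedback strictly lowers the axon-terminal mean", {
  p <- al_params()
  means <- vapply(c(0, 50, 100, 200, 400), function(mu) {
    cpp_dnp_run(poisson_train(150, 40, seed = 31),
                poisson_train(mu, 40, seed = 32 + mu),
                p$axt_alpha, p$axt_beta, p$axt_kappa, 40, 1e-4,
                t_from = 5, trace_stride = 0L)$mean
  }, 1)
  expect_true(all(diff(means) < 0))
})

test_that("graded synapses follow their kinetics and sign convention", {
  s <- synapse_step(0, 0, -65, alpha = 100, beta = 10, gmax = 0.5, e = 0,
                    dt = 1e-4)
  expect_equal(s$i, 0)

  # constant drive equilibrium alpha D / (alpha D + beta)
  x <- 0
  for (k in 1:5000)
    x <- synapse_step(x, 0.4, -65, 100, 10, 0.5, 0, dt = 1e-4)$x
  expect_equal(x, 100 * 0.4 / (100 * 0.4 + 10), tolerance = 1e-3)

  # hand-integrated two-step trace, including the reported current sign
  x0 <- 0.2
  x1 <- x0 + 1e-3 * (50 * 1 * (1 - x0) - 5 * x0)
  s1 <- synapse_step(x0, 1, -60, 50, 5, 0.3, -80, dt = 1e-3)
  expect_equal(s1$x, x1)
  expect_equal(s1$i, 0.3 * x1 * (-60 - (-80)))
  expect_gt(s1$i, 0)   # V above the reversal: positive outward term
})

test_that("onset and offset local neurons split rate transients", {
  t_tot <- 2
  # rate step up at t = 1 s: 80 Hz -> 240 Hz (regular trains)
  up_times <- c(seq(0.005, 1, by = 1 / 80), seq(1, 2, by = 1 / 240))
  on <- run_post_ln(up_times, "onset", t_total = t_tot, dt = 2e-5)
  off <- run_post_ln(up_times, "offset", t_total = t_tot, dt = 2e-5)
  expect_gt(sum(on$ln_spikes > 1 & on$ln_spikes < 1.5), 0)
  expect_equal(sum(off$ln_spikes > 1 & off$ln_spikes < 1.5), 0)
  # after the transient the drives decay towards zero
  expect_lt(tail(on$drive, 1), 20)

  # mirrored: step down produces an offset burst only
  dn_times <- c(seq(0.005, 1, by = 1 / 240), seq(1, 2, by = 1 / 80))
  on2 <- run_post_ln(dn_times, "onset", t_total = t_tot, dt = 2e-5)
  off2 <- run_post_ln(dn_times, "offset", t_total = t_tot, dt = 2e-5)
  expect_gt(sum(off2$ln_spikes > 1 & off2$ln_spikes < 1.5), 0)
  expect_equal(sum(on2$ln_spikes > 1 & on2$ln_spikes < 1.5), 0)
})

test_that("silent input leaves the whole antennal lobe silent", {
  osn <- spike_train_set(rep(list(numeric(0)), 5), "osn", 0.5)
  out <- run_al(osn, t_total = 0.5, dt = 2e-5)
  expect_equal(sum(lengths(out$pn)), 0)
  expect_length(out$preln_spikes, 0)
})

test_that("the Pre-LN rate grows with the total OSN input", {
  mk <- function(rate) spike_train_set(
    lapply(1:5, function(r) poisson_train(rate, 1, seed = 40 + r + rate)),
    "osn", 1)
  lo <- run_al(mk(80), t_total = 1, dt = 2e-5)
  hi <- run_al(mk(160), t_total = 1, dt = 2e-5)
  expect_gt(length(hi$preln_spikes), length(lo$preln_spikes))
  expect_gt(length(lo$preln_spikes), 0)
})

test_that("a single-channel antennal lobe runs as a degenerate circuit", {
  osn <- spike_train_set(list(poisson_train(150, 0.5, seed = 9)), "osn", 0.5)
  out <- run_al(osn, t_total = 0.5, dt = 2e-5)
  expect_length(out$pn, 1)
  expect_gt(length(out$pn[[1]]), 0)
})
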