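test_that("peri-receptor filtering matches a direct discrete convolution", {
  dt <- 1e-4
  p <- otp_params(tau_h = 0.01, gamma = 0.1)
  n <- 400
  u <- c(rep(0, 100), rep(100, 300))

  expect_true(all(peri_receptor(rep(0, n), dt, p) == 0))

  # unit DC gain: gamma = 0 and a long constant input converge to the input
  v0 <- peri_receptor(rep(50, 4000), dt, otp_params(gamma = 0))
  expect_equal(tail(v0, 1), 50, tolerance = 1e-3)

  # oracle: explicit convolution with the discretized exponential kernel
  a <- dt / p$tau_h
  y_oracle <- numeric(n)
  for (k in 2:n) {
    j <- seq_len(k - 1)
    y_oracle[k] <- sum(a * (1 - a)^(k - 1 - j) * u[j])
  }
  v_oracle <- pmax(y_oracle + p$gamma * (u - y_oracle) / p$tau_h, 0)
  expect_equal(peri_receptor(u, dt, p), v_oracle, tolerance = 1e-10)
  # onset overshoot from the derivative path
  expect_gt(max(v_oracle), 100)
})

test_that("competitive binding reaches the closed-form steady state", {
  set.seed(1)
  for (rep in 1:20) {
    n_o <- sample(1:4, 1)
    a <- runif(n_o, 0.001, 0.05)
    v <- runif(n_o, 10, 200)
    d <- runif(n_o, 5, 20)
    b <- a * d
    x1 <- rep(0, n_o)
    for (k in 1:40000) x1 <- bound_receptor_step(x1, v, b, d, dt = 1e-4)
    expect_equal(x1, bound_receptor_steady_state(a, v)$x1, tolerance = 1e-4)
  }
})

test_that("binding trajectory matches an independent ODE solver", {
  a <- c(0.02, 0.005); d <- c(10, 8); b <- a * d; v <- c(80, 120)
  dt <- 1e-5
  n <- 20000
  x1 <- c(0, 0)
  traj <- matrix(0, n, 2)
  for (k in 1:n) {
    x1 <- bound_receptor_step(x1, v, b, d, dt)
    traj[k, ] <- x1
  }
  sol <- deSolve::lsoda(
    y = c(0, 0), times = seq(0, n * dt, by = 5e-3),
    func = function(t, y, parms) list(b * v * (1 - sum(y)) - d * y))
  idx <- round(sol[-1, 1] / dt)
  expect_equal(traj[idx, 1], sol[-1, 2], tolerance = 1e-3)
  expect_equal(traj[idx, 2], sol[-1, 3], tolerance = 1e-3)
})

test_that("binding decays at rate d when the stimulus is removed", {
  x1 <- 0.6
  d <- 12
  for (k in 1:1000) x1 <- bound_receptor_step(x1, 0, 5, d, dt = 1e-4)
  expect_equal(x1, 0.6 * exp(-d * 0.1), tolerance = 1e-3)
})

test_that("closed-form steady states follow the competitive algebra", {
  expect_equal(bound_receptor_steady_state(1, 1)$x1, 0.5)
  two <- bound_receptor_steady_state(c(1, 1), c(1, 1))
  expect_equal(two$x1, c(1, 1) / 3)
  expect_equal(two$total, 2 / 3)
  expect_error(bound_receptor_steady_state(-1, 1), ">= 0")
})

test_that("a mixture binds like a pure odorant at its effective affinity", {
  expect_equal(effective_affinity(0.3, 50), 0.3)
  expect_equal(effective_affinity(c(0.1, 0.3), c(5, 5)), 0.2)
  set.seed(7)
  for (rep in 1:25) {
    n_o <- sample(2:5, 1)
    a <- runif(n_o, 0.001, 0.1)
    v <- runif(n_o, 1, 100)
    mix_total <- bound_receptor_steady_state(a, v)$total
    pure_total <- bound_receptor_steady_state(effective_affinity(a, v),
                                              sum(v))$total
    expect_equal(mix_total, pure_total, tolerance = 1e-12)
  }
  expect_error(effective_affinity(c(1, 1), c(0, 0)), "undefined")
})

test_that("the co-receptor channel honors its fixed points", {
  p <- otp_params()
  # the origin is a fixed point with no bound receptors
  st <- coreceptor_step(0, 0, 0, p, dt = 1e-4)
  expect_equal(c(st$x2, st$x3), c(0, 0))

  # kappa = 0 equilibrium is alpha2 X / (alpha2 X + beta2)
  p0 <- otp_params(kappa = 0)
  x2 <- 0; x3 <- 0
  for (k in 1:60000) {
    st <- coreceptor_step(x2, x3, 0.4, p0, dt = 1e-4)
    x2 <- st$x2; x3 <- st$x3
  }
  expect_equal(x2, p0$alpha2 * 0.4 / (p0$alpha2 * 0.4 + p0$beta2),
               tolerance = 1e-4)

  # calcium feedback suppresses the equilibrium below the kappa = 0 value,
  # and integration agrees with the algebraic root
  x2k <- 0; x3k <- 0
  for (k in 1:60000) {
    st <- coreceptor_step(x2k, x3k, 0.4, p, dt = 1e-4)
    x2k <- st$x2; x3k <- st$x3
  }
  expect_lt(x2k, x2)
  root <- stats::uniroot(function(z) {
    x3s <- p$alpha3 * z / p$beta3
    p$alpha2 * 0.4 * (1 - z) - p$beta2 * z - p$kappa * z^(2 / 3) * x3s^(2 / 3)
  }, c(1e-6, 1))$root
  expect_equal(x2k, root, tolerance = 1e-3)
})

test_that("the transduction current has exact Hill half-saturation", {
  p <- otp_params()
  expect_equal(transduction_current(0, p), 0)
  expect_equal(transduction_current(p$c, p), p$i_max / 2)
  # dynamic mode converges to the steady value for constant gating
  x2 <- rep(0.3, 100000)
  dyn <- transduction_current(x2, p, mode = "dynamic", dt = 2e-4)
  expect_equal(tail(dyn, 1), transduction_current(0.3, p),
               tolerance = 1e-6 * p$i_max)
})

test_that("an OSN is silent without odor and fires monotonically with it", {
  at <- synth_affinity_profile(23, "sparse", k = 1, seed = 7)
  dom <- which.max(affinity(at)[1, , 1])
  silent <- make_mixture(list(at), 0, t_on = 0.1, t_off = 0.7)
  r0 <- run_osn(silent, dom, t_total = 0.8, dt = 2e-5)
  expect_length(r0$spikes[[1]], 0)

  rates <- vapply(c(50, 100, 150, 200), function(amp) {
    od <- make_mixture(list(at), amp, t_on = 0.1, t_off = 0.7)
    firing_rates(run_osn(od, dom, t_total = 0.8, dt = 2e-5)$spikes,
                 c(0.4, 0.7))
  }, 1)
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[4], rates[1])
})

test_that("a single-component mixture reproduces the pure odorant exactly", {
  at <- synth_affinity_profile(23, "sparse", k = 1, seed = 7)
  dom <- which.max(affinity(at)[1, , 1])
  od <- make_mixture(list(at), 100, t_on = 0.1, t_off = 0.7)
  r1 <- run_osn(od, dom, t_total = 0.8, dt = 2e-5)
  r2 <- run_osn(od, dom, t_total = 0.8, dt = 2e-5)
  expect_identical(r1$spikes[[1]], r2$spikes[[1]])

  # backward-Euler mixture update with |O| = 1 equals the mono-molecular
  # implicit update algebraically; check to floating-point accuracy
  b <- 0.15; d <- 10; v <- 80; dt <- 1e-5
  x_mix <- 0; x_mono <- 0
  for (k in 1:5000) {
    x_mix <- bound_receptor_step(x_mix, v, b, d, dt)
    x_mono <- (x_mono + dt * b * v) / (1 + dt * (b * v + d))
    expect_lt(abs(x_mix - x_mono), 1e-12)
  }
})
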