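# Spike detection, Poisson sources, balanced weights, bias measurement.

test_that("spike detection interpolates single upward crossings", {
  tt <- c(0, 1, 2)
  V <- c(-70, -70, 20)   # crosses 0 between t=1 and t=2
  ev <- detect_spikes(V, tt)
  expect_length(ev$times, 1)
  expect_equal(ev$times, 1 + 70 / 90)
  expect_length(detect_spikes(rep(-70, 100), seq(0, 1, length.out = 100))$times,
                0)
})

test_that("threshold chatter within the merge window collapses to one spike", {
  tt <- seq(0, 0.002, by = 1e-4)
  V <- ifelse(seq_along(tt) %% 2 == 0, 1, -1)  # wobbles across 0 every 0.1 ms
  ev <- detect_spikes(V, tt, merge_window = 2e-3)
  expect_length(ev$times, 1)
})

test_that("spike count is invariant to output sampling above 2 kHz", {
  fx <- make_fixture("spiker")
  tr <- suppressWarnings(run_simulation(fx$spec, list(duration = 2)))
  V <- trace_series(tr, "A:V")
  n_full <- length(detect_spikes(V, tr$time)$times)
  for (stride in c(2L, 4L)) {   # 5 kHz and 2.5 kHz
    i <- seq(1, length(V), by = stride)
    expect_equal(length(detect_spikes(V[i], tr$time[i])$times), n_full)
  }
})

test_that("poisson trains have the right moments and exponential ISIs", {
  expect_length(poisson_train(0, 10, 1)$times, 0)
  expect_length(poisson_train(50, 0, 1)$times, 0)
  counts <- vapply(1:60, function(s)
    length(poisson_train(50, 20, seed = s)$times), 0)
  # mean count 1000, sd sqrt(1000); the mean of 60 runs has SE ~ 4.1
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000) / sqrt(60) + 1)
  isi <- diff(poisson_train(50, 100, seed = 42)$times)
  ks <- suppressWarnings(stats::ks.test(isi, stats::pexp, 50))
  expect_gt(ks$p.value, 0.01)
  # reproducibility
  expect_identical(poisson_train(50, 5, seed = 3)$times,
                   poisson_train(50, 5, seed = 3)$times)
})

test_that("balanced weight satisfies the mean-driving-current balance", {
  # symmetric rates/taus: w_e = w_i * |E_i - V_r| / |E_e - V_r|
  w_e <- balanced_weight(1e-5, 50, 50, 0.025, 0.025, -90, 60, V_r = -60)
  expect_equal(w_e, 1e-5 * 30 / 120)
  # oracle: the two mean currents cancel
  expect_equal(w_e * 50 * 0.025 * (60 - (-60)) +
                 1e-5 * 50 * 0.025 * (-90 - (-60)), 0)
  # equidistant rest: equal weights
  expect_equal(balanced_weight(2e-5, 50, 50, 0.025, 0.025, -90, 60, -15),
               2e-5)
  # doubling the excitatory rate halves the weight
  expect_equal(balanced_weight(1e-5, 50, 100, 0.025, 0.025, -90, 60, -60),
               w_e / 2)
  expect_error(balanced_weight(1e-5, 50, 50, 0.025, 0.025, -90, 60,
                               V_r = -90), "degenerate")
})

test_that("noise conductance decays exponentially and jumps by w", {
  g <- noise_state_update(1, tau = 0.025, dt = 0.025)
  expect_equal(g, exp(-1))
  expect_equal(noise_state_update(0.5, 0.025, 0, n_events = 1, w = 2e-5),
               0.5 + 2e-5)
  expect_equal(noise_current(-60, 0, 0), 0)
  expect_equal(noise_current(60, g_i = 1e-5, g_e = 3, E_i = -90, E_e = 60),
               1e-5 * 150)
  expect_equal(noise_current(-60, g_i = 1e-5, g_e = 0), 1e-5 * 30)
})

test_that("long-run conductance mean matches Campbell's theorem", {
  # shot noise: E[g] = w * lambda * tau
  lambda <- 50; tau <- 0.025; w <- 1e-5; dur <- 400
  ev <- poisson_train(lambda, dur, seed = 8)$times
  dt <- 1e-3
  n <- dur / dt
  inc <- tabulate(ceiling(ev / dt), n)
  g <- numeric(n); gg <- 0
  for (k in seq_len(n)) {
    gg <- noise_state_update(gg, tau, dt, inc[k], w)
    g[k] <- gg
  }
  m <- mean(g[-(1:1000)])
  sdg <- w * sqrt(lambda * tau / 2)
  se <- sdg * sqrt(2 * tau / dur)
  expect_lt(abs(m - w * lambda * tau), 4 * se + w * lambda * dt)  # dt bias
})

test_that("per-target noise substreams are statistically independent", {
  spec <- network_spec(
    list(leak_cell("P1", Cm = 0.005, g = 0.05),
         leak_cell("P2", Cm = 0.005, g = 0.05)),
    noise = noise_spec(c("P1", "P2"), rate_i = 50, w_i = 1e-5, seed = 21),
    sim = simulation_config(duration = 60, dt = 1e-3, record_dt = 0.01,
                            seed = 2))
  tr <- run_simulation(spec)
  t1 <- tr$events[["noise_i:P1"]]$times
  t2 <- tr$events[["noise_i:P2"]]$times
  bins <- seq(0, 60, by = 1)
  c1 <- table(cut(t1, bins)); c2 <- table(cut(t2, bins))
  r <- suppressWarnings(stats::cor.test(as.numeric(c1), as.numeric(c2)))
  expect_gt(r$p.value, 0.01)
  expect_lt(abs(unname(r$estimate)), 0.35)
})

test_that("bias measurement is exact for zero-weight noise", {
  spec <- noise_cell_spec(w_i = 0, seed = 4, duration = 10)
  tr <- run_simulation(spec)
  b <- measure_bias(trace_series(tr, "P:V"), -60,
                    trace_series(tr, "P:I_noise"))
  expect_equal(b$voltage_bias, 0)
  expect_equal(b$current_bias, 0)
  expect_error(measure_bias(rnorm(100), 0), "1000")
})
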