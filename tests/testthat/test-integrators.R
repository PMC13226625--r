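# Fixed-step and adaptive integration, relaxation, convergence order.

# scalar linear problem dy/dt = -k*y realised as a leak cell with
# g/Cm = k and rest at 0 mV
decay_cell <- function(k = 2, V0 = 10) {
  network_spec(point_neuron("D", Cm = 1,
                            channels = list(channel_spec("leak", k, 0)),
                            V_init = V0))
}

test_that("one Forward Euler step is the explicit linear map", {
  rt <- build_runtime(decay_cell(k = 2, V0 = 10))
  y <- initial_state(rt)
  y1 <- step_forward_euler(y, rt, dt = 0.1)
  expect_equal(y1[rt$idx$V], 10 * (1 - 2 * 0.1))
  # f == 0 leaves the state unchanged
  rt0 <- build_runtime(network_spec(leak_cell()))
  y0 <- initial_state(rt0)
  expect_identical(step_forward_euler(y0, rt0, 0.1), y0)
})

test_that("one semi-implicit step is the Crank-Nicolson linear map", {
  rt <- build_runtime(decay_cell(k = 2, V0 = 10))
  y <- initial_state(rt)
  y1 <- step_semi_implicit(y, rt, dt = 0.1)   # k*dt = 0.2
  expect_equal(y1[rt$idx$V], 10 * 0.9 / 1.1, tolerance = 1e-9)
})

test_that("non-finite states abort with the offending variable named", {
  # an unstable explicit step: k*dt >> 2 blows up
  rt <- build_runtime(decay_cell(k = 1e6, V0 = 10))
  expect_error(integrate_fixed(rt, initial_state(rt), 0, 10, 0.1),
               "non-finite.*V:D|V:D.*non-finite")
})

test_that("fixed-step methods converge at their classical orders", {
  fe <- convergence_slope("leaky_pulse", "forward_euler",
                          c(0.1, 0.03, 0.01, 0.003, 0.001))
  expect_gt(fe$slope, 0.9); expect_lt(fe$slope, 1.1)
  cn <- convergence_slope("smooth_decay", "semi_implicit_cn",
                          c(0.1, 0.03, 0.01, 0.003, 0.001))
  expect_gt(cn$slope, 1.8); expect_lt(cn$slope, 2.2)
  # on the discontinuous pulse the semi-implicit order drops to ~1 and the
  # solution approaches the Forward Euler one as dt shrinks
  cnp <- convergence_slope("leaky_pulse", "semi_implicit_cn",
                           c(0.1, 0.03, 0.01, 0.003, 0.001))
  expect_gt(cnp$slope, 0.9); expect_lt(cnp$slope, 1.3)
  expect_error(convergence_slope("leaky_pulse", "exact",
                                 c(0.1, 0.03, 0.01, 0.003, 0.001)),
               "degenerate")
  expect_error(convergence_slope("leaky_pulse", "forward_euler",
                                 c(0.1, 0.05)), "2 decades")
})

test_that("Forward Euler error scales ~10x across one decade of dt", {
  fx <- make_fixture("leaky")
  rt <- build_runtime(fx$spec)
  y0 <- initial_state(rt)
  rmse <- vapply(c(1e-2, 1e-3), function(dt) {
    r <- integrate_fixed(rt, y0, 0, 10, dt)
    sqrt(mean((r$Y[, rt$idx$V] - fx$exact(r$times))^2))
  }, 0)
  expect_equal(rmse[1] / rmse[2], 10, tolerance = 0.15)
})

test_that("adaptive integration hits tolerance-level global accuracy", {
  fx <- make_fixture("leaky")
  tr <- run_simulation(fx$spec, list(method = "adaptive", abstol = 1e-6,
                                     reltol = 1e-8, record_dt = 1e-3))
  rmse <- sqrt(mean((trace_series(tr, "L:V") - fx$exact(tr$time))^2))
  expect_lt(rmse, 1e-5)
  # tightening the tolerance strictly decreases the error
  tr2 <- run_simulation(fx$spec, list(method = "adaptive", abstol = 1e-4,
                                      reltol = 1e-6, record_dt = 1e-3))
  rmse2 <- sqrt(mean((trace_series(tr2, "L:V") - fx$exact(tr2$time))^2))
  tr3 <- run_simulation(fx$spec, list(method = "adaptive", abstol = 1e-8,
                                      reltol = 1e-10, record_dt = 1e-3))
  rmse3 <- sqrt(mean((trace_series(tr3, "L:V") - fx$exact(tr3$time))^2))
  expect_lt(rmse3, rmse2)
})

test_that("relaxation exits immediately at rest and settles off-rest cells", {
  r0 <- relax(network_spec(leak_cell()))
  expect_equal(r0$duration, 0)
  # 20 mV off rest with tau = 0.05 s settles well inside the 1 s default
  off <- network_spec(point_neuron("L", Cm = 0.005,
                                   channels = list(channel_spec("leak", 0.1, -60)),
                                   V_init = -40),
                      sim = simulation_config(duration = 1, dt = 1e-4))
  r1 <- relax(off)
  expect_lt(r1$duration, 1)
  expect_gt(r1$duration, 0)
  expect_equal(r1$state[1], -60, tolerance = 1e-3)
})

test_that("a tonically spiking cell relaxes to the cap with a warning", {
  spec <- network_spec(
    point_neuron("T", Cm = spiker_cm(), channels = spiker_channels(),
                 V_init = -40),
    stimuli = list(stimulus_spec("T", "holding_current", 2)),
    sim = simulation_config(duration = 1, dt = 1e-4, relax_max = 0.5))
  expect_warning(r <- relax(spec), "cap")
  expect_equal(r$duration, 0.5)
})

test_that("identical spec + seed + method give bitwise-identical traces", {
  spec <- noise_cell_spec(w_i = 1e-5, seed = 5, duration = 2)
  tr1 <- run_simulation(spec)
  tr2 <- run_simulation(spec)
  expect_identical(tr1$data, tr2$data)
  expect_identical(tr1$time, tr2$time)
})
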