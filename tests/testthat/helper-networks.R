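# Shared builders for small test networks.

leak_cell <- function(name = "L", Cm = 1, g = 0.1, E = -60, V_init = -60) {
  point_neuron(name, Cm = Cm,
               channels = list(channel_spec("leak", g, E)),
               V_init = V_init)
}

# passive cell with balanced background noise (the bias-measurement rig):
# tau_mem = 0.1 s so the time-average of V converges quickly
noise_cell_spec <- function(w_i = 1e-5, seed = 1L, duration = 30,
                            rate = 50, tau = 0.025) {
  network_spec(
    leak_cell("P", Cm = 0.005, g = 0.05),
    noise = noise_spec("P", rate_i = rate, w_i = w_i, tau_i = tau,
                       seed = 101L),
    sim = simulation_config(duration = duration, dt = 5e-4,
                            record_dt = 5e-3, seed = seed))
}

# PSP amplitude after each presynaptic event: deflection of V from its
# value at the event to its extremum within `win` seconds
psp_peaks <- function(V, times, events, sign = 1, win = 0.15) {
  vapply(events, function(t0) {
    w <- times >= t0 & times <= t0 + win
    base <- V[which(times >= t0)[1]]
    max(sign * V[w]) - sign * base
  }, 0)
}

expect_rel_equal <- function(x, y, tol = 1e-6) {
  expect_lt(max(abs(x - y)) / max(1, max(abs(y))), tol)
}
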