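# Current primitives of the membrane equation
#   Cm dV/dt = I_app - sum I_vd - sum I_es - sum I_cs - I_noise
# All currents are in nA and are *outward-positive* membrane currents,
# entering the balance with a minus sign.

#' Voltage-dependent channel current
#'
#' `gbar * A^p * B^q * (V - E) * f_reg` (nA). With `p = 0` the activation
#' factor is 1; with `q = 0` the inactivation factor is dropped.
#'
#' @param V membrane potential (mV).
#' @param ch a [channel_spec()].
#' @param A,B gate values in \[0, 1\] (ignored where the exponent is 0).
#' @param f_reg regulation factor (>= 0; 1 if unregulated).
#' @return current in nA (positive = outward for V > E).
#' @export
channel_current <- function(V, ch, A = 1, B = 1, f_reg = 1) {
  g <- ch$gbar
  if (ch$p > 0) g <- g * A^ch$p
  if (ch$q > 0) g <- g * B
  g * (V - ch$E) * f_reg
}

#' Ion-pool concentration derivative
#'
#' `dc/dt = k1 * (-k2 * I_src - c)` (mM/s): inward (negative) source current
#' accumulates concentration toward the steady state `c* = -k2 * I_src`,
#' and the pool decays at rate `k1` without source current.
#'
#' @param c concentration (mM, >= 0).
#' @param I_src summed source-channel current (nA).
#' @param pool a [pool_spec()] (only `k1`, `k2` are used).
#' @return dc/dt in mM/s.
#' @export
pool_derivative <- function(c, I_src, pool) {
  pool$k1 * (-pool$k2 * I_src - c)
}

#' Regulation factor from a pool concentration
#'
#' `saturating_activation`: `gamma*c / (1 + gamma*c)`;
#' `inhibition`: `1 / (1 + gamma*c)`.
#'
#' @param c concentration (mM, >= 0); vectorised.
#' @param link a [regulation_link()].
#' @return dimensionless factor in \[0, 1\].
#' @export
regulation_factor <- function(c, link) {
  gc <- link$gamma * c
  switch(link$form,
         saturating_activation = gc / (1 + gc),
         inhibition = 1 / (1 + gc))
}

#' Electrical synapse current into compartment i
#'
#' `gbar * (V_i - V_j)` (nA, outward-positive for cell i); antisymmetric in
#' (i, j). A rectifying junction passes current only while `V_i > V_j`.
#'
#' @param V_i,V_j membrane potentials (mV).
#' @param syn an [electrical_synapse()].
#' @return current in nA.
#' @export
electrical_current <- function(V_i, V_j, syn) {
  I <- syn$gbar * (V_i - V_j)
  if (syn$rectifying) I[V_i < V_j] <- 0
  I
}

# dual-exponential kernel internals -------------------------------------

#' Peak time of the dual-exponential synaptic kernel
#'
#' The kernel `k(t) = exp(-t/tau_d) - exp(-t/tau_r)` peaks at
#' `t* = tau_r*tau_d/(tau_d - tau_r) * log(tau_d/tau_r)`.
#'
#' @param tau_rise,tau_decay time constants (s), `tau_decay > tau_rise`.
#' @return peak time (s).
#' @export
dualexp_peak_time <- function(tau_rise, tau_decay) {
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

# normalisation so one unit event peaks at 1
dualexp_norm <- function(tau_rise, tau_decay) {
  tp <- dualexp_peak_time(tau_rise, tau_decay)
  1 / (exp(-tp / tau_decay) - exp(-tp / tau_rise))
}

#' Synaptic time course M1
#'
#' `M1 = Y * (1 + gamma_f * c_pre) * d` where
#' `Y = N * (z_d - z_r)` is the peak-normalised dual-exponential response
#' carried by the two decaying states `z_d` (time constant `tau_decay`) and
#' `z_r` (`tau_rise`), each incremented by 1 per presynaptic event. A single
#' event at plasticity gain 1 peaks at exactly 1.
#'
#' @param z_d,z_r kinetic pair of the dual-exponential response.
#' @param syn a [chemical_synapse()].
#' @param d depression resource in \[0, 1\] (1 if no depression).
#' @param c_pre presynaptic facilitation-pool concentration (mM; ignored if
#'   the synapse has no facilitation term).
#' @return dimensionless M1 >= 0.
#' @export
synapse_m1 <- function(z_d, z_r, syn, d = 1, c_pre = 0) {
  Y <- dualexp_norm(syn$tau_rise, syn$tau_decay) * (z_d - z_r)
  X <- d
  if (!is.null(syn$facilitation)) X <- X * (1 + syn$facilitation$gamma_f * c_pre)
  Y * X
}

#' Event-driven dual-exponential response
#'
#' Evaluates the peak-normalised response `Y(t)` of a synapse to an event
#' train by propagating the kinetic pair `(z_d, z_r)` exactly (closed-form
#' exponential decay between events, unit jump at each event). Equivalent
#' to convolving the event train with the peak-normalised kernel.
#'
#' @param times evaluation times (s, sorted).
#' @param events event times (s, sorted).
#' @param syn a [chemical_synapse()] (only `tau_rise`, `tau_decay` used).
#' @return `Y(t)` at `times`.
#' @export
dualexp_response <- function(times, events, syn) {
  norm <- dualexp_norm(syn$tau_rise, syn$tau_decay)
  zd <- zr <- 0; t_last <- -Inf; ei <- 1
  out <- numeric(length(times))
  for (m in seq_along(times)) {
    t <- times[m]
    while (ei <= length(events) && events[ei] <= t) {
      dt <- if (is.finite(t_last)) events[ei] - t_last else 0
      if (is.finite(t_last)) {
        zd <- zd * exp(-dt / syn$tau_decay)
        zr <- zr * exp(-dt / syn$tau_rise)
      }
      zd <- zd + 1; zr <- zr + 1
      t_last <- events[ei]; ei <- ei + 1
    }
    if (is.finite(t_last)) {
      dt <- t - t_last
      out[m] <- norm * (zd * exp(-dt / syn$tau_decay) -
                          zr * exp(-dt / syn$tau_rise))
    }
  }
  out
}

#' Depression resource: per-spike update and recovery derivative
#'
#' On each presynaptic spike the resource is scaled, `d <- d*(1-u)`;
#' between spikes it recovers as `dd/dt = (1-d)/tau_rec`. A periodic train
#' at interval `D` converges to the fixed point
#' `d* = (1 - exp(-D/tau_rec)) / (1 - (1-u)*exp(-D/tau_rec))`
#' (value just before each spike).
#'
#' @param d resource in \[0, 1\].
#' @param u per-spike utilisation fraction in \[0, 1\].
#' @return updated resource.
#' @export
depression_event_update <- function(d, u) d * (1 - u)

#' @rdname depression_event_update
#' @param tau_rec recovery time constant (s, > 0).
#' @return recovery derivative in 1/s.
#' @export
depression_derivative <- function(d, tau_rec) (1 - d) / tau_rec

#' Voltage-dependence factor M2: relaxation derivative
#'
#' M2 relaxes toward `gate_inf(V_post, h, s)` with time constant `tau_m2`,
#' exactly like a voltage-gated activation variable. When the synapse has no
#' voltage dependence M2 is identically 1 and its derivative 0.
#'
#' @param M2 current value in \[0, 1\].
#' @param V_post postsynaptic potential (mV).
#' @param vd `list(h, s, tau_m2)` or `NULL`.
#' @return dM2/dt in 1/s.
#' @export
m2_derivative <- function(M2, V_post, vd) {
  if (is.null(vd)) return(0 * M2)
  (gate_inf(V_post, vd$h, vd$s) - M2) / vd$tau_m2
}

#' Chemical synapse current
#'
#' `gbar * M1 * M2 * (V_post - E)` (nA, outward-positive for the
#' postsynaptic compartment).
#'
#' @param V_post postsynaptic potential (mV).
#' @param syn a [chemical_synapse()].
#' @param M1 time-course factor (>= 0).
#' @param M2 voltage-dependence factor in \[0, 1\].
#' @return current in nA.
#' @export
chemical_current <- function(V_post, syn, M1, M2 = 1) {
  syn$w * M1 * M2 * (V_post - syn$E)
}

#' Noise current from the balanced conductance pair
#'
#' `I_noise = g_i*(V - E_i) + g_e*(V - E_e)` (nA, outward-positive).
#'
#' @param V membrane potential (mV).
#' @param g_i,g_e conductances (uS, >= 0).
#' @param E_i,E_e reversal potentials (mV).
#' @return current in nA.
#' @export
noise_current <- function(V, g_i, g_e, E_i = -90, E_e = 60) {
  g_i * (V - E_i) + g_e * (V - E_e)
}

#' Decaying-conductance update over a step
#'
#' Exponential decay with time constant `tau` over `dt`, plus an increment
#' `w` per event in `(t, t + dt]` (delta impulses realised as jumps applied
#' at the end of the step).
#'
#' @param g conductance (uS, >= 0).
#' @param tau decay time constant (s, > 0).
#' @param dt step (s, >= 0).
#' @param n_events number of events in the step.
#' @param w weight per event (uS).
#' @return updated conductance (uS).
#' @export
noise_state_update <- function(g, tau, dt, n_events = 0, w = 0) {
  g * exp(-dt / tau) + n_events * w
}
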