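# Self-contained test networks and their oracles. Every fixture is
# generated in code; parameters are frozen constants chosen to produce
# robust qualitative behavior (spiking, adaptation, plasticity) in a
# Morris-Lecar-style two-conductance cell scaled to the package's unit
# system (mV, s, uS, uF, nA).

#' Exact solution of the leaky-integrator pulse problem
#'
#' Closed-form membrane potential of `Cm dV/dt = I_app - g_leak (V - V_leak)`
#' with a square current pulse `I0` on `[t0, t1)` and `V(0) = V_leak`:
#' flat before the pulse, exponential charging toward
#' `V_leak + I0/g_leak` during it, exponential decay back after it, with
#' time constant `tau = Cm/g_leak`.
#'
#' @param t time(s) (s); vectorised.
#' @param Cm membrane capacitance (uF).
#' @param g_leak leak conductance (uS).
#' @param V_leak leak reversal = resting potential (mV).
#' @param I0 pulse amplitude (nA).
#' @param t0,t1 pulse window (s), `t1 > t0 >= 0`.
#' @return membrane potential (mV).
#' @export
leaky_exact <- function(t, Cm = 1, g_leak = 0.1, V_leak = -60, I0 = 2,
                        t0 = 2, t1 = 7) {
  stopifnot(t1 > t0, t0 >= 0)
  tau <- Cm / g_leak
  Vp <- I0 / g_leak
  out <- rep(V_leak, length(t))
  mid <- t >= t0 & t < t1
  out[mid] <- V_leak + Vp * (1 - exp(-(t[mid] - t0) / tau))
  late <- t >= t1
  out[late] <- V_leak + Vp * (1 - exp(-(t1 - t0) / tau)) *
    exp(-(t[late] - t1) / tau)
  out
}

# Morris-Lecar-style spiking compartment in the class-I (SNIC) regime, so
# the firing rate varies continuously with drive and adaptation slows
# firing instead of silencing it. `area` scales all conductances and the
# capacitance together, so 1 nA injected into area 1e-5 corresponds to the
# classic 100 uA/cm^2 drive. Spikes peak above +10 mV, so the 0 mV synaptic
# trigger threshold is crossed once per spike.
spiker_channels <- function(area = 2e-5, g_ca_factor = 1,
                            ca_regulation = NULL, feeds_pool = NULL) {
  list(
    channel_spec("Ca", gbar = 4 * area * 1000 * g_ca_factor, E = 120,
                 activation = gate_spec(h = -1.2, s = 9, tau = 5e-4),
                 p = 1L, regulation = ca_regulation,
                 feeds_pool = feeds_pool),
    channel_spec("K", gbar = 8 * area * 1000, E = -84,
                 activation = gate_spec(h = 12, s = 8.7,
                                        tau = list(base = 5e-4, amp = 0.015,
                                                   h = 12, s = 17.4)),
                 p = 1L),
    channel_spec("leak", gbar = 2 * area * 1000, E = -60))
}

spiker_cm <- function(area = 2e-5) 20 * area

#' Holding current for a target potential
#'
#' Solves the steady-state current balance of one compartment: with every
#' gate, pool and regulation factor at its steady state for voltage `V`,
#' the holding current equals the summed steady channel current at `V`.
#' Synaptic and noise conductances are taken as zero (their pre-event
#' state).
#'
#' @param spec a [network_spec()].
#' @param comp compartment name.
#' @param V_hold target potential (mV).
#' @return holding current (nA).
#' @export
solve_holding_current <- function(spec, comp, V_hold) {
  rt <- build_runtime(spec)
  ci <- match(comp, rt$comp_names)
  if (is.na(ci)) stop("unknown compartment '", comp, "'")
  ks <- which(rt$ch$comp == ci)
  # steady gate factors
  gfac <- vapply(ks, function(k) {
    g <- rt$ch$gbar[k]
    if (rt$ch$act[k] > 0) {
      a <- rt$ch$act[k]
      g <- g * gate_inf(V_hold, rt$gt$h[a], rt$gt$s[a])^rt$ch$p[k]
    }
    if (rt$ch$inact[k] > 0) {
      b <- rt$ch$inact[k]
      g <- g * gate_inf(V_hold, rt$gt$h[b], rt$gt$s[b])
    }
    g
  }, 0)
  I_raw <- gfac * (V_hold - rt$ch$E[ks])
  # pool steady state from the unregulated source currents, then one more
  # pass through regulation (self-consistent for the fixtures' single-link
  # chains; iterate a few times for safety)
  I_ch <- I_raw
  for (iter in 1:8) {
    c_ss <- as.vector(rt$M_pool_src[, ks, drop = FALSE] %*% I_ch)
    c_ss <- pmax(-rt$pl$k2 * c_ss, 0)
    freg <- vapply(seq_along(ks), function(m) {
      k <- ks[m]
      if (rt$ch$reg_pool[k] == 0) return(1)
      gc <- rt$ch$reg_gamma[k] * c_ss[rt$ch$reg_pool[k]]
      if (rt$ch$reg_act[k]) gc / (1 + gc) else 1 / (1 + gc)
    }, 0)
    I_new <- I_raw * freg
    if (max(abs(I_new - I_ch)) < 1e-12) { I_ch <- I_new; break }
    I_ch <- I_new
  }
  sum(I_ch)
}

#' Construct a named test network
#'
#' Returns a fixture: a validated [network_spec()] plus its stimulation
#' protocol and, where one exists, a closed-form oracle.
#'
#' * `leaky` — single leak-only cell (Cm = 1 uF, g = 0.1 uS, rest -60 mV)
#'   with a +2 nA pulse on 2-7 s; exact solution [leaky_exact()].
#' * `spiker` — tonically excitable two-conductance spiking cell.
#' * `spiker_capool` — spiking cell whose Ca channel feeds a Ca pool that
#'   activates a KCa conductance (spike-rate attenuation) and inhibits the
#'   Ca channel (negative feedback); 2 nA, 5 s pulse protocol.
#' * `gap_pair` — spiking cell A electrically coupled to passive cell B;
#'   2 nA, 5 s pulse into A.
#' * `plastic_triad` — three spiking cells: A->B and B->A inhibitory
#'   facilitating (different rates), A->C excitatory depressing, C->A
#'   excitatory with facilitation and depression; pulse-train protocols
#'   drive one cell at a time.
#' * `vdep_pair` — spiking cell A, passive cell B held from -90 to -10 mV
#'   in 10 mV steps by a holding current; A->B excitatory synapse with
#'   postsynaptic voltage dependence; +1 nA, 150 ms pulse into A.
#' * `burst_alternator` — two-cell half-center oscillator (spiking cells
#'   with Ca-pool/KCa burst termination and reciprocal inhibition) with
#'   seconds-scale alternating bursts.
#'
#' @param id fixture name.
#' @return object of class `cpg_fixture`: list with `id`, `spec`,
#'   `protocol` notes, and optional `exact`/`holding` helpers.
#' @export
make_fixture <- function(id = c("leaky", "spiker", "spiker_capool",
                                "gap_pair", "plastic_triad", "vdep_pair",
                                "burst_alternator")) {
  id <- tryCatch(match.arg(id), error = function(e)
    stop("unknown fixture id '", id[1], "'; available: leaky, spiker, ",
         "spiker_capool, gap_pair, plastic_triad, vdep_pair, burst_alternator"))
  fx <- switch(id,
    leaky = {
      spec <- network_spec(
        point_neuron("L", Cm = 1,
                     channels = list(channel_spec("leak", 0.1, -60)),
                     V_init = -60),
        stimuli = list(stimulus_spec("L", "current_pulse", 2, 2, 7)),
        sim = simulation_config(duration = 10, dt = 1e-3))
      list(spec = spec,
           exact = function(t) leaky_exact(t, 1, 0.1, -60, 2, 2, 7),
           protocol = "+2 nA pulse on 2-7 s; record L:V")
    },
    spiker = {
      spec <- network_spec(
        point_neuron("A", Cm = spiker_cm(), channels = spiker_channels(),
                     V_init = -60),
        stimuli = list(stimulus_spec("A", "current_pulse", 2, 0.5, 5.5)),
        sim = simulation_config(duration = 6, dt = 1e-4))
      list(spec = spec, protocol = "2 nA pulse, 5 s; tonic spiking")
    },
    spiker_capool = {
      pool <- pool_spec("ca", k1 = 1, k2 = 0.5, source_channels = "Ca")
      ch <- spiker_channels(
        ca_regulation = regulation_link("ca", "inhibition", gamma = 0.3),
        feeds_pool = "ca")
      ch <- c(ch, list(
        channel_spec("KCa", gbar = 0.03, E = -84,
                     regulation = regulation_link("ca",
                                                  "saturating_activation",
                                                  gamma = 2))))
      spec <- network_spec(
        point_neuron("B4", Cm = spiker_cm(), channels = ch,
                     pools = list(pool), V_init = -60),
        stimuli = list(stimulus_spec("B4", "current_pulse", 2, 0.5, 5.5)),
        sim = simulation_config(duration = 6, dt = 1e-4))
      list(spec = spec,
           protocol = "2 nA pulse, 5 s; Ca accumulates, KCa slows firing")
    },
    gap_pair = {
      spec <- network_spec(
        list(point_neuron("A", Cm = spiker_cm(), channels = spiker_channels(),
                          V_init = -60),
             point_neuron("B", Cm = spiker_cm(),
                          channels = list(channel_spec("leak", 0.04, -60)),
                          V_init = -60)),
        electrical_synapses = list(electrical_synapse("A", "B", 0.005)),
        stimuli = list(stimulus_spec("A", "current_pulse", 2, 0.5, 5.5)),
        sim = simulation_config(duration = 6, dt = 1e-4))
      list(spec = spec,
           protocol = "2 nA into A; sub-threshold same-sign deflections in B")
    },
    plastic_triad = {
      mk_cell <- function(nm) {
        point_neuron(nm, Cm = spiker_cm(),
                     channels = spiker_channels(feeds_pool = "ca"),
                     pools = list(pool_spec("ca", k1 = 0.5, k2 = 0.25,
                                            source_channels = "Ca")),
                     V_init = -60)
      }
      syn <- list(
        chemical_synapse("A", "B", w = 0.002, E = -80, tau_rise = 0.01,
                         tau_decay = 0.05,
                         facilitation = list(pool = "ca", gamma_f = 6)),
        chemical_synapse("B", "A", w = 0.002, E = -80, tau_rise = 0.01,
                         tau_decay = 0.05,
                         facilitation = list(pool = "ca", gamma_f = 2)),
        chemical_synapse("A", "C", w = 0.002, E = 60, tau_rise = 0.01,
                         tau_decay = 0.05,
                         depression = list(u = 0.4, tau_rec = 1)),
        chemical_synapse("C", "A", w = 0.002, E = 60, tau_rise = 0.01,
                         tau_decay = 0.05,
                         facilitation = list(pool = "ca", gamma_f = 4),
                         depression = list(u = 0.3, tau_rec = 1)))
      spec <- network_spec(
        list(mk_cell("A"), mk_cell("B"), mk_cell("C")),
        chemical_synapses = syn,
        stimuli = pulse_train("A", amplitude = 3, width = 0.03,
                              interval = 0.4, n = 8, t_start = 0.2),
        sim = simulation_config(duration = 3.6, dt = 1e-4))
      list(spec = spec,
           protocol = paste("pulse train into A (8 x 30 ms, 3 nA, 2.5 Hz);",
                            "PSPs depress in C, facilitate in B"))
    },
    vdep_pair = {
      spec <- vdep_pair_spec(-60)
      list(spec = spec,
           holding = function(V) solve_holding_current(spec, "B", V),
           protocol = paste("one +1 nA, 150 ms pulse into A per holding",
                            "potential of B (-90..-10 mV)"))
    },
    burst_alternator = burst_alternator_fixture())
  structure(c(list(id = id), fx), class = "cpg_fixture")
}

# vdep_pair with B held by a holding current (resolved at build time from
# the steady-state balance of B's leak channel)
vdep_pair_spec <- function(V_hold, duration = 1.2) {
  A <- point_neuron("A", Cm = spiker_cm(1e-5),
                    channels = spiker_channels(1e-5), V_init = -60)
  B <- point_neuron("B", Cm = spiker_cm(),
                    channels = list(channel_spec("leak", 0.04, -60)),
                    V_init = V_hold)
  I_hold <- 0.04 * (V_hold - (-60))
  network_spec(
    list(A, B),
    chemical_synapses = list(
      chemical_synapse("A", "B", w = 0.004, E = 60, tau_rise = 0.005,
                       tau_decay = 0.03,
                       voltage_dependence = list(h = -20, s = 12,
                                                 tau_m2 = 0.05))),
    stimuli = list(stimulus_spec("B", "holding_current", I_hold),
                   stimulus_spec("A", "current_pulse", 1, 0.3, 0.45)),
    sim = simulation_config(duration = duration, dt = 1e-4))
}

# Half-center oscillator: two adapting class-I cells with reciprocal
# depressing inhibition. Burst termination comes from Ca-pool/KCa
# adaptation plus depression of the active cell's inhibitory synapse;
# the released cell escapes and silences its adapted partner. Burst
# duration is tunable through g_kca (adaptation) and g_inh (inhibition).
#' @keywords internal
burst_alternator_fixture <- function(g_kca = 0.05, g_inh = 0.035,
                                     drive = 3) {
  mk_cell <- function(nm, V0) {
    ch <- spiker_channels(feeds_pool = "ca")
    ch <- c(ch, list(channel_spec("KCa", gbar = g_kca, E = -84,
                                  regulation = regulation_link(
                                    "ca", "saturating_activation", gamma = 4))))
    point_neuron(nm, Cm = spiker_cm(), channels = ch,
                 pools = list(pool_spec("ca", k1 = 1.5, k2 = 0.5,
                                        source_channels = "Ca")),
                 V_init = V0)
  }
  syn <- function(a, b)
    chemical_synapse(a, b, w = g_inh, E = -80, tau_rise = 0.02,
                     tau_decay = 0.15,
                     depression = list(u = 0.15, tau_rec = 1.5))
  spec <- network_spec(
    list(mk_cell("H1", -20), mk_cell("H2", -60)),
    chemical_synapses = list(syn("H1", "H2"), syn("H2", "H1")),
    stimuli = list(stimulus_spec("H1", "holding_current", drive),
                   stimulus_spec("H2", "holding_current", drive)),
    sim = simulation_config(duration = 12, dt = 1e-4, relax_max = 0))
  list(spec = spec,
       protocol = "tonic drive; adaptation/depression-released alternating bursts")
}

#' Regular pulse-train stimuli
#'
#' @param target compartment name.
#' @param amplitude pulse amplitude (nA).
#' @param width pulse width (s).
#' @param interval pulse onset interval (s).
#' @param n number of pulses.
#' @param t_start onset of the first pulse (s).
#' @return list of [stimulus_spec()].
#' @export
pulse_train <- function(target, amplitude, width, interval, n, t_start = 0) {
  lapply(seq_len(n) - 1, function(k)
    stimulus_spec(target, "current_pulse", amplitude,
                  t_start + k * interval, t_start + k * interval + width))
}

#' Synthetic alternating burst trains
#'
#' Ground truth for phase-duration analysis: `n_patterns` alternating
#' protraction/retraction bursts with known durations (optionally jittered)
#' and intra-burst spike interval `isi`. The last spike of each burst falls
#' exactly at onset + duration, so first-to-last-spike burst durations
#' recover the inputs exactly at zero jitter.
#'
#' @param protraction,retraction phase durations (s, > 0).
#' @param n_patterns number of motor patterns.
#' @param isi intra-burst inter-spike interval (s).
#' @param jitter_sd SD of Gaussian jitter on each burst duration (s).
#' @param seed integer seed.
#' @param gap quiet interval between bursts (s); must exceed the burst
#'   detector's `max_isi`.
#' @return list with `protraction` and `retraction` [event_train()]s and
#'   the realised `durations` matrix.
#' @export
synthetic_bursts <- function(protraction, retraction, n_patterns, isi = 0.1,
                             jitter_sd = 0, seed = 1L, gap = 1) {
  stopifnot(protraction > 0, retraction > 0, n_patterns >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  t <- 0.5
  pro <- numeric(0); ret <- numeric(0)
  durs <- matrix(NA_real_, n_patterns, 2,
                 dimnames = list(NULL, c("protraction", "retraction")))
  for (k in seq_len(n_patterns)) {
    dp <- max(isi, protraction + stats::rnorm(1, 0, jitter_sd))
    dr <- max(isi, retraction + stats::rnorm(1, 0, jitter_sd))
    durs[k, ] <- c(dp, dr)
    pro <- c(pro, t + unique(c(seq(0, dp, by = isi), dp)))
    t <- t + dp + gap
    ret <- c(ret, t + unique(c(seq(0, dr, by = isi), dr)))
    t <- t + dr + gap
  }
  list(protraction = event_train(pro, "protraction", "spike"),
       retraction = event_train(ret, "retraction", "spike"),
       durations = durs)
}
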