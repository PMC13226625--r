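# S3 constructors and validation for the network description.
#
# Unit system (closed, no conversion factors): V in mV, t in s, Cm in uF,
# g in uS, I in nA, concentrations in mM, k1 in 1/s, k2 in M/A, gamma in 1/mM.

num1 <- function(x, what, ge = NULL, gt = NULL, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop(sprintf("'%s' must be a single finite number", what), call. = FALSE)
  if (!is.null(ge) && x < ge)
    stop(sprintf("'%s' must be >= %g (got %g)", what, ge, x), call. = FALSE)
  if (!is.null(gt) && x <= gt)
    stop(sprintf("'%s' must be > %g (got %g)", what, gt, x), call. = FALSE)
  as.numeric(x)
}

chr1 <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop(sprintf("'%s' must be a nonempty string", what), call. = FALSE)
  x
}

#' Ion channel description
#'
#' A voltage-dependent conductance contributing the current
#' \deqn{I = \bar g A^p B^q (V - E) f[reg]}
#' where `A` is the activation gate raised to integer power `p`, `B` the
#' optional inactivation gate (`q` is 0 or 1), and `f[reg]` a multiplicative
#' regulation factor driven by an ion pool (see [regulation_link()]).
#' A channel with no activation gate (`activation = NULL`) is ungated
#' (the `A^p` factor is 1); a leak channel is the common case.
#'
#' @param name channel name, unique within its compartment.
#' @param gbar maximum conductance (uS, >= 0).
#' @param E reversal potential (mV).
#' @param activation,inactivation [gate_spec()] objects or `NULL`.
#' @param p activation exponent (integer >= 0; ignored if no activation gate).
#' @param q inactivation exponent, 0 or 1; must satisfy `p >= q`.
#' @param regulation a [regulation_link()] or `NULL`.
#' @param feeds_pool name of an ion pool this channel's current feeds, or `NULL`.
#' @return object of class `cpg_channel`.
#' @export
channel_spec <- function(name, gbar, E, activation = NULL, p = 1L,
                         inactivation = NULL, q = 0L,
                         regulation = NULL, feeds_pool = NULL) {
  name <- chr1(name, "name")
  gbar <- num1(gbar, "gbar", ge = 0)
  E <- num1(E, "E")
  if (!is.null(activation) && !inherits(activation, "cpg_gate"))
    stop("'activation' must be a gate_spec() or NULL")
  if (!is.null(inactivation) && !inherits(inactivation, "cpg_gate"))
    stop("'inactivation' must be a gate_spec() or NULL")
  p <- as.integer(num1(p, "p", ge = 0))
  q <- as.integer(num1(q, "q", ge = 0))
  if (is.null(activation)) p <- 0L
  if (is.null(inactivation)) q <- 0L
  if (!q %in% c(0L, 1L)) stop("'q' must be 0 or 1")
  if (p < q) stop(sprintf("channel '%s': need p >= q (got p=%d, q=%d)", name, p, q))
  if (!is.null(inactivation) && q != 1L)
    stop(sprintf("channel '%s': inactivation gate given but q = 0", name))
  if (!is.null(regulation) && !inherits(regulation, "cpg_regulation"))
    stop("'regulation' must be a regulation_link() or NULL")
  if (!is.null(feeds_pool)) feeds_pool <- chr1(feeds_pool, "feeds_pool")
  structure(list(name = name, gbar = gbar, E = E,
                 activation = activation, p = p,
                 inactivation = inactivation, q = q,
                 regulation = regulation, feeds_pool = feeds_pool),
            class = "cpg_channel")
}

#' Ion pool description
#'
#' A lumped intracellular concentration (second messenger) driven by the
#' currents of named source channels:
#' \deqn{dc/dt = k_1(-k_2 I_{src} - c)}
#' so a steady inward (negative) current gives the steady concentration
#' \eqn{c^* = -k_2 I_{src} \ge 0}, and the pool decays at rate `k1` when the
#' source current is zero.
#'
#' @param name pool name, unique within its compartment.
#' @param k1 decay rate (1/s, > 0).
#' @param k2 current-to-concentration scaling (M/A, i.e. mM per nA after the
#'   closed unit system; >= 0).
#' @param source_channels character vector of channel names (same
#'   compartment) whose currents feed the pool.
#' @param c_init initial concentration (mM, >= 0).
#' @return object of class `cpg_pool`.
#' @export
pool_spec <- function(name, k1, k2, source_channels = character(), c_init = 0) {
  structure(list(name = chr1(name, "name"),
                 k1 = num1(k1, "k1", gt = 0),
                 k2 = num1(k2, "k2", ge = 0),
                 source_channels = as.character(source_channels),
                 c_init = num1(c_init, "c_init", ge = 0)),
            class = "cpg_pool")
}

#' Regulation of a conductance by an ion pool
#'
#' Multiplies a maximal conductance by `f(c)` where `c` is the pool
#' concentration:
#' * `saturating_activation`: `f = gamma*c / (1 + gamma*c)` (0 at c = 0,
#'   saturating at 1) — e.g. a Ca-activated K conductance.
#' * `inhibition`: `f = 1 / (1 + gamma*c)` (1 at c = 0, falling to 0) —
#'   e.g. Ca-dependent negative feedback on a Ca channel.
#'
#' @param pool name of the driving pool (same compartment).
#' @param form `"saturating_activation"` or `"inhibition"`.
#' @param gamma concentration scaling factor (1/mM, >= 0).
#' @return object of class `cpg_regulation`.
#' @export
regulation_link <- function(pool, form = c("saturating_activation", "inhibition"),
                            gamma) {
  form <- match.arg(form)
  structure(list(pool = chr1(pool, "pool"), form = form,
                 gamma = num1(gamma, "gamma", ge = 0)),
            class = "cpg_regulation")
}

#' Compartment description
#'
#' A point (isopotential) compartment with membrane capacitance `Cm`,
#' a set of channels and ion pools. Compartment names are global: synapses
#' address compartments directly. Multi-compartment neurons are expressed as
#' several compartments coupled by electrical synapses.
#'
#' @param name compartment name, unique across the network.
#' @param Cm membrane capacitance (uF, > 0).
#' @param channels list of [channel_spec()].
#' @param pools list of [pool_spec()].
#' @param V_init initial membrane potential (mV) or `NA` to let the
#'   relaxation period settle it (started from -60 mV).
#' @return object of class `cpg_compartment`.
#' @export
compartment_spec <- function(name, Cm, channels = list(), pools = list(),
                             V_init = NA_real_) {
  name <- chr1(name, "name")
  Cm <- num1(Cm, "Cm", gt = 0)
  if (!all(vapply(channels, inherits, TRUE, "cpg_channel")))
    stop("'channels' must be a list of channel_spec() objects")
  if (!all(vapply(pools, inherits, TRUE, "cpg_pool")))
    stop("'pools' must be a list of pool_spec() objects")
  if (!is.na(V_init)) V_init <- num1(V_init, "V_init")
  structure(list(name = name, Cm = Cm, channels = channels, pools = pools,
                 V_init = as.numeric(V_init)),
            class = "cpg_compartment")
}

#' Neuron description
#'
#' @param name neuron name.
#' @param compartments list of [compartment_spec()] (at least one).
#' @return object of class `cpg_neuron`.
#' @export
neuron_spec <- function(name, compartments) {
  if (inherits(compartments, "cpg_compartment")) compartments <- list(compartments)
  if (length(compartments) < 1L ||
      !all(vapply(compartments, inherits, TRUE, "cpg_compartment")))
    stop("'compartments' must be a nonempty list of compartment_spec() objects")
  structure(list(name = chr1(name, "name"), compartments = compartments),
            class = "cpg_neuron")
}

#' Single-compartment neuron shorthand
#'
#' @inheritParams compartment_spec
#' @return a `cpg_neuron` with one compartment named after the neuron.
#' @export
point_neuron <- function(name, Cm, channels = list(), pools = list(),
                         V_init = NA_real_) {
  neuron_spec(name, compartment_spec(name, Cm, channels, pools, V_init))
}

#' Electrical synapse (gap junction)
#'
#' Ohmic coupling injecting `gbar * (V_i - V_j)` as outward current from
#' compartment `cell_i` (equal and opposite into `cell_j`). A rectifying
#' junction passes current only while `V_i > V_j`.
#'
#' @param cell_i,cell_j compartment names (distinct).
#' @param gbar coupling conductance (uS, >= 0).
#' @param rectifying logical.
#' @return object of class `cpg_esyn`.
#' @export
electrical_synapse <- function(cell_i, cell_j, gbar, rectifying = FALSE) {
  cell_i <- chr1(cell_i, "cell_i"); cell_j <- chr1(cell_j, "cell_j")
  if (identical(cell_i, cell_j)) stop("electrical synapse endpoints must differ")
  structure(list(cell_i = cell_i, cell_j = cell_j,
                 gbar = num1(gbar, "gbar", ge = 0),
                 rectifying = isTRUE(rectifying)),
            class = "cpg_esyn")
}

#' Chemical synapse
#'
#' Event-triggered postsynaptic conductance
#' \deqn{I = \bar g M_1(t) M_2(t, V_{post}) (V_{post} - E)}
#' where `M1 = Y(t) * (1 + gamma_f * c_pre) * d` combines a peak-normalised
#' dual-exponential time course `Y` (one increment per presynaptic upward
#' crossing of `threshold`), facilitation through a presynaptic ion pool,
#' and a depression resource `d` (per spike `d <- d*(1-u)`, recovering as
#' `dd/dt = (1-d)/tau_rec`). `M2` relaxes toward a Boltzmann function of the
#' postsynaptic voltage with time constant `tau_m2`, and is identically 1
#' when `voltage_dependence` is absent.
#'
#' @param pre,post compartment names.
#' @param w synaptic weight = maximum conductance (uS): the peak conductance
#'   of a single event at plasticity gain 1.
#' @param E reversal potential (mV).
#' @param tau_rise,tau_decay kernel time constants (s), `tau_decay > tau_rise > 0`.
#' @param threshold presynaptic trigger voltage (mV; default 0).
#' @param facilitation `NULL` or `list(pool = <presynaptic pool name>,
#'   gamma_f = <1/mM>)`.
#' @param depression `NULL` or `list(u = <fraction in [0,1]>, tau_rec = <s>)`.
#' @param voltage_dependence `NULL` or `list(h = <mV>, s = <mV>, tau_m2 = <s>)`.
#' @return object of class `cpg_csyn`.
#' @export
chemical_synapse <- function(pre, post, w, E, tau_rise, tau_decay,
                             threshold = 0, facilitation = NULL,
                             depression = NULL, voltage_dependence = NULL) {
  pre <- chr1(pre, "pre"); post <- chr1(post, "post")
  w <- num1(w, "w", ge = 0); E <- num1(E, "E")
  tau_rise <- num1(tau_rise, "tau_rise", gt = 0)
  tau_decay <- num1(tau_decay, "tau_decay", gt = 0)
  if (tau_decay <= tau_rise) stop("need tau_decay > tau_rise > 0")
  threshold <- num1(threshold, "threshold")
  if (!is.null(facilitation)) {
    facilitation <- list(pool = chr1(facilitation$pool, "facilitation$pool"),
                         gamma_f = num1(facilitation$gamma_f,
                                        "facilitation$gamma_f", ge = 0))
  }
  if (!is.null(depression)) {
    u <- num1(depression$u, "depression$u", ge = 0)
    if (u > 1) stop("'depression$u' must be in [0, 1]")
    depression <- list(u = u,
                       tau_rec = num1(depression$tau_rec, "depression$tau_rec",
                                      gt = 0))
  }
  if (!is.null(voltage_dependence)) {
    voltage_dependence <- list(
      h = num1(voltage_dependence$h, "voltage_dependence$h"),
      s = num1(voltage_dependence$s, "voltage_dependence$s"),
      tau_m2 = num1(voltage_dependence$tau_m2, "voltage_dependence$tau_m2",
                    gt = 0))
    if (voltage_dependence$s == 0) stop("'voltage_dependence$s' must be nonzero")
  }
  structure(list(pre = pre, post = post, w = w, E = E,
                 tau_rise = tau_rise, tau_decay = tau_decay,
                 threshold = threshold, facilitation = facilitation,
                 depression = depression,
                 voltage_dependence = voltage_dependence),
            class = "cpg_csyn")
}

#' Balanced background-noise description
#'
#' Each target compartment receives two independent Poisson event trains
#' driving exponentially decaying conductances: inhibitory (rate `rate_i`,
#' weight `w_i`, time constant `tau_i`, reversal `E_i`) and excitatory
#' (rate `rate_e`, `tau_e`, `E_e`). The excitatory weight is not a free
#' parameter: it is derived at run time from the resting potential so the
#' mean inhibitory and excitatory driving currents balance (see
#' [balanced_weight()]).
#'
#' @param targets character vector of compartment names.
#' @param rate_i,rate_e event rates (Hz, >= 0; default equal).
#' @param w_i inhibitory weight (uS, >= 0).
#' @param tau_i,tau_e conductance decay time constants (s, > 0; default equal).
#' @param E_i,E_e reversal potentials (mV; defaults -90 and +60).
#' @param seed integer master seed for the per-target event substreams.
#' @return object of class `cpg_noise`.
#' @export
noise_spec <- function(targets, rate_i = 50, rate_e = rate_i, w_i = 1e-5,
                       tau_i = 0.025, tau_e = tau_i,
                       E_i = -90, E_e = 60, seed = 1L) {
  if (!is.character(targets) || length(targets) < 1L)
    stop("'targets' must name at least one compartment")
  structure(list(targets = targets,
                 rate_i = num1(rate_i, "rate_i", ge = 0),
                 rate_e = num1(rate_e, "rate_e", ge = 0),
                 w_i = num1(w_i, "w_i", ge = 0),
                 tau_i = num1(tau_i, "tau_i", gt = 0),
                 tau_e = num1(tau_e, "tau_e", gt = 0),
                 E_i = num1(E_i, "E_i"), E_e = num1(E_e, "E_e"),
                 seed = as.integer(num1(seed, "seed"))),
            class = "cpg_noise")
}

#' Applied-current stimulus
#'
#' Either a square current pulse active on `[t_start, t_end)` or a holding
#' current active for the whole run (holding currents also stay on during
#' the relaxation period, so the held potential is the reference state).
#'
#' @param target compartment name.
#' @param kind `"current_pulse"` or `"holding_current"`.
#' @param amplitude nA.
#' @param t_start,t_end pulse window (s); ignored for holding currents.
#' @return object of class `cpg_stimulus`.
#' @export
stimulus_spec <- function(target, kind = c("current_pulse", "holding_current"),
                          amplitude, t_start = 0, t_end = Inf) {
  kind <- match.arg(kind)
  target <- chr1(target, "target")
  amplitude <- num1(amplitude, "amplitude")
  if (kind == "current_pulse") {
    t_start <- num1(t_start, "t_start", ge = 0)
    t_end <- num1(t_end, "t_end", finite = FALSE)
    if (t_end <= t_start) stop("pulse needs t_end > t_start")
  } else {
    t_start <- 0; t_end <- Inf
  }
  structure(list(target = target, kind = kind, amplitude = amplitude,
                 t_start = t_start, t_end = t_end),
            class = "cpg_stimulus")
}

#' Simulation settings
#'
#' @param duration recorded simulation length (s, > 0).
#' @param method `"forward_euler"`, `"semi_implicit_cn"` or `"adaptive"`.
#' @param dt fixed step size (s) for the fixed-step methods.
#' @param abstol,reltol adaptive-solver tolerances.
#' @param relax_max relaxation-period cap (s; default 1, clip 10).
#' @param relax_dvdt_tol relaxation exit threshold on max |dV/dt| (mV/s).
#' @param record character vector of record requests
#'   (`"comp"` or `"comp:quantity"`); `NULL` records membrane potential of
#'   every compartment plus pool, regulation, synapse and noise series.
#' @param seed integer master seed.
#' @param record_dt output sampling interval (s) or `NA` for every step.
#' @return object of class `cpg_simconfig`.
#' @export
simulation_config <- function(duration = 1, method = c("forward_euler",
                              "semi_implicit_cn", "adaptive"),
                              dt = 1e-4, abstol = 1e-6, reltol = 1e-6,
                              relax_max = 1, relax_dvdt_tol = 1e-3,
                              record = NULL, seed = 1L, record_dt = NA_real_) {
  method <- match.arg(method)
  relax_max <- num1(relax_max, "relax_max", ge = 0)
  if (relax_max > 10) stop("'relax_max' is capped at 10 s")
  structure(list(duration = num1(duration, "duration", gt = 0),
                 method = method, dt = num1(dt, "dt", gt = 0),
                 abstol = num1(abstol, "abstol", gt = 0),
                 reltol = num1(reltol, "reltol", gt = 0),
                 relax_max = relax_max,
                 relax_dvdt_tol = num1(relax_dvdt_tol, "relax_dvdt_tol", gt = 0),
                 record = record, seed = as.integer(num1(seed, "seed")),
                 record_dt = as.numeric(record_dt)),
            class = "cpg_simconfig")
}

#' Network description
#'
#' Assembles neurons, synapses, noise, stimuli and simulation settings into
#' a validated, immutable network description.
#'
#' @param neurons list of [neuron_spec()].
#' @param electrical_synapses list of [electrical_synapse()].
#' @param chemical_synapses list of [chemical_synapse()].
#' @param noise a [noise_spec()] or `NULL`.
#' @param stimuli list of [stimulus_spec()].
#' @param sim a [simulation_config()].
#' @return object of class `cpg_network`.
#' @export
network_spec <- function(neurons, electrical_synapses = list(),
                         chemical_synapses = list(), noise = NULL,
                         stimuli = list(), sim = simulation_config()) {
  if (inherits(neurons, "cpg_neuron")) neurons <- list(neurons)
  # canonical ordering (also the workbook row order): neurons alphabetical
  if (length(neurons) > 1L &&
      all(vapply(neurons, inherits, TRUE, "cpg_neuron")))
    neurons <- neurons[order(vapply(neurons, `[[`, "", "name"))]
  spec <- structure(list(neurons = neurons,
                         electrical_synapses = electrical_synapses,
                         chemical_synapses = chemical_synapses,
                         noise = noise, stimuli = stimuli, sim = sim),
                    class = "cpg_network")
  validate_network(spec)
  spec
}

# flat table of compartments: neuron, compartment for cross-referencing
compartment_table <- function(spec) {
  rows <- lapply(spec$neurons, function(nr)
    data.frame(neuron = nr$name,
               compartment = vapply(nr$compartments, `[[`, "", "name"),
               stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Validate a network description
#'
#' Checks every structural invariant: unique names, existing synapse
#' endpoints, existing pools behind every regulation link and facilitation
#' term, existing source channels behind every pool, noise and stimulus
#' targets. Errors name both ends of a dangling reference.
#'
#' @param spec a `cpg_network`.
#' @return invisibly `TRUE`; stops with a diagnostic otherwise.
#' @export
validate_network <- function(spec) {
  stopifnot(inherits(spec, "cpg_network"))
  if (length(spec$neurons) < 1L ||
      !all(vapply(spec$neurons, inherits, TRUE, "cpg_neuron")))
    stop("'neurons' must be a nonempty list of neuron_spec() objects")
  nn <- vapply(spec$neurons, `[[`, "", "name")
  if (anyDuplicated(nn)) stop("duplicate neuron name: ", nn[duplicated(nn)][1])
  ct <- compartment_table(spec)
  if (anyDuplicated(ct$compartment))
    stop("duplicate compartment name: ",
         ct$compartment[duplicated(ct$compartment)][1])
  comps <- ct$compartment
  for (nr in spec$neurons) for (cp in nr$compartments) {
    chn <- vapply(cp$channels, `[[`, "", "name")
    if (anyDuplicated(chn))
      stop(sprintf("compartment '%s': duplicate channel name '%s'",
                   cp$name, chn[duplicated(chn)][1]))
    pln <- vapply(cp$pools, `[[`, "", "name")
    if (anyDuplicated(pln))
      stop(sprintf("compartment '%s': duplicate pool name '%s'",
                   cp$name, pln[duplicated(pln)][1]))
    for (ch in cp$channels) {
      if (!is.null(ch$regulation) && !ch$regulation$pool %in% pln)
        stop(sprintf(
          "channel '%s' in compartment '%s' is regulated by unknown pool '%s'",
          ch$name, cp$name, ch$regulation$pool))
      if (!is.null(ch$feeds_pool) && !ch$feeds_pool %in% pln)
        stop(sprintf(
          "channel '%s' in compartment '%s' feeds unknown pool '%s'",
          ch$name, cp$name, ch$feeds_pool))
    }
    for (pl in cp$pools) {
      bad <- setdiff(pl$source_channels, chn)
      if (length(bad))
        stop(sprintf(
          "pool '%s' in compartment '%s' sources unknown channel '%s'",
          pl$name, cp$name, bad[1]))
    }
  }
  for (es in spec$electrical_synapses) {
    if (!inherits(es, "cpg_esyn")) stop("bad electrical synapse entry")
    for (end in c(es$cell_i, es$cell_j))
      if (!end %in% comps)
        stop(sprintf("electrical synapse %s--%s references unknown compartment '%s'",
                     es$cell_i, es$cell_j, end))
  }
  pools_of <- function(comp) {
    for (nr in spec$neurons) for (cp in nr$compartments)
      if (cp$name == comp) return(vapply(cp$pools, `[[`, "", "name"))
    character()
  }
  for (cs in spec$chemical_synapses) {
    if (!inherits(cs, "cpg_csyn")) stop("bad chemical synapse entry")
    for (end in c(cs$pre, cs$post))
      if (!end %in% comps)
        stop(sprintf("chemical synapse %s->%s references unknown compartment '%s'",
                     cs$pre, cs$post, end))
    if (!is.null(cs$facilitation) &&
        !cs$facilitation$pool %in% pools_of(cs$pre))
      stop(sprintf(
        "chemical synapse %s->%s: facilitation pool '%s' not found in presynaptic compartment '%s'",
        cs$pre, cs$post, cs$facilitation$pool, cs$pre))
  }
  if (!is.null(spec$noise)) {
    if (!inherits(spec$noise, "cpg_noise")) stop("'noise' must be a noise_spec()")
    bad <- setdiff(spec$noise$targets, comps)
    if (length(bad))
      stop(sprintf("noise targets unknown compartment '%s'", bad[1]))
  }
  for (st in spec$stimuli) {
    if (!inherits(st, "cpg_stimulus")) stop("bad stimulus entry")
    if (!st$target %in% comps)
      stop(sprintf("stimulus targets unknown compartment '%s'", st$target))
  }
  if (!inherits(spec$sim, "cpg_simconfig"))
    stop("'sim' must be a simulation_config()")
  invisible(TRUE)
}

#' @export
print.cpg_network <- function(x, ...) {
  ct <- compartment_table(x)
  n_ch <- sum(vapply(x$neurons, function(nr)
    sum(lengths(lapply(nr$compartments, `[[`, "channels"))), 0))
  cat(sprintf(
    "<cpg_network> %d neuron(s), %d compartment(s), %d channel(s)\n",
    length(x$neurons), nrow(ct), n_ch))
  cat(sprintf("  electrical synapses: %d | chemical synapses: %d | noise: %s\n",
              length(x$electrical_synapses), length(x$chemical_synapses),
              if (is.null(x$noise)) "none"
              else paste0(length(x$noise$targets), " target(s)")))
  cat(sprintf("  stimuli: %d | sim: %s, duration %g s\n",
              length(x$stimuli), x$sim$method, x$sim$duration))
  invisible(x)
}
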