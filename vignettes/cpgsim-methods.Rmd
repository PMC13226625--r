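---
title: "cpgsim: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cpgsim: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the equations cpgsim integrates, the closed forms
it adopts where a modelling family offers several, the numerical choices
behind the integrators, and what the built-in fixtures do and do not
establish about real data.

## The model

### Membrane equation and units

Each compartment is a point (isopotential) membrane:

$$C_m \frac{dV_i}{dt} = I_i^{app} - \sum_j I_{ij}^{vd}
  - \sum_k I_{ik}^{es} - \sum_l I_{il}^{cs} - I_i^{noise}$$

The unit system is closed: $V$ in mV, $t$ in s, $C_m$ in µF, conductances
in µS, currents in nA, concentrations in mM, rates in s⁻¹, $\gamma$ in
mM⁻¹. With these units $g(V-E)$ is in nA and $C_m\,dV/dt$ is in nA, so no
conversion constants appear in the code; this is also why workbook values
must be given in exactly these units. Morphology (cable structure) and
temperature dependence are out of scope: multi-compartment neurons are
expressed as point compartments coupled by electrical synapses.

### Channels, gates, pools, regulation

A channel contributes $\bar g A^p B^q (V-E)\, f[\mathrm{reg}]$ with
$p \ge q$ and $q \in \{0,1\}$. Gates follow first-order kinetics toward a
Boltzmann steady state $A_\infty(V) = 1/(1+\exp((h-V)/s))$; a negative
slope factor $s$ yields the falling (inactivation-type) sigmoid. The gate
time constant is either constant or the bell-shaped
$\tau(V)=\tau_{base}+\tau_{amp}/\cosh((V-\tau_h)/(2\tau_s))$ — the form
used by Morris–Lecar-style recovery variables, and flexible enough for
the usual voltage-dependent time constants.

Ion pools are lumped second messengers driven by named source-channel
currents: $dc/dt = k_1(-k_2 I_{src} - c)$. The sign convention is that an
*inward* (negative) current accumulates concentration, matching Ca entry
through a depolarisation-activated Ca channel; the steady state is
$c^\ast = -k_2 I_{src} \ge 0$ and the pool decays at rate $k_1$ when the
source current stops.

Two regulation forms map a pool concentration onto a multiplicative
conductance factor: *saturating activation* $f=\gamma c/(1+\gamma c)$
(e.g. K$_{Ca}$) and *inhibition* $f=1/(1+\gamma c)$ (e.g. Ca-dependent
negative feedback on a Ca channel). Both are bounded in $[0,1]$, monotone,
and exact at the limits, which the unit tests assert. Where a larger
modelling family defines several such transfer functions, these two were
chosen as the minimal pair that expresses both signs of second-messenger
feedback; they are stated per operation in the reference documentation so
every numerical example is reproducible.

### Synapses

Electrical synapses are ohmic, $I^{es}=\bar g_{ij}(V_i-V_j)$,
antisymmetric by construction; a rectifying junction passes current only
while $V_i > V_j$.

Chemical synapses are event-triggered conductances
$I^{cs} = \bar g\, M_1(t)\, M_2(t,V)\,(V-E)$:

* $M_1 = Y(t) \cdot (1+\gamma_f c_{pre}) \cdot d$. $Y$ is a dual-exponential
  response carried by two decaying states $(z_d, z_r)$, each incremented
  by one per presynaptic upward crossing of the trigger threshold
  (default 0 mV). $Y$ is normalised so that a single event at plasticity
  gain 1 peaks at exactly 1, making the synaptic weight $w$ interpretable
  as a peak conductance in µS. Facilitation couples the gain directly to a
  presynaptic ion pool ($1+\gamma_f c_{pre}$); no intermediate transmitter
  pool state is added — with the pool's own first-order kinetics, a second
  linear stage would only add a fitting redundancy at this level of
  abstraction. Depression is the standard resource model: $d \leftarrow
  d(1-u)$ per spike, $dd/dt = (1-d)/\tau_{rec}$ between spikes; a periodic
  train at interval $\Delta$ converges to
  $d^\ast = (1-e^{-\Delta/\tau_{rec}})/(1-(1-u)e^{-\Delta/\tau_{rec}})$,
  which the plasticity tests verify against measured PSP peak ratios.
* $M_2$ relaxes toward a Boltzmann function of the *postsynaptic* voltage
  with time constant $\tau_{m2}$, exactly like a gate; when absent,
  $M_2 \equiv 1$.

### Balanced background noise

Each noise target receives two independent Poisson trains driving
exponentially decaying conductances ($dg/dt = -g/\tau + w\sum_j
\delta(t-T_j)$) with reversals $E_i = -90$ mV and $E_e = +60$ mV by
default. The user sets only the inhibitory weight; the excitatory weight
is derived at run time from the resting potential $V_r$ so the mean
driving currents cancel:

$$w_e = w_i\,\frac{|\lambda_i \tau_i (E_i - V_r)|}
                  {|\lambda_e \tau_e (E_e - V_r)|}.$$

$V_r$ is the compartment voltage after relaxation with noise weights set
to zero, recomputed for every run. The balance is checked two ways: the
algebraic cancellation of the mean currents (Campbell's theorem gives the
mean conductance $w\lambda\tau$), and simulation — the long-run mean noise
current on a passive cell is statistically indistinguishable from zero,
and the voltage histogram's Gaussian-fit mean sits within a microvolt of
the noiseless resting potential at the reference weight (10 pS). The fit
uses nonlinear least squares on a Freedman–Diaconis histogram; the raw
mean is reported alongside since the fitting recipe is a convention.

## Numerics

* **Forward Euler** and a **semi-implicit (Crank–Nicolson) step** are
  implemented in the package. The semi-implicit step applies the
  trapezoidal rule to the whole state vector and solves the implicit
  relation by fixed-point iteration (absolute tolerance $10^{-10}$, at
  most 50 iterations, failure is an error). Applying it to the full
  vector rather than staggering voltage against gate/pool states keeps
  the scalar contract exact — for $dy/dt=-ky$ one step is
  $y(1-k\,dt/2)/(1+k\,dt/2)$ — and retains classical order 2 on smooth
  problems at the fixture step sizes; the convergence tests measure
  log-log slopes of ≈1 (Forward Euler) and ≈2 (semi-implicit on smooth
  decay), dropping to ≈1 on the discontinuous pulse problem as expected
  for a non-smooth right-hand side.
* **Adaptive integration** delegates to `deSolve::lsoda` (stiff-capable,
  embedded error control). Discontinuities are respected structurally:
  pulse edges and Poisson arrival times are segment boundaries, and
  presynaptic threshold crossings are located by the solver's root
  finder, with the synaptic jumps applied at the root. The contract is
  tolerance-governed global accuracy on registered test problems, not
  solver identity.
* **Events at fixed step**: crossings are detected by sign change of
  $(V-\theta)$ across a step, the event time linearly interpolated, and
  jumps applied at the following step boundary. A 2 ms refractory merge
  window collapses numerical chatter around the threshold into one event;
  it is far shorter than any fixture inter-spike interval.
* **Relaxation**: before recording, the network is integrated with pulse
  stimuli and noise disabled until $\max_i |dV_i/dt|$ stays below the
  tolerance (default $10^{-3}$ mV/s) across a whole 0.1 s chunk, or until
  `relax_max` (default 1 s, cap 10 s) is reached — the cap is a logged
  warning, not an error, because tonically active networks never settle.
  The whole-chunk criterion matters: an instantaneous check can be fooled
  by the slow trajectory segments of class-I cells near their firing
  threshold. Holding currents stay active during relaxation, since a held
  potential *is* the reference state the protocol defines (the
  voltage-dependence fixture relies on this); noise is disabled because
  $dV/dt \to 0$ is unattainable under stochastic input.
* **Determinism**: one master seed deterministically spawns per-target,
  per-kind Poisson substreams (all below $2^{31}$), so identical
  spec + seed + method give bitwise-identical traces, and sweep results
  are independent of batch size and execution order.
* **Bounded states**: gates, depression resources and $M_2$ are clamped
  to $[0,1]$, pools and conductances to $\ge 0$, after every step; at the
  fixture step sizes the clamp is a no-op except at event boundaries.
* **Degenerate inputs**: the balance weight errors out when $V_r$
  coincides with a noise reversal; the convergence study rejects fewer
  than 4 step sizes, fewer than two decades of range, or an exact
  "method" (zero RMSE); bias measurement refuses fewer than 1000 samples;
  an empty phase summary yields an `Inf` objective sentinel that can
  never win the argmin while any cell succeeds; sweep ties break to the
  lowest index pair.

## The workbook

Networks are described in a single plain-text file with named `[Sheet]`
sections of tab-separated values (`Neurons`, `Channels`, `Pools`,
`ElectricalSynapses`, `ChemicalSynapses`, `Noise`, `Stimuli`,
`Simulation`); `.xlsx` files with the same sheets are read when `readxl`
is available. The schema is documented at the top of `R/workbook.R` and
carries the same information content as spreadsheet interfaces
traditional in this modelling family, without being byte-compatible with
any particular one. Empty cells mean "absent"; unknown sheets are ignored
with a warning (forward compatibility) while unknown columns are errors
(typo safety); every malformed value is reported with its sheet, row and
column. Save order is canonical — neurons alphabetically, channels and
synapses in declaration order — so save∘load is the identity and
workbook coordinates (`Sheet:row:column`) address any scalar parameter
stably, which is what the grid search patches.

## Fixtures: what they emulate, and what they do not

All test networks are generated in code; their parameters are frozen
constants. The spiking cell is a Morris–Lecar-style two-conductance model
in the class-I (SNIC) regime, scaled so that nA-range injections are
physiological (`area` 2×10⁻⁵ maps 1 nA to the classic 100 µA/cm²) and
spikes peak above +10 mV so the 0 mV synaptic trigger fires once per
spike. Class I was a deliberate choice: its firing rate varies
continuously with drive, so second-messenger adaptation *slows* firing —
a class-II cell near threshold simply stops, which is the wrong
phenomenology for spike-rate attenuation.

* `leaky` — the analytic anchor: a leak cell with a +2 nA pulse on
  2–7 s, with the exact three-piece solution as oracle.
* `spiker_capool` — Ca entry → pool → K$_{Ca}$ activation (plus
  Ca-channel inhibition): during a 2 nA, 5 s pulse the pool rises to a
  plateau and late firing is slower than early firing.
* `gap_pair` — a spiker electrically coupled to a passive cell:
  same-sign subthreshold deflections.
* `plastic_triad` — three spiking cells with facilitating inhibitory
  synapses (A↔B, different rates), a depressing excitatory synapse
  (A→C) and a mixed one (C→A); a 2.5 Hz pulse train into A elicits one
  presynaptic spike per pulse.
* `vdep_pair` — PSP amplitude versus holding potential (−90…−10 mV in
  10 mV steps, one +1 nA/150 ms presynaptic pulse per level). The holding
  current is solved directly from the steady-state current balance at the
  target potential (gates, pools and regulation at steady state), the
  same fixed point a nested relaxation would find, at a fraction of the
  cost. The synapse parameters ($h=-20$ mV, $s=12$ mV, $E=+60$ mV) were
  chosen so the Boltzmann rise dominates the shrinking driving force over
  the whole range, keeping the amplitude strictly increasing.
* `burst_alternator` — a two-cell half-center: adapting class-I cells
  with reciprocal depressing inhibition. Burst termination comes from the
  Ca/K$_{Ca}$ adaptation plus synaptic depression of the active cell's
  inhibition; release then switches the roles. Burst durations sit at the
  seconds scale and respond monotonically to the adaptation conductance,
  which is what the end-to-end sweep test exercises.

What passing these tests shows: the equations are integrated correctly
(analytic and order oracles), the plasticity and regulation machinery
produces the qualitative signatures it is built for, and the statistical
properties of the noise model hold. What they do not show: fidelity to
any particular biological cell. The fixtures are mechanism fixtures, not
parameter reconstructions — reproducing a published CPG requires that
network's own (externally maintained) parameter workbook, which the
schema can express but the package does not ship.

## Synthetic burst trains

`synthetic_bursts()` generates ground truth for the analysis chain:
alternating protraction/retraction bursts with exact (or
Gaussian-jittered) durations and a fixed intra-burst inter-spike
interval. The last spike of each burst lands exactly at onset + duration,
so first-to-last-spike durations recover the inputs identically at zero
jitter; jittered recovery is checked against its own sampling error. It
emulates the *timing* structure of motor programs only — no spike-count
or rate structure within bursts — which is exactly what the phase
extraction consumes.

## Analysis choices

Bursts are maximal runs of spikes with inter-spike intervals ≤ `max_isi`
(default 0.5 s) and at least `min_spikes` (default 3) spikes; the
defaults separate seconds-scale motor-program phases from intra-burst
intervals and are explicit arguments everywhere. Phase duration is
first-to-last spike of the burst; pairing assigns each retraction burst
to the most recent preceding protraction burst; the first pattern is
excluded from summaries (settling transient) and an unpaired trailing
burst is dropped with a warning. The sweep objective is
$(\bar P - P^\ast)^2 + (\bar R - R^\ast)^2$ in s²; any monotone transform
of it has the same argmin, which the tests assert.

## Problem sizes

The test suite and acceptance script run at sizes chosen to make every
check statistically decisive on a single CPU: convergence studies use
five step sizes over two decades on a 10 s problem; noise-balance checks
use ten seeds of 25 s each on a passive cell with a 0.1 s membrane time
constant (the across-seed standard error of the mean noise current is
then well below the effect sizes probed); circuit fixtures run 6–12 s of
model time at dt = 10⁻⁴ s; the full-size sweep shape (60×60 = 3600
cells) is exercised with a closed-form mock backend and the real
simulation backend with a small mesh. Longer runs sharpen the stochastic
estimates but change no conclusion.

## Known limitations

* Pure-R inner loop: tens of microseconds per step and cell; fine for the
  few-cell circuits the package targets, slow for hundreds of cells.
* Fixed-step event times are first-order interpolations; synaptic state
  jumps land on step boundaries. The adaptive path locates events by
  root-finding instead, so cross-method trace agreement is limited by the
  event handling, not the smooth dynamics.
* The semi-implicit method iterates to a fixed point, so its stability
  advantage over Forward Euler is bounded by the iteration's contraction
  condition (`dt` times the local Lipschitz constant below ~2).
* One regulation link per channel and one facilitation pool per synapse;
  cascaded second-messenger systems are out of scope.
* Noise parameters are shared across the targets of one noise block
  (per-target rates or weights require separate blocks, which the schema
  does not currently express).
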