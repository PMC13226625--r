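#' Gate description for a voltage-dependent channel
#'
#' A gating variable follows first-order kinetics
#' \deqn{dA/dt = (A_\infty(V) - A)/\tau(V)}
#' with a Boltzmann steady state \eqn{A_\infty(V) = 1/(1 + \exp((h - V)/s))}.
#' A negative slope factor `s` gives a falling (inactivation-type) sigmoid.
#' The time constant is either a positive constant (seconds) or the
#' bell-shaped voltage-dependent form
#' \deqn{\tau(V) = \tau_{base} + \tau_{amp} / \cosh((V - \tau_h)/(2\tau_s))}
#'
#' @param h half-activation voltage (mV).
#' @param s activation slope factor (mV, nonzero; sign sets the direction).
#' @param tau either a single positive number (s), or a list with elements
#'   `base` (s, > 0), `amp` (s, >= 0), `h` (mV), `s` (mV, nonzero).
#' @return an object of class `cpg_gate`.
#' @export
gate_spec <- function(h, s, tau = 0.01) {
  stopifnot(is.numeric(h), length(h) == 1L, is.finite(h))
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s == 0)
    stop("gate slope factor 's' must be a nonzero finite number (mV)")
  if (is.numeric(tau)) {
    if (length(tau) != 1L || !is.finite(tau) || tau <= 0)
      stop("constant gate time constant must be a positive number (s)")
    tau <- list(base = as.numeric(tau), amp = 0, h = 0, s = 1)
  } else if (is.list(tau)) {
    tau <- utils::modifyList(list(amp = 0, h = 0, s = 1), tau)
    if (!all(c("base", "amp", "h", "s") %in% names(tau)))
      stop("voltage-dependent tau needs elements base, amp, h, s")
    if (tau$base <= 0 || tau$amp < 0 || tau$s == 0)
      stop("tau(V) must be positive for all V: need base > 0, amp >= 0, s != 0")
    tau <- tau[c("base", "amp", "h", "s")]
    tau[] <- lapply(tau, as.numeric)
  } else stop("'tau' must be a number or a list")
  structure(list(h = as.numeric(h), s = as.numeric(s), tau = tau),
            class = "cpg_gate")
}

#' Steady-state activation of a gate
#'
#' Boltzmann sigmoid `1/(1 + exp((h - V)/s))`; strictly increasing in `V`
#' for `s > 0`, strictly decreasing for `s < 0`.
#'
#' @param V membrane potential (mV); vectorised.
#' @param h half-activation voltage (mV).
#' @param s slope factor (mV, nonzero).
#' @return value(s) in (0, 1).
#' @export
gate_inf <- function(V, h, s) {
  if (any(s == 0)) stop("slope factor s must be nonzero")
  1 / (1 + exp((h - V) / s))
}

#' Gate time constant at a voltage
#'
#' @param V membrane potential (mV); vectorised.
#' @param gate a `cpg_gate` (or its `tau` list).
#' @return time constant(s) in seconds, strictly positive.
#' @export
gate_tau <- function(V, gate) {
  tau <- if (inherits(gate, "cpg_gate")) gate$tau else gate
  if (tau$amp == 0) rep_len(tau$base, length(V))
  else tau$base + tau$amp / cosh((V - tau$h) / (2 * tau$s))
}

#' Time derivative of a gating variable
#'
#' First-order relaxation toward the steady state:
#' `(gate_inf(V) - A) / gate_tau(V)`.
#'
#' @param A current gate value in \[0, 1\]; vectorised.
#' @param V membrane potential (mV).
#' @param gate a `cpg_gate`.
#' @return dA/dt in 1/s.
#' @export
gate_derivative <- function(A, V, gate) {
  (gate_inf(V, gate$h, gate$s) - A) / gate_tau(V, gate)
}
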