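# Point events: spike detection, Poisson sources, and the balanced
# excitatory/inhibitory background-noise weights.

#' Event train
#'
#' A sorted vector of event times with a source label and kind.
#'
#' @param times numeric vector of times (s), strictly increasing, >= 0.
#' @param source source identifier.
#' @param kind `"spike"`, `"poisson_e"` or `"poisson_i"`.
#' @return object of class `cpg_events`.
#' @export
event_train <- function(times, source = "", kind = c("spike", "poisson_e",
                                                     "poisson_i")) {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  if (length(times)) {
    if (any(times < 0) || is.unsorted(times, strictly = TRUE))
      stop("event times must be strictly increasing and >= 0")
  }
  structure(list(source = source, times = times, kind = kind),
            class = "cpg_events")
}

#' @export
print.cpg_events <- function(x, ...) {
  cat(sprintf("<cpg_events> %s '%s': %d event(s)%s\n", x$kind, x$source,
              length(x$times),
              if (length(x$times))
                sprintf(" on [%.4g, %.4g] s", min(x$times), max(x$times))
              else ""))
  invisible(x)
}

#' Detect spikes in a voltage trace
#'
#' One event per upward crossing of `threshold`, with the crossing time
#' linearly interpolated between samples. Crossings within the refractory
#' merge window of the previous event are collapsed, so numerical chatter
#' around the threshold yields a single spike.
#'
#' @param V sampled membrane potential (mV).
#' @param times sample times (s), same length as `V`, increasing.
#' @param threshold trigger voltage (mV; default 0).
#' @param merge_window refractory merge window (s; default 2 ms).
#' @param source source label for the returned train.
#' @return a [event_train()] of kind `"spike"`.
#' @export
detect_spikes <- function(V, times, threshold = 0, merge_window = 2e-3,
                          source = "") {
  stopifnot(length(V) == length(times))
  if (length(V) < 2L) return(event_train(numeric(), source, "spike"))
  up <- which(V[-length(V)] < threshold & V[-1] >= threshold)
  if (!length(up)) return(event_train(numeric(), source, "spike"))
  tev <- times[up] + (times[up + 1] - times[up]) *
    (threshold - V[up]) / (V[up + 1] - V[up])
  # sequential merge: an event is kept only if >= merge_window after the
  # last *kept* event
  out <- numeric(0); last <- -Inf
  for (tt in tev) if (tt - last >= merge_window) { out <- c(out, tt); last <- tt }
  event_train(out, source, "spike")
}

#' Homogeneous Poisson event train
#'
#' Event times on `[0, duration]` with exponential inter-event intervals at
#' the given rate; reproducible for a fixed seed. The RNG state of the
#' caller is left untouched.
#'
#' @param rate event rate (Hz, >= 0).
#' @param duration train length (s, >= 0).
#' @param seed integer seed.
#' @param source,kind labels for the returned train.
#' @return a [event_train()].
#' @export
poisson_train <- function(rate, duration, seed = 1L, source = "",
                          kind = "poisson_e") {
  stopifnot(rate >= 0, duration >= 0)
  if (rate == 0 || duration == 0) return(event_train(numeric(), source, kind))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  # draw in blocks until past the end
  t_acc <- numeric(0); t_last <- 0
  repeat {
    n_blk <- max(16L, ceiling(1.2 * rate * (duration - t_last)))
    t_new <- t_last + cumsum(stats::rexp(n_blk, rate))
    t_acc <- c(t_acc, t_new)
    t_last <- t_acc[length(t_acc)]
    if (t_last > duration) break
  }
  event_train(t_acc[t_acc <= duration], source, kind)
}

#' Balanced excitatory noise weight
#'
#' Given the inhibitory weight, rates, time constants, reversal potentials
#' and the resting potential, returns the excitatory weight for which the
#' mean steady driving currents of the two noise conductances cancel:
#' `w_e * lambda_e * tau_e * (E_e - V_r) = w_i * lambda_i * tau_i * |E_i - V_r|`
#' i.e. `w_e = w_i * |lambda_i * tau_i * (E_i - V_r)| /
#' |lambda_e * tau_e * (E_e - V_r)|`.
#'
#' @param w_i inhibitory weight (uS, >= 0).
#' @param lambda_i,lambda_e event rates (Hz, > 0).
#' @param tau_i,tau_e conductance time constants (s, > 0).
#' @param E_i,E_e reversal potentials (mV).
#' @param V_r resting potential (mV); must differ from both reversals.
#' @return excitatory weight (uS).
#' @export
balanced_weight <- function(w_i, lambda_i, lambda_e, tau_i, tau_e,
                            E_i = -90, E_e = 60, V_r) {
  stopifnot(w_i >= 0, lambda_i > 0, lambda_e > 0, tau_i > 0, tau_e > 0)
  if (V_r == E_i || V_r == E_e)
    stop("resting potential coincides with a noise reversal potential; ",
         "the balance condition is degenerate")
  w_i * abs(lambda_i * tau_i * (E_i - V_r)) /
    abs(lambda_e * tau_e * (E_e - V_r))
}

#' Noise bias of a simulated trace
#'
#' Compares a run with noise against the noiseless run of the same network:
#' the voltage bias is the mean of a Gaussian fit to the voltage histogram
#' minus the noiseless resting potential, and the current bias is the time
#' average of the injected noise current. The Gaussian is fit by nonlinear
#' least squares on a Freedman-Diaconis histogram; the raw mean is also
#' reported.
#'
#' @param V_noisy sampled voltage with noise (mV), >= 1000 samples.
#' @param V_rest noiseless resting potential (mV, scalar).
#' @param I_noise sampled noise current (nA), or `NULL`.
#' @return list with `voltage_bias` (Gaussian-fit mean minus `V_rest`, mV),
#'   `voltage_bias_raw` (raw mean minus `V_rest`), `current_bias` (mean nA,
#'   or `NA`), `fit_mean`, `fit_sd`.
#' @export
measure_bias <- function(V_noisy, V_rest, I_noise = NULL) {
  if (length(V_noisy) < 1000)
    stop("need at least 1000 voltage samples for a stable histogram fit")
  stopifnot(length(V_rest) == 1L)
  raw_mean <- mean(V_noisy)
  sdv <- stats::sd(V_noisy)
  if (sdv == 0) {
    fit_mean <- raw_mean; fit_sd <- 0
  } else {
    bw <- 2 * stats::IQR(V_noisy) / length(V_noisy)^(1 / 3)
    if (bw <= 0) bw <- sdv / 10
    breaks <- seq(min(V_noisy) - bw, max(V_noisy) + bw, by = bw)
    h <- graphics::hist(V_noisy, breaks = breaks, plot = FALSE)
    df <- data.frame(x = h$mids, y = h$density)
    fit <- tryCatch(
      stats::nls(y ~ a * exp(-(x - m)^2 / (2 * s^2)), data = df,
                 start = list(a = max(df$y), m = raw_mean, s = sdv),
                 control = stats::nls.control(warnOnly = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) { fit_mean <- raw_mean; fit_sd <- sdv }
    else { cf <- stats::coef(fit); fit_mean <- unname(cf["m"]); fit_sd <- abs(unname(cf["s"])) }
  }
  list(voltage_bias = fit_mean - V_rest,
       voltage_bias_raw = raw_mean - V_rest,
       current_bias = if (is.null(I_noise)) NA_real_ else mean(I_noise),
       fit_mean = fit_mean, fit_sd = fit_sd)
}
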