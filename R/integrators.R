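# Time integration: fixed-step explicit (Forward Euler), fixed-step
# semi-implicit (trapezoidal / Crank-Nicolson with fixed-point iteration),
# and adaptive stiff-capable integration via deSolve::lsoda.
#
# Event handling at fixed step: presynaptic threshold crossings are detected
# by sign change of (V - threshold) across a step, the event time is
# linearly interpolated, and the synaptic jumps (zd,zr += 1, d *= 1-u) are
# applied at the following step boundary. Poisson noise events falling in
# (t, t+dt] are applied as conductance jumps at the step boundary.
# A per-synapse refractory merge window (default 2 ms) collapses multiple
# crossings of one spike.

CPG_REFRACTORY <- 2e-3

clamp_state <- function(y, idx) {
  if (length(idx$gate)) y[idx$gate] <- pmin(pmax(y[idx$gate], 0), 1)
  if (length(idx$pool)) y[idx$pool] <- pmax(y[idx$pool], 0)
  if (length(idx$d)) y[idx$d] <- pmin(pmax(y[idx$d], 0), 1)
  if (length(idx$M2)) y[idx$M2] <- pmin(pmax(y[idx$M2], 0), 1)
  if (length(idx$gi)) y[idx$gi] <- pmax(y[idx$gi], 0)
  if (length(idx$ge)) y[idx$ge] <- pmax(y[idx$ge], 0)
  y
}

check_finite <- function(y, rt, t) {
  if (all(is.finite(y))) return(invisible())
  bad <- which(!is.finite(y))[1]
  stop(sprintf("integration failure at t = %.6g s: state '%s' is non-finite",
               t, rt$state_names[bad]))
}

#' One Forward Euler step
#'
#' `y <- y + dt * f(t, y)` on the full network state.
#'
#' @param y state vector.
#' @param model a `cpg_runtime` or `cpg_network`.
#' @param dt step size (s, > 0).
#' @param t current time (s).
#' @param stim_on evaluate with pulse stimuli active.
#' @return advanced state vector.
#' @export
step_forward_euler <- function(y, model, dt, t = 0, stim_on = TRUE) {
  rt <- if (inherits(model, "cpg_runtime")) model else build_runtime(model)
  stopifnot(dt > 0)
  y1 <- y + dt * rhs_eval(rt, t, y, stim_on)
  check_finite(y1, rt, t + dt)
  y1
}

#' One semi-implicit (Crank-Nicolson) step
#'
#' Trapezoidal rule `y1 = y + dt/2 * (f(t, y) + f(t + dt, y1))`, solved by
#' fixed-point iteration to absolute tolerance 1e-10 (at most 50
#' iterations). For the scalar linear test `dy/dt = -k*y` the step is
#' exactly `y * (1 - k*dt/2) / (1 + k*dt/2)`.
#'
#' @inheritParams step_forward_euler
#' @return advanced state vector.
#' @export
step_semi_implicit <- function(y, model, dt, t = 0, stim_on = TRUE) {
  rt <- if (inherits(model, "cpg_runtime")) model else build_runtime(model)
  stopifnot(dt > 0)
  f0 <- rhs_eval(rt, t, y, stim_on)
  z <- y + dt * f0
  base <- y + (dt / 2) * f0
  for (it in seq_len(50)) {
    z_new <- base + (dt / 2) * rhs_eval(rt, t + dt, z, stim_on)
    if (max(abs(z_new - z)) < 1e-10) { z <- z_new; check_finite(z, rt, t + dt); return(z) }
    z <- z_new
  }
  stop(sprintf(
    "semi-implicit step failed to converge in 50 iterations at t = %.6g s (dt = %g)",
    t, dt))
}

# Pre-generated noise events for one run: list with w_i, w_e and, per
# target, sorted event-time vectors ti / te on [0, t_end - t0].
make_noise_events <- function(rt, t0, t_end, master_seed) {
  if (rt$n_nz == 0L) return(NULL)
  nz <- rt$nz
  dur <- t_end - t0
  ti <- vector("list", rt$n_nz); te <- vector("list", rt$n_nz)
  for (k in seq_len(rt$n_nz)) {
    ti[[k]] <- t0 + poisson_train(nz$rate_i, dur,
                                  seed = substream_seed(master_seed, k, 1L))$times
    te[[k]] <- t0 + poisson_train(nz$rate_e, dur,
                                  seed = substream_seed(master_seed, k, 2L))$times
  }
  list(ti = ti, te = te)
}

# deterministic substream seed below 2^31
substream_seed <- function(master, target, kind) {
  as.integer((abs(as.numeric(master)) * 1009 + target * 7919 + kind * 104729) %%
               2147483647)
}

# Fixed-step driver. noise: list(events = make_noise_events(), w_i, w_e
# (per-target vectors)) or NULL. Returns recorded grid, state matrix,
# per-synapse event trains, final state and step counts.
integrate_fixed <- function(rt, y0, t0, t_end, dt, method = "forward_euler",
                            stim_on = TRUE, noise = NULL,
                            record_dt = NA_real_, refractory = CPG_REFRACTORY) {
  n <- max(1L, as.integer(round((t_end - t0) / dt)))
  stride <- if (is.na(record_dt)) 1L else max(1L, as.integer(round(record_dt / dt)))
  rec_at <- c(seq(0L, n, by = stride), n)
  rec_at <- unique(rec_at)
  Y <- matrix(NA_real_, length(rec_at), rt$n_state)
  times <- t0 + dt * rec_at
  idx <- rt$idx
  step_fn <- switch(method,
                    forward_euler = step_forward_euler,
                    semi_implicit_cn = step_semi_implicit,
                    stop("unknown fixed-step method: ", method))

  # per-step noise increment counts
  has_noise <- !is.null(noise) && rt$n_nz > 0L
  if (has_noise) {
    inc_i <- matrix(0, n, rt$n_nz); inc_e <- matrix(0, n, rt$n_nz)
    for (k in seq_len(rt$n_nz)) {
      bi <- ceiling((noise$events$ti[[k]] - t0) / dt)
      bi <- bi[bi >= 1 & bi <= n]
      if (length(bi)) inc_i[, k] <- tabulate(bi, n)
      be <- ceiling((noise$events$te[[k]] - t0) / dt)
      be <- be[be >= 1 & be <= n]
      if (length(be)) inc_e[, k] <- tabulate(be, n)
    }
    any_ev <- rowSums(inc_i) + rowSums(inc_e) > 0
  }

  syn_events <- vector("list", rt$n_cs)
  last_ev <- rep(-Inf, rt$n_cs)
  y <- y0
  rec_ptr <- 1L
  if (rec_at[1] == 0L) { Y[1, ] <- y; rec_ptr <- 2L }
  n_events <- 0L
  cs_pre <- rt$cs_pre; cs_thresh <- rt$cs_thresh
  for (k in seq_len(n)) {
    t <- t0 + (k - 1) * dt
    V_old <- y[idx$V]
    y <- step_fn(y, rt, dt, t, stim_on)
    if (has_noise && any_ev[k]) {
      y[idx$gi] <- y[idx$gi] + inc_i[k, ] * noise$w_i
      y[idx$ge] <- y[idx$ge] + inc_e[k, ] * noise$w_e
    }
    if (rt$n_cs) {
      V_new <- y[idx$V]
      vo <- V_old[cs_pre]; vn <- V_new[cs_pre]
      crossed <- vo < cs_thresh & vn >= cs_thresh
      if (any(crossed)) {
        tev <- t + dt * (cs_thresh - vo) / (vn - vo)
        fire <- which(crossed & (tev - last_ev) >= refractory)
        if (length(fire)) {
          y[idx$zd[fire]] <- y[idx$zd[fire]] + 1
          y[idx$zr[fire]] <- y[idx$zr[fire]] + 1
          y[idx$d[fire]] <- y[idx$d[fire]] * (1 - rt$cs_dep_u[fire])
          last_ev[fire] <- tev[fire]
          for (s in fire) syn_events[[s]] <- c(syn_events[[s]], tev[s])
          n_events <- n_events + length(fire)
        }
      }
    }
    y <- clamp_state(y, idx)
    if (rec_ptr <= length(rec_at) && rec_at[rec_ptr] == k) {
      Y[rec_ptr, ] <- y; rec_ptr <- rec_ptr + 1L
    }
  }
  list(times = times, Y = Y, y_end = y, steps = n,
       syn_events = syn_events, event_count = n_events)
}

# Adaptive driver (deSolve::lsoda). Discontinuities -- pulse edges and
# Poisson noise arrivals -- are segment boundaries; presynaptic threshold
# crossings are located by lsoda's root finder and the synaptic jumps
# applied at the root.
integrate_adaptive <- function(rt, y0, t0, t_end, abstol = 1e-6, reltol = 1e-6,
                               stim_on = TRUE, noise = NULL,
                               record_dt = 1e-3, refractory = CPG_REFRACTORY) {
  idx <- rt$idx
  grid <- seq(t0, t_end, by = record_dt)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  func <- function(t, y, parms) list(rhs_eval(rt, t, y, stim_on))
  rootfunc <- if (rt$n_cs > 0)
    function(t, y, parms) y[idx$V][rt$cs_pre] - rt$cs_thresh else NULL

  # breakpoints with attached conductance jumps
  bp_t <- numeric(); bp_gi <- list(); bp_ge <- list()
  if (stim_on && length(rt$st_comp)) {
    edges <- c(rt$st_t0[!rt$st_hold], rt$st_t1[!rt$st_hold])
    edges <- edges[is.finite(edges) & edges > t0 & edges < t_end]
    bp_t <- c(bp_t, edges)
  }
  has_noise <- !is.null(noise) && rt$n_nz > 0L
  jumps <- list()
  if (has_noise) {
    for (k in seq_len(rt$n_nz)) {
      for (tt in noise$events$ti[[k]])
        jumps[[length(jumps) + 1L]] <- list(t = tt, slot = idx$gi[k],
                                            w = noise$w_i[k])
      for (tt in noise$events$te[[k]])
        jumps[[length(jumps) + 1L]] <- list(t = tt, slot = idx$ge[k],
                                            w = noise$w_e[k])
    }
  }
  ev <- c(bp_t, vapply(jumps, `[[`, 0, "t"))
  ev_jump <- c(vector("list", length(bp_t)), jumps)
  o <- order(ev)
  ev <- ev[o]; ev_jump <- ev_jump[o]
  keep <- ev > t0 & ev < t_end
  ev <- ev[keep]; ev_jump <- ev_jump[keep]

  seg_ends <- c(ev, t_end)
  out_t <- numeric(0); out_Y <- NULL
  y <- y0; t_cur <- t0
  syn_events <- vector("list", rt$n_cs)
  last_ev <- rep(-Inf, rt$n_cs)
  n_events <- 0L; steps <- 0L
  record <- function(tt, yy) {
    out_t <<- c(out_t, tt)
    out_Y <<- rbind(out_Y, matrix(yy, 1))
  }
  record(t_cur, y)
  for (m in seq_along(seg_ends)) {
    seg_end <- seg_ends[m]
    while (t_cur < seg_end - 1e-12) {
      pts <- grid[grid > t_cur + 1e-12 & grid < seg_end - 1e-12]
      tv <- unique(c(t_cur, pts, seg_end))
      sol <- deSolve::lsoda(y, tv, func, parms = NULL,
                            rtol = reltol, atol = abstol,
                            rootfunc = rootfunc)
      steps <- steps + attr(sol, "istate")[3]
      troot <- attr(sol, "troot")
      got_root <- !is.null(troot) && length(troot) > 0 && is.finite(troot[1]) &&
        troot[1] < seg_end - 1e-12
      t_reached <- sol[nrow(sol), 1]
      for (r in 2:nrow(sol)) {
        tt <- sol[r, 1]
        if (any(abs(grid - tt) < 1e-12) || (!got_root && r == nrow(sol) &&
                                            abs(tt - seg_end) < 1e-12))
          record(tt, sol[r, -1])
      }
      y <- unname(sol[nrow(sol), -1])
      if (got_root) {
        t_cur <- t_reached
        dy <- rhs_eval(rt, t_cur, y, stim_on)
        vpre <- y[idx$V][rt$cs_pre]
        rising <- dy[idx$V][rt$cs_pre] > 0
        at_thr <- abs(vpre - rt$cs_thresh) < 1e-6 * (1 + abs(rt$cs_thresh))
        fire <- which(at_thr & rising & (t_cur - last_ev) >= refractory)
        if (length(fire)) {
          y[idx$zd[fire]] <- y[idx$zd[fire]] + 1
          y[idx$zr[fire]] <- y[idx$zr[fire]] + 1
          y[idx$d[fire]] <- y[idx$d[fire]] * (1 - rt$cs_dep_u[fire])
          last_ev[fire] <- t_cur
          for (s in fire) syn_events[[s]] <- c(syn_events[[s]], t_cur)
          n_events <- n_events + length(fire)
        }
        # nudge past the root so it is not re-detected immediately
        t_cur <- t_cur + 1e-9
      } else t_cur <- seg_end
      check_finite(y, rt, t_cur)
    }
    jmp <- if (m <= length(ev_jump)) ev_jump[[m]] else NULL
    if (!is.null(jmp)) y[jmp$slot] <- y[jmp$slot] + jmp$w
    t_cur <- seg_end
  }
  # interpolate recorded rows onto the requested grid
  ix <- match(round(grid / record_dt), round(out_t / record_dt))
  ok <- !is.na(ix)
  list(times = grid[ok], Y = out_Y[ix[ok], , drop = FALSE], y_end = y,
       steps = steps, syn_events = syn_events, event_count = n_events)
}

#' Relaxation period
#'
#' Integrates the network with pulse stimuli and noise disabled (holding
#' currents stay on) until `max |dV/dt| < relax_dvdt_tol` over all
#' compartments, or until `relax_max` is reached (a warning, not an error:
#' tonically active networks never settle). Recording then starts at t = 0.
#'
#' @param model a `cpg_runtime` or `cpg_network`.
#' @param y initial state (default [initial_state()]).
#' @param relax_max cap on the relaxation duration (s).
#' @param relax_dvdt_tol exit threshold on |dV/dt| (mV/s).
#' @param method,dt,abstol,reltol integration controls (defaults from the
#'   network's simulation config).
#' @return list with `state` (relaxed state vector) and `duration` (s).
#' @export
relax <- function(model, y = NULL, relax_max = NULL, relax_dvdt_tol = NULL,
                  method = NULL, dt = NULL, abstol = NULL, reltol = NULL) {
  rt <- if (inherits(model, "cpg_runtime")) model else build_runtime(model)
  cfg <- rt$spec$sim
  if (is.null(y)) y <- initial_state(rt)
  if (is.null(relax_max)) relax_max <- cfg$relax_max
  if (is.null(relax_dvdt_tol)) relax_dvdt_tol <- cfg$relax_dvdt_tol
  if (is.null(method)) method <- cfg$method
  if (is.null(dt)) dt <- cfg$dt
  if (is.null(abstol)) abstol <- cfg$abstol
  if (is.null(reltol)) reltol <- cfg$reltol

  dvdt <- function(yy) max(abs(rhs_eval(rt, 0, yy, stim_on = FALSE)[rt$idx$V]))
  t_done <- 0
  if (dvdt(y) < relax_dvdt_tol || relax_max == 0)
    return(list(state = y, duration = 0))
  chunk <- min(0.1, relax_max)
  while (t_done < relax_max) {
    step_to <- min(t_done + chunk, relax_max)
    if (method == "adaptive") {
      r <- integrate_adaptive(rt, y, t_done, step_to, abstol, reltol,
                              stim_on = FALSE,
                              record_dt = (step_to - t_done) / 5)
    } else {
      r <- integrate_fixed(rt, y, t_done, step_to, dt, method,
                           stim_on = FALSE,
                           record_dt = (step_to - t_done) / 5)
    }
    y <- r$y_end
    t_done <- step_to
    # settled only if |dV/dt| stayed below tolerance across the whole
    # chunk (an instantaneous check can be fooled by slow spike upstrokes)
    worst <- max(apply(r$Y, 1, dvdt))
    if (worst < relax_dvdt_tol) return(list(state = y, duration = t_done))
  }
  warning(sprintf(
    "relaxation reached the %g s cap with max |dV/dt| = %.3g mV/s",
    relax_max, dvdt(y)))
  list(state = y, duration = t_done)
}

# registered convergence-study problems: each has a network, a protocol,
# an initial state and an exact solution over time.
convergence_problem <- function(problem) {
  leaky_cell <- function(V0) {
    network_spec(
      point_neuron("L", Cm = 1,
                   channels = list(channel_spec("leak", gbar = 0.1, E = -60)),
                   V_init = V0),
      stimuli = if (problem == "leaky_pulse")
        list(stimulus_spec("L", "current_pulse", 2, 2, 7)) else list(),
      sim = simulation_config(duration = 10))
  }
  switch(problem,
         leaky_pulse = list(
           spec = leaky_cell(-60),
           t_end = 10,
           exact = function(t) leaky_exact(t, Cm = 1, g_leak = 0.1,
                                           V_leak = -60, I0 = 2,
                                           t0 = 2, t1 = 7)),
         smooth_decay = list(
           spec = leaky_cell(-40),
           t_end = 2,
           exact = function(t) -60 + 20 * exp(-t / 10)),
         stop("unknown convergence problem: ", problem,
              " (available: leaky_pulse, smooth_decay)"))
}

#' Empirical convergence order of a fixed-step method
#'
#' Integrates a registered test problem with an exact solution at each step
#' size, computes the RMSE of the recorded membrane potential against the
#' exact solution, and returns the least-squares slope of
#' `log10(RMSE)` versus `log10(dt)`.
#'
#' @param problem `"leaky_pulse"` (leak cell with a +2 nA pulse on 2-7 s,
#'   three-piece exact solution) or `"smooth_decay"` (leak cell released
#'   20 mV off rest, exponential exact solution).
#' @param method `"forward_euler"`, `"semi_implicit_cn"`, or `"exact"`
#'   (evaluates the exact solution itself; degenerate by construction and
#'   rejected with an error).
#' @param dts at least 4 step sizes (s) spanning at least two decades.
#' @return list with `slope`, and per-dt `rmse` (mV).
#' @export
convergence_slope <- function(problem, method, dts) {
  if (length(dts) < 4L || max(dts) / min(dts) < 100)
    stop("need >= 4 step sizes spanning >= 2 decades")
  pr <- convergence_problem(problem)
  rt <- build_runtime(pr$spec)
  y0 <- initial_state(rt)
  rmse <- vapply(dts, function(dt) {
    if (method == "exact") {
      tv <- seq(0, pr$t_end, by = dt)
      V <- pr$exact(tv)
    } else {
      r <- integrate_fixed(rt, y0, 0, pr$t_end, dt, method)
      tv <- r$times
      V <- r$Y[, rt$idx$V[1]]
    }
    sqrt(mean((V - pr$exact(tv))^2))
  }, 0)
  if (any(rmse == 0))
    stop("degenerate convergence study: RMSE is exactly zero")
  fit <- stats::lm(log10(rmse) ~ log10(dts))
  list(slope = unname(stats::coef(fit)[2]), dts = dts, rmse = rmse)
}
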