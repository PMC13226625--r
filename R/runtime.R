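# Runtime ("compiled") network model: flat, vectorised arrays built once
# from a cpg_network, plus the assembled ODE right-hand side.
#
# State vector layout (names in rt$state_names):
#   V     per compartment (mV)
#   gate  one entry per channel gate (activation then inactivation,
#         channel declaration order)
#   pool  per ion pool (mM)
#   zd,zr dual-exponential kinetic pair per chemical synapse
#   d     depression resource per chemical synapse (1 when unused)
#   M2    voltage-dependence factor per chemical synapse (1 when unused)
#   gi,ge noise conductances per noise target (uS)

incidence <- function(rows, n_rows, n_cols, w = 1) {
  M <- matrix(0, n_rows, n_cols)
  if (n_cols > 0 && length(rows)) M[cbind(rows, seq_len(n_cols))] <- w
  M
}

#' Build the runtime model for a network
#'
#' Flattens a validated [network_spec()] into indexed arrays used by the
#' derivative assembly and the integrators. Users normally do not call this
#' directly; [run_simulation()] does.
#'
#' @param spec a `cpg_network`.
#' @return an object of class `cpg_runtime`.
#' @export
build_runtime <- function(spec) {
  validate_network(spec)
  ct <- compartment_table(spec)
  comp_names <- ct$compartment
  n_comp <- length(comp_names)
  comp_idx <- function(nm) match(nm, comp_names)

  comps <- unlist(lapply(spec$neurons, `[[`, "compartments"), recursive = FALSE)
  Cm <- vapply(comps, `[[`, 0, "Cm")
  V_init <- vapply(comps, `[[`, 0, "V_init")

  # flatten channels / gates / pools ------------------------------------
  ch <- list(comp = integer(), gbar = numeric(), E = numeric(),
             p = integer(), q = integer(), act = integer(), inact = integer(),
             reg_pool = integer(), reg_act = logical(), reg_gamma = numeric(),
             name = character())
  gt <- list(h = numeric(), s = numeric(), tau_base = numeric(),
             tau_amp = numeric(), tau_h = numeric(), tau_s = numeric(),
             comp = integer(), name = character())
  pl <- list(comp = integer(), k1 = numeric(), k2 = numeric(),
             c_init = numeric(), name = character())
  pool_key <- character()   # "comp|pool" for lookup
  pool_src <- list()        # channel indices feeding each pool

  add_gate <- function(g, ci, nm) {
    gt$h <<- c(gt$h, g$h); gt$s <<- c(gt$s, g$s)
    gt$tau_base <<- c(gt$tau_base, g$tau$base)
    gt$tau_amp <<- c(gt$tau_amp, g$tau$amp)
    gt$tau_h <<- c(gt$tau_h, g$tau$h); gt$tau_s <<- c(gt$tau_s, g$tau$s)
    gt$comp <<- c(gt$comp, ci); gt$name <<- c(gt$name, nm)
    length(gt$h)
  }

  for (cp in comps) {
    ci <- comp_idx(cp$name)
    for (p in cp$pools) {
      pl$comp <- c(pl$comp, ci); pl$k1 <- c(pl$k1, p$k1)
      pl$k2 <- c(pl$k2, p$k2); pl$c_init <- c(pl$c_init, p$c_init)
      pl$name <- c(pl$name, p$name)
      pool_key <- c(pool_key, paste0(cp$name, "|", p$name))
      pool_src[[length(pool_key)]] <- integer()
    }
  }
  for (cp in comps) {
    ci <- comp_idx(cp$name)
    for (c0 in cp$channels) {
      k <- length(ch$comp) + 1L
      ch$comp <- c(ch$comp, ci); ch$gbar <- c(ch$gbar, c0$gbar)
      ch$E <- c(ch$E, c0$E); ch$p <- c(ch$p, c0$p); ch$q <- c(ch$q, c0$q)
      ch$name <- c(ch$name, paste0(cp$name, ":", c0$name))
      ch$act <- c(ch$act, if (is.null(c0$activation)) 0L else
        add_gate(c0$activation, ci, paste0(cp$name, ":", c0$name, ":m")))
      ch$inact <- c(ch$inact, if (is.null(c0$inactivation)) 0L else
        add_gate(c0$inactivation, ci, paste0(cp$name, ":", c0$name, ":h")))
      if (is.null(c0$regulation)) {
        ch$reg_pool <- c(ch$reg_pool, 0L)
        ch$reg_act <- c(ch$reg_act, TRUE); ch$reg_gamma <- c(ch$reg_gamma, 0)
      } else {
        pi <- match(paste0(cp$name, "|", c0$regulation$pool), pool_key)
        ch$reg_pool <- c(ch$reg_pool, pi)
        ch$reg_act <- c(ch$reg_act,
                        c0$regulation$form == "saturating_activation")
        ch$reg_gamma <- c(ch$reg_gamma, c0$regulation$gamma)
      }
      if (!is.null(c0$feeds_pool)) {
        pi <- match(paste0(cp$name, "|", c0$feeds_pool), pool_key)
        pool_src[[pi]] <- union(pool_src[[pi]], k)
      }
    }
    # pools may also name their sources explicitly
    chn_local <- vapply(cp$channels, `[[`, "", "name")
    for (p in cp$pools) {
      pi <- match(paste0(cp$name, "|", p$name), pool_key)
      src <- match(p$source_channels, chn_local)
      glob <- which(ch$comp == ci)[src]
      pool_src[[pi]] <- union(pool_src[[pi]], glob)
    }
  }
  n_ch <- length(ch$comp); n_gate <- length(gt$h); n_pool <- length(pl$k1)

  # synapses -------------------------------------------------------------
  es <- spec$electrical_synapses
  n_es <- length(es)
  es_i <- vapply(es, function(e) comp_idx(e$cell_i), 0L)
  es_j <- vapply(es, function(e) comp_idx(e$cell_j), 0L)
  es_g <- vapply(es, `[[`, 0, "gbar")
  es_rect <- vapply(es, `[[`, TRUE, "rectifying")

  cs <- spec$chemical_synapses
  n_cs <- length(cs)
  cs_pre <- vapply(cs, function(s) comp_idx(s$pre), 0L)
  cs_post <- vapply(cs, function(s) comp_idx(s$post), 0L)
  cs_w <- vapply(cs, `[[`, 0, "w")
  cs_E <- vapply(cs, `[[`, 0, "E")
  cs_taur <- vapply(cs, `[[`, 0, "tau_rise")
  cs_taud <- vapply(cs, `[[`, 0, "tau_decay")
  cs_norm <- if (n_cs) mapply(dualexp_norm, cs_taur, cs_taud) else numeric()
  cs_thresh <- vapply(cs, `[[`, 0, "threshold")
  cs_fac_pool <- vapply(cs, function(s) {
    if (is.null(s$facilitation)) 0L
    else match(paste0(s$pre, "|", s$facilitation$pool), pool_key)
  }, 0L)
  cs_fac_gamma <- vapply(cs, function(s)
    if (is.null(s$facilitation)) 0 else s$facilitation$gamma_f, 0)
  cs_dep_u <- vapply(cs, function(s)
    if (is.null(s$depression)) 0 else s$depression$u, 0)
  cs_dep_taurec <- vapply(cs, function(s)
    if (is.null(s$depression)) Inf else s$depression$tau_rec, 0)
  cs_has_vd <- vapply(cs, function(s) !is.null(s$voltage_dependence), TRUE)
  cs_vd_h <- vapply(cs, function(s)
    if (is.null(s$voltage_dependence)) 0 else s$voltage_dependence$h, 0)
  cs_vd_s <- vapply(cs, function(s)
    if (is.null(s$voltage_dependence)) 1 else s$voltage_dependence$s, 0)
  cs_vd_tau <- vapply(cs, function(s)
    if (is.null(s$voltage_dependence)) 1 else s$voltage_dependence$tau_m2, 0)
  cs_name <- vapply(cs, function(s) paste0(s$pre, "->", s$post), "")

  # noise ----------------------------------------------------------------
  nz <- spec$noise
  n_nz <- if (is.null(nz)) 0L else length(nz$targets)
  nz_comp <- if (n_nz) vapply(nz$targets, comp_idx, 0L) else integer()

  # stimuli --------------------------------------------------------------
  st <- spec$stimuli
  st_comp <- vapply(st, function(s) comp_idx(s$target), 0L)
  st_amp <- vapply(st, `[[`, 0, "amplitude")
  st_t0 <- vapply(st, `[[`, 0, "t_start")
  st_t1 <- vapply(st, `[[`, 0, "t_end")
  st_hold <- vapply(st, function(s) s$kind == "holding_current", TRUE)

  # state layout ---------------------------------------------------------
  off <- 0L
  seq_off <- function(n) { s <- if (n > 0) off + seq_len(n) else integer(); off <<- off + n; s }
  idx <- list(V = seq_off(n_comp), gate = seq_off(n_gate),
              pool = seq_off(n_pool), zd = seq_off(n_cs), zr = seq_off(n_cs),
              d = seq_off(n_cs), M2 = seq_off(n_cs),
              gi = seq_off(n_nz), ge = seq_off(n_nz))
  state_names <- c(paste0("V:", comp_names), gt$name,
                   if (n_pool) paste0("pool:", comp_names[pl$comp], ":", pl$name),
                   if (n_cs) paste0("zd:", cs_name), if (n_cs) paste0("zr:", cs_name),
                   if (n_cs) paste0("d:", cs_name), if (n_cs) paste0("M2:", cs_name),
                   if (n_nz) paste0("gi:", comp_names[nz_comp]),
                   if (n_nz) paste0("ge:", comp_names[nz_comp]))

  M_pool_src <- matrix(0, n_pool, n_ch)
  for (pi in seq_len(n_pool))
    if (length(pool_src[[pi]])) M_pool_src[pi, pool_src[[pi]]] <- 1
  M_es <- matrix(0, n_comp, n_es)
  if (n_es) { M_es[cbind(es_i, seq_len(n_es))] <- 1
              M_es[cbind(es_j, seq_len(n_es))] <-
                M_es[cbind(es_j, seq_len(n_es))] - 1 }

  structure(list(
    spec = spec, comp_names = comp_names, n_comp = n_comp, Cm = Cm,
    V_init = V_init,
    ch = ch, n_ch = n_ch, gt = gt, n_gate = n_gate, pl = pl, n_pool = n_pool,
    M_ch = incidence(ch$comp, n_comp, n_ch),
    M_pool_src = M_pool_src, M_es = M_es,
    M_cs = incidence(cs_post, n_comp, n_cs),
    M_nz = incidence(nz_comp, n_comp, n_nz),
    es_i = es_i, es_j = es_j, es_g = es_g, es_rect = es_rect, n_es = n_es,
    cs_pre = cs_pre, cs_post = cs_post, cs_w = cs_w, cs_E = cs_E,
    cs_taur = cs_taur, cs_taud = cs_taud, cs_norm = cs_norm,
    cs_thresh = cs_thresh, cs_fac_pool = cs_fac_pool,
    cs_fac_gamma = cs_fac_gamma, cs_dep_u = cs_dep_u,
    cs_dep_taurec = cs_dep_taurec, cs_has_vd = cs_has_vd,
    cs_vd_h = cs_vd_h, cs_vd_s = cs_vd_s, cs_vd_tau = cs_vd_tau,
    cs_name = cs_name, n_cs = n_cs,
    nz = nz, n_nz = n_nz, nz_comp = nz_comp,
    st_comp = st_comp, st_amp = st_amp, st_t0 = st_t0, st_t1 = st_t1,
    st_hold = st_hold,
    idx = idx, n_state = off, state_names = state_names,
    # hot-loop index caches
    hot = list(actI = which(ch$act > 0L), inactI = which(ch$inact > 0L),
               regI = which(ch$reg_pool > 0L),
               reg_actI = which(ch$reg_pool > 0L & ch$reg_act),
               reg_inhI = which(ch$reg_pool > 0L & !ch$reg_act),
               gate_vdI = which(gt$tau_amp > 0),
               facI = which(cs_fac_pool > 0L),
               depI = which(is.finite(cs_dep_taurec)),
               vdI = which(cs_has_vd), rectI = which(es_rect))),
    class = "cpg_runtime")
}

#' Initial state vector for a runtime model
#'
#' Compartments start at their `V_init` (default -60 mV where unset); gates
#' and M2 at their steady state for that voltage; pools at `c_init`;
#' synaptic kinetic states at 0; depression resources at 1; noise
#' conductances at 0.
#'
#' @param rt a `cpg_runtime`.
#' @return numeric state vector.
#' @export
initial_state <- function(rt) {
  y <- numeric(rt$n_state)
  V0 <- ifelse(is.na(rt$V_init), -60, rt$V_init)
  y[rt$idx$V] <- V0
  if (rt$n_gate)
    y[rt$idx$gate] <- gate_inf(V0[rt$gt$comp], rt$gt$h, rt$gt$s)
  if (rt$n_pool) y[rt$idx$pool] <- rt$pl$c_init
  if (rt$n_cs) {
    y[rt$idx$d] <- 1
    y[rt$idx$M2] <- ifelse(rt$cs_has_vd,
                           gate_inf(V0[rt$cs_post], rt$cs_vd_h, rt$cs_vd_s), 1)
  }
  y
}

# applied current per compartment at time t (holding currents always on;
# pulses only when stim_on)
applied_current <- function(rt, t, stim_on = TRUE) {
  I <- numeric(rt$n_comp)
  if (length(rt$st_comp)) {
    on <- rt$st_hold | (stim_on & t >= rt$st_t0 & t < rt$st_t1)
    if (any(on)) {
      k <- which(on)
      for (m in k) I[rt$st_comp[m]] <- I[rt$st_comp[m]] + rt$st_amp[m]
    }
  }
  I
}

# Core RHS. With breakdown = TRUE returns list(dy, currents) where currents
# is the per-compartment breakdown (I_app, I_vd, I_es, I_cs, I_noise),
# satisfying Cm * dV/dt = I_app - I_vd - I_es - I_cs - I_noise to round-off;
# otherwise just the derivative vector (hot path).
rhs_eval <- function(rt, t, y, stim_on = TRUE, breakdown = FALSE) {
  idx <- rt$idx
  V <- y[idx$V]
  dy <- numeric(rt$n_state)

  # channels and gates
  I_vd <- numeric(rt$n_comp)
  I_ch <- numeric(rt$n_ch)
  hot <- rt$hot
  if (rt$n_ch) {
    ch <- rt$ch
    g <- ch$gbar
    if (rt$n_gate) {
      A <- y[idx$gate]
      if (length(hot$actI)) {
        i <- hot$actI
        g[i] <- g[i] * A[ch$act[i]]^ch$p[i]
      }
      if (length(hot$inactI)) {
        i <- hot$inactI
        g[i] <- g[i] * A[ch$inact[i]]
      }
      gV <- V[rt$gt$comp]
      ginf <- 1 / (1 + exp((rt$gt$h - gV) / rt$gt$s))
      gtau <- rt$gt$tau_base
      if (length(hot$gate_vdI)) {
        i <- hot$gate_vdI
        gtau[i] <- gtau[i] +
          rt$gt$tau_amp[i] / cosh((gV[i] - rt$gt$tau_h[i]) / (2 * rt$gt$tau_s[i]))
      }
      dy[idx$gate] <- (ginf - A) / gtau
    }
    if (length(hot$reg_actI)) {
      i <- hot$reg_actI
      gc <- ch$reg_gamma[i] * y[idx$pool[ch$reg_pool[i]]]
      g[i] <- g[i] * gc / (1 + gc)
    }
    if (length(hot$reg_inhI)) {
      i <- hot$reg_inhI
      gc <- ch$reg_gamma[i] * y[idx$pool[ch$reg_pool[i]]]
      g[i] <- g[i] / (1 + gc)
    }
    I_ch <- g * (V[ch$comp] - ch$E)
    I_vd <- drop(rt$M_ch %*% I_ch)
  }

  # pools
  if (rt$n_pool) {
    cc <- y[idx$pool]
    I_src <- drop(rt$M_pool_src %*% I_ch)
    dy[idx$pool] <- rt$pl$k1 * (-rt$pl$k2 * I_src - cc)
  }

  # electrical synapses
  I_es <- numeric(rt$n_comp)
  if (rt$n_es) {
    Ie <- rt$es_g * (V[rt$es_i] - V[rt$es_j])
    if (length(hot$rectI)) {
      i <- hot$rectI
      Ie[i][V[rt$es_i[i]] < V[rt$es_j[i]]] <- 0
    }
    I_es <- drop(rt$M_es %*% Ie)
  }

  # chemical synapses
  I_cs <- numeric(rt$n_comp)
  if (rt$n_cs) {
    zd <- y[idx$zd]; zr <- y[idx$zr]; d <- y[idx$d]; M2 <- y[idx$M2]
    gain <- d
    if (length(hot$facI)) {
      i <- hot$facI
      gain[i] <- gain[i] *
        (1 + rt$cs_fac_gamma[i] * y[idx$pool[rt$cs_fac_pool[i]]])
    }
    M1 <- rt$cs_norm * (zd - zr) * gain
    Vpost <- V[rt$cs_post]
    I_each <- rt$cs_w * M1 * M2 * (Vpost - rt$cs_E)
    I_cs <- drop(rt$M_cs %*% I_each)
    dy[idx$zd] <- -zd / rt$cs_taud
    dy[idx$zr] <- -zr / rt$cs_taur
    if (length(hot$depI)) {
      i <- hot$depI
      dy[idx$d[i]] <- (1 - d[i]) / rt$cs_dep_taurec[i]
    }
    if (length(hot$vdI)) {
      i <- hot$vdI
      dy[idx$M2[i]] <- (gate_inf(Vpost[i], rt$cs_vd_h[i], rt$cs_vd_s[i]) -
                          M2[i]) / rt$cs_vd_tau[i]
    }
  }

  # noise conductances
  I_noise <- numeric(rt$n_comp)
  if (rt$n_nz) {
    gi <- y[idx$gi]; ge <- y[idx$ge]
    Vn <- V[rt$nz_comp]
    I_noise <- drop(rt$M_nz %*%
                      (gi * (Vn - rt$nz$E_i) + ge * (Vn - rt$nz$E_e)))
    dy[idx$gi] <- -gi / rt$nz$tau_i
    dy[idx$ge] <- -ge / rt$nz$tau_e
  }

  I_app <- applied_current(rt, t, stim_on)
  dy[idx$V] <- (I_app - I_vd - I_es - I_cs - I_noise) / rt$Cm
  if (!breakdown) return(dy)
  list(dy = dy,
       currents = list(I_app = I_app, I_vd = I_vd, I_es = I_es,
                       I_cs = I_cs, I_noise = I_noise))
}

#' Assemble the state derivative and current breakdown
#'
#' Evaluates the full right-hand side of the network ODE system at state
#' `y`: per-compartment `Cm*dV/dt = I_app - sum(I_vd) - sum(I_es) -
#' sum(I_cs) - I_noise`, plus gate, pool, synaptic-kinetics and noise-state
#' derivatives. The returned breakdown satisfies that identity to round-off.
#'
#' @param y numeric state vector (see [initial_state()] for the layout), or
#'   `NULL` for the initial state.
#' @param model a `cpg_runtime` or `cpg_network`.
#' @param t time (s); affects pulse stimuli.
#' @param stim_on logical; evaluate with pulse stimuli active.
#' @return list with `derivative` (numeric vector) and `currents`
#'   (per-compartment breakdown: `I_app`, `I_vd`, `I_es`, `I_cs`,
#'   `I_noise`, all nA).
#' @export
assemble_derivative <- function(y = NULL, model, t = 0, stim_on = TRUE) {
  rt <- if (inherits(model, "cpg_runtime")) model else build_runtime(model)
  if (is.null(y)) y <- initial_state(rt)
  if (length(y) != rt$n_state)
    stop(sprintf("state has %d elements, model needs %d", length(y), rt$n_state))
  r <- rhs_eval(rt, t, y, stim_on, breakdown = TRUE)
  list(derivative = r$dy, currents = r$currents)
}
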