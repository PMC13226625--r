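# Run orchestration: build runtime, relax, resolve noise weights, simulate,
# record, and package the results.

spec_hash <- function(spec) {
  tmp <- tempfile(); on.exit(unlink(tmp))
  writeBin(serialize(spec, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

apply_overrides <- function(cfg, overrides) {
  allowed <- c("duration", "method", "dt", "abstol", "reltol", "relax_max",
               "relax_dvdt_tol", "record", "seed", "record_dt")
  bad <- setdiff(names(overrides), allowed)
  if (length(bad)) stop("unknown override(s): ", paste(bad, collapse = ", "))
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  do.call(simulation_config, cfg[allowed])
}

# derive every recordable series from recorded state rows
derive_traces <- function(rt, times, Y) {
  idx <- rt$idx
  data <- list()
  for (i in seq_len(rt$n_comp))
    data[[paste0(rt$comp_names[i], ":V")]] <- Y[, idx$V[i]]
  for (p in seq_len(rt$n_pool))
    data[[paste0(rt$comp_names[rt$pl$comp[p]], ":[", rt$pl$name[p], "]")]] <-
      Y[, idx$pool[p]]
  if (rt$n_ch) {
    for (k in seq_len(rt$n_ch)) {
      g <- rep(rt$ch$gbar[k], nrow(Y))
      if (rt$ch$act[k] > 0)
        g <- g * Y[, idx$gate[rt$ch$act[k]]]^rt$ch$p[k]
      if (rt$ch$inact[k] > 0)
        g <- g * Y[, idx$gate[rt$ch$inact[k]]]
      freg <- NULL
      if (rt$ch$reg_pool[k] > 0) {
        gc <- rt$ch$reg_gamma[k] * Y[, idx$pool[rt$ch$reg_pool[k]]]
        freg <- if (rt$ch$reg_act[k]) gc / (1 + gc) else 1 / (1 + gc)
        g <- g * freg
      }
      I <- g * (Y[, idx$V[rt$ch$comp[k]]] - rt$ch$E[k])
      data[[paste0("I:", rt$ch$name[k])]] <- I
      if (!is.null(freg)) data[[paste0("f:", rt$ch$name[k])]] <- freg
    }
  }
  if (rt$n_cs) {
    for (s in seq_len(rt$n_cs)) {
      gain <- Y[, idx$d[s]]
      if (rt$cs_fac_pool[s] > 0)
        gain <- gain * (1 + rt$cs_fac_gamma[s] *
                          Y[, idx$pool[rt$cs_fac_pool[s]]])
      M1 <- rt$cs_norm[s] * (Y[, idx$zd[s]] - Y[, idx$zr[s]]) * gain
      Vpost <- Y[, idx$V[rt$cs_post[s]]]
      data[[paste0("I:", rt$cs_name[s])]] <-
        rt$cs_w[s] * M1 * Y[, idx$M2[s]] * (Vpost - rt$cs_E[s])
      data[[paste0("M1:", rt$cs_name[s])]] <- M1
    }
  }
  if (rt$n_nz) {
    for (k in seq_len(rt$n_nz)) {
      Vn <- Y[, idx$V[rt$nz_comp[k]]]
      data[[paste0(rt$comp_names[rt$nz_comp[k]], ":I_noise")]] <-
        Y[, idx$gi[k]] * (Vn - rt$nz$E_i) + Y[, idx$ge[k]] * (Vn - rt$nz$E_e)
    }
  }
  data
}

filter_record <- function(data, record, comp_names) {
  if (is.null(record)) return(data)
  keep <- rep(FALSE, length(data))
  nm <- names(data)
  for (req in record) {
    if (req %in% comp_names) {
      keep <- keep | startsWith(nm, paste0(req, ":"))
    } else keep <- keep | nm == req
  }
  if (!any(keep)) stop("record request matched no series")
  data[keep]
}

#' Run one network simulation
#'
#' Relaxes the network (pulse stimuli and noise off, holding currents on),
#' resolves the balanced excitatory noise weight from the relaxed resting
#' potential of each noise target, then integrates for the configured
#' duration with recording starting at t = 0. Deterministic for a fixed
#' spec + seed + method.
#'
#' @param spec a [network_spec()].
#' @param overrides named list overriding [simulation_config()] fields
#'   (e.g. `list(duration = 0.1, method = "adaptive", seed = 7)`).
#' @return a `cpg_traces` object; its `report` element is the integration
#'   report (method, steps, step size or tolerance, relaxation duration,
#'   event count) and its `events` element holds one spike train per
#'   chemical synapse plus the Poisson noise trains.
#' @export
run_simulation <- function(spec, overrides = list()) {
  validate_network(spec)
  cfg <- apply_overrides(unclass(spec$sim), overrides)
  spec$sim <- cfg
  rt <- build_runtime(spec)
  y0 <- initial_state(rt)
  rx <- relax(rt, y0, method = cfg$method, dt = cfg$dt,
              abstol = cfg$abstol, reltol = cfg$reltol,
              relax_max = cfg$relax_max, relax_dvdt_tol = cfg$relax_dvdt_tol)
  y <- rx$state

  noise <- NULL
  if (rt$n_nz > 0) {
    nz <- rt$nz
    V_r <- y[rt$idx$V][rt$nz_comp]
    w_e <- vapply(V_r, function(v)
      if (nz$w_i == 0) 0
      else balanced_weight(nz$w_i, nz$rate_i, nz$rate_e, nz$tau_i, nz$tau_e,
                           nz$E_i, nz$E_e, v), 0)
    master <- (as.numeric(nz$seed) + 31 * as.numeric(cfg$seed)) %% 2147483647
    noise <- list(events = make_noise_events(rt, 0, cfg$duration, master),
                  w_i = rep(nz$w_i, rt$n_nz), w_e = w_e)
  }

  record_dt <- if (!is.na(cfg$record_dt)) cfg$record_dt
  else if (cfg$method == "adaptive") 1e-3 else NA_real_
  if (cfg$method == "adaptive") {
    r <- integrate_adaptive(rt, y, 0, cfg$duration, cfg$abstol, cfg$reltol,
                            stim_on = TRUE, noise = noise,
                            record_dt = record_dt)
    res_ctrl <- c(abstol = cfg$abstol, reltol = cfg$reltol)
  } else {
    r <- integrate_fixed(rt, y, 0, cfg$duration, cfg$dt, cfg$method,
                         stim_on = TRUE, noise = noise,
                         record_dt = record_dt)
    res_ctrl <- c(dt = cfg$dt)
  }

  data <- filter_record(derive_traces(rt, r$times, r$Y), cfg$record,
                        rt$comp_names)
  events <- list()
  if (rt$n_cs)
    for (s in seq_len(rt$n_cs))
      events[[paste0("spikes:", rt$cs_name[s])]] <-
        event_train(r$syn_events[[s]] %||% numeric(), rt$cs_name[s], "spike")
  if (!is.null(noise)) {
    for (k in seq_len(rt$n_nz)) {
      cn <- rt$comp_names[rt$nz_comp[k]]
      events[[paste0("noise_i:", cn)]] <-
        event_train(noise$events$ti[[k]], cn, "poisson_i")
      events[[paste0("noise_e:", cn)]] <-
        event_train(noise$events$te[[k]], cn, "poisson_e")
    }
  }
  report <- structure(list(method = cfg$method, steps = r$steps,
                           control = res_ctrl,
                           relax_duration = rx$duration,
                           event_count = r$event_count),
                      class = "cpg_report")
  manifest <- list(seed = cfg$seed, method = cfg$method,
                   spec_hash = spec_hash(spec),
                   relax_duration = rx$duration,
                   w_e = if (is.null(noise)) NULL else noise$w_e)
  new_traceset(r$times, data, events, manifest, report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cpg_report <- function(x, ...) {
  cat(sprintf(
    "<cpg_report> %s: %d steps (%s), relaxation %.3g s, %d synaptic event(s)\n",
    x$method, x$steps,
    paste(names(x$control), signif(x$control, 3), sep = "=", collapse = ", "),
    x$relax_duration, x$event_count))
  invisible(x)
}

#' Run a batch of simulations
#'
#' Runs each item (a spec, or `list(spec, overrides)`) in order, isolating
#' per-item failures: a failing item yields a `cpg_failure` sentinel
#' carrying the error message while the rest of the batch completes.
#' Results are identical to serial execution for any `batch_size`.
#'
#' @param items list of [network_spec()] objects or `list(spec, overrides)`
#'   pairs.
#' @param batch_size number of items per processing chunk (>= 1; chunking
#'   only, results are order-preserving and batch-size invariant).
#' @param fn worker function, default [run_simulation()].
#' @return list of results (traces or `cpg_failure`).
#' @export
run_batch <- function(items, batch_size = 1L, fn = NULL) {
  stopifnot(batch_size >= 1L)
  if (is.null(fn))
    fn <- function(it) {
      if (inherits(it, "cpg_network")) run_simulation(it)
      else run_simulation(it[[1]], it[[2]])
    }
  out <- vector("list", length(items))
  chunks <- split(seq_along(items),
                  ceiling(seq_along(items) / batch_size))
  for (ch in chunks) {
    out[ch] <- lapply(items[ch], function(it)
      tryCatch(fn(it), error = function(e)
        structure(list(error = conditionMessage(e)), class = "cpg_failure")))
  }
  out
}
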