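# Burst detection, motor-pattern phase durations, and the two-parameter
# grid search fitting phase durations to target values.

#' Detect bursts in a spike train
#'
#' A burst is a maximal run of spikes whose consecutive inter-spike
#' intervals are all `<= max_isi`, containing at least `min_spikes` spikes.
#' Burst onset and offset are the first and last spike times.
#'
#' @param spikes a [event_train()] or sorted numeric spike times (s).
#' @param max_isi maximum intra-burst inter-spike interval (s).
#' @param min_spikes minimum spikes per burst.
#' @param source source label attached to the result.
#' @return `data.frame` with columns `onset`, `offset`, `duration`,
#'   `n_spikes`, `source` (zero rows if none).
#' @export
detect_bursts <- function(spikes, max_isi = 0.5, min_spikes = 3L,
                          source = "") {
  tt <- if (inherits(spikes, "cpg_events")) spikes$times else as.numeric(spikes)
  if (inherits(spikes, "cpg_events") && !nzchar(source)) source <- spikes$source
  empty <- data.frame(onset = numeric(), offset = numeric(),
                      duration = numeric(), n_spikes = integer(),
                      source = character())
  if (length(tt) == 0) return(empty)
  if (is.unsorted(tt)) stop("spike times must be sorted")
  grp <- cumsum(c(1, diff(tt) > max_isi))
  on <- tapply(tt, grp, min); off <- tapply(tt, grp, max)
  n <- tapply(tt, grp, length)
  keep <- n >= min_spikes
  if (!any(keep)) return(empty)
  data.frame(onset = unname(on[keep]), offset = unname(off[keep]),
             duration = unname(off[keep] - on[keep]),
             n_spikes = as.integer(unname(n[keep])), source = source)
}

#' Motor-pattern phase durations
#'
#' Pairs each protraction burst with the next retraction burst that starts
#' after it (and before the following protraction burst); each pair is one
#' motor pattern. Phase duration is first-to-last spike of the burst. The
#' first pattern is excluded from the summary; unpaired bursts at the tail
#' are dropped with a warning.
#'
#' @param pro_bursts,ret_bursts burst tables from [detect_bursts()] for the
#'   protraction- and retraction-phase cells.
#' @return object of class `cpg_phase_summary`: per-phase mean, SD, SEM and
#'   `n` (patterns after exclusion); `empty` is `TRUE` when no pattern
#'   survives exclusion. The per-pattern duration matrix is in `$patterns`.
#' @export
phase_durations <- function(pro_bursts, ret_bursts) {
  pairs <- NULL
  if (nrow(pro_bursts)) {
    nxt_pro <- c(pro_bursts$onset[-1], Inf)
    for (k in seq_len(nrow(pro_bursts))) {
      cand <- which(ret_bursts$onset >= pro_bursts$offset[k] &
                      ret_bursts$onset < nxt_pro[k])
      if (length(cand)) {
        pairs <- rbind(pairs, c(pro_bursts$duration[k],
                                ret_bursts$duration[cand[1]]))
      } else if (k < nrow(pro_bursts)) {
        warning("protraction burst ", k, " has no matching retraction burst")
      } else {
        warning("unpaired trailing protraction burst dropped")
      }
    }
  }
  mk <- function(x) {
    if (length(x) == 0)
      return(c(mean = NA_real_, sd = NA_real_, sem = NA_real_))
    c(mean = mean(x), sd = stats::sd(x),
      sem = stats::sd(x) / sqrt(length(x)))
  }
  kept <- if (is.null(pairs) || nrow(pairs) < 2L) NULL
  else pairs[-1, , drop = FALSE]   # first pattern excluded
  n <- if (is.null(kept)) 0L else nrow(kept)
  structure(list(
    protraction = mk(kept[, 1]), retraction = mk(kept[, 2]),
    n = n, empty = n < 1L,
    patterns = if (is.null(pairs)) matrix(numeric(), 0, 2) else pairs),
    class = "cpg_phase_summary")
}

#' @export
print.cpg_phase_summary <- function(x, ...) {
  if (x$empty) { cat("<cpg_phase_summary> empty (no pattern after exclusion)\n")
    return(invisible(x)) }
  cat(sprintf(
    "<cpg_phase_summary> %d pattern(s): protraction %.3g +/- %.3g s, retraction %.3g +/- %.3g s\n",
    x$n, x$protraction["mean"], x$protraction["sd"],
    x$retraction["mean"], x$retraction["sd"]))
  invisible(x)
}

#' Squared-error objective against target phase durations
#'
#' `(mean_P - target_P)^2 + (mean_R - target_R)^2` in s^2. An empty
#' summary yields `Inf` (the sentinel worst objective, never selected as an
#' argmin when any grid cell succeeds).
#'
#' @param summary a `cpg_phase_summary`.
#' @param target_protraction,target_retraction target durations (s).
#' @return squared error (s^2).
#' @export
phase_objective <- function(summary, target_protraction, target_retraction) {
  if (summary$empty) return(Inf)
  (summary$protraction[["mean"]] - target_protraction)^2 +
    (summary$retraction[["mean"]] - target_retraction)^2
}

# default simulation backend for the sweep: run, detect spikes on the two
# phase cells, extract bursts, summarise
sweep_backend <- function(cells, burst_args, overrides = list()) {
  function(spec) {
    tr <- run_simulation(spec, overrides)
    summ <- lapply(cells, function(cn) {
      sp <- detect_spikes(trace_series(tr, paste0(cn, ":V")), tr$time,
                          source = cn)
      do.call(detect_bursts, c(list(sp), burst_args))
    })
    phase_durations(summ[[1]], summ[[2]])
  }
}

#' Two-parameter grid search on phase durations
#'
#' Simulates the network once per mesh cell with two scalar parameters
#' patched by workbook address (`"Sheet:row:column"`, row 1-based within
#' the sheet's data rows), extracts protraction/retraction phase durations,
#' and minimises the squared error against target durations. Each cell uses
#' a deterministic seed derived from the master seed and cell index, so
#' results are identical for any batch size or execution order. Individual
#' simulation failures leave an `Inf` sentinel in that cell and the sweep
#' continues.
#'
#' @param spec a [network_spec()].
#' @param param1,param2 `list(address = "Sheet:row:column", values = <mesh>)`.
#' @param targets `c(protraction, retraction)` target durations (s).
#' @param cells `c(protraction_cell, retraction_cell)` compartment names
#'   whose spiking defines the phases.
#' @param batch_size chunk size for batched execution (results are
#'   batch-size invariant).
#' @param seed master seed; cell (i, j) runs with
#'   `seed + (i-1)*length(mesh2) + (j-1)`.
#' @param burst_args list passed to [detect_bursts()] (`max_isi`,
#'   `min_spikes`).
#' @param overrides simulation overrides applied to every cell.
#' @param simulate_fn optional backend: `function(spec)` returning a
#'   `cpg_phase_summary` (used by tests with mock dynamics); default runs
#'   [run_simulation()].
#' @return object of class `cpg_sweep`: axes, duration matrices
#'   (`protraction`, `retraction`), `objective` matrix, and `argmin`
#'   (indices, parameter values, objective; ties broken by lowest index
#'   pair).
#' @export
grid_search <- function(spec, param1, param2, targets, cells = NULL,
                        batch_size = 1L, seed = spec$sim$seed,
                        burst_args = list(max_isi = 0.5, min_spikes = 3L),
                        overrides = list(), simulate_fn = NULL) {
  stopifnot(length(param1$values) >= 1L, length(param2$values) >= 1L,
            length(targets) == 2L)
  if (is.null(simulate_fn)) {
    if (is.null(cells) || length(cells) != 2L)
      stop("'cells' must name the protraction and retraction compartments")
    simulate_fn <- sweep_backend(cells, burst_args, overrides)
  }
  n1 <- length(param1$values); n2 <- length(param2$values)
  cells_ij <- expand.grid(j = seq_len(n2), i = seq_len(n1))[, c("i", "j")]
  one_cell <- function(m) {
    i <- cells_ij$i[m]; j <- cells_ij$j[m]
    sp <- set_workbook_param(spec, param1$address, param1$values[i])
    sp <- set_workbook_param(sp, param2$address, param2$values[j])
    sp$sim$seed <- as.integer((seed + (i - 1) * n2 + (j - 1)) %% 2147483647)
    tryCatch({
      summ <- simulate_fn(sp)
      c(P = unname(summ$protraction[["mean"]]),
        R = unname(summ$retraction[["mean"]]),
        obj = phase_objective(summ, targets[1], targets[2]))
    }, error = function(e) {
      warning(sprintf("sweep cell (%d, %d) failed: %s", i, j,
                      conditionMessage(e)))
      c(P = NA_real_, R = NA_real_, obj = Inf)
    })
  }
  res <- vector("list", nrow(cells_ij))
  chunks <- split(seq_len(nrow(cells_ij)),
                  ceiling(seq_len(nrow(cells_ij)) / max(1L, batch_size)))
  for (ch in chunks) res[ch] <- lapply(ch, one_cell)
  res <- do.call(rbind, res)
  shape <- function(col) matrix(res[, col], n1, n2, byrow = TRUE)
  obj <- shape("obj")
  best <- which(obj == min(obj), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  structure(list(
    axis1 = param1, axis2 = param2, targets = targets,
    protraction = shape("P"), retraction = shape("R"), objective = obj,
    argmin = list(index = unname(best),
                  values = c(param1$values[best[1]], param2$values[best[2]]),
                  objective = obj[best[1], best[2]]),
    seed = seed),
    class = "cpg_sweep")
}

#' @export
print.cpg_sweep <- function(x, ...) {
  cat(sprintf("<cpg_sweep> %d x %d mesh (%d cells)\n",
              nrow(x$objective), ncol(x$objective), length(x$objective)))
  cat(sprintf("  argmin at (%d, %d): %s = %.6g, %s = %.6g, objective %.6g s^2\n",
              x$argmin$index[1], x$argmin$index[2],
              x$axis1$address, x$argmin$values[1],
              x$axis2$address, x$argmin$values[2], x$argmin$objective))
  invisible(x)
}

#' Write a sweep result to disk
#'
#' A JSON manifest (axes, targets, argmin, seed) plus one TSV matrix per
#' quantity (protraction, retraction, objective) with axis values in the
#' header row/column.
#'
#' @param x a `cpg_sweep`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_sweep <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(axis1 = x$axis1, axis2 = x$axis2, targets = x$targets,
         argmin = x$argmin, seed = x$seed),
    file.path(dir, "sweep.json"), auto_unbox = TRUE, digits = NA)
  for (q in c("protraction", "retraction", "objective")) {
    m <- x[[q]]
    df <- data.frame(axis1 = x$axis1$values, m, check.names = FALSE)
    names(df) <- c(paste0(x$axis1$address, "\\", x$axis2$address),
                   format(x$axis2$values))
    utils::write.table(df, file.path(dir, paste0(q, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
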