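# Workbook-based network description: a single plain-text file with named
# [Sheet] sections of tab-separated values (information-equivalent to a
# spreadsheet with named sheets; .xlsx files are also read when the readxl
# package is installed). Sheet and column schema:
#
#   Neurons            neuron, compartment, Cm, V_init
#   Channels           neuron, compartment, channel, gbar, E, p, q,
#                      act_h, act_s, act_tau_base, act_tau_amp, act_tau_h,
#                      act_tau_s, inact_h, inact_s, inact_tau_base,
#                      inact_tau_amp, inact_tau_h, inact_tau_s,
#                      regulation_pool, regulation_form, gamma, feeds_pool
#   Pools              neuron, compartment, pool, k1, k2, source_channels,
#                      c_init
#   ElectricalSynapses cell_i, cell_j, gbar, rectifying
#   ChemicalSynapses   pre, post, w, E, tau_rise, tau_decay, threshold,
#                      fac_pool, fac_gamma, dep_u, dep_tau_rec, vd_h, vd_s,
#                      vd_tau
#   Noise (optional)   target, rate_i, rate_e, interval_i, interval_e, w_i,
#                      tau_i, tau_e, E_i, E_e, seed
#   Stimuli            target, kind, amplitude, t_start, t_end
#   Simulation         setting, value   (duration, method, dt, abstol,
#                      reltol, relax_max, relax_dvdt_tol, seed, record_dt,
#                      record*)
#
# Empty cells are "absent". Unknown sheets are ignored with a warning;
# unknown columns inside known sheets are errors. Canonical row ordering on
# save: neurons alphabetically, channels and synapses in declaration order.

wb_schema <- list(
  Neurons = c("neuron", "compartment", "Cm", "V_init"),
  Channels = c("neuron", "compartment", "channel", "gbar", "E", "p", "q",
               "act_h", "act_s", "act_tau_base", "act_tau_amp", "act_tau_h",
               "act_tau_s", "inact_h", "inact_s", "inact_tau_base",
               "inact_tau_amp", "inact_tau_h", "inact_tau_s",
               "regulation_pool", "regulation_form", "gamma", "feeds_pool"),
  Pools = c("neuron", "compartment", "pool", "k1", "k2", "source_channels",
            "c_init"),
  ElectricalSynapses = c("cell_i", "cell_j", "gbar", "rectifying"),
  ChemicalSynapses = c("pre", "post", "w", "E", "tau_rise", "tau_decay",
                       "threshold", "fac_pool", "fac_gamma", "dep_u",
                       "dep_tau_rec", "vd_h", "vd_s", "vd_tau"),
  Noise = c("target", "rate_i", "rate_e", "interval_i", "interval_e", "w_i",
            "tau_i", "tau_e", "E_i", "E_e", "seed"),
  Stimuli = c("target", "kind", "amplitude", "t_start", "t_end"),
  Simulation = c("setting", "value"))
wb_mandatory <- setdiff(names(wb_schema), "Noise")

wb_err <- function(sheet, row, col, msg)
  stop(sprintf("workbook error [sheet %s, row %s, column %s]: %s",
               sheet, row, col, msg), call. = FALSE)

wb_cell <- function(df, sheet, row, col) {
  if (!col %in% names(df)) return(NA_character_)
  v <- df[[col]][row]
  v <- as.character(v)
  if (is.na(v) || !nzchar(trimws(v))) NA_character_ else trimws(v)
}

wb_num <- function(df, sheet, row, col, default = NA_real_) {
  v <- wb_cell(df, sheet, row, col)
  if (is.na(v)) return(default)
  x <- suppressWarnings(as.numeric(v))
  if (is.na(x)) wb_err(sheet, row, col, sprintf("'%s' is not numeric", v))
  x
}

wb_lgl <- function(df, sheet, row, col, default = FALSE) {
  v <- wb_cell(df, sheet, row, col)
  if (is.na(v)) return(default)
  if (toupper(v) %in% c("TRUE", "T", "1", "YES")) return(TRUE)
  if (toupper(v) %in% c("FALSE", "F", "0", "NO")) return(FALSE)
  wb_err(sheet, row, col, sprintf("'%s' is not logical", v))
}

check_sheets <- function(sheets) {
  missing <- setdiff(wb_mandatory, names(sheets))
  if (length(missing))
    stop("workbook schema error: missing mandatory sheet '", missing[1], "'",
         call. = FALSE)
  extra <- setdiff(names(sheets), names(wb_schema))
  if (length(extra))
    warning("ignoring unknown sheet(s): ", paste(extra, collapse = ", "))
  for (sh in intersect(names(sheets), names(wb_schema))) {
    bad <- setdiff(names(sheets[[sh]]), wb_schema[[sh]])
    if (length(bad))
      stop(sprintf("workbook schema error: unknown column '%s' in sheet %s",
                   bad[1], sh), call. = FALSE)
    # normalise cells: trimmed strings, empty -> NA
    sheets[[sh]][] <- lapply(sheets[[sh]], function(col) {
      col <- trimws(as.character(col))
      col[!nzchar(col)] <- NA_character_
      col
    })
  }
  sheets[intersect(names(wb_schema), names(sheets))]
}

# sheets (list of data frames) -> cpg_network
sheets_to_spec <- function(sheets) {
  sheets <- check_sheets(sheets)
  ne <- sheets$Neurons
  if (nrow(ne) == 0) stop("workbook has no neurons", call. = FALSE)
  gate_from <- function(df, row, prefix) {
    h <- wb_num(df, "Channels", row, paste0(prefix, "_h"))
    if (is.na(h)) return(NULL)
    s <- wb_num(df, "Channels", row, paste0(prefix, "_s"))
    base <- wb_num(df, "Channels", row, paste0(prefix, "_tau_base"))
    amp <- wb_num(df, "Channels", row, paste0(prefix, "_tau_amp"), 0)
    if (is.na(s)) wb_err("Channels", row, paste0(prefix, "_s"), "missing")
    if (is.na(base)) wb_err("Channels", row, paste0(prefix, "_tau_base"),
                            "missing")
    gate_spec(h, s, tau = list(
      base = base, amp = amp,
      h = wb_num(df, "Channels", row, paste0(prefix, "_tau_h"), 0),
      s = wb_num(df, "Channels", row, paste0(prefix, "_tau_s"), 1)))
  }
  neurons <- list()
  for (nn in unique(ne$neuron)) {
    rows <- which(ne$neuron == nn)
    comps <- lapply(rows, function(r) {
      cn <- wb_cell(ne, "Neurons", r, "compartment")
      if (is.na(cn)) cn <- nn
      ch_comp <- sheets$Channels$compartment
      ch_comp[is.na(ch_comp)] <- sheets$Channels$neuron[is.na(ch_comp)]
      chrows <- which(sheets$Channels$neuron == nn & ch_comp == cn)
      channels <- lapply(chrows, function(cr) {
        df <- sheets$Channels
        reg <- NULL
        rp <- wb_cell(df, "Channels", cr, "regulation_pool")
        if (!is.na(rp)) {
          form <- wb_cell(df, "Channels", cr, "regulation_form")
          if (is.na(form)) wb_err("Channels", cr, "regulation_form", "missing")
          reg <- regulation_link(rp, form,
                                 wb_num(df, "Channels", cr, "gamma", 0))
        }
        act <- gate_from(df, cr, "act")
        channel_spec(
          name = wb_cell(df, "Channels", cr, "channel"),
          gbar = wb_num(df, "Channels", cr, "gbar"),
          E = wb_num(df, "Channels", cr, "E"),
          activation = act,
          p = if (is.null(act)) 0L else wb_num(df, "Channels", cr, "p", 1),
          inactivation = gate_from(df, cr, "inact"),
          q = wb_num(df, "Channels", cr, "q", 0),
          regulation = reg,
          feeds_pool = {
            fp <- wb_cell(df, "Channels", cr, "feeds_pool")
            if (is.na(fp)) NULL else fp
          })
      })
      pl_comp <- sheets$Pools$compartment
      pl_comp[is.na(pl_comp)] <- sheets$Pools$neuron[is.na(pl_comp)]
      plrows <- which(sheets$Pools$neuron == nn & pl_comp == cn)
      pools <- lapply(plrows, function(pr) {
        df <- sheets$Pools
        src <- wb_cell(df, "Pools", pr, "source_channels")
        pool_spec(wb_cell(df, "Pools", pr, "pool"),
                  k1 = wb_num(df, "Pools", pr, "k1"),
                  k2 = wb_num(df, "Pools", pr, "k2"),
                  source_channels = if (is.na(src)) character()
                  else strsplit(src, ";", fixed = TRUE)[[1]],
                  c_init = wb_num(df, "Pools", pr, "c_init", 0))
      })
      compartment_spec(cn, Cm = wb_num(ne, "Neurons", r, "Cm"),
                       channels = channels, pools = pools,
                       V_init = wb_num(ne, "Neurons", r, "V_init"))
    })
    neurons[[length(neurons) + 1L]] <- neuron_spec(nn, comps)
  }

  es <- sheets$ElectricalSynapses
  esyn <- lapply(seq_len(nrow(es)), function(r)
    electrical_synapse(wb_cell(es, "ElectricalSynapses", r, "cell_i"),
                       wb_cell(es, "ElectricalSynapses", r, "cell_j"),
                       wb_num(es, "ElectricalSynapses", r, "gbar"),
                       wb_lgl(es, "ElectricalSynapses", r, "rectifying")))

  cs <- sheets$ChemicalSynapses
  csyn <- lapply(seq_len(nrow(cs)), function(r) {
    fac <- NULL
    fp <- wb_cell(cs, "ChemicalSynapses", r, "fac_pool")
    if (!is.na(fp))
      fac <- list(pool = fp,
                  gamma_f = wb_num(cs, "ChemicalSynapses", r, "fac_gamma", 0))
    dep <- NULL
    du <- wb_num(cs, "ChemicalSynapses", r, "dep_u")
    if (!is.na(du))
      dep <- list(u = du,
                  tau_rec = wb_num(cs, "ChemicalSynapses", r, "dep_tau_rec"))
    vd <- NULL
    vh <- wb_num(cs, "ChemicalSynapses", r, "vd_h")
    if (!is.na(vh))
      vd <- list(h = vh, s = wb_num(cs, "ChemicalSynapses", r, "vd_s"),
                 tau_m2 = wb_num(cs, "ChemicalSynapses", r, "vd_tau"))
    chemical_synapse(wb_cell(cs, "ChemicalSynapses", r, "pre"),
                     wb_cell(cs, "ChemicalSynapses", r, "post"),
                     w = wb_num(cs, "ChemicalSynapses", r, "w"),
                     E = wb_num(cs, "ChemicalSynapses", r, "E"),
                     tau_rise = wb_num(cs, "ChemicalSynapses", r, "tau_rise"),
                     tau_decay = wb_num(cs, "ChemicalSynapses", r, "tau_decay"),
                     threshold = wb_num(cs, "ChemicalSynapses", r, "threshold", 0),
                     facilitation = fac, depression = dep,
                     voltage_dependence = vd)
  })

  noise <- NULL
  nz <- sheets$Noise
  if (!is.null(nz) && nrow(nz) > 0) {
    rate_of <- function(r, rc, ic, dflt) {
      rate <- wb_num(nz, "Noise", r, rc)
      if (!is.na(rate)) return(rate)
      intv <- wb_num(nz, "Noise", r, ic)
      if (!is.na(intv)) return(1 / intv)
      dflt
    }
    first <- list(rate_i = rate_of(1, "rate_i", "interval_i", 50),
                  rate_e = rate_of(1, "rate_e", "interval_e", NA),
                  w_i = wb_num(nz, "Noise", 1, "w_i", 1e-5),
                  tau_i = wb_num(nz, "Noise", 1, "tau_i", 0.025),
                  tau_e = wb_num(nz, "Noise", 1, "tau_e", NA),
                  E_i = wb_num(nz, "Noise", 1, "E_i", -90),
                  E_e = wb_num(nz, "Noise", 1, "E_e", 60),
                  seed = wb_num(nz, "Noise", 1, "seed", 1))
    if (is.na(first$rate_e)) first$rate_e <- first$rate_i
    if (is.na(first$tau_e)) first$tau_e <- first$tau_i
    for (r in seq_len(nrow(nz))[-1]) {
      this <- c(rate_of(r, "rate_i", "interval_i", 50),
                rate_of(r, "rate_e", "interval_e", NA))
      if (!isTRUE(all.equal(this[1], first$rate_i)))
        wb_err("Noise", r, "rate_i",
               "per-target noise parameters must be identical")
    }
    noise <- noise_spec(targets = vapply(seq_len(nrow(nz)), function(r)
      wb_cell(nz, "Noise", r, "target"), ""),
      rate_i = first$rate_i, rate_e = first$rate_e, w_i = first$w_i,
      tau_i = first$tau_i, tau_e = first$tau_e, E_i = first$E_i,
      E_e = first$E_e, seed = first$seed)
  }

  st <- sheets$Stimuli
  stimuli <- lapply(seq_len(nrow(st)), function(r)
    stimulus_spec(wb_cell(st, "Stimuli", r, "target"),
                  wb_cell(st, "Stimuli", r, "kind"),
                  wb_num(st, "Stimuli", r, "amplitude"),
                  wb_num(st, "Stimuli", r, "t_start", 0),
                  wb_num(st, "Stimuli", r, "t_end", Inf)))

  si <- sheets$Simulation
  cfg <- list()
  rec <- character()
  for (r in seq_len(nrow(si))) {
    key <- wb_cell(si, "Simulation", r, "setting")
    val <- wb_cell(si, "Simulation", r, "value")
    if (is.na(key)) next
    if (key == "record") { rec <- c(rec, val); next }
    if (key == "method") { cfg$method <- val; next }
    if (!key %in% c("duration", "dt", "abstol", "reltol", "relax_max",
                    "relax_dvdt_tol", "seed", "record_dt"))
      wb_err("Simulation", r, "setting", sprintf("unknown setting '%s'", key))
    cfg[[key]] <- wb_num(si, "Simulation", r, "value")
  }
  if (length(rec)) cfg$record <- rec
  sim <- do.call(simulation_config, cfg)

  network_spec(neurons, esyn, csyn, noise, stimuli, sim)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "", ifelse(is.infinite(x), ifelse(x > 0, "Inf", "-Inf"),
                              sprintf("%.17g", x)))
}

# cpg_network -> list of data frames in canonical order
as_sheets <- function(spec) {
  validate_network(spec)
  ord <- order(vapply(spec$neurons, `[[`, "", "name"))
  neurons <- spec$neurons[ord]
  ne <- ch <- pl <- NULL
  for (nr in neurons) for (cp in nr$compartments) {
    ne <- rbind(ne, data.frame(neuron = nr$name, compartment = cp$name,
                               Cm = fmt_num(cp$Cm),
                               V_init = fmt_num(cp$V_init)))
    for (c0 in cp$channels) {
      gc <- function(g, field) if (is.null(g)) "" else fmt_num(g[[field]])
      gt <- function(g, field) if (is.null(g)) "" else fmt_num(g$tau[[field]])
      ch <- rbind(ch, data.frame(
        neuron = nr$name, compartment = cp$name, channel = c0$name,
        gbar = fmt_num(c0$gbar), E = fmt_num(c0$E),
        p = if (is.null(c0$activation)) "" else fmt_num(c0$p),
        q = if (is.null(c0$inactivation)) "" else fmt_num(c0$q),
        act_h = gc(c0$activation, "h"), act_s = gc(c0$activation, "s"),
        act_tau_base = gt(c0$activation, "base"),
        act_tau_amp = gt(c0$activation, "amp"),
        act_tau_h = gt(c0$activation, "h"),
        act_tau_s = gt(c0$activation, "s"),
        inact_h = gc(c0$inactivation, "h"),
        inact_s = gc(c0$inactivation, "s"),
        inact_tau_base = gt(c0$inactivation, "base"),
        inact_tau_amp = gt(c0$inactivation, "amp"),
        inact_tau_h = gt(c0$inactivation, "h"),
        inact_tau_s = gt(c0$inactivation, "s"),
        regulation_pool = if (is.null(c0$regulation)) "" else c0$regulation$pool,
        regulation_form = if (is.null(c0$regulation)) "" else c0$regulation$form,
        gamma = if (is.null(c0$regulation)) "" else fmt_num(c0$regulation$gamma),
        feeds_pool = c0$feeds_pool %||% ""))
    }
    for (p0 in cp$pools)
      pl <- rbind(pl, data.frame(
        neuron = nr$name, compartment = cp$name, pool = p0$name,
        k1 = fmt_num(p0$k1), k2 = fmt_num(p0$k2),
        source_channels = paste(p0$source_channels, collapse = ";"),
        c_init = fmt_num(p0$c_init)))
  }
  empty_df <- function(cols)
    as.data.frame(stats::setNames(rep(list(character()), length(cols)), cols))
  es <- if (length(spec$electrical_synapses))
    do.call(rbind, lapply(spec$electrical_synapses, function(e)
      data.frame(cell_i = e$cell_i, cell_j = e$cell_j,
                 gbar = fmt_num(e$gbar),
                 rectifying = if (e$rectifying) "TRUE" else "FALSE")))
  else empty_df(wb_schema$ElectricalSynapses)
  cs <- if (length(spec$chemical_synapses))
    do.call(rbind, lapply(spec$chemical_synapses, function(s)
      data.frame(pre = s$pre, post = s$post, w = fmt_num(s$w),
                 E = fmt_num(s$E), tau_rise = fmt_num(s$tau_rise),
                 tau_decay = fmt_num(s$tau_decay),
                 threshold = fmt_num(s$threshold),
                 fac_pool = if (is.null(s$facilitation)) "" else s$facilitation$pool,
                 fac_gamma = if (is.null(s$facilitation)) "" else
                   fmt_num(s$facilitation$gamma_f),
                 dep_u = if (is.null(s$depression)) "" else fmt_num(s$depression$u),
                 dep_tau_rec = if (is.null(s$depression)) "" else
                   fmt_num(s$depression$tau_rec),
                 vd_h = if (is.null(s$voltage_dependence)) "" else
                   fmt_num(s$voltage_dependence$h),
                 vd_s = if (is.null(s$voltage_dependence)) "" else
                   fmt_num(s$voltage_dependence$s),
                 vd_tau = if (is.null(s$voltage_dependence)) "" else
                   fmt_num(s$voltage_dependence$tau_m2))))
  else empty_df(wb_schema$ChemicalSynapses)
  nz <- if (!is.null(spec$noise)) {
    n0 <- spec$noise
    do.call(rbind, lapply(n0$targets, function(tg)
      data.frame(target = tg, rate_i = fmt_num(n0$rate_i),
                 rate_e = fmt_num(n0$rate_e), interval_i = "",
                 interval_e = "", w_i = fmt_num(n0$w_i),
                 tau_i = fmt_num(n0$tau_i), tau_e = fmt_num(n0$tau_e),
                 E_i = fmt_num(n0$E_i), E_e = fmt_num(n0$E_e),
                 seed = fmt_num(n0$seed))))
  } else empty_df(wb_schema$Noise)
  st <- if (length(spec$stimuli))
    do.call(rbind, lapply(spec$stimuli, function(s)
      data.frame(target = s$target, kind = s$kind,
                 amplitude = fmt_num(s$amplitude),
                 t_start = fmt_num(s$t_start), t_end = fmt_num(s$t_end))))
  else empty_df(wb_schema$Stimuli)
  cfg <- spec$sim
  si <- rbind(
    data.frame(setting = "duration", value = fmt_num(cfg$duration)),
    data.frame(setting = "method", value = cfg$method),
    data.frame(setting = "dt", value = fmt_num(cfg$dt)),
    data.frame(setting = "abstol", value = fmt_num(cfg$abstol)),
    data.frame(setting = "reltol", value = fmt_num(cfg$reltol)),
    data.frame(setting = "relax_max", value = fmt_num(cfg$relax_max)),
    data.frame(setting = "relax_dvdt_tol", value = fmt_num(cfg$relax_dvdt_tol)),
    data.frame(setting = "seed", value = fmt_num(cfg$seed)),
    if (!is.na(cfg$record_dt))
      data.frame(setting = "record_dt", value = fmt_num(cfg$record_dt)),
    if (!is.null(cfg$record))
      data.frame(setting = "record", value = cfg$record))
  list(Neurons = ne, Channels = ch %||% empty_df(wb_schema$Channels),
       Pools = pl %||% empty_df(wb_schema$Pools),
       ElectricalSynapses = es, ChemicalSynapses = cs, Noise = nz,
       Stimuli = st, Simulation = si)
}

#' Load a network description from a workbook
#'
#' Reads a plain-text workbook (named `[Sheet]` sections of tab-separated
#' values; see the package vignette for the schema) or, when the readxl
#' package is installed, an `.xlsx` spreadsheet with the same sheet names
#' and columns. The result is fully cross-referenced and validated; any
#' malformed value is reported with its sheet, row and column.
#'
#' @param path workbook file.
#' @return a validated [network_spec()].
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx workbooks requires the 'readxl' package")
    nm <- readxl::excel_sheets(path)
    sheets <- lapply(nm, function(s)
      as.data.frame(readxl::read_excel(path, sheet = s, col_types = "text")))
    names(sheets) <- nm
  } else {
    sheets <- read_text_workbook(path)
  }
  sheets_to_spec(sheets)
}

read_text_workbook <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  sec <- grepl("^\\[.+\\]\\s*$", lines)
  if (!any(sec)) stop("not a workbook: no [Sheet] sections found in ", path)
  starts <- which(sec)
  sheets <- list()
  for (m in seq_along(starts)) {
    nm <- sub("^\\[(.+)\\]\\s*$", "\\1", lines[starts[m]])
    end <- if (m < length(starts)) starts[m + 1] - 1L else length(lines)
    body <- lines[(starts[m] + 1L):end]
    body <- body[nzchar(trimws(body))]
    if (length(body) == 0) { sheets[[nm]] <- NULL; next }
    hdr <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
    rows <- lapply(body[-1], function(ln) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      length(f) <- length(hdr)
      f
    })
    df <- as.data.frame(do.call(rbind, rows) %||%
                          matrix(character(), 0, length(hdr)),
                        stringsAsFactors = FALSE)
    names(df) <- hdr
    sheets[[nm]] <- df
  }
  sheets
}

#' Save a network description to a text workbook
#'
#' Emits every mandatory sheet (empty sheets as a bare header) in canonical
#' order: neurons alphabetically, channels and synapses in declaration
#' order. The emitted file re-loads to a field-by-field equal network.
#'
#' @param spec a [network_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_network <- function(spec, path) {
  sheets <- as_sheets(spec)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path))
  on.exit(close(con))
  writeLines("# cpgsim workbook v1", con)
  for (nm in names(sheets)) {
    df <- sheets[[nm]]
    writeLines(paste0("[", nm, "]"), con)
    writeLines(paste(names(df), collapse = "\t"), con)
    if (nrow(df))
      writeLines(apply(as.matrix(df), 1, paste, collapse = "\t"), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Field-by-field equality of two network descriptions
#'
#' @param a,b `cpg_network` objects.
#' @return logical.
#' @export
network_equal <- function(a, b) {
  isTRUE(all.equal(a, b, tolerance = 0, check.attributes = TRUE))
}

#' Patch one scalar parameter by workbook address
#'
#' Addresses any scalar cell of the workbook representation as
#' `"Sheet:row:column"` (row is 1-based among the sheet's data rows,
#' following canonical ordering), sets it, and rebuilds the validated
#' network. This is the parameter addressing used by [grid_search()].
#'
#' @param spec a [network_spec()].
#' @param address `"Sheet:row:column"` string.
#' @param value new value.
#' @return a new `cpg_network`.
#' @export
set_workbook_param <- function(spec, address, value) {
  parts <- strsplit(address, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L)
    stop("parameter address must be 'Sheet:row:column', got '", address, "'")
  sheet <- parts[1]; row <- as.integer(parts[2]); col <- parts[3]
  sheets <- as_sheets(spec)
  if (!sheet %in% names(sheets)) stop("no sheet '", sheet, "' in workbook")
  df <- sheets[[sheet]]
  if (is.na(row) || row < 1L || row > nrow(df))
    wb_err(sheet, parts[2], col, "row out of range")
  if (!col %in% names(df))
    wb_err(sheet, row, col, "no such column")
  df[[col]][row] <- if (is.numeric(value)) fmt_num(value) else as.character(value)
  sheets[[sheet]] <- df
  sheets_to_spec(sheets)
}
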