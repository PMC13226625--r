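# TraceSet: recorded time series keyed by "compartment:quantity", plus the
# run manifest and per-synapse event trains.

new_traceset <- function(time, data, events = list(), manifest = list(),
                         report = NULL) {
  stopifnot(all(lengths(data) == length(time)))
  structure(list(time = time, data = data, events = events,
                 manifest = manifest, report = report),
            class = "cpg_traces")
}

#' @export
print.cpg_traces <- function(x, ...) {
  cat(sprintf("<cpg_traces> %d series x %d samples on [%.4g, %.4g] s\n",
              length(x$data), length(x$time), min(x$time), max(x$time)))
  nm <- names(x$data)
  cat("  series:", paste(utils::head(nm, 8), collapse = ", "),
      if (length(nm) > 8) sprintf("... (%d more)", length(nm) - 8) else "", "\n")
  if (!is.null(x$manifest$method))
    cat(sprintf("  run: method %s, seed %s, relaxation %.3g s\n",
                x$manifest$method, x$manifest$seed,
                x$manifest$relax_duration))
  invisible(x)
}

#' Extract one recorded series
#'
#' @param traces a `cpg_traces`.
#' @param name series name (e.g. `"A:V"`).
#' @return numeric vector.
#' @export
trace_series <- function(traces, name) {
  if (!name %in% names(traces$data))
    stop("no recorded series '", name, "'; available: ",
         paste(names(traces$data), collapse = ", "))
  traces$data[[name]]
}

#' Convert a trace set to a data frame
#'
#' First column `time` (s), one column per recorded series.
#'
#' @param x a `cpg_traces`.
#' @param ... unused.
#' @return `data.frame`.
#' @export
as.data.frame.cpg_traces <- function(x, ...) {
  df <- data.frame(time = x$time, check.names = FALSE)
  for (nm in names(x$data)) df[[nm]] <- x$data[[nm]]
  df
}

#' Write recorded traces to disk
#'
#' `tsv` writes a tab-separated table, first column time (s), one column
#' per series, values at full double precision. `binary` writes the same
#' table as an RDS file, which round-trips bitwise.
#'
#' @param traces a nonempty `cpg_traces`.
#' @param path output file.
#' @param format `"tsv"` or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, format = c("tsv", "binary")) {
  format <- match.arg(format)
  if (!inherits(traces, "cpg_traces") || length(traces$data) == 0)
    stop("empty trace set")
  df <- as.data.frame(traces)
  if (format == "binary") {
    saveRDS(df, path)
  } else {
    m <- vapply(df, function(col) sprintf("%.17g", col),
                character(nrow(df)))
    if (nrow(df) == 1L) m <- matrix(m, 1)
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste(names(df), collapse = "\t"), con)
    writeLines(apply(m, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read traces written by [write_traces()]
#'
#' @param path file path.
#' @param format `"tsv"` or `"binary"`.
#' @return `data.frame` with a `time` column.
#' @export
read_traces <- function(path, format = c("tsv", "binary")) {
  format <- match.arg(format)
  if (format == "binary") readRDS(path)
  else utils::read.delim(path, check.names = FALSE)
}
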