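#' Uniformly sampled recording trace
#'
#' Container for a single-channel intracellular recording (or surrogate): a
#' uniform time grid in seconds, signal values, physical units and a channel
#' identifier.
#'
#' @param t Time grid (seconds), strictly uniform.
#' @param x Signal values (finite).
#' @param units `"mV"` (current clamp) or `"nA"` (voltage clamp).
#' @param channel Channel identifier.
#' @return Data frame of class `"pe_trace"` with columns `t`, `x` and
#'   attributes `units`, `channel`, `fs` (sampling rate, Hz).
#' @export
pe_trace <- function(t, x, units = c("nA", "mV"), channel = "ch1") {
  units <- match.arg(units)
  if (length(t) < 2L) stop("trace needs at least two samples", call. = FALSE)
  if (length(t) != length(x)) stop("t and x lengths differ", call. = FALSE)
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-9 * max(abs(t)))
    stop("time grid is not uniform", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite signal values", call. = FALSE)
  structure(data.frame(t = t, x = x),
            class = c("pe_trace", "data.frame"),
            units = units, channel = channel, fs = 1 / dt[1])
}

trace_fs <- function(trace) attr(trace, "fs")
trace_units <- function(trace) attr(trace, "units")

rebuild_trace <- function(trace, x) {
  structure(data.frame(t = trace$t, x = x),
            class = c("pe_trace", "data.frame"),
            units = attr(trace, "units"), channel = attr(trace, "channel"),
            fs = attr(trace, "fs"))
}

#' @export
print.pe_trace <- function(x, ...) {
  cat(sprintf("Trace '%s': %d samples at %.6g Hz (%.3g s), units %s\n",
              attr(x, "channel"), nrow(x), attr(x, "fs"),
              nrow(x) / attr(x, "fs"), attr(x, "units")))
  invisible(x)
}

#' @export
plot.pe_trace <- function(x, ...) {
  plot(x$t, x$x, type = "l", xlab = "time (s)",
       ylab = paste0("signal (", attr(x, "units"), ")"), ...)
  invisible(x)
}

#' Write a trace to a columnar text file
#'
#' Plain tab-separated text with `# key: value` metadata header lines
#' (units, channel, sampling rate), readable by [read_timeseries()].
#'
#' @param trace A [pe_trace()].
#' @param path Output file path.
#' @param extra Optional named list of extra metadata entries.
#' @export
write_timeseries <- function(trace, path, extra = NULL) {
  meta <- c(list(units = attr(trace, "units"),
                 channel = attr(trace, "channel"),
                 fs_hz = attr(trace, "fs")), extra)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, format(meta[[k]], digits = 15)), con)
  writeLines("t\tx", con)
  write.table(data.frame(t = trace$t, x = trace$x), con, sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
}

#' Read a columnar time-series file
#'
#' Expects the format written by [write_timeseries()]: `# key: value`
#' metadata lines, a header naming a time column `t`, and tab-separated
#' values.  The grid must be uniform (relative jitter below 1e-9) and units
#' must be present in the metadata.
#'
#' @param path File path.
#' @return A [pe_trace()].
#' @export
read_timeseries <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    k <- sub(":.*$", "", kv)
    v <- trimws(sub("^[^:]*:", "", kv))
    meta[[k]] <- v
  }
  if (is.null(meta$units))
    stop("missing units metadata in ", path, call. = FALSE)
  body <- lines[!grepl("^#", lines)]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!"t" %in% header)
    stop("no time column 't' in header of ", path, call. = FALSE)
  if (length(body) < 3L)
    stop("time series too short in ", path, call. = FALSE)
  df <- read.table(text = body[-1], sep = "\t", col.names = header)
  pe_trace(df$t, df$x, units = meta$units,
           channel = if (is.null(meta$channel)) "ch1" else meta$channel)
}
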