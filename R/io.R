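#' Read and write transmission traces
#'
#' Traces are stored as plain CSV (columns `time_s`, `transmission_v`,
#' plus optional ground-truth columns `occupancy`, `state`, `position`)
#' with a JSON sidecar `<path>.meta.json` carrying the sampling rate,
#' units, filter history, provenance metadata and ground-truth boundary
#' times. `write_trace()` writes values at 9 significant digits, so a
#' round trip is exact to better than 1e-8 relative. `read_trace()`
#' requires either the sidecar, an explicit `fs`, or a uniform `time_s`
#' column (relative tolerance 1e-6) from which `fs` is inferred.
#'
#' @param trace a trace tibble.
#' @param path file path (CSV).
#' @param fs sampling rate override, Hz.
#' @return `read_trace()` returns a `ferro_trace`; ground-truth columns
#'   and boundaries are restored when present. `write_trace()` returns
#'   `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  trace <- as_trace(trace)
  df <- data.frame(time_s = signif(trace$time, 12),
                   transmission_v = signif(trace$value, 9))
  for (col in c("occupancy", "state", "position")) {
    if (!is.null(trace[[col]])) {
      df[[col]] <- if (is.numeric(trace[[col]])) signif(trace[[col]], 9) else trace[[col]]
    }
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort(sprintf("cannot write trace to '%s'.", path),
                 class = "ferrotrace_io_error")
  meta <- list(fs = trace_fs(trace), units = trace_units(trace),
               history = as.list(trace_history(trace)),
               metadata = attr(trace, "metadata") %||% list())
  if (!is.null(attr(trace, "truth_boundaries"))) {
    meta$truth_boundaries <- as.list(attr(trace, "truth_boundaries"))
  }
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, fs = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: '%s'.", path), class = "ferrotrace_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "transmission_v") %in% names(df))) {
    abort("CSV must have header columns `time_s` and `transmission_v`.",
          class = "ferrotrace_format_error")
  }
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  if (is.null(fs)) fs <- meta$fs
  if (is.null(fs)) {
    dt <- diff(df$time_s)
    if (length(dt) < 1) {
      abort("cannot infer sampling rate from a single sample; pass `fs`.",
            class = "ferrotrace_format_error")
    }
    fs <- 1 / stats::median(dt)
  }
  # uniformity check on the time column
  if (nrow(df) > 2) {
    dt <- diff(df$time_s)
    md <- stats::median(dt)
    if (any(abs(dt - md) > 1e-6 * abs(md))) {
      abort("non-uniform time column (relative tolerance 1e-6).",
            class = "ferrotrace_format_error")
    }
  }
  tr <- new_trace(df$transmission_v, fs = fs, t0_offset = df$time_s[1])
  if (!is.null(meta)) {
    attr(tr, "units") <- meta$units %||% "V"
    attr(tr, "history") <- unlist(meta$history) %||% character()
    attr(tr, "metadata") <- meta$metadata %||% list()
    if ("truth_boundaries" %in% names(meta)) {
      attr(tr, "truth_boundaries") <- as.numeric(unlist(meta$truth_boundaries))
    }
  }
  for (col in c("occupancy", "position")) {
    if (!is.null(df[[col]])) tr[[col]] <- as.numeric(df[[col]])
  }
  if (!is.null(df$state)) {
    st <- as.character(df$state)
    st[st == "" | st == "NA"] <- NA_character_
    tr$state <- st
  }
  tr
}
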