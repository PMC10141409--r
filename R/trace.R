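#' @importFrom rlang .data abort warn .env
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange summarise group_by ungroup
NULL

# Physical constants (SI)
.kB <- 1.380649e-23      # Boltzmann, J/K
.eps0 <- 8.8541878128e-12 # vacuum permittivity, F/m
.c_light <- 299792458     # speed of light, m/s

#' Construct a transmission trace
#'
#' A trace is a tibble with columns `time` (seconds) and `value` (the
#' transmitted optical signal), carrying the sampling rate, units and a
#' processing history as attributes. All analysis functions in ferrotrace
#' take a trace (or plain data frame with these columns) as their first
#' argument and return tibbles, so calls compose with the pipe.
#'
#' @param values numeric vector of transmitted signal samples.
#' @param fs sampling rate in Hz (> 0).
#' @param units character, units of `values` (default `"V"`).
#' @param t0_offset time of the first sample, seconds.
#' @param metadata named list of provenance fields (source, seed, preset ...).
#' @return A tibble of class `ferro_trace` with columns `time`, `value`.
#' @examples
#' tr <- new_trace(sin(2 * pi * 5 * (0:999) / 1000), fs = 1000)
#' trace_fs(tr)
#' @export
new_trace <- function(values, fs, units = "V", t0_offset = 0, metadata = list()) {
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("`fs` must be a single positive number.", class = "ferrotrace_invalid_parameter")
  }
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    abort("trace values must be finite.", class = "ferrotrace_invalid_parameter")
  }
  tr <- tibble(
    time = t0_offset + (seq_along(values) - 1) / fs,
    value = values
  )
  attr(tr, "fs") <- fs
  attr(tr, "units") <- units
  attr(tr, "history") <- character()
  attr(tr, "metadata") <- metadata
  class(tr) <- c("ferro_trace", class(tr))
  tr
}

#' Sampling rate of a trace
#'
#' Returns the `fs` attribute if present, otherwise infers it from the
#' median spacing of the `time` column (dplyr verbs can drop attributes).
#'
#' @param trace a trace tibble.
#' @return Sampling rate in Hz.
#' @export
trace_fs <- function(trace) {
  fs <- attr(trace, "fs")
  if (!is.null(fs)) return(fs)
  tt <- trace[["time"]]
  if (is.null(tt) || length(tt) < 2) {
    abort("cannot determine sampling rate: no `fs` attribute and no usable `time` column.",
          class = "ferrotrace_format_error")
  }
  1 / stats::median(diff(tt))
}

#' @rdname trace_fs
#' @export
trace_units <- function(trace) attr(trace, "units") %||% "V"

#' @rdname trace_fs
#' @export
trace_history <- function(trace) attr(trace, "history") %||% character()

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rebuild a trace from an existing one with new values, appending a history
# entry. Keeps time axis, metadata and class.
trace_update <- function(trace, values, history_entry = NULL, fs = NULL,
                         time = NULL, units = NULL) {
  old_fs <- trace_fs(trace)
  fs <- fs %||% old_fs
  t0 <- if (nrow(trace) > 0) trace$time[1] else 0
  out <- tibble(
    time = time %||% (t0 + (seq_along(values) - 1) / fs),
    value = as.numeric(values)
  )
  attr(out, "fs") <- fs
  attr(out, "units") <- units %||% trace_units(trace)
  attr(out, "history") <- c(trace_history(trace), history_entry)
  attr(out, "metadata") <- attr(trace, "metadata") %||% list()
  for (a in c("truth_boundaries", "config", "preset", "exposure_time")) {
    if (!is.null(attr(trace, a))) attr(out, a) <- attr(trace, a)
  }
  class(out) <- c("ferro_trace", class(tibble()))
  out
}

as_trace <- function(x, fs = NULL) {
  if (inherits(x, "ferro_trace")) return(x)
  if (is.data.frame(x)) {
    if (!all(c("time", "value") %in% names(x))) {
      abort("a trace data frame needs `time` and `value` columns.",
            class = "ferrotrace_format_error")
    }
    fs <- fs %||% attr(x, "fs") %||% (1 / stats::median(diff(x$time)))
    tr <- new_trace(x$value, fs = fs, t0_offset = x$time[1])
    attr(tr, "units") <- attr(x, "units") %||% "V"
    attr(tr, "history") <- attr(x, "history") %||% character()
    attr(tr, "metadata") <- attr(x, "metadata") %||% list()
    return(tr)
  }
  abort("cannot interpret input as a trace.", class = "ferrotrace_format_error")
}

#' @export
print.ferro_trace <- function(x, ...) {
  fs <- tryCatch(trace_fs(x), error = function(e) NA_real_)
  cat(sprintf("<ferro_trace> %d samples @ %s Hz (%.3f s), units %s\n",
              nrow(x), format(fs), nrow(x) / fs, trace_units(x)))
  h <- trace_history(x)
  if (length(h)) cat("history:", paste(h, collapse = " -> "), "\n")
  NextMethod()
}
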