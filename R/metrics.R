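#' Sliding root-mean-square of a trace
#'
#' RMS of the per-window mean-subtracted signal, computed in windows of
#' `window` seconds advanced by `hop` seconds. The per-window mean
#' subtraction makes the series a local fluctuation amplitude, insensitive
#' to slow level drifts and trapping steps. The default 0.1 s window with
#' 0.05 s hop resolves the few-second dwell times of pore gating with
#' tens of points per dwell.
#'
#' @param trace a trace tibble (normally filtered first).
#' @param window window length, s (>= 10 samples).
#' @param hop window advance, s (<= window).
#' @return A tibble of class `ferro_rms` with columns `time` (window
#'   centre, s) and `rms` (mV when the trace is in volts, otherwise input
#'   units), and attributes `window`, `hop`, `units`.
#' @export
sliding_rms <- function(trace, window = 0.1, hop = 0.05) {
  trace <- as_trace(trace)
  fs <- trace_fs(trace)
  x <- trace$value
  n <- length(x)
  w <- round(window * fs)
  h <- max(1L, round(hop * fs))
  if (w < 10) abort("`window` must span at least 10 samples.",
                    class = "ferrotrace_invalid_parameter")
  if (h > w) abort("`hop` must not exceed `window`.",
                   class = "ferrotrace_invalid_parameter")
  if (w > n) abort("`window` is longer than the trace.",
                   class = "ferrotrace_invalid_parameter")
  starts <- seq.int(1L, n - w + 1L, by = h)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x * x))
  ends <- starts + w - 1L
  mu <- (cs[ends + 1L] - cs[starts]) / w
  msq <- (cs2[ends + 1L] - cs2[starts]) / w
  rms <- sqrt(pmax(0, msq - mu^2))
  scale <- if (identical(trace_units(trace), "V")) 1e3 else 1
  out <- tibble(time = trace$time[1] + (starts + ends - 2) / (2 * fs),
                rms = rms * scale)
  attr(out, "window") <- window
  attr(out, "hop") <- hop
  attr(out, "units") <- if (scale == 1e3) "mV" else trace_units(trace)
  class(out) <- c("ferro_rms", class(out))
  out
}

#' Normalized root-mean-square (NRMS) of a trapped segment
#'
#' Standard deviation of the (filtered) segment divided by its median
#' level. Dividing by the level makes fluctuation magnitudes comparable
#' across nanostructures with different absolute transmission; NRMS is
#' invariant to positive rescaling of the signal.
#'
#' @param trace a trace tibble or numeric vector of segment values.
#' @param fs sampling rate (only needed for the 1 s minimum-length check
#'   when `trace` is a bare vector; default skips the check).
#' @return NRMS, dimensionless.
#' @export
nrms <- function(trace, fs = NULL) {
  x <- if (is.data.frame(trace)) {
    fs <- fs %||% trace_fs(trace)
    trace$value
  } else as.numeric(trace)
  if (!is.null(fs) && length(x) < fs) {
    abort("NRMS needs a segment of at least 1 s.",
          class = "ferrotrace_invalid_parameter")
  }
  med <- stats::median(x)
  if (!(med > 0)) {
    abort("NRMS needs a strictly positive median level.",
          class = "ferrotrace_estimation_error")
  }
  stats::sd(x) / med
}

#' Kernel-density estimate of a signal's probability density
#'
#' Gaussian KDE with Silverman's rule-of-thumb bandwidth, evaluated on a
#' 4096-point grid spanning `[min - 3h, max + 3h]`, renormalised so the
#' trapezoid integral is 1. The grid argmax is the mode used by
#' [mode_normalize()].
#'
#' @param values numeric vector (>= 1000 values).
#' @param n_grid grid size.
#' @return A tibble of class `ferro_pdf` with columns `grid`, `density`
#'   and attributes `bandwidth`, `mode`.
#' @export
estimate_pdf <- function(values, n_grid = 4096) {
  values <- as.numeric(values)
  if (length(values) < 1000) {
    abort("PDF estimation needs at least 1000 values.",
          class = "ferrotrace_invalid_parameter")
  }
  if (stats::sd(values) == 0) {
    abort("degenerate (constant) input.", class = "ferrotrace_estimation_error")
  }
  h <- stats::bw.nrd0(values)
  d <- stats::density(values, bw = h, n = n_grid,
                      from = min(values) - 3 * h, to = max(values) + 3 * h)
  dx <- d$x[2] - d$x[1]
  area <- sum((d$y[-1] + d$y[-n_grid]) / 2) * dx
  dens <- d$y / area
  out <- tibble(grid = d$x, density = dens)
  attr(out, "bandwidth") <- h
  attr(out, "mode") <- d$x[which.max(dens)]
  class(out) <- c("ferro_pdf", class(out))
  out
}

#' Quartiles of a sample
#'
#' Linear-interpolation quartiles (the default continuous quantile
#' definition), as used for interquartile-range box summaries of trace
#' value distributions.
#'
#' @param values numeric vector (>= 4 values).
#' @return Tibble with columns `q1`, `q2`, `q3`.
#' @export
quartile_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4) {
    abort("need at least 4 values.", class = "ferrotrace_invalid_parameter")
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble(q1 = q[1], q2 = q[2], q3 = q[3])
}

# Welch PSD: Hann window, 50% overlap, per-segment mean removal.
# Returns tibble(freq, psd) on the one-sided frequency grid.
welch_psd <- function(x, fs, nseg) {
  n <- length(x)
  nseg <- min(nseg, n)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))  # Hann
  step <- max(1L, nseg %/% 2L)
  starts <- seq.int(1L, n - nseg + 1L, by = step)
  acc <- numeric(nseg %/% 2 + 1)
  for (s in starts) {
    seg <- x[seq.int(s, s + nseg - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- Mod(stats::fft(seg))^2
    acc <- acc + sp[seq_len(nseg %/% 2 + 1)]
  }
  scale <- fs * sum(win^2)
  psd <- acc / (length(starts) * scale)
  # one-sided: double everything but DC (and Nyquist for even nseg)
  psd[-1] <- 2 * psd[-1]
  if (nseg %% 2 == 0) psd[length(psd)] <- psd[length(psd)] / 2
  tibble(freq = (seq_along(psd) - 1) * fs / nseg, psd = psd)
}

#' Fraction of spectral power inside a band
#'
#' Welch power-spectral-density estimate (Hann window, 50% overlap,
#' segment length the power of two closest to `4 / f_lo` seconds) and the
#' ratio of in-band power `[f_lo, f_hi]` to the total power above
#' `f_lo / 2` (excluding the DC-adjacent region, where window leakage of
#' the mean dominates).
#'
#' @param trace a trace tibble or numeric vector.
#' @param f_lo,f_hi band edges, Hz.
#' @param fs sampling rate (required when `trace` is a bare vector).
#' @return Dimensionless fraction in `[0, 1]`.
#' @export
psd_band_fraction <- function(trace, f_lo = 3, f_hi = 150, fs = NULL) {
  if (is.data.frame(trace)) {
    fs <- fs %||% trace_fs(trace)
    x <- trace$value
  } else x <- as.numeric(trace)
  if (is.null(fs)) abort("`fs` is required.", class = "ferrotrace_invalid_parameter")
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < fs / 2)) {
    abort("band must satisfy 0 < f_lo < f_hi < fs/2.",
          class = "ferrotrace_invalid_parameter")
  }
  if (length(x) < 10 / f_lo * fs) {
    abort("segment must span at least 10 / f_lo seconds.",
          class = "ferrotrace_invalid_parameter")
  }
  nseg <- 2^round(log2(4 / f_lo * fs))
  p <- welch_psd(x - mean(x), fs, nseg)
  denom <- sum(p$psd[p$freq > f_lo / 2])
  num <- sum(p$psd[p$freq >= f_lo & p$freq <= f_hi])
  num / denom
}
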