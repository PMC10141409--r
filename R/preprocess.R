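#' Zero-phase Gaussian low-pass filter
#'
#' Convolves the trace with a symmetric Gaussian kernel whose magnitude
#' response is \eqn{H(f) = \exp(-f^2/(2\sigma_f^2))} with \eqn{\sigma_f}
#' chosen so that the response at the cutoff is \eqn{1/\sqrt 2} (-3 dB
#' convention, i.e. \eqn{\sigma_f = f_c/\sqrt{\ln 2}}). Symmetric
#' convolution is zero-phase, so step edges and segment boundaries are not
#' shifted; edges are handled by reflection.
#'
#' @param trace a trace tibble.
#' @param cutoff -3 dB cutoff frequency, Hz; must be below Nyquist.
#' @return The filtered trace (same length), with the filter appended to
#'   its history.
#' @export
gaussian_lowpass <- function(trace, cutoff) {
  trace <- as_trace(trace)
  fs <- trace_fs(trace)
  if (!(cutoff > 0 && cutoff < fs / 2)) {
    abort("`cutoff` must lie in (0, fs/2).", class = "ferrotrace_invalid_parameter")
  }
  x <- trace$value
  sigma_samp <- fs * sqrt(log(2)) / (2 * pi * cutoff)
  r <- max(3L, ceiling(6 * sigma_samp))
  kernel <- stats::dnorm(seq.int(-r, r), sd = sigma_samp)
  kernel <- kernel / sum(kernel)
  n <- length(x)
  if (r >= n) abort("trace shorter than the filter kernel.",
                    class = "ferrotrace_invalid_parameter")
  xp <- c(x[seq.int(r + 1, 2)], x, x[seq.int(n - 1, n - r)])  # reflect
  y <- if (length(kernel) <= 64) {
    as.numeric(stats::filter(xp, kernel, sides = 2))[seq.int(r + 1, r + n)]
  } else {
    # FFT convolution for long kernels (low cutoff relative to fs)
    stats::convolve(xp, kernel, type = "filter")
  }
  trace_update(trace, y, sprintf("gaussian_lowpass(%g Hz)", cutoff))
}

#' Decimate a trace
#'
#' Anti-alias low-pass filtering (zero-phase Chebyshev-I at
#' `0.4 * (fs / factor)`, via [signal::decimate()]) followed by
#' subsampling by the integer `factor`. The sampling rate attribute is
#' updated and the operation recorded in the filter history.
#'
#' @param trace a trace tibble.
#' @param factor integer decimation factor >= 2.
#' @return Decimated trace with `ceiling(n / factor)` samples.
#' @export
decimate_trace <- function(trace, factor) {
  trace <- as_trace(trace)
  if (length(factor) != 1 || factor != round(factor) || factor < 2) {
    abort("`factor` must be an integer >= 2.", class = "ferrotrace_invalid_parameter")
  }
  fs <- trace_fs(trace)
  # one anti-alias + subsample stage; reflection padding suppresses the
  # filtfilt start-up transient
  stage <- function(x, q, ftype) {
    n <- length(x)
    flt <- if (ftype == "iir") signal::cheby1(8, 0.05, 0.8 / q)
           else signal::Arma(b = signal::fir1(30 * q, 1 / q), a = 1)
    # normalize to exactly unit DC gain (even-order Chebyshev-I sits at the
    # ripple minimum at DC)
    flt$b <- flt$b * sum(flt$a) / sum(flt$b)
    pad <- min(n - 1L, 30L * q)
    xp <- c(2 * x[1] - x[seq.int(pad + 1L, 2L)], x,
            2 * x[n] - x[seq.int(n - 1L, n - pad)])
    y <- signal::filtfilt(flt, xp)[seq.int(pad + 1L, pad + n)]
    y[seq.int(1L, n, q)]
  }
  # large factors are applied in stages <= 10 (IIR anti-alias filters get
  # numerically fragile at very low normalized cutoffs); a residual prime
  # stage > 10 falls back to the FIR design
  remaining <- as.integer(factor)
  y <- trace$value
  while (remaining > 1L) {
    q <- 1L
    for (d in 10:2) if (remaining %% d == 0L) { q <- d; break }
    ftype <- "iir"
    if (q == 1L) { q <- remaining; ftype <- "fir" }
    y <- stage(y, q, ftype)
    remaining <- remaining %/% q
  }
  t0 <- trace$time[1]
  trace_update(trace, y, sprintf("decimate(%d)", as.integer(factor)),
               fs = fs / factor,
               time = t0 + (seq_along(y) - 1) * factor / fs)
}

#' Normalize a trace to its most probable value
#'
#' Divides the trace by the mode of a Gaussian kernel-density estimate of
#' its values (Silverman bandwidth, 4096-point grid; the same estimator
#' as [estimate_pdf()]), so that the most probable transmission level
#' maps to 1. This is the normalisation used to overlay probability
#' density functions of traces recorded on different nanostructures.
#'
#' @param trace a trace tibble with at least 1000 samples.
#' @return The normalized (dimensionless) trace; the divisor is stored in
#'   attribute `mode_value`.
#' @export
mode_normalize <- function(trace) {
  trace <- as_trace(trace)
  x <- trace$value
  if (length(x) < 1000) {
    abort("mode normalization needs at least 1000 samples.",
          class = "ferrotrace_invalid_parameter")
  }
  if (stats::sd(x) == 0) {
    warn("constant trace: mode normalization returns all ones.")
    out <- trace_update(trace, rep(1, length(x)), "mode_normalize",
                        units = "dimensionless")
    attr(out, "mode_value") <- x[1]
    return(out)
  }
  pdf <- estimate_pdf(x)
  m <- attr(pdf, "mode")
  out <- trace_update(trace, x / m, "mode_normalize", units = "dimensionless")
  attr(out, "mode_value") <- m
  out
}
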