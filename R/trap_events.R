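#' Detect mean-shift change points in a trace
#'
#' Binary segmentation on the cumulative-sum least-squares statistic:
#' each segment is split at the sample that maximises the reduction in
#' residual sum of squares, the split is kept if the reduction exceeds
#' `penalty`, and the procedure recurses. Detected points are at least
#' `min_separation` apart. The default penalty is the BIC-like rule
#' `2 * sigma^2 * log(n)` with the noise scale estimated robustly from
#' the median absolute deviation of first differences.
#'
#' Mean-shift detection assumes roughly level-stationary noise between
#' steps; run it on a filtered (and, for strongly band-limited noise,
#' decimated) trace so neighbouring samples are not heavily correlated.
#'
#' @param trace a trace tibble.
#' @param min_separation minimum spacing between change points, s.
#' @param penalty cost-reduction threshold; `NULL` for the default rule.
#' @return Tibble with columns `time` (s), `index` (sample) and `gain`
#'   (residual sum-of-squares reduction), sorted by time.
#' @export
detect_steps <- function(trace, min_separation = 1, penalty = NULL) {
  trace <- as_trace(trace)
  fs <- trace_fs(trace)
  x <- trace$value
  n <- length(x)
  msep <- max(2L, round(min_separation * fs))
  if (n < 2 * msep) {
    abort("trace shorter than twice `min_separation`.",
          class = "ferrotrace_invalid_parameter")
  }
  if (is.null(penalty)) {
    sigma <- stats::mad(diff(x)) / sqrt(2)
    if (sigma == 0) sigma <- stats::sd(x) / sqrt(2)
    penalty <- 2 * sigma^2 * log(n)
  }
  cs <- c(0, cumsum(x))
  # best split of [l, r]: change point k means mean shift between x[k] and
  # x[k+1]; candidate k in [l + msep - 1, r - msep]
  best_split <- function(l, r) {
    lo <- l + msep - 1L
    hi <- r - msep
    if (hi < lo) return(NULL)
    k <- seq.int(lo, hi)
    n1 <- k - l + 1L
    n2 <- r - k
    s1 <- cs[k + 1L] - cs[l]
    s2 <- cs[r + 1L] - cs[k + 1L]
    stot <- cs[r + 1L] - cs[l]
    gain <- s1^2 / n1 + s2^2 / n2 - stot^2 / (r - l + 1L)
    i <- which.max(gain)
    list(k = k[i], gain = gain[i])
  }
  found_k <- integer(0)
  found_g <- numeric(0)
  queue <- list(c(1L, n))
  while (length(queue)) {
    seg <- queue[[1]]
    queue <- queue[-1]
    sp <- best_split(seg[1], seg[2])
    if (is.null(sp) || sp$gain <= penalty) next
    found_k <- c(found_k, sp$k)
    found_g <- c(found_g, sp$gain)
    queue <- c(queue, list(c(seg[1], sp$k)), list(c(sp$k + 1L, seg[2])))
  }
  o <- order(found_k)
  tibble(time = trace$time[1] + (found_k[o] - 1L + 0.5) / fs,
         index = found_k[o], gain = found_g[o])
}

#' Characterize a trapping event
#'
#' Given detected change points, identifies the trapping step (the point
#' with the largest upward level shift between adjacent-segment medians),
#' estimates the pre-trap baseline `T0` (median of the pre-trap window),
#' the trapped level (median after a settling exclusion of `settle`
#' seconds, up to the next change point), the step height `deltaT` and
#' the dielectric-loading ratio `deltaT / T0`. A later change point whose
#' following level returns within 3 pre-trap noise standard deviations of
#' `T0` is reported as the release. Medians make the level estimates
#' robust to asymmetric conformational fluctuations.
#'
#' @param trace a trace tibble.
#' @param change_points output of [detect_steps()] (or a tibble with a
#'   `time` column).
#' @param settle post-trap settling time excluded from the trapped-level
#'   window, s.
#' @return One-row tibble of class `ferro_trap_event`: `t_trap`,
#'   `t_release` (NA if none), `T0`, `deltaT`, `ratio`, `confidence`.
#' @export
characterize_trap <- function(trace, change_points, settle = 0.5) {
  trace <- as_trace(trace)
  fs <- trace_fs(trace)
  x <- trace$value
  t0 <- trace$time[1]
  n <- length(x)
  if (is.null(change_points) || nrow(change_points) < 1) {
    abort("need at least one change point.", class = "ferrotrace_invalid_parameter")
  }
  cp_idx <- sort(round((change_points$time - t0) * fs + 0.5))
  cp_idx <- cp_idx[cp_idx >= 1 & cp_idx < n]
  bounds <- c(0L, cp_idx, n)
  # level of each inter-change-point segment (settling excluded)
  n_settle <- round(settle * fs)
  levels <- vapply(seq_len(length(bounds) - 1L), function(i) {
    lo <- bounds[i] + 1L
    hi <- bounds[i + 1L]
    lo2 <- min(lo + n_settle, hi)
    stats::median(x[seq.int(lo2, hi)])
  }, numeric(1))
  shifts <- diff(levels)
  up <- which(shifts > 0)
  if (length(up) == 0) up <- seq_along(shifts)
  j <- up[which.max(abs(shifts[up]))]   # trapping step
  i_trap <- cp_idx[j]
  if (i_trap < fs) {
    abort("no pre-trap window of at least 1 s.",
          class = "ferrotrace_estimation_error")
  }
  pre <- x[seq_len(i_trap)]
  T0 <- stats::median(pre)
  if (!(T0 > 0)) abort("non-positive baseline.", class = "ferrotrace_estimation_error")
  sd_pre <- stats::sd(pre)
  trapped <- levels[j + 1L]
  deltaT <- trapped - T0
  # release: first later change point whose following level is back at T0
  t_release <- NA_real_
  if (j + 1L <= length(shifts)) {
    for (m in seq.int(j + 1L, length(shifts))) {
      if (abs(levels[m + 1L] - T0) <= 3 * sd_pre) {
        t_release <- t0 + (cp_idx[m] - 0.5) / fs
        break
      }
    }
  }
  out <- tibble(
    t_trap = t0 + (i_trap - 0.5) / fs,
    t_release = t_release,
    T0 = T0, deltaT = deltaT, ratio = deltaT / T0,
    confidence = "detected")
  class(out) <- c("ferro_trap_event", class(out))
  out
}

#' Detect and characterize the trapping event of a raw trace
#'
#' Convenience wrapper: decimates the trace so step detection runs on
#' approximately `detect_fs` Hz samples (where the band-limited
#' conformational noise is close to white), detects change points, and
#' characterizes the trap on the decimated trace.
#'
#' @param trace a trace tibble.
#' @param detect_fs target sampling rate for detection, Hz.
#' @param min_separation,settle passed on to [detect_steps()] /
#'   [characterize_trap()].
#' @return A `ferro_trap_event` tibble.
#' @export
detect_trap_event <- function(trace, detect_fs = 200, min_separation = 1,
                              settle = 0.5) {
  trace <- as_trace(trace)
  fs <- trace_fs(trace)
  fac <- floor(fs / detect_fs)
  dec <- if (fac >= 2) decimate_trace(trace, fac) else trace
  cps <- detect_steps(dec, min_separation = min_separation)
  characterize_trap(dec, cps, settle = settle)
}
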