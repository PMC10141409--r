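#' Simulate trapped-particle position (Ornstein-Uhlenbeck)
#'
#' Overdamped Brownian motion of a particle in a harmonic trap, simulated
#' with the exact discrete-time update of the Ornstein-Uhlenbeck process
#' \deqn{x_{k+1} = x_k e^{-\theta\Delta t} +
#'   \xi_k\sqrt{\frac{k_B T}{\kappa}\left(1 - e^{-2\theta\Delta t}\right)},
#'   \qquad \theta = \kappa/\gamma,}
#' so the sample path has the correct stationary variance \eqn{k_B T/\kappa}
#' and lag-one autocorrelation \eqn{e^{-\theta\Delta t}} at any step size
#' (no Euler discretisation bias). The initial sample is drawn from the
#' stationary distribution.
#'
#' @param kappa trap stiffness, N/m.
#' @param gamma drag coefficient, kg/s.
#' @param temperature K.
#' @param fs sampling rate, Hz.
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @return Numeric vector of positions (m).
#' @export
simulate_ou <- function(kappa, gamma, temperature, fs, n_samples, seed = 1) {
  stopifnot(kappa > 0, gamma > 0, temperature > 0, fs > 0, n_samples >= 1)
  theta <- kappa / gamma
  a <- exp(-theta / fs)
  sd_stat <- sqrt(.kB * temperature / kappa)
  sd_step <- sd_stat * sqrt(1 - a^2)
  withr::with_seed(seed, {
    x0 <- stats::rnorm(1, 0, sd_stat)
    innov <- stats::rnorm(n_samples, 0, sd_step)
    as.numeric(stats::filter(innov, a, method = "recursive", init = x0))
  })
}

#' Simulate the two-state gating process
#'
#' Alternating Markov renewal process: dwell lengths are drawn i.i.d.
#' exponential with means `tau_on` / `tau_off`, states alternate starting
#' from `start_state`. Switch times are snapped to the sample grid.
#'
#' @param kinetics a [gating_kinetics()] object.
#' @param duration s.
#' @param fs Hz.
#' @param seed integer seed.
#' @param start_state `"on"` or `"off"`.
#' @return List with `state` (integer vector, 1 = on, 0 = off, length
#'   `round(duration * fs)`), `boundaries` (switch times, s, on the sample
#'   grid) and `segments` (tibble of t_start, t_end, label).
#' @export
simulate_gating <- function(kinetics, duration, fs, seed = 1,
                            start_state = "on") {
  stopifnot(duration > 0, fs > 0)
  n <- round(duration * fs)
  withr::with_seed(seed, {
    # draw enough dwells to cover the duration; top up if unlucky
    dwells <- numeric(0)
    labels <- integer(0)
    state <- if (start_state == "on") 1L else 0L
    total <- 0
    while (total < duration) {
      k <- max(16, ceiling(2 * (duration - total) /
                             (kinetics$tau_on + kinetics$tau_off)))
      on_d <- stats::rexp(k, 1 / kinetics$tau_on)
      off_d <- stats::rexp(k, 1 / kinetics$tau_off)
      s <- state
      for (i in seq_len(2 * k)) {
        d <- if (s == 1L) on_d[(i + 1) %/% 2] else off_d[(i + 1) %/% 2]
        dwells <- c(dwells, d)
        labels <- c(labels, s)
        total <- total + d
        s <- 1L - s
        if (total >= duration) break
      }
      state <- s
    }
    ends <- cumsum(dwells)
    keep <- which(ends < duration)
    boundaries <- round(ends[keep] * fs) / fs
    boundaries <- boundaries[boundaries > 0 & boundaries < duration]
    boundaries <- unique(boundaries)
    # per-sample label: sample i covers time (i-1)/fs
    tt <- (seq_len(n) - 1) / fs
    seg_idx <- findInterval(tt, boundaries) + 1L
    first <- if (start_state == "on") 1L else 0L
    seg_labels <- rep(c(first, 1L - first), length.out = length(boundaries) + 1L)
    state_vec <- seg_labels[seg_idx]
    starts <- c(0, boundaries)
    ends_t <- c(boundaries, duration)
    segments <- tibble(t_start = starts, t_end = ends_t,
                       label = ifelse(seg_labels == 1L, "on", "off"))
    list(state = state_vec, boundaries = boundaries, segments = segments)
  })
}

#' Band-limited unit-RMS Gaussian noise
#'
#' Spectral synthesis of a Gaussian process whose power is confined to
#' `[f_lo, f_hi]` with a flat in-band spectrum: independent complex
#' Gaussian Fourier coefficients on the in-band bins, Hermitian symmetry,
#' inverse FFT, then exact normalisation to RMS 1.
#'
#' @param f_lo,f_hi band edges, Hz; `0 < f_lo < f_hi < fs/2`.
#' @param fs sampling rate, Hz.
#' @param n_samples length of the series.
#' @param seed integer seed.
#' @return Numeric vector with RMS exactly 1.
#' @export
band_limited_noise <- function(f_lo, f_hi, fs, n_samples, seed = 1) {
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < fs / 2)) {
    abort("need 0 < f_lo < f_hi < fs/2.", class = "ferrotrace_invalid_parameter")
  }
  n <- as.integer(n_samples)
  freqs <- (seq_len(n %/% 2)) * fs / n      # positive-frequency bins 1..n/2
  in_band <- which(freqs >= f_lo & freqs <= f_hi)
  if (length(in_band) == 0) {
    abort("trace too short to resolve the requested band.",
          class = "ferrotrace_invalid_parameter")
  }
  withr::with_seed(seed, {
    spec <- complex(real = rep(0, n), imaginary = rep(0, n))
    coef <- complex(real = stats::rnorm(length(in_band)),
                    imaginary = stats::rnorm(length(in_band)))
    spec[in_band + 1L] <- coef                     # bin k -> index k+1
    nyq <- if (n %% 2 == 0) n %/% 2 else NA_integer_
    if (!is.na(nyq)) spec[nyq + 1L] <- complex(real = Re(spec[nyq + 1L]), imaginary = 0)
    # Hermitian symmetry for a real series
    spec[n - in_band[in_band < n / 2] + 1L] <- Conj(spec[in_band[in_band < n / 2] + 1L])
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
    x / sqrt(mean(x^2))
  })
}

# internal: derive a child seed from a base seed and a stream label,
# keeping results inside 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 101 + k * 7919) %% 2147483629)
}

#' Synthesize a transmission trace with ground truth
#'
#' Composes the full signal model of a trapping experiment,
#' \deqn{T(t) = T_0(1 + \delta\,o(t)) + o(t)\,[c\,x(t) + A(t)\,\zeta(t)]
#'       + n(t),}
#' where `o(t)` is trap occupancy (0 before `t_trap` and after
#' `t_release`), `delta` the preset step contrast, `x(t)` the
#' Ornstein-Uhlenbeck position coupled through the responsivity `c`,
#' `zeta(t)` unit-RMS band-limited conformational noise whose envelope
#' `A(t)` carries the gating state and the exponential mineralization
#' decay, and `n(t)` white instrument noise. With `kinetics = NULL` the
#' envelope is the constant preset amplitude.
#'
#' @param config a [trace_config()].
#' @param preset a [protein_preset()].
#' @param physics a [trap_physics()]; defaults to the preset's radius.
#' @param kinetics a [gating_kinetics()] or `NULL` (no gating /
#'   mineralization).
#' @param amp_profile optional function of time (s) returning an extra
#'   multiplier of the conformational amplitude (used e.g. for the
#'   ferric-control exposure bump).
#' @return A `ferro_trace` tibble with additional ground-truth columns
#'   `occupancy` (0/1), `state` ("on"/"off"/NA outside the trap) and
#'   `position` (m), and attributes `truth_boundaries` (gating switch
#'   times, s) and `config`/`preset` metadata.
#' @export
synthesize_trace <- function(config, preset, physics = NULL, kinetics = NULL,
                             amp_profile = NULL) {
  fs <- config$fs
  if (fs <= 2 * preset$conf_band[2]) {
    abort("sampling rate must exceed twice the conformational band top.",
          class = "ferrotrace_invalid_parameter")
  }
  physics <- physics %||% trap_physics(radius = preset$radius_nm * 1e-9)
  if (physics$corner_hz >= fs / 2) {
    abort("trap corner frequency must be below Nyquist.",
          class = "ferrotrace_invalid_parameter")
  }
  n <- round(config$duration * fs)
  tt <- (seq_len(n) - 1) / fs
  i_trap <- round(config$t_trap * fs) + 1L
  i_rel <- if (is.null(config$t_release)) n + 1L else round(config$t_release * fs) + 1L
  occ <- numeric(n)
  occ[seq.int(i_trap, min(i_rel - 1L, n))] <- 1

  n_occ <- sum(occ == 1)
  value <- config$T0 * (1 + preset$step_contrast * occ)

  position <- numeric(n)
  state_chr <- rep(NA_character_, n)
  boundaries <- numeric(0)
  if (n_occ > 0) {
    idx <- which(occ == 1)
    x <- simulate_ou(physics$kappa, physics$gamma, physics$temperature,
                     fs, n_occ, seed = child_seed(config$seed, 1))
    zeta <- band_limited_noise(preset$conf_band[1], preset$conf_band[2],
                               fs, n_occ, seed = child_seed(config$seed, 2))
    t_occ <- tt[idx]
    amp <- rep(preset$conf_amp_trapped, n_occ)
    state_occ <- rep("on", n_occ)
    if (!is.null(kinetics)) {
      g_start <- max(kinetics$loading_start, config$t_trap)
      g_dur <- (tt[idx[n_occ]] + 1 / fs) - g_start
      if (g_dur > 0) {
        g <- simulate_gating(kinetics, g_dur, fs,
                             seed = child_seed(config$seed, 3))
        gi <- which(t_occ >= g_start)
        k <- pmin(round((t_occ[gi] - g_start) * fs) + 1L, length(g$state))
        on_off <- g$state[k]
        state_occ[gi] <- ifelse(on_off == 1L, "on", "off")
        amp[gi] <- amp[gi] * ifelse(on_off == 1L, kinetics$amp_on, kinetics$amp_off)
        boundaries <- g_start + g$boundaries
      }
      decay <- exp(-pmax(0, t_occ - kinetics$loading_start) /
                     kinetics$mineralization_tau)
      amp <- amp * decay
    }
    if (!is.null(amp_profile)) amp <- amp * amp_profile(t_occ)
    value[idx] <- value[idx] + physics$position_responsivity * x + amp * zeta
    position[idx] <- x
    state_chr[idx] <- state_occ
  }
  if (config$instrument_noise > 0) {
    value <- value + withr::with_seed(
      child_seed(config$seed, 4),
      stats::rnorm(n, 0, config$instrument_noise))
  }

  tr <- new_trace(value, fs = fs,
                  metadata = list(source = "synthetic", seed = config$seed,
                                  preset = preset$name))
  tr$occupancy <- occ
  tr$state <- state_chr
  tr$position <- position
  attr(tr, "truth_boundaries") <- boundaries
  attr(tr, "config") <- config
  attr(tr, "preset") <- preset
  class(tr) <- c("ferro_synthetic", class(tr))
  tr
}

#' Shipped synthetic experiments
#'
#' Convenience wrappers that reproduce the package's standard study
#' conditions at the default detector scale (T0 = 1 V, fs = 10 kHz).
#'
#' `simulate_trap_experiment()` — a plain trapping run: baseline, then a
#' trapped phase with constant conformational amplitude (no iron).
#' `simulate_loading_experiment()` — apo-ferritin trapped at `t_trap`,
#' iron loading starting `loading_delay` seconds later: on/off pore
#' gating plus slow mineralization decay of the fluctuation amplitude.
#' `simulate_control_experiment()` — ferric (Fe3+) control: no gating; at
#' `exposure_delay` seconds after trapping the conformational amplitude
#' steps up slightly (calibrated 14 -> 15 mV median sliding RMS).
#' `simulate_trapped_segment()` — a short steady-state trapped segment
#' with no baseline phase, for per-segment population statistics.
#'
#' @param preset a [protein_preset()].
#' @param seed integer seed.
#' @param duration trace length, s.
#' @param fs sampling rate, Hz.
#' @param t_trap trapping time, s.
#' @param kinetics a [gating_kinetics()]; default has dwell means 3.5 s
#'   and mineralization time constant 600 s.
#' @param loading_delay,exposure_delay s after trapping.
#' @return A synthetic `ferro_trace` (see [synthesize_trace()]).
#' @export
simulate_trap_experiment <- function(preset, seed = 1, duration = 60,
                                     fs = 1e4, t_trap = 5) {
  cfg <- trace_config(fs = fs, duration = duration, t_trap = t_trap, seed = seed)
  synthesize_trace(cfg, preset)
}

#' @rdname simulate_trap_experiment
#' @export
simulate_loading_experiment <- function(seed = 1, duration = 1420,
                                        fs = 1e4, t_trap = 5,
                                        loading_delay = 60,
                                        kinetics = NULL) {
  cfg <- trace_config(fs = fs, duration = duration, t_trap = t_trap, seed = seed)
  kin <- kinetics %||% gating_kinetics(loading_start = t_trap + loading_delay)
  synthesize_trace(cfg, preset_apo(), kinetics = kin)
}

#' @rdname simulate_trap_experiment
#' @export
simulate_control_experiment <- function(seed = 1, duration = 1260,
                                        fs = 1e4, t_trap = 5,
                                        exposure_delay = 25) {
  cfg <- trace_config(fs = fs, duration = duration, t_trap = t_trap, seed = seed)
  t_exp <- t_trap + exposure_delay
  fac <- .cal$control_post_factor
  prof <- function(t) ifelse(t >= t_exp, fac, 1)
  tr <- synthesize_trace(cfg, preset_ferric_control(), amp_profile = prof)
  attr(tr, "exposure_time") <- t_exp
  tr
}

#' @rdname simulate_trap_experiment
#' @export
simulate_trapped_segment <- function(preset, seed = 1, duration = 1, fs = 1e4) {
  cfg <- trace_config(fs = fs, duration = duration, t_trap = 0, seed = seed)
  synthesize_trace(cfg, preset)
}
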