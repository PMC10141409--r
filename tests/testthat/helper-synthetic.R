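# Shared fixtures, built in code. Heavier traces are cached per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# a noiseless config: no instrument noise; pair with quiet_physics()
quiet_config <- function(...) trace_config(instrument_noise = 0, ...)

quiet_physics <- function(radius_nm = 6) {
  trap_physics(radius = radius_nm * 1e-9, position_responsivity = 0)
}

# preset with no conformational noise
silent_preset <- function(step_contrast = 0.05) {
  protein_preset("silent", 6, step_contrast = step_contrast,
                 conf_amp_trapped = 0)
}

# brute-force single-change-point least-squares oracle: best split k
# (boundary between samples k and k+1), exhaustive over all k
brute_force_split <- function(x, margin = 2L) {
  n <- length(x)
  ks <- seq.int(margin, n - margin)
  sse <- vapply(ks, function(k) {
    a <- x[1:k]; b <- x[(k + 1):n]
    sum((a - mean(a))^2) + sum((b - mean(b))^2)
  }, numeric(1))
  ks[which.min(sse)]
}

# synthetic sliding-RMS series with alternating on/off levels
make_rms_series <- function(levels, dwells, hop = 0.05, noise_log_sd = 0,
                            seed = 1) {
  labs <- rep(c(1, 0), length.out = length(dwells))
  rms <- unlist(mapply(function(d, l) rep(levels[2 - l], round(d / hop)),
                       dwells, labs, SIMPLIFY = FALSE))
  if (noise_log_sd > 0) {
    rms <- withr::with_seed(seed, rms * exp(stats::rnorm(length(rms), 0, noise_log_sd)))
  }
  out <- tibble::tibble(time = (seq_along(rms) - 1) * hop + hop / 2, rms = rms)
  class(out) <- c("ferro_rms", class(out))
  attr(out, "window") <- 2 * hop
  attr(out, "hop") <- hop
  out
}

# ground-truth boundary times of make_rms_series
rms_series_boundaries <- function(dwells, hop = 0.05) {
  b <- cumsum(round(dwells / hop) * hop)
  b[-length(b)]
}

# 120 s iron-loading gating trace (tau = 3.5 s), filtered at 1 kHz,
# plus its trapped-span RMS series — reused across gating tests
gating_fixture <- function() {
  fixture("gating", function() {
    kin <- gating_kinetics(loading_start = 5, mineralization_tau = 1e9)
    tr <- synthesize_trace(trace_config(duration = 120, t_trap = 5, seed = 11),
                           preset_apo(), kinetics = kin)
    f <- gaussian_lowpass(tr, 1000)
    rs <- sliding_rms(f, 0.1, 0.05)
    rs2 <- rs[rs$time >= 5.5, ]
    class(rs2) <- class(rs)
    attr(rs2, "window") <- 0.1
    attr(rs2, "hop") <- 0.05
    list(trace = tr, filtered = f, rms = rs2)
  })
}
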