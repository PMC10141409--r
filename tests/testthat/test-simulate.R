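test_that("OU simulation reproduces the stationary closed forms", {
  kB <- 1.380649e-23
  kappa <- 1e-6; gam <- 1e-10; Temp <- 298; fs <- 1e4
  x <- simulate_ou(kappa, gam, Temp, fs, 1e6, seed = 3)
  expect_equal(stats::var(x), kB * Temp / kappa, tolerance = 0.03)
  a_theory <- exp(-(kappa / gam) / fs)
  a_hat <- stats::cor(x[-length(x)], x[-1])
  expect_equal(a_hat, a_theory, tolerance = 0.01)
})

test_that("a very stiff trap freezes the particle", {
  x_soft <- simulate_ou(1e-6, 1e-10, 298, 1e4, 1e4, seed = 1)
  x_stiff <- simulate_ou(1, 1e-10, 298, 1e4, 1e4, seed = 1)
  expect_lt(stats::sd(x_stiff), 1e-2 * stats::sd(x_soft))
})

test_that("gating is an alternating renewal process with exponential dwells", {
  kin <- gating_kinetics(tau_on = 3.5, tau_off = 3.5)
  g <- simulate_gating(kin, duration = 1e4, fs = 100, seed = 5)
  segs <- g$segments
  # boundaries = segments - 1, alternating labels
  expect_equal(length(g$boundaries), nrow(segs) - 1)
  expect_true(all(segs$label[-1] != segs$label[-nrow(segs)]))
  # dwell means (drop censored first/last)
  inner <- segs[-c(1, nrow(segs)), ]
  d <- inner$t_end - inner$t_start
  expect_equal(mean(d[inner$label == "on"]), 3.5, tolerance = 0.05)
  expect_equal(mean(d[inner$label == "off"]), 3.5, tolerance = 0.05)
  # boundaries on the sample grid, strictly increasing
  expect_true(all(abs(g$boundaries * 100 - round(g$boundaries * 100)) < 1e-9))
  expect_true(all(diff(g$boundaries) > 0))

  # tau_off -> infinity: a single on segment
  g1 <- simulate_gating(gating_kinetics(tau_on = 1e12, tau_off = 1e11),
                        duration = 100, fs = 100, seed = 2)
  expect_equal(length(g1$boundaries), 0)
  expect_true(all(g1$state == 1L))
})

test_that("band-limited noise has unit RMS and in-band power", {
  fs <- 2000; n <- 2^15
  z <- band_limited_noise(3, 150, fs, n, seed = 9)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-9)
  # periodogram power fraction inside the band
  sp <- Mod(stats::fft(z))^2
  f <- (seq_len(n %/% 2)) * fs / n
  pos <- sp[2:(n %/% 2 + 1)]
  frac <- sum(pos[f >= 3 & f <= 150]) / sum(pos)
  expect_gt(frac, 0.95)
  # seeding
  expect_identical(z, band_limited_noise(3, 150, fs, n, seed = 9))
  expect_false(identical(z, band_limited_noise(3, 150, fs, n, seed = 10)))
  expect_error(band_limited_noise(3, 1500, 2000, n),
               class = "ferrotrace_invalid_parameter")
})

test_that("synthesized traces honour the signal model exactly when noise-free", {
  # no protein, no noise: constant baseline
  cfg <- quiet_config(fs = 5000, duration = 4, t_trap = 1, seed = 1)
  tr0 <- synthesize_trace(cfg, silent_preset(step_contrast = 0),
                          physics = quiet_physics())
  expect_true(all(tr0$value == 1.0))

  # noise-free trapping step: mean difference is exactly delta * T0
  tr <- synthesize_trace(cfg, silent_preset(0.05), physics = quiet_physics())
  pre <- tr$value[tr$time < 1]
  post <- tr$value[tr$time >= 1]
  expect_equal(mean(post) - mean(pre), 0.05 * 1.0, tolerance = 1e-14)
  # occupancy ground truth matches the phase schedule
  expect_true(all(tr$occupancy[tr$time < 1] == 0))
  expect_true(all(tr$occupancy[tr$time >= 1] == 1))

  # release returns the trace to baseline and clears occupancy
  cfg_r <- quiet_config(fs = 5000, duration = 6, t_trap = 1, t_release = 4,
                        seed = 1)
  trr <- synthesize_trace(cfg_r, silent_preset(0.05), physics = quiet_physics())
  expect_true(all(trr$occupancy[trr$time >= 4] == 0))
  expect_true(all(trr$value[trr$time >= 4] == 1.0))
})

test_that("gating modulates the conformational envelope as programmed", {
  kin <- gating_kinetics(tau_on = 3, tau_off = 3, amp_off = 0.25,
                         loading_start = 0, mineralization_tau = 1e12)
  cfg <- quiet_config(fs = 5000, duration = 60, t_trap = 0, seed = 4)
  pre <- protein_preset("p", 6, step_contrast = 0, conf_amp_trapped = 2e-3)
  tr <- synthesize_trace(cfg, pre, physics = quiet_physics(), kinetics = kin)
  conf <- tr$value - 1.0   # only the conformational term remains
  bnd <- attr(tr, "truth_boundaries")
  segs <- data.frame(t0 = c(0, bnd), t1 = c(bnd, 60))
  segs$label <- vapply(seq_len(nrow(segs)), function(i) {
    tr$state[which(tr$time >= segs$t0[i])[1]]
  }, character(1))
  long <- segs[segs$t1 - segs$t0 >= 1, ]
  rms_of <- function(t0, t1) sqrt(mean(conf[tr$time >= t0 & tr$time < t1]^2))
  r_on <- mapply(rms_of, long$t0[long$label == "on"], long$t1[long$label == "on"])
  r_off <- mapply(rms_of, long$t0[long$label == "off"], long$t1[long$label == "off"])
  # programmed amplitudes 2 mV and 0.5 mV within 5%
  expect_equal(mean(r_on), 2e-3, tolerance = 0.05)
  expect_equal(mean(r_off), 0.25 * 2e-3, tolerance = 0.05)
})

test_that("trapped-segment variance follows the OU energy bookkeeping", {
  # instrument and conformational noise off: var = c^2 kB T / kappa
  phys <- trap_physics(position_responsivity = 1e5)
  cfg <- quiet_config(fs = 1e4, duration = 105, t_trap = 1, seed = 8)
  tr <- synthesize_trace(cfg, silent_preset(0.05), physics = phys)
  v <- stats::var(tr$value[tr$time >= 1])
  expect_equal(v, 1e10 * 1.380649e-23 * 298 / 1e-6, tolerance = 0.03)
})

test_that("synthesis is bit-identical under a fixed seed", {
  cfg <- trace_config(fs = 5000, duration = 5, t_trap = 1, seed = 123)
  kin <- gating_kinetics(loading_start = 2)
  a <- synthesize_trace(cfg, preset_apo(), kinetics = kin)
  b <- synthesize_trace(cfg, preset_apo(), kinetics = kin)
  expect_identical(a$value, b$value)
  expect_identical(attr(a, "truth_boundaries"), attr(b, "truth_boundaries"))
  cfg2 <- trace_config(fs = 5000, duration = 5, t_trap = 1, seed = 124)
  expect_false(identical(synthesize_trace(cfg2, preset_apo())$value, a$value))
})

test_that("ground-truth boundaries lie on the grid inside the trapped span", {
  cfg <- trace_config(fs = 5000, duration = 30, t_trap = 2, seed = 31)
  kin <- gating_kinetics(loading_start = 4)
  tr <- synthesize_trace(cfg, preset_apo(), kinetics = kin)
  b <- attr(tr, "truth_boundaries")
  expect_gt(length(b), 0)
  expect_true(all(diff(b) > 0))
  expect_true(all(b > 2 & b < 30))
  expect_true(all(abs(b * 5000 - round(b * 5000)) < 1e-6))
  expect_equal(nrow(tr), 30 * 5000)
  expect_true(all(lengths(list(tr$occupancy, tr$state, tr$position)) == nrow(tr)))
})
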