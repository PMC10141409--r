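test_that("noise-free alternating RMS levels are segmented exactly", {
  dwells <- rep(4, 8)   # 4 s per state
  rs <- make_rms_series(c(1.0, 0.3), dwells)
  seg <- segment_states(rs, min_dwell = 0.5)
  expect_false(attr(seg, "single_state"))
  expect_equal(nrow(seg), 8)
  expect_equal(seg$label, rep(c("on", "off"), 4))
  truth <- rms_series_boundaries(dwells)
  hop <- 0.05
  expect_true(all(abs(seg$t_end[-nrow(seg)] - truth) <= 0.1 / 2 + hop))
})

test_that("boundary error stays below window + hop over random placements", {
  hop <- 0.05
  for (case in 1:100) {
    dwells <- withr::with_seed(case, stats::runif(6, 1, 5))
    rs <- make_rms_series(c(2.0, 0.5), dwells)
    seg <- segment_states(rs, min_dwell = 0.5)
    truth <- rms_series_boundaries(dwells)
    est <- seg$t_end[-nrow(seg)]
    expect_equal(length(est), length(truth))
    expect_true(all(abs(est - truth) <= 2 * hop + hop))  # window + hop
  }
})

test_that("a constant-amplitude series is declared single-state", {
  rs <- make_rms_series(c(1, 1), rep(3, 6), noise_log_sd = 0.05, seed = 2)
  expect_warning(seg <- segment_states(rs), "single-state")
  expect_true(attr(seg, "single_state"))
  expect_equal(nrow(seg), 1)
})

test_that("segmentation is invariant to positive rescaling", {
  rs <- make_rms_series(c(1.0, 0.3), rep(3, 8), noise_log_sd = 0.1, seed = 3)
  seg1 <- segment_states(rs)
  rs2 <- rs
  rs2$rms <- rs2$rms * 41.7
  seg2 <- segment_states(rs2)
  expect_equal(seg2$label, seg1$label)
  expect_equal(seg2$t_start, seg1$t_start)
  expect_equal(attr(seg2, "threshold"), 41.7 * attr(seg1, "threshold"),
               tolerance = 1e-9)
})

test_that("misassignment vanishes as the level separation grows", {
  sigma <- 0.1
  acc <- vapply(c(2, 4, 8), function(mult) {
    dwells <- withr::with_seed(mult, stats::runif(10, 1.5, 5))
    rs <- make_rms_series(c(exp(mult * sigma), 1), dwells,
                          noise_log_sd = sigma, seed = mult + 50)
    seg <- suppressWarnings(segment_states(rs, min_dwell = 0.5))
    truth_b <- rms_series_boundaries(dwells)
    truth_lab <- rep(c("on", "off"), length.out = length(dwells))
    lab_at <- truth_lab[findInterval(rs$time, truth_b) + 1]
    est_at <- seg$label[findInterval(rs$time, seg$t_start)]
    mean(est_at == lab_at)
  }, numeric(1))
  expect_true(all(diff(acc) >= 0) || acc[3] > 0.99)
  expect_gt(acc[3], acc[1])
})

test_that("the loading preset is segmented to >= 90% ground-truth accuracy", {
  fx <- gating_fixture()
  seg <- segment_states(fx$rms)
  expect_false(attr(seg, "single_state"))
  truth <- fx$trace$state[round(fx$rms$time * 1e4) + 1]
  est <- seg$label[findInterval(fx$rms$time, seg$t_start)]
  expect_gt(mean(est == truth, na.rm = TRUE), 0.90)
})

test_that("dwell statistics use uncensored segments and the exponential MLE", {
  seg <- tibble::tibble(
    t_start = c(0, 1, 3, 6, 10, 12),
    t_end = c(1, 3, 6, 10, 12, 13),
    label = c("off", "on", "off", "on", "off", "on"))
  seg$dwell <- seg$t_end - seg$t_start
  class(seg) <- c("ferro_segments", class(seg))
  dw <- dwell_statistics(seg)
  expect_equal(dw$mean_on, mean(c(2, 4)))
  expect_equal(dw$mean_off, 2.5)
  expect_equal(dw$censored, c("off", "on"))

  single <- seg[1, ]
  expect_error(dwell_statistics(single), class = "ferrotrace_estimation_error")
})

test_that("the dwell estimator is unbiased on exponential simulations", {
  kin <- gating_kinetics(tau_on = 3.5, tau_off = 3.5)
  est <- vapply(1:50, function(s) {
    g <- simulate_gating(kin, duration = 1000, fs = 100, seed = s)
    segs <- g$segments
    segs$dwell <- segs$t_end - segs$t_start
    class(segs) <- c("ferro_segments", class(segs))
    dwell_statistics(segs)$mean_on
  }, numeric(1))
  expect_equal(mean(est), 3.5, tolerance = 0.02)
})

test_that("sliding RMS within truth segments recovers the amplitude ratio", {
  kin <- gating_kinetics(tau_on = 3, tau_off = 3, amp_off = 0.25,
                         loading_start = 0, mineralization_tau = 1e12)
  cfg <- quiet_config(fs = 5000, duration = 80, t_trap = 0, seed = 21)
  pre <- protein_preset("p", 6, step_contrast = 0, conf_amp_trapped = 3e-3)
  tr <- synthesize_trace(cfg, pre, physics = quiet_physics(), kinetics = kin)
  rs <- sliding_rms(tr, 0.1, 0.05)
  truth <- tr$state[round(rs$time * 5000) + 1]
  keep <- !is.na(truth)
  m_on <- mean(rs$rms[keep & truth == "on"])
  m_off <- mean(rs$rms[keep & truth == "off"])
  expect_equal(m_off / m_on, 0.25, tolerance = 0.10)
})

test_that("mineralization trend reports per-interval medians", {
  fs <- 2000
  x <- withr::with_seed(22, c(stats::rnorm(60 * fs, sd = 6.8e-3),
                              stats::rnorm(60 * fs, sd = 5.4e-3)))
  tr <- new_trace(1 + x, fs)
  mt <- mineralization_trend(tr, c(5, 55), c(65, 115))
  expect_equal(mt$median_rms_pre, 6.8, tolerance = 0.05)
  expect_equal(mt$median_rms_post, 5.4, tolerance = 0.05)
  # identical intervals: zero relative change
  mt0 <- mineralization_trend(tr, c(5, 55), c(5, 55))
  expect_equal(mt0$relative_change, 0)
  expect_error(mineralization_trend(tr, c(5, 55), c(100, 130)),
               class = "ferrotrace_invalid_parameter")
})

test_that("the loading preset alternates while kinetics say it should", {
  fx <- gating_fixture()
  seg <- segment_states(fx$rms)
  expect_gte(sum(rle(seg$label)$lengths >= 1) - 1, 3)  # >= 3 alternations
})
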