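test_that("sliding RMS matches closed forms", {
  fs <- 1000
  # constant trace: all zeros
  rs <- sliding_rms(new_trace(rep(2, 5000), fs), 0.1, 0.05)
  expect_true(all(rs$rms == 0))
  expect_equal(nrow(rs), length(seq(1, 5000 - 100 + 1, by = 50)))

  # sinusoid of amplitude A over an integer number of periods: A/sqrt(2)
  A <- 0.004
  t <- (0:(10 * fs - 1)) / fs
  tone <- new_trace(A * sin(2 * pi * 50 * t), fs)
  rs2 <- sliding_rms(tone, 0.1, 0.1)   # window = 5 periods of 50 Hz
  expect_equal(mean(rs2$rms), A / sqrt(2) * 1e3, tolerance = 1e-3)

  # white Gaussian noise sigma = 2 mV: mean RMS within 3%
  x <- withr::with_seed(11, stats::rnorm(2e5, sd = 2e-3))
  rs3 <- sliding_rms(new_trace(x, fs), window = 1, hop = 1)
  expect_gte(nrow(rs3), 100)
  expect_equal(mean(rs3$rms), 2, tolerance = 0.03)

  expect_error(sliding_rms(new_trace(rep(1, 50), fs), window = 1),
               class = "ferrotrace_invalid_parameter")
})

test_that("NRMS is std over median and scale-invariant", {
  expect_equal(nrms(rep(5, 2000)), 0)
  x <- withr::with_seed(12, 1 + 0.01 * stats::rnorm(1e4))
  expect_equal(nrms(x), stats::sd(x) / stats::median(x))
  expect_equal(nrms(3.3 * x), nrms(x), tolerance = 1e-12)
  expect_error(nrms(x - 2), class = "ferrotrace_estimation_error")
})

test_that("apo presets fluctuate more than holo presets on every matched seed", {
  n_apo <- n_holo <- iqr_a <- iqr_h <- numeric(0)
  for (seed in 1:20) {
    a <- gaussian_lowpass(simulate_trapped_segment(preset_apo(), seed = seed,
                                                   duration = 12), 1000)
    h <- gaussian_lowpass(simulate_trapped_segment(preset_holo(), seed = seed,
                                                   duration = 12), 1000)
    n_apo <- c(n_apo, nrms(a)); n_holo <- c(n_holo, nrms(h))
    qa <- quartile_summary(a$value); qh <- quartile_summary(h$value)
    iqr_a <- c(iqr_a, qa$q3 - qa$q1); iqr_h <- c(iqr_h, qh$q3 - qh$q1)
  }
  expect_true(all(n_apo > n_holo))
  expect_true(all(iqr_a > iqr_h))
})

test_that("the KDE is a proper density with the right peak", {
  x <- withr::with_seed(13, stats::rnorm(1e5))
  pdf <- estimate_pdf(x)
  # density at 0 close to 1/sqrt(2*pi)
  d0 <- stats::approx(pdf$grid, pdf$density, xout = 0)$y
  expect_equal(d0, 0.3989423, tolerance = 0.05)
  # trapezoid integral is 1 (enforced)
  dx <- diff(pdf$grid[1:2])
  integral <- sum((pdf$density[-1] + pdf$density[-nrow(pdf)]) / 2) * dx
  expect_equal(integral, 1, tolerance = 1e-6)
  expect_error(estimate_pdf(rep(1, 2000)), class = "ferrotrace_estimation_error")
  expect_error(estimate_pdf(stats::rnorm(10)), class = "ferrotrace_invalid_parameter")
})

test_that("the KDE mode is the divisor used by mode normalization", {
  x <- withr::with_seed(14, c(stats::rnorm(3e4, 1, 0.02),
                              stats::rnorm(1e4, 1.08, 0.01)))
  tr <- new_trace(x, 1000)
  expect_equal(attr(mode_normalize(tr), "mode_value"),
               attr(estimate_pdf(x), "mode"))
})

test_that("quartiles follow the linear-interpolation rule", {
  q <- quartile_summary(1:100)
  expect_equal(unlist(q), c(q1 = 25.75, q2 = 50.5, q3 = 75.25))
  qc <- quartile_summary(rep(7, 10))
  expect_true(qc$q1 == 7 && qc$q2 == 7 && qc$q3 == 7)
  # equivariance under positive rescaling
  x <- withr::with_seed(15, stats::rexp(500))
  expect_equal(unlist(quartile_summary(2.5 * x)),
               2.5 * unlist(quartile_summary(x)))
  expect_error(quartile_summary(1:3), class = "ferrotrace_invalid_parameter")
})

test_that("PSD band fraction isolates in-band power", {
  fs <- 2000; n <- 8 * fs
  # noise generated inside [3, 150] Hz: nearly all power in band
  z <- band_limited_noise(3, 150, fs, n, seed = 16)
  expect_gt(psd_band_fraction(z, 3, 150, fs = fs), 0.9)
  # white noise: fraction equals the bandwidth ratio within 10%
  w <- withr::with_seed(17, stats::rnorm(n))
  expected <- (150 - 3) / (fs / 2 - 1.5)
  expect_equal(psd_band_fraction(w, 3, 150, fs = fs), expected,
               tolerance = 0.10)
  # pure 60 Hz tone
  tone <- sin(2 * pi * 60 * (0:(n - 1)) / fs)
  expect_gt(psd_band_fraction(tone, 3, 150, fs = fs), 0.99)
  expect_error(psd_band_fraction(w, 3, 1500, fs = fs),
               class = "ferrotrace_invalid_parameter")
  expect_error(psd_band_fraction(w[1:100], 3, 150, fs = fs),
               class = "ferrotrace_invalid_parameter")
})
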