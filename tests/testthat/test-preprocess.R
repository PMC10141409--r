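test_that("Gaussian low-pass has unit DC gain and -3 dB at the cutoff", {
  fs <- 1e4
  # constant trace unchanged
  cst <- new_trace(rep(2.5, 5000), fs)
  expect_equal(gaussian_lowpass(cst, 1000)$value, rep(2.5, 5000),
               tolerance = 1e-12)
  # unit sinusoid at f_c attenuated to 1/sqrt(2) within 1%
  fc <- 500
  t <- (0:(10 * fs) - 1) / fs
  tone <- new_trace(sin(2 * pi * fc * t), fs)
  out <- gaussian_lowpass(tone, fc)$value
  core <- out[seq.int(fs, length(out) - fs)]   # avoid edges
  amp <- sqrt(2) * sqrt(mean(core^2))
  expect_equal(amp, 1 / sqrt(2), tolerance = 0.01)
  # filter history recorded
  expect_match(trace_history(gaussian_lowpass(cst, 1000)), "gaussian_lowpass")
  expect_error(gaussian_lowpass(cst, fs), class = "ferrotrace_invalid_parameter")
})

test_that("white noise is attenuated per the filter's power integral", {
  fs <- 1e4; fc <- 1000
  x <- withr::with_seed(2, stats::rnorm(2e5))
  out <- gaussian_lowpass(new_trace(x, fs), fc)$value
  sigma_f <- fc / sqrt(log(2))
  expected <- sqrt(sigma_f * sqrt(pi) / 2 / (fs / 2))
  expect_equal(stats::sd(out), expected, tolerance = 0.03)
})

test_that("decimation preserves the passband and kills the stopband", {
  fs <- 1e4
  cst <- new_trace(rep(1.3, 10000), fs)
  dec <- decimate_trace(cst, 5)
  expect_equal(dec$value, rep(1.3, 2000), tolerance = 1e-6)
  expect_equal(trace_fs(dec), 2000)
  expect_equal(nrow(dec), ceiling(10000 / 5))

  t <- (0:(4 * fs - 1)) / fs
  # tone well below the new Nyquist (1 kHz): amplitude within 2%
  tone <- new_trace(sin(2 * pi * 250 * t), fs)
  y <- decimate_trace(tone, 5)$value
  core <- y[seq.int(200, length(y) - 200)]
  expect_equal(sqrt(2 * mean(core^2)), 1, tolerance = 0.02)
  # tone above the new Nyquist: attenuated by >= 40 dB
  tone_hi <- new_trace(sin(2 * pi * 1600 * t), fs)
  y_hi <- decimate_trace(tone_hi, 5)$value
  expect_lt(sqrt(2 * mean(y_hi^2)), 0.01)

  # large factors are handled in stages
  big <- decimate_trace(tone, 50)
  expect_equal(trace_fs(big), 200)
  expect_equal(nrow(big), ceiling(length(t) / 50))
  expect_error(decimate_trace(cst, 1), class = "ferrotrace_invalid_parameter")
})

test_that("filtering and decimation are linear operators", {
  fs <- 5000
  x <- withr::with_seed(3, stats::rnorm(20000))
  y <- withr::with_seed(4, stats::rnorm(20000))
  a <- 2.7; b <- -1.3
  f <- function(v) gaussian_lowpass(new_trace(v, fs), 400)$value
  expect_equal(f(a * x + b * y), a * f(x) + b * f(y), tolerance = 1e-10)
  d <- function(v) decimate_trace(new_trace(v, fs), 4)$value
  expect_equal(d(a * x + b * y), a * d(x) + b * d(y), tolerance = 1e-8)
})

test_that("mode normalization divides by the density peak", {
  # constant trace: all ones with a warning
  cst <- new_trace(rep(3.2, 2000), 1000)
  expect_warning(out <- mode_normalize(cst))
  expect_true(all(out$value == 1))

  # unimodal Gaussian: mode near the mean
  x <- withr::with_seed(5, stats::rnorm(5e4, mean = 2, sd = 0.01))
  tr <- new_trace(x, 1000)
  norm <- mode_normalize(tr)
  expect_gt(attr(norm, "mode_value"), 1.99)
  expect_lt(attr(norm, "mode_value"), 2.01)
  # normalized mode is at 1
  pdf_after <- estimate_pdf(norm$value)
  expect_equal(attr(pdf_after, "mode"), 1, tolerance = 0.005)

  # bimodal: divides by the taller component, not the mean
  xb <- withr::with_seed(6, c(stats::rnorm(7e4, 1.1, 0.01),
                              stats::rnorm(3e4, 1.0, 0.01)))
  nb <- mode_normalize(new_trace(xb, 1000))
  expect_equal(attr(nb, "mode_value"), 1.1, tolerance = 0.01)
  # brute-force grid density check of the divisor
  grid <- seq(min(xb), max(xb), length.out = 2000)
  h <- stats::bw.nrd0(xb)
  dens <- vapply(grid, function(g) mean(stats::dnorm((g - xb) / h)) / h,
                 numeric(1))
  expect_equal(attr(nb, "mode_value"), grid[which.max(dens)], tolerance = 0.005)

  # scale equivariance: normalizing c*x equals normalizing x
  sc <- mode_normalize(new_trace(3.7 * x, 1000))
  expect_equal(sc$value, norm$value, tolerance = 1e-9)
})
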