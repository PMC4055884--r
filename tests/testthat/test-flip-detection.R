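test_that("bandpass matches the frequency-response oracle", {
  fs <- 100
  t <- seq(0, 60, by = 1 / fs)
  gain_at <- function(f) {
    x <- biosensor_trace(sin(2 * pi * f * t), fs)
    y <- bandpass(x)
    sd(y$samples[1000:5000]) / sd(x$samples[1000:5000])
  }
  expect_lt(abs(gain_at(10) - 1), 0.05)       # passband preserved
  expect_lt(gain_at(48), 0.1)                 # 48 Hz reduced >= 10x
  dc <- biosensor_trace(rep(7, 6000), fs)
  expect_lt(max(abs(bandpass(dc)$samples)), 1e-6 * 7)
  expect_error(bandpass(dc, c(0.2, 60)), class = "tailflip_parameter_error")
})

test_that("agc is invariant to constant and slow multiplicative gain", {
  set.seed(42)
  fs <- 100
  x <- rnorm(fs * 120)
  tr <- biosensor_trace(x, fs)
  a1 <- agc(tr)
  a10 <- agc(biosensor_trace(10 * x, fs))
  expect_equal(a1$samples, a10$samples, tolerance = 1e-12)
  ## slow ramp (period >> window): output ~ AGC of unscaled trace
  ramp <- exp(0.5 * sin(2 * pi * seq_along(x) / (fs * 600)))
  a_ramp <- agc(biosensor_trace(x * ramp, fs))
  mid <- seq(fs * 10, length(x) - fs * 10)
  expect_lt(median(abs(a_ramp$samples[mid] - a1$samples[mid])) /
              median(abs(a1$samples[mid])), 0.05)
  zero <- agc(biosensor_trace(numeric(fs * 60), fs))
  expect_true(all(zero$samples == 0))
})

test_that("noise-free renders are detected exactly and on time", {
  mm0 <- measurement_model(noise_sd = 0, gain_drift_amplitude = 0,
                           artifact_rate = 0)
  truth <- c(10, 10.4, 10.8, 30, 30.3, 30.7, 45.2, 45.5)
  tr <- flip_train(truth, 1)
  det <- detect_flips(render_trace(tr, mm0, seed = 1))
  expect_identical(length(det$times_s), length(truth))
  expect_true(all(abs(det$times_s - truth) <= 0.02))
  ## strong isolated events (single-flip bouts) survive the context rule
  lone <- flip_train(c(10, 25, 40), 1)
  det_lone <- detect_flips(render_trace(lone, mm0, seed = 1))
  expect_identical(length(det_lone$times_s), 3L)
})

test_that("detection count is invariant to trace rescaling", {
  p <- behavior_profile()
  tr <- simulate_flip_train(p, 5, seed = 8, fish_pars = unit_fish())
  x <- render_trace(tr, measurement_model(), seed = 9)
  n0 <- length(detect_flips(x)$times_s)
  x5 <- x; x5$samples <- 5 * x$samples
  expect_identical(length(detect_flips(x5)$times_s), n0)
})

test_that("a burst of 10 flips at 5/s is recovered within one event", {
  mm <- measurement_model(artifact_rate = 0)
  truth <- 20 + 0.2 * (0:9)
  counts <- vapply(1:10, function(s)
    length(detect_flips(render_trace(flip_train(truth, 1), mm, seed = s))$times_s),
    numeric(1))
  expect_true(all(abs(counts - 10) <= 1))
})

test_that("short traces are rejected and counts conserve events", {
  expect_error(detect_flips(biosensor_trace(rnorm(100), 100)),
               class = "tailflip_input_error")
  expect_identical(counts_per_minute(flip_train(numeric(0), 10))$values,
                   rep(0, 10))
  tr <- flip_train(120 + c(1, 5, 10, 20, 30, 40, 50), 5)  # minute 3 of 5
  expect_identical(counts_per_minute(tr, 5)$values, c(0, 0, 7, 0, 0))
  rnd <- simulate_flip_train(behavior_profile(), 7, seed = 2)
  expect_identical(sum(counts_per_minute(rnd)$values),
                   as.numeric(length(rnd$times_s)))
  expect_error(counts_per_minute(flip_train(c(100), 5), span_min = 1),
               class = "tailflip_input_error")
})
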