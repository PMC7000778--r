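test_that("low-pass filter has unit DC gain and the analytic stopband/cutoff response", {
  rate <- 1000
  expect_equal(butterworth_lowpass(rep(3.7, 500), rate, 30),
               rep(3.7, 500), tolerance = 1e-9)
  t <- (0:4999) / rate
  mid <- 1500:3500                      # avoid filtfilt edge transients
  # 200 Hz sine: two-pass 2nd-order magnitude 1/(1 + (f/fc)^4) < 0.01
  y <- butterworth_lowpass(sin(2 * pi * 200 * t), rate, 30)
  expect_lt(max(abs(y[mid])), 0.01)
  # sine at the cutoff: amplitude 1/2 (each pass -3 dB)
  yc <- butterworth_lowpass(sin(2 * pi * 30 * t), rate, 30)
  expect_equal(max(abs(yc[mid])), 0.5, tolerance = 0.02)
})

test_that("filtering is idempotent in the passband limit", {
  rate <- 1000
  t <- (0:9999) / rate
  x <- sin(2 * pi * 0.5 * t)
  twice <- butterworth_lowpass(butterworth_lowpass(x, rate, 30), rate, 30)
  thrice <- butterworth_lowpass(twice, rate, 30)
  mid <- 2000:8000
  expect_lt(max(abs(thrice[mid] - twice[mid])) / max(abs(twice[mid])),
            1e-6)
})

test_that("filter rejects bad parameters and data", {
  expect_error(butterworth_lowpass(rnorm(100), 1000, 500), "cutoff")
  expect_error(butterworth_lowpass(c(rnorm(99), NA), 1000, 30),
               "non-finite")
  expect_error(butterworth_lowpass(rnorm(10), 1000, 30, order = 3),
               "order")
})

test_that("half-sine pulse stance is detected within 2 samples of the analytic crossings", {
  h <- halfsine
  f <- make_grf_pulse(h$peak, h$duration, h$rate, pad = h$pad)
  st <- detect_stances(f, h$rate, threshold = h$threshold)
  expect_equal(nrow(st), 1L)
  cross <- halfsine_crossings()
  expect_lt(abs((st$onset - 1) / h$rate - cross[["on"]]) * h$rate, 2)
  expect_lt(abs((st$offset - 1) / h$rate - cross[["off"]]) * h$rate, 2)
  # supra-threshold mean tends to the half-sine mean 2/pi * peak
  w <- st$onset:(st$offset - 1)
  expect_equal(mean(f[w]), 2 / pi * h$peak, tolerance = 0.02)
})

test_that("a short mid-stance dip is merged, and all-zero traces give no stance", {
  h <- halfsine
  f <- make_grf_pulse(h$peak, h$duration, h$rate, pad = h$pad)
  st0 <- detect_stances(f, h$rate)
  dip <- f
  mid <- round(h$pad * h$rate) + round(h$duration * h$rate / 2)
  dip[mid:(mid + 4)] <- 10              # 5 ms dip below threshold
  st1 <- detect_stances(dip, h$rate)
  expect_equal(nrow(st1), 1L)
  expect_equal(st1$onset, st0$onset)
  expect_equal(st1$offset, st0$offset)
  expect_equal(nrow(detect_stances(numeric(2000), h$rate)), 0L)
})

test_that("detection is invariant to sub-threshold aerial noise", {
  h <- halfsine
  f <- make_grf_pulse(h$peak, h$duration, h$rate, pad = h$pad)
  st0 <- detect_stances(f, h$rate)
  set.seed(11)
  noisy <- f
  aerial <- f < h$threshold
  noisy[aerial] <- noisy[aerial] + runif(sum(aerial), -h$threshold / 3,
                                         h$threshold / 3)
  st1 <- detect_stances(noisy, h$rate)
  expect_identical(st1$onset, st0$onset)
  expect_identical(st1$offset, st0$offset)
})

test_that("stance and aerial samples partition the trace between first onset and last offset", {
  fx <- default_session_noisy()
  st <- fx$fit$stances
  span <- max(st$offset) - min(st$onset)
  stance_n <- sum(st$offset - st$onset)
  aerial_n <- sum(st$onset[-1] - st$offset[-nrow(st)])
  expect_identical(stance_n + aerial_n, span)
})

test_that("leg labels alternate from the configured first leg and match simulator truth", {
  st <- data.frame(onset = c(1, 100, 200, 300), offset = c(50, 150, 250, 350),
                   leg = "unassigned")
  expect_equal(assign_legs(st, "AL")$leg, c("AL", "UL", "AL", "UL"))
  expect_equal(assign_legs(st, "UL")$leg, c("UL", "AL", "UL", "AL"))
  expect_equal(nrow(assign_legs(empty <- st[0, ], "AL")), 0L)
  fx <- default_session_noiseless()
  n <- nrow(fx$fit$stances)
  expect_equal(fx$fit$stances$leg, fx$ses$truth$leg[seq_len(n)])
})

test_that("belt speed is recovered from markers", {
  rate <- 200
  t <- (0:199) / rate
  expect_equal(belt_speed_from_marker(1 - 3 * t, rate, 0.2, 0.8), 3.0)
  expect_equal(belt_speed_from_marker(rep(0.5, 200), rate, 0.2, 0.8), 0.0)
  expect_error(belt_speed_from_marker(1 - 3 * t, rate, 0.2, 0.205),
               "insufficient-data")
  # simulated session with 1 mm marker noise: within 2% of the belt speed
  p <- slip_params(n_strides = 8, noise_sigma_force = 0,
                   noise_sigma_marker = 0.001, seed = 3)
  ses <- generate_session(p)
  fit <- analyze_session(ses)
  expect_lt(abs(fit$qc$belt_speed_mean - ses$config$belt_velocity) /
              ses$config$belt_velocity, 0.02)
})
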