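test_that("step metrics follow their definitions on a constructed trace", {
  rate <- 1000; m <- 70; g <- 9.81
  f_v <- numeric(500)
  f_v[101:200] <- 2 * m * g               # stance 1: exactly 100 samples
  f_v[301:400] <- 1.5 * m * g             # stance 2
  st <- assign_legs(detect_stances(f_v, rate), "AL")
  rec <- step_metrics(st, f_v, rate = rate, v = 8, body_mass = m)
  expect_equal(nrow(rec), 1L)             # last stance has no aerial time
  expect_equal(rec$t_c, 0.100)
  expect_equal(rec$L_c, 0.800)
  expect_equal(rec$t_a, 0.100)
  expect_equal(rec$t_step, 0.200)
  expect_equal(rec$f_step, 5)
  expect_equal(rec$F_avg_bw, 2.0)
  expect_equal(rec$F_peak_v, 2 * m * g)
})

test_that("step time and frequency are reciprocal and stride times close", {
  fx <- default_session_noisy()
  rec <- fx$fit$records
  expect_equal(rec$f_step * rec$t_step, rep(1, nrow(rec)))
  # t_step(AL) + t_step(UL) equals same-leg onset-to-onset stride time
  st <- fx$fit$stances
  rate <- fx$ses$config$force_rate
  for (i in seq_len(nrow(rec) - 1)) {
    stride <- (st$onset[i + 2] - st$onset[i]) / rate
    expect_lt(abs(rec$t_step[i] + rec$t_step[i + 1] - stride), 1 / rate)
  }
})

test_that("impulse-momentum holds over strides of steady simulated running", {
  fx <- default_session_noiseless()
  rec <- fx$fit$records
  cfg <- fx$ses$config
  g <- 9.81
  # mean over a stride of per-step vertical impulse equals m*g*stride time
  for (i in seq_len(nrow(rec) - 1)) {
    imp <- rec$F_avg[i] * rec$t_c[i] + rec$F_avg[i + 1] * rec$t_c[i + 1]
    expect_equal(imp, cfg$body_mass * g * (rec$t_step[i] + rec$t_step[i + 1]),
                 tolerance = 0.01)
  }
  # equivalently: stance-average vGRF in BW times duty factor is 1
  s <- fx$fit$summary$both
  expect_equal(s[["F_avg_bw"]] * s[["t_c"]] / s[["t_step"]], 1,
               tolerance = 0.02)
})

test_that("trial summary averages per leg and across legs", {
  rec <- data.frame(leg = c("AL", "AL", "UL"),
                    onset = c(1, 200, 100), offset = c(50, 250, 150),
                    f_step = c(1.9, 2.1, 2.2), t_c = c(0.11, 0.13, 0.10))
  s <- summarize_trial(rec)
  expect_equal(s$per_leg$f_step, c(2.0, 2.2))
  expect_equal(s$both[["f_step"]], 2.1)
  expect_equal(s$stride_count, 1L)
  expect_error(summarize_trial(rec[rec$leg == "AL", ]), "missing-leg")
})

test_that("per-leg trial means match simulator ground truth within 2%", {
  fx <- default_session_noiseless()
  tr <- fx$ses$truth
  pl <- fx$fit$summary$per_leg
  for (leg in c("AL", "UL")) {
    # truth rows that correspond to complete steps in the pipeline
    tt <- tr[tr$leg == leg & tr$stance < max(tr$stance), ]
    est <- pl[pl$leg == leg, ]
    expect_equal(est$t_step, mean(tt$t_c + tt$t_a), tolerance = 0.02)
    expect_equal(est$F_peak_v, mean(tt$peak_vgrf), tolerance = 0.02)
  }
})

test_that("vmax-trial validity needs 8 strides and station keeping", {
  rec <- data.frame(leg = rep(c("AL", "UL"), 8),
                    onset = seq(1, by = 200, length.out = 16),
                    offset = seq(101, by = 200, length.out = 16))
  ok <- vmax_trial_valid(rec, touchdown_pos = rep(0.1, 16))
  expect_true(ok$valid)
  expect_equal(ok$stride_count, 8L)
  # 7 strides is invalid regardless of drift
  rec7 <- rec[1:14, ]
  expect_false(vmax_trial_valid(rec7, touchdown_pos = rep(0, 14))$valid)
  # monotone 0.5 m drift exceeds the 0.3 m default limit
  drift <- vmax_trial_valid(rec, touchdown_pos = seq(0, 0.5, length.out = 16))
  expect_false(drift$valid)
  expect_equal(drift$drift_m, 0.5)
  # marker-free fallback runs with a notice
  f_ap <- rnorm(3500, 0, 1)
  expect_message(
    out <- vmax_trial_valid(rec, f_ap = f_ap, rate = 1000, body_mass = 75),
    "fallback")
  expect_equal(out$method, "impulse")
})
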