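test_that("contact angle follows the half-chord geometry", {
  expect_equal(contact_angle(0, 0.1, 1), 0)
  expect_equal(contact_angle(8, 0.1, 1.0), asin(0.4))
  expect_equal(contact_angle(8, 0.25, 1.0), pi / 2)   # boundary accepted
  expect_error(contact_angle(8, 0.3, 1.0), "geometry")
})

test_that("CoM displacement matches the cosine closed form and the flat case", {
  m <- 75; g <- 9.81; rate <- 1000; T <- 0.4
  n <- T * rate
  # constant body weight: no excursion
  expect_equal(com_vertical_displacement(rep(m * g, n), m, rate), 0)
  # f_v = m*g*(1 - cos(2*pi*t/T)) over one stride:
  # a = -g*cos, v = -(g*T/2/pi)*sin (zero mean), y = (g*(T/2/pi)^2)*cos,
  # so touchdown-to-minimum is 2*g*(T/(2*pi))^2
  t <- (0:(n - 1)) / rate
  f_v <- m * g * (1 - cos(2 * pi * t / T))
  dy <- com_vertical_displacement(f_v, m, rate)
  expect_equal(dy, 2 * g * (T / (2 * pi))^2, tolerance = 1e-3)
})

test_that("non-steady strides are rejected", {
  m <- 75; g <- 9.81
  expect_error(com_vertical_displacement(rep(1.3 * m * g, 400), m, 1000),
               "non-steady")
})

test_that("leg compression and stiffness follow the spring-mass formulas", {
  expect_equal(leg_compression(0.05, 1.0, 0), 0.05)
  expect_equal(leg_compression(0, 1.0, pi / 3), 0.5)
  expect_equal(leg_compression(0.04, 1.0, 0.4115), 0.04 + 1 - cos(0.4115))
  expect_equal(leg_stiffness(2000, 0.05), 40)
  expect_equal(leg_stiffness(4000, 0.05), 80)      # linear in peak force
  expect_error(leg_stiffness(2000, 0), "degenerate-compression")
  expect_equal(rsp_displacement(1600, 16), 0.1)
  expect_equal(rsp_displacement(1600, 8), 0.2)     # inverse in k_RSP
  expect_error(rsp_displacement(0, 16), "peak_resultant_grf")
})

test_that("double-integrated delta_y matches the simulator trajectory on true windows", {
  fx <- default_session_noiseless()
  tr <- fx$ses$truth
  cfg <- fx$ses$config
  rate <- cfg$force_rate
  errs <- vapply(seq_len(nrow(tr) - 2), function(i) {
    on <- round(tr$t_td[i] * rate) + 1
    nxt <- round(tr$t_td[i + 2] * rate) + 1
    off <- round((tr$t_td[i] + tr$t_c[i]) * rate) + 1
    dy <- com_vertical_displacement(fx$ses$forces$f_v[on:(nxt - 1)],
                                    cfg$body_mass, rate,
                                    stance = c(1L, off - on))
    abs(dy - tr$delta_y[i]) / tr$delta_y[i]
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("each leg uses its own length in the estimation chain", {
  fx <- default_session_noiseless()
  cfg <- fx$ses$config
  rec <- fx$fit$records
  ok <- !is.na(rec$theta)
  # recompute theta per record with the leg-tagged L0 and compare
  L0 <- ifelse(rec$leg == "AL", cfg$L0_AL, cfg$L0_UL)
  expect_equal(rec$theta[ok],
               asin(cfg$belt_velocity * rec$t_c[ok] / (2 * L0[ok])))
  # swapping lengths changes theta for every stance (lengths differ)
  L0sw <- ifelse(rec$leg == "AL", cfg$L0_UL, cfg$L0_AL)
  expect_true(all(rec$theta[ok] !=
                    asin(cfg$belt_velocity * rec$t_c[ok] / (2 * L0sw[ok]))))
  # delta_rsp exists only for affected-leg stances
  expect_true(all(is.na(rec$delta_rsp[rec$leg == "UL"])))
  expect_true(all(!is.na(rec$delta_rsp[rec$leg == "AL" & ok])))
})

test_that("estimated leg stiffness is strictly increasing in true stiffness", {
  ks <- c(12, 15, 18)
  est <- vapply(ks, function(k) {
    ses <- symmetric_session(k, n_strides = 4)
    analyze_session(ses)$summary$both[["k_leg"]]
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})
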