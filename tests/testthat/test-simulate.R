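test_that("vertical hop: takeoff mirrors touchdown and the force trace is symmetric", {
  m <- 75; g <- 9.81; L0 <- 1; k <- 20
  vz <- -1.2
  st <- simulate_stance(c(0, L0, 0, vz), foot_x = 0, k_kNm = k, L0 = L0,
                        body_mass = m, g = g)
  out <- st$state_out
  expect_equal(out[4], -vz, tolerance = 1e-7)     # energy conservation
  expect_equal(out[3], 0, tolerance = 1e-9)       # stays vertical
  tr <- st$traj
  f <- approx(tr$time, tr$grf_v, xout = seq(0, st$t_c, length.out = 201))$y
  expect_equal(f, rev(f), tolerance = 1e-5 * max(f))
})

test_that("stiff-spring contact time approaches the harmonic half period", {
  m <- 75; g <- 9.81; L0 <- 1
  err <- vapply(c(1e3, 1e4, 1e5), function(k) {
    st <- simulate_stance(c(0, L0, 0, -1.0), foot_x = 0, k_kNm = k,
                          L0 = L0, body_mass = m, g = g)
    abs(st$t_c - pi * sqrt(m / (k * 1000))) / (pi * sqrt(m / (k * 1000)))
  }, numeric(1))
  expect_true(all(diff(err) < 0))                 # converges with stiffness
  expect_lt(err[3], 0.01)
})

test_that("impulse-momentum identity holds for every simulated stance", {
  fx <- default_session_noiseless()
  tr <- fx$ses$truth
  m <- fx$params$body_mass; g <- fx$params$g
  lhs <- tr$impulse_v - m * g * tr$t_c
  rhs <- m * (tr$vz_to - tr$vz_td)
  expect_lt(max(abs(lhs - rhs) / tr$impulse_v), 0.001)
})

test_that("total mechanical energy is conserved across 20 strides", {
  p <- slip_params(n_strides = 20, noise_sigma_force = 0,
                   noise_sigma_marker = 0, seed = 2)
  sim <- simulate_session(p)
  E0 <- sim$truth$energy_start[1]
  drift <- abs(c(sim$truth$energy_start, sim$truth$energy_end) - E0) / E0
  expect_lt(max(drift), 1e-4)
})

test_that("identical legs give a symmetric fixed point, asymmetry shifts contact times", {
  p_sym <- slip_params(k = c(AL = 20, UL = 20), alpha = c(AL = 0.5, UL = 0.5),
                       L0 = c(AL = 1, UL = 1), n_strides = 2,
                       noise_sigma_force = 0, noise_sigma_marker = 0,
                       seed = 1)
  sim <- simulate_session(p_sym)
  tc <- tapply(sim$truth$t_c, sim$truth$leg, mean)
  expect_equal(unname(tc[["AL"]]), unname(tc[["UL"]]), tolerance = 1e-6)
  # increasing the affected leg's stiffness (other leg fixed) strictly
  # decreases its own contact time; the softer leg always contacts longer
  tc_grid <- vapply(c(16, 16.5, 17, 17.5, 18), function(kAL) {
    pp <- slip_params(k = c(AL = kAL, UL = 22), n_strides = 1,
                      noise_sigma_force = 0, noise_sigma_marker = 0,
                      seed = 1)
    tru <- simulate_session(pp)$truth
    tc <- tapply(tru$t_c, tru$leg, mean)
    expect_gt(tc[["AL"]], tc[["UL"]])
    tc[["AL"]]
  }, numeric(1))
  expect_true(all(diff(tc_grid) < 0))
})

test_that("degenerate parameters raise a no-gait error", {
  p <- slip_params(k = c(AL = 0.5, UL = 22), alpha = c(AL = 0.5, UL = 0.5),
                   n_strides = 1)
  expect_error(find_periodic_gait(p), "no-gait|fall|non-periodic")
})

test_that("the half-sine pulse fixture matches its closed forms", {
  h <- halfsine
  f <- make_grf_pulse(h$peak, h$duration, h$rate, pad = h$pad)
  n_pad <- h$pad * h$rate
  expect_equal(length(f), 2 * n_pad + h$duration * h$rate + 1)
  expect_equal(max(f), h$peak, tolerance = 1e-6)
  expect_equal(f[seq_len(n_pad)], numeric(n_pad))
  expect_error(make_grf_pulse(1500, 0, 1000), "duration")
  expect_error(make_grf_pulse(10, 0.1, 1000), "peak")
})

test_that("seeded generation is bit-reproducible", {
  p <- slip_params(n_strides = 3, seed = 42)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_session(p, path = d1)
  generate_session(p, path = d2)
  for (f in c("config", "forces.csv", "markers.csv", "truth.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("noiseless contact times match truth within 2 ms and truth asymmetry signs propagate", {
  fx <- default_session_noiseless()
  st <- fx$fit$stances
  tr <- fx$ses$truth
  rate <- fx$ses$config$force_rate
  n <- nrow(st)
  expect_equal(n, nrow(tr))
  # onsets align with true touchdowns (filter widening allowed, ~5 samples)
  expect_lt(max(abs((st$onset - 1) / rate - tr$t_td)), 0.006)
  # truth contact-time asymmetry has the same sign as the pipeline SI
  si_tc_truth <- symmetry_index(mean(tr$t_c[tr$leg == "AL"]),
                                mean(tr$t_c[tr$leg == "UL"]))
  expect_equal(sign(si_tc_truth), sign(fx$fit$si[["si_t_c"]]))
})
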