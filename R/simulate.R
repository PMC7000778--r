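#' Parameters for the two-leg spring-mass running simulator
#'
#' The simulator models steady treadmill running as a spring-loaded
#' inverted pendulum (SLIP): a point mass on a massless linear leg
#' spring, with stance governed by the spring and gravity and flight
#' ballistic. The two legs may differ in stiffness, natural length and
#' touchdown angle, which produces asymmetric gaits with known ground
#' truth. The system is conservative (no hysteresis), so total
#' mechanical energy is an integration-quality diagnostic.
#'
#' Defaults describe a sprint-like trial for an athlete with a
#' unilateral transtibial amputation: 75 kg at about 8 m/s, the
#' affected leg (AL) 2 cm longer than the unaffected leg (standard
#' prosthesis-height practice), about 18% softer, and touching down at
#' a slightly steeper angle. At the resulting periodic gait the AL
#' stance-average vertical force is about 6% below the UL, the AL
#' contact time about 9% longer and the AL stiffness 20% lower —
#' asymmetry directions and magnitudes typical of treadmill sprinting
#' with a running-specific prosthesis.
#'
#' @param body_mass kg.
#' @param v target forward velocity at apex, m/s (the realised stride
#'   average is reported in the session config).
#' @param L0 named numeric, natural leg lengths in m for \code{AL}
#'   and \code{UL}.
#' @param k named numeric, leg stiffnesses in kN/m.
#' @param alpha named numeric, touchdown angles from vertical in rad.
#' @param g gravitational acceleration, m/s^2.
#' @param force_rate,marker_rate output sampling rates, Hz.
#' @param noise_sigma_force additive Gaussian noise SD on every force
#'   channel, N (the medio-lateral channel is pure noise).
#' @param noise_sigma_marker additive Gaussian noise SD on marker
#'   positions, m.
#' @param n_strides number of complete strides to generate.
#' @param first_contact_leg leg of the first recorded touchdown.
#' @param seed master seed for all noise streams.
#' @return Object of class \code{"slip_params"}.
#' @export
slip_params <- function(body_mass = 75, v = 8,
                        L0 = c(AL = 1.02, UL = 1.00),
                        k = c(AL = 18, UL = 22),
                        alpha = c(AL = 0.54, UL = 0.52),
                        g = 9.81, force_rate = 1000, marker_rate = 200,
                        noise_sigma_force = 5, noise_sigma_marker = 0.001,
                        n_strides = 10, first_contact_leg = "AL",
                        seed = 1L) {
  p <- list(body_mass = body_mass, v = v,
            L0 = L0[c("AL", "UL")], k = k[c("AL", "UL")],
            alpha = alpha[c("AL", "UL")], g = g,
            force_rate = force_rate, marker_rate = marker_rate,
            noise_sigma_force = noise_sigma_force,
            noise_sigma_marker = noise_sigma_marker,
            n_strides = as.integer(n_strides),
            first_contact_leg = first_contact_leg, seed = as.integer(seed))
  stopifnot(body_mass > 0, v > 0, all(p$L0 > 0), all(p$k > 0),
            all(p$alpha >= 0 & p$alpha < pi / 2), g > 0,
            force_rate > 0, marker_rate > 0, p$n_strides >= 1,
            first_contact_leg %in% c("AL", "UL"))
  class(p) <- "slip_params"
  p
}

slip_energy <- function(m, g, k_Nm, L0, x, z, vx, vz, foot_x = NA) {
  spring <- if (is.na(foot_x)) 0 else {
    L <- sqrt((x - foot_x)^2 + z^2)
    0.5 * k_Nm * (L0 - L)^2
  }
  0.5 * m * (vx^2 + vz^2) + m * g * z + spring
}

#' Integrate one SLIP stance phase
#'
#' From a touchdown state, integrates the planar stance dynamics
#' \deqn{m \ddot x = F_s (x - x_f)/L, \quad m \ddot z = F_s z/L - m g,
#' \quad F_s = k (L_0 - L)}
#' with the foot fixed at \code{foot_x}, until the leg returns to its
#' natural length (takeoff, located by the integrator's root finder).
#' Integration uses \code{deSolve::lsodar} at tight tolerances; the
#' trajectory is reported on a fine time grid (0.1 ms) plus any
#' requested extra times, so ground reaction forces can be sampled
#' exactly on the force-plate grid.
#'
#' @param state numeric \code{c(x, z, vx, vz)} at touchdown; the CoM
#'   height must equal \code{L0 * cos(alpha)} for a consistent geometry.
#' @param foot_x fore-aft foot position, m.
#' @param k_kNm leg stiffness in kN/m.
#' @param L0 natural leg length, m.
#' @param body_mass kg.
#' @param g m/s^2.
#' @param extra_times additional output times (s, relative to
#'   touchdown).
#' @param t_max give up if no takeoff occurs within this horizon, s.
#' @return List with \code{traj} (data frame: time, x, z, vx, vz, L,
#'   grf_v, grf_ap, energy), \code{t_c} (contact time, s) and
#'   \code{state_out} (state at takeoff).
#' @export
simulate_stance <- function(state, foot_x, k_kNm, L0, body_mass, g = 9.81,
                            extra_times = NULL, t_max = 2) {
  k_Nm <- k_kNm * 1000
  m <- body_mass
  t_guard <- 0.25 * pi * sqrt(m / k_Nm)
  deriv <- function(t, y, parms) {
    L <- sqrt((y[1] - foot_x)^2 + y[2]^2)
    Fs <- k_Nm * (L0 - L)
    list(c(y[3], y[4],
           Fs * (y[1] - foot_x) / (L * m),
           Fs * y[2] / (L * m) - g))
  }
  root <- function(t, y, parms) {
    L <- sqrt((y[1] - foot_x)^2 + y[2]^2)
    c(if (t < t_guard) -1 else L - L0, y[2])
  }
  times <- sort(unique(c(seq(0, t_max, by = 1e-4), extra_times)))
  times <- times[times >= 0 & times <= t_max]
  sol <- deSolve::lsodar(y = state, times = times, func = deriv,
                         parms = NULL, rootfunc = root,
                         rtol = 1e-11, atol = 1e-11)
  tc <- attr(sol, "troot")
  if (is.null(tc) || length(tc) == 0)
    stop("non-periodic error: no takeoff within ", t_max, " s",
         call. = FALSE)
  last <- sol[nrow(sol), ]
  if (last[3] <= 1e-9)
    stop("fall error: CoM reached the ground during stance", call. = FALSE)
  tr <- as.data.frame(unclass(sol))
  names(tr) <- c("time", "x", "z", "vx", "vz")
  L <- sqrt((tr$x - foot_x)^2 + tr$z^2)
  Fs <- pmax(0, k_Nm * (L0 - L))
  tr$L <- L
  tr$grf_v <- Fs * tr$z / L
  tr$grf_ap <- Fs * (tr$x - foot_x) / L
  tr$energy <- slip_energy(m, g, k_Nm, L0, tr$x, tr$z, tr$vx, tr$vz,
                           foot_x)
  list(traj = tr, t_c = tc[length(tc)],
       state_out = unname(last[2:5]))
}

# ballistic flight from takeoff to the height of the next touchdown;
# closed form, no integration error
simulate_flight <- function(state, z_target, g = 9.81) {
  z0 <- state[2]; vz <- state[4]
  apex <- if (vz > 0) z0 + vz^2 / (2 * g) else z0
  if (apex < z_target - 1e-12)
    stop("no-gait error: flight apex ", signif(apex, 6),
         " m below the next touchdown height ", signif(z_target, 6), " m",
         call. = FALSE)
  disc <- max(0, vz^2 + 2 * g * (z0 - z_target))
  t_f <- (vz + sqrt(disc)) / g
  list(t_a = t_f, apex = apex,
       state_out = c(state[1] + state[3] * t_f, z_target, state[3],
                     vz - g * t_f))
}

# one full step: stance of `leg` from its touchdown state, then flight
# to the touchdown height of `next_leg`
slip_step <- function(state, leg, next_leg, p, extra_times = NULL) {
  z_td_next <- p$L0[[next_leg]] * cos(p$alpha[[next_leg]])
  foot_x <- state[1] + p$L0[[leg]] * sin(p$alpha[[leg]])
  st <- simulate_stance(state, foot_x, p$k[[leg]], p$L0[[leg]],
                        p$body_mass, p$g, extra_times = extra_times)
  fl <- simulate_flight(st$state_out, z_td_next, p$g)
  list(stance = st, flight = fl, foot_x = foot_x,
       state_out = fl$state_out)
}

# apex -> (descend, AL-step, UL-step) -> apex map at fixed total energy.
# Apex state is parameterised by height alone; forward velocity follows
# from the energy. Returns NULL when the candidate fails to run.
two_step_map <- function(y_apex, E, p, legs = c("AL", "UL")) {
  m <- p$body_mass; g <- p$g
  vx2 <- 2 * (E / m - g * y_apex)
  if (vx2 <= 0) return(NULL)
  state <- c(0, y_apex, sqrt(vx2), 0)
  z_td1 <- p$L0[[legs[1]]] * cos(p$alpha[[legs[1]]])
  if (y_apex <= z_td1) return(NULL)
  fl0 <- tryCatch(simulate_flight(state, z_td1, g), error = function(e) NULL)
  if (is.null(fl0)) return(NULL)
  state <- fl0$state_out
  out <- tryCatch({
    s1 <- slip_step(state, legs[1], legs[2], p)
    s2 <- slip_step(s1$state_out, legs[2], legs[1], p)
    s2
  }, error = function(e) NULL)
  if (is.null(out)) return(NULL)
  to <- out$stance$state_out                # takeoff of the second stance
  apex <- to[2] + max(0, to[4])^2 / (2 * g)
  list(y_next = apex, vx_next = to[3])
}

#' Find the periodic two-step gait
#'
#' Locates the steady gait of the asymmetric two-leg SLIP as a fixed
#' point of the apex-to-apex return map over one full stride
#' (affected-leg step then unaffected-leg step). Because the model is
#' conservative, total energy is invariant under the map; the apex
#' state is therefore parameterised by apex height alone (forward
#' velocity follows from the energy budget set by the target velocity)
#' and the fixed point is found by 1-D root bracketing and
#' \code{uniroot} on the apex-height residual.
#'
#' @param p a [slip_params()].
#' @param y_range search bracket for apex height above the higher
#'   touchdown height, m.
#' @param n_scan grid size of the bracketing sweep.
#' @return List with \code{y_apex}, \code{vx_apex}, \code{E} (total
#'   energy, J), \code{residual_y} and \code{residual_vx} (map residuals
#'   at the fixed point, both < 1e-6 by construction), and
#'   \code{belt_velocity} (realised stride-average forward velocity,
#'   m/s).
#' @export
find_periodic_gait <- function(p, y_range = c(1e-4, 0.2), n_scan = 41) {
  g <- p$g; m <- p$body_mass
  z_td_max <- max(p$L0 * cos(p$alpha))
  y0 <- z_td_max + 0.03
  E <- m * (g * y0 + 0.5 * p$v^2)
  legs <- if (p$first_contact_leg == "AL") c("AL", "UL") else c("UL", "AL")
  resid <- function(y) {
    r <- two_step_map(y, E, p, legs)
    if (is.null(r)) NA_real_ else r$y_next - y
  }
  ys <- z_td_max + seq(y_range[1], y_range[2], length.out = n_scan)
  rs <- vapply(ys, resid, numeric(1))
  ok <- which(!is.na(rs))
  sgn <- sign(rs[ok])
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(flip)) {
    diag <- paste(sprintf("y=%.4f r=%s", ys[ok],
                          signif(rs[ok], 3)), collapse = "; ")
    stop("no-gait error: no fixed point of the stride return map in the ",
         "bracket; sweep: ", diag, call. = FALSE)
  }
  lo <- ys[ok[flip[1]]]; hi <- ys[ok[flip[1] + 1]]
  sol <- stats::uniroot(resid, lower = lo, upper = hi, tol = 1e-10)
  y_star <- sol$root
  r <- two_step_map(y_star, E, p, legs)
  vx_star <- sqrt(2 * (E / m - g * y_star))
  # realised stride-average forward velocity, from one cycle at the
  # fixed point
  cyc <- cycle_details(y_star, E, p, legs)
  list(y_apex = y_star, vx_apex = vx_star, E = E,
       residual_y = r$y_next - y_star,
       residual_vx = r$vx_next - vx_star,
       belt_velocity = cyc$dx / cyc$dt, legs = legs)
}

# distance and duration of one full stride cycle starting at the apex
cycle_details <- function(y_apex, E, p, legs) {
  m <- p$body_mass; g <- p$g
  state <- c(0, y_apex, sqrt(2 * (E / m - g * y_apex)), 0)
  z_td1 <- p$L0[[legs[1]]] * cos(p$alpha[[legs[1]]])
  fl0 <- simulate_flight(state, z_td1, g)
  t <- fl0$t_a; state <- fl0$state_out
  s1 <- slip_step(state, legs[1], legs[2], p)
  t <- t + s1$stance$t_c + s1$flight$t_a
  s2 <- slip_step(s1$state_out, legs[2], legs[1], p)
  to <- s2$stance$state_out                 # takeoff of the second stance
  t_rise <- max(0, to[4]) / g
  t <- t + s2$stance$t_c + t_rise
  list(dx = to[1] + to[3] * t_rise, dt = t)
}

#' Simulate a steady treadmill session
#'
#' Starting from the periodic gait located by [find_periodic_gait()],
#' integrates \code{2 * n_strides + 2} alternating-leg stances with
#' ballistic flight in between, samples the ground reaction forces on
#' the force-plate grid, and records per-stance ground truth (contact
#' and aerial times, peak and stance-average vertical GRF, maximum
#' spring compression, CoM drop, touchdown/takeoff vertical velocities
#' and total energy). No noise is added here; noise belongs to
#' [generate_session()].
#'
#' @param p a [slip_params()].
#' @return List with \code{truth} (per-stance data frame), \code{grid}
#'   (force time grid, s), \code{grf} (data frame \code{f_v},
#'   \code{f_ap} on the grid, N), \code{foot_x} (per-stance lab-frame
#'   foot positions), \code{belt_velocity}, \code{fixed_point} and
#'   \code{params}.
#' @export
simulate_session <- function(p) {
  fp <- find_periodic_gait(p)
  g <- p$g; m <- p$body_mass
  legs <- fp$legs
  n_stance <- 2L * p$n_strides + 2L
  pad <- 0.1                                 # quiet lead-in/out, s
  rate <- p$force_rate
  # descend from apex to the first touchdown
  state <- c(0, fp$y_apex, fp$vx_apex, 0)
  z_td1 <- p$L0[[legs[1]]] * cos(p$alpha[[legs[1]]])
  fl0 <- simulate_flight(state, z_td1, g)
  state <- fl0$state_out
  t_now <- pad
  truth <- vector("list", n_stance)
  segs <- vector("list", n_stance)
  foot_x <- numeric(n_stance)
  for (i in seq_len(n_stance)) {
    leg <- legs[(i - 1) %% 2 + 1]
    nxt <- legs[i %% 2 + 1]
    # force-grid times falling inside this stance, relative to touchdown
    gi <- seq(ceiling(t_now * rate), ceiling((t_now + 0.5) * rate))
    extra <- gi / rate - t_now
    extra <- extra[extra > 0]
    stp <- slip_step(state, leg, nxt, p, extra_times = extra)
    tr <- stp$stance$traj
    truth[[i]] <- data.frame(
      stance = i, leg = leg, t_td = t_now, t_c = stp$stance$t_c,
      t_a = stp$flight$t_a,
      peak_vgrf = max(tr$grf_v),
      avg_vgrf = trapz_nonuniform(tr$time, tr$grf_v) / stp$stance$t_c,
      max_compression = p$L0[[leg]] - min(tr$L),
      z_td = tr$z[1], min_z = min(tr$z),
      delta_y = tr$z[1] - min(tr$z),
      vz_td = tr$vz[1], vz_to = stp$stance$state_out[4],
      impulse_v = trapz_nonuniform(tr$time, tr$grf_v),
      energy_start = tr$energy[1], energy_end = tr$energy[nrow(tr)],
      k_true = p$k[[leg]], L0 = p$L0[[leg]], alpha = p$alpha[[leg]],
      stringsAsFactors = FALSE)
    segs[[i]] <- data.frame(time = tr$time + t_now, grf_v = tr$grf_v,
                            grf_ap = tr$grf_ap)
    foot_x[i] <- stp$foot_x
    t_now <- t_now + stp$stance$t_c + stp$flight$t_a
    state <- stp$state_out
  }
  truth <- do.call(rbind, truth)
  t_end <- t_now + pad
  n <- ceiling(t_end * rate)
  grid <- (seq_len(n) - 1) / rate
  f_v <- numeric(n); f_ap <- numeric(n)
  for (i in seq_len(n_stance)) {
    sg <- segs[[i]]
    sg <- sg[!duplicated(sg$time), ]
    i0 <- truth$t_td[i]; i1 <- i0 + truth$t_c[i]
    idx <- which(grid >= i0 & grid <= i1)
    f_v[idx] <- stats::approx(sg$time, sg$grf_v, xout = grid[idx],
                              rule = 2)$y
    f_ap[idx] <- stats::approx(sg$time, sg$grf_ap, xout = grid[idx],
                               rule = 2)$y
  }
  list(truth = truth, grid = grid,
       grf = data.frame(f_v = f_v, f_ap = f_ap),
       foot_x = foot_x, belt_velocity = fp$belt_velocity,
       fixed_point = fp, params = p)
}

trapz_nonuniform <- function(t, y) {
  n <- length(t)
  sum((t[-1] - t[-n]) * (y[-1] + y[-n]) / 2)
}

# lab -> treadmill-frame marker traces: the foot rides the belt during
# its own stance and swings smoothly (cosine ease) to the next
# touchdown position otherwise
marker_paths <- function(sim) {
  p <- sim$params
  vb <- sim$belt_velocity
  t_end <- sim$grid[length(sim$grid)]
  mt <- seq(0, t_end, by = 1 / p$marker_rate)
  truth <- sim$truth
  out <- list()
  for (leg in c("AL", "UL")) {
    idx <- which(truth$leg == leg)
    pos <- rep(NA_real_, length(mt))
    tm_pos <- function(x_lab, t) x_lab - vb * t   # treadmill frame
    for (j in seq_along(idx)) {
      i <- idx[j]
      td <- truth$t_td[i]; to <- td + truth$t_c[i]
      in_st <- mt >= td & mt <= to
      pos[in_st] <- tm_pos(sim$foot_x[i], mt[in_st])
      if (j < length(idx)) {
        i2 <- idx[j + 1]
        td2 <- truth$t_td[i2]
        sw <- mt > to & mt < td2
        s <- (mt[sw] - to) / (td2 - to)
        p0 <- tm_pos(sim$foot_x[i], to)
        p1 <- tm_pos(sim$foot_x[i2], td2)
        pos[sw] <- p0 + (p1 - p0) * (1 - cos(pi * s)) / 2
      }
    }
    first_td <- truth$t_td[idx[1]]
    pos[mt < first_td] <- tm_pos(sim$foot_x[idx[1]], first_td)
    last_i <- idx[length(idx)]
    last_to <- truth$t_td[last_i] + truth$t_c[last_i]
    pos[mt > last_to] <- tm_pos(sim$foot_x[last_i], last_to)
    out[[leg]] <- pos
  }
  list(time = mt, ap_AL = out$AL, ap_UL = out$UL)
}

#' Generate a synthetic session directory with ground truth
#'
#' Runs [simulate_session()], adds seeded Gaussian sensor noise to the
#' force channels (the medio-lateral channel is pure noise) and marker
#' traces, and writes a session directory — \code{config},
#' \code{forces.csv}, \code{markers.csv} — consumable by
#' [read_session()] and [analyze_session()], plus \code{truth.csv} with
#' the per-stance ground truth. The config's belt velocity is the
#' realised stride-average forward velocity of the periodic gait, and
#' \code{k_RSP} is the affected leg's true stiffness.
#'
#' All randomness derives from \code{p$seed}; repeated calls with the
#' same parameters produce byte-identical files.
#'
#' @param p a [slip_params()].
#' @param path session directory to create; \code{NULL} skips writing
#'   and returns the in-memory session.
#' @param subject_id subject label for the config.
#' @return Invisibly, a list with \code{config}, \code{forces},
#'   \code{markers}, \code{truth} and \code{sim} (the noiseless
#'   [simulate_session()] output).
#' @export
generate_session <- function(p, path = NULL, subject_id = "SIM01") {
  sim <- simulate_session(p)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(p$seed)
  n <- length(sim$grid)
  sf <- p$noise_sigma_force
  f_v <- sim$grf$f_v + stats::rnorm(n, 0, sf)
  f_ap <- sim$grf$f_ap + stats::rnorm(n, 0, sf)
  f_ml <- stats::rnorm(n, 0, sf)
  forces <- force_trace(sim$grid, f_ml, f_ap, f_v, rate = p$force_rate)
  mp <- marker_paths(sim)
  sm <- p$noise_sigma_marker
  markers <- marker_trace(mp$time,
                          mp$ap_AL + stats::rnorm(length(mp$time), 0, sm),
                          mp$ap_UL + stats::rnorm(length(mp$time), 0, sm),
                          rate = p$marker_rate)
  cfg <- trial_config(subject_id = subject_id, body_mass = p$body_mass,
                      belt_velocity = sim$belt_velocity,
                      force_rate = p$force_rate,
                      marker_rate = p$marker_rate,
                      rsp_model = "SIM", stiffness_category = 0L,
                      height_offset = 0,
                      first_contact_leg = p$first_contact_leg,
                      L0_AL = p$L0[["AL"]], L0_UL = p$L0[["UL"]],
                      k_RSP = p$k[["AL"]])
  out <- list(config = cfg, forces = forces, markers = markers,
              truth = sim$truth, sim = sim)
  if (!is.null(path)) {
    write_session(cfg, forces, markers, path)
    write_csv_exact(sim$truth, file.path(path, "truth.csv"))
  }
  invisible(out)
}

#' Half-sine GRF test pulse
#'
#' Analytic single-stance fixture: \code{F(t) = peak * sin(pi t /
#' duration)} on \code{[0, duration]}, zero-padded on both sides. Its
#' threshold crossings have the closed form \code{t = (duration / pi) *
#' asin(threshold / peak)} and its mirror, and its supra-threshold mean
#' tends to \code{2 / pi * peak} for thresholds far below the peak.
#'
#' @param peak pulse peak in N (> 30 so the contact threshold is
#'   crossed).
#' @param duration pulse duration in s.
#' @param rate sampling rate in Hz.
#' @param pad zero padding on each side, s.
#' @return Numeric force series; the pulse starts at \code{pad} seconds.
#' @export
make_grf_pulse <- function(peak, duration, rate, pad = 0.1) {
  stopifnot(peak > 30, rate > 0)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  n_pad <- round(pad * rate)
  t <- seq(0, duration, by = 1 / rate)
  pulse <- peak * sin(pi * t / duration)
  c(numeric(n_pad), pulse, numeric(n_pad))
}
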