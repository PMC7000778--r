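#' Leg contact angle at touchdown
#'
#' Under the spring-mass model the leg sweeps a symmetric arc during
#' stance, so the angle of the leg from vertical at initial contact is
#' \code{theta = asin(v * t_c / (2 * L0))}: half the swept chord
#' (\code{v * t_c}) over the leg length.
#'
#' @param v running (belt) velocity in m/s.
#' @param t_c ground contact time in s.
#' @param L0 initial leg length in m — for the affected leg measured to
#'   the distal end of the unloaded prosthesis, for the unaffected leg
#'   to the floor during standing.
#' @return Contact angle in rad, in \code{[0, pi/2]}.
#' @export
contact_angle <- function(v, t_c, L0) {
  stopifnot(v >= 0, t_c > 0, L0 > 0)
  arg <- v * t_c / (2 * L0)
  if (arg > 1)
    stop("geometry error: v*t_c/(2*L0) = ", signif(arg, 4),
         " > 1; contact length exceeds the leg sweep capability",
         call. = FALSE)
  asin(arg)
}

#' Vertical CoM excursion during stance by double integration
#'
#' Twice integrates the vertical acceleration of the centre of mass,
#' \code{a = f_v / m - g}, over one full stride (onset of a stance to
#' the next onset of the same leg). Integration constants follow the
#' steady-running closure: the mean vertical velocity over the stride is
#' zero and positions are relative. The excursion is read
#' touchdown-to-minimum within the target stance, i.e. how far the CoM
#' drops below its touchdown height — the quantity that adds to the
#' geometric drop \code{L0 * (1 - cos(theta))} in the leg-compression
#' formula.
#'
#' The stride must be steady: the mean vertical force over the window
#' has to equal body weight within 15%, otherwise the trial is flagged
#' as drifting.
#'
#' @param f_v filtered vertical GRF in N over exactly one stride window.
#' @param body_mass body mass in kg.
#' @param rate sampling rate in Hz.
#' @param stance optional integer pair \code{c(first, last)}: sample
#'   range of the target stance within the window; defaults to the whole
#'   window.
#' @param g gravitational acceleration, m/s^2.
#' @return Downward CoM excursion \code{delta_y} in m (non-negative).
#' @export
com_vertical_displacement <- function(f_v, body_mass, rate, stance = NULL,
                                      g = 9.81) {
  bw <- body_mass * g
  if (abs(mean(f_v) - bw) > 0.15 * bw)
    stop("non-steady-trial error: mean vertical force deviates from body ",
         "weight by more than 15% over the stride", call. = FALSE)
  n <- length(f_v)
  dt <- 1 / rate
  a <- f_v / body_mass - g
  vel <- cumtrapz_uniform(a, dt)
  vel <- vel - mean(vel)
  y <- cumtrapz_uniform(vel, dt)
  if (is.null(stance)) stance <- c(1L, n)
  w <- stance[1]:stance[2]
  max(0, y[1] - min(y[w]))
}

# cumulative trapezoidal integral on a uniform grid, first value 0
cumtrapz_uniform <- function(x, dt) {
  c(0, cumsum((x[-length(x)] + x[-1]) / 2 * dt))
}

#' Maximum leg compression
#'
#' Spring-mass leg compression after McMahon & Cheng: the vertical CoM
#' drop during stance plus the geometric shortening implied by the
#' touchdown angle, \code{delta_L = delta_y + L0 * (1 - cos(theta))}.
#'
#' @param delta_y downward CoM excursion in m.
#' @param L0 initial leg length in m.
#' @param theta contact angle in rad.
#' @return Maximum leg compression in m.
#' @export
leg_compression <- function(delta_y, L0, theta) {
  stopifnot(is.finite(delta_y), is.finite(theta), L0 > 0)
  delta_y + L0 * (1 - cos(theta))
}

#' Leg stiffness
#'
#' The spring-mass leg stiffness is the ratio of peak vertical GRF to
#' maximum leg compression during stance, reported in kN/m.
#'
#' @param peak_vgrf peak vertical GRF in N.
#' @param delta_L maximum leg compression in m.
#' @return Leg stiffness in kN/m.
#' @export
leg_stiffness <- function(peak_vgrf, delta_L) {
  stopifnot(peak_vgrf > 0)
  if (!is.finite(delta_L) || delta_L <= 0)
    stop("degenerate-compression error: delta_L must be positive",
         call. = FALSE)
  (peak_vgrf / delta_L) / 1000
}

#' Prosthesis displacement
#'
#' Displacement of the running-specific prosthesis under the peak
#' resultant GRF, \code{delta_RSP = peak_resultant_grf / k_RSP}, using
#' the bench-measured prosthesis spring constant.
#'
#' @param peak_resultant_grf peak resultant GRF in N.
#' @param k_RSP prosthesis stiffness in kN/m.
#' @return Prosthesis displacement in m.
#' @export
rsp_displacement <- function(peak_resultant_grf, k_RSP) {
  stopifnot(peak_resultant_grf > 0, k_RSP > 0)
  peak_resultant_grf / (k_RSP * 1000)
}

#' Per-stance spring-mass estimates for a trial
#'
#' Runs the estimation chain for every stance that has a complete stride
#' window after it (onset to the next same-leg onset): contact angle
#' from belt velocity, contact time and the leg's own length; CoM drop
#' by double integration over the stride; leg compression; leg
#' stiffness; and, for affected-leg stances, the prosthesis
#' displacement from the peak resultant GRF.
#'
#' The affected leg always uses \code{L0_AL} and the unaffected leg
#' \code{L0_UL}; the leg label on each stance keys the lookup so the
#' lengths can never be swapped.
#'
#' @param records step table from [step_metrics()] (row order matches
#'   the stance order).
#' @param stances labeled stance table.
#' @param f_v filtered vertical GRF in N for the whole trial.
#' @param config a [trial_config()].
#' @param rate force sampling rate in Hz.
#' @return \code{records} with columns \code{theta}, \code{delta_y},
#'   \code{delta_L}, \code{k_leg} (kN/m) and \code{delta_rsp} (m, NA for
#'   unaffected-leg stances) appended; rows without a complete stride
#'   window carry NA.
#' @export
stance_spring_mass <- function(records, stances, f_v, config, rate) {
  n <- nrow(stances)
  L0 <- c(AL = config$L0_AL, UL = config$L0_UL)
  v <- config$belt_velocity
  m <- config$body_mass
  theta <- delta_y <- delta_L <- k_leg <- delta_rsp <- rep(NA_real_,
                                                           nrow(records))
  for (i in seq_len(nrow(records))) {
    if (i + 2 > n) next                       # needs next same-leg onset
    leg <- records$leg[i]
    on <- stances$onset[i]; nxt <- stances$onset[i + 2]
    th <- contact_angle(v, records$t_c[i], L0[[leg]])
    dy <- com_vertical_displacement(f_v[on:(nxt - 1L)], m, rate,
                                    stance = c(1L, stances$offset[i] - on))
    dL <- leg_compression(dy, L0[[leg]], th)
    theta[i] <- th; delta_y[i] <- dy; delta_L[i] <- dL
    k_leg[i] <- leg_stiffness(records$F_peak_v[i], dL)
    if (leg == "AL")
      delta_rsp[i] <- rsp_displacement(records$F_peak_res[i], config$k_RSP)
  }
  records$theta <- theta
  records$delta_y <- delta_y
  records$delta_L <- delta_L
  records$k_leg <- k_leg
  records$delta_rsp <- delta_rsp
  records
}
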