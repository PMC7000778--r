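#' Analyse a treadmill running session
#'
#' The full measurement chain for one trial: zero-phase Butterworth
#' filtering of the ground reaction forces (30 Hz cutoff) and marker
#' positions (7 Hz), ground-contact detection on the filtered vertical
#' force with a 30 N threshold, alternating leg labelling, per-step
#' spatiotemporal and force metrics, per-stance spring-mass estimates
#' (contact angle, CoM drop by double integration, leg compression, leg
#' stiffness, prosthesis displacement), trial-level per-leg and two-leg
#' averages, between-leg symmetry indices, a belt-speed check from the
#' markers, and the stride-count/station-keeping validity flag used for
#' maximum-velocity trials.
#'
#' @param session a session directory path, or a list with
#'   \code{config}, \code{forces} and optional \code{markers} as
#'   returned by [read_session()] or [generate_session()].
#' @param cutoff_grf,cutoff_marker low-pass cutoffs in Hz.
#' @param threshold contact threshold in N.
#' @param min_contact,min_aerial event-cleaning guards in s, see
#'   [detect_stances()].
#' @return Object of class \code{"gait_session"}: list with
#'   \code{config}, \code{stances}, \code{records} (per-step metrics
#'   plus spring-mass columns), \code{summary} (a
#'   \code{trial_summary}), \code{si} (named vector of symmetry
#'   indices), \code{qc} (belt-speed estimates and trial validity) and
#'   \code{filtered} (the filtered force channels).
#' @examples
#' \donttest{
#' p <- slip_params(n_strides = 8, seed = 7)
#' ses <- generate_session(p)
#' fit <- analyze_session(ses)
#' print(fit)
#' }
#' @export
analyze_session <- function(session, cutoff_grf = 30, cutoff_marker = 7,
                            threshold = 30, min_contact = 0.05,
                            min_aerial = 0.02) {
  if (is.character(session)) session <- read_session(session)
  cfg <- session$config
  forces <- session$forces
  rate <- cfg$force_rate
  f_v <- butterworth_lowpass(forces$f_v, rate, cutoff_grf)
  f_ap <- butterworth_lowpass(forces$f_ap, rate, cutoff_grf)
  f_ml <- butterworth_lowpass(forces$f_ml, rate, cutoff_grf)
  stances <- detect_stances(f_v, rate, threshold = threshold,
                            min_contact = min_contact,
                            min_aerial = min_aerial)
  if (nrow(stances) < 3)
    stop("fewer than 3 ground contacts detected; not a running trial",
         call. = FALSE)
  stances <- assign_legs(stances, cfg$first_contact_leg)
  records <- step_metrics(stances, f_v, f_ml, f_ap, rate,
                          v = cfg$belt_velocity, body_mass = cfg$body_mass)
  records <- stance_spring_mass(records, stances, f_v, cfg, rate)
  summ <- summarize_trial(records, cfg)
  si <- symmetry_indices(summ,
                         variables = c("t_c", "t_a", "t_step", "f_step",
                                       "L_c", "F_avg_bw", "F_peak_v",
                                       "k_leg"))
  qc <- session_qc(session, stances, records, f_v, f_ap, cutoff_marker)
  out <- list(config = cfg, stances = stances, records = records,
              summary = summ, si = si, qc = qc,
              filtered = data.frame(time = forces$time, f_ml = f_ml,
                                    f_ap = f_ap, f_v = f_v))
  class(out) <- "gait_session"
  out
}

session_qc <- function(session, stances, records, f_v, f_ap,
                       cutoff_marker) {
  cfg <- session$config
  rate <- cfg$force_rate
  belt <- NULL
  touchdown_pos <- NULL
  if (!is.null(session$markers)) {
    mk <- session$markers
    mrate <- cfg$marker_rate
    ap <- list(AL = butterworth_lowpass(mk$ap_AL, mrate, cutoff_marker),
               UL = butterworth_lowpass(mk$ap_UL, mrate, cutoff_marker))
    belt <- vapply(seq_len(nrow(stances)), function(i) {
      leg <- stances$leg[i]
      tryCatch(belt_speed_from_marker(ap[[leg]], mrate,
                                      (stances$onset[i] - 1) / rate,
                                      (stances$offset[i] - 1) / rate),
               error = function(e) NA_real_)
    }, numeric(1))
    # marker-consistency check on the leg labelling: during a stance the
    # grounded leg's marker moves at belt speed, the swing leg's does not
    swing <- vapply(seq_len(nrow(stances)), function(i) {
      leg <- setdiff(c("AL", "UL"), stances$leg[i])
      tryCatch(belt_speed_from_marker(ap[[leg]], mrate,
                                      (stances$onset[i] - 1) / rate,
                                      (stances$offset[i] - 1) / rate),
               error = function(e) NA_real_)
    }, numeric(1))
    ok <- !is.na(belt) & !is.na(swing)
    if (any(ok) &&
        mean(abs(belt[ok] - cfg$belt_velocity)) >
        mean(abs(swing[ok] - cfg$belt_velocity)))
      warning("marker-consistency check disagrees with the configured ",
              "first_contact_leg; leg labels may be swapped",
              call. = FALSE)
    td_idx <- pmax(1, round((stances$onset - 1) / rate * cfg$marker_rate) + 1)
    own <- ifelse(stances$leg == "AL", "AL", "UL")
    touchdown_pos <- vapply(seq_along(td_idx), function(i)
      ap[[own[i]]][min(td_idx[i], length(ap[[own[i]]]))], numeric(1))
  }
  validity <- if (!is.null(touchdown_pos)) {
    vmax_trial_valid(records, touchdown_pos = touchdown_pos)
  } else {
    suppressMessages(
      vmax_trial_valid(records, f_ap = f_ap, rate = rate,
                       body_mass = cfg$body_mass))
  }
  list(belt_speed = belt, belt_speed_mean =
         if (is.null(belt)) NA_real_ else mean(belt, na.rm = TRUE),
       validity = validity)
}

#' @export
print.gait_session <- function(x, digits = 4, ...) {
  cfg <- x$config
  cat(sprintf("Gait session: subject %s, RSP %s, belt %.2f m/s\n",
              cfg$subject_id, cfg$rsp_model, cfg$belt_velocity))
  cat(sprintf("  %d stances, %d steps, %d strides; vmax-trial valid: %s\n",
              nrow(x$stances), nrow(x$records), x$summary$stride_count,
              x$qc$validity$valid))
  if (!is.na(x$qc$belt_speed_mean))
    cat(sprintf("  marker belt-speed check: %.2f m/s\n",
                x$qc$belt_speed_mean))
  cat("two-leg averages:\n")
  show <- intersect(c("t_c", "t_a", "f_step", "L_c", "F_avg_bw", "k_leg"),
                    names(x$summary$both))
  print(signif(x$summary$both[show], digits))
  cat("symmetry indices (AL vs UL):\n")
  print(signif(x$si, digits))
  invisible(x)
}

#' @export
summary.gait_session <- function(object, ...) {
  print(object$summary)
  cat("\nsymmetry indices:\n")
  print(signif(object$si, 4))
  invisible(object)
}

#' @export
coef.gait_session <- function(object, ...) {
  object$summary$both
}

#' Plot the filtered vertical GRF with detected stances
#'
#' Shades each detected stance by leg, the standard visual check that
#' contact detection and leg labelling are sound.
#'
#' @param x a \code{gait_session}.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gait_session <- function(x, ...) {
  ft <- x$filtered
  rate <- x$config$force_rate
  graphics::plot(ft$time, ft$f_v, type = "l", xlab = "time (s)",
                 ylab = "vertical GRF (N)", ...)
  cols <- c(AL = grDevices::adjustcolor("firebrick", 0.25),
            UL = grDevices::adjustcolor("steelblue", 0.25))
  for (i in seq_len(nrow(x$stances))) {
    graphics::rect((x$stances$onset[i] - 1) / rate, 0,
                   (x$stances$offset[i] - 1) / rate,
                   max(ft$f_v), border = NA,
                   col = cols[[x$stances$leg[i]]])
  }
  graphics::abline(h = 30, lty = 3)
  graphics::legend("topright", fill = cols, legend = names(cols),
                   bty = "n")
  invisible(x)
}

#' Long-format results rows for a session
#'
#' Flattens a [analyze_session()] result into the results-table
#' vocabulary: per-leg and two-leg means of every metric plus the
#' symmetry indices (under \code{leg = "both"}).
#'
#' @param fit a \code{gait_session}.
#' @return Data frame ready for [write_results()].
#' @export
results_table <- function(fit) {
  cfg <- fit$config
  map <- c(t_c = "contact_time", t_a = "aerial_time",
           t_step = "step_time", f_step = "step_frequency",
           L_c = "contact_length", F_avg = "stance_avg_vgrf",
           F_avg_bw = "stance_avg_vgrf_bw", F_peak_v = "peak_vgrf",
           F_peak_res = "peak_resultant_grf", theta = "contact_angle",
           delta_y = "delta_y", delta_L = "delta_L",
           k_leg = "leg_stiffness", delta_rsp = "delta_rsp")
  key <- function(variable, leg, value)
    data.frame(subject = cfg$subject_id, rsp_model = cfg$rsp_model,
               stiffness_category = cfg$stiffness_category,
               height_offset = cfg$height_offset,
               velocity = cfg$belt_velocity, variable = variable,
               leg = leg, value = value, stringsAsFactors = FALSE)
  rows <- list()
  pl <- fit$summary$per_leg
  for (v in intersect(names(map), names(pl))) {
    for (leg in c("AL", "UL")) {
      val <- pl[pl$leg == leg, v]
      if (is.finite(val)) rows[[length(rows) + 1]] <- key(map[[v]], leg, val)
    }
    bv <- fit$summary$both[[v]]
    if (is.finite(bv)) rows[[length(rows) + 1]] <- key(map[[v]], "both", bv)
  }
  for (nm in names(fit$si)) {
    base <- sub("^si_", "", nm)
    if (base %in% names(map))
      rows[[length(rows) + 1]] <- key(paste0("si_", map[[base]]), "both",
                                      fit$si[[nm]])
  }
  do.call(rbind, rows)
}
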