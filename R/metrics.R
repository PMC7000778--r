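#' Per-step spatiotemporal and force metrics
#'
#' A step runs from the onset of one stance to the onset of the next
#' (opposite-leg) stance and is attributed to the leg of the first
#' stance: step time is the ground contact time plus the subsequent
#' aerial time, step frequency its reciprocal, and contact length the
#' product of contact time and belt velocity. Stance-average and peak
#' vertical GRF come from the filtered vertical channel over the
#' half-open stance window; the peak resultant force uses all three
#' channels. The last stance has no subsequent aerial phase and yields
#' no record.
#'
#' @param stances labeled stance table from [assign_legs()].
#' @param f_v,f_ml,f_ap filtered GRF channels in N.
#' @param rate force sampling rate in Hz.
#' @param v belt velocity in m/s.
#' @param body_mass body mass in kg (for body-weight normalisation,
#'   g = 9.81 m/s^2).
#' @return Data frame with one row per step: \code{leg}, \code{onset},
#'   \code{offset}, \code{t_c}, \code{t_a}, \code{t_step},
#'   \code{f_step}, \code{L_c}, \code{F_avg}, \code{F_avg_bw},
#'   \code{F_peak_v}, \code{F_peak_res}.
#' @export
step_metrics <- function(stances, f_v, f_ml = NULL, f_ap = NULL, rate, v,
                         body_mass) {
  n <- nrow(stances)
  if (n < 2)
    stop("need at least 2 stances to form a step", call. = FALSE)
  if (any(stances$offset[-n] > stances$onset[-1]))
    stop("internal consistency error: overlapping stances", call. = FALSE)
  if (is.null(f_ml)) f_ml <- numeric(length(f_v))
  if (is.null(f_ap)) f_ap <- numeric(length(f_v))
  g <- 9.81
  idx <- seq_len(n - 1)
  rec <- lapply(idx, function(i) {
    on <- stances$onset[i]; off <- stances$offset[i]
    w <- on:(off - 1L)
    t_c <- (off - on) / rate
    t_a <- (stances$onset[i + 1] - off) / rate
    F_avg <- mean(f_v[w])
    res <- sqrt(f_v[w]^2 + f_ap[w]^2 + f_ml[w]^2)
    data.frame(leg = stances$leg[i], onset = on, offset = off,
               t_c = t_c, t_a = t_a, t_step = t_c + t_a,
               f_step = 1 / (t_c + t_a), L_c = v * t_c,
               F_avg = F_avg, F_avg_bw = F_avg / (body_mass * g),
               F_peak_v = max(f_v[w]), F_peak_res = max(res),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rec)
}

#' Trial-level summary of per-step metrics
#'
#' Computes per-leg means of every step metric over all complete steps
#' and the two-leg average (arithmetic mean of the two per-leg means),
#' the standard way to report a variable "averaged over both legs".
#'
#' @param records step table from [step_metrics()] (optionally with
#'   spring-mass columns appended, see [stance_spring_mass()]).
#' @param config a [trial_config()] (carried through for reporting).
#' @return An object of class \code{"trial_summary"}: list with
#'   \code{per_leg} (data frame, rows AL/UL), \code{both} (named numeric
#'   vector), \code{stride_count} and \code{config}.
#' @export
summarize_trial <- function(records, config = NULL) {
  for (leg in c("AL", "UL"))
    if (!any(records$leg == leg))
      stop("missing-leg error: no steps recorded for leg ", leg,
           call. = FALSE)
  num_cols <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                      c("onset", "offset"))
  per_leg <- do.call(rbind, lapply(c("AL", "UL"), function(leg) {
    sub <- records[records$leg == leg, num_cols, drop = FALSE]
    cbind(data.frame(leg = leg, n_steps = nrow(sub)),
          as.data.frame(as.list(colMeans(sub, na.rm = TRUE))))
  }))
  both <- colMeans(per_leg[num_cols])
  out <- list(per_leg = per_leg, both = both,
              stride_count = min(per_leg$n_steps), config = config)
  class(out) <- "trial_summary"
  out
}

#' @export
print.trial_summary <- function(x, digits = 4, ...) {
  cat("Trial summary (", x$stride_count, " strides)\n", sep = "")
  df <- x$per_leg
  df[-1] <- lapply(df[-1], signif, digits = digits)
  print(df, row.names = FALSE)
  cat("both-legs average:\n")
  print(signif(x$both, digits))
  invisible(x)
}

#' Validity of a maximum-velocity trial
#'
#' A maximum-velocity trial counts only if the athlete completed at
#' least \code{min_strides} strides while holding their fore-aft
#' station on the treadmill. Station keeping is checked from the
#' fore-aft marker position at each touchdown; when no markers are
#' available the net fore-aft drift is estimated from the fore-aft GRF
#' impulse (drift = net velocity change times half the observation
#' span) and a notice is emitted.
#'
#' @param records step table from [step_metrics()].
#' @param touchdown_pos optional fore-aft marker position (m) at each
#'   stance onset.
#' @param min_strides minimum stride count (a stride is one step of each
#'   leg).
#' @param drift_limit largest tolerated fore-aft excursion in m. The
#'   criterion is qualitative in origin; 0.3 m is roughly a third of a
#'   treadmill deck.
#' @param f_ap,rate,body_mass fore-aft GRF channel (N), its rate (Hz)
#'   and body mass (kg) for the impulse fallback.
#' @return List with \code{valid}, \code{stride_count}, \code{drift_m}
#'   and \code{method} ("marker" or "impulse").
#' @export
vmax_trial_valid <- function(records, touchdown_pos = NULL, min_strides = 8,
                             drift_limit = 0.3, f_ap = NULL, rate = NULL,
                             body_mass = NULL) {
  strides <- min(sum(records$leg == "AL"), sum(records$leg == "UL"))
  if (!is.null(touchdown_pos) && length(touchdown_pos) >= 2) {
    drift <- abs(touchdown_pos[length(touchdown_pos)] - touchdown_pos[1])
    method <- "marker"
  } else if (!is.null(f_ap) && !is.null(rate) && !is.null(body_mass)) {
    message("no touchdown positions; using fore-aft impulse drift fallback")
    span <- (max(records$offset) - min(records$onset)) / rate
    w <- min(records$onset):(max(records$offset) - 1L)
    dv <- sum(f_ap[w]) / rate / body_mass
    drift <- abs(dv) * span / 2
    method <- "impulse"
  } else {
    stop("need touchdown positions or (f_ap, rate, body_mass)",
         call. = FALSE)
  }
  list(valid = strides >= min_strides && drift <= drift_limit,
       stride_count = strides, drift_m = drift, method = method)
}
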