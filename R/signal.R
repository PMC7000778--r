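#' Zero-phase Butterworth low-pass filter
#'
#' Biomechanics-standard low-pass filtering of force and marker series.
#' By default a 2nd-order Butterworth design is applied forward and
#' backward (\code{signal::filtfilt}), which cancels the phase shift and
#' doubles the magnitude order — the usual reading of a "4th-order
#' zero-phase" filter in gait analysis. A single-pass design of the full
#' stated order is available with \code{zero_phase = FALSE} for
#' sensitivity checks.
#'
#' @param x numeric series on a uniform grid.
#' @param rate sampling rate in Hz.
#' @param cutoff low-pass cutoff in Hz; must be below the Nyquist
#'   frequency. At the cutoff the two-pass magnitude response is 1/2.
#' @param order effective filter order, 2 or 4. With
#'   \code{zero_phase = TRUE} the design order is \code{order/2} per pass.
#' @param zero_phase apply forward-backward (default) or single pass.
#' @return Filtered series, same length as \code{x}. DC gain is 1.
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' noisy <- sin(2 * pi * 3 * t) + 0.2 * sin(2 * pi * 200 * t)
#' smooth <- butterworth_lowpass(noisy, rate = 1000, cutoff = 30)
#' @export
butterworth_lowpass <- function(x, rate, cutoff = 30, order = 4,
                                zero_phase = TRUE) {
  if (!order %in% c(2, 4))
    stop("parameter error: filter order must be 2 or 4", call. = FALSE)
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= rate / 2)
    stop("parameter error: cutoff must lie in (0, rate/2)", call. = FALSE)
  if (any(!is.finite(x)))
    stop("data error: input contains non-finite values", call. = FALSE)
  design_order <- if (zero_phase) order / 2 else order
  if (length(x) <= 6 * design_order)
    stop("data error: series too short for the requested filter",
         call. = FALSE)
  bf <- signal::butter(design_order, cutoff / (rate / 2), type = "low")
  if (zero_phase) {
    # odd-reflection padding confines the forward-backward start-up
    # transients to the pads (MATLAB-style filtfilt edge handling)
    n <- length(x)
    pad <- min(n - 1, ceiling(6 * rate / cutoff))
    left <- 2 * x[1] - x[(pad + 1):2]
    right <- 2 * x[n] - x[(n - 1):(n - pad)]
    y <- as.numeric(signal::filtfilt(bf, c(left, x, right)))
    y[(pad + 1):(pad + n)]
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

#' Detect ground contacts from the vertical GRF
#'
#' Finds stance phases as maximal runs of filtered vertical force at or
#' above a force threshold (30 N by default), then cleans the event
#' list: aerial gaps shorter than \code{min_aerial} are merged into the
#' surrounding contact (filter ringing or brief unloading), and contacts
#' shorter than \code{min_contact} are discarded (crossing artefacts).
#' For sprint running, contact times near 0.1 s and aerial times near
#' 0.05-0.15 s make the 50 ms / 20 ms defaults safe guards.
#'
#' Intervals use the half-open convention \code{[onset, offset)}:
#' \code{onset} is the first sample at/above threshold, \code{offset} the
#' first sample below it again, and contact time is
#' \code{(offset - onset)/rate}, so stance and aerial samples partition
#' the trace exactly.
#'
#' @param f_v filtered vertical GRF in N (filtering is the caller's
#'   responsibility).
#' @param rate sampling rate in Hz.
#' @param threshold contact threshold in N.
#' @param min_contact minimum contact duration in s; shorter contacts are
#'   dropped.
#' @param min_aerial minimum aerial duration in s; shorter gaps are
#'   merged.
#' @return Data frame with columns \code{onset}, \code{offset} (1-based
#'   sample indices) and \code{leg} (\code{"unassigned"}); zero rows when
#'   no contact is found.
#' @export
detect_stances <- function(f_v, rate, threshold = 30, min_contact = 0.05,
                           min_aerial = 0.02) {
  stopifnot(threshold > 0, rate > 0)
  on_ground <- f_v >= threshold
  r <- rle(on_ground)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  onset <- starts[r$values]
  offset <- ends[r$values] + 1L          # half-open: first sample below
  if (length(onset) == 0)
    return(empty_stances())
  # merge aerial gaps shorter than min_aerial
  min_gap <- round(min_aerial * rate)
  if (length(onset) > 1) {
    keep_on <- onset[1]
    m_on <- c(); m_off <- c()
    for (i in seq_len(length(onset) - 1)) {
      gap <- onset[i + 1] - offset[i]
      if (gap >= min_gap) {
        m_on <- c(m_on, keep_on); m_off <- c(m_off, offset[i])
        keep_on <- onset[i + 1]
      }
    }
    m_on <- c(m_on, keep_on); m_off <- c(m_off, offset[length(offset)])
    onset <- m_on; offset <- m_off
  }
  # drop contacts shorter than min_contact
  keep <- (offset - onset) >= round(min_contact * rate)
  onset <- onset[keep]; offset <- offset[keep]
  if (length(onset) == 0) return(empty_stances())
  data.frame(onset = as.integer(onset), offset = as.integer(offset),
             leg = "unassigned", stringsAsFactors = FALSE)
}

empty_stances <- function() {
  data.frame(onset = integer(), offset = integer(), leg = character(),
             stringsAsFactors = FALSE)
}

#' Label stances with alternating legs
#'
#' On a treadmill the two legs strictly alternate; given which leg makes
#' the first recorded contact, every stance gets its leg label.
#'
#' @param stances stance table from [detect_stances()], time-ordered.
#' @param first_contact_leg \code{"AL"} or \code{"UL"}.
#' @return The stance table with \code{leg} filled in.
#' @export
assign_legs <- function(stances, first_contact_leg) {
  if (!first_contact_leg %in% c("AL", "UL"))
    stop("first_contact_leg must be \"AL\" or \"UL\"", call. = FALSE)
  n <- nrow(stances)
  if (n == 0) return(stances)
  if (is.unsorted(stances$onset, strictly = TRUE))
    stop("stances must be time-ordered", call. = FALSE)
  pair <- if (first_contact_leg == "AL") c("AL", "UL") else c("UL", "AL")
  stances$leg <- pair[(seq_len(n) - 1) %% 2 + 1]
  stances
}

#' Belt speed from a fore-aft marker during stance
#'
#' During ground contact the foot (or prosthesis tip) rides the belt, so
#' the fore-aft velocity of its marker measures the belt speed. Used as a
#' quality-control channel to confirm the nominal treadmill velocity,
#' never as the velocity entering the contact-length or contact-angle
#' computations.
#'
#' The mean speed is taken over the central half of the stance: the 7 Hz
#' marker filter needs tens of milliseconds to settle, so the first and
#' last quarter of a sprint stance under-read the belt speed.
#'
#' @param ap fore-aft marker position in m, already low-pass filtered
#'   (7 Hz recommended).
#' @param rate marker sampling rate in Hz.
#' @param onset_s,offset_s stance interval in seconds on the marker
#'   timebase (e.g. stance sample indices divided by the force rate).
#' @return Mean magnitude of the fore-aft marker velocity over the
#'   central half of the stance, in m/s.
#' @export
belt_speed_from_marker <- function(ap, rate, onset_s, offset_s) {
  i0 <- max(1L, ceiling(onset_s * rate) + 1L)
  i1 <- min(length(ap), floor(offset_s * rate) + 1L)
  if (i1 - i0 + 1L < 3L)
    stop("insufficient-data error: stance shorter than 3 marker samples",
         call. = FALSE)
  vel <- abs(diff(ap[i0:i1]) * rate)
  q <- floor(length(vel) / 4)
  if (q > 0) vel <- vel[(q + 1):(length(vel) - q)]
  mean(vel)
}
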