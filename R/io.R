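#' Trial configuration
#'
#' Bundles the subject- and trial-level constants every downstream stage
#' needs: body mass, treadmill belt velocity, sampling rates, the
#' running-specific prosthesis (RSP) configuration under test, per-leg
#' standing leg lengths and the prosthesis spring constant.
#'
#' Leg-length conventions follow standard practice for athletes with a
#' unilateral transtibial amputation: the affected-leg length \code{L0_AL}
#' is measured from the greater trochanter to the distal end of the
#' unloaded prosthesis, the unaffected-leg length \code{L0_UL} from the
#' greater trochanter to the floor during standing.
#'
#' @param subject_id character label for the athlete.
#' @param body_mass body mass in kg.
#' @param belt_velocity treadmill belt velocity in m/s.
#' @param force_rate force-plate sampling rate in Hz.
#' @param marker_rate motion-capture sampling rate in Hz.
#' @param rsp_model prosthesis model label (e.g. \code{"OBK"}, \code{"OSR"},
#'   \code{"FDM"}).
#' @param stiffness_category integer offset from the manufacturer
#'   recommended stiffness category (-1, 0 or +1).
#' @param height_offset prosthesis height offset from recommended, cm
#'   (-2, 0 or +2).
#' @param first_contact_leg which leg touches down first in the trace,
#'   \code{"AL"} or \code{"UL"}.
#' @param L0_AL,L0_UL standing leg lengths in m (affected / unaffected).
#' @param k_RSP prosthesis stiffness in kN/m.
#' @return An object of class \code{"trial_config"} (a named list).
#' @export
trial_config <- function(subject_id = "S01", body_mass, belt_velocity,
                         force_rate = 1000, marker_rate = 200,
                         rsp_model = "SIM", stiffness_category = 0L,
                         height_offset = 0, first_contact_leg = "AL",
                         L0_AL, L0_UL, k_RSP) {
  cfg <- list(subject_id = as.character(subject_id),
              body_mass = as.numeric(body_mass),
              belt_velocity = as.numeric(belt_velocity),
              force_rate = as.numeric(force_rate),
              marker_rate = as.numeric(marker_rate),
              rsp_model = as.character(rsp_model),
              stiffness_category = as.integer(stiffness_category),
              height_offset = as.numeric(height_offset),
              first_contact_leg = as.character(first_contact_leg),
              L0_AL = as.numeric(L0_AL),
              L0_UL = as.numeric(L0_UL),
              k_RSP = as.numeric(k_RSP))
  class(cfg) <- "trial_config"
  validate_trial_config(cfg)
  cfg
}

validate_trial_config <- function(cfg) {
  need <- c("subject_id", "body_mass", "belt_velocity", "force_rate",
            "marker_rate", "rsp_model", "stiffness_category",
            "height_offset", "first_contact_leg", "L0_AL", "L0_UL",
            "k_RSP")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("configuration error: missing key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  chk_pos <- function(key) {
    v <- cfg[[key]]
    if (!is.finite(v) || v <= 0)
      stop("configuration error: '", key, "' must be a positive number, got ",
           v, call. = FALSE)
  }
  for (key in c("body_mass", "belt_velocity", "force_rate", "marker_rate",
                "L0_AL", "L0_UL", "k_RSP")) chk_pos(key)
  if (!cfg$first_contact_leg %in% c("AL", "UL"))
    stop("configuration error: 'first_contact_leg' must be \"AL\" or \"UL\"",
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.trial_config <- function(x, ...) {
  cat("Trial configuration\n")
  cat(sprintf("  subject %s, mass %.1f kg, belt %.2f m/s\n",
              x$subject_id, x$body_mass, x$belt_velocity))
  cat(sprintf("  RSP %s, stiffness cat %+d, height %+g cm, k_RSP %.1f kN/m\n",
              x$rsp_model, x$stiffness_category, x$height_offset, x$k_RSP))
  cat(sprintf("  L0 AL %.3f m / UL %.3f m, first contact %s\n",
              x$L0_AL, x$L0_UL, x$first_contact_leg))
  cat(sprintf("  rates: forces %g Hz, markers %g Hz\n",
              x$force_rate, x$marker_rate))
  invisible(x)
}

#' Force and marker traces
#'
#' `force_trace()` holds a uniformly sampled 3-component ground reaction
#' force series (medio-lateral, fore-aft with anterior positive, vertical
#' with up positive, all in N). `marker_trace()` holds fore-aft marker
#' positions (m, lab frame) for the two legs.
#'
#' @param time time stamps in s, strictly increasing and uniform.
#' @param f_ml,f_ap,f_v force channels in N.
#' @param rate nominal sampling rate in Hz.
#' @return A data frame of class \code{"force_trace"} with a \code{rate}
#'   attribute.
#' @export
force_trace <- function(time, f_ml, f_ap, f_v, rate) {
  x <- data.frame(time = time, f_ml = f_ml, f_ap = f_ap, f_v = f_v)
  attr(x, "rate") <- rate
  class(x) <- c("force_trace", "data.frame")
  validate_uniform_trace(x, rate, "force")
  x
}

#' @rdname force_trace
#' @param ap_AL,ap_UL fore-aft marker positions (m) for the affected and
#'   unaffected leg.
#' @export
marker_trace <- function(time, ap_AL, ap_UL, rate) {
  x <- data.frame(time = time, ap_AL = ap_AL, ap_UL = ap_UL)
  attr(x, "rate") <- rate
  class(x) <- c("marker_trace", "data.frame")
  validate_uniform_trace(x, rate, "marker")
  x
}

validate_uniform_trace <- function(x, rate, what) {
  n <- nrow(x)
  if (n < 2)
    stop("format error: ", what, " trace needs at least 2 samples",
         call. = FALSE)
  dt <- diff(x$time)
  if (any(dt <= 0))
    stop("format error: ", what, " time stamps must be strictly increasing",
         call. = FALSE)
  if (any(abs(dt - 1 / rate) > 1e-9 + 1e-9 / rate))
    stop("format error: ", what, " time grid is not uniform at ", rate, " Hz",
         call. = FALSE)
  if (any(!is.finite(as.matrix(x[-1]))))
    stop("data error: ", what, " trace contains non-finite values",
         call. = FALSE)
  invisible(x)
}

# full-precision numeric formatting so CSV round trips are exact
fmt_num <- function(x) sprintf("%.17g", x)

write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Read a session directory
#'
#' A session is one treadmill trial stored as a directory containing
#' \code{config} (flat \code{key: value} text), \code{forces.csv}
#' (\code{time_s,f_ml_N,f_ap_N,f_v_N}) and optionally \code{markers.csv}
#' (\code{time_s,ap_AL_m,ap_UL_m}). All stored values are SI; body-weight
#' normalisation happens downstream, never in storage.
#'
#' @param path session directory.
#' @return A list with elements \code{config} (\code{trial_config}),
#'   \code{forces} (\code{force_trace}) and \code{markers}
#'   (\code{marker_trace} or \code{NULL} when no marker file is present).
#' @seealso [write_session()], [generate_session()]
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) stop("session directory not found: ", path,
                              call. = FALSE)
  cfg_path <- file.path(path, "config")
  f_path <- file.path(path, "forces.csv")
  if (!file.exists(cfg_path)) stop("configuration error: missing config file",
                                   call. = FALSE)
  if (!file.exists(f_path)) stop("format error: missing forces.csv",
                                 call. = FALSE)
  cfg <- read_config(cfg_path)
  fr <- utils::read.csv(f_path, colClasses = "numeric")
  expect_cols(fr, c("time_s", "f_ml_N", "f_ap_N", "f_v_N"), "forces.csv")
  forces <- force_trace(fr$time_s, fr$f_ml_N, fr$f_ap_N, fr$f_v_N,
                        rate = cfg$force_rate)
  markers <- NULL
  m_path <- file.path(path, "markers.csv")
  if (file.exists(m_path)) {
    mk <- utils::read.csv(m_path, colClasses = "numeric")
    expect_cols(mk, c("time_s", "ap_AL_m", "ap_UL_m"), "markers.csv")
    markers <- marker_trace(mk$time_s, mk$ap_AL_m, mk$ap_UL_m,
                            rate = cfg$marker_rate)
  }
  list(config = cfg, forces = forces, markers = markers)
}

expect_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("format error: ", what, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(df)
}

read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hit <- regexpr(":", lines, fixed = TRUE)
  if (any(hit < 0))
    stop("configuration error: line without 'key: value': ",
         lines[which(hit < 0)[1]], call. = FALSE)
  keys <- trimws(substr(lines, 1, hit - 1))
  vals <- trimws(substr(lines, hit + 1, nchar(lines)))
  cfg <- stats::setNames(as.list(vals), keys)
  num_keys <- c("body_mass", "belt_velocity", "force_rate", "marker_rate",
                "height_offset", "L0_AL", "L0_UL", "k_RSP")
  for (key in intersect(num_keys, names(cfg))) {
    v <- suppressWarnings(as.numeric(cfg[[key]]))
    if (is.na(v))
      stop("configuration error: key '", key, "' is not numeric: ",
           cfg[[key]], call. = FALSE)
    cfg[[key]] <- v
  }
  if ("stiffness_category" %in% names(cfg))
    cfg$stiffness_category <- as.integer(cfg$stiffness_category)
  class(cfg) <- "trial_config"
  validate_trial_config(cfg)
  cfg
}

#' Write a session directory
#'
#' Inverse of [read_session()]: writes \code{config}, \code{forces.csv}
#' and (when supplied) \code{markers.csv} with full numeric precision so
#' that read/write round trips are exact.
#'
#' @param config a [trial_config()].
#' @param forces a [force_trace()].
#' @param markers optional [marker_trace()].
#' @param path directory to create (existing files are overwritten).
#' @return \code{path}, invisibly.
#' @export
write_session <- function(config, forces, markers = NULL, path) {
  validate_trial_config(config)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  keys <- c("subject_id", "body_mass", "belt_velocity", "force_rate",
            "marker_rate", "rsp_model", "stiffness_category",
            "height_offset", "first_contact_leg", "L0_AL", "L0_UL", "k_RSP")
  val <- vapply(keys, function(k) {
    v <- config[[k]]
    if (is.numeric(v) && !is.integer(v)) fmt_num(v) else as.character(v)
  }, character(1))
  writeLines(paste0(keys, ": ", val), file.path(path, "config"))
  write_csv_exact(data.frame(time_s = forces$time, f_ml_N = forces$f_ml,
                             f_ap_N = forces$f_ap, f_v_N = forces$f_v),
                  file.path(path, "forces.csv"))
  if (!is.null(markers))
    write_csv_exact(data.frame(time_s = markers$time, ap_AL_m = markers$ap_AL,
                               ap_UL_m = markers$ap_UL),
                    file.path(path, "markers.csv"))
  invisible(path)
}

#' Results-table vocabulary
#'
#' Long-format results rows are keyed by
#' (\code{subject}, \code{rsp_model}, \code{stiffness_category},
#' \code{height_offset}, \code{velocity}, \code{variable}, \code{leg})
#' with one numeric \code{value}. \code{leg} is \code{"AL"}, \code{"UL"}
#' or \code{"both"} (the two-leg average). The variable vocabulary covers
#' the spatiotemporal, force and spring-mass metrics; symmetry indices
#' use the \code{si_} prefix on a base variable name.
#'
#' @return Character vector of admissible base variable names.
#' @export
results_vocabulary <- function() {
  c("step_frequency", "step_time", "contact_time", "aerial_time",
    "contact_length", "stance_avg_vgrf", "stance_avg_vgrf_bw",
    "peak_vgrf", "peak_resultant_grf", "leg_stiffness", "delta_rsp",
    "contact_angle", "delta_y", "delta_L", "vmax")
}

check_results_vocab <- function(variable) {
  base <- sub("^si_", "", variable)
  bad <- unique(variable[!base %in% results_vocabulary()])
  if (length(bad))
    stop("vocabulary error: unknown variable name(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(variable)
}

results_key_cols <- function() {
  c("subject", "rsp_model", "stiffness_category", "height_offset",
    "velocity", "variable", "leg")
}

#' Write and read long-format results tables
#'
#' `write_results()` enforces the [results_vocabulary()], writes a
#' deterministic column order, and sorts rows by the full key so that
#' repeated runs produce byte-identical files; `read_results()` reads
#' such a file back.
#'
#' @param rows data frame with the key columns
#'   \code{subject, rsp_model, stiffness_category, height_offset,
#'   velocity, variable, leg} plus \code{value}.
#' @param path CSV file path.
#' @return \code{write_results()}: \code{path} invisibly;
#'   \code{read_results()}: the rows as a data frame.
#' @export
write_results <- function(rows, path) {
  cols <- c(results_key_cols(), "value")
  if (nrow(rows) == 0 && !all(cols %in% names(rows)))
    rows <- stats::setNames(
      data.frame(character(), character(), integer(), numeric(), numeric(),
                 character(), character(), numeric(),
                 stringsAsFactors = FALSE), cols)
  expect_cols(rows, cols, "results table")
  rows <- rows[cols]
  check_results_vocab(rows$variable)
  key <- do.call(paste, c(rows[results_key_cols()], sep = "\r"))
  if (anyDuplicated(key))
    stop("results table has duplicate keys", call. = FALSE)
  rows <- rows[order(key), , drop = FALSE]
  write_csv_exact(rows, path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    subject = "character", rsp_model = "character",
    stiffness_category = "integer", height_offset = "numeric",
    velocity = "numeric", variable = "character", leg = "character",
    value = "numeric"))
  check_results_vocab(df$variable)
  df
}
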