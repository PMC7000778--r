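#' Linear mixed model with a subject random intercept
#'
#' Repeated-measures analysis of trial-level outcomes across prosthesis
#' configurations: fixed effects for the terms of interest, a random
#' intercept per subject to absorb between-athlete variability.
#' Estimation is delegated to \code{lmerTest::lmer} (REML, Satterthwaite
#' p-values); this wrapper pins down the encoding (prosthesis model as a
#' categorical factor, stiffness/height/velocity as continuous), checks
#' the fixed design for rank deficiency, and extracts a compact result.
#'
#' @param data data frame of trial-level observations.
#' @param response name of the response column.
#' @param fixed character vector of fixed-effect column names. Columns
#'   named in \code{categorical} (default \code{"rsp_model"}) are coerced
#'   to factors; \code{reference} picks their reference level.
#' @param group name of the grouping column (random intercept), default
#'   \code{"subject"}.
#' @param categorical columns to treat as categorical.
#' @param reference optional named character vector of reference levels,
#'   e.g. \code{c(rsp_model = "FDM")}.
#' @return Object of class \code{"lmm_fit"}: list with \code{coefficients}
#'   (data frame: term, estimate, se, df, t, p), \code{ranef_var}
#'   (random-intercept variance), \code{sigma2} (residual variance),
#'   \code{n_obs}, \code{n_groups}, \code{formula} and \code{model} (the
#'   underlying fit).
#' @export
fit_lmm <- function(data, response, fixed, group = "subject",
                    categorical = "rsp_model", reference = NULL) {
  cols <- c(response, fixed, group)
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (v in intersect(categorical, fixed)) {
    data[[v]] <- factor(data[[v]])
    if (!is.null(reference) && v %in% names(reference))
      data[[v]] <- stats::relevel(data[[v]], ref = reference[[v]])
  }
  data[[group]] <- factor(data[[group]])
  if (nlevels(data[[group]]) < 2)
    stop("design error: random-intercept grouping needs at least 2 ",
         "subjects", call. = FALSE)
  fixed_fml <- stats::reformulate(fixed, response = response)
  X <- stats::model.matrix(fixed_fml, data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design error: fixed-effects design is rank deficient; aliased ",
         "term(s): ", paste(aliased, collapse = ", "), call. = FALSE)
  }
  fml <- stats::as.formula(paste(response, "~",
                                 paste(fixed, collapse = " + "),
                                 "+ (1 |", group, ")"))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(fml, data = data)))
  ct <- as.data.frame(stats::coef(summary(fit)))
  coefs <- data.frame(term = rownames(ct), estimate = ct[["Estimate"]],
                      se = ct[["Std. Error"]], df = ct[["df"]],
                      t = ct[["t value"]], p = ct[["Pr(>|t|)"]],
                      row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- list(coefficients = coefs,
              ranef_var = vc$vcov[vc$grp == group][1],
              sigma2 = vc$vcov[vc$grp == "Residual"][1],
              n_obs = stats::nobs(fit),
              n_groups = nlevels(data[[group]]),
              formula = fml, model = fit)
  class(out) <- "lmm_fit"
  out
}

#' @export
print.lmm_fit <- function(x, digits = 4, ...) {
  cat("Linear mixed model:", deparse(x$formula), "\n")
  cat(sprintf("  %d observations, %d subjects; random-intercept var %.4g, residual var %.4g\n",
              x$n_obs, x$n_groups, x$ranef_var, x$sigma2))
  df <- x$coefficients
  df[-1] <- lapply(df[-1], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Configuration analysis of maximum running velocity
#'
#' Runs the study's mixed-model battery on trial-level data: (1) v_max
#' against prosthesis model, stiffness category and height offset;
#' (2) v_max against prosthesis model, measured prosthesis stiffness
#' (kN/m) and height offset; and, for any requested biomechanical
#' variables, the variable against prosthesis model with velocity as a
#' covariate ("while accounting for differences in v_max"). Each model
#' takes a subject random intercept. Pairwise prosthesis-model contrasts
#' are obtained by refitting with each model as the reference level and
#' Bonferroni-adjusting over the number of pairs; the global reference
#' level is the model with the slowest group-mean v_max, so faster
#' models appear as positive coefficients and positive percent
#' differences.
#'
#' @param data data frame with one row per subject x configuration:
#'   columns \code{subject}, \code{rsp_model}, \code{stiffness_category},
#'   \code{height_offset}, \code{vmax}, optionally \code{k_rsp} and
#'   biomechanical variable columns.
#' @param biomech_vars optional character vector of variable columns to
#'   analyse with velocity as covariate.
#' @return Object of class \code{"vmax_analysis"}: list with
#'   \code{vmax_category} and (when \code{k_rsp} is present)
#'   \code{vmax_actual} \code{lmm_fit}s, \code{model_contrasts} (data
#'   frame of pairwise prosthesis-model contrasts on v_max with
#'   Bonferroni-adjusted p), \code{percent_differences} (model-level
#'   mean v_max contrasts), and \code{biomech} (list of \code{lmm_fit}s).
#' @export
analyze_vmax <- function(data, biomech_vars = NULL) {
  stopifnot(all(c("subject", "rsp_model", "vmax") %in% names(data)))
  cells <- table(data$subject, data$rsp_model)
  if (any(cells == 0))
    message("unbalanced design: some subject/model cells are empty; ",
            "mixed models proceed on the available trials")
  means <- sort(tapply(data$vmax, data$rsp_model, mean))
  ref <- names(means)[1]                      # slowest model is reference
  varying <- function(cols)                   # constant columns are aliased
    cols[vapply(cols, function(cl)
      cl %in% names(data) && length(unique(data[[cl]])) > 1, logical(1))]
  fixed1 <- varying(c("rsp_model", "stiffness_category", "height_offset"))
  m1 <- fit_lmm(data, "vmax", fixed1, reference = c(rsp_model = ref))
  m2 <- NULL
  if ("k_rsp" %in% names(data)) {
    fixed2 <- varying(c("rsp_model", "k_rsp", "height_offset"))
    m2 <- fit_lmm(data, "vmax", fixed2, reference = c(rsp_model = ref))
  }
  # pairwise model contrasts on vmax by reference rotation
  mods <- names(means)
  pairs <- utils::combn(mods, 2, simplify = FALSE)
  contr <- do.call(rbind, lapply(pairs, function(pr) {
    # contrast pr[2] (faster) relative to pr[1] (slower by group mean)
    f <- fit_lmm(data, "vmax", fixed1, reference = c(rsp_model = pr[1]))
    term <- paste0("rsp_model", pr[2])
    row <- f$coefficients[f$coefficients$term == term, ]
    data.frame(model = pr[2], reference = pr[1], beta = row$estimate,
               p = row$p, stringsAsFactors = FALSE)
  }))
  contr$p_adj <- bonferroni(contr$p, m = nrow(contr))
  pct <- do.call(rbind, lapply(pairs, function(pr) {
    data.frame(model = pr[2], reference = pr[1],
               pct_diff = percent_difference(means[[pr[2]]], means[[pr[1]]]),
               stringsAsFactors = FALSE)
  }))
  biomech <- NULL
  if (!is.null(biomech_vars)) {
    biomech <- lapply(stats::setNames(biomech_vars, biomech_vars),
                      function(v)
                        fit_lmm(data, v, c("rsp_model", "vmax"),
                                reference = c(rsp_model = ref)))
  }
  out <- list(vmax_category = m1, vmax_actual = m2,
              model_contrasts = contr, percent_differences = pct,
              model_means = means, reference = ref, biomech = biomech)
  class(out) <- "vmax_analysis"
  out
}

#' @export
print.vmax_analysis <- function(x, digits = 4, ...) {
  cat("Maximum-velocity configuration analysis\n")
  cat("group-mean vmax by prosthesis model (m/s):\n")
  print(signif(x$model_means, digits))
  cat("pairwise model contrasts (Bonferroni-adjusted):\n")
  df <- x$model_contrasts
  df$pct_diff <- x$percent_differences$pct_diff
  df[c("beta", "p", "p_adj")] <- lapply(df[c("beta", "p", "p_adj")],
                                        signif, digits = digits)
  print(df, row.names = FALSE)
  cat("\nv_max ~ model + stiffness category + height:\n")
  print(x$vmax_category, digits = digits)
  if (!is.null(x$vmax_actual)) {
    cat("\nv_max ~ model + measured stiffness + height:\n")
    print(x$vmax_actual, digits = digits)
  }
  invisible(x)
}
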