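#' Random-intercept mixed model for one hormone
#'
#' Fits, by REML, a linear mixed model for one hormone's concentrations
#' with the requested covariates as fixed effects and a participant-level
#' random intercept capturing individual differences:
#' `value ~ covariates + (1 | participant)`. The returned variance
#' components feed [adjusted_icc()], the reliability of the hormone
#' conditional on the covariates.
#'
#' @param cohort Long-format cohort table (see [simulate_cohort()] for the
#'   column contract) or a data.frame with columns `participant_id`,
#'   `value` and the covariates.
#' @param response Hormone name selecting rows `hormone == response`;
#'   ignored (with a message) when `cohort` has no `hormone` column.
#' @param covariates Character vector of covariate keys (`glucose`,
#'   `hba1c`, `activity`, `diet`, `weight`) or literal column names; may
#'   be empty for the unconditional model.
#' @param log_transform Model `log(value)` instead of `value`; requires
#'   strictly positive values.
#' @return Object of class `variance_components`: `sigma2_between`,
#'   `sigma2_residual`, fixed-effect `beta`, REML log-likelihood,
#'   `converged` flag with any optimizer `messages`, and the underlying
#'   `lme4` fit in `$fit`. Missing covariate or response cells fail
#'   loudly (complete-case analysis; no imputation).
#' @export
fit_random_intercept_lmm <- function(cohort, response = NULL,
                                     covariates = character(0),
                                     log_transform = FALSE) {
  cohort <- as.data.frame(cohort)
  if ("hormone" %in% names(cohort) && !is.null(response)) {
    cohort <- cohort[cohort$hormone == response, , drop = FALSE]
    if (nrow(cohort) == 0L) {
      stop("no rows for hormone ", sQuote(response), call. = FALSE)
    }
  }
  value_col <- if ("value_pgml" %in% names(cohort)) "value_pgml" else "value"
  if (!value_col %in% names(cohort)) {
    stop("cohort has neither `value_pgml` nor `value` column", call. = FALSE)
  }
  if (!"participant_id" %in% names(cohort)) {
    stop("cohort has no `participant_id` column", call. = FALSE)
  }
  cov_cols <- resolve_covariates(covariates, names(cohort))

  d <- data.frame(participant_id = factor(cohort$participant_id),
                  value = cohort[[value_col]])
  for (cc in cov_cols) d[[cc]] <- cohort[[cc]]
  if (anyNA(d)) {
    bad <- names(d)[vapply(d, anyNA, logical(1))]
    stop("missing values in ", paste(bad, collapse = ", "),
         "; complete cases are required (no imputation is performed)",
         call. = FALSE)
  }
  counts <- table(d$participant_id)
  if (any(counts < 2L)) {
    stop("every participant needs at least 2 observations; offending: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  if (log_transform) {
    if (any(d$value <= 0)) {
      stop("log transform requires strictly positive values", call. = FALSE)
    }
    d$value <- log(d$value)
  }

  rhs <- if (length(cov_cols) > 0L) paste(cov_cols, collapse = " + ") else "1"
  form <- stats::as.formula(paste("value ~", rhs, "+ (1 | participant_id)"))
  fit <- lme4::lmer(form, data = d, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))

  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_between <- vc$vcov[vc$grp == "participant_id"][1]
  sigma2_residual <- vc$vcov[vc$grp == "Residual"][1]
  messages <- unlist(fit@optinfo$conv$lme4$messages) %||% character(0)
  structure(
    list(sigma2_between = sigma2_between,
         sigma2_residual = sigma2_residual,
         beta = lme4::fixef(fit),
         reml_loglik = as.numeric(stats::logLik(fit)),
         converged = length(messages) == 0L,
         messages = messages,
         covariates = cov_cols,
         n_participants = nlevels(d$participant_id),
         n_obs = nrow(d),
         fit = fit),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Random-intercept model variance components (REML)\n")
  cat(sprintf("  between-participant variance: %.6g\n", x$sigma2_between))
  cat(sprintf("  residual variance:            %.6g\n", x$sigma2_residual))
  cat(sprintf("  fixed effects: %s\n",
              paste(sprintf("%s=%.4g", names(x$beta), x$beta),
                    collapse = ", ")))
  cat(sprintf("  REML logLik %.4f; converged: %s\n",
              x$reml_loglik, x$converged))
  if (!x$converged) cat("  optimizer messages: ",
                        paste(x$messages, collapse = "; "), "\n")
  invisible(x)
}

#' Covariate-adjusted ICC from mixed-model variance components
#'
#' The adjusted ICC is the variance ratio
#' `sigma^2_between / (sigma^2_between + sigma^2_residual)` from a
#' random-intercept model with covariates as fixed effects — reliability of
#' the measurement conditional on the covariates. The confidence interval
#' is a seeded parametric bootstrap: simulate response vectors from the
#' fitted model, refit, and take the percentile interval of the bootstrap
#' variance ratios.
#'
#' @param vc A `variance_components` from [fit_random_intercept_lmm()].
#' @param bootstrap_reps Number of parametric-bootstrap refits for the CI
#'   (default 500); 0 skips the CI (returned bounds `NA`).
#' @param seed Seed for the bootstrap stream.
#' @param conf_level Confidence level, default 0.95.
#' @return An `icc_estimate` with `method = "adjusted_lmm"`; its `p_value`
#'   is `NA` (no significance test is defined for the ratio here). Both
#'   variance components equal to zero yield a degenerate flagged result.
#' @export
adjusted_icc <- function(vc, bootstrap_reps = 500, seed = NULL,
                         conf_level = 0.95) {
  stopifnot(inherits(vc, "variance_components"))
  assert_scalar_number(bootstrap_reps, "bootstrap_reps", min = 0)
  if (!vc$converged) {
    warning("variance components come from a non-converged fit; ",
            "adjusted ICC may be unreliable", call. = FALSE)
  }
  tot <- vc$sigma2_between + vc$sigma2_residual
  n <- vc$n_participants
  k <- max(2L, as.integer(round(vc$n_obs / max(n, 1L))))
  if (tot <= 0) {
    return(new_icc_estimate(NA_real_, NA_real_, NA_real_, NA_real_,
                            "adjusted_lmm", n, k, conf_level,
                            degenerate = TRUE,
                            extra = list(variance_components = vc)))
  }
  est <- vc$sigma2_between / tot

  ci <- c(NA_real_, NA_real_)
  boot <- NULL
  if (bootstrap_reps > 0) {
    if (!is.null(seed)) set.seed(substream_seed(seed, "adjusted_icc_bootstrap"))
    sims <- stats::simulate(vc$fit, nsim = as.integer(bootstrap_reps))
    ratios <- vapply(sims, function(y) {
      r <- tryCatch({
        refit_i <- suppressWarnings(suppressMessages(lme4::refit(vc$fit, y)))
        v <- as.data.frame(lme4::VarCorr(refit_i))
        s2b <- v$vcov[v$grp == "participant_id"][1]
        s2e <- v$vcov[v$grp == "Residual"][1]
        if (s2b + s2e <= 0) NA_real_ else s2b / (s2b + s2e)
      }, error = function(e) NA_real_)
      r
    }, numeric(1))
    boot <- ratios[!is.na(ratios)]
    if (length(boot) >= 2L) {
      alpha <- 1 - conf_level
      ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2),
                                   type = 7))
    }
  }
  new_icc_estimate(est, ci[1], ci[2], NA_real_, "adjusted_lmm", n, k,
                   conf_level,
                   extra = list(variance_components = vc,
                                bootstrap_reps = as.integer(bootstrap_reps),
                                bootstrap_kept = length(boot %||% numeric(0)),
                                seed = seed))
}
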