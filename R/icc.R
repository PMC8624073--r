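#' Two-way ANOVA decomposition for a complete ratings matrix
#'
#' Decomposes an `n x k` participant-by-assessment matrix into
#' between-participant (rows), between-assessment (columns) and residual
#' sums of squares — the machinery behind the two-way absolute-agreement
#' intra-class correlation. The identity
#' `SS_total = SS_rows + SS_cols + SS_error` holds exactly.
#'
#' @param data A [paired_matrix()] or complete numeric `n x k` matrix,
#'   `n >= 2`, `k >= 2`, no missing cells.
#' @return Object of class `anova_decomposition`: mean squares `MSR`,
#'   `MSC`, `MSE`, sums of squares, degrees of freedom, `n` and `k`.
#' @export
anova_decomposition <- function(data) {
  x <- unclass(as.matrix(data))
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("decomposition requires a complete, finite numeric matrix",
         call. = FALSE)
  }
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need at least a 2 x 2 matrix", call. = FALSE)
  gm <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_rows <- k * sum((row_means - gm)^2)
  ss_cols <- n * sum((col_means - gm)^2)
  ss_total <- sum((x - gm)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  if (ss_error < 0) ss_error <- max(ss_error, 0)  # guard tiny negative round-off
  df_rows <- n - 1L; df_cols <- k - 1L; df_error <- (n - 1L) * (k - 1L)
  structure(
    list(MSR = ss_rows / df_rows, MSC = ss_cols / df_cols,
         MSE = ss_error / df_error,
         ss = c(rows = ss_rows, cols = ss_cols, error = ss_error,
                total = ss_total),
         df = c(rows = df_rows, cols = df_cols, error = df_error),
         n = n, k = k),
    class = "anova_decomposition"
  )
}

new_icc_estimate <- function(estimate, ci_low, ci_high, p_value, method,
                             n, k, conf_level, degenerate = FALSE,
                             extra = list()) {
  category <- if (is.na(estimate)) NA_character_ else classify_reliability(estimate)
  structure(
    c(list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
           p_value = p_value, category = category, method = method,
           n = n, k = k, conf_level = conf_level, degenerate = degenerate),
      extra),
    class = "icc_estimate"
  )
}

#' @export
print.icc_estimate <- function(x, ...) {
  lab <- switch(x$method, icc_a1 = "ICC(A,1)", adjusted_lmm = "adjusted ICC",
                x$method)
  if (isTRUE(x$degenerate)) {
    cat(sprintf("%s: degenerate input (no variance); no estimate\n", lab))
    return(invisible(x))
  }
  cat(sprintf("%s = %.3f [%s%% CI %.3f, %.3f], %s reliability",
              lab, x$estimate, format(100 * x$conf_level),
              x$ci_low, x$ci_high, x$category))
  if (!is.na(x$p_value %||% NA)) cat(sprintf(", p = %.4g", x$p_value))
  cat(sprintf("  (n = %d, k = %d)\n", x$n, x$k))
  invisible(x)
}

#' Absolute-agreement intra-class correlation ICC(A,1)
#'
#' Single-measurement, absolute-agreement ICC under the two-way model:
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`,
#' where MSR, MSC, MSE are the participants, assessments and residual mean
#' squares. Confidence limits use the F-based procedure with a
#' Satterthwaite approximation for the denominator degrees of freedom; the
#' p-value tests ICC = 0 via `F = MSR / MSE` on `(n-1, (n-1)(k-1))`
#' degrees of freedom.
#'
#' Degenerate inputs (zero total variance) yield a flagged result with no
#' numeric estimate. Perfect absolute agreement with distinct participants
#' (MSC = MSE = 0, MSR > 0) yields estimate 1 with a point CI. Negative
#' estimates are reported as computed (not truncated) and classified as
#' poor.
#'
#' @param data A [paired_matrix()] or complete numeric `n x k` matrix.
#' @param conf_level Confidence level, default 0.95.
#' @return An `icc_estimate` with fields `estimate`, `ci_low`, `ci_high`,
#'   `p_value`, `category`, `method = "icc_a1"`, plus the underlying
#'   [anova_decomposition()] in `$anova`.
#' @references McGraw, K.O. & Wong, S.P. (1996). Forming inferences about
#'   some intraclass correlation coefficients. Psychological Methods, 1,
#'   30-46.
#' @export
icc_a1 <- function(data, conf_level = 0.95) {
  assert_scalar_number(conf_level, "conf_level", min = 0, strict_min = TRUE)
  if (conf_level >= 1) stop("`conf_level` must be in (0, 1)", call. = FALSE)
  a <- anova_decomposition(data)
  n <- a$n; k <- a$k
  alpha <- 1 - conf_level
  tol <- 1e-12 * (1 + a$ss[["total"]])

  if (a$ss[["total"]] <= tol) {
    return(new_icc_estimate(NA_real_, NA_real_, NA_real_, NA_real_, "icc_a1",
                            n, k, conf_level, degenerate = TRUE,
                            extra = list(anova = a)))
  }
  if (a$MSE <= tol && a$MSC <= tol) {
    # perfect absolute agreement between columns, distinct rows
    return(new_icc_estimate(1, 1, 1, 0, "icc_a1", n, k, conf_level,
                            extra = list(anova = a)))
  }

  est <- (a$MSR - a$MSE) /
    (a$MSR + (k - 1) * a$MSE + (k / n) * (a$MSC - a$MSE))

  # F-based interval with Satterthwaite df (two-way agreement, single score)
  aa <- (k * est) / (n * (1 - est))
  bb <- 1 + (k * est * (n - 1)) / (n * (1 - est))
  v <- (aa * a$MSC + bb * a$MSE)^2 /
    ((aa * a$MSC)^2 / (k - 1) + (bb * a$MSE)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (a$MSR - f_l * a$MSE) /
    (f_l * (k * a$MSC + (k * n - k - n) * a$MSE) + n * a$MSR)
  upper <- n * (f_u * a$MSR - a$MSE) /
    (k * a$MSC + (k * n - k - n) * a$MSE + n * f_u * a$MSR)

  p <- if (a$MSE <= tol) 0 else
    stats::pf(a$MSR / a$MSE, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)

  new_icc_estimate(est, min(lower, upper), max(lower, upper), p, "icc_a1",
                   n, k, conf_level, extra = list(anova = a))
}

#' Classify an ICC estimate into reliability categories
#'
#' Interpretation bands: below 0.5 poor, 0.5 to below 0.75 moderate, 0.75
#' to 0.90 good, above 0.90 excellent. Intervals are left-closed, with 0.90
#' itself classified as good (only estimates strictly above 0.90 are
#' excellent); negative estimates are poor. A total, monotone step function
#' on estimates up to 1.
#'
#' @param estimate Numeric vector of ICC estimates, each <= 1.
#' @return Character vector of categories among
#'   `c("poor", "moderate", "good", "excellent")`.
#' @examples
#' classify_reliability(c(0.99, 0.89, 0.51, 0.29))
#' @export
classify_reliability <- function(estimate) {
  if (!is.numeric(estimate)) stop("`estimate` must be numeric", call. = FALSE)
  if (any(!is.na(estimate) & estimate > 1)) {
    stop("ICC estimates cannot exceed 1", call. = FALSE)
  }
  out <- rep(NA_character_, length(estimate))
  ok <- !is.na(estimate)
  out[ok & estimate < 0.5] <- "poor"
  out[ok & estimate >= 0.5 & estimate < 0.75] <- "moderate"
  out[ok & estimate >= 0.75 & estimate <= 0.90] <- "good"
  out[ok & estimate > 0.90] <- "excellent"
  out
}
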