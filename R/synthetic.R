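#' Hormone simulation preset
#'
#' Marginal and reliability parameters for one simulated hormone. Observed
#' concentrations are log-normal: on the log scale a participant carries a
#' latent level `b_i ~ N(0, sigma_b^2)` and each assessment adds residual
#' noise `e_it ~ N(0, sigma_e^2)`, with
#' `sigma_b^2 / (sigma_b^2 + sigma_e^2) = true_icc` and
#' `sigma_b^2 + sigma_e^2 = log_sd_total^2`. The observed value is
#' `exp(log_median + b_i + covariate effects + e_it)` pg/mL, subsequently
#' passed through the assay censoring rules ([apply_assay_limits()]).
#'
#' @param name Hormone name.
#' @param log_median Log of the median concentration (log-pg/mL).
#' @param log_sd_total Total SD on the log scale; must be > 0.
#' @param true_icc True intra-class correlation in `[0, 1)`; 1 is rejected
#'   (degenerate zero residual variance).
#' @param detection_limit,upper_standard,dilution_factor Assay settings, as
#'   in [assay_config()].
#' @return Object of class `hormone_spec`.
#' @export
hormone_spec <- function(name, log_median, log_sd_total, true_icc,
                         detection_limit = 0, upper_standard = NULL,
                         dilution_factor = 1) {
  assert_scalar_number(log_median, "log_median")
  assert_scalar_number(log_sd_total, "log_sd_total", min = 0, strict_min = TRUE)
  assert_scalar_number(true_icc, "true_icc", min = 0)
  if (true_icc >= 1) {
    stop("`true_icc` must be < 1: residual variance would be degenerate",
         call. = FALSE)
  }
  assay <- assay_config(name, detection_limit = detection_limit,
                        upper_standard = upper_standard,
                        dilution_factor = dilution_factor)
  structure(
    list(name = name, log_median = log_median, log_sd_total = log_sd_total,
         true_icc = true_icc, assay = assay),
    class = "hormone_spec"
  )
}

# Log-scale SD from a median/quartile summary of a log-normal marginal:
# method of quantiles, sd = log(q3/q1) / (2 * qnorm(0.75)).
log_sd_from_iqr <- function(q1, q3) log(q3 / q1) / (2 * stats::qnorm(0.75))

#' Default hormone presets for the four-hormone fasting panel
#'
#' Log-normal marginals located at the baseline medians of the panel
#' (ghrelin 771.92, leptin 5056.90, GLP-1 168.78, PP 37.29 pg/mL) with
#' log-scale spread derived from the printed interquartile ranges by the
#' method of quantiles, and true ICC presets 0.99 (ghrelin), 0.51 (leptin),
#' 0.79 (GLP-1), 0.89 (PP). Assay dilution factors and the PP upper
#' standard follow [default_assay_configs()].
#'
#' @return Named list of [hormone_spec()] objects.
#' @export
default_hormone_specs <- function() {
  list(
    ghrelin = hormone_spec("ghrelin", log_median = log(771.92),
                           log_sd_total = log_sd_from_iqr(662.63, 898.21),
                           true_icc = 0.99, dilution_factor = 10),
    leptin  = hormone_spec("leptin", log_median = log(5056.90),
                           log_sd_total = log_sd_from_iqr(3704.31, 8132.15),
                           true_icc = 0.51, dilution_factor = 50),
    GLP1    = hormone_spec("GLP1", log_median = log(168.78),
                           log_sd_total = log_sd_from_iqr(203.21, 315.32),
                           true_icc = 0.79, dilution_factor = 6),
    PP      = hormone_spec("PP", log_median = log(37.29),
                           log_sd_total = log_sd_from_iqr(12.49, 289.28),
                           true_icc = 0.89, dilution_factor = 2,
                           upper_standard = 2276.02)
  )
}

#' Covariate simulation settings
#'
#' Marginal parameters per assessment plus optional effect sizes on the
#' log-hormone scale. Effects are applied to the covariate centered at its
#' baseline mean, so switching an effect on does not move the hormone's
#' median. Default effect sizes are 0 (pure reliability structure).
#'
#' @param name Covariate key; one of `glucose`, `hba1c`, `activity`,
#'   `diet`, `weight`.
#' @param dist `"normal"` or `"lognormal"`.
#' @param bl,fu Length-2 numeric `c(location, scale)` per assessment; for
#'   `"lognormal"` these are meanlog/sdlog.
#' @param effects Named numeric vector of slopes per hormone on the
#'   log-hormone scale, per unit of (centered) covariate.
#' @param round_to Optional rounding unit for the simulated values (e.g. 1
#'   for integer index points), or `NULL`.
#' @param clamp Optional `c(lo, hi)` range for the simulated values.
#' @return Object of class `covariate_spec`.
#' @export
covariate_spec <- function(name, dist = c("normal", "lognormal"), bl, fu = bl,
                           effects = numeric(0), round_to = NULL, clamp = NULL) {
  dist <- match.arg(dist)
  stopifnot(length(bl) == 2L, length(fu) == 2L, bl[2] >= 0, fu[2] >= 0)
  structure(
    list(name = name, dist = dist, bl = as.numeric(bl), fu = as.numeric(fu),
         effects = effects, round_to = round_to, clamp = clamp),
    class = "covariate_spec"
  )
}

#' Default covariate settings emulating a normal-weight adult cohort
#'
#' Glucose (mmol/L) and HbA1c (%) are normal with assessment-specific means
#' and SDs (4.90 +/- 0.66 vs 5.22 +/- 0.54; 5.37 +/- 0.19 vs 5.41 +/- 0.26);
#' total physical activity (h/week) is log-normal around a median of about
#' 11.5 h/week; the dietary habits index is integer-valued around 82 points
#' (clamped to `[0, 127]`); body weight (kg) is centered at 67 kg at
#' baseline, with follow-up weight equal to baseline plus a drift term
#' governed by `weight_drift_sd` in [simulation_config()]. All effect sizes
#' default to 0.
#'
#' @return Named list of [covariate_spec()] objects.
#' @export
default_covariate_specs <- function() {
  list(
    glucose  = covariate_spec("glucose", "normal",
                              bl = c(4.90, 0.66), fu = c(5.22, 0.54)),
    hba1c    = covariate_spec("hba1c", "normal",
                              bl = c(5.37, 0.19), fu = c(5.41, 0.26)),
    activity = covariate_spec("activity", "lognormal",
                              bl = c(log(11.54), log_sd_from_iqr(4.57, 16.70)),
                              fu = c(log(10.53), log_sd_from_iqr(8.53, 13.52))),
    diet     = covariate_spec("diet", "normal",
                              bl = c(82, (88 - 79) / (2 * stats::qnorm(0.75))),
                              fu = c(83, (90 - 81) / (2 * stats::qnorm(0.75))),
                              round_to = 1, clamp = c(0, 127)),
    weight   = covariate_spec("weight", "normal",
                              bl = c(67, (76.25 - 57) / (2 * stats::qnorm(0.75))),
                              clamp = c(35, 200))
  )
}

#' Simulation configuration
#'
#' @param n_participants Number of participants (>= 2); default 17, the
#'   study-design size this generator emulates.
#' @param n_assessments Number of repeated assessments (>= 2); default 2
#'   (baseline and follow-up).
#' @param hormone_specs Named list of [hormone_spec()]; defaults to the
#'   four-hormone panel presets.
#' @param covariate_specs Named list of [covariate_spec()].
#' @param weight_drift_sd SD (kg) of the between-assessment weight change;
#'   0 means perfectly stable weight.
#' @param seed Master seed; fully determines the output. Per-hormone
#'   substreams are derived from it deterministically by hormone name, so
#'   adding a hormone does not perturb the others.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 17, n_assessments = 2,
                              hormone_specs = default_hormone_specs(),
                              covariate_specs = default_covariate_specs(),
                              weight_drift_sd = 0, seed = 1) {
  assert_scalar_number(n_participants, "n_participants", min = 2)
  assert_scalar_number(n_assessments, "n_assessments", min = 2)
  assert_scalar_number(weight_drift_sd, "weight_drift_sd", min = 0)
  assert_scalar_number(seed, "seed")
  stopifnot(length(hormone_specs) >= 1,
            all(vapply(hormone_specs, inherits, logical(1), "hormone_spec")),
            all(vapply(covariate_specs, inherits, logical(1), "covariate_spec")))
  names(hormone_specs) <- vapply(hormone_specs, `[[`, character(1), "name")
  names(covariate_specs) <- vapply(covariate_specs, `[[`, character(1), "name")
  structure(
    list(n_participants = as.integer(n_participants),
         n_assessments = as.integer(n_assessments),
         hormone_specs = hormone_specs, covariate_specs = covariate_specs,
         weight_drift_sd = weight_drift_sd, seed = seed),
    class = "simulation_config"
  )
}

assessment_labels <- function(k) {
  if (k == 2L) c("BL", "FU") else c("BL", paste0("FU", seq_len(k - 1L)))
}

simulate_one_covariate <- function(spec, n, k, seed, weight_drift_sd) {
  set.seed(substream_seed(seed, paste0("covariate:", spec$name)))
  draw <- function(par, n) {
    switch(spec$dist,
           normal = stats::rnorm(n, par[1], par[2]),
           lognormal = stats::rlnorm(n, par[1], par[2]))
  }
  if (identical(spec$name, "weight")) {
    bl <- draw(spec$bl, n)
    out <- matrix(NA_real_, n, k)
    out[, 1] <- bl
    for (t in seq_len(k)[-1]) {
      out[, t] <- bl + if (weight_drift_sd > 0)
        stats::rnorm(n, 0, weight_drift_sd) else 0
    }
  } else {
    out <- matrix(NA_real_, n, k)
    for (t in seq_len(k)) {
      out[, t] <- draw(if (t == 1L) spec$bl else spec$fu, n)
    }
  }
  if (!is.null(spec$round_to)) out <- round(out / spec$round_to) * spec$round_to
  if (!is.null(spec$clamp)) out <- pmin(pmax(out, spec$clamp[1]), spec$clamp[2])
  out
}

covariate_center <- function(spec) {
  # baseline mean on the natural scale
  switch(spec$dist,
         normal = spec$bl[1],
         lognormal = exp(spec$bl[1] + spec$bl[2]^2 / 2))
}

#' Simulate a participant-by-assessment hormone cohort
#'
#' Generates a long-format cohort table with the reliability structure the
#' analysis assumes: per hormone, a participant-level latent log
#' concentration and assessment-level residual noise whose variance split is
#' governed by the hormone's `true_icc` (see [hormone_spec()]); covariates
#' drawn from their marginal specs, entering additively on the log-hormone
#' scale through the configured effect sizes; raw values passed through the
#' assay censoring pathway ([apply_assay_limits()]) rather than truncating
#' the distribution. The same config and seed always yield an identical
#' table.
#'
#' @param config A [simulation_config()].
#' @return A `data.frame` in long format with columns `participant_id`,
#'   `assessment`, `hormone`, `value_pgml`, `glucose_mmol_l`, `hba1c_pct`,
#'   `activity_h_week`, `diet_index`, `weight_kg`.
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_participants = 17, seed = 42))
#' head(cohort)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_participants
  k <- config$n_assessments
  assess <- assessment_labels(k)
  ids <- sprintf("P%02d", seq_len(n))

  cov_mats <- lapply(config$covariate_specs, simulate_one_covariate,
                     n = n, k = k, seed = config$seed,
                     weight_drift_sd = config$weight_drift_sd)

  base <- data.frame(
    participant_id = rep(ids, times = k),
    assessment = rep(assess, each = n),
    stringsAsFactors = FALSE
  )
  cov_cols <- c(glucose = "glucose_mmol_l", hba1c = "hba1c_pct",
                activity = "activity_h_week", diet = "diet_index",
                weight = "weight_kg")
  for (key in names(cov_cols)) {
    base[[cov_cols[[key]]]] <-
      if (key %in% names(cov_mats)) as.vector(cov_mats[[key]]) else NA_real_
  }

  rows <- lapply(config$hormone_specs, function(spec) {
    set.seed(substream_seed(config$seed, paste0("hormone:", spec$name)))
    sigma_b <- sqrt(spec$true_icc) * spec$log_sd_total
    sigma_e <- sqrt(1 - spec$true_icc) * spec$log_sd_total
    b <- stats::rnorm(n, 0, sigma_b)
    e <- matrix(stats::rnorm(n * k, 0, sigma_e), n, k)
    shift <- matrix(0, n, k)
    for (cv in config$covariate_specs) {
      eff <- if (spec$name %in% names(cv$effects)) cv$effects[[spec$name]] else 0
      if (is.finite(eff) && eff != 0) {
        shift <- shift + eff * (cov_mats[[cv$name]] - covariate_center(cv))
      }
    }
    raw <- exp(spec$log_median + b + shift + e)
    value <- apply_assay_limits(as.vector(raw), spec$assay)
    cbind(base, data.frame(hormone = spec$name, value_pgml = value,
                           stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  cols <- c("participant_id", "assessment", "hormone", "value_pgml",
            unname(cov_cols))
  out <- out[order(match(out$hormone, names(config$hormone_specs)),
                   out$assessment, out$participant_id), cols]
  rownames(out) <- NULL
  validate_cohort(out)
  out
}

validate_cohort <- function(cohort) {
  needed <- c("participant_id", "assessment", "hormone", "value_pgml")
  missing <- setdiff(needed, names(cohort))
  if (length(missing) > 0L) {
    stop("cohort table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  key <- paste(cohort$participant_id, cohort$assessment, cohort$hormone)
  if (anyDuplicated(key)) {
    stop("duplicated (participant, assessment, hormone) rows in cohort",
         call. = FALSE)
  }
  v <- cohort$value_pgml
  if (any(!is.na(v) & v < 0)) {
    stop("negative hormone concentrations in cohort", call. = FALSE)
  }
  invisible(cohort)
}

#' Simulate exchangeable null pairs
#'
#' Draws `n` participants' baseline and follow-up values iid from the same
#' log-normal distribution, so the two columns are exchangeable within
#' participant: the null hypothesis of the paired permutation test holds
#' exactly. Used for type-I-error studies.
#'
#' @param n Number of pairs (>= 2).
#' @param log_sd_total SD on the log scale (> 0).
#' @param seed Seed; fully determines the matrix.
#' @param log_median Log-scale location (default 0).
#' @return A [paired_matrix()] of dimension `n` x 2.
#' @export
simulate_null_pairs <- function(n, log_sd_total = 0.5, seed = 1,
                                log_median = 0) {
  assert_scalar_number(n, "n", min = 2)
  assert_scalar_number(log_sd_total, "log_sd_total", min = 0, strict_min = TRUE)
  set.seed(substream_seed(seed, "null_pairs"))
  m <- matrix(stats::rlnorm(2 * n, log_median, log_sd_total), nrow = n, ncol = 2,
              dimnames = list(NULL, c("BL", "FU")))
  paired_matrix(m)
}
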