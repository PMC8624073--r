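#' Analysis configuration for the reliability pipeline
#'
#' @param hormones Hormone names to analyze; `NULL` means all hormones
#'   present in the cohort.
#' @param covariates Covariate keys for the adjusted ICC (empty vector
#'   disables the adjusted stage).
#' @param permutation_iterations Monte Carlo iterations per permutation
#'   test (default 100000).
#' @param bootstrap_reps Parametric-bootstrap refits for adjusted-ICC CIs
#'   (default 500).
#' @param conf_level Confidence level in (0, 1), default 0.95.
#' @param exclude_ids Participant ids dropped before analysis (subgroup
#'   re-analysis); recorded in the report metadata.
#' @param log_transform Analyze log concentrations instead of raw pg/mL.
#' @param assays Optional named list of [assay_config()] applied to each
#'   hormone's values before analysis; `NULL` skips censoring (e.g. for
#'   already-processed tables).
#' @param seed Master seed; substreams are derived per stage and hormone.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(hormones = NULL,
                            covariates = c("glucose", "hba1c", "activity", "diet"),
                            permutation_iterations = 100000,
                            bootstrap_reps = 500,
                            conf_level = 0.95,
                            exclude_ids = NULL,
                            log_transform = FALSE,
                            assays = NULL,
                            seed = 1) {
  assert_scalar_number(permutation_iterations, "permutation_iterations", min = 1)
  assert_scalar_number(bootstrap_reps, "bootstrap_reps", min = 0)
  assert_scalar_number(conf_level, "conf_level", min = 0, strict_min = TRUE)
  if (conf_level >= 1) stop("`conf_level` must be in (0, 1)", call. = FALSE)
  assert_scalar_number(seed, "seed")
  if (!is.null(assays)) {
    stopifnot(all(vapply(assays, inherits, logical(1), "assay_config")))
  }
  structure(
    list(hormones = hormones, covariates = covariates,
         permutation_iterations = as.integer(permutation_iterations),
         bootstrap_reps = as.integer(bootstrap_reps),
         conf_level = conf_level,
         exclude_ids = exclude_ids,
         log_transform = isTRUE(log_transform),
         assays = assays, seed = seed),
    class = "analysis_config"
  )
}

#' Extract one variable's complete baseline/follow-up pairs
#'
#' @param cohort Long-format cohort table.
#' @param variable A hormone name, or a covariate key/column name.
#' @param assessments Which two assessment labels form the pair
#'   (default `c("BL", "FU")`).
#' @return A [paired_matrix()] restricted to participants with both
#'   assessments present.
#' @export
cohort_to_paired <- function(cohort, variable, assessments = c("BL", "FU")) {
  cohort <- as.data.frame(cohort)
  stopifnot(length(assessments) == 2L)
  if (variable %in% unique(cohort$hormone)) {
    sub <- cohort[cohort$hormone == variable, ]
    col <- if ("value_pgml" %in% names(sub)) "value_pgml" else "value"
  } else {
    col <- resolve_covariates(variable, names(cohort))
    # covariates repeat across hormone rows; deduplicate
    sub <- unique(cohort[, c("participant_id", "assessment", col)])
  }
  bl <- sub[sub$assessment == assessments[1], c("participant_id", col)]
  fu <- sub[sub$assessment == assessments[2], c("participant_id", col)]
  m <- merge(bl, fu, by = "participant_id", suffixes = c("_bl", "_fu"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2L) {
    stop("fewer than 2 complete pairs for ", sQuote(variable), call. = FALSE)
  }
  m <- m[order(m$participant_id), ]
  paired_matrix(cbind(BL = m[[2]], FU = m[[3]]), ids = m$participant_id)
}

#' Split a cohort by between-assessment weight change
#'
#' Partitions participants by whether the absolute weight change between
#' baseline and follow-up exceeds a threshold, for exploratory subgroup
#' reliability analyses (weight fluctuation is a candidate explanation for
#' degraded leptin reliability). Participants with missing weight at
#' either assessment are routed to an explicit `unknown` bucket.
#'
#' @param cohort Long-format cohort table with a `weight_kg` column.
#' @param threshold Weight-change threshold in kg; change strictly greater
#'   than it assigns the participant to the `changed` group.
#' @return List with cohort subsets `stable`, `changed`, `unknown`, and
#'   `summary` (per-participant weight change).
#' @export
weight_change_split <- function(cohort, threshold) {
  cohort <- as.data.frame(cohort)
  assert_scalar_number(threshold, "threshold", min = 0)
  stopifnot("weight_kg" %in% names(cohort))
  w <- unique(cohort[, c("participant_id", "assessment", "weight_kg")])
  bl <- w[w$assessment == "BL", c("participant_id", "weight_kg")]
  fu <- w[w$assessment == "FU", c("participant_id", "weight_kg")]
  m <- merge(bl, fu, by = "participant_id", all = TRUE,
             suffixes = c("_bl", "_fu"))
  m$delta <- m$weight_kg_fu - m$weight_kg_bl
  m$group <- ifelse(is.na(m$delta), "unknown",
                    ifelse(abs(m$delta) > threshold, "changed", "stable"))
  pick <- function(g) {
    ids <- m$participant_id[m$group == g]
    cohort[cohort$participant_id %in% ids, , drop = FALSE]
  }
  list(stable = pick("stable"), changed = pick("changed"),
       unknown = pick("unknown"),
       summary = m[, c("participant_id", "delta", "group")])
}

#' Run the full reliability pipeline
#'
#' Stages, in order: assay censoring (if configured), subgroup exclusion,
#' per-variable paired permutation tests (hormones and covariates),
#' ICC(A,1) per hormone, and — when covariates are configured — the
#' random-intercept mixed model and adjusted ICC per hormone. Identical
#' cohort, config and seed yield an identical report. Any stage failure
#' aborts with a stage-named error.
#'
#' @param cohort Long-format cohort table ([simulate_cohort()] contract or
#'   [read_cohort_csv()] output).
#' @param config An [analysis_config()].
#' @return Object of class `reliability_report`: `$hormones` (one row per
#'   hormone: ICC estimate/CI/p/category, adjusted ICC/CI/category,
#'   permutation p), `$covariates` (permutation p per covariate), `$meta`
#'   (seed, sample sizes, exclusions, config echo).
#' @export
run_pipeline <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  cohort <- as.data.frame(cohort)
  validate_cohort(cohort)

  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- stage: preprocess (assay censoring) -------------------------------
  cohort <- with_stage("preprocess", {
    if (!is.null(config$assays)) {
      for (h in names(config$assays)) {
        idx <- cohort$hormone == h
        cohort$value_pgml[idx] <-
          apply_assay_limits(cohort$value_pgml[idx], config$assays[[h]])
      }
    }
    cohort
  })

  # -- stage: filter ------------------------------------------------------
  excluded <- character(0)
  if (!is.null(config$exclude_ids) && length(config$exclude_ids) > 0L) {
    excluded <- as.character(config$exclude_ids)
    cohort <- with_stage("filter", {
      kept <- cohort[!cohort$participant_id %in% excluded, , drop = FALSE]
      if (nrow(kept) == 0L) stop("all participants excluded")
      kept
    })
  }

  hormones <- config$hormones %||% unique(cohort$hormone)
  missing_h <- setdiff(hormones, unique(cohort$hormone))
  if (length(missing_h) > 0L) {
    stop("pipeline stage 'filter' failed: hormone(s) not in cohort: ",
         paste(missing_h, collapse = ", "), call. = FALSE)
  }

  transform_pairs <- function(pm) {
    if (!config$log_transform) return(pm)
    if (any(pm <= 0)) {
      # censored zeros cannot be log-transformed; shift by half the smallest
      # positive value (documented degenerate-input handling)
      shift <- min(pm[pm > 0]) / 2
      pm[pm <= 0] <- shift
    }
    paired_matrix(log(unclass(pm)))
  }

  # -- stage: permutation tests ------------------------------------------
  perm_for <- function(variable) {
    pm <- cohort_to_paired(cohort, variable)
    paired_permutation_test(pm, iterations = config$permutation_iterations,
                            seed = substream_seed(config$seed,
                                                  paste0("perm:", variable)))
  }
  perm_h <- with_stage("permutation_tests",
                       lapply(stats::setNames(hormones, hormones), perm_for))
  cov_keys <- config$covariates %||% character(0)
  perm_c <- with_stage("permutation_tests",
                       lapply(stats::setNames(cov_keys, cov_keys), perm_for))

  # -- stage: ICC ---------------------------------------------------------
  icc_h <- with_stage("icc", lapply(stats::setNames(hormones, hormones),
    function(h) icc_a1(transform_pairs(cohort_to_paired(cohort, h)),
                       conf_level = config$conf_level)))

  # -- stage: adjusted ICC ------------------------------------------------
  adj_h <- NULL
  if (length(cov_keys) > 0L) {
    adj_h <- with_stage("adjusted_icc", lapply(
      stats::setNames(hormones, hormones),
      function(h) {
        vc <- fit_random_intercept_lmm(cohort, response = h,
                                       covariates = cov_keys,
                                       log_transform = config$log_transform)
        adjusted_icc(vc, bootstrap_reps = config$bootstrap_reps,
                     seed = substream_seed(config$seed, paste0("boot:", h)),
                     conf_level = config$conf_level)
      }))
  }

  hdf <- do.call(rbind, lapply(hormones, function(h) {
    ii <- icc_h[[h]]; aa <- adj_h[[h]]
    data.frame(
      hormone = h, n_pairs = ii$n,
      icc = ii$estimate, icc_ci_low = ii$ci_low, icc_ci_high = ii$ci_high,
      icc_p = ii$p_value, icc_category = ii$category %||% NA_character_,
      adj_icc = if (is.null(aa)) NA_real_ else aa$estimate,
      adj_ci_low = if (is.null(aa)) NA_real_ else aa$ci_low,
      adj_ci_high = if (is.null(aa)) NA_real_ else aa$ci_high,
      adj_category = if (is.null(aa)) NA_character_ else aa$category %||% NA_character_,
      perm_p = perm_h[[h]]$p_value,
      stringsAsFactors = FALSE
    )
  }))
  rownames(hdf) <- NULL

  cdf <- if (length(cov_keys) > 0L) {
    data.frame(covariate = cov_keys,
               perm_p = vapply(perm_c, `[[`, numeric(1), "p_value"),
               observed_diff = vapply(perm_c, `[[`, numeric(1),
                                      "observed_statistic"),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(covariate = character(0), perm_p = numeric(0),
               observed_diff = numeric(0))
  }

  structure(
    list(hormones = hdf, covariates = cdf,
         meta = list(
           seed = config$seed,
           n_participants = length(unique(cohort$participant_id)),
           excluded_ids = excluded,
           hormone_list = hormones,
           covariate_list = cov_keys,
           permutation_iterations = config$permutation_iterations,
           bootstrap_reps = config$bootstrap_reps,
           conf_level = config$conf_level,
           log_transform = config$log_transform,
           package_version = as.character(utils::packageVersion("ghrelkit"))
         )),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("Reliability report: %d participants, %d hormone(s)\n",
              x$meta$n_participants, nrow(x$hormones)))
  if (length(x$meta$excluded_ids) > 0L) {
    cat("  excluded:", paste(x$meta$excluded_ids, collapse = ", "), "\n")
  }
  df <- x$hormones
  df$icc <- sprintf("%.3f [%.3f, %.3f]", df$icc, df$icc_ci_low, df$icc_ci_high)
  keep <- c("hormone", "n_pairs", "icc", "icc_category", "perm_p")
  if (any(!is.na(x$hormones$adj_icc))) {
    df$adj <- sprintf("%.3f [%.3f, %.3f]", x$hormones$adj_icc,
                      x$hormones$adj_ci_low, x$hormones$adj_ci_high)
    keep <- c(keep, "adj", "adj_category")
  }
  print(df[, keep], row.names = FALSE)
  if (nrow(x$covariates) > 0L) {
    cat("Covariate permutation tests (FU - BL):\n")
    print(x$covariates, row.names = FALSE)
  }
  invisible(x)
}
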