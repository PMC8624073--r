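#' Read a long-format cohort CSV
#'
#' Expected header:
#' `participant_id,assessment,hormone,value_pgml,glucose_mmol_l,hba1c_pct,activity_h_week,diet_index,weight_kg`
#' (covariate columns are optional). Hormone values may carry the
#' case-insensitive sentinel "BDL" (or be empty) for below-detection
#' samples; these are read as `NA` and resolved to 0 by the assay
#' censoring stage.
#'
#' @param path CSV file path.
#' @return Cohort `data.frame` passing [simulate_cohort()]'s column
#'   contract, with `value_pgml` numeric and `NA` marking below-detection
#'   samples.
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  needed <- c("participant_id", "assessment", "hormone", "value_pgml")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0L) {
    stop("cohort CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  v <- trimws(raw$value_pgml)
  bdl <- toupper(v) %in% c("BDL", "")
  num <- suppressWarnings(as.numeric(v))
  if (any(is.na(num) & !bdl)) {
    stop("non-numeric value_pgml entries that are not the 'BDL' sentinel",
         call. = FALSE)
  }
  num[bdl] <- NA_real_
  raw$value_pgml <- num
  for (cc in intersect(c("glucose_mmol_l", "hba1c_pct", "activity_h_week",
                         "diet_index", "weight_kg"), names(raw))) {
    raw[[cc]] <- suppressWarnings(as.numeric(raw[[cc]]))
  }
  validate_cohort(raw)
  raw
}

#' Write a cohort table to CSV
#'
#' Below-detection samples (`NA` in `value_pgml`) are written with the
#' "BDL" sentinel rather than an empty cell.
#'
#' @param cohort Cohort `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cohort <- as.data.frame(cohort)
  validate_cohort(cohort)
  out <- cohort
  out$value_pgml <- ifelse(is.na(out$value_pgml), "BDL",
                           sprintf("%.15g", out$value_pgml))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a simulation configuration from JSON
#'
#' The JSON mirrors [simulation_config()]: top-level `n_participants`,
#' `n_assessments`, `weight_drift_sd`, `seed`; `hormones` as a list of
#' [hormone_spec()] field sets (with optional `assays`-style fields); an
#' optional `covariates` list of [covariate_spec()] field sets.
#'
#' @param path JSON file path.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  hs <- if (!is.null(j$hormones)) {
    lapply(j$hormones, function(h) {
      hormone_spec(h$name, log_median = h$log_median,
                   log_sd_total = h$log_sd_total, true_icc = h$true_icc,
                   detection_limit = h$detection_limit %||% 0,
                   upper_standard = h$upper_standard,
                   dilution_factor = h$dilution_factor %||% 1)
    })
  } else default_hormone_specs()
  cs <- if (!is.null(j$covariates)) {
    lapply(j$covariates, function(cv) {
      covariate_spec(cv$name, dist = cv$dist %||% "normal",
                     bl = unlist(cv$bl), fu = unlist(cv$fu %||% cv$bl),
                     effects = unlist(cv$effects) %||% numeric(0),
                     round_to = cv$round_to, clamp = unlist(cv$clamp))
    })
  } else default_covariate_specs()
  simulation_config(
    n_participants = j$n_participants %||% 17,
    n_assessments = j$n_assessments %||% 2,
    hormone_specs = hs, covariate_specs = cs,
    weight_drift_sd = j$weight_drift_sd %||% 0,
    seed = j$seed %||% 1
  )
}

#' Read an analysis configuration from JSON
#'
#' Mirrors [analysis_config()] fields; an `assays` object maps hormone
#' names to `detection_limit` / `upper_standard` / `dilution_factor`.
#'
#' @param path JSON file path.
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  assays <- NULL
  if (!is.null(j$assays)) {
    assays <- lapply(names(j$assays), function(h) {
      a <- j$assays[[h]]
      assay_config(h, detection_limit = a$detection_limit %||% 0,
                   upper_standard = a$upper_standard,
                   dilution_factor = a$dilution_factor %||% 1)
    })
    names(assays) <- names(j$assays)
  }
  analysis_config(
    hormones = unlist(j$hormones),
    covariates = unlist(j$covariates) %||% character(0),
    permutation_iterations = j$permutation_iterations %||% 100000,
    bootstrap_reps = j$bootstrap_reps %||% 500,
    conf_level = j$conf_level %||% 0.95,
    exclude_ids = unlist(j$exclude_ids),
    log_transform = isTRUE(j$log_transform),
    assays = assays,
    seed = j$seed %||% 1
  )
}

report_as_list <- function(report) {
  stopifnot(inherits(report, "reliability_report"))
  list(hormones = report$hormones, covariates = report$covariates,
       meta = report$meta)
}

#' Write a reliability report to JSON
#'
#' Serialization is deterministic: identical reports produce byte-identical
#' files.
#'
#' @param report A `reliability_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_as_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Export a report as a Table-4-style TSV
#'
#' One row per hormone with ICC, adjusted ICC, their CIs and categories,
#' and the permutation p-value.
#'
#' @param report A `reliability_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
report_to_tsv <- function(report, path) {
  stopifnot(inherits(report, "reliability_report"))
  utils::write.table(report$hormones, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Export forest-plot-ready estimates
#'
#' Long CSV with columns `label,estimate,ci_low,ci_high,panel`, one row
#' per hormone per panel (`ICC`, and `adjusted ICC` when computed) — the
#' structure a forest plot of reliability estimates consumes.
#'
#' @param report A `reliability_report`.
#' @param path Output path.
#' @return The exported `data.frame`, invisibly.
#' @export
report_to_forest_csv <- function(report, path) {
  stopifnot(inherits(report, "reliability_report"))
  h <- report$hormones
  rows <- data.frame(label = h$hormone, estimate = h$icc,
                     ci_low = h$icc_ci_low, ci_high = h$icc_ci_high,
                     panel = "ICC", stringsAsFactors = FALSE)
  if (any(!is.na(h$adj_icc))) {
    rows <- rbind(rows, data.frame(label = h$hormone, estimate = h$adj_icc,
                                   ci_low = h$adj_ci_low,
                                   ci_high = h$adj_ci_high,
                                   panel = "adjusted ICC",
                                   stringsAsFactors = FALSE))
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(rows)
}
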