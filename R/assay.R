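#' Per-hormone assay post-processing settings
#'
#' Bundles the deterministic laboratory rules applied to raw ELISA readouts:
#' the detection limit (below which a sample is reported as 0 pg/mL), the
#' highest calibrator of the standard curve (above which a sample is censored
#' to that concentration), and the dilution factor used when the sample was
#' diluted in assay buffer before measurement.
#'
#' @param hormone Hormone name (e.g. "ghrelin").
#' @param detection_limit Assay floor in pg/mL; values below it are reported
#'   as 0. Defaults to 0 (no floor), since kit-specific limits are inputs,
#'   not package constants.
#' @param upper_standard Highest standard in pg/mL, or `NULL` if the assay
#'   has no configured ceiling.
#' @param dilution_factor Dimensionless dilution ratio (10 for a 1:10
#'   dilution); must be >= 1.
#' @return An object of class `assay_config`.
#' @seealso [apply_assay_limits()], [apply_dilution()], [default_assay_configs()]
#' @export
assay_config <- function(hormone, detection_limit = 0, upper_standard = NULL,
                         dilution_factor = 1) {
  stopifnot(is.character(hormone), length(hormone) == 1L, nzchar(hormone))
  assert_scalar_number(detection_limit, "detection_limit", min = 0)
  assert_scalar_number(dilution_factor, "dilution_factor", min = 1)
  if (!is.null(upper_standard)) {
    assert_scalar_number(upper_standard, "upper_standard", min = 0)
    if (upper_standard <= detection_limit) {
      stop("`upper_standard` must exceed `detection_limit`", call. = FALSE)
    }
  }
  structure(
    list(hormone = hormone, detection_limit = detection_limit,
         upper_standard = upper_standard, dilution_factor = dilution_factor),
    class = "assay_config"
  )
}

#' Default assay settings for the four-hormone panel
#'
#' Dilution factors follow the wet-lab protocol for the panel (ghrelin 1:10,
#' leptin 1:50, GLP-1 1:6, PP 1:2); only the PP assay has a configured
#' ceiling, at its highest standard of 2276.02 pg/mL. Detection limits
#' default to 0 because the kits' floors are study inputs.
#'
#' @return Named list of [assay_config()] objects.
#' @export
default_assay_configs <- function() {
  list(
    ghrelin = assay_config("ghrelin", dilution_factor = 10),
    leptin  = assay_config("leptin",  dilution_factor = 50),
    GLP1    = assay_config("GLP1",    dilution_factor = 6),
    PP      = assay_config("PP",      dilution_factor = 2,
                           upper_standard = 2276.02)
  )
}

#' Apply detection-limit and upper-standard censoring
#'
#' Reproduces the reporting rule for ELISA concentrations: samples flagged
#' below the detection limit (encoded as `NA`, or the string "BDL" in input
#' files) are set to 0 pg/mL; samples above the highest standard are set to
#' that standard; in-range values pass through unchanged. The operation is
#' idempotent and its output always lies in `[0, upper_standard]` when a
#' ceiling is configured.
#'
#' @param values Numeric vector of concentrations in pg/mL; `NA` marks a
#'   below-detection sample. A character vector is accepted, with the
#'   sentinel "BDL" (case-insensitive) or an empty string marking
#'   below-detection samples.
#' @param config An [assay_config()].
#' @return Numeric vector of censored concentrations.
#' @examples
#' pp <- assay_config("PP", upper_standard = 2276.02, dilution_factor = 2)
#' apply_assay_limits(c(NA, 5000, 800), pp)  # 0, 2276.02, 800
#' @export
apply_assay_limits <- function(values, config) {
  stopifnot(inherits(config, "assay_config"))
  if (is.character(values)) {
    bdl <- toupper(trimws(values)) %in% c("BDL", "")
    out <- suppressWarnings(as.numeric(values))
    if (any(is.na(out) & !bdl)) {
      stop("non-numeric concentration that is not the 'BDL' sentinel",
           call. = FALSE)
    }
    out[bdl] <- NA_real_
    values <- out
  }
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  bdl <- is.na(values)
  if (any(!bdl & (!is.finite(values) | values < 0))) {
    stop("concentrations must be finite and non-negative (or NA/'BDL')",
         call. = FALSE)
  }
  out <- values
  out[bdl] <- 0
  out[!bdl & values < config$detection_limit] <- 0
  if (!is.null(config$upper_standard)) {
    out[out > config$upper_standard] <- config$upper_standard
  }
  out
}

#' Correct a measured concentration for sample dilution
#'
#' Samples are diluted in assay buffer before measurement; the reported
#' concentration is the measured value multiplied by the dilution factor.
#' Dilution correction precedes limit censoring: [apply_assay_limits()]
#' operates on the final reported concentration.
#'
#' @param measured Numeric vector of measured (diluted) concentrations in
#'   pg/mL; must be non-negative.
#' @param config An [assay_config()].
#' @return Numeric vector of dilution-corrected concentrations.
#' @export
apply_dilution <- function(measured, config) {
  stopifnot(inherits(config, "assay_config"))
  if (!is.numeric(measured) || any(!is.na(measured) & (measured < 0 | !is.finite(measured)))) {
    stop("`measured` must be non-negative finite numbers", call. = FALSE)
  }
  measured * config$dilution_factor
}
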