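`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic per-label substream seed: a named component (one hormone, the
# covariate block, one bootstrap) always sees the same stream for a given
# master seed, so adding a hormone does not perturb the others.
substream_seed <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2022102953
  as.integer((as.numeric(seed) %% 2147483647 + h) %% 2147483647)
}

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_min && x <= min) {
    stop(sprintf("`%s` must be > %s", name, format(min)), call. = FALSE)
  }
  if (!strict_min && x < min) {
    stop(sprintf("`%s` must be >= %s", name, format(min)), call. = FALSE)
  }
  invisible(x)
}

# Friendly covariate keys used by the CLI and configs -> cohort column names.
covariate_columns <- function() {
  c(glucose  = "glucose_mmol_l",
    hba1c    = "hba1c_pct",
    activity = "activity_h_week",
    diet     = "diet_index",
    weight   = "weight_kg")
}

resolve_covariates <- function(covariates, data_names) {
  if (length(covariates) == 0L) return(character(0))
  map <- covariate_columns()
  cols <- ifelse(covariates %in% names(map), map[covariates], covariates)
  missing <- setdiff(cols, data_names)
  if (length(missing) > 0L) {
    stop("covariate column(s) not found in cohort: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unname(cols)
}
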