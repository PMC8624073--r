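#' Canonical food-frequency categories
#'
#' The six consumption-frequency categories of the 37-item food-frequency
#' list, ordered from most to least frequent.
#'
#' @return Character vector of length 6.
#' @export
ffq_categories <- function() {
  c("almost daily", "several times per week", "about once a week",
    "several times per month", "once a month or less", "never")
}

canonical_category <- function(x) {
  cats <- ffq_categories()
  idx <- match(tolower(trimws(x)), cats)
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    stop("unknown frequency categor", if (length(bad) > 1) "ies: " else "y: ",
         paste(sQuote(bad), collapse = ", "),
         "; expected one of: ", paste(cats, collapse = ", "), call. = FALSE)
  }
  cats[idx]
}

#' Load a dietary-habits scoring scheme
#'
#' A scheme maps each of 37 food-frequency items to points per consumption
#' category; the per-item maxima sum to 127, the score of a maximally
#' healthy diet. Each item carries a direction: `healthy_frequent` items
#' (fruits, vegetables, whole grains, fish, unsaturated fats, ...) award the
#' most points to frequent consumption, `healthy_rare` items (fatty and
#' cured products, sweets, soft drinks, butter, salt habits, ...) to rare
#' consumption. The packaged default scheme is a documented modeling choice
#' (the original instrument's per-item weights are not published) and can be
#' replaced by any user file passing the same self-checks.
#'
#' @param path Path to a scheme JSON file; `NULL` loads the packaged
#'   default.
#' @return An object of class `diet_scheme`: list with `items` (named list
#'   of per-item category->points maps), `direction`, and `max_total`.
#' @export
load_diet_scheme <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "diet_scheme.json", package = "ghrelkit",
                        mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$items) || length(raw$items) == 0L) {
    stop("scheme file has no items", call. = FALSE)
  }
  cats <- ffq_categories()
  items <- list(); direction <- character(0)
  for (it in raw$items) {
    id <- it$id
    pts <- unlist(it$points)
    names(pts) <- canonical_category(names(pts))
    if (!setequal(names(pts), cats)) {
      stop("item ", sQuote(id), " does not map all six categories",
           call. = FALSE)
    }
    if (any(pts < 0)) stop("negative points for item ", sQuote(id), call. = FALSE)
    items[[id]] <- pts[cats]
    direction[id] <- it$direction %||% NA_character_
  }
  if (length(items) != 37L) {
    stop("scheme must have exactly 37 items, found ", length(items),
         call. = FALSE)
  }
  max_total <- sum(vapply(items, max, numeric(1)))
  asserted <- raw$max_total %||% 127
  if (max_total != 127 || asserted != 127) {
    stop("scheme self-check failed: per-item maxima sum to ", max_total,
         ", expected 127", call. = FALSE)
  }
  structure(list(items = items, direction = direction, max_total = 127),
            class = "diet_scheme")
}

#' Score a food-frequency response into the dietary habits index
#'
#' Sums per-item points under a scoring scheme; the maximum attainable score
#' is 127 points (a maximally healthy diet) and the minimum 0. Scoring is
#' additive, so replacing any single item's category with a healthier one
#' never decreases the score.
#'
#' @param response Named character vector (or two-column data.frame with
#'   columns `item`, `category`) giving one frequency category per scheme
#'   item. Categories are matched case-insensitively against
#'   [ffq_categories()].
#' @param scheme A `diet_scheme`, e.g. from [load_diet_scheme()].
#' @return Single number: the dietary habits score in points.
#' @examples
#' scheme <- load_diet_scheme()
#' best <- healthiest_response(scheme)
#' dietary_habits_score(best, scheme)  # 127
#' @export
dietary_habits_score <- function(response, scheme) {
  stopifnot(inherits(scheme, "diet_scheme"))
  if (is.data.frame(response)) {
    stopifnot(all(c("item", "category") %in% names(response)))
    response <- stats::setNames(as.character(response$category),
                                as.character(response$item))
  }
  if (is.null(names(response)) || any(!nzchar(names(response)))) {
    stop("`response` must be named by item id", call. = FALSE)
  }
  if (anyDuplicated(names(response))) {
    stop("duplicated item(s) in response: ",
         paste(unique(names(response)[duplicated(names(response))]),
               collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(response), names(scheme$items))
  if (length(unknown) > 0L) {
    stop("unknown item(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(names(scheme$items), names(response))
  if (length(missing) > 0L) {
    stop("missing item(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  cats <- canonical_category(response[names(scheme$items)])
  sum(vapply(seq_along(cats),
             function(i) scheme$items[[i]][[cats[[i]]]],
             numeric(1)))
}

#' Construct the maximally healthy (or unhealthy) response profile
#'
#' @param scheme A `diet_scheme`.
#' @param healthiest If `TRUE` (default) pick each item's maximal-point
#'   category; otherwise a minimal-point category.
#' @return Named character vector usable as a [dietary_habits_score()]
#'   response.
#' @export
healthiest_response <- function(scheme, healthiest = TRUE) {
  stopifnot(inherits(scheme, "diet_scheme"))
  vapply(scheme$items, function(pts) {
    names(pts)[if (healthiest) which.max(pts) else which.min(pts)]
  }, character(1))
}

#' Total weekly physical-activity hours
#'
#' Sums hours per week over all activity records (daily, leisure, and
#' athletic categories alike), giving the total physical activity index in
#' h/week.
#'
#' @param records Data.frame of activity records with at least a
#'   `hours_per_week` column (optionally `activity`, `category`, `met`).
#' @return Total hours per week (0 for an empty record set).
#' @export
total_activity_hours <- function(records) {
  if (is.null(records) || nrow(as.data.frame(records)) == 0L) return(0)
  records <- as.data.frame(records)
  stopifnot("hours_per_week" %in% names(records))
  h <- records$hours_per_week
  if (any(!is.finite(h) | h < 0)) {
    stop("hours_per_week must be finite and non-negative", call. = FALSE)
  }
  sum(h)
}

#' Activity energy from MET values
#'
#' Two conventions are provided. `"standard"` is the usual MET-to-energy
#' conversion, sum(MET x hours x weight), in kcal/week (1 MET is about
#' 1 kcal per kg body weight per hour). `"weight_squared"` follows the
#' alternative survey-index rule: sum(MET x hours) divided by the
#' square of body weight; its units (MET.h/(week.kg^2)) conflict with
#' kcal/week, so both modes are exposed and callers choose rather than
#' the package guessing intent.
#'
#' @param records Data.frame with columns `hours_per_week` and `met`.
#' @param weight Body weight in kg; must be positive.
#' @param mode `"weight_squared"` (default) or `"standard"`.
#' @return Single number in the mode's units (0 for no records).
#' @export
met_energy <- function(records, weight, mode = c("weight_squared", "standard")) {
  mode <- match.arg(mode)
  assert_scalar_number(weight, "weight", min = 0, strict_min = TRUE)
  if (is.null(records) || nrow(as.data.frame(records)) == 0L) return(0)
  records <- as.data.frame(records)
  stopifnot(all(c("hours_per_week", "met") %in% names(records)))
  if (any(records$met <= 0) || any(records$hours_per_week < 0)) {
    stop("MET values must be positive and hours non-negative", call. = FALSE)
  }
  met_hours <- sum(records$met * records$hours_per_week)
  switch(mode,
         standard = met_hours * weight,
         weight_squared = met_hours / weight^2)
}
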