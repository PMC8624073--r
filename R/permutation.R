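#' Paired baseline/follow-up matrix
#'
#' Container for one variable's complete pairs: an `n x 2` matrix with
#' column 1 the baseline and column 2 the follow-up value per participant.
#' Incomplete pairs are rejected; the permutation machinery assumes
#' complete pairs only.
#'
#' @param values Numeric `n x 2` matrix (or something coercible to one).
#' @param ids Optional participant identifiers (length `n`).
#' @return Object of classes `paired_matrix` and `matrix`.
#' @export
paired_matrix <- function(values, ids = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != 2L) {
    stop("`values` must have exactly 2 columns (baseline, follow-up)",
         call. = FALSE)
  }
  if (nrow(values) < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("incomplete pairs: paired analyses require complete, finite pairs ",
         "for every participant", call. = FALSE)
  }
  if (!is.null(ids)) {
    stopifnot(length(ids) == nrow(values))
    rownames(values) <- as.character(ids)
  }
  if (is.null(colnames(values))) colnames(values) <- c("BL", "FU")
  class(values) <- c("paired_matrix", class(values))
  values
}

as_paired_matrix <- function(data) {
  if (inherits(data, "paired_matrix")) return(data)
  paired_matrix(data)
}

# Comparison slack so that null statistics tied with the observed one (in
# particular the identity permutation) are counted as at least as extreme
# despite floating-point summation order.
tie_eps <- function(d) 1e-12 * (1 + max(abs(d)))

new_permutation_result <- function(observed, p, iterations, seed, method, n) {
  structure(
    list(observed_statistic = observed, p_value = p, iterations = iterations,
         seed = seed, method = method, n = n),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Paired permutation test (%s)\n", x$method))
  cat(sprintf("  n pairs: %d\n", x$n))
  cat(sprintf("  observed mean difference (FU - BL): %.6g\n",
              x$observed_statistic))
  cat(sprintf("  two-sided p: %.6g", x$p_value))
  if (x$method == "monte_carlo") {
    cat(sprintf("  (%d iterations, seed %s)", x$iterations,
                format(x$seed %||% NA)))
  }
  cat("\n")
  invisible(x)
}

#' Monte Carlo paired permutation test
#'
#' Tests whether a variable's mean differs between baseline and follow-up.
#' Under the null the two values of each participant are exchangeable, so
#' null draws swap each participant's pair independently with probability
#' 1/2 (equivalently, sign-flip the paired differences). The statistic is
#' the difference of assessment means, `T = mean(FU) - mean(BL)`; the
#' two-sided Monte Carlo p-value uses the add-one convention
#' `p = (1 + b) / (1 + iterations)` with `b` the number of null draws with
#' `|T_perm| >= |T_obs|`, which guarantees `p > 0` and a valid level-alpha
#' test.
#'
#' @param data A [paired_matrix()] or `n x 2` numeric matrix of complete
#'   pairs.
#' @param iterations Number of Monte Carlo permutations (default 100000).
#' @param seed Seed for the permutation stream (`NULL` leaves the RNG
#'   state alone).
#' @return A `permutation_result` with the observed statistic, p-value,
#'   iteration count, seed and method.
#' @seealso [exact_sign_flip_test()] for the exact enumeration over all
#'   `2^n` within-pair swaps.
#' @export
paired_permutation_test <- function(data, iterations = 100000, seed = NULL) {
  data <- as_paired_matrix(data)
  assert_scalar_number(iterations, "iterations", min = 1)
  iterations <- as.integer(iterations)
  d <- data[, 2] - data[, 1]
  n <- length(d)
  t_obs <- sum(d) / n
  eps <- tie_eps(d)
  if (!is.null(seed)) set.seed(substream_seed(seed, "paired_permutation"))
  b <- 0L
  chunk <- max(1L, min(iterations, as.integer(2e7 / n)))
  done <- 0L
  while (done < iterations) {
    m <- min(chunk, iterations - done)
    signs <- matrix(sample(c(-1, 1), m * n, replace = TRUE), nrow = m)
    t_perm <- as.vector(signs %*% d) / n
    b <- b + sum(abs(t_perm) >= abs(t_obs) - eps)
    done <- done + m
  }
  p <- (1 + b) / (1 + iterations)
  new_permutation_result(t_obs, p, iterations, seed, "monte_carlo", n)
}

#' Exact sign-flip permutation test
#'
#' Enumerates all `2^n` within-pair swap assignments (swapping a pair's
#' labels is equivalent to flipping the sign of its difference) and returns
#' the exact two-sided p-value, the fraction of assignments whose statistic
#' is at least as extreme as the observed one. Serves as the brute-force
#' oracle for [paired_permutation_test()]; limited to `n <= 22`.
#'
#' @param data A [paired_matrix()] or `n x 2` numeric matrix.
#' @return A `permutation_result` with `method = "exact"`; its p-value lies
#'   on the grid `k / 2^n` and is at least `1 / 2^n` (the identity
#'   assignment always ties the observed statistic).
#' @export
exact_sign_flip_test <- function(data) {
  data <- as_paired_matrix(data)
  d <- data[, 2] - data[, 1]
  n <- length(d)
  if (n > 22L) {
    stop("exact enumeration is limited to n <= 22 pairs (2^n assignments); ",
         "use paired_permutation_test() for larger n", call. = FALSE)
  }
  t_obs <- sum(d) / n
  eps <- tie_eps(d)
  sums <- 0
  for (di in d) sums <- c(sums + di, sums - di)  # all 2^n signed sums
  p <- mean(abs(sums / n) >= abs(t_obs) - eps)
  new_permutation_result(t_obs, p, as.integer(2^n), NULL, "exact", n)
}
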