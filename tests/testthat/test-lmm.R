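make_cohort <- function(n, icc, seed, covariate_effects = NULL, drift = 0) {
  covs <- default_covariate_specs()
  if (!is.null(covariate_effects)) {
    for (nm in names(covariate_effects)) {
      covs[[nm]]$effects <- covariate_effects[[nm]]
    }
  }
  simulate_cohort(simulation_config(
    n_participants = n,
    hormone_specs = list(hormone_spec("h", log_median = 0, log_sd_total = 1,
                                      true_icc = icc)),
    covariate_specs = covs, weight_drift_sd = drift, seed = seed
  ))
}

test_that("intercept-only REML matches the closed-form one-way solution on balanced data", {
  co <- make_cohort(25, 0.7, seed = 42)
  vc <- fit_random_intercept_lmm(co, "h", log_transform = TRUE)
  pm <- cohort_to_paired(co, "h")
  oracle <- oracle_oneway_reml(log(unclass(pm)))
  expect_equal(vc$sigma2_between, oracle$sigma2_between, tolerance = 1e-6)
  expect_equal(vc$sigma2_residual, oracle$sigma2_residual, tolerance = 1e-6)
  expect_true(vc$converged)
})

test_that("variance components recover simulated truth at large n", {
  # sigma_b^2 = sigma_e^2 = 1 on the log scale (icc 0.5, total sd sqrt(2))
  co <- simulate_cohort(simulation_config(
    n_participants = 500,
    hormone_specs = list(hormone_spec("h", log_median = 0,
                                      log_sd_total = sqrt(2),
                                      true_icc = 0.5)),
    seed = 2))
  vc <- fit_random_intercept_lmm(co, "h",
                                 covariates = c("glucose", "hba1c"),
                                 log_transform = TRUE)
  expect_lt(abs(vc$sigma2_between - 1), 0.1)
  expect_lt(abs(vc$sigma2_residual - 1), 0.1)
  expect_true(all(abs(vc$beta[c("glucose_mmol_l", "hba1c_pct")]) < 0.1))
})

test_that("REML estimates beat a brute-force variance-component grid", {
  co <- make_cohort(20, 0.6, seed = 11)
  vc <- fit_random_intercept_lmm(co, "h", covariates = "glucose",
                                 log_transform = TRUE)
  sub <- co[co$hormone == "h", ]
  y <- log(sub$value_pgml)
  X <- cbind(1, sub$glucose_mmol_l)
  id <- sub$participant_id
  at_hat <- oracle_reml_loglik(y, X, id, vc$sigma2_between,
                               vc$sigma2_residual)
  grid_b <- seq(0.001, 2, length.out = 50)
  grid_e <- seq(0.01, 2, length.out = 50)
  best_grid <- max(vapply(grid_b, function(s2b) {
    max(vapply(grid_e, function(s2e) {
      oracle_reml_loglik(y, X, id, s2b, s2e)
    }, numeric(1)))
  }, numeric(1)))
  expect_gte(at_hat, best_grid - 1e-6)
})

test_that("covariate effects configured in the generator are recovered as fixed effects", {
  co <- make_cohort(300, 0.6, seed = 13,
                    covariate_effects = list(glucose = c(h = 0.3)))
  vc <- fit_random_intercept_lmm(co, "h", covariates = "glucose",
                                 log_transform = TRUE)
  expect_lt(abs(vc$beta[["glucose_mmol_l"]] - 0.3), 0.06)
})

test_that("missing covariate cells and singleton participants fail loudly", {
  co <- make_cohort(10, 0.7, seed = 3)
  co$glucose_mmol_l[4] <- NA
  expect_error(fit_random_intercept_lmm(co, "h", covariates = "glucose"),
               "complete cases")
  co2 <- make_cohort(10, 0.7, seed = 3)
  co2 <- co2[!(co2$participant_id == "P01" & co2$assessment == "FU"), ]
  expect_error(fit_random_intercept_lmm(co2, "h"), "at least 2 observations")
})

test_that("adjusted ICC is the variance-component ratio with the forced edge cases", {
  vc <- structure(list(sigma2_between = 3, sigma2_residual = 1,
                       beta = c(`(Intercept)` = 0), reml_loglik = 0,
                       converged = TRUE, messages = character(0),
                       covariates = character(0), n_participants = 10,
                       n_obs = 20, fit = NULL),
                  class = "variance_components")
  r <- adjusted_icc(vc, bootstrap_reps = 0)
  expect_equal(r$estimate, 0.75)
  expect_equal(r$category, "good")
  vc$sigma2_between <- 0
  expect_equal(adjusted_icc(vc, bootstrap_reps = 0)$estimate, 0)
  vc$sigma2_residual <- 0
  expect_true(adjusted_icc(vc, bootstrap_reps = 0)$degenerate)
})

test_that("bootstrap CI is seeded-reproducible and brackets the estimate", {
  co <- make_cohort(30, 0.7, seed = 21)
  vc <- fit_random_intercept_lmm(co, "h", covariates = "glucose",
                                 log_transform = TRUE)
  r1 <- adjusted_icc(vc, bootstrap_reps = 100, seed = 5)
  r2 <- adjusted_icc(vc, bootstrap_reps = 100, seed = 5)
  expect_identical(c(r1$ci_low, r1$ci_high), c(r2$ci_low, r2$ci_high))
  expect_lt(r1$ci_low, r1$ci_high)
  expect_gte(r1$estimate, r1$ci_low - 0.15)
  expect_lte(r1$estimate, r1$ci_high + 0.15)
})

test_that("with zero covariate effects the adjusted ICC tracks ICC(A,1)", {
  # reduced-scale version of the null-equivalence study in the acceptance
  # suite
  diffs <- vapply(1:20, function(i) {
    co <- make_cohort(100, 0.7, seed = 3000 + i)
    pm <- cohort_to_paired(co, "h")
    icc <- icc_a1(log(unclass(pm)))$estimate
    vc <- fit_random_intercept_lmm(co, "h",
                                   covariates = c("glucose", "hba1c",
                                                  "activity", "diet"),
                                   log_transform = TRUE)
    abs(adjusted_icc(vc, bootstrap_reps = 0)$estimate - icc)
  }, numeric(1))
  expect_lt(mean(diffs), 0.05)
})
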