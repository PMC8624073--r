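test_that("the same seed reproduces the cohort exactly; different seeds differ", {
  cfg <- simulation_config(seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c2 <- simulate_cohort(simulation_config(seed = 43))
  expect_false(identical(a, c2))
})

test_that("cohort tables honor their key and positivity invariants", {
  co <- simulate_cohort(simulation_config(n_participants = 17, seed = 1))
  expect_equal(nrow(co), 17 * 2 * 4)
  key <- paste(co$participant_id, co$assessment, co$hormone)
  expect_false(anyDuplicated(key) > 0)
  expect_true(all(co$value_pgml >= 0))
  expect_setequal(unique(co$assessment), c("BL", "FU"))
  expect_setequal(unique(co$hormone), c("ghrelin", "leptin", "GLP1", "PP"))
})

test_that("per-hormone substreams are stable when hormones are added or dropped", {
  specs <- default_hormone_specs()
  full <- simulate_cohort(simulation_config(hormone_specs = specs, seed = 9))
  solo <- simulate_cohort(simulation_config(hormone_specs = specs["leptin"],
                                            seed = 9))
  merged <- merge(full[full$hormone == "leptin",
                       c("participant_id", "assessment", "value_pgml")],
                  solo[, c("participant_id", "assessment", "value_pgml")],
                  by = c("participant_id", "assessment"))
  expect_equal(merged$value_pgml.x, merged$value_pgml.y)
})

test_that("degenerate true ICC of 1 is rejected at spec construction", {
  expect_error(hormone_spec("x", 0, 1, true_icc = 1), "degenerate")
  expect_error(hormone_spec("x", 0, 1, true_icc = -0.1), ">=")
  expect_error(hormone_spec("x", 0, 0, true_icc = 0.5), "> 0")
})

test_that("simulated marginals match their log-normal targets", {
  # ghrelin preset: baseline median within 10% of 771.92 pg/mL at n = 1000
  cfg <- simulation_config(n_participants = 1000, seed = 123)
  co <- simulate_cohort(cfg)
  bl <- co[co$hormone == "ghrelin" & co$assessment == "BL", "value_pgml"]
  expect_equal(median(bl), 771.92, tolerance = 0.10)
  # log-scale total variance equals log_sd_total^2 within sampling error
  spec <- default_hormone_specs()$ghrelin
  expect_equal(sd(log(bl)), spec$log_sd_total, tolerance = 0.12)
})

test_that("estimated ICC converges to the configured truth", {
  # Monte Carlo recovery at the excellent-reliability preset: mean
  # estimated ICC over replicates within +/- 0.02 of 0.99, cross-checked
  # against the sums-of-squares oracle
  ests <- vapply(1:100, function(i) {
    co <- simulate_cohort(simulation_config(
      n_participants = 200,
      hormone_specs = list(hormone_spec("h", 0, 1, true_icc = 0.99)),
      covariate_specs = list(), seed = 200 + i))
    x <- log(unclass(cohort_to_paired(co, "h")))
    est <- icc_a1(x)$estimate
    expect_equal(est, oracle_icc_a1(x), tolerance = 1e-10)
    est
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.99), 0.02)
})

test_that("below-detection and above-standard simulated values pass the censoring pathway", {
  spec <- hormone_spec("h", log_median = 1, log_sd_total = 1, true_icc = 0.5,
                       detection_limit = 2, upper_standard = 10)
  co <- simulate_cohort(simulation_config(
    n_participants = 300, hormone_specs = list(spec),
    covariate_specs = list(), seed = 31))
  v <- co$value_pgml
  expect_true(all(v == 0 | (v >= 2 & v <= 10)))
  expect_true(any(v == 0))      # floor reached
  expect_true(any(v == 10))     # ceiling reached
})

test_that("weight drift with a weight effect lowers the estimated ICC", {
  est_for <- function(drift, seed) {
    covs <- default_covariate_specs()
    covs$weight$effects <- c(h = 0.05)
    co <- simulate_cohort(simulation_config(
      n_participants = 80,
      hormone_specs = list(hormone_spec("h", 8.5, 0.583, true_icc = 0.51)),
      covariate_specs = covs, weight_drift_sd = drift, seed = seed))
    icc_a1(log(unclass(cohort_to_paired(co, "h"))))$estimate
  }
  seeds <- 1:25
  stable <- vapply(seeds, function(s) est_for(0, s), numeric(1))
  drifting <- vapply(seeds, function(s) est_for(5, s), numeric(1))
  expect_lt(mean(drifting), mean(stable))
})

test_that("null pair generator is seeded, exchangeable and correctly shaped", {
  m <- simulate_null_pairs(17, 0.5, seed = 4)
  expect_equal(dim(m), c(17L, 2L))
  expect_identical(unclass(m), unclass(simulate_null_pairs(17, 0.5, seed = 4)))
  expect_error(simulate_null_pairs(1, 0.5, seed = 1), ">= 2")
  # column means agree on average over replicates (exchangeability)
  d <- vapply(1:2000, function(i) {
    m <- simulate_null_pairs(10, 0.4, seed = i)
    mean(m[, 2]) - mean(m[, 1])
  }, numeric(1))
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})
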