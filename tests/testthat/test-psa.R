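test_that("fixed specs return the base paramset unchanged", {
  base <- base_case_fixture(60, "male", 0.10)
  specs <- list(dist_spec(c("costs", "annual_drug_cost"), "fixed",
                          mean = base$costs$annual_drug_cost))
  p <- sample_paramset(base, specs, seed = 1, draw = 1)
  expect_equal(unclass(p), unclass(base))
})

test_that("draws are reproducible given (seed, draw) and differ across draws", {
  base <- base_case_fixture(60, "male", 0.10)
  specs <- default_psa_specs(base)
  a <- sample_paramset(base, specs, seed = 5, draw = 3)
  b <- sample_paramset(base, specs, seed = 5, draw = 3)
  expect_identical(a, b)
  c <- sample_paramset(base, specs, seed = 5, draw = 4)
  expect_false(identical(a, c))
  d <- sample_paramset(base, specs, seed = 6, draw = 3)
  expect_false(identical(a, d))
})

test_that("sampling hits the specified means (law of large numbers)", {
  specs <- list(
    beta = dist_spec(c("adverse", "annual_probability"), "beta",
                     mean = 0.02, se = 0.005),
    gamma = dist_spec(c("costs", "annual_drug_cost"), "gamma",
                      mean = 400, se = 80),
    lognormal = dist_spec("effect", "lognormal", mean = 0.8, se = 0.1,
                          match = list(event_category = "mi"), column = "rr")
  )
  set.seed(99)
  for (nm in names(specs)) {
    draws <- replicate(10000, htnce:::draw_spec(specs[[nm]]))
    se_mean <- stats::sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - specs[[nm]]$mean), 3 * se_mean,
              label = paste("mean of", nm, "draws"))
  }
})

test_that("sampled parameter sets always validate and respect roles", {
  base <- base_case_fixture(60, "female", 0.10)
  specs <- default_psa_specs(base)
  for (i in 1:25) {
    p <- sample_paramset(base, specs, seed = 11, draw = i)
    expect_s3_class(validate_paramset(p), "paramset")
    expect_true(all(p$costs$event_costs >= 0))
    expect_true(all(p$utilities$multipliers$event_multiplier <= 1))
    expect_true(p$adverse$annual_probability >= 0 &&
                  p$adverse$annual_probability <= 1)
    expect_true(all(p$effect$rr > 0))
  }
})

test_that("degenerate distributions reproduce the deterministic result exactly", {
  base <- base_case_fixture(60, "male", 0.10)
  specs <- list(dist_spec(c("costs", "annual_drug_cost"), "fixed",
                          mean = base$costs$annual_drug_cost))
  det <- evaluate_paramset(base)
  psa <- run_psa(base, specs, n_draws = 3, seed = 1)
  expect_true(psa$prob_ce %in% c(0, 1))
  expect_equal(psa$prob_ce, as.numeric(det$cost_effective))
  expect_equal(psa$draws$delta_cost, rep(det$delta_cost, 3))
  psa1 <- run_psa(base, specs, n_draws = 1, seed = 1)
  expect_true(psa1$prob_ce %in% c(0, 1))
})

test_that("PSA is deterministic given its seed and obeys CEAC identities", {
  base <- base_case_fixture(60, "male", 0.10, max_cycles = 30)
  specs <- default_psa_specs(base)
  a <- run_psa(base, specs, n_draws = 40, seed = 3)
  b <- run_psa(base, specs, n_draws = 40, seed = 3)
  expect_identical(a$draws, b$draws)

  # CEAC endpoints: at zero WTP only cost savings count; at a huge WTP only
  # QALY gains count.
  grid <- c(0, seq(1000, 50000, by = 7000), 1e9)
  psa <- run_psa(base, specs, n_draws = 40, seed = 3, wtp_grid = grid)
  expect_equal(psa$ceac$prob_ce[1], mean(psa$draws$delta_cost < 0))
  expect_equal(psa$ceac$prob_ce[nrow(psa$ceac)],
               mean(psa$draws$delta_qalys > 0))
  if (all(psa$draws$delta_qalys > 0))
    expect_true(all(diff(psa$ceac$prob_ce) >= 0))
})

test_that("disjoint seed blocks agree within binomial error", {
  base <- base_case_fixture(60, "male", 0.10, max_cycles = 30)
  specs <- default_psa_specs(base)
  n <- 60
  p1 <- run_psa(base, specs, n_draws = n, seed = 101)$prob_ce
  p2 <- run_psa(base, specs, n_draws = n, seed = 202)$prob_ce
  pool <- (p1 + p2) / 2
  se <- sqrt(2 * pool * (1 - pool) / n)
  expect_lt(abs(p1 - p2), 1.96 * se + 1e-9)
})

test_that("as variances shrink the mean PSA ICER approaches the deterministic ICER", {
  base <- base_case_fixture(60, "male", 0.10, max_cycles = 30)
  det <- evaluate_paramset(base)
  psa <- run_psa(base, default_psa_specs(base, cv = 0.005), n_draws = 30,
                 seed = 4)
  icer_mean <- mean(psa$draws$delta_cost) / mean(psa$draws$delta_qalys)
  expect_lt(abs(icer_mean - det$icer) / det$icer, 0.02)
})

test_that("a spec that can never validate errors after bounded retries", {
  base <- base_case_fixture(60, "male", 0.10)
  specs <- list(dist_spec(c("risk_increment"), "fixed", mean = -1))
  expect_error(sample_paramset(base, specs, seed = 1, draw = 1,
                               max_retries = 3),
               "no valid draw")
})
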