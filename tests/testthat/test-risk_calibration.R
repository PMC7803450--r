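test_that("constant-risk calibration matches the closed form", {
  expect_equal(solve_first_event_risk(1 - (1 - 0.01)^10, delta = 0), 0.01,
               tolerance = 1e-12)
  expect_equal(solve_first_event_risk(0.10, delta = 0),
               1 - 0.9^(1 / 10), tolerance = 1e-12)
  expect_equal(solve_first_event_risk(0, delta = 0), 0)
  expect_lt(solve_first_event_risk(1e-8, delta = 0), 2e-9)
})

test_that("calibration with an additive increment matches a uniroot oracle", {
  cases <- expand.grid(r10 = c(0.05, 0.10, 0.20, 0.40),
                       delta = c(2e-4, 5e-4, 1e-3, 3e-3))
  # Drop pairs where the increment alone compounds past the target risk.
  feasible <- mapply(function(r10, d) 1 - prod(1 - (0:9) * d) < r10,
                     cases$r10, cases$delta)
  expect_gt(sum(feasible), 10)
  for (i in which(feasible)) {
    r10 <- cases$r10[i]; delta <- cases$delta[i]
    p1 <- solve_first_event_risk(r10, delta)
    expect_lt(abs(p1 - oracle_first_event_risk(r10, delta)), 1e-10)
    p <- p1 + (0:9) * delta
    expect_lt(abs((1 - prod(1 - p)) - r10), 1e-10)
  }
})

test_that("calibration is monotone in risk and in the increment", {
  p1 <- vapply(c(0.05, 0.10, 0.15, 0.20), solve_first_event_risk, numeric(1),
               delta = 1e-3)
  expect_true(all(diff(p1) > 0))
  p1d <- vapply(c(0, 5e-4, 1e-3, 2e-3), function(d)
    solve_first_event_risk(0.10, d), numeric(1))
  expect_true(all(diff(p1d) < 0))
})

test_that("an increment too large for the target risk is an explicit infeasibility", {
  expect_error(solve_first_event_risk(0.01, delta = 0.01), "no feasible")
})

test_that("the annual schedule follows the additive rule and splits by category", {
  p <- toy_paramset()
  sched <- annual_schedule(0.02, 0, p$events, p$profile, 5)
  expect_equal(sched$p_total, rep(0.02, 5))
  expect_equal(sched$mi, rep(0.01, 5))
  expect_equal(sched$stroke, rep(0.006, 5))
  expect_equal(sched$fatal_cvd, rep(0.004, 5))
  expect_equal(sched$stable_angina, rep(0, 5))

  sched <- annual_schedule(0.02, 0.001, p$events, p$profile, 10)
  expect_equal(sched$p_total, 0.02 + (0:9) * 0.001)
  expect_equal(rowSums(sched[, event_categories()]), sched$p_total)
})

test_that("the schedule switches the category split at an age-band boundary", {
  # Two bands meeting at age 65; the split flips from all-MI to all-stroke.
  bands <- data.frame(age_lo = c(40, 65), age_hi = c(64, 115))
  ev <- do.call(rbind, lapply(c("male", "female"), function(sx) {
    df <- cbind(bands, sex = sx)
    for (cat in event_categories()) df[[cat]] <- 0
    df$mi <- c(1, 0); df$stroke <- c(0, 1)
    df
  }))
  sched <- annual_schedule(0.02, 0, ev, list(start_age = 60, sex = "male"), 10)
  expect_equal(sched$mi, c(rep(0.02, 5), rep(0, 5)))      # ages 60..64
  expect_equal(sched$stroke, c(rep(0, 5), rep(0.02, 5)))  # ages 65..69
})

test_that("the schedule caps total risk with a warning, not an error", {
  p <- toy_paramset()
  expect_warning(
    sched <- annual_schedule(0.9, 0.05, p$events, p$profile, 10,
                             risk_cap = 0.95),
    "cap")
  expect_true(all(sched$p_total <= 0.95))
})

test_that("non-CVD death probability is the lifetable value scaled by the non-circulatory fraction", {
  m <- list(lifetable = data.frame(age = c(60, 60), sex = c("male", "female"),
                                   all_cause_q = c(0.02, 0.015),
                                   noncirc_fraction = c(0.7, 1)))
  expect_equal(non_cvd_death_prob(60, "male", m), 0.014)
  expect_equal(non_cvd_death_prob(60, "female", m), 0.015)
  m$lifetable$noncirc_fraction[1] <- 0
  expect_equal(non_cvd_death_prob(60, "male", m), 0)
  expect_error(non_cvd_death_prob(61, "male", m), "no entry")
})

test_that("SMR scaling acts on the rate scale and is monotone", {
  expect_equal(post_event_death_prob(0.01, 1), 0.01)
  expect_equal(post_event_death_prob(0, 5), 0)
  expect_equal(post_event_death_prob(0.01, 2), 1 - 0.99^2)
  q <- seq(0, 0.5, by = 0.05)
  for (smr in c(1, 1.5, 2.5, 10)) {
    got <- post_event_death_prob(q, smr)
    expect_equal(got, 1 - exp(-smr * (-log(1 - q))), tolerance = 1e-12)
    expect_true(all(got <= 1 & got >= q - 1e-15))
  }
  expect_true(all(diff(post_event_death_prob(0.02, c(1, 2, 4, 8))) > 0))
})
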