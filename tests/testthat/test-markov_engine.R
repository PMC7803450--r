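test_that("death rows are absorbing and forbidden transitions are exactly zero", {
  p <- base_case_fixture(60, "female", 0.20)
  mask <- transition_mask()
  for (arm in c("treated", "comparator")) {
    m <- build_transition_matrix(p, arm, 3)
    expect_equal(m["death_cvd", ], (state_names() == "death_cvd") * 1,
                 ignore_attr = TRUE)
    expect_equal(m["death_noncvd", ], (state_names() == "death_noncvd") * 1,
                 ignore_attr = TRUE)
    expect_true(all(m[!mask] == 0))
    expect_equal(rowSums(m), rep(1, n_states()), ignore_attr = TRUE)
  }
})

test_that("zero risks and zero mortality freeze the cohort except tunnel flushing", {
  p <- toy_paramset(r10 = 0, q = 0)
  m <- build_transition_matrix(p, "comparator", 1)
  # Well, post-event and death rows are identity rows; event-year states are
  # one-cycle tunnels and still move to their own post-event state.
  keep <- !startsWith(state_names(), "event_")
  expect_equal(m[keep, ], diag(n_states())[keep, ], ignore_attr = TRUE)
  for (cat in nonfatal_categories())
    expect_equal(m[paste0("event_", cat), paste0("post_", cat)], 1)
})

test_that("matrix entries match a hand-written reduced fixture", {
  # Constant lifetable q = 0.02, non-circulatory fraction 0.7, first-event
  # split MI 0.5 / stroke 0.3 / fatal 0.2 on an annual risk of exactly 0.01,
  # SMR 2 after MI. All numbers below are hand-computed.
  p <- toy_paramset(r10 = 1 - (1 - 0.01)^10, delta = 0)
  mc <- build_transition_matrix(p, "comparator", 1)
  expect_equal(mc["well", "event_mi"], 0.005)
  expect_equal(mc["well", "event_stroke"], 0.003)
  expect_equal(mc["well", "death_cvd"], 0.002)
  expect_equal(mc["well", "death_noncvd"], 0.014)
  expect_equal(mc["well", "well"], 1 - 0.01 - 0.014)
  expect_equal(mc["event_mi", "post_mi"], 1 - 0.014)
  expect_equal(mc["event_mi", "death_noncvd"], 0.014)
  expect_equal(mc["post_mi", "post_mi"], 0.98^2)
  expect_equal(mc["post_mi", "death_noncvd"], 0.02)          # background
  expect_equal(mc["post_mi", "death_cvd"], 1 - 0.98^2 - 0.02) # SMR excess

  # Treated arm: RR 0.8 (MI), 0.75 (stroke), 0.85 (fatal), age factor 1.
  mt <- build_transition_matrix(p, "treated", 1)
  expect_equal(mt["well", "event_mi"], 0.005 * 0.8)
  expect_equal(mt["well", "event_stroke"], 0.003 * 0.75)
  expect_equal(mt["well", "death_cvd"], 0.002 * 0.85)
  expect_equal(mt["well", "well"],
               1 - 0.004 - 0.00225 - 0.0017 - 0.014)
})

test_that("the background_split death attribution moves circulatory background deaths", {
  p <- toy_paramset()
  p$smr_split <- "background_split"
  m <- build_transition_matrix(p, "comparator", 1)
  expect_equal(m["post_mi", "death_noncvd"], 0.02 * 0.7)
  expect_equal(m["post_mi", "death_cvd"], 0.02 * 0.3 + (1 - 0.98^2 - 0.02))
  expect_equal(m["post_mi", "post_mi"], 0.98^2)
})

test_that("cycle-1 occupancy equals the first matrix's well row", {
  p <- base_case_fixture(50, "male", 0.10)
  tr <- run_cohort(p, "treated")
  m1 <- build_transition_matrix(p, "treated", 1)
  expect_equal(unclass(tr)[2, ], m1["well", ])
  expect_equal(unclass(tr)[1, "well"], 1)
})

test_that("with no mortality and no events the cohort stays well throughout", {
  p <- toy_paramset(r10 = 0, q = 0, max_cycles = 55)
  tr <- run_cohort(p, "comparator")
  expect_equal(unclass(tr)[, "well"], rep(1, 56), ignore_attr = TRUE)
})

test_that("trace conservation, positivity and monotone death occupancy", {
  for (seed in 1:8) {
    p <- random_paramset(seed)
    for (arm in c("treated", "comparator")) {
      occ <- unclass(run_cohort(p, arm))
      expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
      expect_true(all(occ >= 0))
      expect_true(all(diff(occ[, "death_cvd"]) >= -1e-15))
      expect_true(all(diff(occ[, "death_noncvd"]) >= -1e-15))
    }
  }
})

test_that("cohort trace matches a seeded microsimulation", {
  p <- base_case_fixture(60, "male", 0.10, max_cycles = 12)
  n <- 2e5
  for (arm in c("treated", "comparator")) {
    trace <- unclass(run_cohort(p, arm))
    freq <- microsimulate(p, arm, n_persons = n, seed = 20260929)
    expect_microsim_agreement(trace, freq, n)
  }
})

test_that("half-cycle correction gives half a cycle of payoff when everyone dies in cycle 1", {
  p <- toy_paramset(r10 = 0, q = 1, noncirc = 1, max_cycles = 3,
                    drug_cost = 0, monitoring_cost = 0)
  p$settings$discount_rate_qalys <- 0
  res <- run_arm(p, "comparator")
  expect_equal(res$discounted_qalys, 0.5)
  expect_equal(res$life_years, 0.5)
})

test_that("a constant-payoff cohort reproduces the annuity closed form", {
  p <- toy_paramset(r10 = 0, q = 0, max_cycles = 10, drug_cost = 60,
                    monitoring_cost = 40)
  p$settings$discount_rate_qalys <- 0
  res <- run_arm(p, "treated")
  expect_equal(res$discounted_qalys, 10)
  expect_equal(res$discounted_cost, annuity(100, 0.035, 10),
               tolerance = 1e-12)
})

test_that("raising a state cost raises that arm's discounted cost; raising risk lowers QALYs", {
  p <- base_case_fixture(60, "male", 0.10)
  base_cost <- run_arm(p, "treated")$discounted_cost
  p2 <- p
  p2$costs$event_costs[["stroke"]] <- p2$costs$event_costs[["stroke"]] + 5000
  expect_gt(run_arm(p2, "treated")$discounted_cost, base_cost)

  q_lo <- run_arm(p, "comparator")$discounted_qalys
  p3 <- p; p3$profile$r10 <- 0.20
  expect_lt(run_arm(p3, "comparator")$discounted_qalys, q_lo)
  q_lo_t <- run_arm(p, "treated")$discounted_qalys
  expect_lt(run_arm(p3, "treated")$discounted_qalys, q_lo_t)
})

test_that("trace exports to a per-cycle data frame", {
  p <- toy_paramset(max_cycles = 4)
  df <- as.data.frame(run_cohort(p, "treated"))
  expect_equal(nrow(df), 5)
  expect_equal(df$cycle, 0:4)
  expect_true(all(state_names() %in% names(df)))
})
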