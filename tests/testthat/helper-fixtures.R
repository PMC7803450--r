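# Shared fixtures and independent oracles used across test files.

# A deliberately simple parameter set for hand calculation: one age band,
# constant lifetable, events restricted to MI / stroke / fatal CVD.
toy_paramset <- function(r10 = 1 - (1 - 0.01)^10, delta = 0, q = 0.02,
                         noncirc = 0.7, smr_mi = 2, rr_mi = 0.8,
                         rr_stroke = 0.75, rr_fatal = 0.85, max_cycles = 10,
                         sex = "male", drug_cost = 25, monitoring_cost = 110,
                         ae_prob = 0, ae_background = 0, ae_cost = 0,
                         ae_disutility = 0, utility = 1, delay = "never") {
  nf <- nonfatal_categories()
  band <- data.frame(age_lo = 40, age_hi = 115)
  events <- do.call(rbind, lapply(c("male", "female"), function(sx) {
    df <- cbind(band, sex = sx)
    for (cat in event_categories()) df[[cat]] <- 0
    df$mi <- 0.5; df$stroke <- 0.3; df$fatal_cvd <- 0.2
    df
  }))
  lt <- do.call(rbind, lapply(c("male", "female"), function(sx)
    data.frame(age = 40:115, sex = sx, all_cause_q = q,
               noncirc_fraction = noncirc)))
  rr <- c(stable_angina = 1, unstable_angina = 1, mi = rr_mi,
          stroke = rr_stroke, tia = 1, heart_failure = 1,
          fatal_cvd = rr_fatal)
  effect <- do.call(rbind, lapply(event_categories(), function(cat)
    cbind(band, data.frame(event_category = cat, rr = rr[[cat]],
                           age_factor = 1))))
  utilities <- list(
    baseline = do.call(rbind, lapply(c("male", "female"), function(sx)
      cbind(band, data.frame(sex = sx, utility = utility)))),
    multipliers = data.frame(event_category = nf,
                             event_multiplier = c(1, 1, 0.8, 0.7, 1, 1),
                             post_multiplier = c(1, 1, 0.9, 0.75, 1, 1)))
  smr <- c(stable_angina = 1, unstable_angina = 1, mi = smr_mi, stroke = 2,
           tia = 1, heart_failure = 1)
  costs <- list(annual_drug_cost = drug_cost,
                annual_monitoring_cost = monitoring_cost,
                event_costs = stats::setNames(c(0, 0, 4000, 11900, 0, 0), nf),
                post_event_costs = stats::setNames(c(0, 0, 250, 2500, 0, 0), nf))
  paramset(
    settings = list(cycle_length = 1, max_cycles = max_cycles,
                    discount_rate_costs = 0.035, discount_rate_qalys = 0.035,
                    wtp_threshold = 20000, currency_year = "2016/17"),
    profile = list(start_age = 60, sex = sex, r10 = r10),
    events = events,
    mortality = list(lifetable = lt, smr = smr),
    effect = effect,
    adverse = list(annual_probability = ae_prob,
                   background_probability = ae_background,
                   cost_per_event = ae_cost, disutility = ae_disutility),
    utilities = utilities,
    costs = costs,
    risk_increment = delta,
    comparator_treatment_delay = delay
  )
}

# Annuity closed form: present value of a constant payoff over n cycles,
# first cycle discounted at power 1.
annuity <- function(a, r, n) if (r == 0) a * n else a * (1 - (1 + r)^-n) / r

# Independent root-finding oracle for the risk calibration (uniroot on the
# compounding equation, not the package's own bisection).
oracle_first_event_risk <- function(r10, delta, horizon = 10) {
  f <- function(p1) 1 - prod(1 - (p1 + (seq_len(horizon) - 1) * delta)) - r10
  stats::uniroot(f, c(1e-12, 1 - (horizon - 1) * delta - 1e-12),
                 tol = 1e-13)$root
}

# Assert agreement between a cohort trace and microsimulated frequencies.
# Per cell the binomial z-score must stay below a multiplicity-corrected
# bound (family-wise level 1% across all state x cycle cells; a flat 3-SE
# rule would falsely fail a correct engine in most runs with ~300 cells),
# and cells beyond 3 SE must be no more frequent than binomial sampling
# itself produces.
expect_microsim_agreement <- function(trace, freq, n) {
  se <- sqrt(trace * (1 - trace) / n)
  dev <- abs(freq - trace)
  n_cells <- length(trace)
  z_star <- stats::qnorm(1 - 0.01 / (2 * n_cells))
  expect_true(all(dev <= z_star * se + 3 / n),
              label = sprintf("all %d cells within %.1f binomial SEs",
                              n_cells, z_star))
  n_over_3se <- sum(dev > 3 * se + 3 / n)
  expect_lte(n_over_3se, stats::qbinom(0.995, n_cells, 0.0027) + 1)
}

# Seeded microsimulation: pushes individual persons through the same
# per-cycle transition matrices by sampling each person's next state, as an
# independent check on the deterministic cohort propagation.
microsimulate <- function(p, arm, n_persons = 1e5, seed = 1) {
  ctx <- htnce:::arm_context(p, arm)
  n_cycles <- p$settings$max_cycles
  k <- n_states()
  counts <- matrix(0, n_cycles + 1, k,
                   dimnames = list(0:n_cycles, state_names()))
  set.seed(seed)
  state <- rep(1L, n_persons)
  counts[1, 1] <- n_persons
  for (t in seq_len(n_cycles)) {
    m <- build_transition_matrix(p, arm, t, ctx)
    new_state <- integer(n_persons)
    for (s in unique(state)) {
      idx <- state == s
      new_state[idx] <- sample.int(k, sum(idx), replace = TRUE,
                                   prob = m[s, ])
    }
    state <- new_state
    counts[t + 1, ] <- tabulate(state, k)
  }
  counts / n_persons
}
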