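# Cohort engine: per-cycle transition matrices over the 15-state space,
# forward propagation, and half-cycle-corrected discounted payoffs.

# Precompute everything run_cohort/accumulate need for one arm: the calibrated
# risk schedule and, per cycle, ages and on-treatment flags per state.
arm_context <- function(p, arm) {
  n <- p$settings$max_cycles
  p1 <- solve_first_event_risk(p$profile$r10, p$risk_increment, 10)
  sched <- annual_schedule(p1, p$risk_increment, p$events, p$profile, n,
                           p$risk_cap)
  ages <- p$profile$start_age + seq_len(n) - 1
  sex <- p$profile$sex

  lt <- p$mortality$lifetable
  lt <- lt[lt$sex == sex, ]
  i <- match(ages, lt$age)
  if (anyNA(i))
    stop(sprintf("lifetable: no entry for age %s, sex %s",
                 ages[which(is.na(i))[1]], sex))
  q_all <- lt$all_cause_q[i]
  q_nc <- q_all * lt$noncirc_fraction[i]

  # Effective RR per cycle and category: base RR x age factor of the band
  # containing the age reached that cycle.
  cats <- event_categories()
  rr_mat <- matrix(NA_real_, n, length(cats), dimnames = list(NULL, cats))
  for (cat in cats) {
    rows <- p$effect[p$effect$event_category == cat, , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      in_band <- ages >= rows$age_lo[j] & ages <= rows$age_hi[j]
      rr_mat[in_band, cat] <- rows$rr[j] * rows$age_factor[j]
    }
  }
  if (anyNA(rr_mat))
    stop("effect table: age bands do not cover every modelled age")

  list(arm = arm, schedule = sched, p1 = p1, ages = ages,
       q_nc = q_nc, q_all = q_all, rr = rr_mat,
       p_event = as.matrix(sched[, cats]))
}

# Integer state indices; order fixed by state_names().
.i_well <- 1L
.i_event <- 2:7
.i_post <- 8:13
.i_dcvd <- 14L
.i_dnc <- 15L

#' Build the transition matrix for one cycle
#'
#' Constructs the row-stochastic 15 x 15 matrix governing transitions during
#' cycle `cycle` (ages advance by one year per cycle from the starting age):
#'
#' * well -> event-year states: calibrated per-category first-event
#'   probabilities for the age reached, multiplied by the effective relative
#'   risk when the arm is on treatment in the well state;
#' * well -> CVD death: the fatal-CVD category of the same distribution;
#' * well / event-year -> non-CVD death: lifetable probability times the
#'   non-circulatory fraction;
#' * event-year -> own post-event state (one-cycle tunnel; repeat events are
#'   not modelled);
#' * post-event -> death: all-cause probability raised to the category's
#'   standardized mortality ratio on the rate scale, attributed between CVD
#'   and non-CVD death by the configured split rule;
#' * death states absorbing.
#'
#' @param p a `paramset`.
#' @param arm `"treated"` or `"comparator"`.
#' @param cycle 1-based cycle number (<= `max_cycles`).
#' @param context optional precomputed output of the internal arm context
#'   (used by [run_cohort()] to avoid re-calibrating per cycle).
#' @return row-stochastic matrix with state names on both dimensions.
#' @export
build_transition_matrix <- function(p, arm, cycle, context = NULL) {
  stopifnot(cycle >= 1, cycle <= p$settings$max_cycles)
  if (is.null(context)) context <- arm_context(p, arm)
  s <- state_names()
  nf <- nonfatal_categories()
  age <- p$profile$start_age + cycle - 1
  sex <- p$profile$sex
  delay <- p$comparator_treatment_delay

  m <- matrix(0, n_states(), n_states(), dimnames = list(s, s))
  q_nc <- context$q_nc[cycle]
  q_all <- context$q_all[cycle]
  noncirc <- q_nc / q_all
  if (!is.finite(noncirc)) noncirc <- 1

  # Well row: first-event split (treated if on treatment) + non-CVD death.
  pc <- context$p_event[cycle, ]
  if (arm_is_on_treatment(arm, cycle, "well", delay)) {
    pc <- treated_event_prob(pc, context$rr[cycle, ])
  }
  stay <- 1 - sum(pc) - q_nc
  if (stay < -1e-9)
    stop(sprintf(
      "transition matrix construction: well-row probabilities sum to %.6f > 1 at cycle %d",
      sum(pc) + q_nc, cycle))
  m[.i_well, .i_event] <- pc[1:6]
  m[.i_well, .i_dcvd] <- pc[[7]] # fatal first CVD events
  m[.i_well, .i_dnc] <- q_nc
  m[.i_well, .i_well] <- max(stay, 0)

  # Event-year tunnels: to own post-event state or non-CVD death.
  m[cbind(.i_event, .i_dnc)] <- q_nc
  m[cbind(.i_event, .i_post)] <- 1 - q_nc

  # Post-event states: SMR-adjusted all-cause mortality, split between death
  # causes by the configured rule; remainder stays put (no repeat events).
  qp <- post_event_death_prob(q_all, p$mortality$smr[nf])
  excess <- qp - q_all
  if (p$smr_split == "excess_to_cvd") {
    d_nc <- rep(q_all, 6)
    d_cvd <- excess
  } else { # background_split
    d_nc <- rep(q_all * noncirc, 6)
    d_cvd <- q_all * (1 - noncirc) + excess
  }
  m[cbind(.i_post, .i_dnc)] <- d_nc
  m[cbind(.i_post, .i_dcvd)] <- d_cvd
  m[cbind(.i_post, .i_post)] <- 1 - qp

  m[.i_dcvd, .i_dcvd] <- 1
  m[.i_dnc, .i_dnc] <- 1

  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-9))
    stop("transition matrix construction: row sums deviate from 1 by more than 1e-9")
  m
}

#' Run the cohort through the model
#'
#' Starts the whole cohort in the well state and propagates the occupancy
#' vector through the per-cycle transition matrices for `max_cycles` one-year
#' cycles.
#'
#' @inheritParams build_transition_matrix
#' @return a `cohort_trace`: numeric matrix with one row per cycle boundary
#'   (0 .. `max_cycles`) and one column per state; rows sum to 1.
#' @export
run_cohort <- function(p, arm = c("treated", "comparator")) {
  arm <- match.arg(arm)
  validate_paramset(p)
  ctx <- arm_context(p, arm)
  n <- p$settings$max_cycles
  occ <- matrix(0, n + 1, n_states(),
                dimnames = list(0:n, state_names()))
  occ[1, "well"] <- 1
  for (t in seq_len(n)) {
    m <- build_transition_matrix(p, arm, t, ctx)
    occ[t + 1, ] <- occ[t, ] %*% m
  }
  structure(occ, class = c("cohort_trace", "matrix"), arm = arm,
            start_age = p$profile$start_age)
}

#' Export a cohort trace as a data frame
#'
#' @param x a `cohort_trace`.
#' @param ... unused.
#' @return data frame with a `cycle` column (boundary index) followed by one
#'   column per state.
#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  cbind(data.frame(cycle = as.integer(rownames(unclass(x)))),
        as.data.frame(unclass(x)))
}

#' Accumulate discounted, half-cycle-corrected costs and QALYs
#'
#' Payoffs use the half-cycle correction: each cycle's state occupancy is
#' taken as the mean of the occupancies at its two boundaries, reflecting
#' transitions occurring on average mid-cycle. The one exception is one-off
#' event-year costs, which are within-cycle quantities applied in full to the
#' cohort entering an event state that cycle. Cycle t payoffs are discounted
#' by `(1 + r)^-t`.
#'
#' Per alive state the annual QALY payoff is the age/sex baseline utility
#' times the state multiplier, minus the adverse-event disutility times the
#' adverse-event probability (treatment-dependent). The annual cost is drug
#' plus monitoring cost while on treatment, the expected adverse-event cost,
#' and the post-event annual cost where applicable.
#'
#' @param trace a `cohort_trace` from [run_cohort()].
#' @param p the `paramset` that produced it.
#' @param arm `"treated"` or `"comparator"`.
#' @return an `arm_result`: list with `discounted_cost`, `discounted_qalys`,
#'   `life_years` (undiscounted), `trace` and a per-cycle breakdown
#'   `by_cycle`.
#' @export
accumulate <- function(trace, p, arm = c("treated", "comparator")) {
  arm <- match.arg(arm)
  occ <- unclass(trace)
  n <- nrow(occ) - 1L
  s <- state_names()
  nf <- nonfatal_categories()
  sex <- p$profile$sex
  alive <- !is_death_state(s)
  event_cols <- paste0("event_", nf)
  post_cols <- paste0("post_", nf)

  um <- p$utilities$multipliers
  mult <- stats::setNames(rep(0, length(s)), s)
  mult["well"] <- 1
  mult[paste0("event_", um$event_category)] <- um$event_multiplier
  mult[paste0("post_", um$event_category)] <- um$post_multiplier

  post_cost <- stats::setNames(rep(0, length(s)), s)
  post_cost[paste0("post_", nf)] <- p$costs$post_event_costs[nf]
  event_cost <- p$costs$event_costs[nf]

  rc <- p$settings$discount_rate_costs
  rq <- p$settings$discount_rate_qalys
  delay_c <- delay_cycles(p)
  ae <- p$adverse

  ages <- p$profile$start_age + seq_len(n) - 1
  ub <- p$utilities$baseline
  ub <- ub[ub$sex == sex, , drop = FALSE]
  u_base <- rep(NA_real_, n)
  for (j in seq_len(nrow(ub))) {
    in_band <- ages >= ub$age_lo[j] & ages <= ub$age_hi[j]
    u_base[in_band] <- ub$utility[j]
  }
  if (anyNA(u_base))
    stop("utilities$baseline: age bands do not cover every modelled age")

  # On-treatment indicator per cycle (rows) and state (columns): the treated
  # arm is on treatment in every alive state; the comparator only after its
  # delay, except event-year/post-event states (treated in both arms).
  on_tr <- matrix(rep(alive, each = n), n, length(s))
  if (arm == "comparator")
    on_tr[, .i_well] <- seq_len(n) >= delay_c
  ae_p <- on_tr * ae$annual_probability +
    (!on_tr) * rep(alive, each = n) * ae$background_probability

  u_mat <- outer(u_base, mult) - ae$disutility * ae_p
  if (any(u_mat < 0)) {
    warning("negative state utility clamped to 0", call. = FALSE)
    u_mat <- pmax(u_mat, 0)
  }
  cost_mat <- rep(post_cost, each = n) + ae_p * ae$cost_per_event +
    on_tr * (p$costs$annual_drug_cost + p$costs$annual_monitoring_cost)

  occ_mid <- (occ[seq_len(n), , drop = FALSE] +
                occ[seq_len(n) + 1L, , drop = FALSE]) / 2
  qalys <- rowSums(occ_mid * u_mat)
  costs <- rowSums(occ_mid * cost_mat) +
    as.numeric(occ[seq_len(n) + 1L, event_cols, drop = FALSE] %*% event_cost)
  lys <- rowSums(occ_mid[, alive, drop = FALSE])

  t <- seq_len(n)
  dq <- (1 + rq)^(-t)
  dc <- (1 + rc)^(-t)
  structure(list(
    discounted_cost = sum(costs * dc),
    discounted_qalys = sum(qalys * dq),
    life_years = sum(lys),
    trace = trace,
    by_cycle = data.frame(cycle = t, age = p$profile$start_age + t - 1,
                          qalys = qalys, costs = costs, life_years = lys,
                          disc_qalys = qalys * dq, disc_costs = costs * dc)
  ), class = "arm_result", arm = arm)
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result: %s>\n  discounted cost  %12.2f\n  discounted QALYs %12.4f\n  life-years       %12.4f\n",
              attr(x, "arm"), x$discounted_cost, x$discounted_qalys,
              x$life_years))
  invisible(x)
}

#' Run one arm end to end
#'
#' Convenience wrapper: [run_cohort()] then [accumulate()].
#'
#' @inheritParams run_cohort
#' @return an `arm_result`.
#' @export
run_arm <- function(p, arm = c("treated", "comparator")) {
  arm <- match.arg(arm)
  accumulate(run_cohort(p, arm), p, arm)
}
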