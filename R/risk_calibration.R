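#' Calibrate the annual first-event probability to a 10-year CVD risk
#'
#' The annual probability of a first CVD event is assumed to grow additively
#' with age: in cycle t it is `p1 + (t - 1) * delta`. This solves for the
#' starting probability `p1` such that the schedule, compounded over the
#' `horizon`, reproduces the stated cumulative risk:
#' `1 - prod(1 - (p1 + (t-1) * delta)) = r10`.
#'
#' For `delta = 0` the closed form `1 - (1 - r10)^(1/horizon)` is used;
#' otherwise bisection on the (monotone) compounding equation, to a tolerance
#' of 1e-12 on `p1`.
#'
#' @param r10 cumulative first-event risk over the horizon, in `[0, 1)`
#'   (0 gives `p1 = 0`, used for lifetable-validation runs).
#' @param delta additive annual increment of the event probability (>= 0).
#' @param horizon compounding horizon in years (default 10).
#' @return `p1`, the calibrated first-year event probability.
#' @export
solve_first_event_risk <- function(r10, delta = 0, horizon = 10) {
  stopifnot(is.numeric(r10), length(r10) == 1L, r10 >= 0, r10 < 1,
            is.numeric(delta), length(delta) == 1L, delta >= 0,
            is.numeric(horizon), length(horizon) == 1L, horizon >= 1)
  if (r10 == 0) return(0)
  if (delta == 0) return(1 - (1 - r10)^(1 / horizon))

  compounded <- function(p1) {
    p <- p1 + (seq_len(horizon) - 1) * delta
    1 - prod(1 - p)
  }
  hi <- 1 - (horizon - 1) * delta - 1e-12
  if (hi <= 1e-12 || compounded(1e-12) > r10)
    stop(sprintf(
      "no feasible first-year probability: increment %.4g already compounds past risk %.4g over %d years",
      delta, r10, horizon))
  lo <- 1e-12
  if (compounded(hi) < r10)
    stop(sprintf(
      "no root in (0, 1): risk %.4g not reachable with increment %.4g over %d years",
      r10, delta, horizon))
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (compounded(mid) < r10) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Per-cycle first-event probabilities split by category
#'
#' Expands the calibrated first-year probability into a per-cycle schedule
#' `p(t) = p1 + (t - 1) * delta`, capped at `risk_cap` (with a warning the
#' first time the cap binds), and splits each cycle's total across the seven
#' event categories using the age/sex distribution of first events for the
#' age reached in that cycle.
#'
#' @param p1 calibrated first-year event probability
#'   (see [solve_first_event_risk()]).
#' @param delta additive annual increment.
#' @param events event-distribution table (see [paramset()]).
#' @param profile risk profile giving `start_age` and `sex`.
#' @param n_cycles number of one-year cycles.
#' @param risk_cap maximum allowed total annual probability (< 1).
#' @return data frame with one row per cycle: `cycle`, `age`, `p_total`, and
#'   one column per event category whose values sum to `p_total`.
#' @export
annual_schedule <- function(p1, delta, events, profile, n_cycles,
                            risk_cap = 0.99) {
  stopifnot(p1 >= 0, p1 <= 1, delta >= 0, n_cycles >= 1)
  t <- seq_len(n_cycles)
  age <- profile$start_age + t - 1
  p_total <- p1 + (t - 1) * delta
  if (any(p_total > risk_cap)) {
    warning(sprintf(
      "annual first-event risk reaches cap %.3g at cycle %d; capped thereafter",
      risk_cap, min(which(p_total > risk_cap))), call. = FALSE)
    p_total <- pmin(p_total, risk_cap)
  }
  cats <- event_categories()
  ev <- events[events$sex == profile$sex, , drop = FALSE]
  frac <- matrix(NA_real_, n_cycles, length(cats), dimnames = list(NULL, cats))
  for (j in seq_len(nrow(ev))) {
    in_band <- age >= ev$age_lo[j] & age <= ev$age_hi[j]
    if (any(in_band))
      frac[in_band, ] <- matrix(as.numeric(ev[j, cats]), sum(in_band),
                                length(cats), byrow = TRUE)
  }
  if (anyNA(frac))
    stop(sprintf("events: no age band covers ages %s (sex %s)",
                 paste(unique(age[!stats::complete.cases(frac)]),
                       collapse = ", "), profile$sex))
  cbind(data.frame(cycle = t, age = age, p_total = p_total),
        as.data.frame(p_total * frac))
}

#' Non-CVD death probability from the lifetable
#'
#' The annual probability of death from non-cardiovascular causes is the
#' all-cause lifetable probability at the given age and sex multiplied by the
#' non-circulatory fraction of deaths at that age and sex.
#'
#' @param age integer age (must be within the lifetable's range).
#' @param sex `"male"` or `"female"`.
#' @param mortality mortality model (see [paramset()]).
#' @return probability in `[0, 1]`.
#' @export
non_cvd_death_prob <- function(age, sex, mortality) {
  lt <- mortality$lifetable
  i <- which(lt$age == age & lt$sex == sex)
  if (length(i) != 1L)
    stop(sprintf("lifetable: no entry for age %s, sex %s", age, sex))
  lt$all_cause_q[i] * lt$noncirc_fraction[i]
}

# All-cause lifetable probability at (age, sex); internal.
all_cause_q <- function(age, sex, mortality) {
  lt <- mortality$lifetable
  i <- which(lt$age == age & lt$sex == sex)
  if (length(i) != 1L)
    stop(sprintf("lifetable: no entry for age %s, sex %s", age, sex))
  lt$all_cause_q[i]
}

#' Post-event death probability from a standardized mortality ratio
#'
#' Applies the SMR on the rate (hazard) scale rather than multiplying
#' probabilities directly, so the result stays in `[base_q, 1]` for any
#' SMR >= 1: `q' = 1 - (1 - base_q)^smr`, equivalent to multiplying the
#' cumulative hazard `-log(1 - base_q)` by `smr`.
#'
#' @param base_q background annual death probability, in `[0, 1]`.
#' @param smr standardized mortality ratio (>= 1).
#' @return adjusted annual death probability.
#' @export
post_event_death_prob <- function(base_q, smr) {
  stopifnot(all(base_q >= 0), all(base_q <= 1), all(smr >= 1))
  1 - (1 - base_q)^smr
}
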