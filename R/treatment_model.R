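#' Effective relative risk for an event category at a given age
#'
#' The base relative risk of each CVD event category under antihypertensive
#' treatment is adjusted by a relative age transformation: the effective RR is
#' the base `rr` times the `age_factor` of the age band containing the current
#' age. The RR is assumed constant across risk subgroups, so absolute benefit
#' scales with baseline risk.
#'
#' @param effect treatment-effect table (see [paramset()]).
#' @param event_category one of [event_categories()].
#' @param age current integer age.
#' @return effective relative risk (> 0).
#' @export
effective_rr <- function(effect, event_category, age) {
  if (!event_category %in% event_categories())
    stop("unknown event category: ", event_category)
  rows <- effect[effect$event_category == event_category, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("effect table has no rows for category ", event_category)
  row <- band_row(rows, age, what = paste0("effect[", event_category, "]"))
  row$rr * row$age_factor
}

#' Event probability under treatment
#'
#' Multiplies an untreated event probability by a relative risk, capping at 1
#' (with a warning when the cap binds, which can only happen for RR > 1).
#'
#' @param p_untreated untreated annual event probability in `[0, 1]`.
#' @param rr relative risk (> 0).
#' @return treated probability `min(p_untreated * rr, 1)`.
#' @export
treated_event_prob <- function(p_untreated, rr) {
  stopifnot(all(p_untreated >= 0), all(p_untreated <= 1), all(rr > 0))
  p <- p_untreated * rr
  if (any(p > 1)) {
    warning("treated event probability capped at 1", call. = FALSE)
    p <- pmin(p, 1)
  }
  p
}

#' Is an arm on drug treatment in a given cycle and state?
#'
#' The treated arm receives antihypertensive treatment in every alive state
#' and cycle. The comparator ("no treatment") arm starts treatment only once
#' the delay has elapsed (`cycle >= delay`) -- in the base case the delay is
#' `"never"` -- except that anyone who has had a nonfatal CVD event (an
#' event-year or post-event state) is treated in both arms. Dead states are
#' never on treatment.
#'
#' @param arm `"treated"` or `"comparator"`.
#' @param cycle 1-based cycle number.
#' @param state a state name (see [state_names()]).
#' @param delay comparator treatment delay in cycles, or `"never"`/`Inf`.
#' @return logical.
#' @export
arm_is_on_treatment <- function(arm, cycle, state, delay = "never") {
  if (!state %in% state_names()) stop("unknown state: ", state)
  if (is_death_state(state)) return(FALSE)
  if (arm == "treated") return(TRUE)
  if (arm != "comparator") stop("unknown arm: ", arm)
  if (is_event_state(state) || is_post_state(state)) return(TRUE)
  d <- if (identical(delay, "never")) Inf else as.numeric(delay)
  cycle >= d
}
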