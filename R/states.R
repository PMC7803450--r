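#' Event categories and state space
#'
#' The model distinguishes seven categories of first cardiovascular (CVD)
#' event: six nonfatal events -- stable angina (SA), unstable angina (UA),
#' myocardial infarction (MI), stroke, transient ischaemic attack (TIA) and
#' heart failure (HF) -- plus fatal CVD. Each nonfatal category has a one-year
#' tunnel ("event-year") state carrying first-year costs and utilities, and an
#' absorbing-until-death "post-event" state for subsequent years. Together
#' with the event-free ("well") state and the two death states this gives the
#' 15-state space of the cohort model.
#'
#' @return `event_categories()` returns the seven category labels;
#'   `nonfatal_categories()` the six nonfatal ones; `state_names()` the
#'   ordered 15 state labels.
#' @export
event_categories <- function() .cats

#' @rdname event_categories
#' @export
nonfatal_categories <- function() .nonfatal

#' @rdname event_categories
#' @export
state_names <- function() .states

.cats <- c("stable_angina", "unstable_angina", "mi", "stroke", "tia",
           "heart_failure", "fatal_cvd")
.nonfatal <- .cats[1:6]
.states <- c("well", paste0("event_", .nonfatal), paste0("post_", .nonfatal),
             "death_cvd", "death_noncvd")

#' @rdname event_categories
#' @export
n_states <- function() length(state_names())

# Index helpers (internal).
state_index <- function(state) {
  i <- match(state, state_names())
  if (anyNA(i)) stop("unknown state: ", paste(state[is.na(i)], collapse = ", "))
  i
}

is_death_state <- function(state) state %in% c("death_cvd", "death_noncvd")
is_event_state <- function(state) startsWith(state, "event_")
is_post_state  <- function(state) startsWith(state, "post_")

#' Permitted-transition mask of the model structure
#'
#' Logical 15 x 15 matrix with `TRUE` where the model structure permits a
#' transition: the well state can stay well, move to any event-year state or
#' die; an event-year state is a one-cycle tunnel that moves to its own
#' post-event state or to death; post-event states persist or die (no repeat
#' events); death states are absorbing.
#'
#' @return logical matrix with state names on both dimensions.
#' @export
transition_mask <- function() {
  s <- state_names()
  m <- matrix(FALSE, n_states(), n_states(), dimnames = list(s, s))
  nf <- nonfatal_categories()
  m["well", c("well", paste0("event_", nf), "death_cvd", "death_noncvd")] <- TRUE
  for (c in nf) {
    m[paste0("event_", c), c(paste0("post_", c), "death_cvd", "death_noncvd")] <- TRUE
    m[paste0("post_", c), c(paste0("post_", c), "death_cvd", "death_noncvd")] <- TRUE
  }
  m["death_cvd", "death_cvd"] <- TRUE
  m["death_noncvd", "death_noncvd"] <- TRUE
  m
}
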