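# Synthetic parameter bundles. The shipped base case is a clearly labelled
# synthetic stand-in with UK-plausible magnitudes: a Gompertz lifetable,
# age/sex-banded first-event distributions, meta-analysis-scale relative
# risks, EQ-5D-scale utilities and 2016/17-scale costs. The generator ranges
# are documented in the methods vignette.

synthetic_age_bands <- function() {
  data.frame(age_lo = c(40, 50, 60, 70, 80),
             age_hi = c(49, 59, 69, 79, 115))
}

synthetic_lifetable <- function(ages = 40:115) {
  # Gompertz hazard per sex, capped; non-circulatory fraction declines with
  # age as circulatory causes take a larger share of deaths.
  rows <- lapply(c("male", "female"), function(sx) {
    a <- if (sx == "male") 3.3e-5 else 1.6e-5
    b <- if (sx == "male") 0.093 else 0.097
    data.frame(age = ages, sex = sx,
               all_cause_q = pmin(a * exp(b * ages), 0.7),
               noncirc_fraction = pmin(pmax(0.92 - 0.002 * (ages - 40), 0.55),
                                       0.95))
  })
  do.call(rbind, rows)
}

synthetic_event_distribution <- function() {
  bands <- synthetic_age_bands()
  # Fractions of first CVD events by category: with age, stroke, heart
  # failure and fatal events take a larger share, infarction and angina a
  # smaller one; women have relatively more strokes, men more infarctions.
  male <- rbind(
    c(0.16, 0.08, 0.30, 0.18, 0.10, 0.06, 0.12),
    c(0.15, 0.08, 0.28, 0.20, 0.11, 0.07, 0.11),
    c(0.14, 0.07, 0.25, 0.24, 0.12, 0.08, 0.10),
    c(0.12, 0.06, 0.22, 0.26, 0.12, 0.10, 0.12),
    c(0.09, 0.05, 0.18, 0.28, 0.12, 0.13, 0.15))
  female <- rbind(
    c(0.18, 0.08, 0.22, 0.22, 0.12, 0.06, 0.12),
    c(0.17, 0.08, 0.21, 0.24, 0.12, 0.07, 0.11),
    c(0.16, 0.07, 0.19, 0.27, 0.13, 0.08, 0.10),
    c(0.13, 0.06, 0.17, 0.29, 0.13, 0.10, 0.12),
    c(0.10, 0.05, 0.14, 0.30, 0.13, 0.13, 0.15))
  mk <- function(m, sx) {
    df <- cbind(bands, sex = sx, as.data.frame(m))
    names(df)[4:10] <- event_categories()
    df
  }
  rbind(mk(male, "male"), mk(female, "female"))
}

synthetic_effect_table <- function() {
  bands <- synthetic_age_bands()
  # Base relative risks on the scale of antihypertensive primary-prevention
  # meta-analyses; the age factor attenuates the proportional effect at
  # older ages.
  rr <- c(stable_angina = 0.90, unstable_angina = 0.88, mi = 0.85,
          stroke = 0.75, tia = 0.78, heart_failure = 0.72, fatal_cvd = 0.85)
  age_factor <- c(0.92, 0.96, 1.00, 1.04, 1.08)
  do.call(rbind, lapply(event_categories(), function(cat)
    data.frame(event_category = cat, age_lo = bands$age_lo,
               age_hi = bands$age_hi, rr = rr[[cat]],
               age_factor = age_factor)))
}

synthetic_utilities <- function() {
  bands <- synthetic_age_bands()
  baseline <- rbind(
    data.frame(bands, sex = "male",
               utility = c(0.89, 0.86, 0.82, 0.78, 0.72)),
    data.frame(bands, sex = "female",
               utility = c(0.87, 0.84, 0.80, 0.76, 0.69)))
  multipliers <- data.frame(
    event_category = nonfatal_categories(),
    event_multiplier = c(0.88, 0.84, 0.80, 0.63, 0.90, 0.71),
    post_multiplier  = c(0.91, 0.90, 0.88, 0.70, 0.94, 0.78))
  list(baseline = baseline, multipliers = multipliers)
}

synthetic_costs <- function() {
  list(
    annual_drug_cost = 25,
    annual_monitoring_cost = 110,
    event_costs = c(stable_angina = 2700, unstable_angina = 3300, mi = 4000,
                    stroke = 11900, tia = 1500, heart_failure = 5700),
    post_event_costs = c(stable_angina = 300, unstable_angina = 300,
                         mi = 250, stroke = 2500, tia = 100,
                         heart_failure = 1500))
}

#' Synthetic base-case parameter bundle
#'
#' Builds a complete, internally consistent `paramset` for one scenario
#' cell: a synthetic stand-in (see the methods vignette for every value and
#' its rationale) for the base-case input tables of the published model,
#' which are not redistributable here. The bundle has the stated structure:
#' Gompertz-like lifetable with mortality increasing in age, non-circulatory
#' death fractions in (0.55, 0.95), first-event distributions summing to one
#' per age/sex stratum, treatment relative risks below one, utilities
#' declining with age with state multipliers in (0.5, 1], and event costs
#' far exceeding annual drug costs.
#'
#' @param age starting age, one of 40, 50, 60, 70, 75.
#' @param sex `"male"` or `"female"`.
#' @param r10 10-year CVD risk subgroup, one of 0.05, 0.10, 0.15, 0.20 (other
#'   values in (0, 1) are accepted for threshold searches).
#' @param max_cycles model horizon; defaults to 60 one-year cycles, shortened
#'   so the cohort never outruns the lifetable (`age + max_cycles <= 115`).
#' @param risk_increment additive annual risk increase (default 0.001/year).
#' @param comparator_treatment_delay `"never"` (base case) or a cycle number.
#' @param smr_split post-event death attribution rule, see [paramset()].
#' @return a validated `paramset`.
#' @export
base_case_fixture <- function(age = 60, sex = c("male", "female"),
                              r10 = 0.10, max_cycles = min(60, 115 - age),
                              risk_increment = 0.001,
                              comparator_treatment_delay = "never",
                              smr_split = "excess_to_cvd") {
  sex <- match.arg(sex)
  if (!age %in% c(40, 50, 60, 70, 75))
    stop("unsupported starting age: ", age, " (use 40, 50, 60, 70 or 75)")
  if (r10 <= 0 || r10 >= 1)
    stop("unsupported 10-year risk: ", r10)
  paramset(
    settings = list(cycle_length = 1, max_cycles = max_cycles,
                    discount_rate_costs = 0.035, discount_rate_qalys = 0.035,
                    wtp_threshold = 20000, currency_year = "2016/17"),
    profile = list(start_age = age, sex = sex, r10 = r10),
    events = synthetic_event_distribution(),
    mortality = list(
      lifetable = synthetic_lifetable(),
      smr = c(stable_angina = 1.5, unstable_angina = 2.0, mi = 2.5,
              stroke = 2.5, tia = 1.5, heart_failure = 3.5)),
    effect = synthetic_effect_table(),
    adverse = list(annual_probability = 0.02, background_probability = 0,
                   cost_per_event = 400, disutility = 0.05),
    utilities = synthetic_utilities(),
    costs = synthetic_costs(),
    risk_increment = risk_increment,
    comparator_treatment_delay = comparator_treatment_delay,
    smr_split = smr_split
  )
}

#' Random valid parameter set
#'
#' Draws a complete `paramset` from documented ranges for property-style
#' tests: every draw satisfies every type invariant, and the same seed
#' reproduces the same bundle. Ranges are deliberately wide (risk 2--30%,
#' increments up to 0.2 percentage points/year, random Gompertz lifetables,
#' Dirichlet-style event splits) while staying clear of degenerate corners.
#'
#' @param seed integer seed.
#' @return a validated `paramset`.
#' @export
random_paramset <- function(seed = 1) {
  with_seed(seed, {
    age <- sample(c(40, 50, 60, 70, 75), 1)
    sex <- sample(c("male", "female"), 1)
    bands <- synthetic_age_bands()

    lt <- do.call(rbind, lapply(c("male", "female"), function(sx) {
      a <- stats::runif(1, 1e-5, 5e-5)
      b <- stats::runif(1, 0.085, 0.105)
      ages <- 40:115
      data.frame(age = ages, sex = sx,
                 all_cause_q = pmin(a * exp(b * ages), 0.7),
                 noncirc_fraction = pmin(pmax(
                   stats::runif(1, 0.85, 0.95) -
                     stats::runif(1, 0.001, 0.003) * (ages - 40), 0.55), 0.95))
    }))

    events <- do.call(rbind, lapply(c("male", "female"), function(sx) {
      m <- t(vapply(seq_len(nrow(bands)), function(i) {
        w <- stats::rgamma(7, shape = c(4, 2, 6, 6, 3, 2, 3))
        w / sum(w)
      }, numeric(7)))
      df <- cbind(bands, sex = sx, as.data.frame(m))
      names(df)[4:10] <- event_categories()
      df
    }))

    rr <- stats::runif(7, 0.6, 0.95)
    af <- sort(stats::runif(5, 0.9, 1.05))
    effect <- do.call(rbind, lapply(seq_along(event_categories()), function(k)
      data.frame(event_category = event_categories()[k],
                 age_lo = bands$age_lo, age_hi = bands$age_hi,
                 rr = rr[k], age_factor = af)))

    u0 <- stats::runif(1, 0.85, 0.95)
    drop <- sort(stats::runif(5, 0, 0.2))
    utilities <- list(
      baseline = do.call(rbind, lapply(c("male", "female"), function(sx)
        data.frame(bands, sex = sx,
                   utility = pmax(u0 - drop - (sx == "female") * 0.02, 0.5)))),
      multipliers = data.frame(
        event_category = nonfatal_categories(),
        event_multiplier = stats::runif(6, 0.55, 0.95),
        post_multiplier = stats::runif(6, 0.6, 1.0)))

    # The additive increment must stay feasible: the 10-year risk cannot be
    # below what the increment alone compounds to (~45 * delta over 10 years).
    r10 <- stats::runif(1, 0.02, 0.30)
    delta <- stats::runif(1, 0, r10 / 50)

    costs <- list(
      annual_drug_cost = stats::runif(1, 10, 100),
      annual_monitoring_cost = stats::runif(1, 50, 200),
      event_costs = stats::setNames(stats::runif(6, 1000, 15000),
                                    nonfatal_categories()),
      post_event_costs = stats::setNames(stats::runif(6, 0, 3000),
                                         nonfatal_categories()))

    paramset(
      settings = list(cycle_length = 1, max_cycles = min(60, 115 - age),
                      discount_rate_costs = 0.035,
                      discount_rate_qalys = 0.035,
                      wtp_threshold = 20000, currency_year = "2016/17"),
      profile = list(start_age = age, sex = sex, r10 = r10),
      events = events,
      mortality = list(lifetable = lt,
                       smr = stats::setNames(stats::runif(6, 1, 4),
                                             nonfatal_categories())),
      effect = effect,
      adverse = list(annual_probability = stats::runif(1, 0, 0.05),
                     background_probability = 0,
                     cost_per_event = stats::runif(1, 100, 1000),
                     disutility = stats::runif(1, 0, 0.1)),
      utilities = utilities,
      costs = costs,
      risk_increment = delta
    )
  })
}
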