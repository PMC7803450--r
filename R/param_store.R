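#' Assemble a model parameter set
#'
#' A `paramset` bundles every input the cohort model needs for one scenario:
#' economic settings, the risk profile of the cohort, the age/sex distribution
#' of first CVD events, a mortality model (lifetable, non-circulatory death
#' fractions, post-event standardized mortality ratios), relative treatment
#' effects, an adverse-event model, utilities and costs, plus the additive
#' annual risk increment and the comparator's treatment delay.
#'
#' @param settings list with `cycle_length` (years, fixed 1), `max_cycles`,
#'   `discount_rate_costs`, `discount_rate_qalys` (fractions per year),
#'   `wtp_threshold` (currency per QALY) and `currency_year` (label).
#' @param profile list with `start_age` (40--75), `sex` (`"male"`/`"female"`)
#'   and `r10`, the 10-year risk of a first CVD event (0 allowed only for
#'   lifetable-validation runs).
#' @param events data frame with columns `age_lo`, `age_hi`, `sex` and one
#'   column per event category (see [event_categories()]); each row's category
#'   fractions must sum to 1.
#' @param mortality list with `lifetable` (data frame `age`, `sex`,
#'   `all_cause_q`, `noncirc_fraction`) and `smr`, a named vector of
#'   standardized mortality ratios (>= 1) per nonfatal category.
#' @param effect data frame with columns `event_category`, `age_lo`, `age_hi`,
#'   `rr` (base relative risk under treatment) and `age_factor` (relative age
#'   transformation applied multiplicatively to `rr`).
#' @param adverse list with `annual_probability` (on treatment),
#'   `background_probability` (off treatment, default 0), `cost_per_event` and
#'   `disutility`.
#' @param utilities list with `baseline` (data frame `age_lo`, `age_hi`,
#'   `sex`, `utility`) and `multipliers` (data frame `event_category`,
#'   `event_multiplier`, `post_multiplier`, all in (0, 1]).
#' @param costs list with `annual_drug_cost`, `annual_monitoring_cost`, and
#'   named vectors `event_costs` (one-off first-year cost) and
#'   `post_event_costs` (annual) per nonfatal category.
#' @param risk_increment additive annual increase in first-event probability
#'   (fraction per year, >= 0).
#' @param comparator_treatment_delay cycle at which the no-treatment arm
#'   starts drug treatment anyway, or `"never"` (the base case).
#' @param risk_cap maximum total annual first-event probability; the additive
#'   schedule is capped here with a warning.
#' @param smr_split how post-event deaths are attributed:
#'   `"excess_to_cvd"` sends the excess over background all-cause mortality to
#'   CVD death and the background to non-CVD death; `"background_split"`
#'   additionally splits the background by the non-circulatory fraction.
#' @return object of class `paramset`.
#' @export
paramset <- function(settings, profile, events, mortality, effect, adverse,
                     utilities, costs, risk_increment = 0,
                     comparator_treatment_delay = "never", risk_cap = 0.99,
                     smr_split = c("excess_to_cvd", "background_split")) {
  p <- structure(list(
    settings = settings, profile = profile, events = events,
    mortality = mortality, effect = effect, adverse = adverse,
    utilities = utilities, costs = costs, risk_increment = risk_increment,
    comparator_treatment_delay = comparator_treatment_delay,
    risk_cap = risk_cap, smr_split = match.arg(smr_split)
  ), class = "paramset")
  validate_paramset(p)
}

#' @export
print.paramset <- function(x, ...) {
  cat("<paramset>\n")
  cat(sprintf("  profile: %s, start age %d, 10-year CVD risk %.1f%%\n",
              x$profile$sex, as.integer(x$profile$start_age),
              100 * x$profile$r10))
  cat(sprintf("  horizon: %d one-year cycles; discounting %.1f%%/yr; WTP %s/QALY\n",
              x$settings$max_cycles, 100 * x$settings$discount_rate_qalys,
              format(x$settings$wtp_threshold, big.mark = ",")))
  cat(sprintf("  risk increment: +%.4f/yr; comparator delay: %s\n",
              x$risk_increment, as.character(x$comparator_treatment_delay)))
  invisible(x)
}

# Find the row of a banded table containing `age` (and matching `sex` if the
# table has a sex column). Errors with the table name if no band matches.
band_row <- function(df, age, sex = NULL, what = "table") {
  keep <- df$age_lo <= age & age <= df$age_hi
  if (!is.null(sex) && "sex" %in% names(df)) keep <- keep & df$sex == sex
  i <- which(keep)
  if (length(i) == 0L)
    stop(sprintf("%s: no age band covers age %s (sex %s)", what, age,
                 if (is.null(sex)) "any" else sex))
  if (length(i) > 1L)
    stop(sprintf("%s: overlapping age bands at age %s", what, age))
  df[i, , drop = FALSE]
}

delay_cycles <- function(p) {
  d <- p$comparator_treatment_delay
  if (identical(d, "never")) Inf else as.numeric(d)
}

#' Validate a parameter set
#'
#' Checks every documented invariant and reports all violations together,
#' each prefixed with the offending field path.
#'
#' @param p a `paramset`.
#' @return `p`, invisibly, if valid; otherwise an error listing every
#'   violation.
#' @export
validate_paramset <- function(p) {
  errs <- character()
  add <- function(cond, msg) if (!isTRUE(cond)) errs[[length(errs) + 1L]] <<- msg

  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

  s <- p$settings
  add(num1(s$cycle_length) && s$cycle_length == 1,
      "settings$cycle_length: must be 1 year")
  add(num1(s$max_cycles) && s$max_cycles >= 1,
      "settings$max_cycles: must be >= 1")
  for (f in c("discount_rate_costs", "discount_rate_qalys"))
    add(num1(s[[f]]) && s[[f]] >= 0 && s[[f]] <= 0.1,
        sprintf("settings$%s: must be in [0, 0.1]", f))
  add(num1(s$wtp_threshold) && s$wtp_threshold > 0,
      "settings$wtp_threshold: must be > 0")

  pr <- p$profile
  add(num1(pr$start_age) && pr$start_age >= 40 && pr$start_age <= 75,
      "profile$start_age: must be in [40, 75]")
  add(identical(pr$sex, "male") || identical(pr$sex, "female"),
      "profile$sex: must be 'male' or 'female'")
  add(num1(pr$r10) && pr$r10 >= 0 && pr$r10 < 1,
      "profile$r10: must be in [0, 1)")
  if (num1(pr$start_age) && num1(s$max_cycles))
    add(pr$start_age + s$max_cycles <= 115,
        "profile: start_age + max_cycles must be <= 115")

  ev <- p$events
  cats <- event_categories()
  add(is.data.frame(ev) && all(c("age_lo", "age_hi", "sex", cats) %in% names(ev)),
      "events: must have columns age_lo, age_hi, sex and every event category")
  if (is.data.frame(ev) && all(cats %in% names(ev))) {
    fr <- as.matrix(ev[, cats])
    add(all(fr >= 0), "events: all fractions must be >= 0")
    tot <- rowSums(fr)
    bad <- which(abs(tot - 1) > 1e-9)
    for (i in bad)
      add(FALSE, sprintf("events[age %d-%d, %s]: fractions sum to %.6f, not 1",
                         ev$age_lo[i], ev$age_hi[i], ev$sex[i], tot[i]))
  }

  lt <- p$mortality$lifetable
  add(is.data.frame(lt) &&
        all(c("age", "sex", "all_cause_q", "noncirc_fraction") %in% names(lt)),
      "mortality$lifetable: must have columns age, sex, all_cause_q, noncirc_fraction")
  if (is.data.frame(lt) && all(c("all_cause_q", "noncirc_fraction") %in% names(lt))) {
    add(all(lt$all_cause_q >= 0 & lt$all_cause_q <= 1),
        "mortality$lifetable$all_cause_q: probabilities must be in [0, 1]")
    add(all(lt$noncirc_fraction >= 0 & lt$noncirc_fraction <= 1),
        "mortality$lifetable$noncirc_fraction: must be in [0, 1]")
  }
  smr <- p$mortality$smr
  add(is.numeric(smr) && all(nonfatal_categories() %in% names(smr)),
      "mortality$smr: named vector covering every nonfatal category")
  if (is.numeric(smr)) add(all(smr >= 1), "mortality$smr: all values must be >= 1")

  ef <- p$effect
  add(is.data.frame(ef) &&
        all(c("event_category", "age_lo", "age_hi", "rr", "age_factor") %in% names(ef)),
      "effect: must have columns event_category, age_lo, age_hi, rr, age_factor")
  if (is.data.frame(ef) && all(c("rr", "age_factor") %in% names(ef))) {
    add(all(ef$rr > 0), "effect$rr: relative risks must be > 0")
    add(all(ef$age_factor > 0), "effect$age_factor: must be > 0")
  }

  ae <- p$adverse
  for (f in c("annual_probability", "background_probability"))
    add(num1(ae[[f]]) && ae[[f]] >= 0 && ae[[f]] <= 1,
        sprintf("adverse$%s: must be in [0, 1]", f))
  add(num1(ae$cost_per_event) && ae$cost_per_event >= 0,
      "adverse$cost_per_event: must be >= 0")
  add(num1(ae$disutility) && ae$disutility >= 0 && ae$disutility <= 1,
      "adverse$disutility: must be in [0, 1]")

  ub <- p$utilities$baseline
  add(is.data.frame(ub) && all(c("age_lo", "age_hi", "sex", "utility") %in% names(ub)),
      "utilities$baseline: must have columns age_lo, age_hi, sex, utility")
  if (is.data.frame(ub) && "utility" %in% names(ub)) {
    add(all(ub$utility >= 0 & ub$utility <= 1),
        "utilities$baseline$utility: must be in [0, 1]")
    for (sx in unique(ub$sex)) {
      u <- ub$utility[ub$sex == sx][order(ub$age_lo[ub$sex == sx])]
      if (is.unsorted(rev(u)) && any(diff(u) > 0))
        warning("utilities$baseline: utility increases with age for sex ", sx,
                call. = FALSE)
    }
  }
  um <- p$utilities$multipliers
  add(is.data.frame(um) &&
        all(c("event_category", "event_multiplier", "post_multiplier") %in% names(um)),
      "utilities$multipliers: must have columns event_category, event_multiplier, post_multiplier")
  if (is.data.frame(um) && "event_multiplier" %in% names(um)) {
    ok <- function(x) all(x > 0 & x <= 1)
    add(ok(um$event_multiplier) && ok(um$post_multiplier),
        "utilities$multipliers: multipliers must be in (0, 1]")
    add(all(nonfatal_categories() %in% um$event_category),
        "utilities$multipliers: must cover every nonfatal category")
  }

  co <- p$costs
  add(num1(co$annual_drug_cost) && co$annual_drug_cost >= 0,
      "costs$annual_drug_cost: must be a finite value >= 0")
  add(num1(co$annual_monitoring_cost) && co$annual_monitoring_cost >= 0,
      "costs$annual_monitoring_cost: must be a finite value >= 0")
  for (f in c("event_costs", "post_event_costs")) {
    v <- co[[f]]
    add(is.numeric(v) && all(nonfatal_categories() %in% names(v)) &&
          all(is.finite(v)) && all(v >= 0),
        sprintf("costs$%s: named finite vector >= 0 covering every nonfatal category", f))
  }

  add(num1(p$risk_increment) && p$risk_increment >= 0,
      "risk_increment: must be >= 0")
  add(identical(p$comparator_treatment_delay, "never") ||
        (num1(as.numeric(p$comparator_treatment_delay)) &&
           p$comparator_treatment_delay >= 1),
      "comparator_treatment_delay: must be 'never' or an integer >= 1")
  add(num1(p$risk_cap) && p$risk_cap > 0 && p$risk_cap < 1,
      "risk_cap: must be in (0, 1)")

  if (length(errs))
    stop("invalid paramset:\n", paste0("  - ", errs, collapse = "\n"),
         call. = FALSE)
  invisible(p)
}

#' Load a parameter set from a configuration file
#'
#' Reads a YAML configuration holding scalar inputs plus the relative file
#' names of the CSV tables (event distribution, lifetable, treatment relative
#' risks, baseline utilities, state multipliers, event costs), which are
#' resolved against the configuration file's directory. The result is fully
#' validated; any invariant violation is reported with its field path.
#'
#' @param path path to the YAML configuration.
#' @return a validated `paramset`.
#' @export
load_paramset <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  dir <- dirname(path)
  tab <- function(key) {
    f <- cfg$tables[[key]]
    if (is.null(f)) stop("config tables$", key, ": missing table file entry")
    fp <- file.path(dir, f)
    if (!file.exists(fp)) stop("config tables$", key, ": file not found: ", fp)
    utils::read.csv(fp, stringsAsFactors = FALSE)
  }
  need <- function(x, path_lab) {
    if (is.null(x)) stop("config ", path_lab, ": missing field")
    x
  }

  events <- tab("events")
  lifetable <- tab("lifetable")
  effect <- tab("rr")
  baseline <- tab("baseline_utility")
  multipliers <- tab("multipliers")
  ec <- tab("event_costs")
  if (!all(c("event_category", "event_year_cost", "post_event_annual_cost") %in%
             names(ec)))
    stop("event_costs table: needs columns event_category, event_year_cost, post_event_annual_cost")

  costs <- list(
    annual_drug_cost = need(cfg$costs$annual_drug_cost, "costs$annual_drug_cost"),
    annual_monitoring_cost = need(cfg$costs$annual_monitoring_cost,
                                  "costs$annual_monitoring_cost"),
    event_costs = stats::setNames(ec$event_year_cost, ec$event_category),
    post_event_costs = stats::setNames(ec$post_event_annual_cost, ec$event_category)
  )

  paramset(
    settings = need(cfg$settings, "settings"),
    profile = need(cfg$profile, "profile"),
    events = events,
    mortality = list(lifetable = lifetable,
                     smr = unlist(need(cfg$smr, "smr"))),
    effect = effect,
    adverse = need(cfg$adverse, "adverse"),
    utilities = list(baseline = baseline, multipliers = multipliers),
    costs = costs,
    risk_increment = need(cfg$risk_increment, "risk_increment"),
    comparator_treatment_delay = need(cfg$comparator_treatment_delay,
                                      "comparator_treatment_delay"),
    risk_cap = if (is.null(cfg$risk_cap)) 0.99 else cfg$risk_cap,
    smr_split = if (is.null(cfg$smr_split)) "excess_to_cvd" else cfg$smr_split
  )
}

#' Save a parameter set to a configuration file plus CSV tables
#'
#' Inverse of [load_paramset()]: writes the YAML configuration at `path` and
#' the stratified tables as CSV files in the same directory. A saved set
#' reloads identically (floats to within 1e-12), and saving a reloaded set
#' reproduces the files byte for byte.
#'
#' @param p a validated `paramset`.
#' @param path destination for the YAML configuration; tables are written
#'   alongside it.
#' @return `path`, invisibly.
#' @export
save_paramset <- function(p, path) {
  validate_paramset(p)
  if (any(!is.finite(unlist(p$costs))))
    stop("refusing to save paramset with non-finite costs")
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  tables <- list(
    events = "event_distribution.csv",
    lifetable = "lifetable.csv",
    rr = "treatment_rr.csv",
    baseline_utility = "baseline_utility.csv",
    multipliers = "state_multipliers.csv",
    event_costs = "event_costs.csv"
  )
  wcsv <- function(df, f) utils::write.csv(df, file.path(dir, f), row.names = FALSE,
                                           quote = FALSE)
  wcsv(p$events, tables$events)
  wcsv(p$mortality$lifetable, tables$lifetable)
  wcsv(p$effect, tables$rr)
  wcsv(p$utilities$baseline, tables$baseline_utility)
  wcsv(p$utilities$multipliers, tables$multipliers)
  nf <- nonfatal_categories()
  wcsv(data.frame(event_category = nf,
                  event_year_cost = unname(p$costs$event_costs[nf]),
                  post_event_annual_cost = unname(p$costs$post_event_costs[nf])),
       tables$event_costs)

  cfg <- list(
    schema_version = 1L,
    settings = p$settings,
    profile = p$profile,
    risk_increment = p$risk_increment,
    comparator_treatment_delay = p$comparator_treatment_delay,
    risk_cap = p$risk_cap,
    smr_split = p$smr_split,
    adverse = p$adverse,
    smr = as.list(p$mortality$smr[nf]),
    costs = list(annual_drug_cost = p$costs$annual_drug_cost,
                 annual_monitoring_cost = p$costs$annual_monitoring_cost),
    tables = tables
  )
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}
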