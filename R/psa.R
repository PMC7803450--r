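# Probabilistic sensitivity analysis: per-parameter sampling distributions,
# reproducible parameter draws, and CEAC summaries.

#' Define a sampling distribution for one parameter
#'
#' A `dist_spec` attaches a sampling rule to one parameter of a `paramset`
#' for probabilistic sensitivity analysis. Families are chosen by parameter
#' role: `"beta"` for probabilities and utility multipliers (bounded on
#' `[0, 1]`), `"gamma"` for costs (positive, right-skewed), `"lognormal"` for
#' relative risks (sampled on the log scale), `"fixed"` for parameters held
#' at their base value. Hyperparameters are given as a mean and an
#' uncertainty (standard error) and converted by method of moments.
#'
#' Scalar parameters are addressed by `path`, a character vector into the
#' nested `paramset` (e.g. `c("costs", "annual_drug_cost")` or
#' `c("costs", "event_costs", "mi")`). Cells of stratified tables are
#' addressed by `path` to the data frame plus `match` (named list of
#' column = value filters selecting the rows) and `column`; one value is
#' sampled and written to every matching row, so e.g. an event category's RR
#' moves jointly across age bands while the age factors stay fixed.
#'
#' @param path character vector locating the parameter.
#' @param family `"beta"`, `"gamma"`, `"lognormal"` or `"fixed"`.
#' @param mean mean of the sampling distribution (for `"lognormal"`, the
#'   mean of the ratio on the natural scale).
#' @param se standard error; ignored for `"fixed"`.
#' @param match,column table-cell addressing, see Details.
#' @return a `dist_spec`.
#' @export
dist_spec <- function(path, family = c("beta", "gamma", "lognormal", "fixed"),
                      mean, se = 0, match = NULL, column = NULL) {
  family <- match.arg(family)
  stopifnot(is.character(path), length(path) >= 1L, is.numeric(mean),
            is.numeric(se), se >= 0)
  if (family == "beta" && (mean <= 0 || mean >= 1))
    stop("beta family needs mean in (0, 1): ", paste(path, collapse = "$"))
  if (family %in% c("gamma", "lognormal") && mean <= 0)
    stop(family, " family needs mean > 0: ", paste(path, collapse = "$"))
  structure(list(path = path, family = family, mean = mean, se = se,
                 match = match, column = column),
            class = "dist_spec")
}

# Draw one value from a spec (assumes RNG state already set by caller).
draw_spec <- function(spec) {
  m <- spec$mean; s <- spec$se
  if (spec$family == "fixed" || s == 0) return(m)
  switch(spec$family,
    beta = {
      v <- s^2
      if (v >= m * (1 - m))
        stop("beta spec variance too large for mean ", m)
      k <- m * (1 - m) / v - 1
      stats::rbeta(1, m * k, (1 - m) * k)
    },
    gamma = stats::rgamma(1, shape = (m / s)^2, rate = m / s^2),
    lognormal = {
      sdlog <- sqrt(log(1 + (s / m)^2))
      stats::rlnorm(1, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
    }
  )
}

get_param <- function(p, path) {
  x <- p
  for (k in path) x <- x[[k]]
  x
}

set_param <- function(p, path, value) {
  p[[path]] <- value
  p
}

apply_spec <- function(p, spec, value) {
  if (is.null(spec$column)) return(set_param(p, spec$path, value))
  df <- get_param(p, spec$path)
  keep <- rep(TRUE, nrow(df))
  for (col in names(spec$match)) keep <- keep & df[[col]] == spec$match[[col]]
  if (!any(keep))
    stop("dist_spec matches no rows of ", paste(spec$path, collapse = "$"))
  df[keep, spec$column] <- value
  set_param(p, spec$path, df)
}

# Seed stream: one reproducible sub-seed per (seed, draw) pair, < 2^31.
draw_seed <- function(seed, draw) {
  (as.numeric(seed) * 48271 + as.numeric(draw) * 9973) %% 2147483629
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Sample one parameter set for the PSA
#'
#' Draws every parameter that has a `dist_spec` from its distribution,
#' leaving the rest at their base values, and validates the result. Draws
#' are reproducible given `(seed, draw)`. If a sampled set violates a
#' `paramset` invariant it is resampled (up to `max_retries` times, each
#' retry with its own reproducible sub-seed) before erroring.
#'
#' @param base a validated `paramset`.
#' @param specs list of `dist_spec`s.
#' @param seed integer RNG seed for the whole PSA.
#' @param draw 1-based draw index.
#' @param max_retries resampling attempts on invariant violation.
#' @return a validated `paramset`.
#' @export
sample_paramset <- function(base, specs, seed = 1, draw = 1,
                            max_retries = 100) {
  for (attempt in 0:max_retries) {
    p <- base
    res <- with_seed(draw_seed(seed, draw + attempt * 1e6), {
      try({
        for (spec in specs) p <- apply_spec(p, spec, draw_spec(spec))
        validate_paramset(p)
        p
      }, silent = TRUE)
    })
    if (!inherits(res, "try-error")) return(res)
  }
  stop("sample_paramset: no valid draw after ", max_retries, " retries: ",
       attr(res, "condition")$message)
}

#' Run a probabilistic sensitivity analysis
#'
#' Samples `n_draws` parameter sets, reruns both arms for each, and
#' summarizes the paired incremental costs and QALYs: the probability that
#' treatment is cost-effective at the willingness-to-pay threshold (fraction
#' of draws with positive net monetary benefit) and the cost-effectiveness
#' acceptability curve (CEAC) over a threshold grid.
#'
#' @param base a validated `paramset`.
#' @param specs list of `dist_spec`s.
#' @param n_draws number of Monte-Carlo draws (the package default in
#'   scenario runs is 5000; tests use fewer).
#' @param seed integer RNG seed; results are deterministic given it.
#' @param wtp willingness-to-pay threshold; defaults to the one in `base`.
#' @param wtp_grid thresholds for the CEAC (default 0 to 50,000 in steps of
#'   1000).
#' @return a `psa_result`: list with `draws` (data frame of `delta_cost`,
#'   `delta_qalys`, `nmb`), `prob_ce`, `ceac` (data frame `wtp`, `prob_ce`),
#'   `wtp`, `seed`, `n_draws`.
#' @export
run_psa <- function(base, specs, n_draws = 5000, seed = 1,
                    wtp = base$settings$wtp_threshold,
                    wtp_grid = seq(0, 50000, by = 1000)) {
  stopifnot(n_draws >= 1)
  dc <- dq <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    p <- sample_paramset(base, specs, seed, i)
    res <- compare_arms(run_arm(p, "treated"), run_arm(p, "comparator"), wtp)
    dc[i] <- res$delta_cost
    dq[i] <- res$delta_qalys
  }
  nmb <- wtp * dq - dc
  ceac <- data.frame(
    wtp = wtp_grid,
    prob_ce = vapply(wtp_grid, function(l) mean(l * dq - dc > 0), numeric(1))
  )
  structure(list(
    draws = data.frame(delta_cost = dc, delta_qalys = dq, nmb = nmb),
    prob_ce = mean(nmb > 0),
    mean_delta_cost = mean(dc), mean_delta_qalys = mean(dq),
    ceac = ceac, wtp = wtp, seed = seed, n_draws = n_draws
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(paste0("<psa_result: %d draws, seed %s>\n",
                     "  mean incremental cost  %10.2f\n",
                     "  mean incremental QALYs %10.5f\n",
                     "  P(cost-effective at %s/QALY) = %.3f\n"),
              x$n_draws, format(x$seed), x$mean_delta_cost,
              x$mean_delta_qalys, format(x$wtp, big.mark = ","), x$prob_ce))
  invisible(x)
}

#' Default PSA distribution specifications for a parameter set
#'
#' Builds one `dist_spec` per uncertain input, with families chosen by
#' parameter role: beta for the adverse-event probability, utility
#' multipliers and non-fatal event fractions are left fixed (the event split
#' is a composition; see the methods vignette), gamma for every cost,
#' lognormal for each event category's relative risk and each standardized
#' mortality ratio. Uncertainty defaults to a coefficient of variation
#' `cv` around the base-case value.
#'
#' @param base a validated `paramset`.
#' @param cv relative standard error attached to each parameter
#'   (default 0.2, i.e. 20%).
#' @return list of `dist_spec`s.
#' @export
default_psa_specs <- function(base, cv = 0.2) {
  specs <- list()
  add <- function(s) specs[[length(specs) + 1L]] <<- s

  for (cat in event_categories())
    add(dist_spec(c("effect"), "lognormal",
                  mean = base$effect$rr[base$effect$event_category == cat][1],
                  se = cv * base$effect$rr[base$effect$event_category == cat][1],
                  match = list(event_category = cat), column = "rr"))
  for (cat in nonfatal_categories()) {
    add(dist_spec(c("costs", "event_costs", cat), "gamma",
                  mean = base$costs$event_costs[[cat]],
                  se = cv * base$costs$event_costs[[cat]]))
    if (base$costs$post_event_costs[[cat]] > 0)
      add(dist_spec(c("costs", "post_event_costs", cat), "gamma",
                    mean = base$costs$post_event_costs[[cat]],
                    se = cv * base$costs$post_event_costs[[cat]]))
    um <- base$utilities$multipliers
    for (col in c("event_multiplier", "post_multiplier")) {
      mu <- um[[col]][um$event_category == cat]
      if (mu < 1)  # a multiplier of exactly 1 carries no decrement to vary
        add(dist_spec(c("utilities", "multipliers"), "beta", mean = mu,
                      se = cv / 4 * (1 - mu),
                      match = list(event_category = cat), column = col))
    }
  }
  add(dist_spec(c("costs", "annual_drug_cost"), "gamma",
                mean = base$costs$annual_drug_cost,
                se = cv * base$costs$annual_drug_cost))
  add(dist_spec(c("costs", "annual_monitoring_cost"), "gamma",
                mean = base$costs$annual_monitoring_cost,
                se = cv * base$costs$annual_monitoring_cost))
  add(dist_spec(c("adverse", "annual_probability"), "beta",
                mean = base$adverse$annual_probability,
                se = cv * base$adverse$annual_probability))
  add(dist_spec(c("adverse", "cost_per_event"), "gamma",
                mean = base$adverse$cost_per_event,
                se = cv * base$adverse$cost_per_event))
  add(dist_spec(c("adverse", "disutility"), "beta",
                mean = base$adverse$disutility,
                se = cv * base$adverse$disutility))
  specs
}
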