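# Search for the 10-year CVD risk at which treatment becomes cost-effective.

with_r10 <- function(p, r) {
  p$profile$r10 <- r
  p
}

#' Find the 10-year risk at which treatment becomes cost-effective
#'
#' Bisects on the 10-year CVD risk to locate the level `r*` at which the
#' treated-vs-untreated comparison crosses the willingness-to-pay threshold
#' (net monetary benefit crossing zero). The search assumes — and first
#' verifies on a small set of probe points across the bracket — that
#' cost-effectiveness is monotone in risk (the ICER falls as baseline risk
#' rises); a non-monotone pattern aborts with a diagnostic table of the
#' probes.
#'
#' @param base a validated `paramset`; its `r10` is overridden during the
#'   search.
#' @param wtp willingness-to-pay threshold; defaults to the one in `base`.
#' @param bracket numeric length-2, the risk interval searched. The lower
#'   end must be reachable given the additive risk increment: with increment
#'   `delta` the 10-year risk cannot fall below what `delta` alone compounds
#'   to (about 4.4% at `delta = 0.001`).
#' @param tol bisection tolerance on the risk (default 1e-4, i.e. 0.01
#'   percentage points of 10-year risk).
#' @param n_probes probe points for the monotonicity check.
#' @return list with `risk`, `flag` (`"converged"`,
#'   `"cost-effective throughout"` or `"never within bracket"`), `wtp`, and
#'   `probes` (the diagnostic table).
#' @export
find_threshold_risk <- function(base, wtp = base$settings$wtp_threshold,
                                bracket = c(0.05, 0.30), tol = 1e-4,
                                n_probes = 5) {
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2],
            bracket[1] > 0, bracket[2] < 1, tol > 0)
  nmb_at <- function(r) {
    res <- evaluate_paramset(with_r10(base, r), wtp)
    res$nmb
  }
  probes <- seq(bracket[1], bracket[2], length.out = n_probes)
  probe_nmb <- vapply(probes, nmb_at, numeric(1))
  probe_df <- data.frame(r10 = probes, nmb = probe_nmb,
                         cost_effective = probe_nmb > 0)
  if (is.unsorted(probe_nmb)) {
    print(probe_df)
    stop("net monetary benefit is not monotone in risk across the bracket; ",
         "bisection is invalid (probe table printed above)")
  }
  if (probe_nmb[1] > 0)
    return(list(risk = bracket[1], flag = "cost-effective throughout",
                wtp = wtp, probes = probe_df))
  if (probe_nmb[n_probes] <= 0)
    return(list(risk = bracket[2], flag = "never within bracket",
                wtp = wtp, probes = probe_df))
  lo <- bracket[1]; hi <- bracket[2]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (nmb_at(mid) > 0) hi <- mid else lo <- mid
  }
  list(risk = (lo + hi) / 2, flag = "converged", wtp = wtp,
       probes = probe_df)
}

#' Probability that treatment is cost-effective at a given risk level
#'
#' Runs the probabilistic sensitivity analysis with the cohort's 10-year
#' risk set to `r` and returns the probability of cost-effectiveness at the
#' willingness-to-pay threshold. At the deterministic threshold risk this is
#' expected to sit near 0.5.
#'
#' @param base a validated `paramset`.
#' @param specs list of `dist_spec`s.
#' @param r 10-year risk at which to evaluate.
#' @param n_draws,seed,wtp passed to [run_psa()].
#' @return probability in `[0, 1]`.
#' @export
probabilistic_threshold <- function(base, specs, r, n_draws = 1000, seed = 1,
                                    wtp = base$settings$wtp_threshold) {
  run_psa(with_r10(base, r), specs, n_draws = n_draws, seed = seed,
          wtp = wtp)$prob_ce
}

#' Run the age x sex x risk scenario grid
#'
#' Evaluates the deterministic comparison for every combination of starting
#' age, sex and 10-year risk subgroup, using the synthetic base-case
#' parameter bundle for each cell; mirrors the layout of subgroup results
#' tables (one row per cell with incremental cost, incremental QALYs, ICER
#' and dominance).
#'
#' @param ages starting ages (subset of 40, 50, 60, 70, 75).
#' @param sexes `"male"`, `"female"` or both.
#' @param risks 10-year risk subgroups.
#' @param wtp willingness-to-pay threshold.
#' @param paramset_fn function `(age, sex, r10) -> paramset`; defaults to
#'   [base_case_fixture()].
#' @return data frame with one row per scenario.
#' @export
run_scenarios <- function(ages = c(40, 50, 60, 70, 75),
                          sexes = c("male", "female"),
                          risks = c(0.05, 0.10, 0.15, 0.20),
                          wtp = 20000, paramset_fn = base_case_fixture) {
  grid <- expand.grid(age = ages, sex = sexes, r10 = risks,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    res <- evaluate_paramset(paramset_fn(g$age, g$sex, g$r10), wtp)
    data.frame(age = g$age, sex = g$sex, r10 = g$r10,
               delta_cost = res$delta_cost, delta_qalys = res$delta_qalys,
               icer = res$icer, dominance = res$dominance,
               nmb = res$nmb, cost_effective = res$cost_effective)
  })
  do.call(rbind, rows)
}
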