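#' Incremental cost-effectiveness comparison of two arms
#'
#' Computes the incremental cost and QALYs of treatment versus no treatment,
#' the incremental cost-effectiveness ratio (ICER = delta cost / delta QALYs),
#' the net monetary benefit at the willingness-to-pay threshold
#' (`nmb = wtp * dQ - dC`), and a dominance classification: treatment is
#' *dominant* when cheaper and more effective, *dominated* when costlier and
#' less effective. Treatment is cost-effective at `wtp` when dominant or when
#' it gains QALYs at an ICER at or below the threshold.
#'
#' @param treated,comparator `arm_result`s from the same `paramset`.
#' @param wtp willingness-to-pay threshold (currency per QALY).
#' @return a `ce_result`: list with `delta_cost`, `delta_qalys`, `icer`
#'   (`NA` when undefined), `dominance` (`"dominant"`, `"dominated"` or
#'   `"none"`), `nmb`, `cost_effective` and `wtp`.
#' @export
compare_arms <- function(treated, comparator, wtp = 20000) {
  dc <- treated$discounted_cost - comparator$discounted_cost
  dq <- treated$discounted_qalys - comparator$discounted_qalys
  dominance <- "none"
  icer <- NA_real_
  if (abs(dq) < 1e-12) {
    # No meaningful QALY difference: classify by cost sign, ICER undefined.
    if (dc > 0) dominance <- "dominated"
    if (dc < 0) dominance <- "dominant"
  } else if (dc < 0 && dq > 0) {
    dominance <- "dominant"
  } else if (dc > 0 && dq < 0) {
    dominance <- "dominated"
  } else {
    # Trade-off quadrants (incl. dc == 0): the ratio is meaningful.
    icer <- dc / dq
  }
  nmb <- wtp * dq - dc
  ce <- dominance == "dominant" ||
    (dq > 0 && !is.na(icer) && icer <= wtp)
  structure(list(delta_cost = dc, delta_qalys = dq, icer = icer,
                 dominance = dominance, nmb = nmb, cost_effective = ce,
                 wtp = wtp),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  icer_lab <- if (x$dominance != "none") x$dominance
  else if (is.na(x$icer)) "undefined"
  else sprintf("%.0f per QALY", x$icer)
  cat(sprintf(paste0("<ce_result>\n  incremental cost  %12.2f\n",
                     "  incremental QALYs %12.5f\n  ICER              %s\n",
                     "  NMB at %s: %.2f (%scost-effective)\n"),
              x$delta_cost, x$delta_qalys, icer_lab,
              format(x$wtp, big.mark = ","), x$nmb,
              if (x$cost_effective) "" else "not "))
  invisible(x)
}

#' Run and compare both arms for a parameter set
#'
#' @param p a `paramset`.
#' @param wtp willingness-to-pay threshold; defaults to the one in `p`.
#' @return a `ce_result` with the two `arm_result`s attached as attributes
#'   `treated` and `comparator`.
#' @export
evaluate_paramset <- function(p, wtp = p$settings$wtp_threshold) {
  tr <- run_arm(p, "treated")
  co <- run_arm(p, "comparator")
  res <- compare_arms(tr, co, wtp)
  attr(res, "treated") <- tr
  attr(res, "comparator") <- co
  res
}

#' Number needed to treat over the 10-year horizon
#'
#' A deliberately crude companion calculation, separate from the Markov
#' model: the absolute 10-year risk reduction is approximated as
#' `r10 * (1 - mean RR)`, where the mean RR is the unweighted average of the
#' effective per-category relative risks at the profile's starting age, and
#' NNT is its reciprocal, rounded up.
#'
#' @param r10 10-year first-event risk, in (0, 1).
#' @param effect treatment-effect table.
#' @param profile risk profile (`start_age` is used for the age adjustment;
#'   the relative-risk table is not sex-specific, so results are identical
#'   for a pooled-sex calculation).
#' @return list with `nnt` (integer, ceiling), `nnt_raw`, `mean_rr` and
#'   `arr` (absolute risk reduction).
#' @export
nnt_10yr <- function(r10, effect, profile) {
  stopifnot(r10 > 0, r10 < 1)
  rr <- vapply(event_categories(), function(cat)
    effective_rr(effect, cat, profile$start_age), numeric(1))
  mean_rr <- mean(rr)
  if (mean_rr >= 1)
    stop(sprintf("mean relative risk %.3f >= 1: no absolute risk reduction, NNT undefined",
                 mean_rr))
  arr <- r10 * (1 - mean_rr)
  # Small slack so floating-point overshoot (e.g. 50.000000000000007)
  # does not bump the reported integer.
  list(nnt = ceiling(1 / arr - 1e-9), nnt_raw = 1 / arr, mean_rr = mean_rr,
       arr = arr)
}

#' Write a per-risk-subgroup results table
#'
#' Summarizes a list of `ce_result`s (one per risk subgroup) in the layout of
#' a base-case results table: incremental cost, incremental QALYs, ICER and,
#' when available, the probability of cost-effectiveness.
#'
#' @param results named list of `ce_result`s; names are subgroup labels
#'   (e.g. `"0.05"`).
#' @param path optional CSV destination; omit to just get the data frame.
#' @param prob_ce optional numeric vector (same length) of probabilities
#'   cost-effective at the threshold, from a PSA.
#' @return the data frame, invisibly if written.
#' @export
ce_results_table <- function(results, path = NULL, prob_ce = NULL) {
  df <- data.frame(
    risk_subgroup = names(results),
    delta_cost = vapply(results, `[[`, numeric(1), "delta_cost"),
    delta_qalys = vapply(results, `[[`, numeric(1), "delta_qalys"),
    icer = vapply(results, `[[`, numeric(1), "icer"),
    dominance = vapply(results, `[[`, character(1), "dominance"),
    cost_effective = vapply(results, `[[`, logical(1), "cost_effective"),
    row.names = NULL
  )
  if (!is.null(prob_ce)) df$prob_cost_effective <- prob_ce
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
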