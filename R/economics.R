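# Economic valuation of a cohort trace: discounted costs by category, life
# years and QALYs, plus strategy comparison (ICERs, dominance, net monetary
# benefit) and a publication-style results table.

#' Discount factor for an annual cycle
#'
#' Cycle 0 (the entry year) is undiscounted; cycle t is weighted
#' `1 / (1 + rate)^t`.
#'
#' @param rate annual discount rate (fraction, >= 0).
#' @param cycle_index 0-based cycle index (integer >= 0, vectorised).
#' @return discount multiplier(s).
#' @export
discount_factor <- function(rate, cycle_index) {
  stopifnot(rate >= 0)
  if (any(cycle_index < 0)) stop("cycle_index must be >= 0")
  1 / (1 + rate)^cycle_index
}

#' Utility weight of the CVD state
#'
#' Stroke and coronary disease utilities weighted by their shares of all CVD
#' cases.
#' @param ps a `ht_parameter_set`.
#' @return utility in \[0,1\].
#' @export
cvd_utility <- function(ps) {
  ps$prop_stroke * ps$u_stroke + ps$prop_cad * ps$u_cad
}

#' Accrue discounted costs, life years and QALYs over a trace
#'
#' Per cycle: screening cost is the screened mass times the strategy's
#' expected per-person cost (already recorded in the trace flows); direct
#' medical cost maps state occupancy to annual treatment cost (white-coat and
#' controlled HT at the controlled-HT cost, uncontrolled HT at its own cost,
#' prevalent CVD at the chronic cost, the new-event flow at the acute cost;
#' undiagnosed HT is untreated and accrues nothing); direct non-medical cost
#' prices clinic visits (4/year controlled and white-coat, 8/year
#' uncontrolled and chronic CVD) and acute admission days for new CVD events.
#' Utility weights: no-HT and white-coat 1, any true-HT state `u_ht`, CVD the
#' stroke/CAD-weighted mix, death 0. All streams are discounted per cycle and
#' summed.
#'
#' @param trace a `cohort_trace`.
#' @param ps a `ht_parameter_set`.
#' @param strat a `ht_strategy` or strategy name (label only; the screening
#'   cost stream is already in the trace).
#' @return an `econ_result`: list with `strategy`, `screening_cost`,
#'   `direct_medical_cost`, `direct_nonmedical_cost`, `total_cost`,
#'   `total_ly`, `total_qaly` (all discounted).
#' @export
accrue <- function(trace, ps, strat) {
  name <- if (is.character(strat)) strat else strat$name
  df <- discount_factor(ps$discount_rate, trace$cycle)

  screening <- sum(trace$screen_cost * df)

  medical_cycle <-
    (trace$wcht_transient + trace$ht_controlled) * ps$cost_ht_controlled +
    trace$ht_uncontrolled * ps$cost_ht_uncontrolled +
    trace$cvd_prevalent * ps$cost_cvd_chronic +
    trace$new_cvd * ps$cost_cvd_acute
  medical <- sum(medical_cycle * df)

  nonmed_cycle <-
    ((trace$wcht_transient + trace$ht_controlled) * ps$visits_controlled +
       trace$ht_uncontrolled * ps$visits_uncontrolled +
       trace$cvd_prevalent * ps$visits_cvd_chronic) * ps$nonmed_visit_cost +
    trace$new_cvd * ps$acute_admission_days * ps$nonmed_inpatient_cost_per_day
  nonmed <- sum(nonmed_cycle * df)

  alive <- 1 - trace$dead
  ly <- sum(alive * df)
  u_cvd <- cvd_utility(ps)
  qaly_cycle <-
    (trace$no_ht + trace$wcht_transient) * ps$u_healthy +
    (trace$undiagnosed_ht + trace$ht_controlled + trace$ht_uncontrolled) *
      ps$u_ht +
    trace$cvd * u_cvd +
    trace$dead * ps$u_death
  qaly <- sum(qaly_cycle * df)

  structure(list(
    strategy = name,
    screening_cost = screening,
    direct_medical_cost = medical,
    direct_nonmedical_cost = nonmed,
    total_cost = screening + medical + nonmed,
    total_ly = ly,
    total_qaly = qaly
  ), class = "econ_result")
}

#' @export
print.econ_result <- function(x, ...) {
  cat(sprintf(
    "<econ_result> %s: total cost %s baht (screening %s, medical %s, non-medical %s); %.4f LY, %.4f QALY\n",
    x$strategy,
    format(round(x$total_cost), big.mark = ","),
    format(round(x$screening_cost), big.mark = ","),
    format(round(x$direct_medical_cost), big.mark = ","),
    format(round(x$direct_nonmedical_cost), big.mark = ","),
    x$total_ly, x$total_qaly))
  invisible(x)
}

dominance_class <- function(delta_cost, delta_qaly) {
  if (delta_cost == 0 && delta_qaly == 0) return("equivalent")
  if (delta_cost >= 0 && delta_qaly <= 0) return("dominated")
  if (delta_cost <= 0 && delta_qaly >= 0) return("dominant")
  if (delta_cost > 0 && delta_qaly > 0) return("trade_off_NE")
  "trade_off_SW"
}

#' Incremental cost-effectiveness table
#'
#' One row per non-comparator strategy: incremental cost, life years and
#' QALYs against the comparator, the ICER per QALY (and per LY), and the
#' cost-effectiveness-plane quadrant. A negative ICER in the dominated
#' quadrant (more cost, fewer QALYs) is not interpretable as a price per
#' QALY; a positive ICER in the southwest quadrant (less cost, fewer QALYs)
#' reads as cost saved per QALY lost. A zero QALY increment leaves the ICER
#' undefined (`NA`) rather than dividing.
#'
#' @param results list of `econ_result`, one per strategy (named or not).
#' @param comparator strategy name to compare against.
#' @return data.frame with columns `comparison`, `delta_cost`, `delta_ly`,
#'   `delta_qaly`, `icer_ly`, `icer_qaly`, `dominance_class`.
#' @export
icer_table <- function(results, comparator) {
  nm <- vapply(results, function(r) r$strategy, character(1))
  names(results) <- nm
  if (!comparator %in% nm) stop("comparator not among results: ", comparator)
  base <- results[[comparator]]
  rows <- lapply(results[nm != comparator], function(r) {
    dc <- r$total_cost - base$total_cost
    dl <- r$total_ly - base$total_ly
    dq <- r$total_qaly - base$total_qaly
    data.frame(
      comparison = paste(r$strategy, "vs", comparator),
      delta_cost = dc, delta_ly = dl, delta_qaly = dq,
      icer_ly = if (dl == 0) NA_real_ else dc / dl,
      icer_qaly = if (dq == 0) NA_real_ else dc / dq,
      dominance_class = dominance_class(dc, dq),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Net monetary benefit
#'
#' `NMB = WTP x QALYs - cost`; at a given willingness-to-pay threshold the
#' strategy with the largest NMB is the cost-effective choice.
#'
#' @param result an `econ_result` (or any list with `total_cost`,
#'   `total_qaly`).
#' @param wtp willingness to pay, baht per QALY (>= 0).
#' @return baht.
#' @export
net_monetary_benefit <- function(result, wtp) {
  stopifnot(wtp >= 0)
  wtp * result$total_qaly - result$total_cost
}

#' Base-case analysis of all strategies
#'
#' Runs the cohort model once per strategy on the same parameter set and
#' returns the economic results, outcome summaries and the incremental table
#' against the comparator.
#'
#' @param ps a `ht_parameter_set`.
#' @param comparator comparator strategy name (default `"CBPM"`, current
#'   practice).
#' @param strategies strategy names to evaluate.
#' @return list with `economics` (list of `econ_result`), `outcomes` (list of
#'   outcome summaries), `icer` (data.frame), `traces` (list of
#'   `cohort_trace`).
#' @export
base_case_analysis <- function(ps, comparator = "CBPM",
                               strategies = STRATEGY_NAMES) {
  traces <- lapply(strategies, function(s) run_cohort(ps, s))
  names(traces) <- strategies
  econ <- lapply(strategies, function(s) accrue(traces[[s]], ps, s))
  names(econ) <- strategies
  outc <- lapply(traces, summarize_outcomes)
  list(economics = econ, outcomes = outc,
       icer = icer_table(econ, comparator), traces = traces)
}

#' Publication-style results table
#'
#' Rearranges a [base_case_analysis()] result into the reporting layout used
#' in cost-utility studies: cost rows (with category percentages of total),
#' outcome rows, and increments plus ICERs against the comparator. Costs and
#' ICERs are rounded to whole baht, LYs/QALYs to 4 decimals; computation is
#' done at full precision upstream.
#'
#' @param bc result of [base_case_analysis()].
#' @param comparator comparator strategy name (must match the one used).
#' @return data.frame, one row per reported quantity, one column per strategy
#'   and per comparison.
#' @export
results_table <- function(bc, comparator = "CBPM") {
  econ <- bc$economics
  outc <- bc$outcomes
  strategies <- names(econ)
  others <- setdiff(strategies, comparator)

  cost_row <- function(field, digits = 0) {
    vapply(strategies, function(s) {
      x <- econ[[s]][[field]]
      sprintf("%s (%.2f)", format(round(x, digits), big.mark = ","),
              100 * x / econ[[s]]$total_cost)
    }, character(1))
  }
  num_row <- function(get, digits) {
    vapply(strategies, function(s) sprintf(paste0("%.", digits, "f"), get(s)),
           character(1))
  }
  inc_row <- function(get, digits) {
    out <- vapply(others, function(s) {
      sprintf(paste0("%.", digits, "f"), get(s) - get(comparator))
    }, character(1))
    names(out) <- paste(others, "vs", comparator)
    out
  }
  pad <- function(x, extra) c(x, stats::setNames(rep("", length(extra)),
                                                 extra))
  inc_names <- paste(others, "vs", comparator)

  rows <- list(
    "Screening cost (%)" = pad(cost_row("screening_cost"), inc_names),
    "Direct medical cost (%)" = pad(cost_row("direct_medical_cost"),
                                    inc_names),
    "Direct non-medical cost (%)" = pad(cost_row("direct_nonmedical_cost"),
                                        inc_names),
    "Total costs" = c(
      num_row(function(s) round(econ[[s]]$total_cost), 0),
      inc_row(function(s) round(econ[[s]]$total_cost), 0)),
    "HT prevalence (%)" = c(
      num_row(function(s) 100 * outc[[s]]$ht_prevalence, 2),
      inc_row(function(s) 100 * outc[[s]]$ht_prevalence, 2)),
    "Incidence of CVD (%)" = c(
      num_row(function(s) 100 * outc[[s]]$cvd_incidence, 2),
      inc_row(function(s) 100 * outc[[s]]$cvd_incidence, 2)),
    "CVD mortality (%)" = c(
      num_row(function(s) 100 * outc[[s]]$cvd_mortality, 2),
      inc_row(function(s) 100 * outc[[s]]$cvd_mortality, 2)),
    "WCHT incidence" = c(
      num_row(function(s) outc[[s]]$wcht_incidence, 3),
      inc_row(function(s) outc[[s]]$wcht_incidence, 3)),
    "Probability to be undiagnosed HT" = c(
      num_row(function(s) outc[[s]]$p_undiagnosed, 3),
      inc_row(function(s) outc[[s]]$p_undiagnosed, 3)),
    "Total LYs" = c(
      num_row(function(s) econ[[s]]$total_ly, 4),
      inc_row(function(s) econ[[s]]$total_ly, 4)),
    "Total QALYs" = c(
      num_row(function(s) econ[[s]]$total_qaly, 4),
      inc_row(function(s) econ[[s]]$total_qaly, 4))
  )
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- c(strategies, inc_names)

  icer <- bc$icer
  quadrant_code <- c(dominated = "c", trade_off_SW = "d", trade_off_NE = "",
                     dominant = "", equivalent = "")
  icer_row <- stats::setNames(rep("", ncol(tab)), names(tab))
  for (i in seq_len(nrow(icer))) {
    lbl <- icer$comparison[i]
    val <- icer$icer_qaly[i]
    icer_row[lbl] <- if (is.na(val)) "undefined" else
      paste0(format(round(val), big.mark = ","),
             quadrant_code[[icer$dominance_class[i]]])
  }
  tab <- rbind(tab, "ICER (baht/QALY)" = icer_row)
  tab
}
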