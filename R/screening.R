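# Screening strategies: the four blood-pressure screening protocols, their
# combined diagnostic performance, per-person screening cost and the
# classification split of a screened pool.
#
# Serial protocols assume the clinic (CBPM) and home (HBPM) test errors are
# conditionally independent given true hypertension status; under that
# assumption the serial performance follows from the component sensitivities
# and specificities alone.

STRATEGY_NAMES <- c("CBPM", "HBPM", "Serial1", "Serial2")

#' Diagnostic performance (sensitivity/specificity pair)
#' @param sensitivity probability a truly hypertensive person screens positive.
#' @param specificity probability a truly normotensive person screens negative.
#' @return object of class `diag_performance`.
#' @export
diag_performance <- function(sensitivity, specificity) {
  stopifnot(is.finite(sensitivity), sensitivity >= 0, sensitivity <= 1,
            is.finite(specificity), specificity >= 0, specificity <= 1)
  structure(list(sensitivity = sensitivity, specificity = specificity),
            class = "diag_performance")
}

#' Serial screening, confirmation among first-stage positives
#'
#' CBPM first; only persons with high clinic BP go on to HBPM, and a subject
#' is screen-positive only if positive on both. Sensitivity multiplies;
#' specificity is the chance of a negative at either stage:
#' `Se = Se_C * Se_H`, `Sp = Sp_C + (1 - Sp_C) * Sp_H`.
#'
#' @param cbpm,hbpm `diag_performance` of the component tests.
#' @return `diag_performance` of the serial protocol.
#' @export
compose_serial1 <- function(cbpm, hbpm) {
  diag_performance(
    sensitivity = cbpm$sensitivity * hbpm$sensitivity,
    specificity = cbpm$specificity + (1 - cbpm$specificity) * hbpm$specificity
  )
}

#' Serial screening, confirmation among first-stage negatives
#'
#' CBPM first; persons with normal clinic BP go on to HBPM, and a subject is
#' screen-positive if positive at either stage:
#' `Se = Se_C + (1 - Se_C) * Se_H`, `Sp = Sp_C * Sp_H`.
#'
#' @inheritParams compose_serial1
#' @return `diag_performance` of the serial protocol.
#' @export
compose_serial2 <- function(cbpm, hbpm) {
  diag_performance(
    sensitivity = cbpm$sensitivity + (1 - cbpm$sensitivity) * hbpm$sensitivity,
    specificity = cbpm$specificity * hbpm$specificity
  )
}

#' Build a screening strategy from a parameter set
#' @param name one of `"CBPM"`, `"HBPM"`, `"Serial1"`, `"Serial2"`.
#' @param ps a `ht_parameter_set` supplying the component test performance.
#' @return object of class `ht_strategy` with fields `name` and `performance`.
#' @export
strategy <- function(name, ps) {
  name <- match.arg(name, STRATEGY_NAMES)
  cbpm <- diag_performance(ps$se_cbpm, ps$sp_cbpm)
  hbpm <- diag_performance(ps$se_hbpm, ps$sp_hbpm)
  perf <- switch(name,
    CBPM = cbpm,
    HBPM = hbpm,
    Serial1 = compose_serial1(cbpm, hbpm),
    Serial2 = compose_serial2(cbpm, hbpm)
  )
  structure(list(name = name, performance = perf), class = "ht_strategy")
}

#' Classification split of a screened pool
#'
#' Given the fraction `pi` of the screened pool with true hypertension and the
#' strategy's combined performance, returns the four destinations: true
#' positives become new diagnoses, false negatives stay undiagnosed (masked
#' hypertension), false positives become white-coat hypertension, true
#' negatives remain without hypertension.
#'
#' @param true_ht_fraction fraction of the screened pool with true HT.
#' @param perf `diag_performance` of the screening strategy.
#' @return named list `to_new_diagnosis`, `to_undiagnosed`, `to_wcht`,
#'   `to_no_ht`; nonnegative, summing to 1.
#' @export
classify_screened <- function(true_ht_fraction, perf) {
  stopifnot(true_ht_fraction >= 0, true_ht_fraction <= 1)
  pi <- true_ht_fraction
  se <- perf$sensitivity
  sp <- perf$specificity
  list(
    to_new_diagnosis = pi * se,
    to_undiagnosed   = pi * (1 - se),
    to_wcht          = (1 - pi) * (1 - sp),
    to_no_ht         = (1 - pi) * sp
  )
}

#' Expected screening cost per screened person
#'
#' Single-stage strategies cost their unit price. Serial strategies always pay
#' the clinic test, plus the home test for the routed subgroup: first-stage
#' positives under Serial1 (`pi * Se_C + (1 - pi) * (1 - Sp_C)` of the pool),
#' first-stage negatives under Serial2 (`pi * (1 - Se_C) + (1 - pi) * Sp_C`).
#' The routing rate is evaluated at the screened pool's current true-HT
#' fraction, so serial screening cost varies cycle to cycle.
#'
#' @param strat a `ht_strategy`.
#' @param true_ht_fraction fraction of the screened pool with true HT.
#' @param ps a `ht_parameter_set` supplying unit costs and first-stage
#'   performance.
#' @return baht per screened person.
#' @export
expected_screening_cost <- function(strat, true_ht_fraction, ps) {
  stopifnot(true_ht_fraction >= 0, true_ht_fraction <= 1)
  pi <- true_ht_fraction
  c_c <- ps$cost_screen_cbpm
  c_h <- ps$cost_screen_hbpm
  switch(strat$name,
    CBPM = c_c,
    HBPM = c_h,
    Serial1 = c_c + c_h * (pi * ps$se_cbpm + (1 - pi) * (1 - ps$sp_cbpm)),
    Serial2 = c_c + c_h * (pi * (1 - ps$se_cbpm) + (1 - pi) * ps$sp_cbpm),
    stop("unknown strategy: ", strat$name)
  )
}
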