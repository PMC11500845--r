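# Annual-cycle Markov cohort engine.
#
# Nine health states; two of them (new HT diagnosis, white-coat HT temporary)
# are within-cycle tunnels resolved before the cycle's occupancy is recorded,
# so the recorded state vector has seven entries:
#   no_ht, undiagnosed_ht, wcht_transient, ht_controlled, ht_uncontrolled,
#   cvd, dead
# The cohort enters at start_age, 100% in no_ht (never diagnosed, no CVD
# history). Each cycle applies, in order: (1) HT incidence within the no-HT
# pool; (2) screening of the no-HT and undiagnosed-HT pools with tunnel
# resolution (new diagnosis -> ht_uncontrolled, false positive ->
# wcht_transient); (3) control-status switching, plus white-coat cases
# developing true HT at the general incidence rate (they move to
# ht_controlled: already treated, now truly hypertensive); (4) first CVD
# events from undiagnosed (at uncontrolled risk), uncontrolled and controlled
# HT; (5) mortality, CVD case fatality first, then background mortality,
# treated as sequential conditional risks. No half-cycle correction is
# applied.

STATE_NAMES <- c("no_ht", "undiagnosed_ht", "wcht_transient", "ht_controlled",
                 "ht_uncontrolled", "cvd", "dead")
FLOW_NAMES <- c("screened", "pi_screen", "screen_cost", "new_diagnosis",
                "new_wcht", "new_cvd", "cvd_deaths", "other_deaths",
                "cvd_prevalent")

#' Annual probability of death from CVD at a given age
#'
#' Case fatality among prevalent CVD cases is age-stratified with a cutoff at
#' 45 years; the boundary age belongs to the older stratum.
#'
#' @param age age in years.
#' @param ps a `ht_parameter_set` (fields `p_cvd_death_young`,
#'   `p_cvd_death_old`).
#' @return annual probability of CVD death.
#' @export
cvd_death_probability <- function(age, ps) {
  ifelse(age < 45, ps$p_cvd_death_young, ps$p_cvd_death_old)
}

#' Advance the cohort one annual cycle
#'
#' @param state named numeric vector over the seven recorded states
#'   (see `htcue:::STATE_NAMES`); nonnegative, summing to 1.
#' @param age age of the cohort at the start of the cycle, in years.
#' @param ps a `ht_parameter_set`.
#' @param strat a `ht_strategy`.
#' @return list with `state` (end-of-cycle vector) and `flows` (named vector:
#'   persons screened, true-HT fraction of the screened pool, screening cost
#'   paid, new diagnoses, new white-coat cases, new CVD events, CVD deaths,
#'   other deaths, prevalent CVD survivors).
#' @export
step_cycle <- function(state, age, ps, strat) {
  if (abs(sum(state) - 1) > 1e-9 || any(state < -1e-12)) {
    stop("invalid state vector at age ", age,
         ": entries must be nonnegative and sum to 1")
  }
  inc <- band_value(ps$ht_incidence, age)
  p_cvd_u <- band_value(ps$p_cvd_given_uncontrolled, age)
  p_cvd_c <- band_value(ps$p_cvd_given_controlled, age)
  p_bg <- band_value(ps$p_death_other, age)
  p_cf <- cvd_death_probability(age, ps)

  s <- unname(state[STATE_NAMES])

  # (1) HT incidence: part of the no-HT pool becomes latently hypertensive
  #     (still unscreened this instant).
  latent <- s[1L] * inc

  # (2) annual screening of the no-HT pool (incident cases included) and the
  #     previously missed (masked HT) pool; persons already diagnosed (WCHT,
  #     controlled/uncontrolled HT, CVD) are not re-screened.
  pool <- s[1L] + s[2L]
  pi <- if (pool > 0) (latent + s[2L]) / pool else 0
  split <- classify_screened(pi, strat$performance)
  new_diag <- pool * split$to_new_diagnosis
  undx <- pool * split$to_undiagnosed
  new_wcht <- pool * split$to_wcht
  no_ht <- pool * split$to_no_ht
  screen_cost <- pool * expected_screening_cost(strat, pi, ps)

  # tunnels resolve within-cycle: new diagnoses start uncontrolled, new
  # white-coat cases move to the transient white-coat state
  unctrl <- s[5L] + new_diag
  wcht <- s[3L] + new_wcht
  ctrl <- s[4L]

  # (3) control-status switching; white-coat cases develop true HT at the
  #     general incidence rate and continue under treatment as controlled
  ctrl2 <- ctrl * (1 - ps$p_controlled_to_uncontrolled) +
    unctrl * ps$p_uncontrolled_to_controlled + wcht * inc
  unctrl2 <- unctrl * (1 - ps$p_uncontrolled_to_controlled) +
    ctrl * ps$p_controlled_to_uncontrolled
  wcht2 <- wcht * (1 - inc)

  # (4) first CVD events; masked (undiagnosed) HT carries uncontrolled risk
  new_cvd <- undx * p_cvd_u + unctrl2 * p_cvd_u + ctrl2 * p_cvd_c
  undx <- undx * (1 - p_cvd_u)
  unctrl2 <- unctrl2 * (1 - p_cvd_u)
  ctrl2 <- ctrl2 * (1 - p_cvd_c)
  cvd_tot <- s[6L] + new_cvd

  # (5) mortality: CVD case fatality first, then background mortality for all
  #     alive states (sequential conditional risks)
  cvd_deaths <- cvd_tot * p_cf
  cvd_alive <- cvd_tot - cvd_deaths
  cvd_prevalent <- s[6L] * (1 - p_cf) * (1 - p_bg)
  alive_other <- c(no_ht, undx, wcht2, ctrl2, unctrl2)
  other_deaths <- sum(alive_other) * p_bg + cvd_alive * p_bg

  out <- c(alive_other * (1 - p_bg), cvd_alive * (1 - p_bg),
           s[7L] + cvd_deaths + other_deaths)
  if (any(out < -1e-12)) {
    bad <- STATE_NAMES[which(out < -1e-12)]
    stop("probability overflow at age ", age, " in state(s): ",
         paste(bad, collapse = ", "))
  }
  names(out) <- STATE_NAMES
  flows <- c(screened = pool, pi_screen = pi, screen_cost = screen_cost,
             new_diagnosis = new_diag, new_wcht = new_wcht, new_cvd = new_cvd,
             cvd_deaths = cvd_deaths, other_deaths = other_deaths,
             cvd_prevalent = cvd_prevalent)
  list(state = out, flows = flows)
}

#' Run the cohort model over the lifetime horizon
#'
#' Iterates [step_cycle()] from `start_age` up to (not including) `end_age`,
#' starting from 100% occupancy of the no-HT state. Deterministic given the
#' parameter set.
#'
#' @param ps a `ht_parameter_set`.
#' @param strat a `ht_strategy` (or strategy name, resolved against `ps`).
#' @return a `cohort_trace`: data.frame with one row per cycle, columns
#'   `cycle` (0-based), `age` (age at cycle start), the seven end-of-cycle
#'   state occupancies and the nine per-cycle flows. The initial state vector
#'   is stored in attribute `initial_state`, the strategy name in `strategy`.
#' @export
run_cohort <- function(ps, strat) {
  if (is.character(strat)) strat <- strategy(strat, ps)
  assert_valid(ps)
  ages <- seq.int(ps$start_age, ps$end_age - 1L)
  n <- length(ages)
  states <- matrix(NA_real_, n, length(STATE_NAMES),
                   dimnames = list(NULL, STATE_NAMES))
  flows <- matrix(NA_real_, n, length(FLOW_NAMES),
                  dimnames = list(NULL, FLOW_NAMES))
  s <- c(1, 0, 0, 0, 0, 0, 0)
  names(s) <- STATE_NAMES
  init <- s
  for (i in seq_len(n)) {
    step <- step_cycle(s, ages[i], ps, strat)
    s <- step$state
    states[i, ] <- s
    flows[i, ] <- step$flows
  }
  tr <- data.frame(cycle = seq_len(n) - 1L, age = ages, states, flows)
  attr(tr, "initial_state") <- init
  attr(tr, "strategy") <- strat$name
  class(tr) <- c("cohort_trace", "data.frame")
  tr
}

#' Lifetime outcome summary of a cohort trace
#'
#' Tallies the epidemiological outcomes reported alongside costs: lifetime
#' cumulative CVD incidence and CVD mortality (fractions of the cohort),
#' cumulative white-coat diagnoses per person, hypertension prevalence
#' (both the time-averaged share of true hypertension among the alive and the
#' terminal-cycle share; the time-averaged figure is the headline one), and
#' the time-averaged probability of carrying undiagnosed hypertension.
#'
#' @param trace a `cohort_trace`.
#' @return named list: `cvd_incidence`, `cvd_mortality`, `wcht_incidence`,
#'   `ht_prevalence` (time-averaged), `ht_prevalence_terminal`,
#'   `p_undiagnosed`.
#' @export
summarize_outcomes <- function(trace) {
  alive <- 1 - trace$dead
  ht <- trace$undiagnosed_ht + trace$ht_controlled + trace$ht_uncontrolled
  prev <- ifelse(alive > 0, ht / alive, NA_real_)
  undx <- ifelse(alive > 0, trace$undiagnosed_ht / alive, NA_real_)
  list(
    cvd_incidence = sum(trace$new_cvd),
    cvd_mortality = sum(trace$cvd_deaths),
    wcht_incidence = sum(trace$new_wcht),
    ht_prevalence = mean(prev, na.rm = TRUE),
    ht_prevalence_terminal = prev[nrow(trace)],
    p_undiagnosed = mean(undx, na.rm = TRUE)
  )
}

#' Hypertension prevalence by age band
#'
#' Per band, the share of true hypertension (undiagnosed + controlled +
#' uncontrolled) among the alive cohort, averaged over the band's cycles.
#' A band with no alive mass yields `NA` with a warning, never a silent zero.
#'
#' @param trace a `cohort_trace`.
#' @param bands data.frame with columns `lower`, `upper` (ages, inclusive).
#' @return data.frame `lower`, `upper`, `prevalence`.
#' @export
prevalence_by_age_band <- function(trace, bands) {
  alive <- 1 - trace$dead
  ht <- trace$undiagnosed_ht + trace$ht_controlled + trace$ht_uncontrolled
  prev <- vapply(seq_len(nrow(bands)), function(i) {
    sel <- trace$age >= bands$lower[i] & trace$age <= bands$upper[i]
    if (!any(sel) || all(alive[sel] <= 0)) {
      warning(sprintf("band %d-%d has no alive cohort mass; prevalence NA",
                      bands$lower[i], bands$upper[i]))
      return(NA_real_)
    }
    ok <- sel & alive > 0
    mean(ht[ok] / alive[ok])
  }, numeric(1))
  data.frame(lower = bands$lower, upper = bands$upper, prevalence = prev)
}
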