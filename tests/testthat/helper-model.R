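# Shared fixtures and independent oracles.

# Default synthetic parameter set, optionally with a short horizon for speed.
make_ps <- function(end_age = 100, ...) {
  ps <- default_parameter_set(synthetic_spec(...))
  ps$end_age <- end_age
  ps
}

# Brute-force oracle for serial test composition: enumerates the four joint
# (CBPM, HBPM) outcomes for a diseased and a healthy subject under
# conditional independence and applies the routing rule literally.
serial_oracle <- function(se_c, sp_c, se_h, sp_h,
                          confirm_among = c("positives", "negatives")) {
  confirm_among <- match.arg(confirm_among)
  out <- c(se = NA_real_, sp = NA_real_)
  for (status in c("diseased", "healthy")) {
    p_pos_c <- if (status == "diseased") se_c else 1 - sp_c
    p_pos_h <- if (status == "diseased") se_h else 1 - sp_h
    p_positive <- 0
    for (c_pos in c(TRUE, FALSE)) {
      for (h_pos in c(TRUE, FALSE)) {
        p <- (if (c_pos) p_pos_c else 1 - p_pos_c) *
          (if (h_pos) p_pos_h else 1 - p_pos_h)
        final_pos <- if (confirm_among == "positives") {
          c_pos && h_pos                   # confirmed among screen-positives
        } else {
          c_pos || h_pos                   # negatives retested; either fires
        }
        if (final_pos) p_positive <- p_positive + p
      }
    }
    if (status == "diseased") out["se"] <- p_positive
    else out["sp"] <- 1 - p_positive
  }
  out
}

# A hand-specifiable parameter set that collapses the model to three states
# (no_ht, ht_uncontrolled, dead): perfect tests, no control switching, no
# CVD, constant incidence and mortality across ages.
collapsed_ps <- function(inc, p_death, end_age = 45) {
  ps <- make_ps(end_age = end_age)
  ps$se_cbpm <- 1; ps$sp_cbpm <- 1; ps$se_hbpm <- 1; ps$sp_hbpm <- 1
  ps$p_controlled_to_uncontrolled <- 0
  ps$p_uncontrolled_to_controlled <- 0
  ps$ht_incidence$value[] <- inc
  ps$p_cvd_given_uncontrolled$value[] <- 0
  ps$p_cvd_given_controlled$value[] <- 0
  ps$p_death_other$value[] <- p_death
  ps
}

# Economic results whose four strategies carry prescribed totals; used to
# exercise comparison arithmetic on externally given operands.
econ_stub <- function(strategy, total_cost, total_qaly, total_ly) {
  structure(list(strategy = strategy,
                 screening_cost = 0, direct_medical_cost = total_cost,
                 direct_nonmedical_cost = 0,
                 total_cost = total_cost, total_ly = total_ly,
                 total_qaly = total_qaly),
            class = "econ_result")
}

# Published lifetime totals of the four screening strategies (comparator
# CBPM first); used as printed operands for derived-arithmetic checks.
published_totals <- function() {
  list(
    CBPM    = econ_stub("CBPM",    110588, 22.1557, 39.9470),
    HBPM    = econ_stub("HBPM",    110588 + 179,   22.1557 - 0.0046,
                        39.9470 - 0.0063),
    Serial1 = econ_stub("Serial1", 110588 - 32278, 22.1557 - 0.0271,
                        39.9470 - 0.0298),
    Serial2 = econ_stub("Serial2", 110588 + 7695,  22.1557 + 0.0007,
                        39.9470 - 0.0027)
  )
}

# Minimal hand-built trace with full column layout, for accrual unit tests.
hand_trace <- function(states, flows = NULL, start_age = 35) {
  n <- nrow(states)
  if (is.null(flows)) {
    flows <- matrix(0, n, length(htcue:::FLOW_NAMES),
                    dimnames = list(NULL, htcue:::FLOW_NAMES))
  }
  tr <- data.frame(cycle = seq_len(n) - 1L,
                   age = start_age + seq_len(n) - 1L, states, flows)
  class(tr) <- c("cohort_trace", "data.frame")
  tr
}

zero_states <- function(n) {
  matrix(0, n, length(htcue:::STATE_NAMES),
         dimnames = list(NULL, htcue:::STATE_NAMES))
}
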