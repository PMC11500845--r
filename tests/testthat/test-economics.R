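test_that("discount factors match the closed form", {
  expect_equal(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0, 0:50), rep(1, 51))
  expect_equal(discount_factor(0.03, 1), 0.970874, tolerance = 1e-6)
  expect_equal(discount_factor(0.03, 0:10), 1 / 1.03^(0:10))
  expect_error(discount_factor(0.03, -1), "cycle_index")
  expect_error(discount_factor(-0.01, 1))
})

test_that("the weighted CVD utility reproduces the published value", {
  ps <- make_ps()
  expect_equal(cvd_utility(ps), 0.55 * 0.64 + 0.75 * 0.36)
  expect_equal(round(cvd_utility(ps), 2), 0.62)
})

test_that("single-cell accrual equals the hand computation", {
  ps <- make_ps()
  ps$discount_rate <- 0
  states <- zero_states(1)
  states[1, "ht_controlled"] <- 1
  tr <- hand_trace(states)
  e <- accrue(tr, ps, "CBPM")
  expect_equal(e$direct_medical_cost, ps$cost_ht_controlled)
  expect_equal(e$direct_nonmedical_cost, 4 * ps$nonmed_visit_cost)
  expect_equal(e$screening_cost, 0)
  expect_equal(e$total_cost,
               ps$cost_ht_controlled + 4 * ps$nonmed_visit_cost)
  expect_equal(e$total_qaly, 0.95)
  expect_equal(e$total_ly, 1)
})

test_that("acute CVD accrues on the event flow, chronic on prevalent occupancy", {
  ps <- make_ps()
  ps$discount_rate <- 0
  states <- zero_states(1)
  states[1, "cvd"] <- 0.5
  states[1, "no_ht"] <- 0.5
  flows <- matrix(0, 1, length(htcue:::FLOW_NAMES),
                  dimnames = list(NULL, htcue:::FLOW_NAMES))
  flows[1, "new_cvd"] <- 0.2
  flows[1, "cvd_prevalent"] <- 0.3
  tr <- hand_trace(states, flows)
  e <- accrue(tr, ps, "CBPM")
  expect_equal(e$direct_medical_cost,
               0.2 * ps$cost_cvd_acute + 0.3 * ps$cost_cvd_chronic)
  expect_equal(e$direct_nonmedical_cost,
               0.3 * 8 * ps$nonmed_visit_cost +
                 0.2 * 9.83 * ps$nonmed_inpatient_cost_per_day)
  expect_equal(e$total_qaly, 0.5 * 1 + 0.5 * cvd_utility(ps))
})

test_that("a trace that is all dead after cycle 0 accrues nothing further", {
  ps <- make_ps()
  states <- zero_states(3)
  states[1, "ht_uncontrolled"] <- 1
  states[2:3, "dead"] <- 1
  tr <- hand_trace(states)
  e <- accrue(tr, ps, "CBPM")
  e1 <- accrue(hand_trace(states[1, , drop = FALSE]), ps, "CBPM")
  expect_equal(e$total_cost, e1$total_cost)
  expect_equal(e$total_qaly, e1$total_qaly)
  expect_equal(e$total_ly, e1$total_ly)
})

test_that("accrual invariants: category sum, discount ordering, QALY <= LY", {
  ps <- make_ps()
  tr <- run_cohort(ps, "Serial2")
  e <- accrue(tr, ps, "Serial2")
  expect_equal(e$total_cost,
               e$screening_cost + e$direct_medical_cost +
                 e$direct_nonmedical_cost)
  expect_lte(e$total_qaly, e$total_ly)
  ps0 <- ps; ps0$discount_rate <- 0
  e0 <- accrue(tr, ps0, "Serial2")
  expect_lt(e$total_cost, e0$total_cost)
  expect_lt(e$total_qaly, e0$total_qaly)
})

test_that("ICER table reproduces published derived values from printed operands", {
  res <- published_totals()
  tab <- icer_table(res, "CBPM")
  rownames(tab) <- tab$comparison

  hb <- tab["HBPM vs CBPM", ]
  expect_equal(hb$delta_cost, 179)
  expect_equal(hb$delta_qaly, -0.0046)
  expect_equal(round(hb$icer_qaly), -38913)
  expect_equal(hb$dominance_class, "dominated")

  s1 <- tab["Serial1 vs CBPM", ]
  expect_equal(s1$delta_cost, -32278)
  expect_equal(s1$delta_qaly, -0.0271)
  expect_equal(round(s1$icer_qaly), 1191070)
  expect_equal(s1$dominance_class, "trade_off_SW")

  s2 <- tab["Serial2 vs CBPM", ]
  expect_equal(s2$delta_cost, 7695)
  expect_equal(s2$delta_qaly, 0.0007)
  expect_equal(round(s2$icer_qaly), 10992857)
  expect_equal(s2$dominance_class, "trade_off_NE")
})

test_that("ICER table is anti-symmetric and guards a zero QALY increment", {
  res <- published_totals()
  t1 <- icer_table(res, "CBPM")
  t2 <- icer_table(res, "Serial1")
  r12 <- t1[t1$comparison == "Serial1 vs CBPM", ]
  r21 <- t2[t2$comparison == "CBPM vs Serial1", ]
  expect_equal(r21$delta_cost, -r12$delta_cost)
  expect_equal(r21$delta_qaly, -r12$delta_qaly)
  expect_equal(r21$icer_qaly, r12$icer_qaly)

  res$HBPM$total_qaly <- res$CBPM$total_qaly
  t3 <- icer_table(res, "CBPM")
  expect_true(is.na(t3[t3$comparison == "HBPM vs CBPM", "icer_qaly"]))
  expect_error(icer_table(res, "ABPM"), "comparator")
})

test_that("net monetary benefit arithmetic and the WTP-160k decision", {
  res <- published_totals()
  expect_equal(net_monetary_benefit(res$CBPM, 0), -res$CBPM$total_cost)
  expect_equal(net_monetary_benefit(res$CBPM, 160000),
               160000 * 22.1557 - 110588)
  d <- net_monetary_benefit(res$Serial1, 160000) -
    net_monetary_benefit(res$CBPM, 160000)
  expect_equal(d, 32278 - 160000 * 0.0271)
  expect_gt(d, 0)  # the cost saving outweighs the QALY loss
})

test_that("with perfect tests the strategies differ only in screening cost", {
  ps <- make_ps(end_age = 70)
  ps$se_cbpm <- 1; ps$sp_cbpm <- 1; ps$se_hbpm <- 1; ps$sp_hbpm <- 1
  bc <- base_case_analysis(ps)
  e <- bc$economics
  for (s in c("HBPM", "Serial1", "Serial2")) {
    expect_equal(e[[s]]$total_qaly, e$CBPM$total_qaly, tolerance = 1e-12)
    expect_equal(e[[s]]$total_ly, e$CBPM$total_ly, tolerance = 1e-12)
    expect_equal(e[[s]]$direct_medical_cost, e$CBPM$direct_medical_cost,
                 tolerance = 1e-12)
    expect_equal(e[[s]]$direct_nonmedical_cost,
                 e$CBPM$direct_nonmedical_cost, tolerance = 1e-12)
  }
  expect_false(e$HBPM$screening_cost == e$CBPM$screening_cost)
})

test_that("the results table carries the reporting layout", {
  ps <- make_ps(end_age = 55)
  bc <- base_case_analysis(ps)
  tab <- results_table(bc)
  expect_equal(ncol(tab), 7)  # 4 strategies + 3 comparisons
  expect_true("Total QALYs" %in% rownames(tab))
  expect_true("ICER (baht/QALY)" %in% rownames(tab))
  expect_match(tab["Screening cost (%)", "CBPM"], "\\(")
})
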