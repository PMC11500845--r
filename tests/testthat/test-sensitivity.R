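test_that("PSA draws are deterministic, leave the RNG alone, and honor families", {
  ps <- make_ps()
  d1 <- draw_psa_parameters(ps, 99, 5)
  set.seed(1); before <- stats::runif(1)
  d2 <- draw_psa_parameters(ps, 99, 5)
  set.seed(1); after <- stats::runif(1)
  expect_identical(before, after)  # caller RNG untouched
  for (nm in flat_parameter_names(ps)) {
    expect_identical(get_param(d1, nm), get_param(d2, nm), info = nm)
  }
  d3 <- draw_psa_parameters(ps, 99, 6)
  expect_false(get_param(d3, "cost_cvd_acute") ==
                 get_param(d1, "cost_cvd_acute"))

  # fixed parameters keep their base value
  m <- ps$meta
  fixed <- is.na(m$age_lower) & m$dist_family == "fixed"
  for (nm in m$parameter[fixed]) {
    expect_identical(get_param(d1, nm), get_param(ps, nm), info = nm)
  }
  expect_length(validate_parameter_set(d1), 0)
})

test_that("all-fixed metadata reproduces the base set; tiny SE degenerates to the mean", {
  ps <- make_ps()
  ps$meta$dist_family <- "fixed"
  d <- draw_psa_parameters(ps, 1, 1)
  for (nm in flat_parameter_names(ps)) {
    expect_identical(get_param(d, nm), get_param(ps, nm), info = nm)
  }

  ps2 <- make_ps()
  i <- which(ps2$meta$parameter == "u_stroke")
  ps2$meta$dist_se[i] <- 1e-6
  draws <- vapply(1:20, function(r)
    get_param(draw_psa_parameters(ps2, 3, r), "u_stroke"), numeric(1))
  expect_true(all(abs(draws - 0.55) < 1e-3))
})

test_that("gamma cost draws match their configured moments (law of large numbers)", {
  ps <- make_ps()
  i <- which(ps$meta$parameter == "cost_cvd_acute")
  mu <- ps$meta$value[i]; se <- ps$meta$dist_se[i]
  draws <- vapply(1:4000, function(r)
    get_param(draw_psa_parameters(ps, 17, r), "cost_cvd_acute"), numeric(1))
  expect_lt(abs(mean(draws) - mu), 3 * se / sqrt(length(draws)))
  expect_lt(abs(stats::sd(draws) - se), 0.1 * se)
})

test_that("infeasible beta moments are rejected naming the parameter", {
  ps <- make_ps()
  i <- which(ps$meta$parameter == "u_stroke")
  ps$meta$dist_se[i] <- 0.6   # variance above mean*(1-mean)
  expect_error(draw_psa_parameters(ps, 1, 1), "u_stroke")
})

test_that("PSA is reproducible and collapses to the base case when degenerate", {
  ps <- make_ps(end_age = 60)
  p1 <- run_psa(ps, replications = 3, rng_seed = 11)
  p2 <- run_psa(ps, replications = 3, rng_seed = 11)
  expect_identical(p1, p2)
  p3 <- run_psa(ps, replications = 3, rng_seed = 12)
  expect_false(identical(p1$total_cost, p3$total_cost))

  ps0 <- ps; ps0$meta$dist_family <- "fixed"
  pd <- run_psa(ps0, replications = 1, rng_seed = 5)
  bc <- base_case_analysis(ps0)
  for (s in unique(pd$strategy)) {
    expect_equal(pd$total_cost[pd$strategy == s],
                 bc$economics[[s]]$total_cost)
    expect_equal(pd$total_qaly[pd$strategy == s],
                 bc$economics[[s]]$total_qaly)
  }
})

test_that("CEAC probabilities: conservation, degenerate winner, hand enumeration", {
  ps <- make_ps(end_age = 60)
  psa <- run_psa(ps, replications = 40, rng_seed = 2)
  cc <- ceac(psa, wtp_grid = seq(0, 400000, by = 50000))
  expect_true(all(abs(rowSums(cc[, -1]) - 1) < 1e-12))
  expect_true(all(as.matrix(cc[, -1]) >= 0 & as.matrix(cc[, -1]) <= 1))

  # degenerate PSA: the max-NMB strategy takes probability 1
  ps0 <- ps; ps0$meta$dist_family <- "fixed"
  pd <- run_psa(ps0, replications = 1, rng_seed = 5)
  cd <- ceac(pd, wtp_grid = 160000)
  bc <- base_case_analysis(ps0)
  nmb <- vapply(bc$economics, net_monetary_benefit, numeric(1), wtp = 160000)
  expect_equal(unlist(cd[1, names(which.max(nmb))]), 1,
               ignore_attr = TRUE)
  expect_equal(sum(cd[1, -1]), 1)

  # hand-enumerable toy PSA with three replications
  toy <- data.frame(
    replication = rep(1:3, each = 2),
    strategy = rep(c("A", "B"), 3),
    total_cost = c(100, 90, 100, 110, 100, 100),
    total_qaly = c(1.0, 1.0, 1.0, 1.1, 1.0, 1.0),
    total_ly = 1
  )
  cc2 <- ceac(toy, wtp_grid = c(0, 200))
  # at WTP 0: B wins rep1 (cheaper), A wins rep2, tie rep3 -> A 1.5/3
  expect_equal(cc2$A, c(1.5 / 3, 0.5 / 3))
  # at WTP 200: rep1 B (same QALY, cheaper), rep2 B (dNMB=+10), rep3 tie
  expect_equal(cc2$B, c(1.5 / 3, 2.5 / 3))

  # at WTP 0 the cheapest strategy per replication wins
  cc0 <- ceac(psa, wtp_grid = 0)
  cheapest <- tapply(seq_len(nrow(psa)), psa$replication, function(ix)
    psa$strategy[ix][which.min(psa$total_cost[ix])])
  expect_equal(as.numeric(cc0[1, -1][unique(psa$strategy)]),
               as.numeric(table(factor(cheapest,
                                       unique(psa$strategy))) / 40))
})

test_that("CE-plane points are pairwise differences on common draws", {
  ps <- make_ps(end_age = 60)
  psa <- run_psa(ps, replications = 5, rng_seed = 3)
  pts <- ce_plane_points(psa, "CBPM")
  expect_setequal(unique(pts$strategy), c("HBPM", "Serial1", "Serial2"))
  r2s1 <- pts[pts$replication == 2 & pts$strategy == "Serial1", ]
  base2 <- psa[psa$replication == 2 & psa$strategy == "CBPM", ]
  alt2 <- psa[psa$replication == 2 & psa$strategy == "Serial1", ]
  expect_equal(r2s1$delta_cost, alt2$total_cost - base2$total_cost)
  expect_equal(r2s1$delta_qaly, alt2$total_qaly - base2$total_qaly)

  self <- ce_plane_points(psa[psa$strategy == "CBPM", ], "CBPM")
  expect_equal(nrow(self), 0)

  ps0 <- ps; ps0$meta$dist_family <- "fixed"
  pd <- run_psa(ps0, replications = 1, rng_seed = 5)
  pts0 <- ce_plane_points(pd, "CBPM")
  bc <- base_case_analysis(ps0)
  ic <- bc$icer
  for (i in seq_len(nrow(pts0))) {
    row <- ic[ic$comparison == paste(pts0$strategy[i], "vs CBPM"), ]
    expect_equal(pts0$delta_cost[i], row$delta_cost)
    expect_equal(pts0$delta_qaly[i], row$delta_qaly)
  }
  expect_error(ce_plane_points(pd, "ABPM"), "comparator")
})

test_that("one-way sensitivity: swing arithmetic, inert parameters, ordering", {
  ps <- make_ps(end_age = 60)
  # restrict to a small hand-checkable parameter list
  m <- ps$meta
  keep <- (is.na(m$age_lower) &
             m$parameter %in% c("se_cbpm", "cost_ht_uncontrolled")) |
    (m$parameter == "ht_incidence" & !is.na(m$age_lower) &
       m$age_lower == 40)
  m$owsa_low[!keep] <- NA; m$owsa_high[!keep] <- NA
  # an inert range: low = high = base must give zero swing
  i_se <- which(m$parameter == "se_cbpm")
  m$owsa_low[i_se] <- m$value[i_se]; m$owsa_high[i_se] <- m$value[i_se]
  ps$meta <- m

  tor <- one_way_sensitivity(ps, c("Serial1", "CBPM"))
  expect_equal(nrow(tor), 3)
  expect_true(all(diff(tor$swing) <= 0))  # sorted descending
  expect_equal(tor$swing[tor$parameter == "se_cbpm"], 0)

  # rerun-by-hand oracle for each reported ICER
  icer_at <- function(nm, val) {
    p2 <- set_param(ps, nm, val)
    e1 <- accrue(run_cohort(p2, "Serial1"), p2, "Serial1")
    e0 <- accrue(run_cohort(p2, "CBPM"), p2, "CBPM")
    (e1$total_cost - e0$total_cost) / (e1$total_qaly - e0$total_qaly)
  }
  for (i in seq_len(nrow(tor))) {
    expect_equal(tor$icer_at_low[i], icer_at(tor$parameter[i], tor$low[i]))
    expect_equal(tor$icer_at_high[i], icer_at(tor$parameter[i], tor$high[i]))
    expect_equal(tor$swing[i], abs(tor$icer_at_high[i] - tor$icer_at_low[i]))
  }

  # an out-of-range bound is rejected before any model run
  ps_bad <- ps
  ps_bad$meta$owsa_high[i_se] <- 1.4
  expect_error(one_way_sensitivity(ps_bad, c("Serial1", "CBPM")),
               "se_cbpm")
})
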